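# Differential transcript usage: expression/proportion filtering,
# Dirichlet-multinomial proportion estimates, per-isoform beta-binomial
# usage tests adjusted for cell line, and two-stage (screening/confirmation)
# error control.

#' Usage-filter parameters
#'
#' The six-parameter expression/proportion filter applied before usage
#' testing. Defaults are the thresholds used on the 36-sample design: an
#' isoform must reach count 5 in at least 18 samples and a within-gene
#' proportion of 0.05 in at least 18 samples; its gene must reach total
#' count 10 in at least 18 samples.
#'
#' @param min_samples_feature_expr,min_samples_feature_prop,min_samples_gene_expr
#'   sample-count thresholds (defaults 18).
#' @param min_feature_expr minimum isoform count (default 5).
#' @param min_feature_prop minimum within-gene proportion (default 0.05).
#' @param min_gene_expr minimum gene total count (default 10).
#' @return List of class `filter_params`.
#' @export
filter_params <- function(min_samples_feature_expr = 18,
                          min_samples_feature_prop = 18,
                          min_samples_gene_expr = 18,
                          min_feature_expr = 5,
                          min_feature_prop = 0.05,
                          min_gene_expr = 10) {
  stopifnot(min_feature_expr >= 0, min_gene_expr >= 0,
            min_feature_prop >= 0, min_feature_prop <= 1,
            min_samples_feature_expr >= 0, min_samples_feature_prop >= 0,
            min_samples_gene_expr >= 0)
  structure(list(min_samples_feature_expr = min_samples_feature_expr,
                 min_samples_feature_prop = min_samples_feature_prop,
                 min_samples_gene_expr = min_samples_gene_expr,
                 min_feature_expr = min_feature_expr,
                 min_feature_prop = min_feature_prop,
                 min_gene_expr = min_gene_expr),
            class = "filter_params")
}

#' Filter isoforms and genes ahead of usage testing
#'
#' Keeps an isoform iff it reaches `min_feature_expr` counts in at least
#' `min_samples_feature_expr` samples AND a within-gene proportion of
#' `min_feature_prop` in at least `min_samples_feature_prop` samples
#' (proportions from raw counts; zero-total samples fail the proportion
#' rule). A gene is kept iff its post-filter total reaches `min_gene_expr`
#' in at least `min_samples_gene_expr` samples and at least two isoforms
#' survive. The report lists every removal with the first rule it failed.
#' The filter is idempotent.
#'
#' @param x a [count_matrix()] of isoform counts.
#' @param t2g transcript-to-gene map covering all features.
#' @param params a [filter_params()].
#' @return List: `counts` (filtered `count_matrix`), `report` (data.frame
#'   `feature_id`, `gene_id`, `rule`).
#' @export
filter_features <- function(x, t2g, params = filter_params()) {
  stopifnot(inherits(x, "count_matrix"), inherits(params, "filter_params"))
  n_s <- ncol(x$counts)
  if (max(params$min_samples_feature_expr, params$min_samples_feature_prop,
          params$min_samples_gene_expr) > n_s)
    stop("sample thresholds exceed the ", n_s, " available samples")
  gene <- t2g$gene_id[match(rownames(x$counts), t2g$transcript_id)]
  if (anyNA(gene))
    stop("feature(s) missing from transcript-to-gene map: ",
         paste(head(rownames(x$counts)[is.na(gene)], 5), collapse = ", "))
  tot <- rowsum(x$counts, gene)[gene, , drop = FALSE]  # per-isoform gene totals
  prop <- x$counts / pmax(tot, 1)
  prop[tot == 0] <- 0  # zero-total samples fail the proportion rule

  fail_expr <- rowSums(x$counts >= params$min_feature_expr) < params$min_samples_feature_expr
  fail_prop <- rowSums(prop >= params$min_feature_prop) < params$min_samples_feature_prop
  rule <- rep(NA_character_, nrow(x$counts))
  rule[fail_prop] <- "min_samples_feature_prop"
  rule[fail_expr] <- "min_samples_feature_expr"  # expression rule reported first
  keep_iso <- !(fail_expr | fail_prop)

  # gene rules on post-isoform-filter totals (this makes the filter idempotent)
  g2 <- gene[keep_iso]
  tot2 <- rowsum(x$counts[keep_iso, , drop = FALSE], g2)
  gene_ok <- rowSums(tot2 >= params$min_gene_expr) >= params$min_samples_gene_expr
  n_iso <- table(g2)
  gene_keep <- names(gene_ok)[gene_ok & as.vector(n_iso[names(gene_ok)]) >= 2]
  drop_gene <- keep_iso & !(gene %in% gene_keep)
  rule[drop_gene & !gene_ok[gene]] <- "min_samples_gene_expr"
  rule[drop_gene & gene_ok[gene]] <- "lt2_isoforms"
  keep <- keep_iso & gene %in% gene_keep
  if (!any(keep)) stop("no isoform survives the usage filter")
  report <- data.frame(feature_id = rownames(x$counts)[!keep],
                       gene_id = gene[!keep], rule = rule[!keep],
                       stringsAsFactors = FALSE)
  list(counts = subset_counts(x, features = which(keep)), report = report)
}

# ---- Dirichlet-multinomial ---------------------------------------------------

.dm_loglik <- function(y, a) {
  # y: K x n counts, a: K alpha parameters
  n <- colSums(y)
  A <- sum(a)
  sum(lgamma(A) - lgamma(A + n)) +
    sum(lgamma(y + a) - lgamma(a))
}

#' Maximum-likelihood Dirichlet-multinomial fit of isoform proportions
#'
#' Fits per-group proportion vectors with a single shared precision `gamma`
#' by direct likelihood maximization (BFGS on softmax-transformed
#' proportions and log precision). Zero-total samples are excluded.
#'
#' @param y isoform x sample integer matrix for one gene (>= 2 isoforms).
#' @param groups per-sample group labels (a single group if omitted).
#' @return List: `pi` (group x isoform matrix), `gamma`, `loglik`,
#'   `converged`, `excluded_samples`.
#' @export
fit_dm <- function(y, groups = NULL) {
  y <- as.matrix(y)
  K <- nrow(y)
  if (K < 2) stop("Dirichlet-multinomial fit needs >= 2 isoforms")
  if (is.null(groups)) groups <- rep("all", ncol(y))
  groups <- as.factor(groups)
  tot <- colSums(y)
  excl <- colnames(y)[tot == 0]
  keep <- tot > 0
  if (!any(keep)) stop("all samples have zero gene total")
  y <- y[, keep, drop = FALSE]
  groups <- droplevels(groups[keep])
  G <- nlevels(groups)
  y_by <- lapply(levels(groups), function(g) y[, groups == g, drop = FALSE])
  # init: pooled fractions per group, moderate precision
  pi0 <- t(vapply(y_by, function(m) {
    p <- rowSums(m) + 0.5
    p / sum(p)
  }, numeric(K)))
  par0 <- c(as.vector(t(log(pi0[, -K, drop = FALSE] / pi0[, K]))), log(20))
  unpack <- function(par) {
    th <- exp(par[length(par)])
    pim <- matrix(0, G, K)
    for (g in seq_len(G)) {
      eta <- c(par[((g - 1) * (K - 1) + 1):(g * (K - 1))], 0)
      e <- exp(eta - max(eta))
      pim[g, ] <- e / sum(e)
    }
    list(pi = pim, gamma = th)
  }
  negll <- function(par) {
    u <- unpack(par)
    if (!is.finite(u$gamma) || u$gamma > 1e8) return(1e12)
    -sum(vapply(seq_len(G), function(g)
      .dm_loglik(y_by[[g]], u$gamma * u$pi[g, ]), numeric(1)))
  }
  opt <- optim(par0, negll, method = "BFGS", control = list(maxit = 500))
  u <- unpack(opt$par)
  dimnames(u$pi) <- list(levels(groups), rownames(y))
  list(pi = u$pi, gamma = u$gamma, loglik = -opt$value,
       converged = opt$convergence == 0, excluded_samples = excl,
       last_iterate = if (opt$convergence == 0) NULL else opt$par)
}

# ---- beta-binomial usage regression -----------------------------------------

# negative beta-binomial log-likelihood over par = c(beta, log theta);
# cr = TRUE adds the Cox-Reid adjustment -0.5 log det(X'WX), which corrects
# the small-sample downward bias of the ML precision estimate
.bb_negll <- function(par, y, n, X, cr = FALSE, th_fix = NULL) {
  p <- ncol(X)
  eta <- drop(X %*% par[1:p])
  mu <- 1 / (1 + exp(-eta))
  mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
  th <- if (is.null(th_fix)) exp(par[p + 1]) else th_fix
  if (!is.finite(th) || th > 1e9) return(1e12)
  a <- mu * th; b <- (1 - mu) * th
  ll <- sum(lgamma(y + a) + lgamma(n - y + b) - lgamma(n + th) -
              lgamma(a) - lgamma(b) + lgamma(th))
  if (cr) {
    v <- mu * (1 - mu) * (1 + (n - 1) / (th + 1)) / pmax(n, 1)
    w <- n * mu * (1 - mu) / (1 + (n - 1) / (th + 1))
    ll <- ll - 0.5 * determinant(crossprod(X * sqrt(w)),
                                 logarithm = TRUE)$modulus
  }
  if (!is.finite(ll)) return(1e12)
  -ll
}

.bb_init <- function(y, n, X) {
  init <- tryCatch(
    suppressWarnings(glm.fit(X, cbind(y, n - y), family = binomial())$coefficients),
    error = function(e) rep(0, ncol(X)))
  init[!is.finite(init)] <- 0
  init
}

# free-precision fit (optionally Cox-Reid adjusted)
.bb_fit <- function(y, n, X, cr = FALSE) {
  init <- .bb_init(y, n, X)
  opt <- tryCatch(
    optim(c(init, log(10)), .bb_negll, y = y, n = n, X = X, cr = cr,
          method = "BFGS", control = list(maxit = 300)),
    error = function(e) NULL)
  if (is.null(opt)) return(list(loglik = NA_real_, converged = FALSE))
  list(loglik = -.bb_negll(opt$par, y, n, X, cr = FALSE),
       theta = exp(opt$par[length(opt$par)]),
       converged = opt$convergence == 0, par = opt$par)
}

# fixed-precision fit (the LRT is computed at a common precision so the
# statistic reflects the day terms only)
.bb_fit_fixed <- function(y, n, X, theta) {
  init <- .bb_init(y, n, X)
  opt <- tryCatch(
    optim(init, .bb_negll, y = y, n = n, X = X, th_fix = theta,
          method = "BFGS", control = list(maxit = 300)),
    error = function(e) NULL)
  if (is.null(opt)) return(list(loglik = NA_real_, converged = FALSE))
  list(loglik = -opt$value, converged = opt$convergence == 0, par = opt$par)
}

# one isoform's usage LRT p-value: precision estimated once under the
# reduced (no-day) model with the Cox-Reid adjustment, then held fixed in
# both fits
.bb_usage_p <- function(y, n, Xf, Xr, df) {
  fr0 <- .bb_fit(y, n, Xr, cr = TRUE)
  if (!isTRUE(fr0$converged) || !is.finite(fr0$loglik)) return(NA_real_)
  th <- min(max(fr0$theta, 1e-3), 1e6)
  ff <- .bb_fit_fixed(y, n, Xf, th)
  fr <- .bb_fit_fixed(y, n, Xr, th)
  if (!isTRUE(ff$converged) || !isTRUE(fr$converged) ||
      !is.finite(ff$loglik) || !is.finite(fr$loglik)) return(NA_real_)
  stat <- max(2 * (ff$loglik - fr$loglik), 0)
  pchisq(stat, df, lower.tail = FALSE)
}

#' Per-isoform usage test with cell-line adjustment
#'
#' For every isoform of every (filtered) gene, a beta-binomial regression of
#' the isoform count against the gene total with a logit-linear predictor in
#' day (factor) plus cell line; the likelihood-ratio p-value for the day
#' terms tests whether the isoform's usage proportion changes over
#' differentiation while the cell-line term absorbs line-specific usage.
#' The per-gene screening p-value is the minimum member p with a Sidak
#' correction for the number of isoforms tested.
#'
#' @param x filtered isoform [count_matrix()].
#' @param t2g transcript-to-gene map.
#' @return List: `isoforms` (transcript_id, gene_id, p, converged), `genes`
#'   (gene_id, p_screen, n_isoforms, flagged).
#' @export
test_usage <- function(x, t2g) {
  stopifnot(inherits(x, "count_matrix"))
  gene <- t2g$gene_id[match(rownames(x$counts), t2g$transcript_id)]
  if (anyNA(gene)) stop("feature(s) missing from transcript-to-gene map")
  smp <- x$samples
  multi_line <- length(unique(smp$cell_line)) > 1
  iso_rows <- split(seq_len(nrow(x$counts)), gene)
  iso_out <- list(); gene_out <- list()
  for (g in names(iso_rows)) {
    rows <- iso_rows[[g]]
    if (length(rows) < 2) next
    tot <- colSums(x$counts[rows, , drop = FALSE])
    keep <- tot > 0
    flagged <- !all(keep)
    day_f <- factor(smp$day[keep])
    if (nlevels(day_f) < 2) {
      gene_out[[g]] <- data.frame(gene_id = g, p_screen = NA_real_,
                                  n_isoforms = length(rows), flagged = TRUE)
      next
    }
    Xf <- if (multi_line)
      model.matrix(~ cell_line + day_f, data = data.frame(
        cell_line = smp$cell_line[keep], day_f = day_f))
      else model.matrix(~ day_f)
    Xr <- Xf[, seq_len(ncol(Xf) - (nlevels(day_f) - 1)), drop = FALSE]
    df <- nlevels(day_f) - 1
    nk <- tot[keep]
    if (length(rows) == 2) {
      # two-isoform genes are symmetric (the second isoform's model is the
      # logit mirror of the first at the same precision): one fit serves both
      p1 <- .bb_usage_p(x$counts[rows[1], keep], nk, Xf, Xr, df)
      ps <- c(p1, p1)
    } else {
      ps <- vapply(rows, function(r)
        .bb_usage_p(x$counts[r, keep], nk, Xf, Xr, df), numeric(1))
    }
    iso_out[[g]] <- data.frame(transcript_id = rownames(x$counts)[rows],
                               gene_id = g, p = ps, converged = !is.na(ps),
                               stringsAsFactors = FALSE)
    pmin_ <- suppressWarnings(min(ps, na.rm = TRUE))
    # a two-isoform gene carries a single distinct usage test
    m <- if (length(rows) == 2) as.integer(any(!is.na(ps))) else sum(!is.na(ps))
    gene_out[[g]] <- data.frame(
      gene_id = g,
      p_screen = if (m == 0) NA_real_ else 1 - (1 - pmin_)^m,  # Sidak
      n_isoforms = length(rows), flagged = flagged,
      stringsAsFactors = FALSE)
  }
  iso <- do.call(rbind, iso_out); rownames(iso) <- NULL
  gn <- do.call(rbind, gene_out); rownames(gn) <- NULL
  list(isoforms = iso, genes = gn)
}

#' Stage-wise (screening / confirmation) decisions
#'
#' Stage I screens genes by Benjamini-Hochberg on the gene screening
#' p-values at level `alpha`. Stage II confirms isoforms within each
#' screened gene by Holm adjustment of the member p-values, evaluated at the
#' stage-I adjusted level `alpha * R / G` (R genes rejected among G
#' screened). An isoform can only be confirmed inside a screened gene; this
#' is asserted on every run.
#'
#' @param usage the [test_usage()] result (or a compatible list with
#'   `genes` and `isoforms`).
#' @param alpha overall target level (default 0.05).
#' @return List of class `usage_result`: `genes` (with `padj_screen`,
#'   `screened`), `isoforms` (with `p_holm`, `confirmed`), `alpha`,
#'   `alpha_adj`.
#' @export
stagewise_adjust <- function(usage, alpha = 0.05) {
  gn <- usage$genes
  iso <- usage$isoforms
  gn$padj_screen <- bh_adjust(gn$p_screen)
  gn$screened <- !is.na(gn$padj_screen) & gn$padj_screen <= alpha
  G <- sum(!is.na(gn$p_screen))
  R <- sum(gn$screened)
  alpha_adj <- if (G > 0) alpha * R / G else 0
  iso$p_holm <- NA_real_
  iso$confirmed <- FALSE
  for (g in gn$gene_id[gn$screened]) {
    i <- which(iso$gene_id == g)
    ph <- rep(NA_real_, length(i))
    ok <- !is.na(iso$p[i])
    if (length(i) == 2 && sum(ok) == 2 && iso$p[i][1] == iso$p[i][2]) {
      ph <- iso$p[i]  # the mirrored pair is one distinct test; no Holm doubling
    } else {
      ph[ok] <- p.adjust(iso$p[i][ok], method = "holm")
    }
    iso$p_holm[i] <- ph
    iso$confirmed[i] <- !is.na(ph) & ph <= alpha_adj
  }
  stopifnot(all(iso$gene_id[iso$confirmed] %in% gn$gene_id[gn$screened]))
  structure(list(genes = gn, isoforms = iso, alpha = alpha,
                 alpha_adj = alpha_adj), class = "usage_result")
}

#' Per-sample and per-day isoform usage proportions
#'
#' Per sample, an isoform's proportion is its count over its gene's total;
#' the per-day summary is the mean across samples of that day. Zero-total
#' samples are excluded per gene and counted in the `excluded` attribute.
#' Within a gene, the per-day proportions sum to 1 over isoforms.
#'
#' @param x isoform [count_matrix()].
#' @param t2g transcript-to-gene map.
#' @return List: `per_sample` (tidy data.frame transcript_id, gene_id,
#'   sample_id, day, proportion), `per_day` (transcript_id x day mean
#'   matrix); attribute `excluded` counts skipped zero-total samples.
#' @export
usage_proportions <- function(x, t2g) {
  stopifnot(inherits(x, "count_matrix"))
  gene <- t2g$gene_id[match(rownames(x$counts), t2g$transcript_id)]
  if (anyNA(gene)) stop("feature(s) missing from transcript-to-gene map")
  tot <- rowsum(x$counts, gene)[gene, , drop = FALSE]
  prop <- x$counts / tot  # NaN where the gene total is zero
  prop[tot == 0] <- NA
  long <- data.frame(
    transcript_id = rep(rownames(x$counts), ncol(x$counts)),
    gene_id = rep(gene, ncol(x$counts)),
    sample_id = rep(colnames(x$counts), each = nrow(x$counts)),
    day = rep(x$samples$day, each = nrow(x$counts)),
    proportion = as.vector(prop), stringsAsFactors = FALSE)
  n_excl <- sum(is.na(long$proportion))
  days <- sort(unique(x$samples$day))
  per_day <- vapply(days, function(d)
    rowMeans(prop[, x$samples$day == d, drop = FALSE], na.rm = TRUE),
    numeric(nrow(prop)))
  per_day <- matrix(per_day, nrow = nrow(prop),
                    dimnames = list(rownames(x$counts), days))
  out <- list(per_sample = long[!is.na(long$proportion), ], per_day = per_day)
  attr(out, "excluded") <- n_excl
  out
}

#' Classify the isoform dynamics behind a gene-level change
#'
#' Compares each isoform's change over the window against the aggregate
#' (summed) change: `inverse` when an isoform moves against an aggregate
#' change exceeding `theta`; `single_dominant` when one isoform carries at
#' least `dominance_fraction` of the aggregate change; `cumulative` when at
#' least two isoforms each contribute >= 0.25 of an aggregate change with
#' the same sign; `other` otherwise (including flat aggregates). Precedence:
#' inverse > single_dominant > cumulative.
#'
#' @param iso_traj isoform x day matrix of expression trajectories for the
#'   isoforms of one gene (linear or log scale; deltas are taken on this
#'   scale).
#' @param theta minimal aggregate / opposing change (default 0.5, same units
#'   as `iso_traj`).
#' @param dominance_fraction fraction of the aggregate change an isoform
#'   must carry to dominate (default 0.75).
#' @return One of `"cumulative"`, `"single_dominant"`, `"inverse"`,
#'   `"other"`.
#' @export
classify_die_dynamics <- function(iso_traj, theta = 0.5, dominance_fraction = 0.75) {
  iso_traj <- as.matrix(iso_traj)
  if (nrow(iso_traj) < 2) stop("dynamics are defined for >= 2 isoforms")
  d_iso <- iso_traj[, ncol(iso_traj)] - iso_traj[, 1]
  d_agg <- sum(d_iso)
  if (abs(d_agg) <= theta) return("other")
  opposing <- sign(d_iso) == -sign(d_agg) & abs(d_iso) > theta
  if (any(opposing)) return("inverse")
  if (max(abs(d_iso)) >= dominance_fraction * abs(d_agg)) return("single_dominant")
  contrib <- d_iso / d_agg
  if (sum(contrib >= 0.25) >= 2) return("cumulative")
  "other"
}

#' Full differential-transcript-usage analysis
#'
#' Filter, per-isoform beta-binomial usage tests, and stage-wise decisions.
#'
#' @param x isoform [count_matrix()].
#' @param t2g transcript-to-gene map.
#' @param params a [filter_params()].
#' @param alpha overall stage-wise level (default 0.05).
#' @return A `usage_result` (see [stagewise_adjust()]) with the filter
#'   report attached as `$filter_report`.
#' @export
dtu <- function(x, t2g, params = filter_params(), alpha = 0.05) {
  flt <- filter_features(x, t2g, params)
  res <- stagewise_adjust(test_usage(flt$counts, t2g), alpha = alpha)
  res$filter_report <- flt$report
  res
}
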