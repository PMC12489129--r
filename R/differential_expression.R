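# Negative-binomial machinery for the time-course tests. Models are fitted
# per feature by IRLS (stats::glm.fit) at a fixed, separately estimated
# dispersion, with log effective library sizes as offsets.

.nb_family <- function(alpha) {
  if (alpha < 1e-8) poisson() else MASS::negative.binomial(theta = 1 / alpha)
}

.nb_loglik <- function(y, mu, alpha) {
  if (alpha < 1e-8) sum(dpois(y, mu, log = TRUE))
  else sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}

.fit_feature <- function(y, X, offset, alpha) {
  fit <- suppressWarnings(
    glm.fit(X, y, family = .nb_family(alpha), offset = offset,
            control = list(epsilon = 1e-10, maxit = 100)))
  mu <- fit$fitted.values
  list(loglik = .nb_loglik(y, mu, alpha), coef = fit$coefficients,
       deviance = fit$deviance, qr = fit$qr, converged = fit$converged,
       rank = fit$rank)
}

.effective_lib <- function(x, factors = NULL) {
  if (is.null(factors)) factors <- tmm_factors(x)
  unname(x$lib_sizes * factors[colnames(x$counts)])
}

#' Benjamini-Hochberg adjustment with missing values returned as missing
#'
#' Step-up BH across the non-missing p-values (which alone count toward the
#' number of tests); NA entries stay NA.
#'
#' @param p numeric vector of p-values in [0, 1], NA allowed.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Estimate per-feature NB dispersions
#'
#' Method-of-moments: counts are scaled to a common library size, residual
#' variance is pooled across the cell-line x day condition groups of the
#' fitted mean model, and the raw estimate `(v - m/s) / m^2` is floored at 0
#' and shrunk toward a lowess mean-dispersion trend by a fixed weight.
#' All-zero features have no defined dispersion; they are excluded and listed
#' in the `excluded` attribute of the result.
#'
#' @param x a [count_matrix()].
#' @param factors optional per-sample normalization factors (default TMM).
#' @param shrink_weight weight of the trend in the shrunk estimate
#'   (default 0.5).
#' @return data.frame (`feature_id`, `alpha`, `alpha_raw`, `method`), with
#'   attribute `excluded` naming all-zero features.
#' @export
estimate_dispersions <- function(x, factors = NULL, shrink_weight = 0.5) {
  stopifnot(inherits(x, "count_matrix"))
  eff <- .effective_lib(x, factors)
  s <- eff / mean(eff)
  keep <- rowSums(x$counts) > 0
  excluded <- rownames(x$counts)[!keep]
  y <- x$counts[keep, , drop = FALSE] / rep(s, each = sum(keep))
  grp <- interaction(x$samples$cell_line, x$samples$day, drop = TRUE)
  if (!any(table(grp) >= 2)) stop("no condition group has >= 2 replicates")
  inv_s_mean <- tapply(1 / s, grp, mean)
  num <- 0; den <- 0
  for (g in levels(grp)) {
    j <- which(grp == g)
    if (length(j) < 2) next
    m <- rowMeans(y[, j, drop = FALSE])
    v <- apply(y[, j, drop = FALSE], 1, var)
    w <- length(j) - 1
    num <- num + w * (v - m * inv_s_mean[[g]])
    # m^2 - v/n is the unbiased estimate of mu^2 (m^2 alone overstates it by
    # Var(m), which would bias the dispersion down and inflate the LRT)
    den <- den + w * pmax(m^2 - v / length(j), 0)
  }
  raw <- pmax(num / pmax(den, .Machine$double.eps), 0)
  raw[den == 0] <- 0
  mean_expr <- rowMeans(y)
  ord <- order(mean_expr)
  tr <- rep(median(raw), length(raw))
  if (length(raw) >= 10) {
    lo <- lowess(log(mean_expr[ord] + 1e-8), raw[ord], f = 0.5)
    tr[ord] <- pmax(lo$y, 0)
  }
  alpha <- shrink_weight * tr + (1 - shrink_weight) * raw
  out <- data.frame(feature_id = rownames(x$counts)[keep], alpha = alpha,
                    alpha_raw = raw, alpha_trend = tr, method = "mom_trend",
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

.dispersion_lookup <- function(x, dispersions, factors) {
  if (is.null(dispersions)) dispersions <- estimate_dispersions(x, factors)
  setNames(dispersions$alpha, dispersions$feature_id)
}

#' Full-model negative-binomial likelihood-ratio test
#'
#' Per feature, NB models are fitted by IRLS under the full design (day as a
#' factor plus cell line) and the reduced design (cell line only), at the
#' trended dispersion. The likelihood-ratio (deviance-difference) statistic
#' with df = number of day levels - 1 (5 for six days) is tested
#' quasi-likelihood style: the statistic is scaled by a per-feature
#' quasi-dispersion (residual deviance over residual df, moderated across
#' features by empirical Bayes) and referred to an F distribution. The
#' moderated F accounts for the uncertainty of the estimated dispersion,
#' which a plug-in chi-square reference ignores; the chi-square p is also
#' reported as `p_chisq`. Non-converging fits are flagged with `p = NA`,
#' never dropped silently.
#'
#' @param x a [count_matrix()] (gene-aggregated or isoform-level).
#' @param dispersions optional [estimate_dispersions()] output.
#' @param factors optional normalization factors (default TMM).
#' @return data.frame with columns `feature_id`, `beta` (NA for the LRT),
#'   `stat` (deviance difference), `df`, `p`, `padj`, `p_chisq`, `model`
#'   (`"lrt_full"`), `converged`.
#' @export
nb_lrt <- function(x, dispersions = NULL, factors = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  eff <- .effective_lib(x, factors)
  off <- log(eff)
  if (is.null(dispersions)) dispersions <- estimate_dispersions(x, factors)
  alpha <- setNames(
    if ("alpha_trend" %in% names(dispersions)) dispersions$alpha_trend
    else dispersions$alpha,
    dispersions$feature_id)
  feats <- intersect(rownames(x$counts), names(alpha))
  day_f <- factor(x$samples$day)
  multi_line <- length(unique(x$samples$cell_line)) > 1
  Xf <- if (multi_line) model.matrix(~ cell_line + day_f, data = x$samples)
        else model.matrix(~ day_f)
  Xr <- if (multi_line) model.matrix(~ cell_line, data = x$samples)
        else matrix(1, ncol(x$counts), 1)
  df <- ncol(Xf) - ncol(Xr)
  df_resid <- ncol(x$counts) - ncol(Xf)
  if (df_resid < 1) stop("no residual degrees of freedom under the full design")
  res <- lapply(feats, function(f) {
    y <- x$counts[f, ]
    a <- alpha[[f]]
    ff <- .fit_feature(y, Xf, off, a)
    fr <- .fit_feature(y, Xr, off, a)
    stat <- max(fr$deviance - ff$deviance, 0)
    c(stat = stat, phi = ff$deviance / df_resid,
      converged = as.numeric(ff$converged && fr$converged))
  })
  res <- do.call(rbind, res)
  conv <- res[, "converged"] == 1
  sq <- limma::squeezeVar(pmax(res[conv, "phi"], 1e-8), df = df_resid)
  p <- rep(NA_real_, length(feats))
  p[conv] <- pf((res[conv, "stat"] / df) / sq$var.post, df,
                df_resid + sq$df.prior, lower.tail = FALSE)
  p_chisq <- ifelse(conv, pchisq(res[, "stat"], df, lower.tail = FALSE), NA_real_)
  out <- data.frame(feature_id = feats, beta = NA_real_, stat = res[, "stat"],
                    df = df, p = p, padj = bh_adjust(p), p_chisq = p_chisq,
                    model = "lrt_full", converged = conv,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- setdiff(rownames(x$counts), feats)
  out
}

#' Windowed negative-binomial trend test
#'
#' NB regression of counts on numeric day within a day window (days 0-3 for
#' the canonical differentiation phase, 3-5 for the post-differentiation
#' phase), adjusted for cell line. The slope is reported in log2 units per
#' day with a Wald p-value (t reference with residual degrees of freedom),
#' BH-adjusted across features.
#'
#' @param x a [count_matrix()].
#' @param window length-2 numeric day range, inclusive (default `c(0, 3)`).
#' @param dispersions optional [estimate_dispersions()] output (estimated on
#'   the full design if omitted).
#' @param factors optional normalization factors.
#' @return data.frame with columns `feature_id`, `beta` (log2/day), `stat`
#'   (Wald z), `df`, `p`, `padj`, `model` (`"window_<a>_<b>"`), `converged`.
#' @export
nb_trend <- function(x, window = c(0, 3), dispersions = NULL, factors = NULL) {
  stopifnot(inherits(x, "count_matrix"), length(window) == 2)
  keep_s <- x$samples$day >= window[1] & x$samples$day <= window[2]
  if (length(unique(x$samples$day[keep_s])) < 3)
    stop("window must contain >= 3 distinct days")
  alpha <- .dispersion_lookup(x, dispersions, factors)
  xs <- subset_counts(x, samples = which(keep_s))
  eff_all <- .effective_lib(x, factors)
  off <- log(eff_all[keep_s])
  multi_line <- length(unique(xs$samples$cell_line)) > 1
  X <- if (multi_line) model.matrix(~ cell_line + day, data = xs$samples)
       else model.matrix(~ day, data = xs$samples)
  j_day <- which(colnames(X) == "day")
  feats <- intersect(rownames(xs$counts), names(alpha))
  res <- lapply(feats, function(f) {
    y <- xs$counts[f, ]
    a <- alpha[[f]]
    ft <- .fit_feature(y, X, off, a)
    if (!ft$converged || ft$rank < ncol(X))
      return(c(beta = NA_real_, z = NA_real_, p = NA_real_, converged = 0))
    cov <- chol2inv(qr.R(ft$qr))  # (X'WX)^{-1}, in pivoted column order
    jp <- which(ft$qr$pivot == j_day)
    se <- sqrt(cov[jp, jp])
    z <- unname(ft$coef[j_day]) / se
    c(beta = unname(ft$coef[j_day]) / log(2), z = z,
      p = 2 * pt(-abs(z), df = nrow(X) - ncol(X)), converged = 1)
  })
  res <- do.call(rbind, res)
  out <- data.frame(feature_id = feats, beta = res[, "beta"], stat = res[, "z"],
                    df = 1, p = res[, "p"], padj = bh_adjust(res[, "p"]),
                    model = sprintf("window_%g_%g", window[1], window[2]),
                    converged = res[, "converged"] == 1, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- setdiff(rownames(xs$counts), feats)
  out
}
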