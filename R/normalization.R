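#' TMM normalization factors
#'
#' Trimmed mean of M-values scaling factors: for each sample versus a
#' reference sample, a doubly trimmed (by log-ratio M and by average
#' log-intensity A) weighted mean of gene-wise log ratios over genes nonzero
#' in both samples, rescaled so the factors have geometric mean 1. Computed
#' with edgeR's TMM implementation.
#'
#' @param x a [count_matrix()] (>= 2 samples).
#' @param ref_sample optional reference sample id; default is edgeR's choice
#'   (the sample whose 75th percentile is closest to the mean).
#' @param logratio_trim two-sided trim fraction on M values (default 0.3).
#' @param abs_trim two-sided trim fraction on A values (default 0.05).
#' @return Named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(x, ref_sample = NULL, logratio_trim = 0.3, abs_trim = 0.05) {
  stopifnot(inherits(x, "count_matrix"))
  if (ncol(x$counts) < 2) stop("TMM needs at least 2 samples")
  zero <- colSums(x$counts) == 0
  if (any(zero))
    stop("all-zero sample(s): ", paste(colnames(x$counts)[zero], collapse = ", "))
  ref <- if (is.null(ref_sample)) NULL else {
    i <- match(ref_sample, colnames(x$counts))
    if (is.na(i)) stop("ref_sample '", ref_sample, "' not found")
    i
  }
  f <- edgeR::calcNormFactors(x$counts, lib.size = unname(x$lib_sizes),
                              method = "TMM", refColumn = ref,
                              logratioTrim = logratio_trim, sumTrim = abs_trim)
  setNames(f, colnames(x$counts))
}

#' Counts per million, optionally log2
#'
#' `CPM = count / (library_size * factor) * 1e6`. The log variant is
#' `log2(CPM + prior_count)`, with the prior added on the CPM scale so an
#' all-zero gene maps to the same constant in every sample.
#'
#' @param x a [count_matrix()].
#' @param factors per-sample normalization factors (default all 1).
#' @param log return log2 values (default FALSE).
#' @param prior_count prior added to CPM before the log (default 0.5).
#' @return A `normalized_matrix`: list with `values`, `stage`
#'   (`"cpm"`/`"logcpm"`), and `factors`.
#' @export
cpm <- function(x, factors = NULL, log = FALSE, prior_count = 0.5) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(factors)) factors <- setNames(rep(1, ncol(x$counts)), colnames(x$counts))
  if (any(factors <= 0) || any(!is.finite(factors)))
    stop("normalization factors must be positive and finite")
  eff <- x$lib_sizes * factors[colnames(x$counts)]
  if (any(eff <= 0)) stop("zero effective library size")
  v <- sweep(x$counts, 2, eff, "/") * 1e6
  stage <- "cpm"
  if (log) { v <- log2(v + prior_count); stage <- "logcpm" }
  normalized_matrix(v, stage, factors)
}

#' @rdname cpm
#' @param values numeric matrix.
#' @param stage one of `"cpm"`, `"logcpm"`, `"batch_removed"`, `"zscored"`.
#' @export
normalized_matrix <- function(values, stage, factors = NULL) {
  stage <- match.arg(stage, c("cpm", "logcpm", "batch_removed", "zscored"))
  structure(list(values = as.matrix(values), stage = stage,
                 factors = factors,
                 constant_rows = attr(values, "constant_rows")),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix [", x$stage, "]: ", nrow(x$values), " x ",
      ncol(x$values), "\n", sep = "")
  invisible(x)
}

#' Remove a batch (cell-line) effect from a normalized matrix
#'
#' Per gene, an ordinary-least-squares fit on the preserved design columns
#' plus batch contrasts; the batch-attributable component is subtracted while
#' preserved effects are untouched (limma's removeBatchEffect). With a single
#' batch level the input is returned unchanged. Idempotent.
#'
#' @param x a `normalized_matrix` on the log scale.
#' @param batch per-sample batch labels (e.g. cell line).
#' @param preserve optional per-sample covariate data.frame (e.g. day) whose
#'   effects must be preserved; an intercept is always included.
#' @return A `normalized_matrix` with stage `"batch_removed"`.
#' @export
remove_batch <- function(x, batch, preserve = NULL) {
  stopifnot(inherits(x, "normalized_matrix"))
  batch <- as.factor(batch)
  if (length(batch) != ncol(x$values))
    stop("batch labels must have one entry per sample")
  if (nlevels(batch) < 2) {
    out <- normalized_matrix(x$values, "batch_removed", x$factors)
    return(out)
  }
  design <- if (is.null(preserve)) matrix(1, ncol(x$values), 1) else
    model.matrix(~ ., data = as.data.frame(preserve))
  full <- cbind(design, model.matrix(~ batch)[, -1, drop = FALSE])
  if (qr(full)$rank < ncol(full))
    stop("batch is confounded with the preserved design (aliased columns)")
  v <- limma::removeBatchEffect(x$values, batch = batch, design = design)
  normalized_matrix(v, "batch_removed", x$factors)
}

#' Per-gene z-scores
#'
#' Each row is centred by its mean and scaled by its sample standard
#' deviation (n - 1 denominator). Constant rows are set to zero and flagged
#' in the `constant_rows` attribute rather than propagating NaN.
#'
#' @param x a `normalized_matrix` (>= 2 samples).
#' @return A `normalized_matrix` with stage `"zscored"`; flagged row names in
#'   `$constant_rows`.
#' @export
zscore_genes <- function(x) {
  stopifnot(inherits(x, "normalized_matrix"))
  if (ncol(x$values) < 2) stop("z-scoring needs >= 2 samples")
  mu <- rowMeans(x$values)
  s <- apply(x$values, 1, sd)
  const <- s == 0 | !is.finite(s)
  s[const] <- 1
  v <- (x$values - mu) / s
  v[const, ] <- 0
  attr(v, "constant_rows") <- rownames(x$values)[const]
  normalized_matrix(v, "zscored", x$factors)
}

#' The full normalization chain
#'
#' TMM factors, log2-CPM, cell-line batch removal (preserving day), per-gene
#' z-scores: the chain applied ahead of temporal clustering and composite
#' gene-set scoring.
#'
#' @param x a [count_matrix()].
#' @param batch_col metadata column to remove (default `"cell_line"`;
#'   `NULL` skips batch removal).
#' @param preserve_day keep the day effect in the preserved design
#'   (default TRUE).
#' @param zscore apply per-gene z-scoring (default TRUE).
#' @param prior_count prior for the log transform.
#' @return A `normalized_matrix` at the final stage of the chain.
#' @export
normalize_chain <- function(x, batch_col = "cell_line", preserve_day = TRUE,
                            zscore = TRUE, prior_count = 0.5) {
  f <- tmm_factors(x)
  m <- cpm(x, f, log = TRUE, prior_count = prior_count)
  if (!is.null(batch_col) && length(unique(x$samples[[batch_col]])) > 1) {
    pres <- if (preserve_day) data.frame(day = x$samples$day) else NULL
    m <- remove_batch(m, x$samples[[batch_col]], preserve = pres)
  }
  if (zscore) m <- zscore_genes(m)
  m
}
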