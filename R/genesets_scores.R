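# Composite gene-set scores (OXPHOS complexes, glycolysis, myogenesis
# clusters), linear trend tests, transfer to two-group external datasets,
# over-representation analysis, and the relative qPCR quantification helper.

#' Composite per-sample gene-set score
#'
#' The mean, per sample, of the z-scored (batch-removed) expression of the
#' set's member genes present in the matrix. Because inputs are z-scored,
#' set size does not change the score scale. Missing members are reported.
#'
#' @param z a `normalized_matrix` (typically stage `"zscored"`) or plain
#'   matrix with gene rows.
#' @param gene_set character vector of member gene ids.
#' @param name gene-set name used in messages (default deparse).
#' @return data.frame `sample_id`, `score`, `gene_set`, `n_members_used`;
#'   absent members in the `missing` attribute.
#' @export
composite_score <- function(z, gene_set, name = "gene_set") {
  v <- if (inherits(z, "normalized_matrix")) z$values else as.matrix(z)
  present <- intersect(gene_set, rownames(v))
  if (!length(present))
    stop("no member of gene set '", name, "' present in the matrix")
  sc <- colMeans(v[present, , drop = FALSE])
  out <- data.frame(sample_id = colnames(v), score = unname(sc),
                    gene_set = name, n_members_used = length(present),
                    stringsAsFactors = FALSE)
  attr(out, "missing") <- setdiff(gene_set, present)
  out
}

#' Linear trend of a composite score over days
#'
#' Ordinary least squares of the score on numeric day within a window;
#' samples are treated as independent observations (cell line is handled
#' upstream by batch removal). Returns the slope in score units per day and
#' its two-sided p-value.
#'
#' @param scores data.frame from [composite_score()].
#' @param days numeric day per sample (same order as `scores`).
#' @param window length-2 inclusive day range (default the full range).
#' @return data.frame `beta`, `p`, `window`, `n`.
#' @export
trend_test <- function(scores, days, window = range(days)) {
  stopifnot(nrow(scores) == length(days))
  keep <- days >= window[1] & days <= window[2]
  d <- days[keep]
  if (length(unique(d)) < 3) stop("window must contain >= 3 distinct days")
  fit <- lm(scores$score[keep] ~ d)
  sm <- summary(fit)$coefficients
  data.frame(beta = sm["d", "Estimate"], p = sm["d", "Pr(>|t|)"],
             window = sprintf("%g:%g", window[1], window[2]),
             n = sum(keep))
}

#' Transfer a cluster score onto a two-group external dataset
#'
#' Scores an external (already normalized, gene-row) matrix with a cluster
#' gene set and compares the two groups with a two-sided Welch t-test.
#'
#' @param external_z normalized gene x sample matrix (or
#'   `normalized_matrix`).
#' @param gene_set member gene ids.
#' @param groups per-sample two-level group labels (each level >= 2
#'   samples).
#' @param name gene-set name.
#' @return data.frame `gene_set`, `diff` (group2 - group1 mean score),
#'   `p`, `n1`, `n2`, `n_members_used`.
#' @export
transfer_score <- function(external_z, gene_set, groups, name = "gene_set") {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (any(table(groups) < 2)) stop("each group needs >= 2 samples")
  sc <- composite_score(external_z, gene_set, name = name)
  s1 <- sc$score[groups == levels(groups)[1]]
  s2 <- sc$score[groups == levels(groups)[2]]
  tt <- t.test(s2, s1)
  data.frame(gene_set = name, diff = mean(s2) - mean(s1), p = tt$p.value,
             n1 = length(s1), n2 = length(s2),
             n_members_used = sc$n_members_used[1], stringsAsFactors = FALSE)
}

#' Over-representation analysis against a detected-gene background
#'
#' Hypergeometric upper-tail test of the overlap between a foreground gene
#' list and each gene set, with the set first intersected with the
#' background universe; BH adjustment across sets. Significance is read at
#' `padj < 0.05` by convention.
#'
#' @param foreground character vector of hit genes (must be a subset of
#'   `background`).
#' @param background character vector: the detected-gene universe.
#' @param sets named list of gene sets (e.g. [read_gmt()]).
#' @return data.frame per set: `gene_set`, `k` (overlap), `K` (set size in
#'   background), `n` (foreground size), `N` (background size), `p`, `padj`.
#' @export
ora <- function(foreground, background, sets) {
  foreground <- unique(foreground); background <- unique(background)
  if (!length(foreground)) stop("empty foreground")
  out <- setdiff(foreground, background)
  if (length(out))
    stop("foreground gene(s) not in background: ", paste(head(out, 5), collapse = ", "))
  N <- length(background); n <- length(foreground)
  res <- lapply(names(sets), function(s) {
    members <- intersect(sets[[s]], background)
    K <- length(members)
    k <- length(intersect(foreground, members))
    # P(overlap >= k) drawing n from N with K marked
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(gene_set = s, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$padj <- bh_adjust(res$p)
  res
}

#' Relative qPCR quantification (2^-ddCt)
#'
#' Fold change of a target transcript relative to a reference transcript and
#' a calibrator condition: `2^-((Ct_t - Ct_r) - (Ct_tc - Ct_rc))`.
#'
#' @param ct_target,ct_reference Ct values in the test condition.
#' @param ct_target_calibrator,ct_reference_calibrator Ct values in the
#'   calibrator condition.
#' @return Fold change (vectorized).
#' @export
qpcr_fold_change <- function(ct_target, ct_reference,
                             ct_target_calibrator, ct_reference_calibrator) {
  ddct <- (ct_target - ct_reference) - (ct_target_calibrator - ct_reference_calibrator)
  if (any(!is.finite(ddct))) stop("Ct values must be finite")
  2^(-ddct)
}
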