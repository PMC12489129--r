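#' Per-day temporal profiles of significant features
#'
#' Applies the normalization chain (TMM, log2-CPM, cell-line batch removal,
#' per-gene z-score), keeps features passing the likelihood-ratio
#' significance gate, and averages z-scores per day over cell lines and
#' replicates.
#'
#' @param x a [count_matrix()].
#' @param lrt [nb_lrt()] results for the same features.
#' @param alpha adjusted-p gate (default 0.01).
#' @param batch_col metadata column removed as batch (default `"cell_line"`).
#' @return Feature x day matrix of z-scored mean expression.
#' @export
temporal_profiles <- function(x, lrt, alpha = 0.01, batch_col = "cell_line") {
  stopifnot(inherits(x, "count_matrix"))
  sig <- lrt$feature_id[!is.na(lrt$padj) & lrt$padj <= alpha]
  if (!length(sig)) stop("no feature passes the padj <= ", alpha, " gate")
  z <- normalize_chain(x, batch_col = batch_col)$values[sig, , drop = FALSE]
  days <- sort(unique(x$samples$day))
  prof <- vapply(days, function(d)
    rowMeans(z[, x$samples$day == d, drop = FALSE]), numeric(nrow(z)))
  prof <- matrix(prof, nrow = nrow(z), dimnames = list(sig, days))
  prof
}

#' Hierarchical clustering of temporal profiles
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances) of per-day
#' profiles, cut at `k` clusters. Cluster indices are renumbered by
#' decreasing size so the partition does not depend on input order, and each
#' centroid (profile mean) is named by [label_clusters()].
#'
#' @param profiles feature x day matrix (rows typically z-scored).
#' @param k number of clusters (default 5).
#' @param theta z-unit threshold for shape labeling (default 0.5).
#' @param linkage agglomeration method passed to [hclust()]; the default
#'   `"ward.D"` recovered planted shapes best in the package's benchmark
#'   simulations (see the methods vignette).
#' @return List of class `cluster_assignment`: `assignments` (feature_id,
#'   cluster, label), `centroids` (k x day matrix), `labels`.
#' @export
cluster_profiles <- function(profiles, k = 5, theta = 0.5, linkage = "ward.D") {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < k) stop("k = ", k, " exceeds the ", nrow(profiles), " profiles")
  if (any(!is.finite(profiles))) stop("profiles must be finite")
  hc <- hclust(dist(profiles), method = linkage)
  cl <- cutree(hc, k = k)
  # renumber clusters by decreasing size (ties by first day centroid) so the
  # labels are stable under permutation of the input rows
  sizes <- table(cl)
  ord <- order(-as.vector(sizes), as.numeric(names(sizes)))
  relabel <- setNames(seq_len(k), names(sizes)[ord])
  cl <- relabel[as.character(cl)]
  cent <- t(vapply(seq_len(k), function(i)
    colMeans(profiles[cl == i, , drop = FALSE]), numeric(ncol(profiles))))
  rownames(cent) <- seq_len(k)
  colnames(cent) <- colnames(profiles)
  labels <- label_clusters(cent, theta = theta)
  structure(list(
    assignments = data.frame(feature_id = rownames(profiles),
                             cluster = unname(cl),
                             label = unname(labels[cl]),
                             stringsAsFactors = FALSE),
    centroids = cent, labels = labels), class = "cluster_assignment")
}

#' Rule-based temporal shape labels for cluster centroids
#'
#' Names each centroid over days 0..5 from three contrasts on the z scale:
#' `d1 = c(1) - c(0)`, `dmid = c(3) - c(1)`, `dlate = c(5) - c(3)`, with
#' threshold `theta`:
#' Early-Down (`d1 < -theta`, `|dmid| <= theta`); Down (`d1 < -theta` or
#' `dmid < -theta`, monotone non-increasing to day 3); Early-Up (`d1 >
#' theta`, `|dmid| <= theta`); Up (cumulative rise to day 3 `> theta` with
#' `d1 <= theta`, or monotone increase to day 3); Up-Down (`d1 > theta` and
#' `dlate < -theta`); otherwise Mix. Each centroid takes the satisfied label
#' with the largest margin; duplicated labels keep the largest-margin winner
#' and demote the rest to Mix.
#'
#' @param centroids k x day matrix (columns named by day).
#' @param theta z-unit threshold (default 0.5).
#' @return Character vector of labels, one per centroid row.
#' @export
label_clusters <- function(centroids, theta = 0.5) {
  centroids <- as.matrix(centroids)
  days <- suppressWarnings(as.numeric(colnames(centroids)))
  if (length(days) != ncol(centroids) || anyNA(days))
    days <- seq(0, 5, length.out = ncol(centroids))
  at <- function(v, d) v[which.min(abs(days - d))]
  tol <- theta / 5  # monotonicity slack for noisy centroids
  score_one <- function(v) {
    d1 <- at(v, 1) - at(v, 0)
    dmid <- at(v, 3) - at(v, 1)
    dlate <- at(v, 5) - at(v, 3)
    rise03 <- at(v, 3) - at(v, 0)
    steps03 <- diff(v[days <= 3])
    mono_dec <- min(tol - steps03)   # > 0 when non-increasing to day 3
    mono_inc <- min(steps03)         # > 0 when strictly increasing to day 3
    c(EarlyDown = min(-theta - d1, theta - abs(dmid)),
      Down = min(max(-theta - d1, -theta - dmid), mono_dec),
      EarlyUp = min(d1 - theta, theta - abs(dmid)),
      Up = max(min(rise03 - theta, theta - d1), mono_inc),
      UpDown = min(d1 - theta, -theta - dlate))
  }
  margins <- t(apply(centroids, 1, score_one))
  labels <- apply(margins, 1, function(m)
    if (max(m) > 0) names(m)[which.max(m)] else "Mix")
  best <- apply(margins, 1, max)
  for (lab in unique(labels[labels != "Mix"])) {
    i <- which(labels == lab)
    if (length(i) > 1) labels[i[-which.max(best[i])]] <- "Mix"
  }
  unname(labels)
}

#' Cross-tabulate isoform clusters against parent-gene clusters
#'
#' Counts isoforms per (isoform cluster label, parent-gene cluster label)
#' cell; isoforms whose gene carries no assignment are counted in an
#' `"unclustered"` margin. An isoform absent from the transcript-to-gene map
#' is an error.
#'
#' @param iso_assign isoform-level `cluster_assignment` (or its
#'   `assignments` data.frame).
#' @param gene_assign gene-level `cluster_assignment` (or data.frame).
#' @param t2g transcript-to-gene map.
#' @return Contingency matrix, isoform clusters in rows.
#' @export
cross_tabulate <- function(iso_assign, gene_assign, t2g) {
  ia <- if (inherits(iso_assign, "cluster_assignment")) iso_assign$assignments else iso_assign
  ga <- if (inherits(gene_assign, "cluster_assignment")) gene_assign$assignments else gene_assign
  if (!nrow(ia) || !nrow(ga)) stop("both partitions must be nonempty")
  gene <- t2g$gene_id[match(ia$feature_id, t2g$transcript_id)]
  if (anyNA(gene))
    stop("isoform(s) without gene mapping: ",
         paste(head(ia$feature_id[is.na(gene)], 5), collapse = ", "))
  glab <- ga$label[match(gene, ga$feature_id)]
  glab[is.na(glab)] <- "unclustered"
  table(isoform_cluster = ia$label, gene_cluster = glab)
}

#' Concordance of isoform clusters with gene-level direction
#'
#' Classifies every clustered isoform by its parent gene's state in a
#' windowed gene-level test: `gene_up` (padj below threshold, positive
#' slope), `gene_down` (negative slope), or `gene_ns`.
#'
#' @param iso_assign isoform-level `cluster_assignment` (or data.frame).
#' @param gene_window gene-level [nb_trend()] results.
#' @param t2g transcript-to-gene map.
#' @param alpha adjusted-p threshold (default 0.05).
#' @return Contingency matrix: isoform cluster x gene direction.
#' @export
direction_concordance <- function(iso_assign, gene_window, t2g, alpha = 0.05) {
  ia <- if (inherits(iso_assign, "cluster_assignment")) iso_assign$assignments else iso_assign
  gene <- t2g$gene_id[match(ia$feature_id, t2g$transcript_id)]
  if (anyNA(gene))
    stop("isoform(s) without gene mapping: ",
         paste(head(ia$feature_id[is.na(gene)], 5), collapse = ", "))
  i <- match(gene, gene_window$feature_id)
  padj <- gene_window$padj[i]
  beta <- gene_window$beta[i]
  state <- ifelse(is.na(padj) | padj >= alpha, "gene_ns",
                  ifelse(beta > 0, "gene_up", "gene_down"))
  table(isoform_cluster = ia$label,
        gene_state = factor(state, levels = c("gene_up", "gene_down", "gene_ns")))
}
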