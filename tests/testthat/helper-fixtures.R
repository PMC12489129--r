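# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# minimal count matrix with a plain two-line, three-day design
make_cm <- function(counts, days = NULL, cell_line = NULL, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("f%02d", seq_len(nrow(counts)))
  n <- ncol(counts)
  if (is.null(days)) days <- rep(seq_len(max(n %/% 2, 1)) - 1, length.out = n)
  if (is.null(cell_line)) cell_line <- rep("line1", n)
  count_matrix(counts, data.frame(
    sample_id = colnames(counts), cell_line = cell_line, day = days,
    replicate = stats::ave(seq_len(n), interaction(cell_line, days),
                           FUN = seq_along)), lib_sizes = lib_sizes)
}

# NB counts for a flat (null) gene set under the standard 36-sample design
make_null_counts <- function(n_features, design = design_spec(), mu_log = log(200),
                             mu_sd = 1, alpha_mean = 0.05, alpha_shape = 4,
                             seed = 1) {
  set.seed(seed)
  smp <- design$samples
  mu <- rlnorm(n_features, mu_log, mu_sd)
  al <- rgamma(n_features, alpha_shape, alpha_shape / alpha_mean)
  cnt <- t(mapply(function(m, a) rnbinom(nrow(smp), size = 1 / a, mu = m), mu, al))
  dimnames(cnt) <- list(sprintf("g%05d", seq_len(n_features)), smp$sample_id)
  count_matrix(cnt, smp)
}

# brute-force union-find components over an edge list (oracle for igraph)
uf_components <- function(nodes, edges_a, edges_b) {
  parent <- setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_along(edges_a)) {
    ra <- find(edges_a[i]); rb <- find(edges_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  split(nodes, roots)
}

# z-score matrix rows (profile clustering operates on z-scored profiles)
zscore_rows <- function(m) {
  out <- t(apply(m, 1, function(v) {
    s <- sd(v)
    if (s > 0) (v - mean(v)) / s else v * 0
  }))
  dimnames(out) <- dimnames(m)
  out
}
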