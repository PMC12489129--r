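# Thresholded protein-interaction network from pairwise interface-confidence
# (iPTM) scores: pair enumeration, strict-threshold edges, connected
# components, homodimer detection.

#' Number of unordered protein pairs including self-pairs
#'
#' `n * (n + 1) / 2`: all pairwise interactions computed for a set of n
#' proteins when self-interactions (homodimer candidates) are included.
#'
#' @param n number of proteins (>= 1).
#' @return Integer pair count (1275 for n = 50).
#' @export
pair_count <- function(n) {
  if (any(n < 1) || any(n != round(n))) stop("n must be a positive integer")
  n * (n + 1) / 2
}

#' Symmetric pairwise interaction table
#'
#' Builds the symmetric iPTM matrix (diagonal included) from a long-form
#' pair table. Scores reported for both orderings of a pair are symmetrized
#' by the maximum, since direction-dependent predictions share one
#' threshold. Values must lie in [0, 1].
#'
#' @param pairs data.frame with columns `protein_a`, `protein_b`, `iptm`.
#' @return An `interaction_table`: list with `proteins` and `scores`
#'   (symmetric matrix).
#' @export
interaction_table <- function(pairs) {
  req <- c("protein_a", "protein_b", "iptm")
  miss <- setdiff(req, names(pairs))
  if (length(miss)) stop("pair table missing column(s): ", paste(miss, collapse = ", "))
  if (any(pairs$iptm < 0 | pairs$iptm > 1, na.rm = TRUE))
    stop("iPTM scores must lie in [0, 1]")
  prot <- sort(unique(c(pairs$protein_a, pairs$protein_b)))
  m <- matrix(NA_real_, length(prot), length(prot), dimnames = list(prot, prot))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$protein_a[i]; b <- pairs$protein_b[i]; s <- pairs$iptm[i]
    m[a, b] <- max(m[a, b], s, na.rm = TRUE)
    m[b, a] <- max(m[b, a], s, na.rm = TRUE)
  }
  if (anyNA(diag(m)))
    stop("self-pair score missing for: ",
         paste(head(prot[is.na(diag(m))], 5), collapse = ", "))
  m[is.na(m)] <- 0
  stopifnot(max(abs(m - t(m))) < 1e-9)
  structure(list(proteins = prot, scores = m), class = "interaction_table")
}

#' Threshold an interaction table into a network
#'
#' An edge joins two proteins iff their score strictly exceeds the
#' threshold; a self-loop above threshold marks a homodimer. Proteins with
#' no incident edge are dropped from the graph but listed.
#'
#' @param table an [interaction_table()].
#' @param threshold confidence cutoff (default 0.7, strict).
#' @return List of class `ppi_network`: `edges` (protein_a, protein_b,
#'   iptm; a <= b, self pairs included), `nodes` (retained), `homodimers`,
#'   `dropped`, `threshold`.
#' @export
threshold_network <- function(table, threshold = 0.7) {
  stopifnot(inherits(table, "interaction_table"))
  m <- table$scores
  idx <- which(upper.tri(m, diag = TRUE) & m > threshold, arr.ind = TRUE)
  edges <- data.frame(protein_a = rownames(m)[idx[, 1]],
                      protein_b = colnames(m)[idx[, 2]],
                      iptm = m[idx], stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  structure(list(edges = edges, nodes = nodes,
                 homodimers = edges$protein_a[edges$protein_a == edges$protein_b],
                 dropped = setdiff(table$proteins, nodes),
                 threshold = threshold), class = "ppi_network")
}

#' Connected components of a thresholded network
#'
#' Components over the non-self edges, plus singleton components for
#' proteins whose only confident interaction is with themselves; those are
#' flagged `homodimer_only`. Also reports whether each component is a
#' clique (every pair connected).
#'
#' @param net a [threshold_network()] result.
#' @return data.frame per component: `component`, `size`, `members`
#'   (semicolon-separated), `homodimer_only`, `is_clique`.
#' @export
network_components <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  e <- net$edges[net$edges$protein_a != net$edges$protein_b, , drop = FALSE]
  g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  if (length(net$nodes) == 0)
    return(data.frame(component = integer(0), size = integer(0),
                      members = character(0), homodimer_only = logical(0),
                      is_clique = logical(0)))
  comp <- igraph::components(g)
  res <- lapply(seq_len(comp$no), function(i) {
    members <- net$nodes[comp$membership == i]
    k <- length(members)
    n_edges <- sum(e$protein_a %in% members & e$protein_b %in% members)
    data.frame(component = i, size = k,
               members = paste(sort(members), collapse = ";"),
               homodimer_only = k == 1 && members %in% net$homodimers,
               is_clique = k == 1 || n_edges == k * (k - 1) / 2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
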