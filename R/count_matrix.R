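#' Isoform-by-sample count matrix with sample metadata
#'
#' Container for integer feature x sample counts plus per-sample metadata
#' (cell line, day, replicate) and library sizes. This is the common currency
#' of the pipeline: the synthetic generator produces it, the readers construct
#' it, and every analysis stage consumes it.
#'
#' @param counts integer matrix, features in rows, samples in columns; must
#'   carry unique row and column names.
#' @param samples data.frame with one row per sample and at least columns
#'   `sample_id`, `cell_line`, `day`, `replicate`. Row order must match the
#'   column order of `counts` (matched by `sample_id`).
#' @param lib_sizes optional positive numeric vector of library sizes, one per
#'   sample; defaults to column sums of `counts`.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `samples`, `lib_sizes`.
#' @examples
#' cm <- count_matrix(
#'   matrix(0:5, 2, 3, dimnames = list(c("t1", "t2"), c("s1", "s2", "s3"))),
#'   data.frame(sample_id = c("s1", "s2", "s3"), cell_line = "A",
#'              day = c(0, 1, 2), replicate = 1L)
#' )
#' dim(cm$counts)
#' @export
count_matrix <- function(counts, samples, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have row (feature) and column (sample) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop("non-integer count at feature '", rownames(counts)[bad[1]],
         "', sample '", colnames(counts)[bad[2]], "'")
  }
  storage.mode(counts) <- "double"  # integer-valued, double storage (counts can exceed .Machine$integer.max)

  req <- c("sample_id", "cell_line", "day", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("samples metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids in metadata")
  absent <- setdiff(colnames(counts), samples$sample_id)
  if (length(absent))
    stop("metadata missing sample(s): ", paste(absent, collapse = ", "))
  samples <- samples[match(colnames(counts), samples$sample_id),
                     setdiff(names(samples), "library_size"), drop = FALSE]
  rownames(samples) <- NULL

  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  lib_sizes <- as.numeric(lib_sizes)
  if (length(lib_sizes) != ncol(counts))
    stop("lib_sizes length must equal sample count")
  if (any(!is.finite(lib_sizes)) || any(lib_sizes <= 0))
    stop("lib_sizes must be positive and finite")
  names(lib_sizes) <- colnames(counts)

  structure(list(counts = counts, samples = samples, lib_sizes = lib_sizes),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts), "samples\n")
  cat("  cell lines:", paste(unique(x$samples$cell_line), collapse = ", "), "\n")
  cat("  days:", paste(sort(unique(x$samples$day)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by features and/or samples
#'
#' @param x a [count_matrix()].
#' @param features,samples character or logical/integer index of features /
#'   sample ids to keep; `NULL` keeps all.
#' @return A `count_matrix` restricted to the requested rows and columns.
#' @export
subset_counts <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  fi <- if (is.null(features)) seq_len(nrow(x$counts)) else features
  si <- if (is.null(samples)) seq_len(ncol(x$counts)) else samples
  cm <- x$counts[fi, si, drop = FALSE]
  count_matrix(cm, x$samples[match(colnames(cm), x$samples$sample_id), , drop = FALSE],
               x$lib_sizes[colnames(cm)])
}

#' Aggregate isoform counts to gene level
#'
#' Gene-level "aggregated RNA" counts are the per-sample sums over all member
#' isoforms of each gene.
#'
#' @param x a [count_matrix()] of isoform counts.
#' @param t2g transcript-to-gene map: data.frame with columns `transcript_id`
#'   and `gene_id` covering every feature of `x`.
#' @return A `count_matrix` with one row per gene.
#' @export
aggregate_to_genes <- function(x, t2g) {
  stopifnot(inherits(x, "count_matrix"))
  idx <- match(rownames(x$counts), t2g$transcript_id)
  if (anyNA(idx))
    stop("transcript(s) missing from transcript-to-gene map: ",
         paste(head(rownames(x$counts)[is.na(idx)], 5), collapse = ", "))
  g <- t2g$gene_id[idx]
  agg <- rowsum(x$counts, group = g, reorder = TRUE)
  count_matrix(agg, x$samples, x$lib_sizes)
}
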