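#' Read an isoform count matrix and its sample metadata
#'
#' Counts are a TSV with feature ids in the first column and one integer
#' column per sample; metadata is a TSV with columns `sample_id`, `cell_line`,
#' `day`, `replicate` and optionally `library_size`. Malformed input is
#' rejected, never repaired: duplicate ids, samples absent from the metadata
#' and non-integer cells are hard errors naming the offending record.
#'
#' @param path counts TSV path.
#' @param metadata_path sample metadata TSV path.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, metadata_path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("counts file needs a feature id column plus >=1 sample column")
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(tab[, -1, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)[1, ]
    stop("non-numeric count at feature '", ids[bad[1]], "', sample '",
         colnames(tab)[-1][bad[2]], "'")
  }
  if (any(m != round(m))) {
    bad <- which(m != round(m), arr.ind = TRUE)[1, ]
    stop("non-integer count at feature '", ids[bad[1]], "', sample '",
         colnames(m)[bad[2]], "'")
  }
  rownames(m) <- ids
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
  lib <- if ("library_size" %in% names(meta))
    meta$library_size[match(colnames(m), meta$sample_id)] else NULL
  count_matrix(m, meta, lib)
}

#' Write a count matrix (and optionally its metadata) as TSV
#'
#' @param x a [count_matrix()].
#' @param path counts TSV destination.
#' @param metadata_path optional metadata TSV destination (includes
#'   `library_size`).
#' @return Invisibly, `path`.
#' @export
write_counts <- function(x, path, metadata_path = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  tab <- data.frame(feature_id = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path)) {
    meta <- x$samples
    meta$library_size <- unname(x$lib_sizes)
    write.table(meta, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write counts in MatrixMarket form
#'
#' The MatrixMarket alternative stores the counts as `<prefix>.mtx` with
#' feature ids in `<prefix>.features.tsv` and sample ids in
#' `<prefix>.samples.tsv` (one id per line, no header).
#'
#' @param prefix path prefix for the three files.
#' @param metadata_path sample metadata TSV (as in [read_counts()]).
#' @return `read_counts_mtx`: a [count_matrix()]; `write_counts_mtx`:
#'   invisibly, `prefix`.
#' @export
read_counts_mtx <- function(prefix, metadata_path) {
  mtx <- paste0(prefix, ".mtx")
  if (!file.exists(mtx)) stop("matrix file not found: ", mtx)
  m <- as.matrix(Matrix::readMM(mtx))
  rn <- readLines(paste0(prefix, ".features.tsv"))
  cn <- readLines(paste0(prefix, ".samples.tsv"))
  if (length(rn) != nrow(m) || length(cn) != ncol(m))
    stop("feature/sample id files do not match matrix dimensions")
  dimnames(m) <- list(rn, cn)
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
  lib <- if ("library_size" %in% names(meta))
    meta$library_size[match(cn, meta$sample_id)] else NULL
  count_matrix(m, meta, lib)
}

#' @rdname read_counts_mtx
#' @param x a [count_matrix()].
#' @export
write_counts_mtx <- function(x, prefix) {
  stopifnot(inherits(x, "count_matrix"))
  Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), paste0(prefix, ".mtx"))
  writeLines(rownames(x$counts), paste0(prefix, ".features.tsv"))
  writeLines(colnames(x$counts), paste0(prefix, ".samples.tsv"))
  invisible(prefix)
}

#' Read / write a transcript-to-gene map
#'
#' Two-column TSV (`transcript_id`, `gene_id`).
#'
#' @param path TSV path.
#' @return A data.frame with columns `transcript_id`, `gene_id`.
#' @export
read_t2g <- function(path) {
  t2g <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "gene_id") %in% names(t2g)))
    stop("transcript-to-gene map needs columns transcript_id and gene_id")
  if (anyDuplicated(t2g$transcript_id))
    stop("duplicate transcript ids in transcript-to-gene map")
  t2g[, c("transcript_id", "gene_id")]
}

#' @rdname read_t2g
#' @param t2g the map to write.
#' @export
write_t2g <- function(t2g, path) {
  write.table(t2g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- transcript models (GTF) ------------------------------------------------

#' Validate an exon table of transcript models
#'
#' A transcript model set is a data.frame with one row per exon and columns
#' `transcript_id`, `gene_id`, `chrom`, `strand` (+/-), `start`, `end`
#' (1-based inclusive). Exons of a transcript must be non-overlapping; they
#' are sorted by genomic coordinate on construction so downstream code can
#' rely on the order.
#'
#' @param df exon table.
#' @return The validated, sorted table with class `transcript_models`.
#' @export
transcript_models <- function(df) {
  req <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("exon table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("unknown strand value(s): ",
         paste(unique(df$strand[!df$strand %in% c("+", "-")]), collapse = ", "))
  if (any(df$end < df$start)) {
    i <- which(df$end < df$start)[1]
    stop("exon end < start for transcript '", df$transcript_id[i], "'")
  }
  df <- df[order(df$transcript_id, df$start), req, drop = FALSE]
  rownames(df) <- NULL
  by_tx <- split(seq_len(nrow(df)), df$transcript_id)
  for (idx in by_tx) {
    if (length(idx) > 1) {
      s <- df$start[idx]; e <- df$end[idx]
      if (any(s[-1] <= e[-length(e)]))
        stop("overlapping exons in transcript '", df$transcript_id[idx[1]], "'")
      if (length(unique(df$strand[idx])) > 1 || length(unique(df$chrom[idx])) > 1)
        stop("transcript '", df$transcript_id[idx[1]], "' mixes chrom or strand")
    }
  }
  class(df) <- c("transcript_models", "data.frame")
  df
}

#' Read transcript models from a GTF file
#'
#' Parses 9-column GTF exon records (1-based inclusive coordinates) into a
#' [transcript_models()] exon table. Records failing basic structure checks
#' (end < start, unknown strand) are rejected with the offending line number.
#'
#' @param path GTF path.
#' @return A `transcript_models` exon table.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  # pre-validate raw lines so errors can carry line numbers
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9)
      stop("GTF line ", i, ": expected 9 tab-separated fields, got ", length(f))
    if (f[3] != "exon") next
    s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e)) stop("GTF line ", i, ": non-numeric coordinates")
    if (e < s) stop("GTF line ", i, ": end < start")
    if (!f[7] %in% c("+", "-")) stop("GTF line ", i, ": unknown strand '", f[7], "'")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) stop("no exon records in ", path)
  if (is.null(gr$transcript_id) || is.null(gr$gene_id) ||
      anyNA(gr$transcript_id) || anyNA(gr$gene_id))
    stop("GTF exon records must carry transcript_id and gene_id attributes")
  transcript_models(data.frame(
    transcript_id = gr$transcript_id,
    gene_id = gr$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  ))
}

#' Write transcript models to a GTF file
#'
#' @param tm a [transcript_models()] exon table.
#' @param path destination GTF path.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(tm, path) {
  tm <- transcript_models(tm)
  gr <- GenomicRanges::GRanges(
    seqnames = tm$chrom,
    ranges = IRanges::IRanges(tm$start, tm$end),
    strand = tm$strand
  )
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$source <- "myotime"
  S4Vectors::mcols(gr)$gene_id <- tm$gene_id
  S4Vectors::mcols(gr)$transcript_id <- tm$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Splice junctions of each transcript
#'
#' A junction is represented as (last base of the upstream exon, first base of
#' the downstream exon) in genomic 1-based inclusive coordinates, keyed as
#' `"chrom:strand:end-start"`. Mono-exonic transcripts have an empty chain.
#'
#' @param tm a [transcript_models()] exon table.
#' @return Named list mapping transcript_id to a character vector of junction
#'   keys ordered by genomic coordinate.
#' @export
junction_chains <- function(tm) {
  tm <- transcript_models(tm)
  out <- lapply(split(tm, tm$transcript_id), function(d) {
    n <- nrow(d)
    if (n < 2) return(character(0))
    paste0(d$chrom[1], ":", d$strand[1], ":", d$end[-n], "-", d$start[-1])
  })
  out[unique(tm$transcript_id)]
}

#' Build a reference junction catalog
#'
#' @param tm reference [transcript_models()].
#' @return Character vector of unique junction keys, class `junction_catalog`.
#' @export
junction_catalog <- function(tm) {
  structure(sort(unique(unlist(junction_chains(tm), use.names = FALSE))),
            class = "junction_catalog")
}

# ---- gene sets (GMT) --------------------------------------------------------

#' Read gene sets from a GMT file
#'
#' Each line is `name<TAB>description<TAB>member...`. Duplicate members within
#' a set are collapsed (with a message); duplicate set names and empty member
#' lists are errors.
#'
#' @param path GMT path.
#' @return Named list of unique gene-id character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  nfield <- lengths(strsplit(readLines(path), "\t", fixed = TRUE))
  if (any(nfield < 3))
    stop("GMT line ", which(nfield < 3)[1], ": fewer than 3 tab-separated fields")
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set name(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(m) m[nzchar(m)])
  if (any(lengths(sets) == 0))
    stop("gene set with empty member list: ",
         paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  ndup <- sum(lengths(sets)) - sum(lengths(lapply(sets, unique)))
  if (ndup > 0) message(ndup, " duplicate member(s) collapsed")
  lapply(sets, unique)
}

#' @rdname read_gmt
#' @param sets named list of gene-id vectors.
#' @export
write_gmt <- function(sets, path) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("gene sets must be named")
  writeLines(vapply(names(sets), function(n)
    paste(c(n, "na", sets[[n]]), collapse = "\t"), character(1)), path)
  invisible(path)
}

# ---- confidence tables ------------------------------------------------------

#' Read a per-isoform coding-confidence table
#'
#' TSV with columns `transcript_id`, `has_orf` (0/1 or logical),
#' `orf_matches_known` (0/1 or logical), `mean_plddt`. pLDDT values on the
#' 0-100 scale are normalized to [0, 1] by dividing by 100.
#'
#' @param path TSV path.
#' @return data.frame with normalized `mean_plddt`.
#' @export
read_confidence <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("transcript_id", "has_orf", "orf_matches_known", "mean_plddt")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("confidence table missing column(s): ", paste(miss, collapse = ", "))
  tab$has_orf <- as.logical(tab$has_orf)
  tab$orf_matches_known <- as.logical(tab$orf_matches_known)
  over <- !is.na(tab$mean_plddt) & tab$mean_plddt > 1
  tab$mean_plddt[over] <- tab$mean_plddt[over] / 100
  if (any(tab$mean_plddt < 0 | tab$mean_plddt > 1, na.rm = TRUE))
    stop("mean_plddt outside [0,1] after normalization")
  tab
}

#' Read a pairwise interaction-confidence (iPTM) table
#'
#' Long-form TSV with columns `protein_a`, `protein_b`, `iptm`. Scores for the
#' two orderings of a pair are symmetrized by the maximum; self pairs are
#' allowed and mark potential homodimers.
#'
#' @param path TSV path.
#' @return An `interaction_table` (see [interaction_table()]).
#' @export
read_iptm <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("protein_a", "protein_b", "iptm")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("iPTM table missing column(s): ", paste(miss, collapse = ", "))
  interaction_table(tab)
}
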