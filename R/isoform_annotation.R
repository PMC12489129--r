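# Structural categorization of assembled transcripts against a reference
# splice-junction catalog, and coding-confidence triage of novel isoforms.

#' Classify transcripts against a reference catalog
#'
#' Junction-chain classification: a multi-exon query is a full splice match
#' (FSM) when its junction chain is identical to a reference transcript on
#' the same strand; novel in catalog (NIC) when all its junctions are in the
#' catalog but the chain matches no reference; novel not in catalog (NNC)
#' when at least one junction is absent from the catalog. Mono-exonic
#' queries overlapping a mono-exonic reference exon on the same chromosome
#' and strand are `mono_exon_match`; anything else (including queries on
#' chromosomes absent from the reference) is `other` and flagged. Exon
#' input order does not matter.
#'
#' @param query a [transcript_models()] exon table of queries.
#' @param reference reference [transcript_models()].
#' @param catalog optional [junction_catalog()] (defaults to the reference's
#'   own junctions).
#' @return data.frame per query transcript: `transcript_id`, `category`,
#'   `matched_reference` (FSM only), `novel_junctions`
#'   (semicolon-separated, NNC only), `flagged`.
#' @export
classify_transcripts <- function(query, reference, catalog = NULL) {
  query <- transcript_models(query)
  reference <- transcript_models(reference)
  if (is.null(catalog)) catalog <- junction_catalog(reference)
  q_chain <- junction_chains(query)
  r_chain <- junction_chains(reference)
  chain_key <- vapply(r_chain, paste, character(1), collapse = "|")
  ref_by_chain <- split(names(r_chain), chain_key)
  ref_info <- unique(reference[, c("transcript_id", "chrom", "strand")])
  mono_ref <- reference[!reference$transcript_id %in%
                          names(r_chain)[lengths(r_chain) > 0], , drop = FALSE]
  ref_chroms <- unique(reference$chrom)
  q_info <- unique(query[, c("transcript_id", "chrom", "strand")])
  res <- lapply(q_info$transcript_id, function(tx) {
    chain <- q_chain[[tx]]
    info <- q_info[q_info$transcript_id == tx, ]
    if (!info$chrom %in% ref_chroms)
      return(data.frame(transcript_id = tx, category = "other",
                        matched_reference = NA_character_,
                        novel_junctions = NA_character_, flagged = TRUE,
                        stringsAsFactors = FALSE))
    if (length(chain) == 0) {
      ex <- query[query$transcript_id == tx, ]
      hit <- mono_ref$chrom == ex$chrom[1] & mono_ref$strand == ex$strand[1] &
        mono_ref$start <= ex$end[1] & mono_ref$end >= ex$start[1]
      cat_ <- if (any(hit)) "mono_exon_match" else "other"
      return(data.frame(transcript_id = tx, category = cat_,
                        matched_reference = NA_character_,
                        novel_junctions = NA_character_, flagged = FALSE,
                        stringsAsFactors = FALSE))
    }
    key <- paste(chain, collapse = "|")
    hit <- ref_by_chain[[key]]
    if (!is.null(hit)) {
      # junction keys embed chrom and strand, so a chain match is same-strand
      return(data.frame(transcript_id = tx, category = "FSM",
                        matched_reference = hit[1],
                        novel_junctions = NA_character_, flagged = FALSE,
                        stringsAsFactors = FALSE))
    }
    novel <- setdiff(chain, catalog)
    if (length(novel))
      data.frame(transcript_id = tx, category = "NNC",
                 matched_reference = NA_character_,
                 novel_junctions = paste(novel, collapse = ";"),
                 flagged = FALSE, stringsAsFactors = FALSE)
    else
      data.frame(transcript_id = tx, category = "NIC",
                 matched_reference = NA_character_,
                 novel_junctions = NA_character_, flagged = FALSE,
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Coding-confidence triage of transcripts
#'
#' A transcript whose ORF matches a known protein is `known_coding`
#' regardless of its structure-prediction confidence; other ORF-bearing
#' transcripts are `high_confidence_coding` when mean pLDDT strictly exceeds
#' the threshold (scores on the 0-100 scale are divided by 100 first) and
#' `low_confidence_coding` otherwise or when the score is missing (flagged);
#' transcripts without an ORF are `noncoding`.
#'
#' @param confidence per-isoform table with columns `transcript_id`,
#'   `has_orf`, `orf_matches_known`, `mean_plddt` (see [read_confidence()]).
#' @param threshold pLDDT threshold on the 0-1 scale (default 0.7, strict
#'   inequality).
#' @return data.frame `transcript_id`, `triage`, `mean_plddt`,
#'   `missing_plddt`.
#' @export
coding_triage <- function(confidence, threshold = 0.7) {
  req <- c("transcript_id", "has_orf", "orf_matches_known", "mean_plddt")
  miss <- setdiff(req, names(confidence))
  if (length(miss)) stop("confidence table missing column(s): ", paste(miss, collapse = ", "))
  pl <- confidence$mean_plddt
  over <- !is.na(pl) & pl > 1
  pl[over] <- pl[over] / 100
  if (any(pl < 0 | pl > 1, na.rm = TRUE))
    stop("mean_plddt outside [0,1] after normalization")
  missing_pl <- confidence$has_orf & !confidence$orf_matches_known & is.na(pl)
  triage <- ifelse(!confidence$has_orf, "noncoding",
            ifelse(confidence$orf_matches_known, "known_coding",
            ifelse(!is.na(pl) & pl > threshold, "high_confidence_coding",
                   "low_confidence_coding")))
  data.frame(transcript_id = confidence$transcript_id, triage = triage,
             mean_plddt = pl, missing_plddt = missing_pl,
             stringsAsFactors = FALSE)
}

#' Counts of structural category and coding triage per temporal cluster
#'
#' @param calls [classify_transcripts()] output.
#' @param triage [coding_triage()] output.
#' @param assignments isoform-level cluster assignments (`feature_id`,
#'   `label`), or a `cluster_assignment`.
#' @return data.frame of counts per (cluster label, category, triage); cell
#'   counts sum to the number of classified transcripts present in the
#'   assignments.
#' @export
category_summary <- function(calls, triage, assignments) {
  a <- if (inherits(assignments, "cluster_assignment")) assignments$assignments else assignments
  d <- merge(merge(a[, c("feature_id", "label")], calls,
                   by.x = "feature_id", by.y = "transcript_id"),
             triage[, c("transcript_id", "triage")],
             by.x = "feature_id", by.y = "transcript_id")
  out <- as.data.frame(table(cluster = d$label, category = d$category,
                             triage = d$triage), stringsAsFactors = FALSE)
  names(out)[4] <- "count"
  out[out$count > 0 | TRUE, ]
}
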