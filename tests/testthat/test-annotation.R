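# hand-built reference: gene with exons E1..E6 (100 bp, 100 bp gaps) on chr1+
exon_ladder <- function(n = 6, off = 1000) {
  start <- off + (seq_len(n) - 1) * 200
  cbind(start = start, end = start + 99)
}

make_tx <- function(id, exons, gene = "g1", chrom = "chr1", strand = "+") {
  data.frame(transcript_id = id, gene_id = gene, chrom = chrom,
             strand = strand, start = exons[, "start"], end = exons[, "end"],
             stringsAsFactors = FALSE)
}

test_that("junction-chain classification separates FSM, NIC and NNC by hand", {
  ex <- exon_ladder()
  refA <- make_tx("refA", ex[1:4, ])   # junctions J1 J2 J3
  refB <- make_tx("refB", ex[3:6, ])   # junctions J3 J4 J5
  reference <- transcript_models(rbind(refA, refB))
  # exact chain: FSM with the matching id
  q_fsm <- make_tx("q1", ex[1:4, ])
  # combination of cataloged junctions from both references: NIC
  q_nic <- make_tx("q2", ex[2:5, ])    # J2 J3 J4, all cataloged, no ref chain
  # skipping an internal exon creates a novel junction: NNC
  q_nnc <- make_tx("q3", ex[c(1, 3, 4), ])
  calls <- classify_transcripts(rbind(q_fsm, q_nic, q_nnc), reference)
  expect_equal(calls$category[calls$transcript_id == "q1"], "FSM")
  expect_equal(calls$matched_reference[calls$transcript_id == "q1"], "refA")
  expect_equal(calls$category[calls$transcript_id == "q2"], "NIC")
  expect_equal(calls$category[calls$transcript_id == "q3"], "NNC")
  expect_equal(calls$novel_junctions[calls$transcript_id == "q3"],
               paste0("chr1:+:", ex[1, "end"], "-", ex[3, "start"]))
  # mutual exclusivity: exactly one category per transcript
  expect_equal(anyDuplicated(calls$transcript_id), 0)
})

test_that("mono-exonic and off-reference queries are handled", {
  ex <- exon_ladder()
  reference <- transcript_models(rbind(make_tx("refA", ex[1:4, ]),
                                       make_tx("refM", ex[2, , drop = FALSE])))
  q_mono <- make_tx("qm", cbind(start = ex[2, "start"] + 10,
                                end = ex[2, "end"] + 40))
  q_far <- make_tx("qf", cbind(start = 99000, end = 99100))
  q_chr <- make_tx("qc", ex[1:2, ], chrom = "chrX")
  calls <- classify_transcripts(rbind(q_mono, q_far, q_chr), reference)
  expect_equal(calls$category[calls$transcript_id == "qm"], "mono_exon_match")
  expect_equal(calls$category[calls$transcript_id == "qf"], "other")
  expect_equal(calls$category[calls$transcript_id == "qc"], "other")
  expect_true(calls$flagged[calls$transcript_id == "qc"])
})

test_that("classification ignores exon record order", {
  ex <- exon_ladder()
  reference <- transcript_models(make_tx("refA", ex[1:4, ]))
  q <- make_tx("q1", ex[1:4, ])
  shuffled <- q[c(3, 1, 4, 2), ]
  expect_equal(classify_transcripts(q, reference),
               classify_transcripts(shuffled, reference))
})

test_that("recovered categories equal generator truth exactly", {
  ann <- simulate_annotation(60, novel_fraction = 0.4, seed = 81)
  calls <- classify_transcripts(ann$query, ann$reference, ann$catalog)
  m <- merge(calls, ann$truth, by = "transcript_id")
  expect_equal(m$category.x, m$category.y)
})

test_that("coding triage applies known-match precedence and the strict threshold", {
  conf <- data.frame(
    transcript_id = paste0("t", 1:5),
    has_orf = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    orf_matches_known = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    mean_plddt = c(0.2, 0.9, 0.7, NA, NA))
  tri <- coding_triage(conf, threshold = 0.7)
  expect_equal(tri$triage,
               c("known_coding",           # match dominates low confidence
                 "high_confidence_coding", # 0.9 > 0.7
                 "low_confidence_coding",  # exactly 0.7: strict inequality
                 "low_confidence_coding",  # missing score, flagged
                 "noncoding"))
  expect_true(tri$missing_plddt[4])
  # 0-100 inputs are normalized before thresholding
  conf$mean_plddt <- c(20, 90, 70, NA, NA)
  expect_equal(coding_triage(conf)$triage, tri$triage)
  conf$mean_plddt <- c(20, 90, 70, 150, NA)
  expect_error(coding_triage(conf), "outside")
})

test_that("category summaries conserve totals against a brute-force recount", {
  ann <- simulate_annotation(40, novel_fraction = 0.5, seed = 82)
  calls <- classify_transcripts(ann$query, ann$reference, ann$catalog)
  sim <- simulate_confidence_tables(calls$transcript_id, seed = 82)
  tri <- coding_triage(sim$confidence)
  set.seed(83)
  assign <- data.frame(feature_id = calls$transcript_id,
                       cluster = 1,
                       label = sample(c("Up", "Down"), nrow(calls), TRUE))
  tab <- category_summary(calls, tri, assign)
  expect_equal(sum(tab$count), nrow(calls))
  for (i in sample(nrow(tab), 10)) {
    expect_equal(tab$count[i], sum(
      assign$label == tab$cluster[i] &
        calls$category == tab$category[i] &
        tri$triage == tab$triage[i]))
  }
})
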