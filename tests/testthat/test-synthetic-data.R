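test_that("design grid is balanced and sized as cell lines x days x replicates", {
  d <- design_spec()
  expect_equal(nrow(d$samples), 36)
  tab <- table(d$samples$cell_line, d$samples$day)
  expect_true(all(tab == 3))
  d2 <- design_spec(n_cell_lines = 3, days = 0:2, replicates = 2)
  expect_equal(nrow(d2$samples), 18)
})

test_that("planted isoform proportions sum to one at every condition", {
  tr <- simulate_truth(80, seed = 4)
  for (day in tr$days) {
    sums <- tapply(seq_len(nrow(tr$isoforms)), tr$isoforms$gene_id, function(i) {
      p <- myotime:::.pi_at_day(tr$isoforms$pi0[i], tr$isoforms$pi1[i], day)
      sum(p)
    })
    expect_true(all(abs(sums - 1) < 1e-12))
  }
  expect_true(all(tr$genes$mu > 0))
  expect_true(all(tr$genes$alpha >= 0))
})

test_that("fixed seeds reproduce counts, annotation and confidence bitwise", {
  d <- design_spec()
  tr <- simulate_truth(30, d, seed = 7)
  expect_identical(simulate_counts(d, tr), simulate_counts(d, tr))
  f1 <- tempfile(); f2 <- tempfile()
  write_gtf(simulate_annotation(10, seed = 7)$query, f1)
  write_gtf(simulate_annotation(10, seed = 7)$query, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(simulate_confidence_tables(letters, seed = 3),
                   simulate_confidence_tables(letters, seed = 3))
})

test_that("zero-dispersion counts match the closed-form Poisson mean", {
  # one gene, flat trajectory, fixed proportions, many replicates
  d <- design_spec(n_cell_lines = 1, days = 0:1, replicates = 5000,
                   library_size_cv = 0)
  tr <- simulate_truth(1, d, isoform_count_law = c(0, 1, 0, 0, 0),
                       dtu_fraction = 0, amplitude = 0,
                       label_probs = c(Down = 1), dispersion_mean = 1e-12,
                       batch_sd = 0, gamma = Inf, seed = 2)
  tr$genes$alpha <- 0
  tr$trajectories[] <- 0
  cm <- simulate_counts(d, tr)
  expected <- tr$genes$mu * tr$isoforms$pi0
  observed <- rowMeans(cm$counts)
  expect_true(all(abs(observed / expected - 1) < 0.01))
})

test_that("a planted early-up gene shows the planted day1/day0 fold change", {
  d <- design_spec(n_cell_lines = 1, days = 0:5, replicates = 500,
                   library_size_cv = 0)
  tr <- simulate_truth(1, d, isoform_count_law = c(1, 0, 0, 0, 0),
                       dtu_fraction = 0, amplitude = 2,
                       label_probs = c(EarlyUp = 1), dispersion_mean = 0.05,
                       batch_sd = 0, seed = 11)
  cm <- simulate_counts(d, tr)
  m1 <- mean(cm$counts[, cm$samples$day == 1])
  m0 <- mean(cm$counts[, cm$samples$day == 0])
  expect_lt(abs(m1 / m0 - 4), 0.4)  # +2 log2FC at day 1, within 10%
})

test_that("negative-binomial draws are overdispersed when alpha > 0", {
  d <- design_spec(n_cell_lines = 1, days = 0:1, replicates = 5000,
                   library_size_cv = 0)
  tr <- simulate_truth(1, d, isoform_count_law = c(1, 0, 0, 0, 0),
                       amplitude = 0, label_probs = c(Down = 1),
                       dispersion_mean = 0.3, dispersion_shape = 1e6,
                       batch_sd = 0, seed = 3)
  tr$trajectories[] <- 0
  y <- as.numeric(simulate_counts(d, tr)$counts)
  expect_gt(var(y), mean(y))
})

test_that("annotation generator splits novelty as planted and validates input", {
  ann0 <- simulate_annotation(15, novel_fraction = 0, seed = 1)
  expect_true(all(ann0$truth$category == "FSM"))
  ann <- simulate_annotation(80, novel_fraction = 0.5, seed = 9)
  n_novel <- sum(ann$truth$novel)
  n_tx <- nrow(ann$truth)
  # planted novelty count within the binomial(n, 0.5) 99% interval
  ci <- qbinom(c(0.005, 0.995), n_tx, 0.5)
  expect_gte(n_novel, ci[1]); expect_lte(n_novel, ci[2])
  expect_setequal(unique(ann$truth$category[ann$truth$novel]), c("NIC", "NNC"))
  # catalog contains exactly the junctions of non-novel transcripts
  ref_j <- sort(unique(unlist(junction_chains(ann$reference))))
  expect_identical(as.character(ann$catalog), ref_j)
  expect_error(simulate_annotation(0), "n_genes")
  expect_error(simulate_annotation(5, novel_fraction = 1.2), "novel_fraction")
})

test_that("confidence tables carry symmetric scores and planted structure", {
  sim <- simulate_confidence_tables(sprintf("t%02d", 1:30),
                                    high_conf_fraction = 1, seed = 5)
  tab <- interaction_table(sim$iptm)
  expect_identical(tab$scores, t(tab$scores))
  tri <- coding_triage(sim$confidence)
  novel_orf <- sim$confidence$has_orf & !sim$confidence$orf_matches_known
  expect_true(all(tri$triage[novel_orf] == "high_confidence_coding"))
  comps <- network_components(threshold_network(tab, 0.7))
  expect_equal(nrow(comps), 3)  # two planted cliques + one homodimer
  expect_equal(sum(comps$homodimer_only), 1)
  expect_error(simulate_confidence_tables("a", known_fraction = 2), "fractions")
})
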