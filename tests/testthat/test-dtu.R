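# constructed two-isoform count matrix exercising the filter boundaries
make_filter_cm <- function(iso1_counts, iso2_counts = 50) {
  d <- design_spec()
  cnt <- rbind(gA_i1 = iso1_counts, gA_i2 = iso2_counts,
               gB_i1 = 40, gB_i2 = 40)
  cnt <- matrix(cnt, 4, 36, dimnames = list(
    c("gA_i1", "gA_i2", "gB_i1", "gB_i2"), d$samples$sample_id))
  list(cm = count_matrix(cnt, d$samples),
       t2g = data.frame(transcript_id = rownames(cnt),
                        gene_id = rep(c("gA", "gB"), each = 2)))
}

test_that("the usage filter applies its six thresholds at the boundaries", {
  # isoform at count 5 in exactly 18 of 36 samples, proportion fine: kept
  x <- make_filter_cm(c(rep(5, 18), rep(0, 18)))
  flt <- filter_features(x$cm, x$t2g)
  expect_true("gA_i1" %in% rownames(flt$counts$counts))
  # expressed in only 17 samples: removed with the expression rule named
  x17 <- make_filter_cm(c(rep(5, 17), rep(0, 19)))
  flt17 <- filter_features(x17$cm, x17$t2g)
  expect_false("gA_i1" %in% rownames(flt17$counts$counts))
  expect_equal(flt17$report$rule[flt17$report$feature_id == "gA_i1"],
               "min_samples_feature_expr")
  # a gene reduced to one surviving isoform is dropped entirely
  expect_equal(sort(flt17$report$feature_id),
               c("gA_i1", "gA_i2"))
  expect_equal(flt17$report$rule[flt17$report$feature_id == "gA_i2"],
               "lt2_isoforms")
  # proportion rule: isoform at 2% proportion everywhere fails it
  xp <- make_filter_cm(6, iso2_counts = 400)
  fltp <- filter_features(xp$cm, xp$t2g)
  expect_equal(fltp$report$rule[fltp$report$feature_id == "gA_i1"],
               "min_samples_feature_prop")
  # idempotence
  again <- filter_features(flt$counts, x$t2g)
  expect_equal(rownames(again$counts$counts), rownames(flt$counts$counts))
  expect_equal(nrow(again$report), 0)
  # an empty post-filter set is an error, not an empty object
  d <- design_spec()
  low <- matrix(3, 4, 36, dimnames = list(
    c("gA_i1", "gA_i2", "gB_i1", "gB_i2"), d$samples$sample_id))
  cm_low <- count_matrix(low, d$samples)
  expect_error(filter_features(cm_low, data.frame(
    transcript_id = rownames(low), gene_id = rep(c("gA", "gB"), each = 2))),
    "no isoform survives")
})

test_that("Dirichlet-multinomial fits respect symmetry and known limits", {
  y <- matrix(c(30, 30), 2, 10, dimnames = list(c("i1", "i2"), NULL))
  fit <- fit_dm(y)
  expect_equal(unname(fit$pi[1, ]), c(0.5, 0.5), tolerance = 1e-6)
  # multinomial data (gamma -> Inf): pi-hat equals pooled count fractions
  set.seed(61)
  ym <- sapply(1:40, function(j) rmultinom(1, 500, c(0.3, 0.2, 0.5)))
  rownames(ym) <- paste0("i", 1:3)
  fm <- fit_dm(ym)
  pooled <- rowSums(ym) / sum(ym)
  expect_true(all(abs(fm$pi[1, ] - pooled) < 1e-3))
  expect_gt(fm$gamma, 500)  # near-multinomial: very large precision
  # planted pi and moderate precision at 18 samples
  set.seed(62)
  yd <- sapply(1:18, function(j) {
    p <- rgamma(2, 50 * c(0.2, 0.8)); p <- p / sum(p)
    rmultinom(1, rnbinom(1, mu = 300, size = 20), p)
  })
  rownames(yd) <- c("i1", "i2")
  fd <- fit_dm(yd)
  expect_true(all(abs(fd$pi[1, ] - c(0.2, 0.8)) < 0.05))
  # zero-total samples are excluded and reported
  yz <- cbind(y, c(0, 0)); colnames(yz) <- paste0("s", 1:11)
  expect_identical(fit_dm(yz)$excluded_samples, "s11")
  expect_error(fit_dm(y[1, , drop = FALSE]), ">= 2 isoforms")
})

test_that("the usage test is calibrated under the null and blind to line-only shifts", {
  d <- design_spec()
  # null: proportions constant over days
  tr <- simulate_truth(120, d, isoform_count_law = c(0, 1, 0, 0, 0),
                       dtu_fraction = 0, seed = 63)
  cm <- simulate_counts(d, tr)
  t2g <- tr$isoforms[, c("transcript_id", "gene_id")]
  u <- test_usage(filter_features(cm, t2g)$counts, t2g)
  pg <- u$genes$p_screen
  expect_lt(mean(pg < 0.05, na.rm = TRUE), 0.1)
  expect_gt(suppressWarnings(ks.test(unique(u$isoforms$p), "punif")$p.value), 0.01)
  # cell-line-only proportion shift: the covariate absorbs it
  set.seed(64)
  smp <- d$samples
  line2 <- smp$cell_line == "line2"
  cnt <- matrix(0, 60, 36, dimnames = list(
    paste0(rep(sprintf("g%02d", 1:30), each = 2), "_i", 1:2), smp$sample_id))
  for (g in 1:30) for (j in 1:36) {
    p1 <- if (line2[j]) 0.65 else 0.45
    pj <- rgamma(2, 50 * c(p1, 1 - p1)); pj <- pj / sum(pj)
    cnt[(2 * g - 1):(2 * g), j] <- rmultinom(1, rnbinom(1, mu = 250, size = 20), pj)
  }
  cml <- count_matrix(cnt, smp)
  t2gl <- data.frame(transcript_id = rownames(cnt),
                     gene_id = rep(sprintf("g%02d", 1:30), each = 2))
  ul <- test_usage(filter_features(cml, t2gl)$counts, t2gl)
  expect_lte(mean(ul$genes$p_screen < 0.05, na.rm = TRUE), 0.15)
})

test_that("planted usage switches are screened with high power", {
  d <- design_spec()
  tr <- simulate_truth(60, d, isoform_count_law = c(0, 1, 0, 0, 0),
                       dtu_fraction = 0.5, dtu_swap = 0.4, seed = 65)
  cm <- simulate_counts(d, tr)
  t2g <- tr$isoforms[, c("transcript_id", "gene_id")]
  res <- dtu(cm, t2g)
  true_g <- tr$genes$gene_id[tr$genes$dtu]
  scr <- res$genes$gene_id[res$genes$screened]
  expect_gte(length(intersect(scr, true_g)) / length(true_g), 0.85)
})

test_that("stage-wise decisions follow the two-stage hand computation", {
  # all p = 1: nothing screened, nothing confirmed
  u0 <- list(genes = data.frame(gene_id = c("g1", "g2"), p_screen = c(1, 1),
                                n_isoforms = 2, flagged = FALSE),
             isoforms = data.frame(transcript_id = paste0("t", 1:4),
                                   gene_id = rep(c("g1", "g2"), each = 2),
                                   p = 1, converged = TRUE))
  r0 <- stagewise_adjust(u0)
  expect_equal(sum(r0$genes$screened), 0)
  expect_equal(sum(r0$isoforms$confirmed), 0)
  # one overwhelming gene among nulls: screened and its isoform confirmed
  g <- sprintf("g%02d", 1:20)
  u1 <- list(genes = data.frame(gene_id = g,
                                p_screen = c(1e-10, runif(19, 0.3, 1)),
                                n_isoforms = 3, flagged = FALSE),
             isoforms = data.frame(
               transcript_id = paste0(rep(g, each = 3), "_i", 1:3),
               gene_id = rep(g, each = 3),
               p = c(1e-10, 0.8, 0.9, runif(57, 0.3, 1)), converged = TRUE))
  r1 <- stagewise_adjust(u1, alpha = 0.05)
  expect_true(r1$genes$screened[1])
  expect_equal(sum(r1$genes$screened), 1)
  # stage II level: R*alpha/G = 1 * 0.05 / 20 = 0.0025; Holm p = 3e-10 passes
  expect_equal(r1$alpha_adj, 0.05 / 20)
  expect_true(r1$isoforms$confirmed[1])
  expect_equal(sum(r1$isoforms$confirmed), 1)
  # confirmation never escapes screened genes
  expect_true(all(r1$isoforms$gene_id[r1$isoforms$confirmed] %in%
                    r1$genes$gene_id[r1$genes$screened]))
})

test_that("usage proportions are exact per sample and sum to one per day", {
  d <- design_spec(days = 0:2, replicates = 1)
  cnt <- matrix(c(30, 70, 10, 90, 50, 50), 2,
                dimnames = list(c("g1_i1", "g1_i2"), d$samples$sample_id[1:3]))
  cm <- count_matrix(cnt, d$samples[1:3, ])
  t2g <- data.frame(transcript_id = rownames(cnt), gene_id = "g1")
  up <- usage_proportions(cm, t2g)
  expect_equal(unname(up$per_day["g1_i1", ]), c(0.3, 0.1, 0.5))
  sums <- rowsum(up$per_day, t2g$gene_id)
  expect_true(all(abs(sums - 1) < 1e-12))
  # single-isoform gene: constant 1
  one <- usage_proportions(subset_counts(cm, features = 1),
                           t2g[1, , drop = FALSE])
  expect_true(all(one$per_day == 1))
})

test_that("isoform dynamics are classified by the contribution rules", {
  # two isoforms each carrying half of the aggregate rise
  both <- rbind(c(0, 1, 2), c(0, 1, 2))
  expect_equal(classify_die_dynamics(both), "cumulative")
  # one isoform carries the whole change
  solo <- rbind(c(0, 2, 4), c(1, 1, 1))
  expect_equal(classify_die_dynamics(solo), "single_dominant")
  # one isoform moves against an aggregate rise
  inv <- rbind(c(0, 3, 6), c(2, 1, 0))
  expect_equal(classify_die_dynamics(inv), "inverse")
  # flat aggregate
  flat <- rbind(c(0, 0.1, 0.2), c(0.2, 0.1, 0))
  expect_equal(classify_die_dynamics(flat), "other")
  expect_error(classify_die_dynamics(flat[1, , drop = FALSE]), ">= 2 isoforms")
})
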