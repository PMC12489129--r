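test_that("BH adjustment reproduces the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  p <- c(0.001, NA, 0.5, 0.04)
  adj <- bh_adjust(p)
  expect_true(is.na(adj[2]))
  expect_equal(adj[-2], p.adjust(p[-2], "BH"))
  set.seed(1)
  q <- runif(50)
  a <- bh_adjust(q)
  expect_true(all(diff(a[order(q)]) >= -1e-12))  # monotone in p
  expect_true(all(a >= q))
})

test_that("dispersion estimation recovers Poisson and NB truths", {
  d <- design_spec()
  cmp <- make_null_counts(800, d, alpha_mean = 1e-12, alpha_shape = 1e6, seed = 41)
  cmp$counts[] <- rpois(length(cmp$counts), 150)  # exact Poisson
  disp <- estimate_dispersions(cmp)
  expect_lt(median(disp$alpha), 0.01)
  cmn <- make_null_counts(800, d, alpha_mean = 0.2, alpha_shape = 1e6, seed = 42)
  dn <- estimate_dispersions(cmn)
  expect_gt(median(dn$alpha), 0.1)
  expect_lt(median(dn$alpha), 0.3)
  # constant counts: no residual variance, raw estimate zero
  cc <- make_cm(matrix(7, 3, 8), days = rep(0:3, 2))
  expect_true(all(estimate_dispersions(cc)$alpha_raw == 0))
  # all-zero features are excluded and listed
  cz <- make_cm(rbind(matrix(rpois(32, 20), 4, 8), 0), days = rep(0:3, 2))
  dz <- estimate_dispersions(cz)
  expect_identical(attr(dz, "excluded"), "f05")
  expect_false("f05" %in% dz$feature_id)
})

test_that("the full-model test keeps its null size and finds planted steps", {
  d <- design_spec()
  cm <- make_null_counts(700, d, seed = 43)
  lrt <- nb_lrt(cm)
  expect_true(all(lrt$p >= 0 & lrt$p <= 1, na.rm = TRUE))
  expect_true(all(lrt$padj >= lrt$p - 1e-12, na.rm = TRUE))
  expect_lt(mean(lrt$p < 0.05, na.rm = TRUE), 0.08)
  expect_gt(mean(lrt$p < 0.05, na.rm = TRUE), 0.02)
  # planted +1 log2 step at day 1 among nulls: padj <= 0.01 for >= 90%
  set.seed(44)
  smp <- d$samples
  pl <- 1:100
  cnt <- t(sapply(1:600, function(i) {
    m <- rlnorm(1, log(200), 0.5) * if (i %in% pl) 2^(smp$day >= 1) else 1
    rnbinom(36, size = 1 / 0.05, mu = m)
  }))
  dimnames(cnt) <- list(sprintf("g%04d", 1:600), smp$sample_id)
  res <- nb_lrt(count_matrix(cnt, smp))
  expect_gte(mean(res$padj[pl] <= 0.01), 0.9)
})

test_that("the LRT statistic is invariant to sample order and has a Poisson limit", {
  d <- design_spec(days = 0:3, replicates = 2)
  cm <- make_null_counts(20, d, seed = 45)
  disp <- estimate_dispersions(cm)
  r1 <- nb_lrt(cm, disp)
  perm <- sample(ncol(cm$counts))
  cmp <- count_matrix(cm$counts[, perm], cm$samples[perm, ], cm$lib_sizes[perm])
  r2 <- nb_lrt(cmp, disp)
  expect_equal(r1$stat, r2$stat, tolerance = 1e-8)
  # alpha -> 0 reproduces Poisson regression estimates
  y <- cm$counts[1, ]
  X <- model.matrix(~ cell_line + factor(day), cm$samples)
  off <- log(cm$lib_sizes)
  nb0 <- myotime:::.fit_feature(y, X, off, 1e-12)
  po <- glm.fit(X, y, family = poisson(), offset = off)
  expect_equal(unname(nb0$coef), unname(po$coefficients), tolerance = 1e-6)
})

test_that("windowed trends recover planted slopes with correct sign and size", {
  d <- design_spec()
  smp <- d$samples
  set.seed(46)
  pl <- 1:200
  cnt <- t(sapply(1:1200, function(i) {
    m <- rlnorm(1, log(200), 0.5) * if (i %in% pl) 2^(0.1 * smp$day) else 1
    rnbinom(36, size = 1 / 0.05, mu = m)
  }))
  dimnames(cnt) <- list(sprintf("g%04d", 1:1200), smp$sample_id)
  # equal library sizes and unit factors isolate the estimator from the
  # composition shift of the deliberately large planted fraction
  cm <- count_matrix(cnt, smp, lib_sizes = rep(mean(colSums(cnt)), 36))
  f1 <- setNames(rep(1, 36), smp$sample_id)
  tw <- nb_trend(cm, c(0, 3), factors = f1)
  expect_lt(abs(mean(tw$beta[pl]) - 0.1), 0.02)
  expect_identical(unique(tw$model), "window_0_3")
  # null size at most moderately above nominal
  expect_lte(mean(tw$p[-pl] < 0.05), 0.07)
  # reversing time flips the slope sign (full window: same samples)
  flip <- cm
  flip$samples$day <- max(smp$day) - flip$samples$day
  tw5 <- nb_trend(cm, c(0, 5), factors = f1)
  tw_f <- nb_trend(flip, c(0, 5), factors = f1)
  expect_equal(tw_f$beta, -tw5$beta, tolerance = 1e-6)
  expect_error(nb_trend(cm, c(0, 1)), "3 distinct days")
})

test_that("the full-model test agrees with an independent NB-GLM implementation", {
  # DESeq2's LRT is a separately derived NB likelihood-ratio pipeline; on a
  # mixed null/signal fixture the two rankings should agree closely even
  # though dispersion moderation differs
  d <- design_spec()
  smp <- d$samples
  set.seed(48)
  pl <- 1:20
  cnt <- t(sapply(1:120, function(i) {
    m <- rlnorm(1, log(200), 0.5) * if (i %in% pl) 2^(0.8 * (smp$day >= 2)) else 1
    rnbinom(36, size = 1 / 0.05, mu = m)
  }))
  dimnames(cnt) <- list(sprintf("g%04d", 1:120), smp$sample_id)
  cm <- count_matrix(cnt, smp)
  lrt <- nb_lrt(cm)
  dds <- suppressMessages(DESeq2::DESeqDataSetFromMatrix(
    countData = cnt,
    colData = data.frame(cell_line = factor(smp$cell_line),
                         day = factor(smp$day)),
    design = ~ cell_line + day))
  dds <- suppressMessages(DESeq2::DESeq(dds, test = "LRT",
                                        reduced = ~ cell_line, quiet = TRUE))
  ref <- DESeq2::results(dds)
  common <- intersect(lrt$feature_id, rownames(ref))
  rk <- cor(rank(lrt$p[match(common, lrt$feature_id)]),
            rank(ref$pvalue[match(common, rownames(ref))]),
            use = "complete.obs")
  expect_gt(rk, 0.95)
  # both implementations recover essentially the planted signal set
  mine <- lrt$feature_id[which(lrt$padj <= 0.01)]
  theirs <- rownames(ref)[which(ref$padj <= 0.01)]
  planted <- sprintf("g%04d", pl)
  expect_gte(mean(planted %in% mine), 0.9)
  expect_gte(mean(planted %in% theirs), 0.9)
  expect_gte(length(intersect(mine, theirs)) / length(union(mine, theirs)), 0.85)
})

test_that("BH keeps the empirical FDR near nominal on uniform p-values", {
  set.seed(47)
  fdp <- replicate(500, {
    p <- runif(200)
    rej <- which(bh_adjust(p) <= 0.05)
    if (length(rej)) 1 else 0  # all-null: any rejection is a false discovery
  })
  expect_lte(mean(fdp), 0.07)
})
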