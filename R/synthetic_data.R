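#' Experimental design of the simulated differentiation time course
#'
#' The emulated study design: two myoblast cell lines differentiated over six
#' daily time points (day 0 = proliferating myoblasts through day 5 =
#' myotubes), with equal replication in every cell-line x day condition.
#'
#' @param n_cell_lines number of cell lines (default 2).
#' @param days ordered integer vector of sampling days (default 0:5).
#' @param replicates replicates per cell-line x day condition (default 3,
#'   giving 36 samples; the usage-filter thresholds of 18 are half of that).
#' @param library_size_mean mean sequencing depth in counts (default 1e6).
#' @param library_size_cv coefficient of variation of log-normal library
#'   sizes (default 0.2).
#' @return A list of class `design_spec`, including a `samples` data.frame
#'   with one row per sample (`sample_id`, `cell_line`, `day`, `replicate`).
#' @export
design_spec <- function(n_cell_lines = 2, days = 0:5, replicates = 3,
                        library_size_mean = 1e6, library_size_cv = 0.2) {
  stopifnot(n_cell_lines >= 1, replicates >= 1, length(days) >= 2,
            library_size_mean > 0, library_size_cv >= 0)
  days <- sort(unique(as.integer(days)))
  grid <- expand.grid(replicate = seq_len(replicates), day = days,
                      cell_line = paste0("line", seq_len(n_cell_lines)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("cell_line", "day", "replicate")]
  grid$sample_id <- sprintf("%s_d%d_r%d", grid$cell_line, grid$day, grid$replicate)
  structure(list(n_cell_lines = n_cell_lines, days = days,
                 replicates = replicates,
                 library_size_mean = library_size_mean,
                 library_size_cv = library_size_cv,
                 samples = grid[, c("sample_id", "cell_line", "day", "replicate")]),
            class = "design_spec")
}

#' Canonical temporal cluster shapes
#'
#' Unit log2 fold-change trajectories (relative to day 0) for the five named
#' temporal programs plus the biphasic Up-Down shape seen at isoform level:
#' Down declines linearly to day 3 then stays low; Early-Down drops on day 1;
#' Early-Up rises on day 1 then is stable; Up rises linearly to day 3;
#' Up-Down rises early and falls after day 3; Mix has no deterministic shape
#' (random walk, drawn per gene in [simulate_truth()]). Shapes have unit
#' peak-to-trough range and are scaled by an amplitude when planted.
#'
#' @param days sampling days (default 0:5); trajectories are interpolated at
#'   these days from the day 0..5 canon.
#' @return Matrix with one row per label (Down, EarlyDown, EarlyUp, Up,
#'   UpDown) and one column per day.
#' @export
cluster_shapes <- function(days = 0:5) {
  canon <- rbind(
    Down      = c(0, -1 / 3, -2 / 3, -1, -1, -1),
    EarlyDown = c(0, -1, -1, -1, -1, -1),
    EarlyUp   = c(0, 1, 1, 1, 1, 1),
    Up        = c(0, 1 / 3, 2 / 3, 1, 1, 1),
    UpDown    = c(0, 0.9, 1, 0.6, 0.1, -0.4)
  )
  out <- t(apply(canon, 1, function(v) approx(0:5, v, xout = pmin(pmax(days, 0), 5))$y))
  colnames(out) <- days
  out
}

#' Plant ground truth for a synthetic differentiation dataset
#'
#' Draws per-gene temporal programs (cluster labels and log2 fold-change
#' trajectories), baseline means, NB dispersions, cell-line offsets, isoform
#' complements with baseline proportions, and differential-usage switches.
#' Defaults are the study conditions the generator emulates: cluster label
#' frequencies proportional to the five observed cluster sizes, log-normal
#' baseline means, gamma-distributed dispersions around 0.05, modest
#' cell-line offsets, Dirichlet-multinomial proportion precision 50.
#'
#' @param n_genes number of genes.
#' @param design a [design_spec()].
#' @param isoform_count_law probability weights over 1..5 isoforms per gene.
#' @param dtu_fraction fraction of multi-isoform genes with a planted usage
#'   switch (default 0.1).
#' @param dtu_swap total proportion mass moved between the two most abundant
#'   isoforms of a switching gene, day 0 to day 3 (default 0.4).
#' @param amplitude log2 fold-change amplitude of the planted trajectories
#'   (default 2).
#' @param label_probs named probabilities for the gene-level labels.
#' @param dispersion_mean,dispersion_shape gamma parameters of NB dispersion.
#' @param batch_sd standard deviation (log2) of the per-gene cell-line offset.
#' @param gamma Dirichlet-multinomial precision of isoform proportions across
#'   replicates (`Inf` = exact multinomial split).
#' @param seed integer seed stored in the bundle and used by
#'   [simulate_counts()].
#' @return A list of class `truth_bundle`: `genes` (gene_id, label, mu, alpha,
#'   delta, dtu), `isoforms` (transcript_id, gene_id, pi0, pi1), `trajectories`
#'   (gene x day log2 matrix), `gamma`, `days`, `seed`.
#' @export
simulate_truth <- function(n_genes, design = design_spec(),
                           isoform_count_law = c(0.4, 0.3, 0.15, 0.1, 0.05),
                           dtu_fraction = 0.1, dtu_swap = 0.4, amplitude = 2,
                           label_probs = c(Down = 0.195, EarlyDown = 0.295,
                                           EarlyUp = 0.288, Up = 0.133, Mix = 0.089),
                           dispersion_mean = 0.05, dispersion_shape = 4,
                           batch_sd = 0.25, gamma = 50, seed = 1L) {
  stopifnot(n_genes >= 1, dtu_fraction >= 0, dtu_fraction <= 1,
            length(isoform_count_law) == 5, all(isoform_count_law >= 0))
  set.seed(seed)
  days <- design$days
  shapes <- cluster_shapes(days)
  labels <- sample(names(label_probs), n_genes, replace = TRUE,
                   prob = label_probs / sum(label_probs))
  traj <- matrix(0, n_genes, length(days), dimnames = list(NULL, days))
  for (i in seq_len(n_genes)) {
    if (labels[i] == "Mix") {
      traj[i, ] <- c(0, cumsum(rnorm(length(days) - 1, 0, amplitude / 3)))
    } else {
      traj[i, ] <- shapes[labels[i], ] * amplitude
    }
  }
  gene_id <- sprintf("gene%04d", seq_len(n_genes))
  rownames(traj) <- gene_id
  genes <- data.frame(
    gene_id = gene_id,
    label = labels,
    mu = rlnorm(n_genes, log(200), 1),
    alpha = rgamma(n_genes, shape = dispersion_shape,
                   rate = dispersion_shape / dispersion_mean),
    delta = rnorm(n_genes, 0, batch_sd),
    stringsAsFactors = FALSE
  )
  k <- sample(1:5, n_genes, replace = TRUE,
              prob = isoform_count_law / sum(isoform_count_law))
  genes$dtu <- k >= 2 & runif(n_genes) < dtu_fraction
  iso <- lapply(seq_len(n_genes), function(i) {
    ki <- k[i]
    # baseline proportions: Dirichlet draw kept away from the filter floor
    p0 <- if (ki == 1) 1 else {
      p <- rgamma(ki, 2, 1); p <- p / sum(p)
      0.9 * p + 0.1 / ki
    }
    p0 <- sort(p0, decreasing = TRUE)
    p1 <- p0
    if (genes$dtu[i]) {
      # move `dtu_swap` of proportion mass from the top isoform to the second
      # (0.7 -> 0.3 style switch), clamped away from 0/1 so the usage filter
      # cannot silently discard planted events
      shift <- min(dtu_swap, p0[1] - 0.03, 1 - p0[2] - 0.03)
      p1[1] <- p0[1] - shift
      p1[2] <- p0[2] + shift
    }
    data.frame(transcript_id = sprintf("%s_iso%d", genes$gene_id[i], seq_len(ki)),
               gene_id = genes$gene_id[i], pi0 = p0, pi1 = p1,
               stringsAsFactors = FALSE)
  })
  isoforms <- do.call(rbind, iso)
  rownames(isoforms) <- NULL
  structure(list(genes = genes, isoforms = isoforms, trajectories = traj,
                 gamma = gamma, days = days, seed = as.integer(seed)),
            class = "truth_bundle")
}

# proportion trajectory of a gene's isoforms: linear move pi0 -> pi1 over
# days 0..3, held constant afterwards
.pi_at_day <- function(pi0, pi1, day) {
  w <- pmin(pmax(day / 3, 0), 1)
  p <- (1 - w) * pi0 + w * pi1
  p / sum(p)
}

#' Simulate an isoform count matrix from planted truth
#'
#' Per sample, the gene total is drawn negative-binomially with mean
#' `libsize_factor * mu * 2^(trajectory(day) + delta * [cell line 2])` and
#' variance `mu + alpha * mu^2`; the total is split across the gene's
#' isoforms Dirichlet-multinomially with precision `gamma` around the planted
#' proportions at that day (exact multinomial when `gamma = Inf`). Library
#' sizes are log-normal. Fixing the seed in the truth bundle reproduces the
#' matrix bitwise.
#'
#' @param design a [design_spec()].
#' @param truth a [simulate_truth()] bundle consistent with the design.
#' @return A [count_matrix()] of isoform counts (the transcript-to-gene map
#'   is `truth$isoforms[, c("transcript_id", "gene_id")]`).
#' @export
simulate_counts <- function(design, truth) {
  stopifnot(inherits(design, "design_spec"), inherits(truth, "truth_bundle"))
  if (!identical(design$days, truth$days))
    stop("truth bundle days do not match design days")
  if (any(truth$genes$mu <= 0)) stop("negative or zero baseline mean in truth")
  if (any(truth$isoforms$pi0 < 0 | truth$isoforms$pi0 > 1 |
          truth$isoforms$pi1 < 0 | truth$isoforms$pi1 > 1))
    stop("isoform proportions outside [0,1] in truth")
  set.seed(truth$seed + 1L)
  smp <- design$samples
  n_s <- nrow(smp)
  # log-normal library sizes with the requested mean and cv
  cv <- design$library_size_cv
  sdlog <- sqrt(log(1 + cv^2))
  lib <- rlnorm(n_s, log(design$library_size_mean) - sdlog^2 / 2, sdlog)
  sfac <- lib / design$library_size_mean
  iso_by_gene <- split(seq_len(nrow(truth$isoforms)), truth$isoforms$gene_id)
  counts <- matrix(0, nrow(truth$isoforms), n_s,
                   dimnames = list(truth$isoforms$transcript_id, smp$sample_id))
  day_idx <- match(smp$day, design$days)
  is_line2plus <- smp$cell_line != "line1"
  for (g in seq_len(nrow(truth$genes))) {
    gene <- truth$genes$gene_id[g]
    rows <- iso_by_gene[[gene]]
    mu_s <- sfac * truth$genes$mu[g] *
      2^(truth$trajectories[g, day_idx] + truth$genes$delta[g] * is_line2plus)
    alpha <- truth$genes$alpha[g]
    tot <- if (alpha <= 0) rpois(n_s, mu_s) else
      rnbinom(n_s, size = 1 / alpha, mu = mu_s)
    if (length(rows) == 1) {
      counts[rows, ] <- tot
    } else {
      pi0 <- truth$isoforms$pi0[rows]; pi1 <- truth$isoforms$pi1[rows]
      for (j in seq_len(n_s)) {
        p <- .pi_at_day(pi0, pi1, smp$day[j])
        if (is.finite(truth$gamma)) {
          a <- rgamma(length(p), shape = truth$gamma * p, rate = 1)
          p <- if (sum(a) > 0) a / sum(a) else p
        }
        counts[rows, j] <- if (tot[j] > 0) rmultinom(1, tot[j], p) else 0
      }
    }
  }
  count_matrix(counts, smp, lib)
}

#' Simulate z-scored temporal profiles with planted cluster labels
#'
#' Direct profile-level generator used for clustering-recovery checks:
#' each gene gets its canonical shape scaled to a peak-to-trough amplitude in
#' z-units plus independent Gaussian day noise. Mix genes get random walks.
#'
#' @param n_genes number of genes.
#' @param amplitude peak-to-trough amplitude in z-units (default 1.5).
#' @param noise_sd per-day Gaussian noise s.d. (default 0.3).
#' @param labels labels to draw from (default the five gene-level names).
#' @param days sampling days.
#' @param seed integer seed.
#' @return List with `profiles` (gene x day matrix) and `labels`.
#' @export
simulate_profiles <- function(n_genes, amplitude = 1.5, noise_sd = 0.3,
                              labels = c("Down", "EarlyDown", "EarlyUp", "Up", "Mix"),
                              days = 0:5, seed = 1L) {
  set.seed(seed)
  shapes <- cluster_shapes(days)
  lab <- sample(labels, n_genes, replace = TRUE)
  prof <- t(vapply(lab, function(l) {
    base <- if (l == "Mix") c(0, cumsum(rnorm(length(days) - 1, 0, amplitude / 3)))
            else shapes[l, ] * amplitude
    base + rnorm(length(days), 0, noise_sd)
  }, numeric(length(days))))
  rownames(prof) <- sprintf("gene%04d", seq_len(n_genes))
  colnames(prof) <- days
  list(profiles = prof, labels = setNames(lab, rownames(prof)))
}

#' Simulate a transcript annotation with planted structural categories
#'
#' Builds, per gene, a ladder of exons on a synthetic chromosome and a set of
#' reference transcripts (windows of four consecutive exons). A fraction of
#' transcripts is novel: half reuse only cataloged junctions in a new chain
#' (in-catalog novelty) and half skip an internal exon, creating a junction
#' absent from the catalog (not-in-catalog novelty). The reference junction
#' catalog contains exactly the junctions of the non-novel transcripts.
#'
#' @param n_genes number of genes (>= 1).
#' @param isoform_count_law probability weights over 1..5 transcripts per gene.
#' @param novel_fraction fraction of transcripts that are novel, in [0, 1].
#' @param seed integer seed.
#' @return List with `query` (all transcript models), `reference` (non-novel
#'   models), `catalog` ([junction_catalog()]), `t2g`, and `truth`
#'   (transcript_id, gene_id, novel, category in FSM/NIC/NNC).
#' @export
simulate_annotation <- function(n_genes, isoform_count_law = c(0.3, 0.3, 0.2, 0.1, 0.1),
                                novel_fraction = 0.3, seed = 1L) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (novel_fraction < 0 || novel_fraction > 1)
    stop("novel_fraction must be in [0, 1]")
  set.seed(seed)
  exon_len <- 100L; gap <- 100L; n_exons <- 8L
  rows <- list(); truth <- list()
  for (g in seq_len(n_genes)) {
    gene <- sprintf("gene%04d", g)
    off <- (g - 1L) * 10000L + 1L
    ex_start <- off + (seq_len(n_exons) - 1L) * (exon_len + gap)
    ex_end <- ex_start + exon_len - 1L
    strand <- if (g %% 2 == 0) "-" else "+"
    k <- sample(1:5, 1, prob = isoform_count_law / sum(isoform_count_law))
    starts <- sample(seq_len(n_exons - 3L), k)  # distinct 4-exon windows
    novel <- runif(k) < novel_fraction
    for (i in seq_len(k)) {
      tx <- sprintf("%s_tx%d", gene, i)
      win <- starts[i]:(starts[i] + 3L)
      if (!novel[i]) {
        exons <- win
        cat_i <- "FSM"
      } else if (runif(1) < 0.5 && any(!novel)) {
        # in-catalog novelty: prefix chain of a non-novel sibling
        donor <- starts[which(!novel)[1]]
        exons <- donor:(donor + 2L)
        cat_i <- "NIC"
      } else {
        # not-in-catalog novelty: skip the second exon of the window
        exons <- win[-2]
        cat_i <- "NNC"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tx, gene_id = gene, chrom = "chrS", strand = strand,
        start = ex_start[exons], end = ex_end[exons], stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        transcript_id = tx, gene_id = gene, novel = novel[i], category = cat_i,
        stringsAsFactors = FALSE)
    }
  }
  query <- transcript_models(do.call(rbind, rows))
  truth <- do.call(rbind, truth)
  ref_tx <- truth$transcript_id[!truth$novel]
  reference <- transcript_models(query[query$transcript_id %in% ref_tx, , drop = FALSE])
  list(query = query,
       reference = reference,
       catalog = junction_catalog(reference),
       t2g = unique(truth[, c("transcript_id", "gene_id")]),
       truth = truth)
}

#' Simulate coding-confidence and interaction-confidence tables
#'
#' Per-isoform ORF flags, known-protein matches, and mean pLDDT scores with a
#' planted high/low-confidence split; plus a symmetric pairwise iPTM table
#' for a protein set with planted cliques and homodimers over a low-scoring
#' background.
#'
#' @param transcript_ids character vector of isoform ids.
#' @param known_fraction fraction of ORF-bearing isoforms matching a known
#'   protein (default 0.2).
#' @param high_conf_fraction fraction of novel-ORF isoforms planted above the
#'   confidence threshold (default 0.5).
#' @param orf_fraction fraction of isoforms carrying an ORF (default 0.9).
#' @param n_proteins number of proteins in the interaction table (default 20).
#' @param clique_sizes sizes of planted fully connected clusters.
#' @param n_homodimers number of additional proteins whose only confident
#'   interaction is with themselves.
#' @param seed integer seed.
#' @return List with `confidence` (per-isoform table including the planted
#'   `truth_triage`), `iptm` (long-form symmetric pair table), and
#'   `iptm_truth` (list of planted component memberships).
#' @export
simulate_confidence_tables <- function(transcript_ids, known_fraction = 0.2,
                                       high_conf_fraction = 0.5,
                                       orf_fraction = 0.9, n_proteins = 20,
                                       clique_sizes = c(3, 3),
                                       n_homodimers = 1, seed = 1L) {
  if (known_fraction < 0 || known_fraction > 1 ||
      high_conf_fraction < 0 || high_conf_fraction > 1)
    stop("fractions must be in [0, 1]")
  set.seed(seed)
  n <- length(transcript_ids)
  has_orf <- runif(n) < orf_fraction
  known <- has_orf & runif(n) < known_fraction
  high <- has_orf & !known & runif(n) < high_conf_fraction
  plddt <- rep(NA_real_, n)
  plddt[known] <- runif(sum(known), 0.2, 0.95)
  plddt[high] <- runif(sum(high), 0.75, 0.95)
  low <- has_orf & !known & !high
  plddt[low] <- runif(sum(low), 0.2, 0.65)
  triage <- ifelse(!has_orf, "noncoding",
            ifelse(known, "known_coding",
            ifelse(high, "high_confidence_coding", "low_confidence_coding")))
  confidence <- data.frame(transcript_id = transcript_ids, has_orf = has_orf,
                           orf_matches_known = known, mean_plddt = plddt,
                           truth_triage = triage, stringsAsFactors = FALSE)

  prot <- sprintf("prot%02d", seq_len(n_proteins))
  if (sum(clique_sizes) + n_homodimers > n_proteins)
    stop("planted cliques and homodimers exceed n_proteins")
  pool <- sample(prot)
  comps <- list(); at <- 1
  for (s in clique_sizes) { comps[[length(comps) + 1]] <- pool[at:(at + s - 1)]; at <- at + s }
  homod <- if (n_homodimers > 0) pool[at:(at + n_homodimers - 1)] else character(0)
  pairs <- expand.grid(a = seq_len(n_proteins), b = seq_len(n_proteins))
  pairs <- pairs[pairs$a <= pairs$b, ]
  score <- runif(nrow(pairs), 0.02, 0.3)
  in_clique <- vapply(seq_len(nrow(pairs)), function(i) {
    pa <- prot[pairs$a[i]]; pb <- prot[pairs$b[i]]
    any(vapply(comps, function(cc) pa %in% cc && pb %in% cc, logical(1)))
  }, logical(1))
  score[in_clique] <- runif(sum(in_clique), 0.85, 0.95)
  self_homo <- prot[pairs$a] == prot[pairs$b] & prot[pairs$a] %in% homod
  score[self_homo] <- runif(sum(self_homo), 0.85, 0.95)
  iptm <- data.frame(protein_a = prot[pairs$a], protein_b = prot[pairs$b],
                     iptm = round(score, 4), stringsAsFactors = FALSE)
  list(confidence = confidence, iptm = iptm,
       iptm_truth = list(cliques = comps, homodimers = homod))
}

#' Write a complete synthetic dataset to disk
#'
#' Materializes every on-disk artifact the pipeline reads: counts (TSV and
#' MatrixMarket), sample metadata, transcript-to-gene map, truth table,
#' annotation GTFs, gene sets built from the planted cluster labels, and the
#' confidence tables.
#'
#' @param outdir output directory (created if absent).
#' @param design a [design_spec()].
#' @param truth a [simulate_truth()] bundle.
#' @param seed seed for the annotation and confidence fixtures.
#' @return Invisibly, a named list of written paths.
#' @export
simulate_dataset <- function(outdir, design = design_spec(),
                             truth = simulate_truth(300, design), seed = truth$seed) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  cm <- simulate_counts(design, truth)
  write_counts(cm, p("counts.tsv"), p("samples.tsv"))
  write_counts_mtx(cm, p("counts"))
  write_t2g(truth$isoforms[, c("transcript_id", "gene_id")], p("t2g.tsv"))
  tt <- merge(truth$isoforms, truth$genes, by = "gene_id")
  write.table(tt, p("truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- simulate_annotation(nrow(truth$genes), seed = seed)
  write_gtf(ann$query, p("transcripts.gtf"))
  write_gtf(ann$reference, p("reference.gtf"))
  sets <- split(truth$genes$gene_id, truth$genes$label)
  names(sets) <- paste0("cluster_", names(sets))
  write_gmt(sets, p("genesets.gmt"))
  conf <- simulate_confidence_tables(truth$isoforms$transcript_id, seed = seed)
  write.table(conf$confidence, p("plddt.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(conf$iptm, p("iptm.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(counts = p("counts.tsv"), samples = p("samples.tsv"),
                 mtx = p("counts.mtx"), t2g = p("t2g.tsv"), truth = p("truth.tsv"),
                 gtf = p("transcripts.gtf"), ref_gtf = p("reference.gtf"),
                 gmt = p("genesets.gmt"), plddt = p("plddt.tsv"), iptm = p("iptm.tsv")))
}
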