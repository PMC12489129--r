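# myotime

Temporal transcriptome and splicing-isoform analysis of in vitro human
myogenesis, packaged as a tested, reusable R pipeline.

The motivating setting is a 5-day myoblast-to-myotube differentiation: two
human myoblast cell lines sampled every 24 hours (day 0 through day 5),
with RNA quantified at the level of individual splicing isoforms. The
questions such an experiment raises — which genes follow which temporal
program, which isoforms change their share of their gene's output, which
novel transcripts are credible and protein-coding, and which candidate
proteins interact — each need a dedicated statistical treatment, and
`myotime` implements the full chain for analysts working with isoform-level
count matrices from any comparable time course.

## What it computes

For isoform counts `y_gij` (gene g, isoform i, sample j) with library size
`L_j`:

* **Normalization** — TMM factors `f_j`, `CPM = y / (L_j f_j) x 1e6`,
  `log2(CPM + 0.5)`, removal of the cell-line effect by per-gene OLS
  (preserving the day effect), per-gene z-scores.
* **Differential expression** — NB models with variance `mu + alpha mu^2`
  and offsets `log(L_j f_j)`; windowed trends (days 0–3 and 3–5, slope
  beta in log2/day, Wald t test) and a full-model likelihood-ratio test of
  day (factor, 5 df) adjusted for cell line, with quasi-likelihood F
  moderation for calibrated nulls; BH adjustment.
* **Temporal clustering** — Ward/Euclidean clustering (k = 5) of per-day
  z-score profiles of features with LRT `padj <= 0.01`, rule-based shape
  labels (Down, Early-Down, Early-Up, Up, Up-Down, Mix), isoform-vs-gene
  cluster cross-tabulation, gene-direction concordance.
* **Differential transcript usage** — the six-parameter
  expression/proportion filter (thresholds 5/0.05/10 in >= 18 of 36
  samples), per-isoform beta-binomial usage regression `logit(pi) ~ day +
  cell_line` tested by LRT at a Cox–Reid-adjusted fixed precision,
  Dirichlet-multinomial proportion estimates, and stage-wise error
  control: BH screening of genes at alpha = 0.05, Holm confirmation of
  isoforms at level `alpha R / G`.
* **Gene-set scores** — composite scores (mean z-score of members), OLS
  trends per day window, transfer onto external two-group data,
  hypergeometric over-representation against a detected-gene background,
  and 2^-ddCt qPCR fold changes.
* **Transcript catalog classification** — FSM / NIC / NNC by
  junction-chain comparison with a reference catalog; coding triage of
  novel isoforms by mean pLDDT with a strict 0.7 threshold.
* **Interaction networks** — `n(n+1)/2` scored pairs (1,275 for 50
  proteins), edges at iPTM > 0.7, connected components with homodimer
  flags.

A seeded synthetic-data generator (`simulate_truth`, `simulate_counts`,
`simulate_annotation`, `simulate_confidence_tables`) plants all of the
structure above with known truth, so every stage is testable offline.

## Worked example

```r
library(myotime)

td <- tempfile(); dir.create(td)
design <- design_spec()                       # 2 lines x days 0..5 x 3 reps
truth  <- simulate_truth(300, design, seed = 42)
paths  <- simulate_dataset(td, design, truth) # writes TSV/MTX/GTF/GMT fixtures

cm  <- read_counts(paths$counts, paths$samples)
t2g <- read_t2g(paths$t2g)
g   <- aggregate_to_genes(cm, t2g)

lrt <- nb_lrt(g)
sum(lrt$padj <= 0.01, na.rm = TRUE)           # 297 of 300 genes change
prof <- temporal_profiles(g, lrt, alpha = 0.01)
table(cluster_profiles(prof, k = 5)$assignments$label)
#>      Down EarlyDown   EarlyUp       Mix        Up
#>        62        89        92        16        38

res <- dtu(cm, t2g, alpha = 0.05)
sum(res$genes$screened)                       # 17 genes screened
sum(res$isoforms$confirmed)                   # 33 isoforms confirmed
sum(truth$genes$dtu)                          # 17 switches were planted

head(nb_trend(g, c(0, 3))[order(nb_trend(g, c(0, 3))$padj), ], 3)
#>     feature_id   beta          p       padj
#>       gene0147 -0.813    2.0e-13    3.7e-11   (log2 per day, days 0-3)
```

The cluster table recovers the planted temporal programs; the usage stage
screens exactly the 17 genes whose isoform proportions were switched, and
confirms the isoforms that moved. Windowed slopes are log2 fold change per
day over the canonical differentiation phase.

The pipeline can also be run end to end with `run_all(pipeline_config(...),
outdir)`, or from a shell via the thin wrapper in `inst/scripts/myotime`
(`myotime simulate`, `myotime all`).

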