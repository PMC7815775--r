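# itraqnet

Differential proteomics, interaction-network and qPCR analysis for chronic
low-dose radiation studies.

Populations living on monazite-bearing high-background-radiation coasts
receive chronic external doses from below 1.5 up to beyond 45 mGy/y, and
quantitative proteomics of their peripheral blood mononuclear cells (PBMCs)
is one of the few ways to observe low-dose-radiation biology directly in
healthy humans. `itraqnet` re-implements, as a tested and reusable R
pipeline, the analysis chain such studies use downstream of peptide
identification:

* **Differential calling from iTRAQ 4-plex reporter ratios.** Each
  comparison dose group is one pooled sample measured in two technical
  replicates; ratios are relative to the reference channel (reporter 114,
  the normal-background group). The mean of the two replicate ratios is
  imputed as a third value, the log2 triple is tested against 0 with a
  one-sample Student's t-test (df = 2), p-values are Benjamini–Hochberg
  corrected per group, and a protein is called *up* if FC ≥ 1.2 or *down*
  if FC ≤ 0.83, gated at adjusted P ≤ 0.1. %CV of the technical replicates
  and a Kolmogorov–Smirnov normality check are reported as QC.
* **Fisher's exact over-representation** of differential proteins in
  user-supplied annotation terms (GMT), one-sided hypergeometric upper
  tail `P(X ≥ k)` against the detection-conditioned background, P ≤ 0.05.
* **Protein–protein interaction network analysis** on a merged interactome
  (HPRD/IntAct/MINT/CORUM/PhosphoSitePlus-style edge lists or minimal
  PSI-MITAB): induced subgraphs on the differential protein list annotated
  with per-group log2FC (up/down at |log2FC| > 0.263 = log2 1.2); giant
  connected component (GCC) size scored against a permutation null with an
  empirical z-score and add-one empirical p; degree, betweenness,
  closeness and clustering per node; hub ranking by the multiplicative
  score `log2FC × Degree` and rendering size `(DC + 1) × (|log2FC| + 1)`;
  GraphML/GEXF export for Gephi-style layout tools.
* **qPCR validation** with the dual-reference 2^−ΔΔCt method (Livak–
  Schmittgen), reference-gene stability checks, and per-group mean ± SEM
  with Student's t-tests against the calibrator group.
* **Dosimetry**: survey-meter exposure rates (μR/h, mean of three
  readings, occupancy-weighted indoor/outdoor) converted to annual
  absorbed dose with the factor 0.0767 = 0.8763 × 24 × 365 × 10⁻⁵ and
  stratified into dose groups I (< 1.5), II (1.5–5.0), III (5.0–14.0) and
  IV (> 14.0 mGy/y).

A synthetic-data module generates every pipeline input with planted ground
truth — differential proteins, enriched annotation terms, a dense module
inside a scale-free interactome, qPCR fold changes, dosimetry readings —
so the entire analysis is testable end to end without any external
database.

## Worked example

Simulate a study at half scale and run every stage:

```r
library(itraqnet)

cfg <- config_set(default_config(seed = 11),
                  c("n_proteins=500", "interactome_nodes=400",
                    "planted_module_size=15"))
s <- run_pipeline(cfg, "demo_run")

cat("Group II:", s$differential$II$up, "up,", s$differential$II$down, "down\n")
#> Group II: 25 up, 25 down
cat("Planted recovery:", 100 * s$planted_recovery$recovery_fraction, "%\n")
#> Planted recovery: 100 %
g2 <- s$gcc_significance$II
cat(sprintf("GCC: %d nodes, z = %.2f, empirical p = %.4g\n",
            g2$observed_gcc, g2$z, g2$empirical_p))
#> GCC: 18 nodes, z = 5.46, empirical p = 0.001998
```

The run directory now holds, per group, the differential call table,
volcano-plot data, the Venn partition, enrichment tables, annotated
GraphML/GEXF networks, hub tables and GCC-significance JSON, plus the qPCR
and dosimetry outputs and a consolidated `summary.json`. The top of the
Group II hub table:

```r
head(read_tsv("demo_run/hubs_II.tsv")[, c("rank", "protein_id", "dc",
                                          "log2_fc", "hub_score")], 3)
#>  rank protein_id dc   log2_fc hub_score
#>     1     P00175 13  1.349247  17.54021
#>     2     P00100 12  1.441823  17.30187
#>     3     P00405 12 -1.435676 -17.22811
```

The hub score keeps its sign (`P00405` is a strongly down-regulated,
highly connected node) while ranking uses its magnitude. The qPCR stage
recovers the planted twofold change of `GENE_A` relative to the calibrator
group I:

```r
qp <- read_tsv("demo_run/qpcr_results.tsv")
qp[qp$gene == "GENE_A", ]
#>    gene group n mean_fold    sem        p significant
#>  GENE_A     I 5      1.01 0.0771       NA       FALSE
#>  GENE_A    II 5      2.23 0.1379 0.000201        TRUE
#>  GENE_A   III 5      1.99 0.1538 0.001353        TRUE
```

Re-running `run_pipeline()` with the same config reproduces every output
file byte for byte (`run_checksums()` compares two runs). A thin CLI over
the same functions, with `simulate`/`diff`/`enrich`/`network`/`qpcr`/
`dose`/`run-all` subcommands, is in `inst/scripts/itraqnet-pipeline.R`.

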