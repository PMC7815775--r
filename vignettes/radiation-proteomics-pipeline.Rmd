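---
title: "Methods: differential proteomics, network and qPCR analysis for chronic low-dose radiation studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential proteomics, network and qPCR analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itraqnet)
```

`itraqnet` analyses quantitative proteomics of pooled human PBMC samples
from populations chronically exposed to elevated natural background
radiation, together with the companion analyses such studies report:
annotation enrichment, protein–protein interaction (PPI) network hubs,
qPCR validation and environmental dosimetry. This vignette documents the
statistical model behind each stage, the parameters that matter, the
synthetic-data design used for testing, and the decisions taken where the
design was genuinely open.

## Study design assumed by the pipeline

One reference pool (iTRAQ reporter 114; the normal-background dose group
I) and three comparison pools (reporters 115/116/117; dose groups II–IV),
each pool measured in two technical replicates. The input is therefore a
long table of reporter-ion peak-area ratios (comparison/reference) per
protein, group and replicate. Pooling removes between-subject variance
from the data; the statistics below consequently describe measurement
(technical) error around the pooled effect, not biological variation.

## Differential calling

For each protein × group with a complete replicate pair $(r_1, r_2)$:

1. **Imputation.** The arithmetic mean $(r_1 + r_2)/2$ is appended as a
   third value. This widens the nominal degrees of freedom to 2 at the
   price of pseudo-replication — the test is anti-conservative in the
   usual sense, which is why the fold-change gate below does most of the
   work.
2. **Test.** A one-sample, two-sided Student's t-test of the
   log2-transformed triple against 0 (equivalently, of the ratios against
   1). The log scale symmetrises up- and down-regulation and matches the
   multiplicative error structure of reporter-ion ratios. A zero-variance
   triple ($r_1 = r_2$) is reported as *not testable* (`NA`), never as
   p = 0: a spuriously tied pair should not produce a top hit.
3. **Correction.** Benjamini–Hochberg within each group
   (`stats::p.adjust`), with `NA` entries excluded from the number of
   tests. Ties are handled by stable sorting on input order.
4. **Calling.** *up* if FC ≥ 1.2 and adjusted P ≤ 0.1; *down* if
   FC ≤ 0.83 and adjusted P ≤ 0.1; otherwise *unchanged*. The fold-change
   cutoffs are deliberately permissive (log2 1.2 ≈ 0.263) so that subtle
   but coherent changes survive; both cutoffs and the alpha are
   configurable (`fc_up`, `fc_down`, `alpha_adj`).

%CV is computed on the two *measured* replicates only
(`100 · sd/mean`); including the imputed midpoint would deflate it by
construction. A one-sample Kolmogorov–Smirnov check of each group's log2
fold-change distribution against a fitted normal is reported as QC but
never gates calls — with estimated parameters the KS p-value is
approximate anyway, and a global normality failure is a property of the
biology, not of a single protein.

Proteins missing a replicate in a group are excluded from that group's
testing and listed in a QC table, mirroring the fact that detected-protein
universes differ between groups.

## Enrichment

Over-representation of the differential set in annotation terms (GMT) uses
the one-sided hypergeometric upper tail
$P(X \ge k)$ with $k$ the overlap, $K$ the term size inside the
background, $n$ the selection size and $N$ the background size. The
background is the set of *quantifiable* proteins in the experiment, not
the whole proteome: detection conditions both the selection and the terms,
and using the proteome would inflate every enrichment. Unadjusted
P ≤ 0.05 marks significance (the convention of DAVID-style tools whose
output this stage reproduces); a BH column is emitted alongside for
transparency but does not drive the flag.

## PPI network analysis

Per-group networks are induced subgraphs of a merged interactome on the
**union across groups** of proteins called up or down, annotated with the
group's own log2FC. The union reading is what allows a group's network to
contain *un-regulated* nodes (proteins differential elsewhere but not
here); the modulation classes use strict cutoffs: up-regulated if
log2FC > 0.263, down-regulated if log2FC < −0.263. Isolated nodes are
dropped, which is why a network can hold fewer proteins than the
differential list. Interactome merging drops self-loops and unions the
source/evidence labels of duplicate unordered pairs.

**GCC significance.** The size of the giant connected component is scored
against random expectation: each permutation draws the same number of
nodes uniformly without replacement from the interactome's node set and
records the induced subgraph's largest component. The package reports
$z = (\text{observed} - \bar{s}_{\text{null}})/sd_{\text{null}}$ and the
add-one empirical p-value $(\#\{s_{\text{null}} \ge \text{observed}\} + 1)/(B + 1)$,
which can never be exactly zero. Uniform node resampling is the default
null because it matches the question "would a random protein set of this
size be this connected?"; degree-weighted sampling (`null = "degree"`) is
available for users who want to condition on the selection hitting hubs.
Degree-preserving edge rewiring — a null for a different question, about
the wiring rather than the selection — is out of scope. The observed GCC
size is a small integer, so its null distribution is discrete; the add-one
empirical p of a discrete statistic has expectation
$0.5 + \tfrac{1}{2}E[P(S = s)]$ under its own null, a bias that vanishes
as the support widens. The calibration checks in the test suite therefore
use a selection size near the percolation transition of the simulated
interactome, where the null GCC distribution is widest.

**Node statistics.** Degree is the raw count; betweenness is
unnormalised shortest-path betweenness; closeness is computed within the
node's component as $(\text{reachable} - 1)/\sum d$; local clustering is
triangle density, defined as 0 for degree < 2. Hubs are ranked by the
multiplicative score `log2FC × Degree`, using its absolute value so that
strongly down-regulated, highly connected proteins can top the list, with
the signed score retained in the output; ties break towards higher degree,
then lexicographic id. Node rendering size is
`(DC + 1) × (|log2FC| + 1)`. Networks export to GraphML and GEXF with all
node and edge attributes, for layout in Gephi-class tools (layout itself
is out of scope).

## qPCR (2^−ΔΔCt)

Per sample, ΔCt = Ct(target) − mean Ct of the two reference genes;
combining references by arithmetic mean of Ct is equivalent to the
geometric mean of their linear quantities. ΔΔCt subtracts the *calibrator
group's mean* ΔCt (a population calibrator, not a single sample), and the
fold change is 2^−ΔΔCt with amplification efficiency fixed at 2 — the
standard Livak–Schmittgen assumption; no efficiency correction is
attempted. By construction the calibrator group's geometric mean fold is
exactly 1 (its arithmetic mean exceeds 1 slightly, by Jensen's
inequality), and a constant plate offset on every well cancels exactly.
Reference-gene stability (sd of Ct across samples, default threshold 1
cycle) is validated first and failure warns rather than halts. Groups are
compared to the calibrator with a two-sided two-sample t-test on the
per-sample folds, reported as mean ± SEM with n taken from the data.

## Dosimetry

Annual absorbed dose is
`(indoor_rate × f + outdoor_rate × (1 − f)) × 0.0767` mGy/y, with `f` the
indoor occupancy fraction and 0.0767 = 0.8763 × 24 × 365 × 10⁻⁵ the
conventional (truncated) μR/h-to-mGy/y factor; the exact product 0.076764
is available via `dose_conversion_factor()`, and the factor is an argument
for users with a different calibration. Dose groups are half-open
intervals I [0, 1.5), II [1.5, 5], III (5, 14], IV (14, ∞): published
definitions place exactly 1.5 mGy/y in both the normal- and high-level
strata, so the package assigns it to Group II by default and exposes
`boundary_1.5 = "NLNRA"` for the opposite convention; the printed bounds
5.01/14.01 are treated as the continuous cuts 5.0/14.0 because doses are
real-valued. Internal (ingested/inhaled) dose is out of scope.

## Synthetic data: what it emulates, and what it does not

The generators produce every pipeline input with planted truth:

* `sim_quant()` — per-replicate ratios with Gaussian noise on the log2
  scale (multiplicative on ratios, matching iTRAQ ratio error). A planted
  fraction gets true effects drawn from `effect_range_log2` with a
  configurable up:down split (default 50:50; real low-dose data can be
  overwhelmingly up-regulated, so the split is a parameter rather than an
  assumption). The planted minimum effect must clear log2 1.2 so truth
  and calling thresholds cannot contradict each other.
* `sim_annotation()` — GMT terms whose members are drawn with elevated
  odds from the planted set for the enriched terms.
* `sim_interactome()` — a preferential-attachment (scale-free) background
  (`igraph::sample_pa`) with protein ids assigned in random order so a
  protein's index carries no degree information, plus a planted dense
  module among planted proteins filled to a target internal edge density.
* `sim_ct()` — fixed per-gene baseline Ct in 18–28 cycles; targets in
  non-calibrator groups are shifted by −(planted log2FC) cycles (one
  cycle per doubling); Gaussian cycle noise on **every** well, reference
  genes included.
* `sim_dosimetry()` — indoor/outdoor rates as the mean of three uniform
  readings, mirroring field practice.

Every generator is byte-reproducible under a fixed seed and leaves the
caller's RNG state untouched. Truth tables are written beside the
generated data so downstream checks never re-derive them.

What passing on these data does **not** show: the simulators have no
peptide-to-protein inference, no missingness correlated with abundance, no
ratio compression, no biological covariates (age, smoking), no correlated
annotation terms, and the interactome has no literature ascertainment
bias. Recovery rates on synthetic data are therefore upper bounds on what
identical settings would achieve on real data.

## Default configuration and problem sizes

`default_config()` fixes the analysis thresholds at the published values
(1.2/0.83, adjusted P ≤ 0.1, Fisher P ≤ 0.05, |log2FC| > 0.263, top-10
hubs) and the simulation at 1000 proteins, 10% planted effects with
|log2FC| ∈ [1, 1.5], replicate noise sd 0.1, an 800-node interactome with
a 20-node module at density 0.8, a 4-gene qPCR panel (planted log2FC 1,
0.585, −1, 0) with 5 samples per group and 0.2-cycle noise, and 40
dosimetry subjects. The pipeline default of 1000 GCC permutations keeps a
full run in seconds while leaving the empirical p resolution at 10⁻³;
`gcc_significance()` itself defaults to 10⁴ permutations for single
analyses, and both are configurable. The test suite runs its simulation
properties at 150–1000 proteins and 20–200 replicate datasets per
property, sizes chosen to keep each property's Monte-Carlo error well
below the margin it asserts.

## Numerical choices and degenerate inputs

* Zero-variance ratio triples and zero-variance qPCR comparisons return
  `NA` (flagged), never 0 or 1-by-fiat — except the exactly-equal-means
  zero-variance case, where p = 1 by the equal-means convention.
* The GCC tie-break (equal component sizes) selects the component
  containing the lexicographically smallest protein id, making extraction
  order-invariant.
* Classification uses ≥/≤ at the published fold-change and alpha cutoffs
  but strict inequalities at the ±0.263 modulation cut, following the
  printed definitions.
* Empirical p-values use the add-one convention; z is `NA` with a warning
  when the permutation null degenerates to zero variance.
* Config-derived stage seeds are small deterministic functions of the
  master seed, so every stage (and the pipeline as a whole) is
  reproducible bit for bit; reruns are checksum-identical.

## Known limitations

* With two technical replicates of pooled samples, the t-test's df = 2 is
  nominal and inference is about measurement error only; the calling
  scheme should be read as a ranked filter, not as population-level
  inference. The FDR smoke test in the suite checks conservatism, not
  exactness, for the same reason.
* The qPCR recovery spread under the default noise model is wider than a
  ±0.3 window around a planted twofold change: with 0.2-cycle noise on
  target, references and calibrator wells alike, the group-mean fold for
  n = 5 has sd ≈ 0.22, so single runs land outside [1.7, 2.3] in roughly
  a sixth of seeds. Averaging over seeds recovers the planted fold
  without bias.
* Identifier namespaces are the caller's responsibility: the interactome
  and the quantitation table must share one id space (no UniProt/symbol
  mapping is attempted).
* Enrichment ignores the annotation graph structure (no ancestor
  propagation, no term–term correlation correction), matching the tool
  family it emulates.
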