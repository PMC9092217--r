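---
title: "Methods: qPCR array analysis of extracellular-vesicle miRNAs"
author: "miRcq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: qPCR array analysis of extracellular-vesicle miRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRcq)
```

# Scope and model

`miRcq` analyzes well-level TaqMan-style qPCR array exports from biofluid
extracellular-vesicle studies. The quantification cycle Cq is inversely
proportional to log2 template abundance, so all modelling happens on the
Cq (log2) scale: noise is assumed Gaussian per well, group comparisons are
differences of means of normalized Cq, and a fold change is
$RQ = 2^{-\Delta\Delta Cq}$.

The quantification chain is the standard relative-quantification model:

* within a sample, $\Delta Cq = Cq_{\text{miRNA}} -
  \overline{Cq}_{\text{controls}}$, which removes sample-level loading and
  isolation efficiency (any sample-wide Cq offset cancels exactly; this is
  asserted as a package invariant);
* between groups, $\Delta\Delta Cq = \overline{\Delta Cq}_{\text{test}} -
  \overline{\Delta Cq}_{\text{ref}}$ and $RQ = 2^{-\Delta\Delta Cq}$, so
  $RQ > 1 \iff \Delta\Delta Cq < 0 \iff$ higher expression in the test
  group.

## Censoring and the QC cascade

Wells are processed in a fixed order, and the cascade is idempotent:

1. **Ceiling imputation.** Cq above the detection ceiling (default 34
   cycles) or reported "Undetected" is replaced by the ceiling and flagged
   not-detected. The value 34 stays in the matrix and enters downstream
   means as a censored observation — dropping such wells entirely would
   bias group means of partially detected miRNAs, while treating them as
   detected would overstate evidence. The undetected sentinel (an `NA` Cq
   in the well table) is kept distinct from a measured 34 until this step
   runs, so detection status is never inferred from a magic number.
2. **Quality exclusion.** Detected wells with amplification score < 1.0 or
   Cq confidence < 0.8 are removed per well (other wells of the same probe
   remain usable). Values exactly at a threshold pass: the exclusion rule
   is written as strict inequality, and the pass rule as the complement.
   Censored wells are never quality-excluded — the quality metrics of a
   non-amplification are meaningless.
3. **NTC screen.** A probe is discarded when its water-only well shows a
   good-quality amplification within 1 cycle (absolute difference; the
   proximity rule is direction-free) of the mean imputed Cq of the probe's
   quality-passing experimental wells. A good-quality NTC amplification
   with no usable experimental wells warns rather than excludes, since the
   proximity criterion is then undefined.
4. **Detection filter.** A probe must be expressed — detected *and*
   quality-passing — in at least a configured fraction of samples
   (default 20%). The fraction is converted to a count with the floor
   convention (20% of 56 realizes at 11), which keeps miRNAs that are
   fully detected in one of eight design cells (7 samples) only if they
   also appear sporadically elsewhere; the ceil convention is available in
   the configuration.

## Endogenous controls

Vendor software ranks candidate normalizers by a proprietary stability
score. The package substitutes a transparent, monotone criterion: the
across-sample standard deviation of imputed Cq (group-blind), with a hard
eligibility gate requiring expression in **every** sample. The control
list can also be forced through the configuration, for panels that carry
designated non-changing control probes. A probe may serve as control and
test probe simultaneously only under an explicit override, which warns: a
changing normalizer biases every ΔCq in the study.

## Differential expression

Per-miRNA two-sided Welch tests (unequal variances, Welch–Satterthwaite
degrees of freedom) compare ΔCq between two groups. The
Benjamini–Hochberg step-up runs across exactly the family of tested
probes — probes with fewer than two usable values in a group are reported
untested and never enter the family size $m$ — and the realized threshold
$p_{(k)}$ is reported so the significance line of a volcano plot is
reproducible for that family. A probe is *significant* only when BH-rejected
**and** showing at least the configured fold change (default 1.5);
fold-change probes at $p < 0.05$ without BH rejection are labelled
suggestive. The default $q = 0.20$ is the conventional
hypothesis-generating level for small biomarker panels; pathway
over-representation uses the stricter $q = 0.01$.

Degenerate inputs have explicit contracts: two zero-variance groups with
equal means give $t = 0, p = 1$; with unequal means, $p = 0$ with a
warning (the evidence is formally infinite, but the situation usually
indicates constant imputed values and deserves attention).

Genotype effects are assessed within each sex by a fixed-effects two-way
ANOVA (disease × APOE, main effects + interaction) per probe, with Tukey
HSD over the four cell means using the pooled ANOVA error term
(studentized-range distribution). No three-way disease × sex × APOE model
is fitted: at 7 samples per cell a three-way interaction is
under-powered, and the stratified analysis keeps the error terms honest.
`anovaFromCellSummaries()` reconstructs a main-effect F from published
per-cell mean/SD/n alone (between-SS from size-weighted level means,
within-MS from cell variances), which is how covariate tables printed at
one decimal place are checked: reconstructed F values then differ from
the original by the input rounding, so they are treated as reference
values, not exact targets.

## Fraction pools and target ensembles

Presence/absence profiling calls a miRNA expressed in a
size-exclusion-chromatography fraction pool when it is expressed in at
least a configured number of donor samples (default 2 of 4), and a
three-set Venn partition decomposes the pools into seven disjoint
regions whose counts sum to the union.

Prediction tables are filtered at the conventional cutoffs — retain
CWCS ≤ −0.3 (TargetScan-style; more negative predicts stronger
repression) and target score ≥ 60 (miRDB-style; boundary kept, since the
published exclusion rule is strict "< 60"). The union, intersection and
single-source strategies are benchmarked against validated interaction
pairs by classifying every (miRNA, gene) pair of a **declared closed
universe**. No universally agreed universe exists for such benchmarks;
the default is the union of all genes in both prediction tables plus the
validated genes — the smallest defensible closed world — and it is always
explicit and overridable, because sensitivity/precision/specificity move
substantially with the universe choice. Strategy selection is
lexicographic (sensitivity, then precision, then specificity) by default,
with the full benchmark table attached for audit. Pathway
over-representation is a one-sided hypergeometric test per gene set with
BH control across the tested sets — a generic, open replacement for
knowledge-base pathway tools whose content cannot be redistributed.

# The synthetic-data generator

`syntheticSpec()` / `generateCqDataset()` emulate the statistical
structure the analysis assumes:

* a balanced 2×2×2 design (diagnosis × sex × APOE), default 7 samples per
  cell (56 total);
* 190 test probes with baseline mean Cq drawn uniformly on 24–33 (the
  realistic dynamic range of biofluid EV miRNA panels) and within-group
  SD 0.8 cycles — a typical biofluid qPCR replicate spread, chosen so a
  0.585-cycle (1.5-fold) shift at n = 28 per group gives high but not
  saturated power, keeping power tests informative;
* 5 endogenous-control probes at SD 0.15 cycles, baselines near the
  bottom of the range, exempt from quality failures — controls are by
  definition probes that showed stable good-quality expression everywhere;
* right-censoring at the ceiling: a Gaussian draw above 34 is emitted as
  the undetected sentinel, which makes the detection probability a probit
  function of the distance between baseline and ceiling — probes near the
  ceiling are partially detected, as in real panels;
* a 2% per-well quality-failure rate (amplification score or Cq
  confidence drawn below threshold, split evenly);
* one NTC well per probe; planted contaminated probes amplify within
  0.8 cycles of their experimental mean, clean probes stay undetected;
* planted effects as ΔΔCq shifts on the Cq scale (a 1.5-fold increase in
  the test level is −log2 1.5 ≈ −0.585 cycles), on the diagnosis, sex or
  APOE factor, or as a pure disease × APOE interaction pattern;
* MMSE drawn around 29.3 ± 1.3 (controls) and 21.5 ± 3.1 (patients), age
  around 72.5 ± 7 years, matching the cohort the design emulates.

Everything is integer-seeded; the same spec reproduces bit-identical
output. The truth list records baselines, planted effects, contaminated
probes and quality-failed wells, so tests can assert exact recovery.

What the generator does **not** emulate: plate spatial effects,
amplification-efficiency differences between probes, melt-curve
artefacts, between-plate batch effects, or correlated miRNA co-expression.
Passing tests on synthetic data therefore validate the *arithmetic and
decision logic* of the pipeline under its own model assumptions; they do
not show that the model assumptions hold for any particular instrument
export.

# Numerical and design choices

* **Threshold conventions.** Detection-count floor vs ceil is
  configurable (floor default); quality thresholds pass at equality; the
  NTC window is an absolute difference.
* **BH implementation.** The step-up is implemented directly (sorted
  ranks, largest $k$ with $p_{(k)} \le kq/m$) so the realized threshold
  is available; it is property-tested against `p.adjust(·, "BH")` and an
  exhaustive-subset oracle for $m \le 10$.
* **Means over censored values.** Group means of ΔCq include
  ceiling-imputed 34s from quality-passing wells and omit
  quality-excluded wells; unequal group sizes are handled by the
  arithmetic mean.
* **Tie-breaks.** Control ranking ties break by probe id; strategy-
  selection ties fall to declared table order and are messaged.
* **Problem sizes in the test suite.** Simulation-based checks use 75-probe
  families at n = 28 per group over 200 replicates (FDR calibration,
  planted-effect ranking), 300–400 replicates for ANOVA type-I checks,
  and ~500-sample runs for law-of-large-numbers checks of the generator;
  these sizes give Monte-Carlo errors small enough for the asserted
  bounds while keeping the default suite quick on one CPU.

# Known limitations

* Quantification is the exact-doubling 2^(−ΔΔCq) model; no
  efficiency-corrected (Pfaffl-type) or standard-curve absolute
  quantification.
* Censored values enter group means as the ceiling constant; no
  likelihood-based censored regression (e.g. Tobit) is attempted, matching
  the field-standard workflow the package makes reproducible.
* The endogenous-control stability score is a transparent substitute for
  vendor scores and will not reproduce their rankings exactly.
* Benchmark metrics depend strongly on the declared universe; published
  values obtained under unstated universes are generally not recoverable.
* A statistically adversarial case: a probe can be both a configured
  control and a test probe only under an override, and the resulting
  inference on that probe is circular by construction — the package warns
  but does not forbid it.
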