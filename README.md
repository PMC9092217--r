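# miRcq

Quality control, relative quantification and differential expression for
miRNA qPCR arrays, built for biofluid extracellular-vesicle (EV) studies.

## The problem

TaqMan-style miRNA array studies of cerebrospinal-fluid EVs produce
well-level exports: one quantification cycle (Cq) per sample and probe,
together with vendor quality metrics (amplification score, Cq confidence)
and water-only no-template-control (NTC) wells. Turning those into
defensible biomarker calls requires a chain of decisions — what counts as
detected, which wells to exclude, which probes are contaminated, how to
normalize, how to control the false discovery rate across a family of a
few dozen tested miRNAs — that is usually buried in point-and-click
software. `miRcq` makes the whole chain explicit, configurable and
testable:

1. **Well QC** — Cq values above a detection ceiling (default 34), or
   reported "Undetected", are censored at the ceiling; detected wells with
   amplification score < 1.0 or Cq confidence < 0.8 are excluded; probes
   whose NTC well amplifies within 1 cycle of the experimental mean are
   dropped as contaminated; probes expressed in fewer than 20% of samples
   (floor convention: 11 of 56) are filtered out.
2. **Relative quantification** — within each sample,
   ΔCq = Cq(miRNA) − mean Cq(endogenous controls); between groups,
   ΔΔCq = mean ΔCq(test) − mean ΔCq(reference) and fold change
   RQ = 2^(−ΔΔCq), so RQ > 1 means increased expression in the test group.
3. **Differential expression** — per-miRNA Welch t-tests on ΔCq,
   Benjamini–Hochberg step-up across exactly the tested family (default
   q = 0.20), and a 1.5-fold-change call; a probe is significant only when
   both criteria hold. Sex-stratified two-way ANOVA (disease × APOE
   genotype) with Tukey HSD post hocs covers the genotype contrasts.
4. **Fraction profiling** — presence/absence sets of miRNAs across
   size-exclusion-chromatography fraction pools, with three-set Venn
   partitioning.
5. **Target ensembles** — score-threshold filtering of TargetScan-style
   (CWCS ≤ −0.3) and miRDB-style (score ≥ 60) prediction tables,
   union/intersection benchmarking against validated interaction pairs
   (sensitivity/specificity/precision over a declared closed universe),
   and hypergeometric pathway over-representation.
6. **Synthetic studies** — a generator that emulates a balanced
   2×2×2 cohort (disease × sex × APOE, n = 7 per cell, 56 samples,
   ~190 probes + 5 tight endogenous controls, Gaussian Cq noise with
   right-censoring at 34) with planted effects and recorded ground truth,
   so every stage can be validated without instrument data.

The central data object is a `CqExperiment`, a `SummarizedExperiment`
holding the imputed Cq matrix plus detection and quality masks; normalized
values live in a `NormalizedCq`.

## Worked example

```r
library(miRcq)

spec <- syntheticSpec(
    effects = data.frame(probe = 1:4, factor = "diagnosis",
                         shift = -log2(1.5)),   # 1.5-fold AD increase
    ntcContaminated = "12", seed = 42)
study <- generateCqDataset(spec)
res <- runPipeline(study$wells, study$samples,
                   group = "diagnosis", testLevel = "AD")
```

This prints (output from the code above):

```
> res$cqex
CqExperiment: 195 probes x 56 samples
  expressed wells (detected & qc-pass): 10667 / 10920
  no-template-control records: 195
  diagnosis: AD=28 CTL=28
> as.character(res$ntcExcluded)
[1] "syn-miR-0012"
> res$controls
[1] "syn-ctrl-03" "syn-ctrl-04" "syn-ctrl-02" "syn-ctrl-05" "syn-ctrl-01"
> subset(res$de, significant,
         select = c(probe_id, delta_delta_cq, rq, p_value))
      probe_id delta_delta_cq   rq  p_value
3 syn-miR-0003         -1.038 2.05 2.78e-05
4 syn-miR-0004         -0.688 1.61 1.85e-03
> attr(res$de, "bh_threshold")
[1] 0.00275
```

Reading: the NTC screen recovered exactly the planted contaminated probe;
the five tight control probes were auto-selected as the normalizer; two of
the four planted 1.5-fold AD increases reached both the BH rejection and
the fold-change call at this seed (an honest reflection of the power a
0.585-cycle shift has at n = 28 per group with 0.8-cycle noise), with
ΔΔCq < 0 and RQ > 1.5 as expected for increases; the realized BH
significance line for this family is reported alongside.

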