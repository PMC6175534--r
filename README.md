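# proteoturn

Protein turnover kinetics and proteostasis analysis for dynamic
stable-isotope labeling proteomics.

## What problem this solves

When an organism is switched to food carrying a heavy amino acid (e.g.
D3-leucine), mass spectrometry can report, per protein, the fraction of
molecules synthesized after the switch. Comparing degradation kinetics and
abundance between a mutant and its control then reveals *which* protein
quality-control route is altered: a blocked degradation pathway slows the
turnover of its substrates (half-life fold change > 1) and tends to raise
their abundance, while other perturbations — such as dysregulated
extracellular-vesicle (EV) production — produce the opposite signature of
faster turnover with increased abundance. `proteoturn` is for proteomics
analysts who have such fraction-newly-synthesized and intensity tables
(or want simulated ones) and need the full inference chain behind this
kind of study.

At its core is the first-order labeling model

    f(t) = p · (1 − e^(−k·t)),    t½ = ln 2 / k,

fit per protein and genotype by pooled least squares, with `p` a fixed
plateau absorbing precursor-pool effects. Around the estimator the package
provides:

* replicate-level QC (exclusion at coefficient of variation ≥ 0.25, in
  both genotypes of a comparison), shared-peptide filtering, and flagged
  handling of degenerate fits;
* turnover fold changes with per-protein Welch t tests, and abundance
  fold changes at the second time point with Benjamini–Hochberg calls at
  FDR 0.05;
* quadrant classification of turnover-vs-abundance changes and per-group
  percentages;
* group-level inference: nested ANOVA (genotype tested against
  protein-within-genotype variance) for mean fold changes, Fisher-exact /
  chi-squared prevalence enrichment, and cross-dataset fold-change
  correlations;
* a KFERQ-like motif scanner for endosomal-microautophagy targeting
  sequences (five-residue windows anchored by a terminal Q with 1–2 basic,
  1–2 bulky hydrophobic and exactly one acidic residue), validated
  exhaustively against a brute-force rule checker;
* a ground-truthed synthetic-data generator (labeling design: 3 biological
  replicates at 120 h and 264 h) so the entire pipeline runs and is tested
  without any external data.

## Worked example

Twelve measurements of one protein (two genotypes × three replicates × two
labeling times):

```r
library(proteoturn)

m <- data.frame(
  protein_id = "Cyt-c-p", genotype = rep(c("mutant", "control"), each = 6),
  replicate  = rep(rep(c("r1", "r2", "r3"), each = 2), 2),
  time_h     = rep(c(120, 264), 6),
  fraction_new = c(0.38, 0.66, 0.41, 0.69, 0.36, 0.63,
                   0.50, 0.78, 0.53, 0.81, 0.48, 0.76))

fit <- turnover_fit(m)
fit$estimates[, c("protein_id", "genotype", "t_half", "cv", "passed_qc")]
#>   protein_id genotype   t_half         cv passed_qc
#> 1    Cyt-c-p  control 119.2312 0.07376385      TRUE
#> 2    Cyt-c-p   mutant 170.5911 0.08212651      TRUE

turnover_fold_change(fit, "mutant", "control")
#>   protein_id t_half_mutant t_half_control       fc
#> 1    Cyt-c-p      170.5911       119.2312 1.430759
```

The control half-life is 119 h, the mutant 171 h; replicate CVs of 0.07
and 0.08 pass the 0.25 QC gate, and the fold change of 1.43 means turnover
of this protein is 1.43× slower in the mutant. Motif scanning works on any
sequence source:

```r
kferq_scan("AAKFERQAA")
#>   protein_id start window anchor n_basic n_hydrophobic n_acidic
#> 1        seq     2  KFERQ    end       2             1        1
```

A complete simulated experiment — generation, fitting, QC, fold changes,
BH-corrected abundance calls, motif annotation, quadrants, enrichment,
JSON summary and checksummed manifest — runs with:

```r
report <- run_pipeline(
  pipeline_config(sim = sim_config_gba1b_like(seed = 1)), "run_out")
report$comparisons$mutant_vs_control$quadrants$ev
```

or from the shell via `Rscript inst/scripts/run_pipeline.R --preset gba1b
--seed 1 --out run_out`.

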