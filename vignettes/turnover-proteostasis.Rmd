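---
title: "Turnover kinetics and proteostasis analysis with proteoturn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Turnover kinetics and proteostasis analysis with proteoturn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoturn)
```

## The measurement and the model

In a dynamic stable-isotope labeling experiment, animals are switched to a
diet carrying a heavy amino acid (for example D3-leucine) and sampled after
fixed labeling durations. Mass spectrometry then reports, for each protein,
the *fraction newly synthesized* — the proportion of its molecules made
after the diet switch. For a protein degraded by first-order kinetics with
rate $k$ (h$^{-1}$), that fraction follows

$$ f(t) \;=\; p\,\bigl(1 - e^{-kt}\bigr), \qquad t_{1/2} = \frac{\ln 2}{k}, $$

where $p \in (0, 1]$ is the asymptotic label fraction. Real precursor pools
are not instantly and completely labeled (dietary amino acids are recycled
from degraded protein), which depresses the asymptote below 1; `proteoturn`
absorbs all such precursor effects into the single constant `plateau`
rather than modelling the precursor pool explicitly. This is sufficient for
*fold-change* analyses between genotypes measured under the same labeling
protocol, because the same $p$ applies to both sides of the ratio. It is
not a substitute for a full precursor-pool correction when absolute
half-lives are the quantity of interest.

`turnover_fit()` estimates $k$ per protein and genotype by least squares
over all pooled measurements (peptides, replicates and time points
together). The sum of squares is nearly flat in $k$ once $kt$ saturates, so
the optimizer first locates the basin on a log-spaced rate grid, refines it
with a bounded line search, and polishes with Newton steps on the gradient;
on noise-free data the estimate is exact to near machine precision, and for
a single time point it reduces to the closed-form inversion
$t_{1/2} = t \ln 2 / (-\ln(1 - f/p))$.

Degenerate data are flagged rather than thrown: all-zero fractions give
$k = 0$ (infinite half-life), fractions at or above the plateau at every
time point give a rate capped at $\ln 2 / 0.1$ h$^{-1}$, and fewer than
`min_measurements` pooled points (default 6, configurable to 15 for
sparser multi-strain designs) leaves the protein excluded with `NA`
estimates. Flagged fits never enter fold changes: a capped rate is an
artifact of the bound, not a measurement.

## Quality control

Half-lives are refit within each biological replicate (single-point
replicates use the closed-form inversion, averaged over their points), and
the coefficient of variation of the replicate half-lives is the QC
statistic: a protein passes only when $\mathrm{CV} < 0.25$, with a CV at
exactly 0.25 excluded. Comparisons between genotypes require the protein to
pass in **both** genotypes; every exclusion is written to a ledger with a
reason code. The threshold comparison carries a $10^{-9}$ relative guard so
the boundary decision does not flip on refit rounding.

## Fold changes, significance and quadrants

Fold change is always mutant over control: a half-life fold change above 1
means *slower* turnover in the mutant. Per-protein turnover significance
uses a two-sided Welch $t$ test on replicate half-lives (at least three
finite replicate values per genotype; proteins below that are *untestable*,
not non-significant). A small variance floor replaces a zero pooled
standard error, so identical groups give $p = 1$ and separated constant
groups give a vanishingly small positive $p$. These per-protein flags are
deliberately unadjusted (threshold `alpha`, default 0.05) — they feed the
prevalence comparisons below, where the group-level test carries the
inferential weight.

Abundance is compared at the second (latest) labeling time point, where
genotype differences are most pronounced: per protein, the difference of
mean log2 intensities is tested with a fixed-effect two-group linear model,
and Benjamini–Hochberg adjustment across all testable proteins drives the
three-way `increased` / `decreased` / `unchanged` call at FDR 0.05. The
peptide-level mixed model used by dedicated abundance tools is intentionally
simplified to protein-level intensities, the package's default granularity.

Joining both axes gives the quadrant picture. The turnover axis splits at
fold change 1; the abundance axis splits either at fold change 1
(`fc_threshold` mode) or at the significance call (`significance` mode). A
fold change of exactly 1 goes to the non-slower / non-increased side — a
boundary convention with measure zero under noise. The composite region
"slower and increased-or-unchanged" (the expected signature of a degradation
block) is reported in both readings, because "unchanged" has no natural
definition on a continuous axis: by significance call (default) and by
fold-change threshold.

## Group-level inference

*Nested ANOVA.* Group mean fold-change significance uses a two-level nested
analysis of variance on replicate half-lives: genotype is the fixed effect,
protein is nested within genotype, and the genotype mean square is tested
against the protein-within-genotype mean square — replicate-level variation
never inflates the genotype test. Sums of squares are computed directly
(weighted genotype and cell means), matching sequential linear-model sums
of squares also in unbalanced data; a zero denominator mean square is
reported as $p = 1$ with a flag. The group mean fold change is the
arithmetic mean (with SD) of per-protein half-life ratios. Because the
observations are raw half-lives, a heavy-tailed half-life distribution
makes this test conservative relative to a log-scale analysis; we keep the
raw scale as the field's convention for this design and report the mean
fold change alongside.

*Prevalence enrichment.* Whether an outcome (significantly slowed turnover,
significantly faster turnover, increased abundance) is over- or
under-represented in a protein group is tested on the 2×2 table of group
membership versus outcome: Fisher's exact test (two-sided) when any
expected cell is below 5 or the total is at most 1000, otherwise a
chi-squared test of homogeneity without continuity correction. The switch
is a concrete, configurable stand-in for the usual "exact test unless the
table is large" practice; the test actually used is recorded in every
result. Odds ratios use the Haldane 0.5 correction when a cell is zero, and
a zero margin short-circuits to $p = 1$ with a flag.

*Cross-dataset correlation.* Agreement between two mutants' effects is
measured by the Pearson correlation of log2 fold changes over the common
proteins (Spearman available); fewer than three common proteins is
untestable.

## The KFERQ-like motif scanner

Endosomal microautophagy targets cytosolic proteins through five-residue
chaperone-targeting ("KFERQ-like") sequences. A window qualifies when it
begins or ends with glutamine and, over the four residues excluding that
anchor Q, contains one or two basic residues (K, R), one or two bulky
hydrophobic residues (F, I, L, V) and exactly one acidic residue (D, E).
Four slots leave room for class counts totalling 3 or 4; the default
accepts the 1/1/1 case with one unconstrained residue, and a `strict` flag
requires all four slots to be class members — both variants are exposed
because the published rule wording admits either reading. Interior
glutamines count as unconstrained, windows containing non-standard letters
(B, J, O, U, X, Z) are invalid, coordinates are 0-based and half-open, and
all overlapping hits are reported while per-protein motif status uses
presence. The scanner is validated in the test suite against an
independently coded brute-force checker over all 32,768 pentapeptides on an
8-letter alphabet.

## What the synthetic generator emulates — and what it does not

Every stage is testable without external data because the generator
produces ground-truthed experiments: log-normal base half-lives (median
48 h, $\sigma_{\log} = 1$, spanning hours to weeks as head proteomes do),
multiplicative genotype-by-class half-life effects, additive log2
abundance shifts, three biological replicates at 120 h and 264 h, additive
Gaussian noise on label fractions (SD 0.05) clamped to $[0,1]$ with
clamping counted, replicate log2-intensity noise (SD 0.25), and sequences
over the 19 standard residues excluding glutamine — which makes unplanted
sequences provably motif-free, since a valid window needs a terminal Q.
`plant_motifs()` inserts randomly composed valid windows and neutralizes
the residues beyond the anchor so the planted window is the only one it
creates, giving exact recall/false-positive accounting. Optional
pseudo-peptide fan-out and a configurable shared-peptide fraction exercise
peptide pooling and the shared-peptide exclusion filter.

Two further choices deserve note. First, base half-lives are floored at
`halflife_min_h` (8 h): a protein with a half-life far below the first
sampling time is fully labeled at every sampled time, so its rate is
unidentifiable under this design — such proteins are a property of the
labeling schedule, not of the estimator, and are excluded from the
simulation rather than generated as unlearnable cases. Second, intensity
baselines are drawn at $\log_2$ scale around 20 (typical MS intensity
magnitudes); their absolute level cancels from all fold changes.

The generator does **not** emulate raw spectra, isotope envelopes,
leucine-recycling precursor dynamics, missing-value mechanisms,
between-run normalization artifacts, or correlated noise across peptides
of one protein. Passing tests therefore demonstrate correctness of the
estimators and inference under a clean bounded-noise model, not robustness
to every pathology of real LC-MS data.

## Preset experiments and problem sizes

Two presets bundle the study conditions used throughout the examples and
the acceptance script: `sim_config_atg7_like()` (organellar autophagy
substrates slowed ×1.5 with a +0.25 log2 abundance shift — the signature
of autophagy ablation) and `sim_config_gba1b_like()` (EV-associated
proteins faster ×0.7 with +0.5 log2 abundance, mitochondria mildly slowed
×1.15 — the signature of EV dysregulation without autophagy failure). Both
use 150/50/30 mitochondrial/ribosomal/ER-peroxisomal proteins, 250
EV-associated and 320 unclassified proteins, a scale at which a full
pipeline run completes in well under a minute on one CPU while group sizes
after QC remain close to those of a real head proteome study. Calibration
checks use 200 simulated null datasets for the nested ANOVA and a
600-protein null experiment for the per-protein $t$ test.

```{r, eval = FALSE}
report <- run_pipeline(
  pipeline_config(sim = sim_config_gba1b_like(seed = 1)),
  out_dir = "gba1b_like_run")
report$comparisons$mutant_vs_control$quadrants$ev
```

## Known limitations

* The plateau is a single fixed constant; no per-protein or per-time
  precursor correction is attempted, so absolute half-lives are
  model-dependent even though fold changes are robust.
* The nested ANOVA analyses raw half-lives; for heavy-tailed groups this
  is conservative, and a log-scale variant may be preferable when absolute
  calibration of the group test matters.
* Isoform groups are carried as independent analysis units via the
  `isoform_group` column; the package does not itself cluster peptides
  into isoform groups.
* Group lists are opaque identifier sets: no ortholog mapping or
  annotation mining is performed, and identifier normalization is limited
  to whitespace and case.
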