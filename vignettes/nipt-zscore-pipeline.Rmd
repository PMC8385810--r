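---
title: "Z-score aneuploidy screening from shallow cfDNA sequencing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Z-score aneuploidy screening from shallow cfDNA sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The screening problem

Noninvasive prenatal testing (NIPT) screens for fetal chromosomal
abnormality from cell-free DNA (cfDNA) in maternal plasma. A small fraction
of that cfDNA — the *fetal fraction*, typically 4–20% and rising with
gestational age — is of placental origin. If the fetus carries a trisomy,
the affected chromosome is over-represented in plasma by a factor

$$ 1 + \frac{f \cdot m}{2}, $$

where $f$ is the fetal fraction and $m$ the fraction of fetal (placental)
DNA carrying the abnormality ($m = 1$ for a non-mosaic trisomy). At
$f = 10\%$ that is a 5% excess — invisible per read, detectable only
because shallow whole-genome sequencing counts hundreds of thousands of
fragments per chromosome. The statistic of record is the z-score of the
chromosome's share of reads against a euploid reference panel: with
$p_c$ the sample's chromosome share and $(\mu_c, \sigma_c)$ the panel mean
and SD,

$$ z_c = \frac{p_c - \mu_c}{\sigma_c}. $$

A sample is reported screen-positive for chromosome 21, 18 or 13 when
$z > 3$ **and** the fetal fraction is at least 4%; calls with $3 < z < 5$
carry a *gray-zone* flag (false positives concentrate there), and samples
with unknown or sub-threshold fetal fraction are no-calls rather than
negatives. Subchromosomal events use Stouffer's method over 1-Mb windows:
$Z = \sum_i z_i / \sqrt{k}$ over a candidate run of $k$ windows, with
$Z > 5$ called a microduplication and $Z < -5$ a microdeletion.

The package implements this pipeline end to end — forward simulation with
known truth, GC-bias correction, panel construction, calling, and
screening-performance arithmetic — so that every stage is testable without
access to patient data.

## The forward model (what the simulator emulates)

`simulate_sample()` draws binned fragment counts over 1-Mb windows of an
hg19-scale genome. The expected rate of bin $b$ is

$$ \lambda_b \propto \ell_b \cdot g(\mathrm{GC}_b) \cdot c_b, $$

with $\ell_b$ the bin length, $g$ a smooth unimodal GC-efficiency curve
(`gc_bias_curve()`; amplitude varies between samples, which is exactly the
artifact the correction chain exists to remove), and $c_b$ the mixture copy
factor $(1-f)\,c^{\mathrm{mat}}_b/2 + f\,c^{\mathrm{fet}}_b/2$. Maternal
XX background contributes no chromosome Y beyond a configurable
mapping-noise floor (1% of the per-base rate by default); a male fetus
contributes one X and one Y at half weight each. Mosaicism shrinks the
fetal copy state toward the sex-matched euploid state. Counts are drawn as
a gamma-weighted multinomial — negative-binomial-like overdispersion
(`nb_size`, default $2\times10^4$, i.e. variance about 1.15× Poisson at
typical bin depth) conditioned to sum exactly to the drawn total, so count
conservation holds by construction.

Defaults encode the study conditions this package targets: total depth
log-normal around $9\times10^6$ fragments (0.1× coverage at ~35-bp
semiconductor reads), gestational age $16.99 \pm 2.82$ weeks (range 9–36),
maternal age per indication stratum (advanced maternal age truncated at
35), BMI $22.52 \pm 3.16$, and a fetal-fraction model

$$ f = \mathrm{clip}(0.015 + 0.005\,\mathrm{GA} + \varepsilon,\ 0.01,\ 0.40),
\qquad \varepsilon \sim N(0, 0.0145), $$

whose parameters were set by a closed-form calibration so that the
Pearson correlation between fetal fraction and gestational age over a
cohort-like age distribution is about 0.70, and mean fetal fraction is
about 10% at the median gestational age — both properties the acceptance
suite re-measures. The cohort generator (`simulate_cohort()`) additionally
draws indications (53.1% abnormal serum screening, 23.0% advanced maternal
age, 17.6% voluntary, the rest split among thickened nuchal translucency,
other ultrasound findings, twin/IVF, missed screening, surgery
contraindication and other risks), abnormality classes at the confirmed
prevalences of a 14,316-pregnancy referral cohort (e.g. trisomy 21 at
46/14,316), a record-level screen-error model, and confirmatory-test
uptake per class (98% for trisomy-21 positives down to ~42% for rare
classes), so that evaluation tables have realistic missingness.

What the simulator does **not** emulate: mappability and blacklist
structure, wave artifacts, vanishing twins, maternal tumours, segmental
maternal CNVs, or indication-dependent abnormality enrichment (prevalences
are global). A maternal 47,XXX with a euploid female fetus *is* simulated,
because it is the designed mechanism for sex-chromosome false positives.
Passing tests therefore demonstrate internal statistical correctness of
the pipeline under this generative model, not clinical performance on real
plasma.

## The three-step GC correction

Raw counts are corrected in the order LOESS → intra-run median
normalization → quadratic residualization (`normalize_run()`):

1. **LOESS** (`loess_gc_correct()`): count vs GC, degree 1, span 0.3,
   robust ("symmetric") fitting, weights proportional to bin length so
   zero-count and short terminal bins still inform the fit. The fit uses
   autosomal bins only — sex-chromosome dosage is signal, not bias — and
   each bin is rescaled by median(fitted)/fitted, with the global median
   anchored so the correction changes shape, never scale.
2. **Intra-run median normalization** (`intra_run_normalize()`): each
   usable autosomal bin is divided by the across-sample median of that
   (depth-normalized) bin within the sequencing run, then each sample is
   rescaled to unit mean over usable autosomes. X and Y bins are depth-
   and length-normalized but **not** median-divided: the run median of a
   sex-chromosome bin depends on the run's fetal-sex mix, and dividing by
   it would erase the chrY dosage that fetal-fraction estimation reads.
   A single-sample run is returned unchanged; autosomal bins with zero
   run median are retired for the whole run.
3. **Quadratic residualization** (`residualize_linear()`): a final
   least-squares fit of value on $\mathrm{GC} + \mathrm{GC}^2$ over usable
   autosomes, replacing values by residual + fitted mean.

The steps operate on counts (not log-counts or ratios); that choice, like
the span, the quadratic basis and the median definition of the intra-run
step, is an interpretation — the pipeline this package models names the
three steps without defining them. All are configurable.

**Denominators.** Chromosome and window z-scores are computed on
*autosomal-denominator* shares (`chromosome_shares()`,
`window_proportions()`): each value divided by the autosomal total. With a
full-genome denominator, a male fetus's chrX deficit (about $f/2 \cdot 5\%$
of the genome) would shift every autosomal proportion upward by roughly
0.9 panel SD and wreck euploid calibration; the autosomal denominator makes
autosomal z-scores invariant to sex-chromosome dosage while X and Y shares
ride on top of it. The descriptive full-genome proportion vector
(`chromosome_proportions()`, summing to 1 over all 24 chromosomes) is kept
for reporting.

**Run pairing.** Because the intra-run step divides by a noisy run median,
a test sample must be normalized inside a run whose median reference is
statistically the same one the panel saw. `simulate_reference_panel()`
therefore returns its runs' LOESS-corrected profiles as *companion sets*,
and `call_with_reference()` normalizes each new sample inside one of them,
rotated across samples. Rotating makes the run-median batch effects cancel
exactly between panel mean and test batch; without it the batch mean of
euploid z-scores drifts by several tenths of an SD.

## Reference panel and calling

`build_reference_panel()` takes corrected euploid female-fetus profiles
(at least `min_panel_size = 30`; the bundled simulation workflows use
100–160) and computes per-chromosome and per-window means and unbiased
SDs, rejecting any zero-SD unit. Leave-one-out z-scores of the members
(leave-one-out mean, full-panel SD — the combination whose member mean is
identically zero) are retained as QC. The chrY female baseline $r_{Y0}$
(mapping noise) comes from the same profiles; the male dose-response is
calibrated by regressing male-fetus chrY shares on their known fetal
fractions, stored as $r_Y = 2(\mathrm{slope} + r_{Y0})$ so that

$$ \hat f = \mathrm{clip}\!\left(
   \frac{p_Y - r_{Y0}}{r_Y/2 - r_{Y0}},\ 0,\ 1\right). $$

Fetal fraction is therefore chrY-based and male-only; for female fetuses
an externally supplied value (in practice, from the assay kit) is passed
through, and an unknown fetal fraction yields `no_call_low_ff` rather than
a guess — the $\geq 4\%$ gate is part of the decision rule, not an
afterthought. A documented quirk: in a 47,XYY pregnancy the chrY estimate
doubles (two Y copies); classification handles this, but the reported
fetal fraction for such samples is the Y-dosage-implied value.

**Sex karyotype** (`classify_sex_karyotype()`): Y presence is decided by
comparing $p_Y$ with the midpoint between the female baseline and the
male-fetus expectation at the sample's fetal fraction. Without Y, the ±3
convention on the chrX z-score gives 45,X ($z_X < -3$), 47,XXX
($z_X > +3$) or XX — and a maternal 47,XXX with a euploid female fetus
triggers the XXX branch, reproducing the known false-positive mechanism.
With Y present, the chrX share is tested against the *male* expectation at
the chrY-implied fetal fraction: an excess beyond +3 SD means an extra X
dose relative to an XY fetus. The ambiguity between 47,XXY (true extra X)
and 47,XYY (the doubled chrY estimate makes the male expectation
overshoot) is resolved by the chrX z against the female mean: XXY sits at
the female level ($z_X > -3$), XYY significantly below ($z_X \leq -3$).
Conflicting signals return `undetermined`. Thresholds reuse the ±3
convention for symmetry with the autosomal rule.

**CNV segmentation** (`call_cnv_segments()`): per chromosome, maximal runs
of consecutive windows with single-window $|z| > 2$ (seed threshold) and
consistent sign are combined by Stouffer's formula; a segment is emitted
when $|Z| > 5$, typed by sign. Two emitted same-sign segments separated by
exactly one sub-threshold window merge if the merged statistic still
passes. The seed threshold and one-gap merge are this package's additions
(only the ±5 region rule is externally given); both are configurable. The
scan covers autosomes only and skips chromosomes already flagged as
whole-chromosome aneuploidies, so a trisomy is not re-reported as a
chromosome-length duplication.

## Performance evaluation

`confusion_stats()` reproduces follow-up-study arithmetic: PPV = TP/P with
P all screen positives (confirmed or not), sensitivity = TP/(TP+FN),
FP = P − TP among the confirmed, and specificity/NPV against the
followed-up confirmed-negative pool; declined and lost-to-follow-up
outcomes are excluded before counting, and zero-denominator cells render
NA. `chi_square_2x2()` is the uncorrected Pearson statistic — the Yates
continuity correction is deliberately absent, because the group
comparisons this package reproduces were computed without it.
`stratified_report()` assembles the per-class and per-indication tables
and headline rates; display rounding is half-up to two decimals
(`format_pct()`), while internal values keep full precision.

## Numerical and testing choices

* Problem sizes: the test suite runs most operations on a five-chromosome
  miniature genome (about 190 bins, 2×10⁵ fragments) and reserves the
  genome-wide grid (3,113 bins) for calibration properties: 100 euploid
  samples for z normality, 200 trisomy-21 replicates at 3×10⁶ fragments
  for power, 500 euploids for the false-positive rate, 200 male euploids
  for fetal-fraction recovery, and 100 replicates of a 3-Mb deletion at
  15% fetal fraction for CNV boundary accuracy. These sizes give
  Monte-Carlo standard errors comfortably inside the asserted bands.
* The variance-reduction property of the correction chain is asserted as a
  paired one-sided t-test across the 22 autosomes plus a majority check,
  not as strict per-chromosome reduction: a chromosome whose GC
  composition matches the genome average has nothing to gain from
  correction and pays a small run-median noise cost.
* Degenerate inputs: constant GC makes LOESS the identity (with a
  message) and skips the residual regression; all-zero profiles,
  empty window sets, zero-SD panel units and zero-margin 2×2 tables are
  rejected with informative errors rather than propagating NaN.
* Seeds: every stochastic helper takes a seed and restores the caller's
  RNG state; identical seed and truth give bit-identical counts.

## Known limitations

* Female-fetus fetal fraction is not estimable from chrY; without an
  external value those samples are no-calls. Real deployments use
  SNP-based or fragment-size estimators that are out of scope here.
* Prevalences are indication-independent, so the per-indication efficacy
  table will not show the enrichment a real high-risk referral stream
  produces; only its arithmetic is exercised.
* The specificity/NPV denominators depend on which follow-up pool a study
  used, which printed tables generally under-determine; the functions take
  the pool as an explicit input rather than asserting one.
* Gray-zone behaviour is modelled only through the decision rule; the
  biological drivers of gray-zone false positives (confined placental
  mosaicism, low-level maternal mosaicism) are not simulated beyond the
  mosaic-fraction scalar and the maternal 47,XXX mechanism.
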