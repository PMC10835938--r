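---
title: "Solanidine as a CYP2D6 activity biomarker: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solanidine as a CYP2D6 activity biomarker: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solanidine)
```

## The problem

CYP2D6 metabolizes a large share of commonly prescribed drugs, and its gene
is among the most polymorphic in the P450 family: no-function alleles, gene
deletions and duplications produce metabolic capacities ranging from poor to
ultrarapid. Genotyping predicts activity imperfectly, so a dietary probe
whose plasma level reads out the enzyme's actual activity is attractive.
Solanidine — the aglycone of the potato glycoalkaloids α-solanine and
α-chaconine, ingested by nearly everyone who eats potatoes — is cleared
almost entirely by CYP2D6, and its plasma concentration and its
metabolite-to-parent ratios track CYP2D6 phenotype closely.

This package implements the full analysis chain for evaluating solanidine
and its metabolite ratios as CYP2D6 biomarkers: genotype-to-phenotype
translation, calibration-curve quantification with censoring at the lower
limit of quantification (LLOQ), log-scale phenotype-group contrasts,
classifier-performance evaluation, a non-targeted feature screen, an
additive-dosage association scan, and in vitro clearance kinetics — plus a
synthetic cohort generator calibrated to published group summaries so the
whole chain is testable without access to the original subject-level data.

## Genotype to phenotype

Each CYP2D6 star allele carries an activity value per copy: 0 (no
function), 0.25 or 0.5 (decreased), or 1 (normal). The activity score (AS)
of a diplotype is the sum over both haplotypes of value × copy number, so
`"*1x2/*5"` (a duplicated normal allele opposite the gene deletion) scores
2. Phenotype classes follow the standard bins:

| AS | class |
|---|---|
| 0 | gPM (poor) |
| 0 < AS < 1.25 | gIM (intermediate) |
| 1.25 ≤ AS ≤ 2.25 | gNM (normal) |
| AS > 2.25 | gUM (ultrarapid) |

Boundary inclusivity is exactly as written; the bins partition the axis.
The bundled table (`default_allele_table()`) assigns the package's default
values per current CPIC practice to the alleles in scope (*1, *2, *39
normal; *9, *17, *29, *41, *59, *65, *69, *88 decreased at 0.5; *10 at
0.25; *3, *4, *5, *6, *11, *13 none). The exact decreased-function values
for some rare alleles vary between guideline versions, so the table is an
argument everywhere, never hard-coded. An allele absent from the table is
an error: silently scoring an unknown allele as normal would bias
phenotypes upward. Subjects whose score cannot be computed (an allele with
`NA` value) classify as `indeterminate` and are excluded from analysis.

The NFIB rs28379954 T>C variant has been proposed to raise CYP2D6 activity
in genotypic normal metabolizers. `apply_nfib_reclassification()`
implements the corresponding sensitivity re-analysis — gNM carriers move to
gUM, nothing else changes — as a switchable option, not a default: the
cohort this package is calibrated to did not support the conversion.

## Quantification and censoring

Calibration uses linear regression of response (analyte / internal-standard
peak-area ratio) on nominal concentration with 1/x weighting, the
bioanalytical convention that keeps relative error flat across a
2500-fold range (0.01–25 ng/mL). `quantify()` inverts the fitted line and
flags responses that invert below zero.

Censoring follows two different rules with different rationales:

* **Parent solanidine below its validated LLOQ (0.01 ng/mL) excludes the
  subject.** A non-quantifiable parent most plausibly means no recent
  solanine intake, and every ratio endpoint has the parent in its
  denominator, so imputation would manufacture data.
* **Metabolite responses below their per-ion LLOQ (defined operationally at
  signal-to-noise 10) are imputed at half the LLOQ** and flagged. The
  metabolites are semi-quantitative (no reference standards exist), and
  half-LLOQ substitution is the standard left-censoring treatment.

Zero or negative responses are treated as below-LLOQ. Censoring is
idempotent, and exclusion is a returned state, never an error.

## Group contrasts

Concentrations and ratios are right-skewed and analyzed on the natural-log
scale throughout; printed values are back-transformed. Group summaries are
geometric means with log-scale t intervals. Demographic covariates (sex,
log bodyweight, study period) are screened once per endpoint by forward
stepwise regression (entry p ≤ 0.05, removal p ≥ 0.10) and the selected set
is then fixed in the phenotype ANOVA. Pairwise class-versus-gNM comparisons
use Fisher's least-significant-difference method: contrast standard errors
come from the pooled residual variance of the full model, CIs use the t
quantile at the residual degrees of freedom, and p-values are deliberately
unadjusted — that is what LSD is, and it matches the published analysis; no
multiple-testing correction is layered on top. Back-transformed contrasts
are geometric-mean ratios, reported alongside percent changes
((ratio − 1) × 100).

The contrast table reports both raw per-group geometric means (with their
own t intervals) and covariate-adjusted model ratios; published tables of
this kind are typically a mixture of the two, and emitting both makes the
provenance of every number explicit.

## Biomarker performance

Each task is one phenotype class versus gNM. Orientation is declared per
task (`orient_scores()`): solanidine concentration scores gPM and gIM
positively (impaired clearance, higher level) and gUM negatively;
metabolite ratios the reverse. Metrics:

* **AUROC** is the tie-aware normalized Mann–Whitney statistic — the
  probability that a random positive outranks a random negative, with
  half-credit for ties.
* **AUPRC** is non-interpolated average precision over distinct score
  thresholds. Interpolated variants can only raise the number; the
  conservative standard is used and documented. The no-skill baseline is
  the positive-class prevalence, reported with every result.
* **F1max** is the maximum over thresholds of the harmonic mean of
  precision and recall.

All three are invariant to strictly increasing score transforms, and a
perfectly separated marker scores 1 on all three. Confidence intervals are
percentile intervals over 1000 class-stratified bootstrap resamples
(positives and negatives resampled separately, preserving prevalence and
guaranteeing both classes in every resample), reproducible given a seed.
Paired marker comparisons reuse the same resample indices for both markers,
so the delta CI respects the within-subject pairing; AUROC differences
additionally get a correlated-ROC (DeLong) z-test, cross-checked in the
test suite against an independent implementation. AUPRC differences are
judged by their bootstrap CI alone.

## Feature screening

The non-targeted metabolomics screen normalizes each feature by removing
the median and dividing by the interquartile range (quartiles by linear
interpolation; zero-IQR features are centered and flagged, not divided).
Random-forest and gradient-boosted regression ensembles are then fitted to
the numeric phenotype code (gPM = 0, gIM = 1, gNM = 2, gUM = 3 — ordinal in
activity, configurable) under a repeated nested cross-validation: five
repeats of twofold CV, with a randomized hyperparameter search scored by
inner twofold mean-squared error inside each outer training fold. The
winning configuration is refitted on the outer training data and its
normalized impurity-decrease importances recorded; "impurity" for
regression trees is the variance reduction at each split, the regression
analogue of the Gini decrease. Importances are averaged over all outer
fits, and a feature whose mean importance exceeds 0.01 in either family is
flagged. A full-data refit importance is reported alongside, since
averaging versus refitting is a genuine convention fork.

The random-forest search draws the per-split feature fraction from
0.3–1.0 of the panel. Regression forests conventionally consider most or
all features per split; a sqrt(p)-sized draw — the classification default —
dilutes a single informative feature among hundreds of noise features and
makes the screen structurally insensitive.

The 0.01 threshold is meaningful only relative to panel size. On a full
non-targeted matrix (~10^4 features) a null feature's share of importance
is ~10^-4 and the threshold sits far above the noise floor. On a
desk-scale panel the floor rises: with p features and a target whose
residual variance dominates, the best spuriously correlated null carries
in-sample R² of roughly 2·ln(p)/n, and tree ensembles will allocate it a
percent or more of total importance at n ≈ 300 regardless of
hyperparameters. The package's tests therefore verify the "flagged alone"
property in the regime where it is structurally attainable (a planted
feature that tracks the target closely, 200 nulls, n = 300) and verify
separately that a solanidine feature generated at realistic effect sizes —
which explains only ~20% of phenotype-code variance — always *ranks first*
and is flagged, without asserting that no null crosses the threshold in
that regime.

## Genome-wide association

Per-variant linear regression of the log endpoint on ALT-allele dosage
(0–2, additive coding) with selected demographic covariates as fixed
terms. Covariates are projected out of the endpoint and all dosage columns
once (Frisch–Waugh–Lovell), making each per-variant fit exact at a fraction
of the cost; the test suite verifies equality with per-variant `lm()` fits
to 10^-10. Missing dosages are mean-imputed per variant (standard
practice; the source analysis is silent on the point), monomorphic or
all-missing variants are skipped with a reason, and p < 5×10^-8 flags
genome-wide significance. Linkage disequilibrium is the squared Pearson
correlation of dosages — sign-free, so allele flips do not matter — and the
conditional re-scan adds a named lead variant's dosage to the covariates,
the standard check that remaining hits are LD shadows rather than
independent signals. A minimal VCF path (GT field to dosage, via `vcfR`)
covers genotype files; a plain dosage matrix is the primary interface.

## In vitro kinetics

Substrate depletion is fitted as a first-order log-linear decline;
`k = -slope`, half-life `ln 2 / k`. A slope within 10^-12 of zero is
treated as flat (k = 0) and a rising profile is clipped to zero with a
warning rather than reported as negative elimination. Intrinsic clearance
is `k / protein`, in mL/min/mg microsomal protein. Whole-liver scaling
multiplies by MPPGL and liver mass and converts to L/h, then applies the
well-stirred model `CL_h = Q·fu·CLint / (Q + fu·CLint)`, monotone in CLint
and bounded by hepatic blood flow Q. The default constants (MPPGL 40 mg/g,
liver 1800 g, Q 90 L/h, fu 1) are generic adult values and are arguments,
not claims: the constants behind any particular published scaled-clearance
figure are not asserted here, and predictions shift accordingly with other
choices. Percent inhibition is `(1 - CLint_inhibited / CLint_control) ×
100`, invariant to common rescaling.

The fraction-metabolized estimate `fm = 1 - GM_gNM / GM_gPM` rests on one
explicit assumption: at comparable intake, steady-state concentration
differences between phenotypes reflect inverse clearance differences. With
the calibrated geometric means it gives fm ≈ 0.95 — solanidine clearance in
normal metabolizers is ~95% CYP2D6-mediated, consistent with the near-total
in vitro inhibition by a CYP2D6-specific inhibitor.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, with
defaults fixed to the published study conditions:

* four phenotype groups of 9/89/196/20 subjects (the analyzed group sizes);
* per-group, per-endpoint lognormal distributions whose geometric means are
  the published group summaries (`reference_summary()`) and whose log-SDs
  are backed out of the printed 95% CIs via
  `sigma = sqrt(n)·ln(hi/lo)/(2z)`. The normal quantile is used rather
  than t because the result is a calibration heuristic, not an estimate;
* metabolite responses derived as ratio × solanidine, then censored by
  exactly the quantification rules. The default per-ion response LLOQs are
  calibrated so the censored fractions reproduce the published
  measurable-subject counts (310/308/299/296/225 of 314);
* sex ~ Bernoulli(0.5), bodyweight lognormal around 69.7 kg (SD 12.1),
  study period Bernoulli(0.5), NFIB carriage at the reference rate
  (17/196);
* an illustrative diplotype table per class (gPM `*4/*4`; gIM `*1/*4`,
  `*4/*41`; gNM `*1/*1`, `*1/*41`; gUM `*1x2/*1`) — consistent with the
  class definitions, not a claim about any cohort's genotype mix;
* a SNP panel whose causal variant is the per-subject count of no-function
  alleles, LD proxies built by degrading copies of the causal dosage to
  target r² values (achieved within ±0.05; defaults 0.68/0.84/0.58), and
  independent background variants with MAF ~ U(0.05, 0.5).

What the generator deliberately does not emulate: within-subject
correlation between solanidine and its metabolite ratios (not published;
drawn independently by default, with a `log_cor` hook), covariate effects
on the endpoints (sex, bodyweight and period are drawn but carry no effect,
so covariate selection on synthetic cohorts correctly tends to the empty
set), real LD block structure, and raw LC–MS feature matrices beyond a
labeled panel plus noise. Passing tests on synthetic cohorts therefore
demonstrate that the pipeline recovers what it assumes — calibrated
lognormal group structure under the stated censoring — not that real
plasma data obey those assumptions.

Every stochastic entry point takes a mandatory seed and is bit-reproducible
given it.

## Numerical choices and problem sizes

* Quartiles everywhere are type-7 (linear interpolation), matching the
  robust-scaler convention.
* AUROC uses average ranks for ties; AUPRC and F1max enumerate distinct
  score values as thresholds, so tied scores form a single threshold block.
* The stepwise procedure evaluates partial F tests through the equivalent
  t tests of the joint fit; aliased (perfectly collinear) candidates have
  no partial contribution and can never enter twice.
* Depletion slopes within 10^-12 of zero are flat; genuine rate constants
  live many orders of magnitude above this.
* The test suite sizes simulations for a desk machine: bootstrap coverage
  uses 500 replicates of n = 60 binormal scores at B = 1000; parameter
  recovery uses 200 generator seeds; the association-scan null uses 2000
  variants × 300 subjects; the screen examples use 200–1000 noise features
  at n ≈ 300. The full suite runs in about two minutes.

## Known limitations

* Star-allele calling from raw variants, copy-number inference, and peak
  integration are out of scope; diplotype strings and response tables are
  the interfaces.
* The PR-curve integration and ROC-difference conventions of commercial
  statistics packages vary; the choices here (non-interpolated AP, DeLong
  test, percentile bootstrap) are documented and tested, but other software
  will differ in the third decimal on small cohorts.
* The fm estimate inherits its assumption: different intake distributions
  across phenotype groups would bias it.
* Group CIs and covariate-adjusted ratios answer slightly different
  questions; both are reported, and consumers should pick one consistently.
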