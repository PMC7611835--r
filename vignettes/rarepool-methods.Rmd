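---
title: "Pooled rare-variant discovery and carrier phenotype analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled rare-variant discovery and carrier phenotype analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarepool)
```

# The problem

Heterozygous loss-of-function (LoF) variants in appetite-regulating
receptors such as MC4R are individually rare but collectively consequential:
carriers accumulate excess adiposity from mid-childhood. Screening a birth
cohort of several thousand DNA samples one-by-one is expensive; pooling DNA
from P diploid individuals and sequencing each pool very deeply turns a
heterozygote into a low-frequency allele signal with expected variant allele
fraction (VAF)

$$\mathrm{E}[\mathrm{VAF}] = \frac{1}{2P},$$

i.e. 1% for pools of 50. Detecting such signals reliably requires separating
them from sequencing error, calibrating a VAF decision threshold against
per-individual validation, resolving calls back to carriers, and only then
asking the epidemiological questions: how common are functionally impaired
alleles, and what do carriers' growth trajectories look like?

`rarepool` implements that full chain as composable, pipeable functions,
exercised end to end on a synthetic birth-cohort generator so that no
restricted cohort data are needed.

# The read-count model for pooled sequencing

For pool $j$ and site $s$, the generator draws

* per-sample DNA contribution weights $w_i \sim \mathrm{Lognormal}$ with
  coefficient of variation `contribution_cv` (default 0.4) and mean 1 —
  pooling is never perfectly equimolar;
* the true alternate fraction
  $p_0 = \sum_{i \in \mathrm{carriers}} 0.5\,w_i / \sum_{i \in \mathrm{pool}} w_i$,
  shifted by base error $\epsilon$ to $p = p_0 + \epsilon(1 - 2p_0)$
  (default $\epsilon = 0.001$);
* depth $D \sim \mathrm{Poisson}(\bar d)$ with $\bar d = 43{,}654$ reads, the
  scale of deep amplicon sequencing of a single small gene;
* alternate reads $A \sim \mathrm{BetaBinomial}(D, p, \rho)$ with
  overdispersion $\rho$ (default $10^{-4}$), reads splitting over strands
  with probability 1/2.

Two calibration anchors pin the defaults. First, the expected single-het VAF
is exactly $1/(2P)$ when pooling is equimolar and error-free. Second, the
observed spread of true-positive VAFs in deep pooled screens is about
$1.18\% \pm 0.39\%$; a contribution CV of 0.4 alone reproduces essentially
all of that spread at 1% mean VAF, which is why $\rho$ is kept very small —
larger values double-count variability that belongs to unequal pooling.
Under these defaults the simulated TP VAF SD is 0.40% and the VAF-based
classifier attains a mean AUC of about 0.975.

False positives need to exist for the calibration stage to calibrate
against. The generator injects *error-only* sites whose per-site error rate
is lognormal around 4.5$\epsilon$ (sdlog 0.15), sampled binomially: the
lognormal across sites *is* the between-site error overdispersion, so no
beta-binomial layer is applied on top. This stand-in was chosen so that
false-positive VAFs concentrate just above the permissive first-pass screen
and mostly below the recalibrated cutoff, which is the empirical behaviour
such screens show; it is a model of convenience, not a claim about the error
chemistry.

# Calling and calibration

`call_site()` applies the screening criteria used by pooled-screen callers:
VAF $\ge$ 0.05%, coverage $\ge$ 100 reads, a significance test at
$\alpha = 0.05$, and a strand filter (at least one alternate read per strand
and a minor-strand share of at least 10%). The significance test is a
one-sided exact binomial tail $P(X \ge A \mid D, \epsilon_0)$ against a
configurable null error rate $\epsilon_0$ (default 0.001). The exact tail is
evaluated through `pbinom()` at every depth — it is numerically stable and
fast even at $10^5$ reads, so no normal approximation is used; the test
suite checks it against exhaustive term summation to $10^{-12}$ relative
error.

The workflow is deliberately two-staged: raw calls are screened at an
initial VAF of 0.5% — *below* the theoretical 1% so that unequal pooling
cannot push a real carrier under the bar — and the resulting candidate set
is validated per individual. `roc_analysis()` then treats VAF as a
classifier score: the AUC is the rank statistic
$P(\mathrm{VAF}_{TP} > \mathrm{VAF}_{FP}) + \tfrac12 P(\mathrm{tie})$, which
the tests cross-check against trapezoidal integration of the empirical curve
and against an independent ROC implementation. `choose_vaf_cutoff()`
implements the retain-all-TP rule: the largest grid multiple (default step
0.01%) not exceeding the smallest true-positive VAF, applied inclusively. A
floating-point guard caps the returned threshold at the minimum TP VAF
itself, since a grid multiple one ulp above it would silently drop a
validated call.

One reporting subtlety: screens of this kind often quote "specificity" for
the quantity $TP/(TP+FP)$ among retained calls, which is the positive
predictive value. `confusion_at()` reports both that figure (as `ppv`) and
classical specificity (fraction of false positives removed), separately
labelled.

# Carrier resolution, exclusions, prevalence

`resolve_carriers()` unblinds pools behind confirmed calls and attaches the
validated carriers. `apply_exclusions()` reduces a registry to the analysis
set in a fixed order — missing identifiers, duplicated aliquots, unsequenced
members of split twin pairs, then one member kept per fully sequenced
multiplet (lowest id; the tie-break is the package's choice, since such
rules are rarely printed). Every step appends to a ledger satisfying
$N_\mathrm{in} = N_\mathrm{out} + \sum n_\mathrm{removed}$.

`estimate_prevalence()` counts each carrier once in their most severe class
(cLoF > pLoF > GoF > WT-like — again a documented convention; individuals
carrying two variants are not expected at these frequencies), reports
percentages with exact Clopper–Pearson 95% intervals, and aggregates the LoF
classes with a population "1 in k" rate, $k = \mathrm{round}(N/\mathrm{count})$.
MAFs are allele copies over $2N$ as percentages rounded to 4 decimals; note
that published variant tables sometimes print 0.0173% where $2/(2 \times 5724)$
rounds to 0.0175% — the implementation always uses the arithmetic value.

# Pharmacological classification

Dose-response data are modelled with the logistic in $x = \log_{10}$(dose),

$$y = basal + \frac{E_{max} - basal}{1 + 10^{\,h(\log EC_{50} - x)}},$$

fitted by Levenberg–Marquardt least squares with multi-start initialisation
of $\log EC_{50}$ across the dose range. "4-point"/"3-point sigmoidal" is
read in the Prism sense of 4- vs 3-parameter logistic, the 3-parameter
variant fixing the Hill slope at 1. Flat (signalling-dead) data — response
span under 10 %WT — take a no-fit path: the relative $E_{max}$ is reported
from the top dose alone, mirroring how complete-LoF constructs are handled
in practice.

Curve comparisons follow two routes. The cAMP-style route pools both groups
and compares a full model (separate $E_{max}$ or $\log EC_{50}$ per group;
basal and Hill shared) with a reduced model sharing the tested parameter via
the extra-sum-of-squares F-test
$F = \frac{(SS_r - SS_f)/(df_r - df_f)}{SS_f/df_f}$. The arrestin-style
route fits each experimental replicate separately and compares per-replicate
parameter estimates with a two-sided t-test; its input is the area under the
kinetic luminescence trace above the pre-stimulation baseline, clipped at
zero by default because receptor–arrestin coupling cannot be negative
(`clip = FALSE` is available).

Classification criteria are configurable because quantitative class
definitions are usually buried in supplements: the defaults label a variant
cLoF on the no-fit path or at $E_{max} \le 20$ %WT; pLoF on a significant
efficacy deficit or right-shifted potency ($p < 0.05$); GoF on the mirror
image; otherwise WT-like. Conflicting significant signals in both directions
are flagged ambiguous and the LoF label is reported, erring on the side of
clinical caution.

# Growth trajectories

The longitudinal model is a two-level (occasions within individuals)
linear-spline mixed model. The basis is parameterised as *time accrued per
interval*: with knots at ages $k_1 < \dots < k_m$, term $j$ at age $t$ is
the number of years of interval $j$ elapsed by $t$, so each fixed-effect
coefficient reads directly as trait units per year within its interval.
Fixed effects are the splines plus carrier-by-spline and sex-by-spline
interactions; the carrier interaction terms are the quantities of interest
(intercept difference at the first modelled age and per-interval slope
differences). Estimation is REML via `lme4::lmer`.

Two structural choices deserve comment:

* **Random effects.** The published analyses this design follows do not
  state their random structure. The package default is a random intercept
  plus random per-interval slopes with unstructured covariance
  (`random = "slopes"`), falling back to intercept-only when the slope model
  is singular (`fell_back` records this). For the large simulation studies
  in the test suite the intercept-only model is used directly — it is the
  structure the generator uses there, which keeps interval-coverage checks
  well-posed, and it fits in about 2 s at $N = 5724$ with nine occasions
  where the full slope model takes over a minute.
* **Modelled ranges.** BMI and height are modelled from 18 months (their
  first anchored measure: 16.84 kg/m² and 81.90 cm) to 18 years, weight from
  birth (3.44 kg); knots at 3.5/5/8/15 (BMI), 5/15 (height), 1/8/15 (weight)
  years. Missingness in the generator is missing-at-random with probability
  rising with age (5% at the first occasion to 40% at 18 years), the pattern
  cohort follow-ups typically show; all individuals with at least one
  measure contribute.

`trajectory_contrast()` evaluates the predicted group curves and the carrier
gap $\delta_0 + \sum_j \delta_j B_j(a)$ with delta-method standard errors
from the fixed-effect covariance. Age-specific analyses use OLS with a sex
adjustment (plus same-occasion BMI for blood-pressure-type outcomes), with
fewer-than-two-carrier estimates flagged `unstable` rather than omitted.

The default trait specifications place the carrier slope offsets so that the
carrier/non-carrier gap reaches 4.84 kg/m² (BMI) and 17.76 kg (weight) at 18
years, accruing from age 5 onward — effect sizes of the magnitude reported
for heterozygous MC4R LoF — with no carrier effect at the intercept age.
The recovery study in the acceptance suite simulates 120 replicates per
trait at $N = 5724$ (expected 17 LoF carriers), refits the mixed model, and
checks that the 18-year gap estimator has |relative bias| < 10% with 95%
interval coverage inside [0.92, 0.98].

# Polygenic-score comparison

The generator draws a Gaussian score optionally correlated with the BMI
random intercept: with loading $\lambda$,
$\mathrm{PRS} = \mu + \sigma(\lambda u_0^\ast + \sqrt{1-\lambda^2} z)$. The
default $\lambda = 0.42$ was solved from the variance decomposition of the
default BMI spec at age 18 ($\mathrm{var}(u_0) = 1.69$ of a total
$\approx 3.0$) so the score explains about 10% of BMI variance, verified by
simulation. Comparison utilities give the top-decile-vs-lower-90% contrast
(ties broken by id), univariate $R^2$, and the carrier effect before/after
PRS adjustment. Under the defaults the rare-variant carrier contrast is
roughly double the top-decile PRS contrast and survives PRS adjustment
essentially unchanged — the two signals are independent by construction.

# Numerical and design notes

* Every generator accepts a seed and is bit-reproducible; stage seeds are
  derived from the master seed with a label hash, so stages are independent
  streams and the caller's RNG state is never disturbed.
* The caller's VAF denominator is ref + alt reads; other bases are ignored.
  Coordinates are 1-based fully closed, matching VCF.
* Indels are treated as alt-allele counts at a site; no realignment.
* `fit_dose_response()` declares an EC50 unreliable when it falls more than
  two decades outside the dose range.
* Zero-depth sites yield non-passing calls flagged `zero_depth` rather than
  NaN VAFs.
* Degenerate inputs (no carriers, single-class ROC input, empty overlap,
  zero-variance predictors) raise early, descriptive errors.

## What the simulations do and do not show

The generator reproduces the statistical structure the analyses assume:
binomial carrier sampling, overdispersed pooled read counts, piecewise-linear
growth with two variance levels, MAR dropout, a Gaussian score. It does not
model PCR chemistry, alignment artefacts, batch effects, linkage or
population structure, non-Gaussian trait tails, or informative missingness.
Passing tests therefore demonstrate that the *estimators are correct under
their assumed models* and that the pipeline's calibration logic behaves as
designed — not that those assumptions hold in any particular cohort.

## Problem sizes used by the test suite

Simulation-backed checks run at the cohort scale the pipeline targets
($N = 5724$–5993, depth 43,654) with replicate counts chosen for stable
Monte-Carlo verdicts at package-test scale: 200 replicates for the ROC
study, 120 per trait for mixed-model recovery, 500 seeds for the binomial
carrier check, 300 for F-test null uniformity, 1000 for the cutoff-retention
property.

# A worked run

```{r example, eval = FALSE}
library(rarepool)
cfg <- run_config(seed = 1, sim = sim_config(n_individuals = 5993))
report <- run_end_to_end(cfg, out_dir = "run1")
report
report$prevalence
autoplot(report$association$mlm)
```
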