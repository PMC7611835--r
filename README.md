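# rarepool

Pooled-sequencing rare-variant discovery, pharmacological classification and
carrier growth-trajectory analysis — as one tested, reproducible R pipeline.

## The problem

Heterozygous loss-of-function (LoF) mutations in appetite-regulating
receptors such as *MC4R* predispose carriers to obesity from childhood, but
they are rare (a few per thousand), so population estimates need thousands
of genomes. Pooling DNA from *P* diploid samples and sequencing each pool
very deeply makes this affordable: a single heterozygote appears as a
low-frequency allele with expected variant allele fraction (VAF)

    E[VAF] = 1 / (2P)        (1% in a pool of 50)

The price is a calibration problem — separating ~1% signals from sequencing
error, choosing a VAF cutoff against per-individual validation, and
resolving pooled calls back to named carriers — before any epidemiology can
start. `rarepool` implements that chain end to end:

1. **synthetic cohort** — seeded generators for the registry (sex,
   twins/duplicates/missing ids), heterozygous carriers at configurable
   class prevalences, pooled read counts (Poisson depth, beta-binomial
   overdispersion, lognormal unequal contribution), growth trajectories
   (linear-spline two-level model), dose-response assays and a polygenic
   score;
2. **pool caller** — per-site screening: VAF ≥ 0.05%, coverage ≥ 100, exact
   one-sided binomial tail versus a null error rate, 90/10 strand filter;
3. **calibration** — TP/FP labelling from validation, rank-statistic ROC/AUC,
   retain-all-TP cutoff choice, confusion summaries (PPV and classical
   specificity, separately), cross-platform concordance;
4. **carrier resolution** — pool unblinding, an auditable exclusion ledger
   (missing ids → duplicates → split twins → in-set multiplets), per-class
   prevalence with Clopper–Pearson intervals, "1 in k" rates, MAFs;
5. **pharmacology** — 4-/3-parameter logistic fits (Emax, logEC50),
   extra-sum-of-squares F-tests and replicate-level t-tests versus wild
   type, kinetic AUC-above-baseline, cLoF/pLoF/WT-like/GoF classification;
6. **growth models** — per-interval linear-spline basis, age-specific OLS
   carrier effects, REML mixed models (`lme4`) with carrier x spline and
   sex x spline interactions, predicted trajectories and carrier gaps;
7. **PRS comparison** — top-decile contrast, variance explained, carrier
   effect before/after score adjustment.

Everything takes a data frame first and returns a tibble, so stages chain
with the pipe; fitted objects have `tidy()`, `glance()` and `autoplot()`
methods.

## A worked example

```r
library(rarepool)

cfg    <- run_config(seed = 1, sim = sim_config(n_individuals = 5993))
report <- run_end_to_end(cfg)
report
#> <run_report> analysis N = 5706 | LoF 0.23% (~1 in 439 ) | AUC 0.967 | cutoff 0.005

report$prevalence
#> # A tibble: 6 x 6
#>   class   count percent    ci_lo  ci_hi one_in
#> 1 cLoF        5  0.0876  0.0285   0.204     NA
#> 2 pLoF        8  0.140   0.0605   0.276     NA
#> 3 GoF         2  0.0351  0.00425  0.127     NA
#> 4 WT-like    15  0.263   0.147    0.433     NA
#> 5 none     5676 99.5    99.3     99.6       NA
#> 6 LoF        13  0.228   0.121    0.389    439

trajectory_contrast(report$association$mlm, 18)
#>   age_years mean_noncarrier mean_carrier   gap gap_se gap_lo gap_hi
#> 1        18            22.1         27.3  5.19  0.468   4.28   6.11
```

Reading the output: of 5993 simulated registry entries, 5706 survive the
exclusion ledger; 13 carry a heterozygous LoF variant (0.23%, roughly 1 in
439 — the generator draws carriers binomially at 0.30%, so individual runs
scatter around that). VAF separated true from false calls with AUC 0.967,
and the recalibrated cutoff retained every validated call. At age 18 the
fitted mixed model puts carriers 5.2 kg/m² of BMI above non-carriers
(95% CI 4.3–6.1; the generating gap is 4.84). The polygenic score explains
~10% of BMI variance at 18 but its top-decile contrast (+1.1 kg/m²) is far
smaller than the rare-variant carrier effect, and adjusting for the score
leaves that effect unchanged.

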