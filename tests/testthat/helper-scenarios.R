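# Shared scenario builders used across test files.

# Labelled-call tibble from raw VAF vectors (minimal columns the calibration
# stage needs).
labeled_from <- function(tp_vaf, fp_vaf) {
  tibble::tibble(
    vaf = c(tp_vaf, fp_vaf),
    label = c(rep("TP", length(tp_vaf)), rep("FP", length(fp_vaf)))
  )
}

# Exhaustive pairwise AUC oracle: P(tp > fp) + 0.5 P(tie).
auc_pairwise <- function(tp, fp) {
  cmp <- outer(tp, fp, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Brute-force one-sided binomial tail oracle by term summation.
tail_sum <- function(alt, depth, p0) {
  if (alt == 0) return(1)
  sum(dbinom(alt:depth, depth, p0))
}

# Paper-scale pooled screen: one cohort of `n_carriers` single-het variant
# sites across pools of 50, plus injected error-only sites; returns the
# labelled candidate set surviving the caller + initial 0.5% screen.
roc_scenario <- function(seed, n_carriers = 40, n_fp = 17) {
  n_pools <- ceiling(n_carriers / 3)
  cfg <- sim_config(n_individuals = n_pools * 50, pool_size = 50,
                    mean_depth = 43654, base_error_rate = 0.001,
                    contribution_cv = 0.4, overdispersion = 1e-4,
                    twin_rate = 0, triplet_rate = 0, quad_rate = 0,
                    duplicate_rate = 0, missing_id_rate = 0, seed = seed)
  co <- simulate_cohort(cfg, c(pLoF = n_carriers / (n_pools * 50)),
                        carriers_per_variant = 1)
  des <- assign_pools(co, 50, seed = seed + 7L)
  pp <- simulate_pool_pileups(des, co, cfg, n_error_sites = n_fp)
  calls <- call_pools(pp, call_config())
  cand <- calls[calls$passed & calls$vaf >= 0.005, ]
  cand$label <- ifelse(cand$pos %in% co$variants$pos, "TP", "FP")
  cand
}

# Balanced noise-free trajectory cohort for exact-recovery checks.
flat_spec <- function(...) {
  trait_spec("bmi", ages = c(2, 5, 10, 15), knots = c(5, 10),
             intercept = 16, slopes = c(0, 0, 0), ...)
}
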