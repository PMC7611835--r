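test_that("cohort generation matches binomial carrier sampling and is seeded", {
  cfg <- sim_config(n_individuals = 5724, seed = 1)
  co <- simulate_cohort(cfg, c(pLoF = 0.0023, cLoF = 0.0007,
                               `WT-like` = 0.0037, GoF = 0.0003))
  counts <- table(factor(co$individuals$class,
                         levels = c("pLoF", "cLoF", "WT-like", "GoF")))
  # binomial means 13.2 / 4.0 / 21.2 / 1.7; allow 4 SD around each
  expect_lt(abs(counts[["pLoF"]] - 13.2), 4 * sqrt(13.2))
  expect_lt(abs(counts[["cLoF"]] - 4.0), 4 * sqrt(4))
  expect_lt(abs(counts[["WT-like"]] - 21.2), 4 * sqrt(21.2))
  expect_lt(abs(counts[["GoF"]] - 1.7), 4 * sqrt(1.7) + 1)

  # bit-identical reruns under the same seed
  co2 <- simulate_cohort(cfg, c(pLoF = 0.0023, cLoF = 0.0007,
                                `WT-like` = 0.0037, GoF = 0.0003))
  expect_identical(co$individuals, co2$individuals)
  expect_identical(co$variants, co2$variants)

  # all rare carriers heterozygous; ids unique apart from duplicates
  expect_true(all(co$individuals$copies[!is.na(co$individuals$variant_id)] == 1))
  expect_false(any(duplicated(co$individuals$individual_id)))

  # empty case
  co0 <- simulate_cohort(sim_config(n_individuals = 100, seed = 2),
                         c(pLoF = 0))
  expect_equal(sum(!is.na(co0$individuals$variant_id)), 0)

  expect_error(simulate_cohort(cfg, c(pLoF = 0.9, cLoF = 0.2)), "sum")
})

test_that("mean carrier count converges to the exact binomial mean", {
  counts <- vapply(1:500, function(s) {
    co <- simulate_cohort(sim_config(n_individuals = 1000, seed = s),
                          c(pLoF = 0.01))
    sum(co$individuals$class == "pLoF")
  }, numeric(1))
  # exact mean 10, var 9.9; Monte-Carlo SE of the mean = sqrt(9.9/500)
  expect_lt(abs(mean(counts) - 10), 4 * sqrt(9.9 / 500))
  expect_lt(abs(var(counts) - 9.9), 0.35 * 9.9)
})

test_that("pool assignment covers everyone once with ceiling division", {
  co <- simulate_cohort(sim_config(n_individuals = 5993, seed = 3,
                                   missing_id_rate = 0, duplicate_rate = 0),
                        c(pLoF = 0.002))
  d <- assign_pools(co, 50, seed = 4)
  expect_equal(length(unique(d$pool_id)), 120)
  expect_setequal(d$individual_id, co$individuals$individual_id)
  expect_false(any(duplicated(d$individual_id)))

  co2 <- simulate_cohort(sim_config(n_individuals = 101, seed = 5,
                                    missing_id_rate = 0, duplicate_rate = 0),
                         c(pLoF = 0))
  d2 <- assign_pools(co2, 50, seed = 6)
  expect_equal(sort(as.vector(table(d2$pool_id))), c(1L, 50L, 50L))

  co3 <- simulate_cohort(sim_config(n_individuals = 50, seed = 7,
                                    missing_id_rate = 0, duplicate_rate = 0),
                         c(pLoF = 0))
  d3 <- assign_pools(co3, 50, seed = 8)
  expect_equal(length(unique(d3$pool_id)), 1)
  expect_error(assign_pools(co3, 1), "pool_size")
})

test_that("noise-free pooled pileups recover the theoretical single-het VAF", {
  cfg <- sim_config(n_individuals = 100, pool_size = 50, mean_depth = 1e6,
                    base_error_rate = 0, contribution_cv = 0,
                    overdispersion = 0, twin_rate = 0, triplet_rate = 0,
                    quad_rate = 0, duplicate_rate = 0, missing_id_rate = 0,
                    seed = 11)
  co <- simulate_cohort(cfg, c(pLoF = 2 / 100), carriers_per_variant = 1)
  n_car <- sum(!is.na(co$individuals$variant_id))
  expect_gt(n_car, 0)
  d <- assign_pools(co, 50, seed = 12)
  pp <- simulate_pool_pileups(d, co, cfg, n_error_sites = 0)
  pp$vaf <- (pp$alt_fwd + pp$alt_rev) /
    (pp$ref_fwd + pp$ref_rev + pp$alt_fwd + pp$alt_rev)
  # carrier pools: VAF within Monte-Carlo tolerance of 1/(2*50)
  carrier_pools <- merge(
    d, co$individuals[!is.na(co$individuals$variant_id),
                      c("individual_id", "variant_id")])
  vmap <- co$variants[, c("variant_id", "pos")]
  carrier_pools <- merge(carrier_pools, vmap)
  hit <- merge(pp, carrier_pools[, c("pool_id", "pos")])
  expect_equal(nrow(hit), n_car)
  expect_true(all(abs(hit$vaf - 0.01) < 4 * sqrt(0.01 * 0.99 / 1e6)))
  # non-carrier pools are error-free
  other <- pp[!paste(pp$pool_id, pp$pos) %in%
                paste(carrier_pools$pool_id, carrier_pools$pos), ]
  expect_true(all(other$alt_fwd + other$alt_rev == 0))
})

test_that("paper-scale pileups give mean TP VAF in the observed band", {
  # cv = 0.4, rho = 0.01, depth 43,654: mean true-positive VAF in [0.9%, 1.5%]
  vafs <- unlist(lapply(1:25, function(s) {
    cfg <- sim_config(n_individuals = 200, pool_size = 50, mean_depth = 43654,
                      base_error_rate = 0.001, contribution_cv = 0.4,
                      overdispersion = 0.01, twin_rate = 0, triplet_rate = 0,
                      quad_rate = 0, duplicate_rate = 0, missing_id_rate = 0,
                      seed = s)
    co <- simulate_cohort(cfg, c(pLoF = 0.02), carriers_per_variant = 1)
    d <- assign_pools(co, 50, seed = s + 100L)
    pp <- simulate_pool_pileups(d, co, cfg, n_error_sites = 0)
    pp$vaf <- (pp$alt_fwd + pp$alt_rev) /
      pmax(1, pp$ref_fwd + pp$ref_rev + pp$alt_fwd + pp$alt_rev)
    carrier <- merge(
      merge(d, co$individuals[!is.na(co$individuals$variant_id),
                              c("individual_id", "variant_id")]),
      co$variants[, c("variant_id", "pos")])
    merge(pp, carrier[, c("pool_id", "pos")])$vaf
  }))
  expect_gt(length(vafs), 40)
  expect_gt(mean(vafs), 0.009)
  expect_lt(mean(vafs), 0.015)
  expect_gt(sd(vafs), 0)
})

test_that("the validation oracle returns ground truth with configurable misses", {
  co <- simulate_cohort(sim_config(n_individuals = 50, seed = 21),
                        c(pLoF = 0.1), carriers_per_variant = 1)
  carriers <- co$individuals[!is.na(co$individuals$variant_id), ]
  expect_gt(nrow(carriers), 0)
  v <- simulate_sanger(co, carriers$variant_id, carriers$individual_id)
  expect_true(all(v$carrier))
  expect_true(all(v$zygosity == "het"))
  nc <- co$individuals[is.na(co$individuals$variant_id), ][1, ]
  v2 <- simulate_sanger(co, carriers$variant_id[1], nc$individual_id)
  expect_false(v2$carrier)
  expect_true(is.na(v2$zygosity))
  v3 <- simulate_sanger(co, carriers$variant_id, carriers$individual_id,
                        miss_rate = 1, seed = 1)
  expect_false(any(v3$carrier))
  expect_error(simulate_sanger(co, "V001", "nobody"), "Unknown")
})

test_that("trajectory generator reduces to the deterministic spline mean", {
  co <- simulate_cohort(sim_config(n_individuals = 40, seed = 31),
                        c(pLoF = 0.25), carriers_per_variant = 1)
  # flat, zero-variance spec: every value equals the intercept
  sp0 <- flat_spec()
  ph0 <- simulate_trajectories(co, sp0, seed = 1)
  expect_true(all(ph0$value == 16))

  # carrier delta +0.5/y on the 10-15y interval only: gap at 15 is exactly 2.5
  sp1 <- trait_spec("bmi", ages = c(2, 5, 10, 15), knots = c(5, 10),
                    intercept = 16, slopes = c(0.1, 0.2, 0.3),
                    carrier_effects = c(0, 0, 0, 0.5))
  ph1 <- simulate_trajectories(co, sp1, seed = 1)
  at15 <- ph1[ph1$age_years == 15, ]
  gap <- mean(at15$value[at15$carrier]) - mean(at15$value[!at15$carrier])
  expect_equal(gap, 0.5 * 5, tolerance = 1e-12)

  # noiseless output regressed on the basis recovers generating coefficients
  B <- spline_basis(ph1$age_years, sp1$knots, intercept_age = 2)
  fit <- lm(ph1$value ~ B + ph1$carrier:B + ph1$carrier)
  expect_equal(unname(coef(fit)[1:4]), c(16, 0.1, 0.2, 0.3),
               tolerance = 1e-10)

  # default BMI spec anchors the 18-month mean at 16.84
  co2 <- simulate_cohort(sim_config(n_individuals = 3000, seed = 32),
                         c(pLoF = 0.003))
  ph2 <- simulate_trajectories(co2, trait_spec_bmi(), seed = 2)
  m18mo <- mean(ph2$value[ph2$age_years == 1.5])
  expect_equal(m18mo, 16.84, tolerance = 0.05)

  expect_error(trait_spec("bmi", ages = c(2, 5), knots = c(6),
                          intercept = 1, slopes = c(0, 0)), "inside")
})

test_that("assay generator emits exact curves, flat cLoF profiles and noise", {
  d <- simulate_assay(100, -9, noise_sd = 0)
  mu <- 0 + 100 / (1 + 10^((-9 - d$log10_dose)))
  expect_equal(d$response, mu, tolerance = 1e-12)

  dflat <- simulate_assay(100, -9, noise_sd = 0, flat = TRUE, basal = 2)
  expect_true(all(dflat$response == 2))

  expect_error(simulate_assay(100, -9, doses = c(-1, 1)), "positive")

  dn <- simulate_assay(80, -8.5, noise_sd = 5, replicates = 6, seed = 9)
  f <- fit_dose_response(dn, 4)
  expect_true(f$converged)
  expect_lt(abs(f$estimate[["emax"]] - 80), 2 * 3 * f$se[["emax"]] + 10)
})

test_that("polygenic scores have requested moments and trait coupling", {
  co <- simulate_cohort(sim_config(n_individuals = 5000, seed = 41),
                        c(pLoF = 0.003))
  s0 <- simulate_prs(co, mean = 0, sd = 1, seed = 5)
  expect_lt(abs(mean(s0$prs)), 4 / sqrt(5000))
  expect_lt(abs(sd(s0$prs) - 1), 0.05)

  ph <- simulate_trajectories(co, trait_spec_bmi(), seed = 6)
  u0 <- attr(ph, "ranef_intercept")
  s_ind <- simulate_prs(co, trait_loading = 0, seed = 7)
  d18 <- ph[ph$age_years == 18, ]
  r0 <- cor(d18$value, s_ind$prs[match(d18$individual_id,
                                       s_ind$individual_id)])
  expect_lt(abs(r0), 0.06)

  # loading solved from the variance decomposition for ~10% explained at 18y
  s_l <- simulate_prs(co, trait_loading = 0.42, seed = 8, ranef_intercept = u0)
  r2 <- variance_explained(d18$value, s_l$prs[match(d18$individual_id,
                                                    s_l$individual_id)])
  expect_gt(r2, 0.05)
  expect_lt(r2, 0.16)

  expect_error(simulate_prs(co, sd = 0), "positive")
  expect_error(simulate_prs(co, trait_loading = 0.5), "ranef_intercept")
})
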