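test_that("confirmed calls resolve to validated carriers with zygosity", {
  design <- tibble::tibble(pool_id = rep(c("P1", "P2"), each = 2),
                           individual_id = sprintf("I%d", 1:4))
  calls <- tibble::tibble(pool_id = c("P1", "P2"),
                          variant_key = c("toy1 10 T", "toy1 10 T"))
  vals <- tibble::tibble(
    individual_id = c("I1", "I3", "I4"),
    variant_key = "toy1 10 T", variant_id = "V1",
    carrier = TRUE, zygosity = "het", functional_class = "pLoF")
  ct <- resolve_carriers(calls, design, vals)
  expect_equal(nrow(ct), 3)                 # one + a two-carrier pool
  expect_setequal(ct$individual_id, c("I1", "I3", "I4"))
  expect_true(all(ct$zygosity == "het"))

  # confirmed call with no validated carrier in its pool is flagged
  calls2 <- dplyr::bind_rows(calls, tibble::tibble(
    pool_id = "P1", variant_key = "toy1 99 G"))
  ct2 <- resolve_carriers(calls2, design, vals)
  inc <- attr(ct2, "inconsistent")
  expect_equal(inc$variant_key, "toy1 99 G")
})

test_that("the exclusion ledger reproduces the published registry arithmetic", {
  # registry mirroring the printed step counts: 5993 sequenced entries with
  # 5 missing ids, 214 duplicates, one fully sequenced triplet set and 48
  # fully sequenced twin pairs
  n <- 5993
  reg <- tibble::tibble(
    individual_id = sprintf("ID%06d", 1:n),
    sequenced = TRUE,
    missing_id_flag = c(rep(TRUE, 5), rep(FALSE, n - 5)),
    duplicate_flag = c(rep(FALSE, 5), rep(TRUE, 214), rep(FALSE, n - 219)),
    relatedness_group_id = NA_character_)
  # triplet set (3 members) and 48 twin pairs among the clean rows
  reg$relatedness_group_id[220:222] <- "T001"
  twin_rows <- 223:(223 + 96 - 1)
  reg$relatedness_group_id[twin_rows] <- rep(sprintf("W%03d", 1:48), each = 2)

  res <- apply_exclusions(reg)
  expect_equal(res$ledger$n_removed, c(5L, 214L, 0L, 50L))
  expect_equal(dplyr::last(res$ledger$remaining), 5724L)
  expect_equal(nrow(res$analysis), 5724)
  # conservation: input N = final N + total removed
  expect_equal(n, nrow(res$analysis) + sum(res$ledger$n_removed))
})

test_that("exclusions keep the sequenced twin and the lowest multiplet id", {
  reg <- tibble::tibble(
    individual_id = c("A", "B", "C", "D"),
    sequenced = c(TRUE, TRUE, TRUE, FALSE),
    relatedness_group_id = c("W1", "W1", "W2", "W2"))
  res <- apply_exclusions(reg)
  # in-set pair W1: keep lowest id; split pair W2: drop the unsequenced twin
  expect_setequal(res$analysis$individual_id, c("A", "C"))
  expect_equal(res$ledger$n_removed[res$ledger$step == 3], 1L)
  expect_equal(res$ledger$n_removed[res$ledger$step == 4], 1L)

  # no flags: input unchanged
  clean <- tibble::tibble(individual_id = c("X", "Y"))
  res2 <- apply_exclusions(clean)
  expect_equal(nrow(res2$analysis), 2)
  expect_true(all(res2$ledger$n_removed == 0))
})

test_that("prevalence table reproduces published class frequencies and CIs", {
  carriers <- tibble::tibble(
    individual_id = sprintf("C%02d", 1:40),
    functional_class = c(rep("pLoF", 13), rep("cLoF", 4),
                         rep("WT-like", 21), rep("GoF", 2)))
  pt <- estimate_prevalence(carriers, 5724)
  get <- function(cl, col) pt[[col]][pt$class == cl]
  expect_equal(get("LoF", "count"), 17)
  expect_equal(round(get("LoF", "percent"), 2), 0.30)
  expect_equal(get("LoF", "one_in"), 337)
  expect_equal(round(get("pLoF", "percent"), 2), 0.23)
  expect_equal(round(get("cLoF", "percent"), 2), 0.07)
  expect_equal(round(get("WT-like", "percent"), 2), 0.37)
  expect_equal(round(get("GoF", "percent"), 2), 0.03)
  # class + none counts partition the cohort
  expect_equal(sum(pt$count[pt$class != "LoF"]), 5724)

  # Clopper-Pearson interval against a direct tail-probability oracle
  ci <- c(get("LoF", "ci_lo"), get("LoF", "ci_hi")) / 100
  lo <- uniroot(function(p) pbinom(17 - 1, 5724, p, lower.tail = FALSE) - 0.025,
                c(1e-6, 0.5), tol = 1e-12)$root
  hi <- uniroot(function(p) pbinom(17, 5724, p) - 0.025, c(1e-6, 0.5),
                tol = 1e-12)$root
  expect_equal(ci[1], lo, tolerance = 1e-6)
  expect_equal(ci[2], hi, tolerance = 1e-6)

  # invariant to record ordering; severity rule picks the worse class
  pt2 <- estimate_prevalence(carriers[sample(nrow(carriers)), ], 5724)
  expect_equal(pt2$count, pt$count)
  two <- tibble::tibble(individual_id = c("C01", "C01"),
                        functional_class = c("WT-like", "cLoF"))
  expect_equal(estimate_prevalence(two, 100)$count[
    estimate_prevalence(two, 100)$class == "cLoF"], 1)

  # zero carriers: 0% with an informative upper bound
  none <- estimate_prevalence(carriers[0, ], 100)
  expect_true(all(none$percent[none$class != "none"] == 0))
  expect_gt(none$ci_hi[none$class == "LoF"], 0)
})

test_that("minor allele frequencies match the published variant table", {
  expect_equal(compute_maf(4, 5724), 0.0349)
  expect_equal(compute_maf(3, 5724), 0.0262)
  expect_equal(compute_maf(2, 5724), 0.0175)
  expect_equal(compute_maf(0, 5724), 0)
  expect_equal(compute_maf(1, 5724, zygosity = "hom"), compute_maf(2, 5724))
  expect_error(compute_maf(3, 1), "2N")
})

test_that("obesity crosstab counts strata and leaves empty cells undefined", {
  set.seed(13)
  n <- 5724
  bmi <- rnorm(n, 22, 3)
  # force exactly 208 obese individuals
  obese_idx <- order(bmi, decreasing = TRUE)[1:208]
  bmi[obese_idx] <- 31
  bmi[setdiff(seq_len(n), obese_idx)] <-
    pmin(bmi[setdiff(seq_len(n), obese_idx)], 29.9)
  d <- tibble::tibble(individual_id = sprintf("I%d", 1:n), bmi = bmi,
                      carrier = c(rep(TRUE, 17), rep(FALSE, n - 17)))
  xt <- crosstab_obesity(d)
  expect_equal(xt$n_obese, 208)
  expect_equal(round(xt$pct_obese_overall, 2), 3.63)

  low <- tibble::tibble(individual_id = c("A", "B"), bmi = c(20, 21),
                        carrier = c(TRUE, FALSE))
  xt2 <- crosstab_obesity(low)
  expect_equal(xt2$pct_overweight_carriers, 0)
  expect_true(is.na(xt2$pct_obese_who_carry))   # empty stratum, not 0

  # known-effect synthetic check against direct counting
  d$bmi[d$carrier] <- 27
  xt3 <- crosstab_obesity(d)
  expect_equal(xt3$pct_overweight_carriers, 100)
})

test_that("perfect caller plus perfect validation recovers ground truth", {
  cfg <- sim_config(n_individuals = 300, pool_size = 50, mean_depth = 43654,
                    base_error_rate = 0, contribution_cv = 0,
                    overdispersion = 0, twin_rate = 0, triplet_rate = 0,
                    quad_rate = 0, duplicate_rate = 0, missing_id_rate = 0,
                    seed = 55)
  co <- simulate_cohort(cfg, c(pLoF = 0.03, cLoF = 0.01),
                        carriers_per_variant = 1)
  truth <- co$individuals[!is.na(co$individuals$variant_id),
                          c("individual_id", "variant_id")]
  expect_gt(nrow(truth), 0)
  d <- assign_pools(co, 50, seed = 56)
  pp <- simulate_pool_pileups(d, co, cfg, n_error_sites = 0)
  calls <- call_pools(pp, call_config(strand_filter_on = FALSE))
  passed <- calls[calls$passed, ]
  vk <- dplyr::mutate(co$variants,
                      variant_key = paste(contig, pos, alt))
  q <- merge(merge(passed, d[, c("pool_id", "individual_id")]),
             vk[, c("pos", "variant_key", "variant_id", "functional_class")])
  sang <- simulate_sanger(co, q$variant_id, q$individual_id)
  vals <- dplyr::bind_cols(q[, c("individual_id", "variant_key",
                                 "variant_id", "functional_class")],
                           sang[, c("carrier", "zygosity")])
  ct <- resolve_carriers(
    dplyr::mutate(passed, variant_key = paste(contig, pos, alt)),
    d[, c("pool_id", "individual_id")], vals)
  expect_setequal(paste(ct$individual_id, ct$variant_id),
                  paste(truth$individual_id, truth$variant_id))
})
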