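#' Configuration of an end-to-end pipeline run
#'
#' A fully serialisable bundle of stage configurations; a run is
#' reproducible from this object alone.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param sim A [sim_config()] (its `seed` is overridden by `seed`).
#' @param call A [call_config()].
#' @param class_prevalences Carrier class prevalences for the generator.
#' @param trait_specs Named list of [trait_spec()]s to simulate and model.
#' @param prs_loading Correlation between the polygenic score and the BMI
#'   random intercept.
#' @param n_error_sites Error-only sites injected into the pileups.
#' @param initial_vaf Initial VAF screen applied to raw caller output before
#'   validation (the deliberately permissive 0.5% first-pass cutoff that the
#'   ROC stage later recalibrates).
#' @param grid_step Cutoff grid for [choose_vaf_cutoff()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       sim = sim_config(),
                       call = call_config(),
                       class_prevalences = c(cLoF = 0.0007, pLoF = 0.0023,
                                             `WT-like` = 0.0037, GoF = 0.0003),
                       trait_specs = list(bmi = trait_spec_bmi()),
                       prs_loading = 0.42,
                       n_error_sites = 17,
                       initial_vaf = 0.005,
                       grid_step = 1e-4) {
  sim$seed <- seed
  structure(list(seed = seed, sim = sim, call = call,
                 class_prevalences = class_prevalences,
                 trait_specs = trait_specs, prs_loading = prs_loading,
                 n_error_sites = n_error_sites, initial_vaf = initial_vaf,
                 grid_step = grid_step),
            class = "run_config")
}

#' Run the whole pipeline end to end
#'
#' Simulates the cohort, pools and pileups; calls candidate variants;
#' validates them against the per-individual oracle; recalibrates the VAF
#' cutoff (ROC); resolves carriers, applies the exclusion ledger and
#' estimates prevalence; simulates and models growth trajectories; and
#' compares the carrier effect with a polygenic score. Every intermediate
#' table is written to `out_dir` as TSV (plus a JSON report) when given.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return A `run_report` list of headline numbers and stage outputs:
#'   `prevalence`, `one_in_k`, `auc`, `cutoff`, `confusion`, `effects_18y`,
#'   `trajectory`, `prs`, plus the intermediate tables.
#' @export
run_end_to_end <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, code) {
    t0 <- Sys.time()
    res <- tryCatch(force(code), error = function(e)
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e))))
    message(sprintf("[rarepool] %-12s %6.2fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  cohort <- stage("simulate", simulate_cohort(config$sim, config$class_prevalences))
  design <- stage("pools", assign_pools(cohort, config$sim$pool_size,
                                        seed = sub_seed(config$seed, "pools")))
  pileups <- stage("pileups", simulate_pool_pileups(
    design, cohort, config$sim, n_error_sites = config$n_error_sites))
  pool_sizes <- design |> distinct(.data$pool_id, .data$pool_n) |>
    (\(d) setNames(d$pool_n, d$pool_id))()
  calls <- stage("call", call_pools(pileups, config$call, pool_sizes))
  passed <- calls |> filter(.data$passed, .data$vaf >= config$initial_vaf)

  # validation oracle: every pool member of every passing call is queried
  vkey <- cohort$variants |>
    mutate(variant_key = paste(.data$contig, .data$pos, .data$alt))
  validations <- stage("validate", {
    q <- passed |>
      mutate(variant_key = paste(.data$contig, .data$pos, .data$alt)) |>
      inner_join(design |> select("pool_id", "individual_id"), by = "pool_id",
                 relationship = "many-to-many") |>
      left_join(vkey |> select("variant_key", "variant_id"), by = "variant_key")
    sang <- simulate_sanger(cohort, q$variant_id, q$individual_id)
    bind_cols(q |> select("individual_id", "variant_key"),
              sang |> select("carrier", "zygosity")) |>
      distinct(.data$individual_id, .data$variant_key, .keep_all = TRUE)
  })

  labeled <- stage("label", label_calls(passed, validations,
                                        design |> select("pool_id", "individual_id")))
  no_carriers <- sum(!is.na(cohort$individuals$variant_id)) == 0
  roc <- cutoff <- conf <- NULL
  if (!no_carriers && any(labeled$label == "TP", na.rm = TRUE) &&
      any(labeled$label == "FP", na.rm = TRUE)) {
    roc <- stage("roc", roc_analysis(labeled))
    cutoff <- choose_vaf_cutoff(labeled, config$grid_step)
    conf <- confusion_at(labeled, cutoff)
  } else message("[rarepool] roc          skipped (single-class or no carriers)")

  # carrier resolution + exclusions + prevalence
  confirmed <- labeled |> filter(.data$label == "TP",
                                 is.null(cutoff) | .data$vaf >= (cutoff %||% 0))
  cls <- cohort$individuals |> select("individual_id", true_class = "class")
  validations2 <- validations |>
    left_join(vkey |> select("variant_key", "variant_id", "functional_class"),
              by = "variant_key")
  carriers <- stage("resolve", resolve_carriers(
    confirmed, design |> select("pool_id", "individual_id"), validations2))
  excl <- stage("exclude", apply_exclusions(
    cohort$individuals |> mutate(sequenced = TRUE)))
  N <- nrow(excl$analysis)
  carriers_in <- carriers |>
    filter(.data$individual_id %in% excl$analysis$individual_id)
  prevalence <- stage("prevalence", estimate_prevalence(carriers_in, N))

  # trajectories + growth models + PRS (skipped when no carriers survive)
  assoc <- NULL
  if (nrow(carriers_in) > 0 &&
      any(carriers_in$functional_class %in% c("cLoF", "pLoF"))) {
    assoc <- stage("associate", {
      spec <- config$trait_specs[[1]]
      ph_full <- simulate_trajectories(cohort, spec,
                                       seed = sub_seed(config$seed, "traj"))
      u0 <- attr(ph_full, "ranef_intercept")
      ph <- ph_full |>
        filter(.data$individual_id %in% excl$analysis$individual_id)
      top_age <- max(spec$ages)
      eff <- age_specific_effect(ph |> filter(.data$age_years == top_age))
      mlm <- fit_spline_mlm(ph, spec$knots, intercept_age = spec$ages[1],
                            random = "intercept")
      tc <- trajectory_contrast(mlm, c(spec$ages[1], spec$knots, top_age))
      prs <- simulate_prs(cohort, trait_loading = config$prs_loading,
                          seed = sub_seed(config$seed, "prs"),
                          ranef_intercept = u0)
      d18 <- ph |> filter(.data$age_years == top_age) |>
        left_join(prs, by = "individual_id")
      grp <- prs_top_decile(prs |>
                              filter(.data$individual_id %in% d18$individual_id))
      d18g <- d18 |> left_join(grp |> select("individual_id", "top_decile"),
                               by = "individual_id")
      prs_beta <- lm(value ~ top_decile + sex, data = d18g)
      list(effect_top_age = eff, mlm = mlm, contrast = tc,
           adjusted = adjusted_carrier_effect(d18),
           r2_prs = variance_explained(d18$value, d18$prs),
           r2_carrier = variance_explained(d18$value, d18$carrier),
           prs_group_beta = coef(prs_beta)[["top_decileTRUE"]])
    })
  } else message("[rarepool] associate    skipped (no LoF carriers)")

  report <- list(
    seed = config$seed,
    n_analysis = N,
    ledger = excl$ledger,
    prevalence = prevalence,
    one_in_k = prevalence$one_in[prevalence$class == "LoF"],
    auc = if (!is.null(roc)) roc$auc else NA_real_,
    cutoff = cutoff %||% NA_real_,
    confusion = conf,
    association = assoc,
    tables = list(calls = calls, labeled = labeled, carriers = carriers_in,
                  design = design)
  )
  class(report) <- "run_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_pileup_tsv(pileups, file.path(out_dir, "pileups.tsv"))
    write_table_tsv(calls, file.path(out_dir, "calls.tsv"))
    write_table_tsv(labeled, file.path(out_dir, "labeled_calls.tsv"))
    write_table_tsv(carriers_in, file.path(out_dir, "carriers.tsv"))
    write_table_tsv(excl$ledger, file.path(out_dir, "exclusion_ledger.tsv"))
    write_table_tsv(prevalence, file.path(out_dir, "prevalence.tsv"))
    if (!is.null(roc))
      write_table_tsv(roc$curve, file.path(out_dir, "roc_curve.tsv"))
    if (nrow(confirmed) > 0)
      write_calls_vcf(confirmed, file.path(out_dir, "confirmed.vcf"))
    jsonlite::write_json(
      list(seed = config$seed, n_analysis = N,
           auc = report$auc, cutoff = report$cutoff,
           lof_percent = prevalence$percent[prevalence$class == "LoF"],
           one_in_k = report$one_in_k),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> analysis N =", x$n_analysis,
      "| LoF", sprintf("%.2f%%", x$prevalence$percent[x$prevalence$class == "LoF"]),
      "(~1 in", x$one_in_k, ")",
      "| AUC", format(x$auc, digits = 3),
      "| cutoff", format(x$cutoff, digits = 3), "\n")
  invisible(x)
}

#' Generate the small bundled test fixtures
#'
#' Deterministic miniature datasets used by the unit tests: a 3-pool,
#' 30-individual cohort with 2 variants and its pileups; a 20-individual
#' phenotype table; and a 2-variant dose-response table.
#'
#' @param seed Integer seed.
#' @return A list: `cohort`, `design`, `pileups`, `pheno`, `assay`.
#' @export
make_fixtures <- function(seed = 42) {
  cfg <- sim_config(n_individuals = 30, pool_size = 10, mean_depth = 5000,
                    base_error_rate = 0.001, contribution_cv = 0.2,
                    overdispersion = 0, twin_rate = 0, triplet_rate = 0,
                    quad_rate = 0, duplicate_rate = 0, missing_id_rate = 0,
                    seed = seed)
  cohort <- simulate_cohort(cfg, c(pLoF = 1 / 30, cLoF = 1 / 30),
                            carriers_per_variant = 1)
  design <- assign_pools(cohort, 10, seed = sub_seed(seed, "fixpools"))
  pileups <- simulate_pool_pileups(design, cohort, cfg, n_error_sites = 2)
  small <- sim_config(n_individuals = 20, seed = sub_seed(seed, "fixpheno"))
  co2 <- simulate_cohort(small, c(pLoF = 0.2), carriers_per_variant = 1)
  spec <- trait_spec("bmi", ages = c(2, 5, 10, 15), knots = c(5, 10),
                     intercept = 16, slopes = c(0.2, 0.5, 0.4),
                     carrier_effects = c(0, 0, 0.3, 0.3),
                     ranef_sd = c(1, 0, 0, 0), resid_sd = 0.5)
  pheno <- simulate_trajectories(co2, spec, seed = sub_seed(seed, "fixtraj"))
  assay <- bind_rows(
    simulate_assay(100, -9, replicates = 3, noise_sd = 3,
                   seed = sub_seed(seed, "fixwt")) |> mutate(variant = "WT"),
    simulate_assay(55, -8, replicates = 3, noise_sd = 3,
                   seed = sub_seed(seed, "fixv")) |> mutate(variant = "V1"))
  list(cohort = cohort, design = design, pileups = pileups,
       pheno = pheno, assay = assay)
}
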