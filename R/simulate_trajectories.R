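#' Simulate long-format growth trajectories under a linear-spline model
#'
#' Draws one measurement per individual per occasion age from the two-level
#' linear-spline model described in [trait_spec()]: a piecewise-linear fixed
#' trajectory with sex and carrier offsets, individual-level random
#' intercept/slopes, an occasion-level residual, and missing-at-random
#' dropout whose probability follows the trait specification's age schedule.
#'
#' @param cohort A `cohort_sim`; the carrier flag is `class` in
#'   `carrier_classes`.
#' @param spec A [trait_spec()].
#' @param seed Integer seed.
#' @param carrier_classes Functional classes counted as carriers (default
#'   the loss-of-function classes).
#'
#' @return A tibble (`pheno_long`): `individual_id`, `trait`, `age_years`,
#'   `value`, `sex`, `carrier`. The individual random intercepts are
#'   attached as attribute `"ranef_intercept"` (named vector) for use by
#'   [simulate_prs()].
#' @export
simulate_trajectories <- function(cohort, spec, seed = NULL,
                                  carrier_classes = c("cLoF", "pLoF")) {
  stopifnot(inherits(cohort, "cohort_sim"), inherits(spec, "trait_spec"))
  ind <- cohort$individuals
  n <- nrow(ind)
  ages <- spec$ages
  basis <- spline_basis(ages, spec$knots, intercept_age = ages[1])
  X <- cbind(1, basis)                       # intercept + interval terms
  male <- as.numeric(ind$sex == "M")
  carrier <- as.numeric(ind$class %in% carrier_classes)

  # fixed part per individual x age
  pop <- drop(X %*% c(spec$intercept, spec$slopes))
  sexf <- drop(X %*% spec$sex_effects)
  carf <- drop(X %*% spec$carrier_effects)

  with_seed(seed, {
    u <- matrix(0, n, ncol(X))
    for (j in seq_len(ncol(X))) {
      if (spec$ranef_sd[j] > 0) u[, j] <- rnorm(n, 0, spec$ranef_sd[j])
    }
    ranef_part <- u %*% t(X)                 # n x n_ages
    eps <- if (spec$resid_sd > 0)
      matrix(rnorm(n * length(ages), 0, spec$resid_sd), n) else
      matrix(0, n, length(ages))

    values <- matrix(pop, n, length(ages), byrow = TRUE) +
      outer(male, sexf) + outer(carrier, carf) + ranef_part + eps

    keep <- matrix(runif(n * length(ages)), n) >=
      matrix(spec$missingness, n, length(ages), byrow = TRUE)

    out <- tibble(
      individual_id = rep(ind$individual_id, times = length(ages)),
      trait = spec$trait,
      age_years = rep(ages, each = n),
      value = as.vector(values),
      sex = rep(ind$sex, times = length(ages)),
      carrier = rep(carrier == 1, times = length(ages))
    )[as.vector(keep), ]
    out <- out |> arrange(.data$individual_id, .data$age_years)
    attr(out, "ranef_intercept") <- setNames(u[, 1], ind$individual_id)
    out
  })
}

#' Simulate a per-individual polygenic score
#'
#' Draws Gaussian scores, optionally correlated with the individual-level
#' random intercepts of a simulated trajectory so the score explains a
#' chosen share of trait variance. With standardised intercepts \eqn{u},
#' the score is \eqn{\mu + \sigma(\lambda u^\ast + \sqrt{1-\lambda^2} z)}
#' where \eqn{\lambda} is `trait_loading` and \eqn{z} iid standard normal.
#'
#' @param cohort A `cohort_sim`.
#' @param mean,sd Score mean and standard deviation (`sd > 0`).
#' @param trait_loading Correlation between the score and the trajectory
#'   random intercept; 0 gives an independent score.
#' @param seed Integer seed.
#' @param ranef_intercept Named vector of random intercepts (the
#'   `"ranef_intercept"` attribute of [simulate_trajectories()] output);
#'   required when `trait_loading != 0`.
#'
#' @return A tibble: `individual_id`, `prs`.
#' @export
simulate_prs <- function(cohort, mean = 0, sd = 1, trait_loading = 0,
                         seed = NULL, ranef_intercept = NULL) {
  stopifnot(inherits(cohort, "cohort_sim"))
  if (sd <= 0) abort("`sd` must be positive.")
  if (abs(trait_loading) > 1) abort("`trait_loading` must lie in [-1, 1].")
  ids <- cohort$individuals$individual_id
  with_seed(seed, {
    z <- rnorm(length(ids))
    if (trait_loading != 0) {
      if (is.null(ranef_intercept))
        abort("`ranef_intercept` is required when `trait_loading` != 0.")
      u <- ranef_intercept[ids]
      us <- if (sd(u) > 0) (u - base::mean(u)) / sd(u) else u * 0
      z <- trait_loading * us + sqrt(1 - trait_loading^2) * z
    }
    tibble(individual_id = ids, prs = mean + sd * z)
  })
}

#' Simulate a dose-response assay
#'
#' Generates replicate responses from a four-parameter logistic curve in
#' log10 dose,
#' \deqn{y = basal + (E_{max} - basal) / (1 + 10^{h(\log EC_{50} - x)})}
#' plus iid Gaussian noise. Signalling-dead (complete loss-of-function)
#' profiles are emitted as flat-at-baseline responses via `flat = TRUE`.
#'
#' @param emax Plateau response, in % of wild-type maximum.
#' @param logec50 Base-10 log of the half-maximal concentration (molar).
#' @param doses Agonist concentrations (molar, positive); at least 4
#'   distinct levels are needed for an identifiable 4-parameter fit.
#' @param replicates Replicates per dose.
#' @param noise_sd Residual SD (same units as response).
#' @param seed Integer seed.
#' @param hill Hill slope (default 1).
#' @param basal Response at zero dose.
#' @param flat If `TRUE`, ignore the curve and emit `basal` + noise.
#'
#' @return A tibble (`dose_response`): `dose`, `log10_dose`, `replicate`,
#'   `response`.
#' @export
simulate_assay <- function(emax, logec50, doses = 10^seq(-12, -6, by = 1),
                           replicates = 3, noise_sd = 0, seed = NULL,
                           hill = 1, basal = 0, flat = FALSE) {
  if (any(doses <= 0)) abort("`doses` must be positive molar concentrations.")
  grid <- crossing(dose = sort(doses), replicate = seq_len(replicates))
  x <- log10(grid$dose)
  mu <- if (flat) rep(basal, nrow(grid)) else
    basal + (emax - basal) / (1 + 10^(hill * (logec50 - x)))
  with_seed(seed, {
    grid |>
      mutate(log10_dose = x,
             response = mu + if (noise_sd > 0) rnorm(n(), 0, noise_sd) else 0) |>
      select("dose", "log10_dose", "replicate", "response")
  })
}
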