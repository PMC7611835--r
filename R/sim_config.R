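#' Simulation configuration for the pooled-sequencing cohort generator
#'
#' Collects the knobs that control the synthetic birth cohort and the pooled
#' sequencing read model. Defaults reproduce the design of a large UK birth
#' cohort screened by pooled amplicon sequencing: 5993 banked DNA samples
#' combined into pools of 50 and sequenced to a mean per-pool depth of
#' 43,654x, with a base-call error rate of 0.1%, unequal per-sample DNA
#' contribution (lognormal, CV 0.4) and mild beta-binomial overdispersion.
#'
#' @param n_individuals Number of individuals in the sequenced registry.
#' @param pool_size Diploid samples per pool (last pool may be smaller).
#' @param mean_depth Mean sequencing depth per pool and site (reads).
#' @param base_error_rate Per-read base miscall probability \eqn{\epsilon};
#'   must lie in `[0, 0.01)`.
#' @param contribution_cv Coefficient of variation of the lognormal per-sample
#'   DNA quantity entering a pool; 0 means perfectly equimolar pooling.
#' @param overdispersion Beta-binomial overdispersion \eqn{\rho} of read
#'   counts around the pool allele fraction; 0 recovers the plain binomial.
#' @param twin_rate,triplet_rate,quad_rate Expected fraction of individuals
#'   that are members of twin pairs / triplet sets / quadruplet sets.
#' @param duplicate_rate Fraction of registry entries that are duplicated
#'   aliquots of another sample.
#' @param missing_id_rate Fraction of entries with unlinkable identifiers.
#' @param seed Integer seed making every downstream draw reproducible.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 1000, seed = 1)
sim_config <- function(n_individuals = 5993,
                       pool_size = 50,
                       mean_depth = 43654,
                       base_error_rate = 0.001,
                       contribution_cv = 0.4,
                       overdispersion = 1e-4,
                       twin_rate = 0.02,
                       triplet_rate = 0.002,
                       quad_rate = 0.0007,
                       duplicate_rate = 0.0357,
                       missing_id_rate = 0.00083,
                       seed = NULL) {
  stopifnot(n_individuals >= 1)
  if (pool_size < 2) abort("`pool_size` must be at least 2.")
  if (base_error_rate < 0 || base_error_rate >= 0.01)
    abort("`base_error_rate` must lie in [0, 0.01).")
  if (overdispersion < 0 || overdispersion >= 1)
    abort("`overdispersion` must lie in [0, 1).")
  structure(list(
    n_individuals = as.integer(n_individuals),
    pool_size = as.integer(pool_size),
    mean_depth = mean_depth,
    base_error_rate = base_error_rate,
    contribution_cv = contribution_cv,
    overdispersion = overdispersion,
    twin_rate = twin_rate,
    triplet_rate = triplet_rate,
    quad_rate = quad_rate,
    duplicate_rate = duplicate_rate,
    missing_id_rate = missing_id_rate,
    seed = seed
  ), class = "sim_config")
}

#' Specification of a simulated growth trait trajectory
#'
#' Defines the fixed and random structure of one anthropometric trait as a
#' linear-spline (piecewise linear) mean trajectory with two levels of
#' variation: individual (random intercept and, optionally, random
#' per-interval slopes) and measurement occasion (residual).
#'
#' The mean for individual *i* at age *t* is
#' \deqn{\mu_i(t) = \beta_0 + \sum_j \beta_j B_j(t) +
#'   \mathrm{male}_i (\gamma_0 + \sum_j \gamma_j B_j(t)) +
#'   \mathrm{carrier}_i (\delta_0 + \sum_j \delta_j B_j(t))}
#' where \eqn{B_j(t)} is the time accrued inside spline interval *j* up to
#' age *t* (see [spline_basis()]), so every coefficient reads as
#' units/year within its interval.
#'
#' @param trait Trait name (e.g. `"bmi"`, `"weight"`, `"height"`).
#' @param ages Measurement-occasion ages (years); first age is the intercept.
#' @param knots Interior knot ages, strictly increasing and inside the range
#'   of `ages`.
#' @param intercept Population mean at the first age.
#' @param slopes Population slope per interval (length `length(knots) + 1`),
#'   in trait units per year.
#' @param sex_effects Male-minus-female effects: intercept then one slope
#'   offset per interval.
#' @param carrier_effects Carrier-minus-non-carrier effects, same layout.
#' @param ranef_sd Standard deviations of the individual-level random
#'   intercept and per-interval slopes (length `1 + length(slopes)`); zeros
#'   drop terms.
#' @param resid_sd Occasion-level residual SD.
#' @param missingness Probability a measurement is missing at each age
#'   (length 1 or `length(ages)`), applied missing-at-random.
#'
#' @return A list of class `trait_spec`.
#' @export
trait_spec <- function(trait, ages, knots,
                       intercept, slopes,
                       sex_effects = rep(0, length(slopes) + 1),
                       carrier_effects = rep(0, length(slopes) + 1),
                       ranef_sd = rep(0, length(slopes) + 1),
                       resid_sd = 0,
                       missingness = 0) {
  ages <- sort(unique(ages))
  if (is.unsorted(knots, strictly = TRUE)) abort("`knots` must be strictly increasing.")
  if (min(knots) <= min(ages) || max(knots) >= max(ages))
    abort("`knots` must lie strictly inside the age range.")
  if (length(slopes) != length(knots) + 1)
    abort("`slopes` must have one entry per interval (length(knots) + 1).")
  for (nm in c("sex_effects", "carrier_effects", "ranef_sd")) {
    v <- get(nm)
    if (length(v) != length(slopes) + 1)
      abort(paste0("`", nm, "` must have intercept + one entry per interval."))
  }
  if (any(ranef_sd < 0) || resid_sd < 0) abort("variance components must be >= 0.")
  missingness <- rep_len(missingness, length(ages))
  structure(list(
    trait = trait, ages = ages, knots = knots,
    intercept = intercept, slopes = slopes,
    sex_effects = sex_effects, carrier_effects = carrier_effects,
    ranef_sd = ranef_sd, resid_sd = resid_sd,
    missingness = missingness
  ), class = "trait_spec")
}

#' Default trait specifications for BMI, weight and height
#'
#' Trajectory shapes anchored to published cohort means: BMI 16.84 kg/m2 and
#' height 81.90 cm at the first modelled measure (18 months), birth weight
#' 3.44 kg; knots at 3.5, 5, 8 and 15 years (BMI), 5 and 15 years (height),
#' 1, 8 and 15 years (weight). Carrier slope offsets accrue to an 18-year
#' carrier/non-carrier gap of 4.84 kg/m2 in BMI and 17.76 kg in weight.
#'
#' @param carrier_gap_18y Total carrier-minus-non-carrier gap at 18 years,
#'   in trait units; the default spreads it over the post-5-year intervals
#'   (BMI) or post-1-year intervals (weight).
#' @name default_trait_specs
#' @return A `trait_spec`.
#' @export
trait_spec_bmi <- function(carrier_gap_18y = 4.84) {
  # gap accrues over 5-8 (3y), 8-15 (7y) and 15-18 (3y) in ratio 0.6:2.8:1.44
  w <- c(0, 0, 0.6, 2.8, 1.44) / 4.84 * carrier_gap_18y
  trait_spec(
    trait = "bmi",
    ages = c(1.5, 3.5, 5, 7, 8, 10, 12, 15, 18),
    knots = c(3.5, 5, 8, 15),
    intercept = 16.84,
    slopes = c(-0.5, -0.2, 0.3, 0.6, 0.35),
    sex_effects = c(0.1, 0, 0, -0.05, 0.05, 0.2),
    carrier_effects = c(0, w / c(2, 1.5, 3, 7, 3)),
    ranef_sd = c(1.3, rep(0.08, 5)),
    resid_sd = 0.8,
    missingness = c(0.05, 0.08, 0.1, 0.12, 0.15, 0.2, 0.25, 0.3, 0.4)
  )
}

#' @rdname default_trait_specs
#' @export
trait_spec_weight <- function(carrier_gap_18y = 17.76) {
  w <- c(0, 2.8, 11.2, 3.76) / 17.76 * carrier_gap_18y
  trait_spec(
    trait = "weight",
    ages = c(0, 1, 3, 5, 8, 10, 12, 15, 18),
    knots = c(1, 8, 15),
    intercept = 3.44,
    slopes = c(6.5, 2.6, 5.0, 2.0),
    sex_effects = c(0.12, 0.1, 0.05, 0.3, 1.2),
    carrier_effects = c(0, w / c(1, 7, 7, 3)),
    ranef_sd = c(2.5, 0.3, 0.25, 0.3, 0.3),
    resid_sd = 1.5,
    missingness = c(0.02, 0.05, 0.08, 0.1, 0.15, 0.2, 0.25, 0.3, 0.4)
  )
}

#' @rdname default_trait_specs
#' @export
trait_spec_height <- function(carrier_gap_18y = 2.0) {
  w <- c(0, 1.4, 0.6) / 2 * carrier_gap_18y
  trait_spec(
    trait = "height",
    ages = c(1.5, 3, 5, 8, 10, 12, 15, 18),
    knots = c(5, 15),
    intercept = 81.9,
    slopes = c(7.5, 5.5, 1.5),
    sex_effects = c(0.8, 0.1, 0.2, 1.5),
    carrier_effects = c(0, w / c(3.5, 10, 3)),
    ranef_sd = c(3.5, 0.25, 0.2, 0.2),
    resid_sd = 1.2,
    missingness = c(0.05, 0.08, 0.1, 0.15, 0.2, 0.25, 0.3, 0.4)
  )
}
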