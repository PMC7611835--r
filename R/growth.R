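#' Linear-spline basis in per-interval-slope parameterisation
#'
#' Column *j* is the time (years) accrued inside spline interval *j* up to
#' each age, counting from `intercept_age`; with knots at 1, 8 and 15
#' years, age 10 maps to `(1, 7, 2, 0)`. A coefficient on column *j*
#' therefore reads directly as trait units per year within interval *j*,
#' and with no knots the basis collapses to the single term
#' `age - intercept_age`.
#'
#' @param age Ages (years), each at least `intercept_age`.
#' @param knots Interior knot ages, strictly increasing.
#' @param intercept_age Age at which the model intercept is anchored
#'   (default the smallest input age).
#' @return A matrix with one column per interval (`length(knots) + 1`),
#'   named `s1`, `s2`, ...
#' @export
#' @examples
#' spline_basis(10, knots = c(1, 8, 15), intercept_age = 0)
spline_basis <- function(age, knots = numeric(), intercept_age = min(age)) {
  if (length(knots) && is.unsorted(knots, strictly = TRUE))
    abort("`knots` must be strictly increasing.")
  if (any(age < intercept_age - 1e-9))
    abort("ages must be at or after `intercept_age`.")
  lower <- c(intercept_age, knots)
  upper <- c(knots, Inf)
  B <- vapply(seq_along(lower), function(j)
    pmax(0, pmin(age, upper[j]) - lower[j]), numeric(length(age)))
  B <- matrix(B, nrow = length(age),
              dimnames = list(NULL, paste0("s", seq_along(lower))))
  B
}

#' Age-specific carrier effect by linear regression
#'
#' Ordinary least squares of a trait at one age on carrier status, adjusted
#' for sex (and optionally for same-occasion BMI, as in blood-pressure
#' models), on complete cases. The carrier contrast compares
#' loss-of-function carriers to everyone else. Estimates based on fewer
#' than two carriers with data are flagged unstable rather than dropped.
#'
#' @param data Tibble with `value`, `carrier` (logical), `sex`, and
#'   optionally `bmi`.
#' @param adjust_bmi Additionally adjust for `bmi`?
#' @param conf_level Confidence level.
#' @return An `EffectEstimate` one-row tibble: `beta`, `se`, `ci_lo`,
#'   `ci_hi`, `p_value`, `n`, `n_carriers`, `unstable`, `covariates`.
#' @export
age_specific_effect <- function(data, adjust_bmi = FALSE, conf_level = 0.95) {
  vars <- c("value", "carrier", "sex", if (adjust_bmi) "bmi")
  d <- data |> select(all_of(vars)) |> filter(complete.cases(data[vars]))
  n_car <- sum(d$carrier)
  if (n_car == 0) abort("No carriers with data at this age.")
  if (sd(d$value) == 0) abort("Outcome is constant.")
  f <- if (adjust_bmi) value ~ carrier + sex + bmi else value ~ carrier + sex
  m <- lm(f, data = d)
  co <- summary(m)$coefficients["carrierTRUE", ]
  tcrit <- qt(1 - (1 - conf_level) / 2, m$df.residual)
  tibble(beta = co[["Estimate"]], se = co[["Std. Error"]],
         ci_lo = co[["Estimate"]] - tcrit * co[["Std. Error"]],
         ci_hi = co[["Estimate"]] + tcrit * co[["Std. Error"]],
         p_value = co[["Pr(>|t|)"]],
         n = nrow(d), n_carriers = n_car,
         unstable = n_car < 2,
         covariates = paste(c("sex", if (adjust_bmi) "bmi"), collapse = "+"))
}

#' Fit a linear-spline two-level mixed model of a growth trajectory
#'
#' Restricted-maximum-likelihood fit (via `lme4::lmer`) of the two-level
#' model with occasions nested in individuals: fixed effects are the
#' spline terms plus carrier-by-spline and sex-by-spline interactions
#' (so carrier and sex each get an intercept difference and per-interval
#' slope differences); the individual level carries a random intercept
#' and, with `random = "slopes"`, random per-interval slopes with
#' unstructured covariance. A singular (boundary) covariance fit is
#' reported in the result; with `fallback = TRUE` a singular slope model
#' is refitted with a random intercept only, and the record says so.
#'
#' @param pheno_long Long-format tibble: `individual_id`, `age_years`,
#'   `value`, `sex`, `carrier`.
#' @param knots Interior knot ages.
#' @param intercept_age Age anchoring the intercept (default first
#'   observed age).
#' @param random `"slopes"` (random intercept + spline slopes) or
#'   `"intercept"`.
#' @param fallback Refit with random intercept only if the slope model is
#'   singular?
#' @return An object of class `spline_mlm`: the `lmer` fit plus metadata
#'   (`knots`, `intercept_age`, `age_range`, `random`, `singular`,
#'   `converged`, `fell_back`).
#' @export
fit_spline_mlm <- function(pheno_long, knots, intercept_age = NULL,
                           random = c("slopes", "intercept"),
                           fallback = TRUE) {
  random <- match.arg(random)
  d <- pheno_long |> filter(!is.na(.data$value))
  if (nrow(d) == 0) abort("no observations.")
  intercept_age <- intercept_age %||% min(d$age_years)
  B <- spline_basis(d$age_years, knots, intercept_age)
  md <- bind_cols(d |> select("individual_id", "value", "sex", "carrier"),
                  as_tibble(B)) |>
    mutate(male = as.numeric(.data$sex == "M"),
           carrier = as.numeric(.data$carrier))
  sterms <- colnames(B)
  fx <- paste(c(sterms,
                paste0("carrier + ", paste0("carrier:", sterms, collapse = " + ")),
                paste0("male + ", paste0("male:", sterms, collapse = " + "))),
              collapse = " + ")
  re <- if (random == "slopes")
    paste0("(1 + ", paste(sterms, collapse = " + "), " | individual_id)")
  else "(1 | individual_id)"
  form <- as.formula(paste("value ~", fx, "+", re))

  fit <- lme4::lmer(form, data = md, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  singular <- lme4::isSingular(fit)
  fell_back <- FALSE
  if (singular && random == "slopes" && fallback) {
    form2 <- as.formula(paste("value ~", fx, "+ (1 | individual_id)"))
    fit <- lme4::lmer(form2, data = md, REML = TRUE,
                      control = lme4::lmerControl(calc.derivs = FALSE))
    singular <- lme4::isSingular(fit)
    fell_back <- TRUE
  }
  msgs <- fit@optinfo$conv$lme4$messages
  structure(list(
    fit = fit, knots = knots, intercept_age = intercept_age,
    age_range = range(d$age_years), spline_terms = sterms,
    random = if (fell_back) "intercept" else random,
    singular = singular, fell_back = fell_back,
    converged = is.null(msgs) || !any(grepl("failed to converge", msgs))
  ), class = "spline_mlm")
}

#' @export
print.spline_mlm <- function(x, ...) {
  cat("<spline_mlm> knots:", paste(x$knots, collapse = ", "),
      "| random:", x$random,
      if (x$singular) "| singular covariance (boundary fit)" else "", "\n")
  fe <- lme4::fixef(x$fit)
  cat("carrier terms:\n")
  print(round(fe[grepl("carrier", names(fe))], 4))
  invisible(x)
}

#' Predicted group trajectories and the carrier gap by age
#'
#' Deterministic linear combinations of the fixed effects: mean predicted
#' curves for carriers and non-carriers (at the sample male fraction) and
#' the carrier-minus-non-carrier gap
#' \eqn{\delta_0 + \sum_j \delta_j B_j(a)} with a delta-method standard
#' error from the fixed-effect covariance.
#'
#' @param fit A `spline_mlm`.
#' @param ages Ages (years) inside the modelled range.
#' @param conf_level Confidence level for the gap interval.
#' @return A tibble: `age_years`, `mean_noncarrier`, `mean_carrier`,
#'   `gap`, `gap_se`, `gap_lo`, `gap_hi`.
#' @export
trajectory_contrast <- function(fit, ages, conf_level = 0.95) {
  stopifnot(inherits(fit, "spline_mlm"))
  if (any(ages < fit$age_range[1] - 1e-9 | ages > fit$age_range[2] + 1e-9))
    abort("ages outside the modelled range.")
  B <- spline_basis(ages, fit$knots, fit$intercept_age)
  fe <- lme4::fixef(fit$fit)
  V <- as.matrix(vcov(fit$fit))
  male_mean <- base::mean(fit$fit@frame$male)

  # lme4 orders interaction names by formula entry; normalise lookup
  fix_names <- function(want) {
    have <- names(fe)
    vapply(want, function(w) {
      if (w %in% have) return(w)
      parts <- strsplit(w, ":")[[1]]
      alt <- paste(rev(parts), collapse = ":")
      if (alt %in% have) alt else
        abort(paste("fixed effect", w, "not found"))
    }, character(1))
  }
  row_for <- function(carrier) {
    X <- matrix(0, length(ages), length(fe),
                dimnames = list(NULL, names(fe)))
    X[, "(Intercept)"] <- 1
    X[, fix_names(fit$spline_terms)] <- B
    X[, fix_names("male")] <- male_mean
    X[, fix_names(paste0("male:", fit$spline_terms))] <- B * male_mean
    if (carrier) {
      X[, fix_names("carrier")] <- 1
      X[, fix_names(paste0("carrier:", fit$spline_terms))] <- B
    }
    X
  }
  X0 <- row_for(FALSE); X1 <- row_for(TRUE)
  gapX <- X1 - X0
  gap <- drop(gapX %*% fe)
  gap_se <- sqrt(rowSums((gapX %*% V) * gapX))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble(age_years = ages,
         mean_noncarrier = drop(X0 %*% fe),
         mean_carrier = drop(X1 %*% fe),
         gap = gap, gap_se = gap_se,
         gap_lo = gap - z * gap_se, gap_hi = gap + z * gap_se)
}
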