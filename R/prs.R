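#' Split a polygenic score into top decile vs lower 90%
#'
#' The indicator is `TRUE` for the `ceiling(0.1 * N)` highest scores, with
#' ties broken deterministically by individual id.
#'
#' @param scores Tibble `individual_id`, `prs`.
#' @return The input plus `top_decile` (logical); attribute `degenerate`
#'   is `TRUE` when all scores are equal.
#' @export
prs_top_decile <- function(scores) {
  if (nrow(scores) < 10) abort("Need at least 10 individuals for a decile split.")
  degenerate <- sd(scores$prs) == 0
  if (degenerate) warn("All scores equal; decile split is degenerate.")
  k <- ceiling(0.1 * nrow(scores))
  out <- scores |>
    arrange(desc(.data$prs), .data$individual_id) |>
    mutate(top_decile = row_number() <= k) |>
    arrange(.data$individual_id)
  attr(out, "degenerate") <- degenerate
  out
}

#' Variance in a trait explained by one predictor
#'
#' The R-squared of the univariate linear model `trait ~ predictor`
#' (equivalently the squared correlation), the usual summary of variance
#' explained by a polygenic score or a carrier flag.
#'
#' @param trait,predictor Numeric vectors (or logical predictor) of equal
#'   length; pairs with missing values are dropped.
#' @return R-squared in `[0, 1]`.
#' @export
variance_explained <- function(trait, predictor) {
  ok <- complete.cases(trait, predictor)
  trait <- trait[ok]; predictor <- as.numeric(predictor[ok])
  if (length(trait) < 3) abort("Need at least 3 complete observations.")
  if (sd(predictor) == 0) abort("Predictor has zero variance.")
  summary(lm(trait ~ predictor))$r.squared
}

#' Carrier effect before and after polygenic-score adjustment
#'
#' Fits the sex-adjusted carrier model with and without the polygenic
#' score as a covariate, reporting both carrier estimates side by side —
#' the comparison that shows whether the rare-variant effect is captured
#' by common-variant burden.
#'
#' @param data Tibble with `value`, `carrier` (logical), `prs`, `sex`.
#' @param conf_level Confidence level.
#' @return A two-row tibble (`model` = `"unadjusted"`, `"prs_adjusted"`)
#'   with `beta`, `se`, `ci_lo`, `ci_hi`, `p_value`, `n`.
#' @export
adjusted_carrier_effect <- function(data, conf_level = 0.95) {
  d <- data |> filter(complete.cases(data[c("value", "carrier", "sex", "prs")]))
  if (sum(d$carrier) == 0) abort("No carriers with complete data.")
  if (sd(d$prs) == 0) abort("Polygenic score has zero variance (collinear).")
  one <- function(f, label) {
    m <- lm(f, data = d)
    co <- summary(m)$coefficients["carrierTRUE", ]
    tcrit <- qt(1 - (1 - conf_level) / 2, m$df.residual)
    tibble(model = label, beta = co[["Estimate"]], se = co[["Std. Error"]],
           ci_lo = co[["Estimate"]] - tcrit * co[["Std. Error"]],
           ci_hi = co[["Estimate"]] + tcrit * co[["Std. Error"]],
           p_value = co[["Pr(>|t|)"]], n = nrow(d))
  }
  bind_rows(one(value ~ carrier + sex, "unadjusted"),
            one(value ~ carrier + sex + prs, "prs_adjusted"))
}
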