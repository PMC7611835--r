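#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a dose-response fit
#'
#' @param x A `dose_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @exportS3Method generics::tidy
tidy.dose_fit <- function(x, ...) {
  if (is.null(x$estimate)) return(tibble(term = character(),
                                         estimate = numeric(),
                                         std.error = numeric()))
  tibble(term = names(x$estimate), estimate = unname(x$estimate),
         std.error = unname(x$se[names(x$estimate)]))
}

#' @rdname tidy.dose_fit
#' @exportS3Method generics::glance
glance.dose_fit <- function(x, ...) {
  tibble(rss = x$rss, df.residual = x$df_residual, nobs = x$n,
         n_params = x$n_params, converged = x$converged,
         clof_path = x$clof_path, ec50_reliable = x$ec50_reliable)
}

#' Tidy a linear-spline mixed-model fit
#'
#' @param x A `spline_mlm`.
#' @param effects `"fixed"` for fixed effects, `"ran_pars"` for variance
#'   components.
#' @param conf_level Confidence level for Wald intervals.
#' @param ... Unused.
#' @return A tibble of estimates with standard errors (fixed effects carry
#'   Wald confidence limits).
#' @exportS3Method generics::tidy
tidy.spline_mlm <- function(x, effects = c("fixed", "ran_pars"),
                            conf_level = 0.95, ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") {
    fe <- lme4::fixef(x$fit)
    se <- sqrt(diag(as.matrix(vcov(x$fit))))
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    tibble(term = names(fe), estimate = unname(fe), std.error = unname(se),
           conf.low = unname(fe - z * se), conf.high = unname(fe + z * se))
  } else {
    vc <- as.data.frame(lme4::VarCorr(x$fit))
    tibble(group = vc$grp, term1 = vc$var1, term2 = vc$var2,
           estimate = vc$vcov, sd_cor = vc$sdcor)
  }
}

#' @rdname tidy.spline_mlm
#' @exportS3Method generics::glance
glance.spline_mlm <- function(x, ...) {
  tibble(reml_criterion = as.numeric(lme4::REMLcrit(x$fit)),
         sigma = stats::sigma(x$fit),
         nobs = stats::nobs(x$fit),
         n_individuals = lme4::ngrps(x$fit)[["individual_id"]],
         random = x$random, singular = x$singular,
         converged = x$converged, fell_back = x$fell_back)
}

#' Plot an empirical ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.roc_result <- function(object, ...) {
  cv <- object$curve |> arrange(desc(.data$threshold))
  ggplot2::ggplot(tibble(fpr = 1 - cv$specificity, tpr = cv$sensitivity),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("VAF ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot a fitted dose-response curve with the data
#'
#' @param object A `dose_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dose_fit <- function(object, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$log10_dose,
                                       y = .data$response)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "log10 dose (M)", y = "response (%WT)") +
    ggplot2::theme_minimal()
  if (object$converged) {
    xs <- seq(min(d$log10_dose), max(d$log10_dose), length.out = 200)
    e <- object$estimate
    curve <- tibble(log10_dose = xs,
                    response = logistic4(xs, e[["basal"]], e[["emax"]],
                                         e[["logec50"]], e[["hill"]]))
    p <- p + ggplot2::geom_line(data = curve, colour = "steelblue")
  }
  p
}

#' Plot predicted carrier and non-carrier trajectories
#'
#' @param object A `spline_mlm`.
#' @param ages Prediction grid (default 60 points over the modelled range).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.spline_mlm <- function(object, ages = NULL, ...) {
  ages <- ages %||% seq(object$age_range[1], object$age_range[2],
                        length.out = 60)
  tc <- trajectory_contrast(object, ages) |>
    pivot_longer(c("mean_noncarrier", "mean_carrier"),
                 names_to = "group", values_to = "mean")
  ggplot2::ggplot(tc, ggplot2::aes(x = .data$age_years, y = .data$mean,
                                   colour = .data$group)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::scale_colour_manual(
      values = c(mean_noncarrier = "#9ecae1", mean_carrier = "#08519c"),
      labels = c(mean_noncarrier = "non-carrier", mean_carrier = "carrier")) +
    ggplot2::labs(x = "age (years)", y = "predicted mean", colour = NULL) +
    ggplot2::theme_minimal()
}
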