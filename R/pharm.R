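# 4PL mean function in log10 dose
logistic4 <- function(x, basal, emax, logec50, hill = 1) {
  basal + (emax - basal) / (1 + 10^(hill * (logec50 - x)))
}

#' Fit a sigmoidal (logistic) dose-response curve
#'
#' Least-squares fit of the four-parameter logistic
#' \deqn{y = basal + (E_{max} - basal)/(1 + 10^{h(\log EC_{50} - x)})}
#' in `x = log10(dose)`; the 3-parameter variant fixes the Hill slope at 1.
#' Fitting uses Levenberg-Marquardt with multi-start initialisation of
#' \eqn{\log EC_{50}} across the dose range. Flat (signalling-dead) data —
#' response span below `flat_span` — take the no-fit path used for
#' complete loss-of-function constructs: no curve is fitted and the
#' relative Emax is reported from the response at the top dose alone.
#'
#' @param data A `dose_response` tibble (`dose` or `log10_dose`,
#'   `response`).
#' @param n_params 4 (free Hill slope) or 3 (Hill slope fixed at 1).
#' @param flat_span Minimum range of per-dose mean response (same units as
#'   the response) below which data are declared flat.
#' @return An object of class `dose_fit`: estimates, standard errors,
#'   residual sum of squares, `converged`, `clof_path`, `ec50_reliable`
#'   (EC50 within 100x of the dose range) and the fitted `nls` object.
#' @export
fit_dose_response <- function(data, n_params = 4, flat_span = 10) {
  stopifnot(n_params %in% c(3, 4))
  d <- as_tibble(data)
  if (!"log10_dose" %in% names(d)) d$log10_dose <- log10(d$dose)
  if (length(unique(d$log10_dose)) < n_params)
    abort(sprintf("Need at least %d distinct doses for a %d-parameter fit.",
                  n_params, n_params))
  by_dose <- d |> group_by(.data$log10_dose) |>
    summarise(m = base::mean(.data$response), .groups = "drop")

  if (diff(range(by_dose$m)) < flat_span) {
    top <- max(by_dose$log10_dose)
    return(structure(list(
      estimate = c(basal = base::mean(by_dose$m), emax = by_dose$m[
        by_dose$log10_dose == top], logec50 = NA_real_, hill = NA_real_),
      se = c(basal = NA_real_, emax = NA_real_, logec50 = NA_real_,
             hill = NA_real_),
      rss = NA_real_, df_residual = NA_integer_, n = nrow(d),
      n_params = n_params, converged = FALSE, clof_path = TRUE,
      ec50_reliable = FALSE, fit = NULL, data = d), class = "dose_fit"))
  }

  xr <- range(d$log10_dose)
  starts <- lapply(seq(xr[1], xr[2], length.out = 5), function(ec) {
    s <- list(basal = min(by_dose$m), emax = max(by_dose$m), logec50 = ec)
    if (n_params == 4) s$hill <- 1
    s
  })
  lower <- c(basal = -Inf, emax = -Inf, logec50 = xr[1] - 4)
  upper <- c(basal = Inf, emax = Inf, logec50 = xr[2] + 4)
  if (n_params == 4) {
    lower <- c(lower, hill = 0.1); upper <- c(upper, hill = 10)
  }
  form <- if (n_params == 4)
    response ~ logistic4(log10_dose, basal, emax, logec50, hill)
  else
    response ~ logistic4(log10_dose, basal, emax, logec50, 1)

  best <- NULL
  for (s in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(form, data = d, start = s, lower = lower,
                        upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f) &&
        (is.null(best) || deviance(f) < deviance(best))) best <- f
  }
  if (is.null(best))
    return(structure(list(estimate = NULL, se = NULL, rss = NA_real_,
                          df_residual = NA_integer_, n = nrow(d),
                          n_params = n_params, converged = FALSE,
                          clof_path = FALSE, ec50_reliable = FALSE,
                          fit = NULL, data = d), class = "dose_fit"))

  est <- coef(best)
  if (n_params == 3) est <- c(est, hill = 1)
  se <- tryCatch(sqrt(diag(vcov(best))), error = function(e)
    rep(NA_real_, length(coef(best))))
  if (n_params == 3) se <- c(se, hill = NA_real_)
  names(se) <- names(est)
  structure(list(
    estimate = est, se = se, rss = deviance(best),
    df_residual = nrow(d) - length(coef(best)), n = nrow(d),
    n_params = n_params, converged = TRUE, clof_path = FALSE,
    ec50_reliable = est[["logec50"]] >= xr[1] - 2 &&
      est[["logec50"]] <= xr[2] + 2,
    fit = best, data = d), class = "dose_fit")
}

#' @export
print.dose_fit <- function(x, ...) {
  if (x$clof_path) {
    cat("<dose_fit> flat response (no-fit path); Emax at top dose =",
        format(x$estimate[["emax"]], digits = 3), "\n")
  } else if (!x$converged) {
    cat("<dose_fit> fit did not converge\n")
  } else {
    cat("<dose_fit>", x$n_params, "-parameter logistic: Emax =",
        format(x$estimate[["emax"]], digits = 4), ", logEC50 =",
        format(x$estimate[["logec50"]], digits = 4), "\n")
  }
  invisible(x)
}

# joint logistic fit with optionally shared emax / logec50 between groups;
# basal and hill are always shared. Returns rss and residual df.
joint_fit_rss <- function(d, n_params, share_emax, share_ec50) {
  g <- as.numeric(d$group == levels(factor(d$group))[2])
  by_dose <- d |> group_by(.data$log10_dose) |>
    summarise(m = base::mean(.data$response), .groups = "drop")
  xr <- range(d$log10_dose)
  start <- list(basal = min(by_dose$m), emax1 = max(by_dose$m),
                lec1 = base::mean(xr))
  lower <- c(basal = -Inf, emax1 = -Inf, lec1 = xr[1] - 4)
  upper <- c(basal = Inf, emax1 = Inf, lec1 = xr[2] + 4)
  if (!share_emax) { start$demax <- 0; lower <- c(lower, demax = -Inf)
    upper <- c(upper, demax = Inf) }
  if (!share_ec50) { start$dlec <- 0; lower <- c(lower, dlec = -8)
    upper <- c(upper, dlec = 8) }
  if (n_params == 4) { start$hill <- 1; lower <- c(lower, hill = 0.1)
    upper <- c(upper, hill = 10) }
  form <- paste0("response ~ logistic4(log10_dose, basal, ",
                 if (share_emax) "emax1" else "emax1 + g * demax", ", ",
                 if (share_ec50) "lec1" else "lec1 + g * dlec", ", ",
                 if (n_params == 4) "hill" else "1", ")")
  dd <- d; dd$g <- g
  best <- NULL
  for (lec in seq(xr[1], xr[2], length.out = 3)) {
    s <- start
    s$lec1 <- lec
    # nudge the group offsets off zero so identical arms stay identifiable
    if (!share_emax) s$demax <- 1e-3
    if (!share_ec50) s$dlec <- 1e-3
    f <- tryCatch(
      minpack.lm::nlsLM(as.formula(form), data = dd, start = s,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || deviance(f) < deviance(best)))
      best <- f
  }
  if (is.null(best)) return(NULL)
  list(rss = deviance(best), df = nrow(d) - length(coef(best)))
}

#' Compare a variant curve to wild type
#'
#' With `method = "ftest"` (cAMP-style), pooled data are fitted with the
#' tested parameter either separate per group (full model) or shared
#' (reduced model) and compared by the extra-sum-of-squares F-test
#' \deqn{F = \frac{(SS_r - SS_f)/(df_r - df_f)}{SS_f / df_f}.}
#' With `method = "ttest"` (arrestin-style), the curve is fitted per
#' experimental replicate and the per-replicate Emax / logEC50 estimates
#' are compared by a two-sided t-test.
#'
#' @param data_variant,data_wt `dose_response` tibbles; `method = "ttest"`
#'   requires a `replicate` column with at least 2 replicates per group.
#' @param n_params Passed to the underlying logistic fits.
#' @param method `"ftest"` or `"ttest"`.
#' @return A tibble: `parameter` (`emax`, `logec50`), `statistic`,
#'   `p_value`, plus `emax_ratio` (variant/WT Emax) and `ec50_fold`
#'   (variant/WT EC50 fold change) as attributes `evidence`.
#' @export
compare_to_wt <- function(data_variant, data_wt, n_params = 4,
                          method = c("ftest", "ttest")) {
  method <- match.arg(method)
  dv <- as_tibble(data_variant); dw <- as_tibble(data_wt)
  for (nm in c("dv", "dw")) {
    d <- get(nm)
    if (!"log10_dose" %in% names(d)) d$log10_dose <- log10(d$dose)
    assign(nm, d)
  }
  fit_v <- fit_dose_response(dv, n_params)
  fit_w <- fit_dose_response(dw, n_params)

  evidence <- list(
    emax_ratio = if (!is.null(fit_v$estimate) && !is.null(fit_w$estimate))
      fit_v$estimate[["emax"]] / fit_w$estimate[["emax"]] else NA_real_,
    ec50_fold = if (fit_v$converged && fit_w$converged)
      10^(fit_v$estimate[["logec50"]] - fit_w$estimate[["logec50"]]) else
        NA_real_,
    clof_path = fit_v$clof_path)

  if (method == "ftest") {
    pooled <- bind_rows(dv |> mutate(group = "variant"),
                        dw |> mutate(group = "wt"))
    full <- joint_fit_rss(pooled, n_params, share_emax = FALSE,
                          share_ec50 = FALSE)
    if (is.null(full)) abort("joint full model failed to fit.")
    one <- function(share_emax, share_ec50) {
      red <- joint_fit_rss(pooled, n_params, share_emax, share_ec50)
      if (is.null(red)) return(c(NA_real_, NA_real_))
      fstat <- ((red$rss - full$rss) / (red$df - full$df)) /
        (full$rss / full$df)
      fstat <- max(fstat, 0)
      c(fstat, pf(fstat, red$df - full$df, full$df, lower.tail = FALSE))
    }
    em <- one(TRUE, FALSE); ec <- one(FALSE, TRUE)
    out <- tibble(parameter = c("emax", "logec50"),
                  statistic = c(em[1], ec[1]),
                  p_value = c(em[2], ec[2]),
                  method = "extra-SS F-test")
  } else {
    if (!all(c("replicate") %in% names(dv)) || !"replicate" %in% names(dw))
      abort("t-test comparison needs a `replicate` column.")
    per_rep <- function(d) {
      d |> group_by(.data$replicate) |>
        group_map(function(g, key) {
          f <- fit_dose_response(g, n_params)
          tibble(emax = f$estimate[["emax"]],
                 logec50 = f$estimate[["logec50"]])
        }) |> list_rbind()
    }
    rv <- per_rep(dv); rw <- per_rep(dw)
    if (nrow(rv) < 2 || nrow(rw) < 2)
      abort("t-test comparison needs >= 2 replicates per group.")
    tt <- function(a, b) {
      if (all(is.na(a)) || all(is.na(b))) return(c(NA_real_, NA_real_))
      h <- t.test(a, b)
      c(unname(h$statistic), h$p.value)
    }
    em <- tt(rv$emax, rw$emax); ec <- tt(rv$logec50, rw$logec50)
    out <- tibble(parameter = c("emax", "logec50"),
                  statistic = c(em[1], ec[1]),
                  p_value = c(em[2], ec[2]),
                  method = "two-sided t-test")
  }
  attr(out, "evidence") <- evidence
  attr(out, "fits") <- list(variant = fit_v, wt = fit_w)
  out
}

#' Area under a kinetic trace above baseline
#'
#' Trapezoidal integral of `signal - mean(baseline)` over the stimulation
#' window, by default clipped at zero below baseline (receptor coupling
#' cannot be negative); set `clip = FALSE` to integrate signed deviations.
#'
#' @param time,signal Numeric vectors of equal length.
#' @param baseline_window `c(start, end)` of the pre-stimulation window.
#' @param stim_window `c(start, end)` of the stimulation window; must start
#'   at or after the baseline window ends.
#' @param clip Clip below-baseline deviations to zero?
#' @return The AUC (signal units x time units).
#' @export
arrestin_auc <- function(time, signal, baseline_window, stim_window,
                         clip = TRUE) {
  stopifnot(length(time) == length(signal))
  base_idx <- time >= baseline_window[1] & time <= baseline_window[2]
  stim_idx <- time >= stim_window[1] & time <= stim_window[2]
  if (!any(base_idx) || !any(stim_idx)) abort("empty baseline or stimulation window.")
  if (stim_window[1] < baseline_window[2])
    abort("baseline window must precede the stimulation window.")
  dev <- signal[stim_idx] - base::mean(signal[base_idx])
  if (clip) dev <- pmax(dev, 0)
  trapz(time[stim_idx], dev)
}

#' Default functional-classification criteria
#'
#' Thresholds for [classify_variant()]: constructs with no fit (flat
#' response) or Emax below `clof_emax_max` %WT are complete LoF; a
#' significant Emax deficit or EC50 right-shift (at `alpha`) is partial
#' LoF; the mirror image is GoF; anything else is WT-like.
#'
#' @param clof_emax_max Emax (%WT) at or below which a variant is cLoF.
#' @param alpha Significance level for the Emax / EC50 comparisons.
#' @return A list of class `class_criteria`.
#' @export
class_criteria <- function(clof_emax_max = 20, alpha = 0.05) {
  structure(list(clof_emax_max = clof_emax_max, alpha = alpha),
            class = "class_criteria")
}

#' Assign a functional class from comparison evidence
#'
#' A pure function of the evidence and the criteria: the same inputs
#' always give the same label. Conflicting signals (e.g. higher Emax but
#' right-shifted EC50, both significant) are flagged ambiguous and the
#' more severe (LoF) label is reported.
#'
#' @param evidence A list/one-row tibble with `emax_ratio` (variant/WT,
#'   on the %WT scale where WT = 1), `p_emax`, `ec50_fold` (variant/WT),
#'   `p_ec50`, and optional `clof_path` (flat-response flag).
#' @param criteria A [class_criteria()].
#' @return A one-row tibble: `label` (`cLoF`/`pLoF`/`WT-like`/`GoF`) and
#'   `ambiguous`.
#' @export
classify_variant <- function(evidence, criteria = class_criteria()) {
  ev <- as.list(evidence)
  clof_path <- isTRUE(ev$clof_path)
  emax_pct <- 100 * ev$emax_ratio
  if (clof_path || (!is.na(emax_pct) && emax_pct <= criteria$clof_emax_max))
    return(tibble(label = "cLoF", ambiguous = FALSE))

  sig <- function(p) !is.na(p) && p < criteria$alpha
  lof <- (sig(ev$p_emax) && ev$emax_ratio < 1) ||
    (sig(ev$p_ec50) && ev$ec50_fold > 1)
  gof <- (sig(ev$p_emax) && ev$emax_ratio > 1) ||
    (sig(ev$p_ec50) && ev$ec50_fold < 1)
  if (lof && gof) return(tibble(label = "pLoF", ambiguous = TRUE))
  if (lof) return(tibble(label = "pLoF", ambiguous = FALSE))
  if (gof) return(tibble(label = "GoF", ambiguous = FALSE))
  tibble(label = "WT-like", ambiguous = FALSE)
}
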