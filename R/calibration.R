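#' Label candidate calls against per-individual validation results
#'
#' A candidate call is a true positive (`TP`) when any member of its pool
#' is a confirmed carrier of the called allele; otherwise it is a false
#' positive (`FP`). Calls with no validation attempt are labelled `NA`
#' (unresolved) and excluded from ROC analysis.
#'
#' @param candidates Calls from [call_pools()] (typically `passed` rows).
#' @param validations Tibble `individual_id`, `variant_key` (or `contig` +
#'   `pos` + `alt`), `carrier` — e.g. from [simulate_sanger()] joined to
#'   variant coordinates.
#' @param pool_design Pool design tibble (`pool_id`, `individual_id`).
#' @return `candidates` plus `n_confirmed` (validated carriers in the pool)
#'   and `label` (`"TP"`, `"FP"` or `NA`).
#' @export
label_calls <- function(candidates, validations, pool_design) {
  if (!"variant_key" %in% names(validations)) {
    validations <- validations |>
      mutate(variant_key = paste(.data$contig, .data$pos, .data$alt))
  }
  cand <- candidates |>
    mutate(variant_key = paste(.data$contig, .data$pos, .data$alt))
  # carriers confirmed per pool x allele
  conf <- validations |>
    inner_join(pool_design, by = "individual_id",
               relationship = "many-to-many") |>
    group_by(.data$pool_id, .data$variant_key) |>
    summarise(n_confirmed = sum(.data$carrier),
              attempted = n() > 0, .groups = "drop")
  cand |>
    left_join(conf, by = c("pool_id", "variant_key")) |>
    mutate(
      n_confirmed = ifelse(is.na(.data$attempted), NA_integer_, .data$n_confirmed),
      label = case_when(is.na(.data$attempted) ~ NA_character_,
                        .data$n_confirmed > 0 ~ "TP",
                        TRUE ~ "FP")
    ) |>
    select(-"attempted")
}

#' ROC analysis of VAF as a predictor of call validity
#'
#' The area under the curve is the rank statistic
#' \eqn{P(VAF_{TP} > VAF_{FP}) + \tfrac12 P(VAF_{TP} = VAF_{FP})},
#' computed from the Wilcoxon rank sum; the per-threshold table reports
#' sensitivity, positive predictive value and classical specificity at
#' every observed VAF (inclusive `>=` thresholding).
#'
#' @param labeled Output of [label_calls()]; both labels must be present.
#' @return An object of class `roc_result`: list with `auc`, `curve`
#'   (tibble `threshold`, `sensitivity`, `ppv`, `specificity`), `n_tp`,
#'   `n_fp`.
#' @export
roc_analysis <- function(labeled) {
  lab <- labeled |> filter(!is.na(.data$label))
  tp <- lab$vaf[lab$label == "TP"]
  fp <- lab$vaf[lab$label == "FP"]
  if (length(tp) == 0 || length(fp) == 0)
    abort("ROC needs both TP and FP calls; got a single class.")
  r <- rank(c(tp, fp))
  auc <- (sum(r[seq_along(tp)]) - length(tp) * (length(tp) + 1) / 2) /
    (length(tp) * length(fp))
  thr <- sort(unique(c(0, lab$vaf)))
  curve <- tibble(
    threshold = thr,
    sensitivity = vapply(thr, function(t) base::mean(tp >= t), numeric(1)),
    ppv = vapply(thr, function(t) {
      k <- sum(tp >= t) + sum(fp >= t)
      if (k == 0) NA_real_ else sum(tp >= t) / k
    }, numeric(1)),
    specificity = vapply(thr, function(t) base::mean(fp < t), numeric(1))
  )
  structure(list(auc = auc, curve = curve,
                 n_tp = length(tp), n_fp = length(fp)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC =", format(x$auc, digits = 4),
      sprintf("(%d TP, %d FP)\n", x$n_tp, x$n_fp))
  invisible(x)
}

# trapezoidal AUC over the empirical ROC; used as an internal cross-check
roc_auc_trapezoid <- function(roc) {
  cv <- roc$curve |> arrange(desc(.data$threshold))
  x <- c(0, 1 - cv$specificity, 1)
  y <- c(0, cv$sensitivity, 1)
  trapz(x, y)
}

#' Recalibrate the VAF cutoff from labelled calls
#'
#' Under the default *retain-all-TP* rule the cutoff is the largest
#' multiple of `grid_step` that is at most the smallest true-positive VAF,
#' i.e. the most stringent threshold (maximal false-positive removal) that
#' keeps every validated call when applied inclusively (`VAF >= cutoff`).
#'
#' @param labeled Output of [label_calls()].
#' @param grid_step Threshold grid resolution (default 0.0001 = 0.01%).
#' @return The chosen cutoff (fraction).
#' @export
choose_vaf_cutoff <- function(labeled, grid_step = 1e-4) {
  tp <- labeled$vaf[!is.na(labeled$label) & labeled$label == "TP"]
  if (length(tp) == 0) abort("No true positives; cannot choose a cutoff.")
  k <- floor(min(tp) / grid_step + 1e-9)
  cut <- k * grid_step
  # floating-point guard: the returned threshold must never exceed min TP
  # VAF, or the inclusive rule would drop a validated call
  if (cut > min(tp)) cut <- min(tp)
  cut
}

#' Confusion summary at a VAF threshold
#'
#' Applies the inclusive rule (`VAF >= threshold`) and reports retained
#' counts, sensitivity, the positive predictive value `TP / (TP + FP)`
#' (the screen's working "specificity" figure) and classical specificity
#' (fraction of false positives removed), clearly separated.
#'
#' @param labeled Output of [label_calls()].
#' @param threshold VAF threshold (fraction, `>= 0`).
#' @return One-row tibble: `threshold`, `tp_retained`, `fp_retained`,
#'   `sensitivity`, `ppv`, `specificity`.
#' @export
confusion_at <- function(labeled, threshold) {
  if (threshold < 0) abort("`threshold` must be >= 0.")
  lab <- labeled |> filter(!is.na(.data$label))
  tp <- lab$vaf[lab$label == "TP"]; fp <- lab$vaf[lab$label == "FP"]
  tpr <- sum(tp >= threshold); fpr <- sum(fp >= threshold)
  tibble(threshold = threshold, tp_retained = tpr, fp_retained = fpr,
         sensitivity = if (length(tp)) tpr / length(tp) else NA_real_,
         ppv = if (tpr + fpr > 0) tpr / (tpr + fpr) else NA_real_,
         specificity = if (length(fp)) 1 - fpr / length(fp) else NA_real_)
}

#' Concordance of carrier sets between two sequencing platforms
#'
#' Restricts both carrier sets (records of `individual_id`, `variant_id`)
#' to individuals present in `overlap_ids` and returns the fraction of
#' carriages detected identically by both: |intersection| / |union|.
#'
#' @param carriers_a,carriers_b Tibbles with `individual_id`, `variant_id`.
#' @param overlap_ids Individuals sequenced on both platforms.
#' @return Fraction in `[0, 1]`.
#' @export
concordance <- function(carriers_a, carriers_b, overlap_ids) {
  if (length(overlap_ids) == 0) abort("overlap is empty.")
  key <- function(d) {
    d <- d |> filter(.data$individual_id %in% overlap_ids)
    paste(d$individual_id, d$variant_id)
  }
  a <- unique(key(carriers_a)); b <- unique(key(carriers_b))
  u <- union(a, b)
  if (length(u) == 0) return(1)
  length(intersect(a, b)) / length(u)
}
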