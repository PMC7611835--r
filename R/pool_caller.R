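#' Screening configuration for the pooled variant caller
#'
#' Defaults follow the published pooled-screen criteria: variant allele
#' fraction at least 0.05%, coverage at least 100 reads, significance 0.05
#' and the strand filter on. The significance test is a one-sided exact
#' binomial tail against a null per-read error rate `error_rate_null`; the
#' strand filter requires at least `strand_min_reads_each` alternate reads
#' on each strand and a minor-strand share of at least
#' `strand_min_fraction` (a 90/10-style rule).
#'
#' @param vaf_min Minimum variant allele fraction (fraction, not percent).
#' @param coverage_min Minimum site depth (ref + alt reads).
#' @param alpha Significance threshold for the binomial tail p-value.
#' @param error_rate_null Null per-read error rate \eqn{\epsilon_0}.
#' @param strand_filter_on Apply the strand-balance filter?
#' @param strand_min_fraction Minimum minor-strand fraction of alt reads.
#' @param strand_min_reads_each Minimum alt reads required per strand.
#' @return A list of class `call_config`.
#' @export
call_config <- function(vaf_min = 0.0005, coverage_min = 100, alpha = 0.05,
                        error_rate_null = 0.001, strand_filter_on = TRUE,
                        strand_min_fraction = 0.1, strand_min_reads_each = 1) {
  if (vaf_min <= 0 || vaf_min >= 1) abort("`vaf_min` must lie in (0, 1).")
  if (coverage_min < 1) abort("`coverage_min` must be at least 1.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  structure(list(vaf_min = vaf_min, coverage_min = coverage_min,
                 alpha = alpha, error_rate_null = error_rate_null,
                 strand_filter_on = strand_filter_on,
                 strand_min_fraction = strand_min_fraction,
                 strand_min_reads_each = strand_min_reads_each),
            class = "call_config")
}

#' Expected pooled VAF contributed by heterozygous carriers
#'
#' In an equimolar pool of `pool_size` diploid samples, `n_het`
#' heterozygotes contribute `n_het` alternate allele copies among
#' `2 * pool_size` total copies, so the expected variant allele fraction is
#' `n_het / (2 * pool_size)` — 1% for a single heterozygote in a pool
#' of 50.
#'
#' @param n_het Number of heterozygous carriers in the pool.
#' @param pool_size Number of diploid samples in the pool.
#' @return Expected VAF as a fraction.
#' @export
#' @examples
#' expected_pool_vaf(1, 50)  # 0.01
expected_pool_vaf <- function(n_het, pool_size) {
  if (any(pool_size <= 0)) abort("`pool_size` must be positive.")
  if (any(n_het < 0) || any(n_het > pool_size))
    abort("`n_het` must lie in [0, pool_size].")
  n_het / (2 * pool_size)
}

# one-sided exact binomial tail P(X >= alt | depth, p0); vectorised
binom_tail_p <- function(alt, depth, p0) {
  p <- rep(1, length(alt))
  nz <- alt > 0
  p[nz] <- pbinom(alt[nz] - 1, depth[nz], p0, lower.tail = FALSE)
  p
}

#' Evaluate the screening criteria at one site of one pool
#'
#' Computes the VAF (`alt / (ref + alt)`), the one-sided exact binomial
#' p-value \eqn{P(X \ge alt \mid depth, \epsilon_0)}, the strand-balance
#' verdict, and the overall pass flag: a call passes iff VAF, coverage,
#' p-value and (when on) the strand filter all meet the configured
#' thresholds. A zero-depth site yields a non-passing call with VAF
#' reported as 0 and `zero_depth = TRUE`.
#'
#' @param counts A data frame (or one-row list) with `ref_fwd`, `ref_rev`,
#'   `alt_fwd`, `alt_rev`; extra columns (`pool_id`, `contig`, `pos`, ...)
#'   are carried through.
#' @param config A [call_config()].
#' @param pool_sizes Optional named vector mapping `pool_id` to the number
#'   of diploid samples, used to estimate carriage as
#'   `round(VAF * 2 * pool_size)`.
#' @return A tibble with the input columns plus `depth`, `alt`, `vaf`,
#'   `p_value`, `strand_pass`, `zero_depth`, `passed` and `est_carriers`.
#' @export
call_site <- function(counts, config = call_config(), pool_sizes = NULL) {
  d <- as_tibble(counts)
  need <- c("ref_fwd", "ref_rev", "alt_fwd", "alt_rev")
  miss <- setdiff(need, names(d))
  if (length(miss)) abort(paste("counts lack columns:", paste(miss, collapse = ", ")))
  if (any(unlist(d[need]) < 0)) abort("read counts must be non-negative.")

  alt <- d$alt_fwd + d$alt_rev
  ref <- d$ref_fwd + d$ref_rev
  depth <- ref + alt
  vaf <- ifelse(depth > 0, alt / depth, 0)
  p <- binom_tail_p(alt, depth, config$error_rate_null)
  minor <- pmin(d$alt_fwd, d$alt_rev)
  strand_pass <- if (config$strand_filter_on) {
    minor >= config$strand_min_reads_each &
      ifelse(alt > 0, minor / alt, 0) >= config$strand_min_fraction
  } else rep(TRUE, nrow(d))

  out <- d |> mutate(
    depth = depth, alt_reads = alt, vaf = vaf, p_value = p,
    strand_pass = strand_pass, zero_depth = depth == 0,
    passed = depth > 0 & vaf >= config$vaf_min & depth >= config$coverage_min &
      p < config$alpha & strand_pass
  )
  if (!is.null(pool_sizes) && "pool_id" %in% names(out)) {
    out <- out |> mutate(est_carriers = as.integer(round(
      .data$vaf * 2 * unname(pool_sizes[.data$pool_id]))))
  } else {
    out$est_carriers <- NA_integer_
  }
  out
}

#' Call candidate variants across a table of pooled pileups
#'
#' Applies [call_site()] to every pool-by-site record with a nonzero
#' alternate count and returns candidate calls in deterministic
#' (contig, pos, pool_id) order.
#'
#' @param pileups A `pool_pileup` tibble (see [simulate_pool_pileups()] or
#'   [read_pileup_tsv()]).
#' @param config A [call_config()].
#' @param pool_sizes Optional named vector of pool sizes (see [call_site()]).
#' @return A tibble of candidate calls (all evaluated sites, with `passed`
#'   marking those that survive the screen).
#' @export
call_pools <- function(pileups, config = call_config(), pool_sizes = NULL) {
  need <- c("pool_id", "contig", "pos", "ref", "alt",
            "ref_fwd", "ref_rev", "alt_fwd", "alt_rev")
  miss <- setdiff(need, names(pileups))
  if (length(miss)) abort(paste("pileup lacks columns:", paste(miss, collapse = ", ")))
  cand <- pileups |> filter(.data$alt_fwd + .data$alt_rev > 0)
  if (nrow(cand) == 0) return(call_site(pileups[0, ], config, pool_sizes))
  call_site(cand, config, pool_sizes) |>
    arrange(.data$contig, .data$pos, .data$pool_id)
}
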