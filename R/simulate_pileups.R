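#' Simulate strand-resolved pooled pileups at variant and error-only sites
#'
#' Implements the read-count model of pooled sequencing. For each pool and
#' site the true alternate-allele fraction is the contribution-weighted
#' carrier fraction
#' \deqn{p_0 = \sum_{i \in carriers} 0.5\, w_i \Big/ \sum_{i \in pool} w_i}
#' with per-sample DNA weights \eqn{w_i} lognormal (CV `contribution_cv`);
#' base errors shift it to \eqn{p = p_0 + \epsilon (1 - 2 p_0)}. Depth is
#' Poisson(`mean_depth`) and the alternate read count beta-binomial with
#' overdispersion \eqn{\rho} (binomial when \eqn{\rho = 0}); reads land on
#' each strand with probability 1/2. With equimolar pooling, no errors and
#' no overdispersion a single heterozygote therefore yields an expected VAF
#' of exactly \eqn{1/(2 \times pool\_size)} (1% in a pool of 50); unequal
#' contribution makes the realised true-positive VAFs overdispersed around
#' a slightly higher mean, as observed in practice.
#'
#' In addition to carrier sites, `n_error_sites` error-only sites are
#' emitted (one random pool each) whose per-site error rate is drawn
#' lognormally around `fp_error_mult` times the base error rate, so the
#' calibration stage sees genuine false-positive calls.
#'
#' @param design Pool design from [assign_pools()].
#' @param cohort The `cohort_sim` that generated the design.
#' @param config The [sim_config()] (depth, error, contribution, rho, seed).
#' @param n_error_sites Number of error-only (no-carrier) sites to inject.
#' @param fp_error_mult Multiple of `base_error_rate` around which error-only
#'   site rates are drawn.
#' @param fp_error_sdlog Lognormal log-scale SD of the per-site error rates;
#'   together with `fp_error_mult` this places false-positive VAFs just
#'   around the permissive first-pass screen, as observed in practice.
#'
#' @return A tibble (`pool_pileup`): `pool_id`, `contig`, `pos` (1-based),
#'   `ref`, `alt`, `ref_fwd`, `ref_rev`, `alt_fwd`, `alt_rev`.
#' @export
simulate_pool_pileups <- function(design, cohort, config,
                                  n_error_sites = 17, fp_error_mult = 4.5,
                                  fp_error_sdlog = 0.15) {
  stopifnot(inherits(cohort, "cohort_sim"), inherits(config, "sim_config"))
  eps <- config$base_error_rate
  cv <- config$contribution_cv
  rho <- config$overdispersion

  with_seed(sub_seed(config$seed, "pileup"), {
    ind <- cohort$individuals |> select("individual_id", "variant_id")

    # lognormal contribution weight per pooled sample
    sdlog <- sqrt(log(1 + cv^2))
    w <- if (cv > 0) rlnorm(nrow(design), -sdlog^2 / 2, sdlog) else
      rep(1, nrow(design))
    wt <- design |> mutate(w = w) |>
      left_join(ind, by = "individual_id")
    pool_tot <- wt |> group_by(.data$pool_id) |>
      summarise(wsum = sum(.data$w), .groups = "drop")

    # carrier-weighted alt fraction per (variant, pool) with carriers
    carr <- wt |> filter(!is.na(.data$variant_id)) |>
      group_by(.data$variant_id, .data$pool_id) |>
      summarise(wcar = sum(.data$w), .groups = "drop") |>
      left_join(pool_tot, by = "pool_id") |>
      mutate(p0 = 0.5 * .data$wcar / .data$wsum)

    grid <- crossing(cohort$variants |>
                       select("variant_id", "contig", "pos", "ref", "alt"),
                     pool_id = pool_tot$pool_id) |>
      left_join(carr |> select("variant_id", "pool_id", "p0"),
                by = c("variant_id", "pool_id")) |>
      mutate(p0 = ifelse(is.na(.data$p0), 0, .data$p0),
             p = .data$p0 + eps * (1 - 2 * .data$p0),
             err_site = FALSE) |>
      select(-"variant_id", -"p0")

    # error-only sites: elevated per-site error rate, one pool each
    if (n_error_sites > 0) {
      taken <- unique(cohort$variants$pos)
      fp_pos <- sample(setdiff(seq_len(2000L), taken), n_error_sites)
      bases <- c("A", "C", "G", "T")
      r <- sample(bases, n_error_sites, replace = TRUE)
      a <- vapply(r, function(b) sample(setdiff(bases, b), 1), character(1))
      grid <- bind_rows(grid, tibble(
        contig = "toy1", pos = fp_pos, ref = r, alt = unname(a),
        pool_id = sample(pool_tot$pool_id, n_error_sites, replace = TRUE),
        p = if (eps > 0) rlnorm(n_error_sites, log(fp_error_mult * eps),
                                fp_error_sdlog)
            else 0,
        err_site = TRUE))
    }

    n <- nrow(grid)
    depth <- rpois(n, config$mean_depth)
    p <- pmin(grid$p, 1)
    alt_n <- integer(n)
    pos_p <- which(p > 0 & depth > 0)
    if (length(pos_p)) {
      pp <- p[pos_p]
      # beta-binomial overdispersion models template amplification of the
      # pooled alleles; error-only sites carry their variability in the
      # per-site rate itself and sample binomially around it
      od <- rho > 0 & !grid$err_site[pos_p]
      if (any(od)) pp[od] <- rbeta(sum(od), pp[od] * (1 - rho) / rho,
                                   (1 - pp[od]) * (1 - rho) / rho)
      alt_n[pos_p] <- rbinom(length(pos_p), depth[pos_p], pp)
    }
    ref_n <- depth - alt_n
    alt_f <- rbinom(n, alt_n, 0.5)
    ref_f <- rbinom(n, ref_n, 0.5)

    grid |>
      mutate(ref_fwd = as.integer(ref_f), ref_rev = as.integer(ref_n - ref_f),
             alt_fwd = as.integer(alt_f),
             alt_rev = as.integer(alt_n - alt_f)) |>
      select("pool_id", "contig", "pos", "ref", "alt",
             "ref_fwd", "ref_rev", "alt_fwd", "alt_rev") |>
      arrange(.data$contig, .data$pos, .data$pool_id)
  })
}

#' Query the per-individual validation oracle
#'
#' Capillary (Sanger) re-sequencing of the original sample is treated as a
#' perfect genotype oracle by default; `miss_rate` allows a configurable
#' per-query false-negative rate.
#'
#' @param cohort A `cohort_sim`.
#' @param variant_id,individual_id Which genotype to confirm (vectorised).
#' @param miss_rate Probability a true carrier is reported as non-carrier.
#' @param seed Seed used only when `miss_rate > 0`.
#'
#' @return A tibble: `individual_id`, `variant_id`, `carrier` (logical),
#'   `zygosity` (`"het"`, `"hom"` or `NA` for non-carriers).
#' @export
simulate_sanger <- function(cohort, variant_id, individual_id,
                            miss_rate = 0, seed = NULL) {
  stopifnot(inherits(cohort, "cohort_sim"))
  ind <- cohort$individuals
  unknown <- setdiff(individual_id, ind$individual_id)
  if (length(unknown)) abort(paste("Unknown individual id:", unknown[1]))
  q <- tibble(individual_id = individual_id, variant_id = variant_id)
  res <- q |>
    left_join(ind |> select("individual_id", true_variant = "variant_id",
                            "copies"),
              by = "individual_id") |>
    mutate(
      carrier = !is.na(.data$true_variant) & !is.na(.data$variant_id) &
        .data$true_variant == .data$variant_id,
      zygosity = case_when(.data$carrier & .data$copies >= 2 ~ "hom",
                           .data$carrier ~ "het",
                           TRUE ~ NA_character_)
    )
  if (miss_rate > 0) {
    res <- with_seed(seed, {
      miss <- runif(nrow(res)) < miss_rate
      res |> mutate(carrier = .data$carrier & !miss,
                    zygosity = ifelse(.data$carrier, .data$zygosity, NA_character_))
    })
  }
  res |> select("individual_id", "variant_id", "carrier", "zygosity")
}
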