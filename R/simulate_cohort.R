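#' Simulate a birth-cohort registry with rare heterozygous variant carriers
#'
#' Generates the ground truth every downstream stage consumes: one row per
#' registry individual (sex, multiplet membership, duplicate / missing-id
#' flags) and one row per variant (position on a toy contig, functional
#' class, true carriers). Each individual independently carries a variant of
#' class *c* with probability `class_prevalences[c]`, so class carrier
#' counts are exactly binomial; carriers are then grouped into distinct
#' variants via `carriers_per_variant`, mirroring the observed pattern that
#' a few variants recur in several unrelated carriers.
#'
#' All rare carriers are heterozygous (one alternate allele copy).
#'
#' @param config A [sim_config()].
#' @param class_prevalences Named numeric vector of per-class carrier
#'   probabilities, names among `cLoF`, `pLoF`, `WT-like`, `GoF`;
#'   must sum to at most 1.
#' @param carriers_per_variant Probabilities that a variant has 1, 2, 3, ...
#'   carriers; used when partitioning carriers of a class into variants.
#'
#' @return An object of class `cohort_sim`: a list with tibbles
#'   `individuals` (id, sex, class, variant_id, relatedness_group_id,
#'   multiplet_size, duplicate_flag, missing_id_flag) and `variants`
#'   (variant_id, contig, pos, ref, alt, functional_class, n_carriers).
#' @export
#' @examples
#' co <- simulate_cohort(sim_config(n_individuals = 2000, seed = 7),
#'                       c(pLoF = 0.0023, cLoF = 0.0007))
#' table(co$individuals$class)
simulate_cohort <- function(config,
                            class_prevalences = c(cLoF = 0.0007, pLoF = 0.0023,
                                                  `WT-like` = 0.0037, GoF = 0.0003),
                            carriers_per_variant = c(0.70, 0.20, 0.07, 0.03)) {
  stopifnot(inherits(config, "sim_config"))
  classes <- names(class_prevalences)
  bad <- setdiff(classes, c("cLoF", "pLoF", "WT-like", "GoF"))
  if (length(bad)) abort(paste("Unknown functional class:", paste(bad, collapse = ", ")))
  if (any(class_prevalences < 0) || sum(class_prevalences) > 1)
    abort("`class_prevalences` must be non-negative and sum to at most 1.")

  n <- config$n_individuals
  with_seed(sub_seed(config$seed, "cohort"), {
    ids <- sprintf("ID%06d", seq_len(n))
    sex <- sample(c("M", "F"), n, replace = TRUE)

    # per-individual functional class (multinomial; 'none' absorbs the rest)
    cls <- sample(c(classes, "none"), n, replace = TRUE,
                  prob = c(class_prevalences, 1 - sum(class_prevalences)))

    # partition the carriers of each class into variants
    variant_id <- rep(NA_character_, n)
    var_rows <- list()
    vi <- 0L
    for (cl in classes) {
      idx <- which(cls == cl)
      while (length(idx) > 0) {
        k <- sample(seq_along(carriers_per_variant), 1, prob = carriers_per_variant)
        k <- min(k, length(idx))
        vi <- vi + 1L
        vid <- sprintf("V%03d", vi)
        take <- idx[seq_len(k)]
        variant_id[take] <- vid
        idx <- idx[-seq_len(k)]
        var_rows[[vi]] <- tibble(variant_id = vid, functional_class = cl,
                                 n_carriers = k)
      }
    }
    variants <- if (vi > 0) list_rbind(var_rows) else
      tibble(variant_id = character(), functional_class = character(),
             n_carriers = integer())
    if (nrow(variants) > 0) {
      pos <- sort(sample(seq_len(1000L), nrow(variants)))
      bases <- c("A", "C", "G", "T")
      ref <- sample(bases, nrow(variants), replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
      variants <- variants |>
        mutate(contig = "toy1", pos = pos, ref = ref, alt = unname(alt),
               .after = "variant_id")
    } else {
      variants <- variants |>
        mutate(contig = character(), pos = integer(), ref = character(),
               alt = character(), .after = "variant_id")
    }

    # multiplets: whole groups flagged with a shared relatedness id
    grp <- rep(NA_character_, n)
    msize <- rep(1L, n)
    free <- seq_len(n)
    gi <- 0L
    for (sz in c(4L, 3L, 2L)) {
      rate <- switch(as.character(sz), "4" = config$quad_rate,
                     "3" = config$triplet_rate, "2" = config$twin_rate)
      n_groups <- floor(n * rate / sz)
      for (g in seq_len(n_groups)) {
        if (length(free) < sz) break
        gi <- gi + 1L
        pick <- sample(free, sz)
        grp[pick] <- sprintf("R%04d", gi)
        msize[pick] <- sz
        free <- setdiff(free, pick)
      }
    }

    dup <- rep(FALSE, n)
    dup[sample(free, min(length(free), round(n * config$duplicate_rate)))] <- TRUE
    mis <- rep(FALSE, n)
    mis[sample(which(!dup), round(n * config$missing_id_rate))] <- TRUE

    individuals <- tibble(
      individual_id = ids, sex = sex, class = cls, variant_id = variant_id,
      copies = ifelse(is.na(variant_id), 0L, 1L),
      relatedness_group_id = grp, multiplet_size = msize,
      duplicate_flag = dup, missing_id_flag = mis
    )
    structure(list(individuals = individuals, variants = variants,
                   config = config),
              class = "cohort_sim")
  })
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat("<cohort_sim> ", nrow(x$individuals), " individuals, ",
      nrow(x$variants), " variants (",
      sum(!is.na(x$individuals$variant_id)), " carriers)\n", sep = "")
  invisible(x)
}

#' Randomly assign cohort individuals to sequencing pools
#'
#' Every individual with a usable identifier is placed in exactly one pool;
#' pools are filled to `pool_size`, with only the final pool allowed to be
#' smaller (ceiling division: 5993 samples in pools of 50 gives 120 pools).
#'
#' @param cohort A `cohort_sim` (or a tibble with an `individual_id` column
#'   and optional `missing_id_flag`).
#' @param pool_size Samples per pool; at least 2.
#' @param seed Integer seed for the random shuffle.
#'
#' @return A tibble (`pool_design`): `pool_id`, `individual_id`, `pool_n`
#'   (the realised size of that pool).
#' @export
assign_pools <- function(cohort, pool_size = 50, seed = NULL) {
  ind <- if (inherits(cohort, "cohort_sim")) cohort$individuals else cohort
  if (nrow(ind) == 0) abort("cohort is empty.")
  if (pool_size < 2) abort("`pool_size` must be at least 2.")
  if (!"missing_id_flag" %in% names(ind)) ind$missing_id_flag <- FALSE
  usable <- ind$individual_id[!ind$missing_id_flag]
  with_seed(seed, {
    shuffled <- sample(usable)
    pool_idx <- ceiling(seq_along(shuffled) / pool_size)
    design <- tibble(
      pool_id = sprintf("P%03d", pool_idx),
      individual_id = shuffled
    ) |>
      group_by(.data$pool_id) |>
      mutate(pool_n = n()) |>
      ungroup() |>
      arrange(.data$pool_id, .data$individual_id)
    design
  })
}
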