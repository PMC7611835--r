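#' Read and write the pooled pileup exchange format
#'
#' Plain TSV with columns `pool_id`, `contig`, `pos` (1-based), `ref`,
#' `alt`, `ref_fwd`, `ref_rev`, `alt_fwd`, `alt_rev`. Malformed rows are
#' reported with their line numbers.
#'
#' @param path File path.
#' @param pileups A `pool_pileup` tibble.
#' @return `read_pileup_tsv()` returns the pileup tibble;
#'   `write_pileup_tsv()` returns `path` invisibly.
#' @export
read_pileup_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         pool_id = "c", contig = "c", pos = "i", ref = "c",
                         alt = "c", ref_fwd = "i", ref_rev = "i",
                         alt_fwd = "i", alt_rev = "i"))
  counts <- c("pos", "ref_fwd", "ref_rev", "alt_fwd", "alt_rev")
  bad <- which(!complete.cases(d[counts]) |
                 rowSums(as.matrix(d[counts[-1]]) < 0, na.rm = TRUE) > 0)
  if (length(bad))
    abort(paste0("Malformed pileup rows at line(s): ",
                 paste(bad + 1, collapse = ", "), " of ", path))
  d
}

#' @rdname read_pileup_tsv
#' @export
write_pileup_tsv <- function(pileups, path) {
  readr::write_tsv(pileups, path)
  invisible(path)
}

#' Write candidate calls as a minimal VCF
#'
#' One record per site aggregating the pools in which it was called; INFO
#' keys `VAF` (mean across calling pools), `DP` (total depth), `PP`
#' (minimum binomial p-value) and `POOLS`. Sites are 1-based, matching the
#' VCF convention. Optional `genotypes` (tibble `individual_id`,
#' `variant_key`, `zygosity`) adds per-sample GT columns for confirmed
#' carriers.
#'
#' @param calls A calls tibble from [call_pools()] (rows with `passed` are
#'   written unless `all = TRUE`).
#' @param path Output path.
#' @param all Write non-passing records too?
#' @param genotypes Optional confirmed-carrier genotypes.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path, all = FALSE, genotypes = NULL) {
  keep <- if (all) calls else calls |> filter(.data$passed)
  site <- keep |>
    group_by(.data$contig, .data$pos, .data$ref, .data$alt) |>
    summarise(vaf = base::mean(.data$vaf), dp = sum(.data$depth),
              pp = min(.data$p_value),
              pools = paste(sort(unique(.data$pool_id)), collapse = "|"),
              .groups = "drop") |>
    arrange(.data$contig, .data$pos)

  hdr <- c("##fileformat=VCFv4.2",
           "##source=rarepool",
           "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Mean variant allele fraction across calling pools\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth across calling pools\">",
           "##INFO=<ID=PP,Number=1,Type=Float,Description=\"Minimum binomial tail p-value\">",
           "##INFO=<ID=POOLS,Number=1,Type=String,Description=\"Pools in which the site was called\">")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")

  samples <- character()
  gt_block <- NULL
  if (!is.null(genotypes) && nrow(genotypes) > 0) {
    hdr <- c(hdr, "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
    samples <- sort(unique(genotypes$individual_id))
    cols <- c(cols, "FORMAT", samples)
    key <- paste(site$contig, site$pos, site$alt)
    gkey <- genotypes$variant_key
    gt_block <- vapply(seq_len(nrow(site)), function(i) {
      g <- genotypes[gkey == key[i], ]
      gt <- setNames(rep("0/0", length(samples)), samples)
      gt[g$individual_id] <- ifelse(g$zygosity == "hom", "1/1", "0/1")
      paste(c("GT", unname(gt)), collapse = "\t")
    }, character(1))
  }

  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tVAF=%.6g;DP=%d;PP=%.6g;POOLS=%s",
                  site$contig, site$pos, site$ref, site$alt,
                  site$vaf, as.integer(site$dp), site$pp, site$pools)
  if (!is.null(gt_block)) body <- paste(body, gt_block, sep = "\t")
  writeLines(c(hdr, paste(cols, collapse = "\t"), body), path)
  invisible(path)
}

#' Write cohort tables to plain-text files
#'
#' Truth, phenotype and score tables are exchanged as TSV; configurations
#' as JSON.
#'
#' @param x Object to write (tibble, or `sim_config`/`run_config` list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
write_config_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
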