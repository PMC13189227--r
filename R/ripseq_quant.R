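# RIP-seq style quantification: RPKM/TPM normalization, the IR Alu coverage
# enrichment ratio between immunoprecipitated (IP) and total cytoplasmic
# libraries, and intron versus 3'UTR relative expression stratified by Alu
# category. Counting is assumed strand-aware upstream; this module consumes
# per-region count tables.

#' RPKM normalization of a region count table
#'
#' `rpkm = count / (length/1e3) / (total/1e6)`; TPM rescales RPKM so the
#' library sums to one million.
#'
#' @param counts Tibble with `region_id`, `length` (nt, >= 1), `count`, and
#'   optionally `region_type` and `category` carried through.
#' @param total Total mapped reads for the library (default: sum of `count`).
#' @return `counts` with `rpkm` and `tpm` columns appended.
#' @export
rpkm_table <- function(counts, total = sum(counts$count)) {
  if (!is.numeric(total) || total <= 0) abort_domain("`total` must be > 0.")
  if (any(counts$length < 1)) abort_domain("region lengths must be >= 1.")
  counts |>
    dplyr::mutate(
      rpkm = .data$count / (.data$length / 1e3) / (total / 1e6),
      tpm = rpkm_to_tpm(.data$rpkm)
    )
}

#' Convert RPKM values to TPM
#'
#' @param rpkm Numeric vector with at least one positive value.
#' @return TPM values summing to 1e6 (scale-invariant in the input).
#' @examples
#' rpkm_to_tpm(c(1, 1, 2))
#' @export
rpkm_to_tpm <- function(rpkm) {
  s <- sum(rpkm)
  if (!is.finite(s) || s <= 0) abort_domain("RPKM values must include a positive entry.")
  rpkm / s * 1e6
}

#' IR Alu coverage enrichment ratio
#'
#' Mean over insertion sites of the per-site coverage ratio between the
#' immunoprecipitated and total libraries. Sites with zero denominator
#' coverage are excluded (not imputed) and tallied.
#'
#' @param coverage Tibble with per-site `ip` and `total` coverage (optionally
#'   `site_id`).
#' @param direction `"ip_over_total"` (default) or `"total_over_ip"`; the
#'   ratio's orientation is a configuration switch.
#' @return One-row tibble: `mean_ratio`, `n_sites` (used), `n_excluded`.
#' @export
ir_alu_enrichment <- function(coverage, direction = c("ip_over_total", "total_over_ip")) {
  direction <- match.arg(direction)
  num <- if (direction == "ip_over_total") coverage$ip else coverage$total
  den <- if (direction == "ip_over_total") coverage$total else coverage$ip
  usable <- den > 0
  if (!any(usable)) abort_domain("no sites with nonzero denominator coverage.")
  tibble(
    mean_ratio = mean(num[usable] / den[usable]),
    n_sites = sum(usable),
    n_excluded = sum(!usable)
  )
}

#' Intron versus 3'UTR relative expression by Alu category
#'
#' Within each Alu-content stratum, the ratio of summed intron TPM to summed
#' 3'UTR TPM. Strata missing either region type are omitted with a warning.
#'
#' @param regions Normalized region tibble from [rpkm_table()] with
#'   `region_type` (`"intron"`/`"three_prime_utr"` among others), `category`,
#'   `tpm`.
#' @param intron_type,utr_type Region-type labels to compare.
#' @return Tibble: `category`, `intron_tpm`, `utr_tpm`, `ratio`.
#' @export
intron_vs_utr_expression <- function(regions, intron_type = "intron",
                                     utr_type = "three_prime_utr") {
  sums <- regions |>
    dplyr::filter(.data$region_type %in% c(intron_type, utr_type)) |>
    dplyr::group_by(.data$category, .data$region_type) |>
    dplyr::summarise(tpm = sum(.data$tpm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "region_type", values_from = "tpm")
  for (col in c(intron_type, utr_type)) {
    if (!col %in% names(sums)) sums[[col]] <- NA_real_
  }
  incomplete <- is.na(sums[[intron_type]]) | is.na(sums[[utr_type]])
  if (any(incomplete)) {
    warning(
      "stratum(-a) missing a region type omitted: ",
      paste(sums$category[incomplete], collapse = ", ")
    )
  }
  sums |>
    dplyr::filter(!incomplete) |>
    dplyr::transmute(
      category = .data$category,
      intron_tpm = .data[[intron_type]],
      utr_tpm = .data[[utr_type]],
      ratio = .data$intron_tpm / .data$utr_tpm
    )
}
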