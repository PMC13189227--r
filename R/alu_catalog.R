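# Alu catalogue: assign annotated repeat insertions to gene regions, classify
# each region's Alu content, and tabulate category proportions by region type.
#
# Orientation is the element's annotated strand in genome coordinates. The
# inverted-repeat (IR) class requires at least one pair of insertions on
# opposite element strands -- a condition invariant to the gene's own strand.

ALU_CATEGORIES <- c("NONE", "SINGLE", "MULTI_SAME", "IR")

#' Assign Alu insertions to regions
#'
#' An Alu is assigned to a region when at least `min_overlap_fraction` of the
#' element's length overlaps the region; one element may be assigned to several
#' overlapping regions. Elements on chromosomes absent from the region set are
#' skipped with a message.
#'
#' @param regions Tibble of regions: `region_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, and optionally `region_type`.
#' @param alus Tibble of Alu insertions: `chrom`, `start`, `end`,
#'   `element_strand` (or `strand`), optional `alu_id`.
#' @param min_overlap_fraction Minimum overlapping fraction of the element
#'   (default 0.5).
#' @return A tibble with one row per (region, insertion) assignment:
#'   `region_id`, `alu_id`, `chrom`, `start`, `end`, `element_strand`,
#'   `overlap_fraction`.
#' @export
assign_alus_to_regions <- function(regions, alus, min_overlap_fraction = 0.5) {
  if (min_overlap_fraction <= 0 || min_overlap_fraction > 1) {
    abort_domain("`min_overlap_fraction` must be in (0, 1].")
  }
  if (!"element_strand" %in% names(alus) && "strand" %in% names(alus)) {
    alus <- dplyr::rename(alus, element_strand = "strand")
  }
  if (!"alu_id" %in% names(alus)) {
    alus <- dplyr::mutate(alus, alu_id = paste0("alu", dplyr::row_number()))
  }
  unknown <- !(alus$chrom %in% regions$chrom)
  if (any(unknown)) {
    message(sum(unknown), " Alu(s) on chromosomes absent from the region set skipped.")
    alus <- alus[!unknown, , drop = FALSE]
  }
  if (nrow(alus) == 0L || nrow(regions) == 0L) {
    return(tibble(
      region_id = character(0), alu_id = character(0), chrom = character(0),
      start = integer(0), end = integer(0), element_strand = character(0),
      overlap_fraction = numeric(0)
    ))
  }
  gr_regions <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end)
  )
  gr_alus <- GenomicRanges::GRanges(
    alus$chrom, IRanges::IRanges(alus$start + 1L, alus$end)
  )
  hits <- GenomicRanges::findOverlaps(gr_alus, gr_regions)
  if (length(hits) == 0L) {
    return(tibble(
      region_id = character(0), alu_id = character(0), chrom = character(0),
      start = integer(0), end = integer(0), element_strand = character(0),
      overlap_fraction = numeric(0)
    ))
  }
  qa <- S4Vectors::queryHits(hits)
  sa <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr_alus)[qa], IRanges::ranges(gr_regions)[sa]
  ))
  frac <- ov / (alus$end[qa] - alus$start[qa])
  keep <- frac >= min_overlap_fraction
  tibble(
    region_id = regions$region_id[sa][keep],
    alu_id = alus$alu_id[qa][keep],
    chrom = alus$chrom[qa][keep],
    start = alus$start[qa][keep],
    end = alus$end[qa][keep],
    element_strand = alus$element_strand[qa][keep],
    overlap_fraction = frac[keep]
  )
}

#' Classify a region's Alu content
#'
#' Zero insertions give `NONE`; one gives `SINGLE`; two or more on a single
#' element strand give `MULTI_SAME`; two or more with both strands represented
#' give `IR` (inverted repeat). Permutation-invariant in its input.
#'
#' @param element_strands Character vector of element strands (`"+"`/`"-"`)
#'   for one region's insertions (may be empty).
#' @return One of `"NONE"`, `"SINGLE"`, `"MULTI_SAME"`, `"IR"`.
#' @examples
#' alu_category(c("+", "-"))
#' @export
alu_category <- function(element_strands) {
  n <- length(element_strands)
  if (n == 0L) {
    "NONE"
  } else if (n == 1L) {
    "SINGLE"
  } else if (dplyr::n_distinct(element_strands) == 1L) {
    "MULTI_SAME"
  } else {
    "IR"
  }
}

#' Categorize every region by its Alu content
#'
#' @param regions Region tibble (as in [assign_alus_to_regions()]); must carry
#'   `region_id` and, for downstream proportion tables, `region_type`.
#' @param assignments Assignment tibble from [assign_alus_to_regions()].
#' @return `regions` with `n_alus` and a `category` factor
#'   (`NONE < SINGLE < MULTI_SAME < IR`) appended; regions without assignments
#'   are `NONE`.
#' @export
categorize_regions <- function(regions, assignments) {
  per_region <- assignments |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(
      n_alus = dplyr::n(),
      category = alu_category(.data$element_strand),
      .groups = "drop"
    )
  regions |>
    dplyr::left_join(per_region, by = "region_id") |>
    dplyr::mutate(
      n_alus = dplyr::coalesce(.data$n_alus, 0L),
      category = factor(
        dplyr::coalesce(.data$category, "NONE"),
        levels = ALU_CATEGORIES
      )
    )
}

#' Category proportions by region type
#'
#' @param categorized Tibble from [categorize_regions()] with `region_type`
#'   and `category`.
#' @return A tibble `region_type`, `category`, `n`, `proportion`; proportions
#'   sum to 1 within each region type over the full category grid.
#' @export
category_proportions <- function(categorized) {
  if (!all(c("region_type", "category") %in% names(categorized))) {
    abort_domain("`categorized` must have region_type and category columns.")
  }
  out <- categorized |>
    dplyr::mutate(category = factor(.data$category, levels = ALU_CATEGORIES)) |>
    dplyr::count(.data$region_type, .data$category, .drop = FALSE, name = "n") |>
    dplyr::group_by(.data$region_type) |>
    dplyr::mutate(total = sum(.data$n)) |>
    dplyr::ungroup()
  empty <- unique(out$region_type[out$total == 0])
  if (length(empty) > 0) {
    warning("region type(s) with no regions omitted: ", paste(empty, collapse = ", "))
    out <- dplyr::filter(out, .data$total > 0)
  }
  out |>
    dplyr::mutate(proportion = .data$n / .data$total) |>
    dplyr::select(-"total")
}
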