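# Desk-scale mismatch/indel-tolerant aligner.
#
# Seed-and-verify over small genomes (up to a few Mb): fixed-width exact seeds
# are located with Biostrings::matchPDict (Aho-Corasick), then each candidate
# locus is verified with vectorized mismatch counting, trying the gapless
# placement and every single-indel placement up to the indel cap. By the
# pigeonhole principle, `max_mismatches + max_indels + 1` disjoint seeds
# guarantee one exact seed for any alignment within the error budget, so
# sensitivity is exact for queries long enough to carry that many seeds
# (7 x seed_width nt at the defaults); shorter queries are searched with as
# many disjoint seeds as fit.

#' Alignment constraint and scoring defaults
#'
#' The constraint triple used throughout the lariat pipeline: at most 5
#' mismatches, mismatch rate at most 10% of the aligned query bases, and at
#' most one indel of at most 3 nt. Scoring is +1 match, -1 mismatch, -2 gap
#' open and -1 per gap base.
#'
#' @return Named list of defaults.
#' @export
alignment_defaults <- function() {
  list(
    max_mismatches = 5L, max_mismatch_rate = 0.10,
    max_indel_length = 3L, allow_indel = TRUE,
    score_match = 1, score_mismatch = -1,
    score_gap_open = -2, score_gap_extend = -1,
    seed_width = 12L
  )
}

#' Align query sequences to a small genome
#'
#' @param seqs Named character vector of query sequences (DNA alphabet).
#' @param genome Named character vector of chromosome sequences.
#' @param max_mismatches Maximum substitution count.
#' @param max_mismatch_rate Maximum mismatches as a fraction of aligned query
#'   bases.
#' @param max_indel_length Maximum length of the single tolerated indel.
#' @param allow_indel Permit one indel (default `TRUE`).
#' @param both_strands Also search the reverse strand (default `TRUE`).
#' @param seed_width Exact-seed width in nt.
#' @param score_match,score_mismatch,score_gap_open,score_gap_extend Scoring
#'   scheme (gap of length d costs `gap_open + d * gap_extend`).
#' @return A tibble of alignments: `seq_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open, forward-genome coordinates), `mismatches`,
#'   `indel_len` (0 for gapless), `indel_type` (`"none"`, `"ins"` = extra
#'   query bases, `"del"` = extra genome bases), `score`.
#' @export
align_to_genome <- function(seqs, genome,
                            max_mismatches = 5L, max_mismatch_rate = 0.10,
                            max_indel_length = 3L, allow_indel = TRUE,
                            both_strands = TRUE, seed_width = 12L,
                            score_match = 1, score_mismatch = -1,
                            score_gap_open = -2, score_gap_extend = -1) {
  empty <- tibble(
    seq_id = character(0), chrom = character(0), strand = character(0),
    start = integer(0), end = integer(0), mismatches = integer(0),
    indel_len = integer(0), indel_type = character(0), score = numeric(0)
  )
  if (length(seqs) == 0L) return(empty)
  if (is.null(names(seqs))) names(seqs) <- as.character(seq_along(seqs))
  if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
  seqs <- toupper(seqs)
  genome <- toupper(genome)

  queries <- tibble(
    seq_id = rep(names(seqs), times = if (both_strands) 2L else 1L),
    strand = rep(if (both_strands) c("+", "-") else "+", each = length(seqs)),
    query = c(seqs, if (both_strands) vapply(seqs, revcomp, character(1)))
  )

  max_d <- if (allow_indel) as.integer(max_indel_length) else 0L
  n_seeds_target <- as.integer(max_mismatches) + (if (allow_indel) 1L else 0L) + 1L

  # fixed-width disjoint seeds per query (positions 1-based within the query)
  seed_tbl <- purrr::pmap(queries, function(seq_id, strand, query) {
    L <- nchar(query)
    if (L < seed_width) return(NULL)
    k <- min(n_seeds_target, L %/% seed_width)
    offs <- unique(as.integer(round(seq(1, L - seed_width + 1, length.out = k))))
    seed <- substring(query, offs, offs + seed_width - 1L)
    ok <- !grepl("[^ACGT]", seed)
    if (!any(ok)) return(NULL)
    tibble(seq_id = seq_id, strand = strand, offset = offs[ok], seed = seed[ok])
  }) |> dplyr::bind_rows()
  if (nrow(seed_tbl) == 0L) return(empty)

  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seed_tbl$seed))

  genome_raw <- lapply(genome, charToRaw)
  results <- list()
  for (chrom in names(genome)) {
    subject <- Biostrings::DNAString(genome[[chrom]])
    hits <- Biostrings::matchPDict(pd, subject)
    starts <- Biostrings::startIndex(hits)
    n_hits <- lengths(starts)
    if (sum(n_hits) == 0L) next
    hit_tbl <- tibble(
      seed_row = rep(seq_along(starts), n_hits),
      genome_pos = unlist(starts)
    )
    hit_tbl$seq_id <- seed_tbl$seq_id[hit_tbl$seed_row]
    hit_tbl$strand <- seed_tbl$strand[hit_tbl$seed_row]
    hit_tbl$offset <- seed_tbl$offset[hit_tbl$seed_row]
    # candidate query start on the genome (1-based), padded for indel shifts
    cand <- hit_tbl |>
      dplyr::mutate(base_start = .data$genome_pos - .data$offset + 1L) |>
      tidyr::expand_grid(shift = seq(-max_d, max_d)) |>
      dplyr::mutate(start1 = .data$base_start + .data$shift) |>
      dplyr::distinct(.data$seq_id, .data$strand, .data$start1)
    craw <- genome_raw[[chrom]]
    qmap <- stats::setNames(queries$query, paste(queries$seq_id, queries$strand))
    for (r in seq_len(nrow(cand))) {
      qid <- cand$seq_id[r]
      qstrand <- cand$strand[r]
      q <- qmap[[paste(qid, qstrand)]]
      v <- verify_candidate(
        charToRaw(q), craw, cand$start1[r], max_d,
        score_match, score_mismatch, score_gap_open, score_gap_extend
      )
      if (!is.null(v)) {
        v$seq_id <- qid
        v$chrom <- chrom
        v$strand <- qstrand
        results[[length(results) + 1L]] <- v
      }
    }
  }
  if (length(results) == 0L) return(empty)
  # Overlapping placements of one query are one locus: mapping is
  # score-driven, so the locus's alignment is its best-scoring variant, and
  # the constraint triple is then applied to that alignment as a filter
  # (map-then-filter, not constraint-steered search).
  all_rows <- dplyr::bind_rows(results) |>
    dplyr::group_by(.data$seq_id, .data$chrom, .data$strand) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(
      locus = cumsum(.data$start >= dplyr::lag(cummax(.data$end), default = -1L))
    ) |>
    dplyr::group_by(.data$locus, .add = TRUE) |>
    dplyr::arrange(
      dplyr::desc(.data$score), .data$indel_len, .data$mismatches,
      .by_group = TRUE
    ) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  all_rows |>
    dplyr::filter(
      .data$mismatches <= max_mismatches,
      .data$mismatches <= max_mismatch_rate * .data$aligned_q + 1e-9
    ) |>
    dplyr::select(
      "seq_id", "chrom", "strand", "start", "end",
      "mismatches", "indel_len", "indel_type", "score"
    ) |>
    dplyr::arrange(.data$seq_id, .data$chrom, .data$start)
}

# Verify one candidate placement: gapless plus every single-indel variant.
# The best-scoring variant is the locus's alignment (mapping is score-driven);
# the constraint triple is then applied to it as a filter, mirroring a
# map-then-filter pipeline. Returns the alignment row (1-based start converted
# to 0-based half-open) or NULL when the locus's best alignment violates the
# constraints.
verify_candidate <- function(qraw, craw, start1, max_d,
                             s_match, s_mm, s_open, s_ext) {
  L <- length(qraw)
  G <- length(craw)
  best <- NULL
  consider <- function(mm, indel_len, indel_type, span, aligned_q) {
    gap_pen <- if (indel_len > 0) -(abs(s_open) + indel_len * abs(s_ext)) else 0
    matches <- aligned_q - mm
    score <- matches * s_match + mm * s_mm + gap_pen
    row <- tibble(
      start = start1 - 1L, end = start1 - 1L + span,
      mismatches = as.integer(mm), indel_len = as.integer(indel_len),
      indel_type = indel_type, score = score, aligned_q = aligned_q
    )
    better <- is.null(best) || score > best$score ||
      (score == best$score && (indel_len < best$indel_len ||
        (indel_len == best$indel_len && mm < best$mismatches)))
    if (better) best <<- row
  }
  # gapless
  if (start1 >= 1L && start1 + L - 1L <= G) {
    v0 <- qraw != craw[start1:(start1 + L - 1L)]
    consider(sum(v0), 0L, "none", L, L)
    f0 <- cumsum(as.integer(v0))
  } else {
    f0 <- NULL
  }
  if (max_d > 0L && start1 >= 1L) {
    for (d in seq_len(max_d)) {
      # extra query bases (genome gap): genome span L - d
      if (!is.null(f0) && L - d >= 1L) {
        vi <- qraw[(d + 1L):L] != craw[start1:(start1 + L - d - 1L)]
        si <- cumsum(as.integer(vi))
        tot <- si[length(si)]
        # split i = query bases aligned before the insertion (1 .. L-d-1 to
        # keep the gap internal; i = 0 or L-d would put it at an end)
        i <- 1:(L - d - 1L)
        if (length(i) > 0L) {
          mm_i <- f0[i] + (tot - si[i])
          jbest <- which.min(mm_i)
          consider(mm_i[jbest], d, "ins", L - d, L - d)
        }
      }
      # extra genome bases (query gap): genome span L + d
      if (start1 + L + d - 1L <= G && L >= 2L && !is.null(f0)) {
        vd <- qraw != craw[(start1 + d):(start1 + L + d - 1L)]
        sd_ <- cumsum(as.integer(vd))
        tot <- sd_[length(sd_)]
        i <- 1:(L - 1L)
        mm_i <- f0[i] + (tot - sd_[i])
        jbest <- which.min(mm_i)
        consider(mm_i[jbest], d, "del", L + d, L)
      }
    }
  }
  best
}
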