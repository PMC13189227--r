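# Lariat-read identification and branchpoint calling.
#
# Lariat-spanning reads cross the 2'-5' branchpoint junction: in the read, the
# intron's 3' branch segment comes first and the intron's 5' splice site (5'SS)
# sequence follows -- the inverse of their genomic order. The pipeline:
#   1. drop reads with >5% ambiguous characters;
#   2. drop reads that align end-to-end to the genome;
#   3. find reads carrying exactly one intron's 5'SS key (first 20 nt of the
#      intron, exact match only);
#   4. trim the read to the prefix preceding the key (>= 20 nt required);
#   5. re-align the prefix to the genome under the constraint triple
#      (<=5 mismatches, <=10% rate, <=1 indel of <=3 nt);
#   6. keep same-gene candidates placed downstream of the intron's 5'SS (the
#      inverted order expected of lariat reads) and call the branchpoint at the
#      final aligned base of the best-scoring candidate (transcription
#      orientation).

#' Filter reads with excess ambiguous characters
#'
#' @param reads Tibble with `read_id` and `sequence` (optionally `quality`).
#' @param max_ambiguous_fraction Maximum tolerated fraction of non-ACGT(U)
#'   characters (default 0.05; a 100-nt read with exactly 5 Ns is retained).
#' @return The retained subset of `reads`.
#' @export
filter_ambiguous <- function(reads, max_ambiguous_fraction = 0.05) {
  frac <- purrr::map_dbl(reads$sequence, function(s) {
    ch <- seq_chars(toupper(s))
    sum(!(ch %in% VALID_BASES)) / length(ch)
  })
  reads[frac <= max_ambiguous_fraction, , drop = FALSE]
}

#' Remove reads that align end-to-end to the genome
#'
#' Reads with at least one genomic alignment within the constraint triple are
#' discarded; lariat-junction reads survive because the junction sequence is
#' absent from the genome. Alternatively ingest an external alignment with
#' [read_sam_subset()] and keep the unmapped records via
#' `prefilter_from_sam()`.
#'
#' @param reads Read tibble (`read_id`, `sequence`).
#' @param genome Named character vector of chromosomes.
#' @param ... Constraint/scoring overrides passed to [align_to_genome()].
#' @return The unaligned subset of `reads`.
#' @export
genome_prefilter <- function(reads, genome, ...) {
  if (nrow(reads) == 0L) return(reads)
  aln <- align_to_genome(setNames(reads$sequence, reads$read_id), genome, ...)
  reads[!(reads$read_id %in% aln$seq_id), , drop = FALSE]
}

#' Keep reads an external aligner left unmapped
#'
#' @param reads Read tibble.
#' @param sam SAM-subset tibble from [read_sam_subset()].
#' @return Reads whose records carry the unmapped flag (0x4) or are absent
#'   from the alignment.
#' @export
prefilter_from_sam <- function(reads, sam) {
  mapped <- unique(sam$qname[bitwAnd(sam$flag, 4L) == 0L])
  reads[!(reads$read_id %in% mapped), , drop = FALSE]
}

#' Build the 5' splice-site key index
#'
#' Extracts the first `k` nt of each intron in transcription orientation
#' (reverse-complemented genomic suffix for minus-strand genes). Introns
#' shorter than `k` are skipped with a warning.
#'
#' @param introns Tibble: `intron_id`, `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @param genome Named character vector of chromosomes.
#' @param k Key length (default 20).
#' @return `introns` with a `key` column appended (the index).
#' @export
build_fiveprime_index <- function(introns, genome, k = 20L) {
  short <- (introns$end - introns$start) < k
  if (any(short)) {
    warning(sum(short), " intron(s) shorter than ", k, " nt skipped from the 5'SS index.")
    introns <- introns[!short, , drop = FALSE]
  }
  key <- purrr::pmap_chr(
    introns[c("chrom", "start", "end", "strand")],
    function(chrom, start, end, strand) {
      if (strand == "+") {
        substr(genome[[chrom]], start + 1L, start + k)
      } else {
        revcomp(substr(genome[[chrom]], end - k + 1L, end))
      }
    }
  )
  dplyr::mutate(introns, key = toupper(key))
}

#' Locate the unique 5'SS key in each read
#'
#' Exact substring search of every index key in every read. A read qualifies
#' only if exactly one key of one intron occurs, exactly once (two offsets of
#' one key, or keys of two introns, disqualify it; no mismatches or indels are
#' tolerated in the key).
#'
#' @param reads Read tibble (`read_id`, `sequence`).
#' @param index Index tibble from [build_fiveprime_index()].
#' @return Tibble of qualifying reads: `read_id`, `intron_id`, `offset`
#'   (0-based position of the key within the read).
#' @export
locate_fiveprime <- function(reads, index) {
  out <- tibble(read_id = character(0), intron_id = character(0), offset = integer(0))
  if (nrow(reads) == 0L || nrow(index) == 0L) return(out)
  keys <- Biostrings::DNAStringSet(index$key)
  rs <- Biostrings::DNAStringSet(toupper(reads$sequence))
  counts <- Biostrings::vcountPDict(Biostrings::PDict(keys), rs)
  total <- colSums(counts)
  qualify <- which(total == 1L)
  if (length(qualify) == 0L) return(out)
  rows <- purrr::map(qualify, function(ri) {
    ki <- which(counts[, ri] == 1L)
    at <- Biostrings::matchPattern(keys[[ki]], rs[[ri]])
    tibble(
      read_id = reads$read_id[ri],
      intron_id = index$intron_id[ki],
      offset = as.integer(Biostrings::start(at)[1] - 1L)
    )
  })
  dplyr::bind_rows(rows)
}

#' Trim reads to their branch segment
#'
#' The branch segment is the read prefix preceding the 5'SS key. Reads whose
#' retained prefix is shorter than `min_prefix` are discarded (the <20 nt
#' filter is applied to the retained, re-mapped segment; set
#' `rule = "removed_suffix"` for the alternative reading where the removed
#' suffix must be >= `min_prefix`).
#'
#' @param reads Read tibble.
#' @param hits Tibble from [locate_fiveprime()].
#' @param min_prefix Minimum retained prefix length (default 20).
#' @param rule Which segment the length rule applies to.
#' @return Tibble `read_id`, `intron_id`, `offset`, `prefix`.
#' @export
trim_for_branchpoint <- function(reads, hits, min_prefix = 20L,
                                 rule = c("retained_prefix", "removed_suffix")) {
  rule <- match.arg(rule)
  merged <- dplyr::inner_join(hits, reads, by = "read_id")
  merged <- merged |>
    dplyr::mutate(
      prefix = substr(.data$sequence, 1L, .data$offset),
      removed = nchar(.data$sequence) - .data$offset
    )
  keep <- if (rule == "retained_prefix") {
    nchar(merged$prefix) >= min_prefix
  } else {
    merged$removed >= min_prefix & merged$offset > 0L
  }
  merged |>
    dplyr::filter(keep) |>
    dplyr::select("read_id", "intron_id", "offset", "prefix")
}

#' Align branch segments to the genome
#'
#' All genomic placements of each trimmed prefix satisfying the constraint
#' triple, scored with the default scheme.
#'
#' @param trimmed Tibble from [trim_for_branchpoint()].
#' @param genome Named character vector of chromosomes.
#' @param ... Overrides passed to [align_to_genome()].
#' @return Candidate tibble: `read_id`, `chrom`, `strand`, `start`, `end`,
#'   `mismatches`, `indel_len`, `indel_type`, `score`.
#' @export
align_branch_segment <- function(trimmed, genome, ...) {
  if (nrow(trimmed) == 0L) {
    return(tibble(
      read_id = character(0), chrom = character(0), strand = character(0),
      start = integer(0), end = integer(0), mismatches = integer(0),
      indel_len = integer(0), indel_type = character(0), score = numeric(0)
    ))
  }
  align_to_genome(setNames(trimmed$prefix, trimmed$read_id), genome, ...) |>
    dplyr::rename(read_id = "seq_id")
}

#' Select candidates and call branchpoints
#'
#' Restricts each read's candidates to placements in the same gene as its 5'SS
#' hit, on the gene's strand, with the expected inverted order (the branch
#' segment lies downstream of the intron's 5'SS in transcription orientation
#' and the called base falls inside the intron). The best-scoring candidate is
#' chosen (ties: smallest genomic start, then intron id) and the branchpoint is
#' the final aligned base in transcription orientation.
#'
#' @param candidates Tibble from [align_branch_segment()].
#' @param hits Tibble from [locate_fiveprime()].
#' @param index Intron index from [build_fiveprime_index()] (provides
#'   `gene_id` and intron intervals).
#' @param genes Tibble: `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @return Calls tibble: `read_id`, `intron_id`, `gene_id`, `chrom`, `strand`,
#'   `branchpoint` (0-based genomic coordinate), `mismatches`, `indel_len`,
#'   `score`.
#' @export
select_and_call <- function(candidates, hits, index, genes) {
  empty <- tibble(
    read_id = character(0), intron_id = character(0), gene_id = character(0),
    chrom = character(0), strand = character(0), branchpoint = integer(0),
    mismatches = integer(0), indel_len = integer(0), score = numeric(0)
  )
  if (nrow(candidates) == 0L) return(empty)
  ann <- hits |>
    dplyr::left_join(
      dplyr::select(index, "intron_id", "gene_id",
        intron_chrom = "chrom", intron_start = "start",
        intron_end = "end", intron_strand = "strand"
      ),
      by = "intron_id"
    ) |>
    dplyr::left_join(
      dplyr::select(genes, "gene_id",
        gene_start = "start", gene_end = "end"
      ),
      by = "gene_id"
    )
  joined <- dplyr::inner_join(candidates, ann, by = "read_id")
  admissible <- joined |>
    dplyr::filter(
      .data$chrom == .data$intron_chrom,
      .data$strand == .data$intron_strand,
      .data$start >= .data$gene_start,
      .data$end <= .data$gene_end
    ) |>
    dplyr::mutate(
      branchpoint = ifelse(.data$strand == "+", .data$end - 1L, .data$start),
      downstream = ifelse(.data$strand == "+",
        .data$start > .data$intron_start,
        .data$end < .data$intron_end
      ),
      in_intron = .data$branchpoint >= .data$intron_start &
        .data$branchpoint < .data$intron_end
    ) |>
    dplyr::filter(.data$downstream, .data$in_intron)
  if (nrow(admissible) == 0L) return(empty)
  admissible |>
    dplyr::group_by(.data$read_id) |>
    dplyr::arrange(
      dplyr::desc(.data$score), .data$start, .data$intron_id,
      .by_group = TRUE
    ) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::mutate(branchpoint = as.integer(.data$branchpoint)) |>
    dplyr::select(
      "read_id", "intron_id", "gene_id", "chrom", "strand",
      "branchpoint", "mismatches", "indel_len", "score"
    )
}

#' Run the full lariat-mapping pipeline
#'
#' Chains ambiguity filtering, genome prefiltering, 5'SS key location,
#' trimming, branch-segment alignment and branchpoint calling.
#'
#' @param reads Read tibble (`read_id`, `sequence`), e.g. from [read_fastq()].
#' @param genome Named character vector of chromosomes.
#' @param introns Intron annotation tibble (see [build_fiveprime_index()]).
#' @param genes Gene annotation tibble (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param k 5'SS key length (default 20).
#' @param min_prefix Minimum retained branch-segment length (default 20).
#' @param max_ambiguous_fraction Ambiguity filter threshold (default 0.05).
#' @param prefilter `TRUE` to drop genome-aligned reads with the built-in
#'   aligner; or a SAM-subset tibble whose unmapped records are kept; or
#'   `FALSE` to skip.
#' @param ... Constraint/scoring overrides for the branch-segment alignment.
#' @return A `lariat_mapping`: list with `calls` (per-read branchpoint calls),
#'   `branchpoints` (per unique branchpoint: supporting read count and ids),
#'   and `stages` (reads surviving each pipeline stage, for audit).
#' @export
map_lariat_reads <- function(reads, genome, introns, genes, k = 20L,
                             min_prefix = 20L, max_ambiguous_fraction = 0.05,
                             prefilter = TRUE, ...) {
  stages <- tibble(stage = "input", reads = nrow(reads))
  log_stage <- function(name, tbl) {
    stages <<- dplyr::bind_rows(stages, tibble(stage = name, reads = nrow(tbl)))
    tbl
  }
  reads <- log_stage("ambiguity_filter", filter_ambiguous(reads, max_ambiguous_fraction))
  if (isTRUE(prefilter)) {
    reads <- log_stage("genome_prefilter", genome_prefilter(reads, genome, ...))
  } else if (is.data.frame(prefilter)) {
    reads <- log_stage("genome_prefilter", prefilter_from_sam(reads, prefilter))
  }
  index <- build_fiveprime_index(introns, genome, k = k)
  hits <- locate_fiveprime(reads, index)
  reads <- log_stage("fiveprime_key", reads[reads$read_id %in% hits$read_id, , drop = FALSE])
  trimmed <- trim_for_branchpoint(reads, hits, min_prefix = min_prefix)
  reads <- log_stage("prefix_length", reads[reads$read_id %in% trimmed$read_id, , drop = FALSE])
  candidates <- align_branch_segment(trimmed, genome, ...)
  calls <- select_and_call(candidates, hits, index, genes)
  stages <- dplyr::bind_rows(stages, tibble(stage = "called", reads = nrow(calls)))
  branchpoints <- calls |>
    dplyr::group_by(.data$intron_id, .data$chrom, .data$strand, .data$branchpoint) |>
    dplyr::summarise(
      n_reads = dplyr::n(),
      read_ids = list(sort(.data$read_id)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$branchpoint)
  structure(
    list(calls = calls, branchpoints = branchpoints, stages = stages),
    class = "lariat_mapping"
  )
}

#' @export
print.lariat_mapping <- function(x, ...) {
  cat("<lariat_mapping> ", nrow(x$calls), " calls at ",
    nrow(x$branchpoints), " branchpoint(s)\n",
    sep = ""
  )
  print(x$stages)
  invisible(x)
}

#' Per-intron lariat quantification
#'
#' Raw per-intron lariat read counts (and unique branchpoints) normalized per
#' million total mapped reads in the library.
#'
#' @param calls Calls tibble from [map_lariat_reads()] (or the object itself).
#' @param total_mapped Total mapped reads in the library (> 0).
#' @return Tibble: `intron_id`, `count`, `n_branchpoints`, `per_million`.
#' @export
lariat_quant <- function(calls, total_mapped) {
  if (inherits(calls, "lariat_mapping")) calls <- calls$calls
  if (!is.numeric(total_mapped) || total_mapped <= 0) {
    abort_domain("`total_mapped` must be > 0.")
  }
  calls |>
    dplyr::group_by(.data$intron_id) |>
    dplyr::summarise(
      count = dplyr::n(),
      n_branchpoints = dplyr::n_distinct(.data$branchpoint),
      .groups = "drop"
    ) |>
    dplyr::mutate(per_million = .data$count / total_mapped * 1e6)
}

#' Per-intron fold changes between two libraries
#'
#' Fold change of normalized lariat levels, e.g. a debranching-deficient (KO)
#' library over wild type. With the default zero pseudocount, division by zero
#' is reported as `Inf` and flagged rather than imputed.
#'
#' @param quant_ref,quant_alt Quantification tibbles from [lariat_quant()]
#'   (reference, e.g. WT, and alternative, e.g. KO).
#' @param pseudocount Added to both normalized values (default 0).
#' @return Tibble: `intron_id`, `per_million_ref`, `per_million_alt`,
#'   `fold_change`, `flag` (`"ok"`, `"infinite"`, `"undefined"`).
#' @export
lariat_fold_change <- function(quant_ref, quant_alt, pseudocount = 0) {
  dplyr::full_join(
    dplyr::select(quant_ref, "intron_id", per_million_ref = "per_million"),
    dplyr::select(quant_alt, "intron_id", per_million_alt = "per_million"),
    by = "intron_id"
  ) |>
    dplyr::mutate(
      per_million_ref = dplyr::coalesce(.data$per_million_ref, 0),
      per_million_alt = dplyr::coalesce(.data$per_million_alt, 0),
      fold_change = (.data$per_million_alt + pseudocount) /
        (.data$per_million_ref + pseudocount),
      flag = dplyr::case_when(
        is.nan(.data$fold_change) ~ "undefined",
        is.infinite(.data$fold_change) ~ "infinite",
        TRUE ~ "ok"
      )
    )
}

#' Lariat-associated dsRNA sensor sites
#'
#' Folds each called intron's sequence (memoized per intron), extracts duplex
#' stretches, counts sensor sites, sums the per-call contributions, and
#' normalizes per million total mapped reads.
#'
#' @param calls Calls tibble or `lariat_mapping`.
#' @param genome Named character vector of chromosomes.
#' @param introns Intron annotation used for the mapping.
#' @param total_mapped Total mapped reads in the library.
#' @param folder Folder contract (default [fold_builtin()]).
#' @param panel Sensor panel (default [default_sensor_panel()]).
#' @return Tibble: `sensor`, `sites`, `per_million` (site-read pairs per
#'   million mapped reads).
#' @export
lariat_dsrna_sites <- function(calls, genome, introns, total_mapped,
                               folder = fold_builtin,
                               panel = default_sensor_panel()) {
  if (inherits(calls, "lariat_mapping")) calls <- calls$calls
  if (!is.numeric(total_mapped) || total_mapped <= 0) {
    abort_domain("`total_mapped` must be > 0.")
  }
  base <- tibble(sensor = names(panel), sites = 0L)
  if (nrow(calls) > 0L) {
    uniq <- unique(calls$intron_id)
    per_intron <- purrr::map(setNames(uniq, uniq), function(iid) {
      row <- introns[introns$intron_id == iid, ]
      seq <- region_sequence(
        genome, row$chrom[1], row$start[1], row$end[1], row$strand[1]
      )
      sensor_sites(extract_stretches(folder(seq)$structure), panel)$sites
    })
    tallies <- Reduce(`+`, per_intron[calls$intron_id])
    base$sites <- as.integer(tallies)
  }
  base |>
    dplyr::mutate(per_million = .data$sites / total_mapped * 1e6)
}

#' Extract a region's sequence in transcription orientation
#'
#' @param genome Named character vector of chromosomes.
#' @param chrom,start,end 0-based half-open genomic interval.
#' @param strand `"+"` or `"-"` (minus-strand regions are
#'   reverse-complemented).
#' @return A single string.
#' @export
region_sequence <- function(genome, chrom, start, end, strand = "+") {
  s <- substr(genome[[chrom]], start + 1L, end)
  if (strand == "-") revcomp(s) else s
}
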