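# Readers and writers for the plain-text formats the pipeline exchanges:
# FASTA, FASTQ, BED6, GTF-lite region annotations, SAM subsets, Vienna
# dot-bracket files, TSV reports, and the synthetic ledger. Coordinates are
# 0-based half-open inside the package; GTF-lite and BED follow their own
# conventions at the file boundary (GTF 1-based inclusive, BED 0-based
# half-open).

#' Read a FASTA file
#'
#' @param path FASTA file (wrapped or unwrapped, multi-record).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file.
#' @return Tibble: `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) abort_format("FASTQ record count is not a multiple of 4.")
  ids <- sub("^@", "", sub("\\s.*$", "", lines[seq(1L, length(lines), by = 4L)]))
  tibble(
    read_id = ids,
    sequence = toupper(lines[seq(2L, length(lines), by = 4L)]),
    quality = lines[seq(4L, length(lines), by = 4L)]
  )
}

#' Write reads as FASTQ
#'
#' @param reads Tibble with `read_id`, `sequence`, and optional `quality`
#'   (constant `I` if absent).
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("quality" %in% names(reads)) {
    reads$quality
  } else {
    strrep("I", nchar(reads$sequence))
  }
  writeLines(
    as.vector(rbind(
      paste0("@", reads$read_id), reads$sequence, "+", qual
    )),
    path
  )
  invisible(path)
}

#' Read a BED6 repeat annotation
#'
#' @param path BED6 file (strand column required; score ignored).
#' @return Tibble: `chrom`, `start`, `end`, `alu_id`, `element_strand`
#'   (0-based half-open, as in BED).
#' @export
read_bed6 <- function(path) {
  x <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicdc", comment = "#"
  )
  if (any(is.na(x$strand)) || !all(x$strand %in% c("+", "-"))) {
    abort_format("BED6 strand column must be '+' or '-'.")
  }
  tibble(
    chrom = x$chrom, start = x$start, end = x$end,
    alu_id = x$name, element_strand = x$strand
  )
}

#' Write Alu insertions as BED6
#'
#' @param alus Tibble with `chrom`, `start`, `end`, `alu_id`,
#'   `element_strand`.
#' @param path Output path.
#' @export
write_bed6 <- function(alus, path) {
  readr::write_tsv(
    tibble(
      chrom = alus$chrom, start = alus$start, end = alus$end,
      name = alus$alu_id, score = 0L, strand = alus$element_strand
    ),
    path,
    col_names = FALSE
  )
  invisible(path)
}

#' Read a GTF-lite region annotation
#'
#' Tab-separated: chrom, source, feature (gene / intron / exon /
#' five_prime_utr / three_prime_utr), start (1-based inclusive, per GTF), end,
#' score, strand, frame, attributes carrying `gene_id` and `region_id`.
#' Converted to 0-based half-open on read.
#'
#' @param path GTF-lite file.
#' @return Tibble: `chrom`, `region_type`, `start`, `end`, `strand`,
#'   `gene_id`, `region_id`.
#' @export
read_gtf_lite <- function(path) {
  x <- readr::read_tsv(path,
    col_names = c(
      "chrom", "source", "feature", "start", "end",
      "score", "strand", "frame", "attributes"
    ),
    col_types = "ccciicccc", comment = "#"
  )
  get_attr <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0(key, ' "([^"]*)"'), attrs))
    vapply(m, function(v) if (length(v) == 2L) v[2] else NA_character_, character(1))
  }
  tibble(
    chrom = x$chrom, region_type = x$feature,
    start = x$start - 1L, end = x$end, strand = x$strand,
    gene_id = get_attr(x$attributes, "gene_id"),
    region_id = get_attr(x$attributes, "region_id")
  )
}

#' Write regions as GTF-lite
#'
#' @param regions Tibble with `chrom`, `region_type`, `start`, `end` (0-based
#'   half-open), `strand`, `gene_id`, `region_id`.
#' @param path Output path.
#' @param source Source field.
#' @export
write_gtf_lite <- function(regions, path, source = "lariatdsrna") {
  lines <- sprintf(
    '%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; region_id "%s";',
    regions$chrom, source, regions$region_type,
    regions$start + 1L, regions$end, regions$strand,
    regions$gene_id, regions$region_id
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a SAM subset
#'
#' Minimal SAM ingestion for prefilter purposes: QNAME, FLAG, RNAME, POS,
#' CIGAR and SEQ columns; header lines are skipped.
#'
#' @param path SAM file.
#' @return Tibble: `qname`, `flag`, `rname`, `pos`, `cigar`, `seq`.
#' @export
read_sam_subset <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(tibble(
      qname = character(0), flag = integer(0), rname = character(0),
      pos = integer(0), cigar = character(0), seq = character(0)
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    qname = vapply(fields, `[`, character(1), 1L),
    flag = as.integer(vapply(fields, `[`, character(1), 2L)),
    rname = vapply(fields, `[`, character(1), 3L),
    pos = as.integer(vapply(fields, `[`, character(1), 4L)),
    cigar = vapply(fields, `[`, character(1), 6L),
    seq = vapply(fields, `[`, character(1), 10L)
  )
}

#' Read a Vienna dot-bracket file
#'
#' Records of the form `>id`, sequence line, structure line with an optional
#' trailing `(energy)`.
#'
#' @param path Vienna file.
#' @return Tibble: `id`, `sequence`, `dotbracket`, `mfe` (`NA` when absent).
#' @export
read_vienna <- function(path) {
  lines <- readLines(path)
  heads <- which(startsWith(lines, ">"))
  if (length(heads) == 0L) abort_format("no records in Vienna file.")
  rows <- purrr::map(heads, function(h) {
    if (h + 2L > length(lines)) abort_format("truncated Vienna record.")
    struct_line <- lines[h + 2L]
    m <- regmatches(struct_line, regexec("^([.()]+)(\\s+\\(\\s*(-?[0-9.]+)\\s*\\))?\\s*$", struct_line))[[1]]
    if (length(m) == 0L || m[2] == "") abort_format("could not parse structure line.")
    tibble(
      id = sub("^>", "", lines[h]),
      sequence = lines[h + 1L],
      dotbracket = m[2],
      mfe = if (m[4] == "") NA_real_ else as.numeric(m[4])
    )
  })
  dplyr::bind_rows(rows)
}

#' Write fold results as a Vienna file
#'
#' @param folds A list of `fold_result` objects (named by record id) or a
#'   tibble with `id`, `sequence`, `dotbracket`, `mfe`.
#' @param path Output path.
#' @export
write_vienna <- function(folds, path) {
  if (is.data.frame(folds)) {
    tbl <- folds
  } else {
    tbl <- tibble(
      id = names(folds) %||% as.character(seq_along(folds)),
      sequence = purrr::map_chr(folds, ~ .x$structure$sequence),
      dotbracket = purrr::map_chr(folds, ~ .x$structure$dotbracket),
      mfe = purrr::map_dbl(folds, "mfe")
    )
  }
  lines <- as.vector(rbind(
    paste0(">", tbl$id), tbl$sequence,
    sprintf("%s (%g)", tbl$dotbracket, tbl$mfe)
  ))
  writeLines(lines, path)
  invisible(path)
}

#' Write a TSV report with a provenance header
#'
#' Output files carry a single header comment with the package version, the
#' seed and a hash of the configuration, so reruns with identical
#' configuration are byte-identical.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param seed Seed used for the computation (optional).
#' @param config Named list of stage parameters hashed into the header.
#' @export
write_tsv_report <- function(x, path, seed = NULL, config = list()) {
  header <- sprintf(
    "# lariatdsrna %s seed=%s config=%s",
    as.character(utils::packageVersion("lariatdsrna")),
    if (is.null(seed)) "NA" else format(seed),
    rlang::hash(config)
  )
  writeLines(header, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write a synthetic ledger to a directory
#'
#' Plain-text serialization: `genome.fa`, `regions.gtf`, `alus.bed`,
#' `genes.tsv`, and `params.txt` (key=value lines, including the seed).
#' [read_ledger()] restores an identical object.
#'
#' @param ledger A `synthetic_ledger`.
#' @param dir Output directory (created if absent).
#' @export
write_ledger <- function(ledger, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(ledger$genome, file.path(dir, "genome.fa"))
  write_gtf_lite(ledger$regions, file.path(dir, "regions.gtf"))
  write_bed6(ledger$alus, file.path(dir, "alus.bed"))
  readr::write_tsv(ledger$genes, file.path(dir, "genes.tsv"))
  params <- ledger$params
  lines <- c(
    paste0("seed=", ledger$seed),
    vapply(names(params), function(k) {
      paste0(k, "=", paste(params[[k]], collapse = ","))
    }, character(1))
  )
  writeLines(lines, file.path(dir, "params.txt"))
  invisible(dir)
}

#' Read a synthetic ledger back from a directory
#'
#' @param dir Directory written by [write_ledger()].
#' @return A `synthetic_ledger`.
#' @export
read_ledger <- function(dir) {
  genome <- read_fasta(file.path(dir, "genome.fa"))
  regions <- read_gtf_lite(file.path(dir, "regions.gtf")) |>
    dplyr::select(
      "region_id", "region_type", "gene_id", "chrom",
      "start", "end", "strand"
    )
  bed <- read_bed6(file.path(dir, "alus.bed"))
  genes <- readr::read_tsv(file.path(dir, "genes.tsv"),
    col_types = readr::cols(
      gene_id = "c", chrom = "c", start = "i", end = "i",
      strand = "c", planted_category = "c"
    )
  )
  kv <- strsplit(readLines(file.path(dir, "params.txt")), "=", fixed = TRUE)
  params_raw <- setNames(
    lapply(kv, function(p) strsplit(p[2], ",", fixed = TRUE)[[1]]),
    vapply(kv, `[`, character(1), 1L)
  )
  num_keys <- c(
    "n_genes", "intron_length", "exon_length", "utr5_length",
    "utr3_length", "intergenic_length", "alu_spacer", "alu_mutation_rate"
  )
  params <- lapply(setNames(nm = names(params_raw)), function(k) {
    v <- params_raw[[k]]
    if (k %in% num_keys) {
      if (k == "alu_mutation_rate") as.numeric(v) else as.integer(v)
    } else {
      v
    }
  })
  seed <- params$seed
  params$seed <- NULL
  # region_id -> intron table; Alu region assignment comes from the BED names
  introns <- regions |>
    dplyr::filter(.data$region_type == "intron") |>
    dplyr::transmute(
      intron_id = .data$region_id, gene_id = .data$gene_id,
      chrom = .data$chrom, start = .data$start, end = .data$end,
      strand = .data$strand
    )
  alus <- bed |>
    dplyr::mutate(region_id = sub("_alu[0-9]+$", "_intron", .data$alu_id)) |>
    dplyr::select(
      "alu_id", "region_id", "chrom", "start", "end", "element_strand"
    )
  structure(
    list(
      genome = genome, genes = genes, introns = introns,
      regions = regions, alus = alus, params = params,
      seed = as.integer(seed)
    ),
    class = "synthetic_ledger"
  )
}
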