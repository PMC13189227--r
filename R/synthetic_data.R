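# Synthetic-data generator with a ground-truth ledger.
#
# Generates every input the pipeline consumes, with known truth: genomes
# carrying genes (5'UTR / exon / single intron / exon / 3'UTR) whose introns
# contain planted Alu insertions in chosen orientations, lariat-spanning reads
# with known branchpoints and configurable noise, and per-region count tables
# with planted IP enrichment. The background sequence is repaired post hoc so
# that no 20-mer occurs twice (in either orientation) outside planted Alu
# copies -- the precondition for exact branchpoint recovery.

#' The consensus Alu element sequence
#'
#' The 282-nt consensus Alu used for planted insertions (forward copies on the
#' `+` element strand; reverse-complemented copies on `-`).
#'
#' @return A single DNA string.
#' @export
alu_consensus <- function() {
  paste0(
    "GGCCGGGCGCGGTGGCTCACGCCTGTAATCCCAGCACTTTGGGAGGCCGAGGCGGGCGGA",
    "TCACCTGAGGTCAGGAGTTCGAGACCAGCCTGGCCAACATGGTGAAACCCCGTCTCTACT",
    "AAAAATACAAAAATTAGCCGGGCGTGGTGGCGGGCGCCTGTAATCCCAGCTACTCGGGAG",
    "GCTGAGGCAGGAGAATCGCTTGAACCCGGGAGGCGGAGGTTGCAGTGAGCCGAGATCGCG",
    "CCACTGCACTCCAGCCTGGGCGACAGAGCGAGACTCCGTCTC"
  )
}

#' Generate a synthetic genome with planted Alu insertions
#'
#' Builds `n_genes` genes (5'UTR, exon, intron, exon, 3'UTR; alternating
#' strands) separated by intergenic background on a single chromosome. Each
#' intron receives the Alu content its plan requests: `NONE`, `SINGLE`,
#' `MULTI_SAME` (two copies, same element strand) or `IR` (forward copy +
#' spacer + reverse-complemented copy, guaranteeing a perfect-complement pair
#' of the full consensus length before mutation). Background duplicate 20-mers
#' (either orientation) are resampled away.
#'
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param n_genes Number of genes.
#' @param alu_plan Character vector of per-intron categories, recycled to
#'   `n_genes` (default all `"NONE"`).
#' @param intron_length Intron length (single value or per-gene vector). Must
#'   accommodate the plan's insertions plus 40 nt of flanks.
#' @param exon_length,utr5_length,utr3_length Lengths of the flanking regions.
#' @param intergenic_length Background length between (and around) genes.
#' @param alu_spacer Background nt between planted Alu copies.
#' @param alu_mutation_rate Per-base substitution rate applied to planted Alu
#'   copies (default 0, i.e. pristine consensus copies).
#' @param chrom Chromosome name.
#' @return A `synthetic_ledger`: list with `genome` (named character),
#'   `genes`, `introns`, `regions`, `alus` tibbles (0-based half-open
#'   coordinates), `params`, `seed`.
#' @export
make_genome <- function(seed, n_genes = 8, alu_plan = "NONE",
                        intron_length = 1200L, exon_length = 150L,
                        utr5_length = 100L, utr3_length = 300L,
                        intergenic_length = 500L, alu_spacer = 50L,
                        alu_mutation_rate = 0, chrom = "chr1") {
  alu_plan <- rep(alu_plan, length.out = n_genes)
  bad <- !(alu_plan %in% ALU_CATEGORIES)
  if (any(bad)) abort_domain("alu_plan entries must be one of NONE/SINGLE/MULTI_SAME/IR.")
  intron_length <- rep(as.integer(intron_length), length.out = n_genes)
  alu <- alu_consensus()
  alu_len <- nchar(alu)
  needed <- c(
    NONE = 0L, SINGLE = alu_len,
    MULTI_SAME = 2L * alu_len + alu_spacer, IR = 2L * alu_len + alu_spacer
  )
  if (any(intron_length < needed[alu_plan] + 40L)) {
    abort_domain("intron too short for the requested Alu insertions plus 40 nt of flanks.")
  }

  with_seed(seed, {
    parts <- character(0)
    pos <- 0L # running 0-based genome offset
    genes <- list()
    regions <- list()
    alus <- list()
    push <- function(s) {
      parts[[length(parts) + 1L]] <<- s
      old <- pos
      pos <<- pos + nchar(s)
      old
    }

    for (g in seq_len(n_genes)) {
      push(random_seq(intergenic_length))
      gid <- sprintf("g%03d", g)
      strand <- if (g %% 2L == 1L) "+" else "-"
      # build the intron with planted insertions (genomic-forward sequence;
      # element strands are genome-coordinate strands, independent of the
      # gene's strand)
      plan <- alu_plan[g]
      ilen <- intron_length[g]
      ins <- switch(plan,
        NONE = tibble(seq = character(0), element_strand = character(0)),
        SINGLE = tibble(seq = alu, element_strand = "+"),
        MULTI_SAME = tibble(
          seq = c(alu, alu), element_strand = c("+", "+")
        ),
        IR = tibble(
          seq = c(alu, revcomp(alu)), element_strand = c("+", "-")
        )
      )
      if (alu_mutation_rate > 0 && nrow(ins) > 0) {
        ins$seq <- vapply(ins$seq, mutate_bases,
          character(1), rate = alu_mutation_rate
        )
      }
      n_ins <- nrow(ins)
      ins_total <- sum(nchar(ins$seq)) + max(0L, n_ins - 1L) * alu_spacer
      flank5 <- max(20L, as.integer(floor((ilen - ins_total) / 2)))
      flank3 <- ilen - ins_total - flank5
      intron_parts <- random_seq(flank5)
      ins_offsets <- integer(0)
      off <- flank5
      if (n_ins > 0) {
        for (a in seq_len(n_ins)) {
          ins_offsets <- c(ins_offsets, off)
          intron_parts <- paste0(intron_parts, ins$seq[a])
          off <- off + nchar(ins$seq[a])
          if (a < n_ins) {
            intron_parts <- paste0(intron_parts, random_seq(alu_spacer))
            off <- off + alu_spacer
          }
        }
      }
      intron_seq <- paste0(intron_parts, random_seq(flank3))

      # genomic-forward layout of the transcript regions
      reg_types <- c("five_prime_utr", "exon", "intron", "exon", "three_prime_utr")
      if (strand == "-") reg_types <- rev(reg_types)
      reg_seqs <- lapply(reg_types, function(rt) {
        switch(rt,
          five_prime_utr = random_seq(utr5_length),
          exon = random_seq(exon_length),
          intron = intron_seq,
          three_prime_utr = random_seq(utr3_length)
        )
      })
      gene_start <- pos
      exon_i <- 0L
      for (ri in seq_along(reg_types)) {
        rstart <- push(reg_seqs[[ri]])
        rt <- reg_types[ri]
        rid <- if (rt == "exon") {
          exon_i <- exon_i + 1L
          sprintf("%s_exon%d", gid, exon_i)
        } else {
          sprintf("%s_%s", gid, sub("_prime_utr", "utr", rt))
        }
        regions[[length(regions) + 1L]] <- tibble(
          region_id = rid, region_type = rt, gene_id = gid, chrom = chrom,
          start = rstart, end = rstart + nchar(reg_seqs[[ri]]), strand = strand
        )
        if (rt == "intron" && n_ins > 0) {
          for (a in seq_len(n_ins)) {
            alus[[length(alus) + 1L]] <- tibble(
              alu_id = sprintf("%s_alu%d", gid, a),
              region_id = rid, chrom = chrom,
              start = rstart + ins_offsets[a],
              end = rstart + ins_offsets[a] + nchar(ins$seq[a]),
              element_strand = ins$element_strand[a]
            )
          }
        }
      }
      genes[[length(genes) + 1L]] <- tibble(
        gene_id = gid, chrom = chrom, start = gene_start, end = pos,
        strand = strand, planted_category = plan
      )
    }
    push(random_seq(intergenic_length))

    genome_str <- paste(parts, collapse = "")
    alus_tbl <- if (length(alus)) dplyr::bind_rows(alus) else tibble(
      alu_id = character(0), region_id = character(0), chrom = character(0),
      start = integer(0), end = integer(0), element_strand = character(0)
    )
    genome_str <- repair_duplicate_kmers(genome_str, protect = alus_tbl)

    regions_tbl <- dplyr::bind_rows(regions)
    genes_tbl <- dplyr::bind_rows(genes)
    introns_tbl <- regions_tbl |>
      dplyr::filter(.data$region_type == "intron") |>
      dplyr::transmute(
        intron_id = .data$region_id, gene_id = .data$gene_id,
        chrom = .data$chrom, start = .data$start, end = .data$end,
        strand = .data$strand
      )
    structure(
      list(
        genome = setNames(genome_str, chrom),
        genes = genes_tbl, introns = introns_tbl,
        regions = regions_tbl, alus = alus_tbl,
        params = list(
          n_genes = n_genes, alu_plan = alu_plan,
          intron_length = intron_length, exon_length = exon_length,
          utr5_length = utr5_length, utr3_length = utr3_length,
          intergenic_length = intergenic_length, alu_spacer = alu_spacer,
          alu_mutation_rate = alu_mutation_rate
        ),
        seed = seed
      ),
      class = "synthetic_ledger"
    )
  })
}

#' @export
print.synthetic_ledger <- function(x, ...) {
  cat("<synthetic_ledger> ", nchar(x$genome[[1]]), " nt genome, ",
    nrow(x$genes), " genes, ", nrow(x$alus), " planted Alu(s), seed ",
    x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

mutate_bases <- function(seq, rate) {
  ch <- seq_chars(seq)
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

#' Validate 20-mer uniqueness of a genome
#'
#' @param genome_str A genome string (or named vector; first element used).
#' @param k Window width (default 20).
#' @param both_strands Also treat a window matching another window's reverse
#'   complement as a duplicate (default `TRUE`).
#' @return Integer vector of 1-based offending window starts (empty when the
#'   genome is k-mer unique).
#' @export
duplicate_kmer_positions <- function(genome_str, k = 20L, both_strands = TRUE) {
  genome_str <- genome_str[[1]]
  n <- nchar(genome_str)
  if (n < k) return(integer(0))
  starts <- seq_len(n - k + 1L)
  fwd <- substring(genome_str, starts, starts + k - 1L)
  off <- duplicated(fwd) | duplicated(fwd, fromLast = TRUE)
  if (both_strands) {
    rc <- revcomp(genome_str)
    rcw <- substring(rc, starts, starts + k - 1L)
    off <- off | (fwd %in% rcw)
  }
  starts[off]
}

# Resample background windows until no 20-mer repeats (either orientation).
# Windows overlapping planted Alu intervals are left untouched: repeat copies
# necessarily share k-mers, which is the biological point of the insertions.
repair_duplicate_kmers <- function(genome_str, protect, k = 20L, max_iter = 25L) {
  if (nrow(protect) > 0) {
    prot_start <- protect$start + 1L - (k - 1L) # window starts touching an Alu
    prot_end <- protect$end
  }
  for (iter in seq_len(max_iter)) {
    off <- duplicate_kmer_positions(genome_str, k)
    if (nrow(protect) > 0 && length(off) > 0) {
      touches <- purrr::map_lgl(off, function(p) {
        any(p >= prot_start & p <= prot_end)
      })
      off <- off[!touches]
    }
    if (length(off) == 0L) return(genome_str)
    for (p in off) {
      substr(genome_str, p, p + k - 1L) <- random_seq(k)
    }
  }
  warning("duplicate k-mers remained after ", max_iter, " repair iterations.")
  genome_str
}

#' Simulate lariat-spanning reads for one intron
#'
#' Each read is the intron's branch segment -- genomic bases ending at the
#' branchpoint, in transcription orientation, of length `read_length - k` --
#' followed by the intron's first `k` nt (the 5'SS key): the inverted segment
#' order characteristic of reads crossing the 2'-5' lariat junction. Noise
#' (substitutions and at most one indel) is applied to the branch segment
#' only.
#'
#' @param ledger A `synthetic_ledger` from [make_genome()].
#' @param intron_id Intron to simulate from.
#' @param n Number of reads.
#' @param branchpoint 0-based genomic branchpoint coordinate; default places
#'   it 30 nt upstream of the intron's 3' end (transcription orientation).
#' @param read_length Total read length (default 100). The branch segment is
#'   `read_length - k` nt; segments shorter than the mapper's minimum-prefix
#'   filter are generated faithfully but yield no calls downstream.
#' @param k 5'SS key length (default 20).
#' @param n_mismatches Exact number of substitutions planted in each branch
#'   segment (default 0).
#' @param indel `NULL`, or `list(type = "ins"|"del", length = d)`: insert `d`
#'   random bases into, or delete `d` bases from, the branch segment.
#' @param seed RNG seed.
#' @return List of two tibbles: `reads` (`read_id`, `sequence`, `quality`;
#'   constant high qualities) and `truth` (`read_id`, `intron_id`, `chrom`,
#'   `strand`, `branchpoint`).
#' @export
simulate_lariat_reads <- function(ledger, intron_id, n = 50,
                                  branchpoint = NULL, read_length = 100L,
                                  k = 20L, n_mismatches = 0L, indel = NULL,
                                  seed = NULL) {
  row <- ledger$introns[ledger$introns$intron_id == intron_id, ]
  if (nrow(row) != 1L) abort_domain("unknown intron_id.")
  plen <- as.integer(read_length) - as.integer(k)
  if (plen < 1L) abort_domain("read_length must exceed the key length k.")
  chrom <- row$chrom
  genome <- ledger$genome
  strand <- row$strand
  key <- if (strand == "+") {
    substr(genome[[chrom]], row$start + 1L, row$start + k)
  } else {
    revcomp(substr(genome[[chrom]], row$end - k + 1L, row$end))
  }
  # geometry: the whole branch segment must lie inside the intron, strictly
  # downstream of the 5'SS
  build_prefix <- function(bp) {
    if (strand == "+") {
      if (bp - plen + 1L <= row$start || bp >= row$end) {
        abort_domain("infeasible branchpoint/read-length geometry for this intron.")
      }
      substr(genome[[chrom]], bp - plen + 2L, bp + 1L)
    } else {
      if (bp < row$start || bp + plen >= row$end) {
        abort_domain("infeasible branchpoint/read-length geometry for this intron.")
      }
      revcomp(substr(genome[[chrom]], bp + 1L, bp + plen))
    }
  }
  if (is.null(branchpoint)) {
    # the generator guarantees that the clean junction read has no end-to-end
    # genomic alignment under the mapper's tolerance (a genuinely chimeric
    # read); it walks the candidate branchpoint upstream until that holds
    branchpoint <- if (strand == "+") row$end - 30L else row$start + 29L
    step <- if (strand == "+") -1L else 1L
    for (try in 1:50) {
      clean <- paste0(build_prefix(branchpoint), key)
      hits <- align_to_genome(c(probe = clean), genome)
      if (nrow(hits) == 0L) break
      branchpoint <- branchpoint + step
    }
  }
  prefix <- build_prefix(branchpoint)
  with_seed(seed, {
    reads <- purrr::map(seq_len(n), function(i) {
      p <- prefix
      if (n_mismatches > 0L) {
        posns <- sample(nchar(p), n_mismatches)
        ch <- seq_chars(p)
        for (j in posns) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1L)
        p <- paste(ch, collapse = "")
      }
      if (!is.null(indel)) {
        # plant the indel in the central half of the segment: an indel at the
        # very edge is indistinguishable from a shorter indel plus a trimmed
        # flank, which would blur the constraint boundary being simulated
        d <- indel$length
        lo <- max(2L, as.integer(floor(nchar(p) / 4)))
        hi <- min(nchar(p) - d - 1L, as.integer(ceiling(3 * nchar(p) / 4)))
        at <- sample(seq(lo, hi), 1L)
        p <- if (indel$type == "ins") {
          paste0(substr(p, 1L, at), random_seq(d), substr(p, at + 1L, nchar(p)))
        } else {
          paste0(substr(p, 1L, at), substr(p, at + d + 1L, nchar(p)))
        }
      }
      paste0(p, key)
    })
    ids <- sprintf("%s_read%04d", intron_id, seq_len(n))
    list(
      reads = tibble(
        read_id = ids,
        sequence = unlist(reads),
        quality = strrep("I", nchar(unlist(reads)))
      ),
      truth = tibble(
        read_id = ids, intron_id = intron_id, chrom = chrom,
        strand = strand, branchpoint = as.integer(branchpoint)
      )
    )
  })
}

#' Simulate total and IP count tables over a ledger's regions
#'
#' Per-region counts for a paired (cytoplasmic total, J2-IP) experiment. The
#' total library draws negative-binomial counts with mean
#' `expression x length/1e3`; the IP library resamples the same molecule pool,
#' `Poisson(enrichment x total)`, with `enrichment` applied at IR-category
#' regions and 1 elsewhere -- so the per-site IP/total ratio is conditionally
#' unbiased for the planted enrichment. `noise = "none"` gives the
#' deterministic limit.
#'
#' @param ledger A `synthetic_ledger`.
#' @param expression Mean expression per kilobase (single value or per-region).
#' @param ip_enrichment Planted IP enrichment at IR regions (default 2.2).
#' @param dispersion Negative-binomial size parameter (default 100).
#' @param noise `"nb"` (default) or `"none"`.
#' @param seed RNG seed.
#' @return Tibble: `region_id`, `region_type`, `category`, `length`,
#'   `count_total`, `count_ip`, `planted_enrichment`.
#' @export
simulate_counts <- function(ledger, expression = 100, ip_enrichment = 2.2,
                            dispersion = 100, noise = c("nb", "none"),
                            seed = NULL) {
  noise <- match.arg(noise)
  cat_tbl <- categorize_regions(
    ledger$regions,
    tibble(
      region_id = ledger$alus$region_id,
      element_strand = ledger$alus$element_strand
    ) |>
      dplyr::mutate(alu_id = ledger$alus$alu_id)
  )
  regions <- cat_tbl |>
    dplyr::mutate(
      length = .data$end - .data$start,
      expression = rep(expression, length.out = dplyr::n()),
      mu = .data$expression * .data$length / 1e3,
      enr = ifelse(.data$category == "IR", ip_enrichment, 1)
    )
  with_seed(seed, {
    if (noise == "nb") {
      total <- rnbinom(nrow(regions), mu = regions$mu, size = dispersion)
      ip <- rpois(nrow(regions), lambda = regions$enr * total)
    } else {
      total <- round(regions$mu)
      ip <- round(regions$enr * total)
    }
    regions |>
      dplyr::transmute(
        region_id = .data$region_id, region_type = .data$region_type,
        category = .data$category, length = .data$length,
        count_total = as.numeric(total), count_ip = as.numeric(ip),
        planted_enrichment = .data$enr
      )
  })
}

#' Simulate per-site IP/total coverage at IR Alu insertion sites
#'
#' Site-level counterpart of [simulate_counts()] for enrichment-recovery
#' studies: per-site total coverage is negative-binomial around
#' `mean_coverage`, and IP coverage resamples it with the planted enrichment,
#' `Poisson(enrichment x total)`.
#'
#' @param n_sites Number of IR Alu insertion sites.
#' @param enrichment Planted IP enrichment (default 2.2).
#' @param mean_coverage Mean total coverage per site (default 300).
#' @param dispersion Negative-binomial size (default 100).
#' @param seed RNG seed.
#' @return Tibble: `site_id`, `total`, `ip`.
#' @export
simulate_ip_coverage <- function(n_sites = 1000, enrichment = 2.2,
                                 mean_coverage = 300, dispersion = 100,
                                 seed = NULL) {
  with_seed(seed, {
    total <- rnbinom(n_sites, mu = mean_coverage, size = dispersion)
    ip <- rpois(n_sites, lambda = enrichment * total)
    tibble(
      site_id = sprintf("site%04d", seq_len(n_sites)),
      total = as.numeric(total), ip = as.numeric(ip)
    )
  })
}
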