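# Stage-by-stage checks of the lariat pipeline, then end-to-end recovery on
# ledgers with planted branchpoints.

test_that("ambiguity filter applies the 5% boundary inclusively", {
  reads <- tibble::tibble(
    read_id = c("five", "six", "allN"),
    sequence = c(
      paste0(strrep("N", 5), strrep("A", 95)),
      paste0(strrep("N", 6), strrep("A", 94)),
      strrep("N", 50)
    )
  )
  kept <- filter_ambiguous(reads)
  expect_equal(kept$read_id, "five") # 5% retained, 6% and all-N removed
})

test_that("genome prefilter discards genomic reads and keeps junction reads", {
  led <- test_ledger(seed = 55, plan = c("NONE", "NONE"))
  genomic <- substr(led$genome[[1]], 101, 200)
  sim <- simulate_lariat_reads(led, "g001_intron", n = 1, seed = 3)
  set.seed(4)
  novel <- random_dna(100)
  reads <- tibble::tibble(
    read_id = c("genomic", "junction", "novel"),
    sequence = c(genomic, sim$reads$sequence[1], novel)
  )
  kept <- genome_prefilter(reads, led$genome)
  expect_setequal(kept$read_id, c("junction", "novel"))
})

test_that("SAM-subset ingestion keeps only unmapped records", {
  reads <- tibble::tibble(read_id = c("a", "b", "c"), sequence = rep("ACGT", 3))
  sam <- tibble::tibble(
    qname = c("a", "b"), flag = c(0L, 4L), rname = c("chr1", "*"),
    pos = c(10L, 0L), cigar = c("4M", "*"), seq = c("ACGT", "ACGT")
  )
  kept <- prefilter_from_sam(reads, sam)
  expect_setequal(kept$read_id, c("b", "c"))
})

test_that("5'SS index keys follow transcription orientation", {
  genome <- c(chr1 = paste(rep(c("A", "C", "G", "T"), 100), collapse = ""))
  introns <- tibble::tibble(
    intron_id = c("p", "m", "short"),
    gene_id = c("g1", "g2", "g3"),
    chrom = "chr1",
    start = c(100L, 100L, 40L),
    end = c(200L, 200L, 55L),
    strand = c("+", "-", "+")
  )
  expect_warning(idx <- build_fiveprime_index(introns, genome), "skipped")
  expect_equal(nrow(idx), 2L)
  expect_equal(idx$key[idx$intron_id == "p"], substr(genome[[1]], 101, 120))
  expect_equal(idx$key[idx$intron_id == "m"], revcomp(substr(genome[[1]], 181, 200)))
})

test_that("5'SS location requires a unique, exact key occurrence", {
  led <- test_ledger(seed = 56, plan = c("NONE", "NONE"))
  idx <- build_fiveprime_index(led$introns, led$genome)
  key1 <- idx$key[1]
  key2 <- idx$key[2]
  set.seed(9)
  pad <- random_dna(30)
  mismatched_key <- paste0("T", substr(key1, 2, 20)) # one mismatch
  if (mismatched_key == key1) mismatched_key <- paste0("A", substr(key1, 2, 20))
  reads <- tibble::tibble(
    read_id = c("unique", "two_keys", "twice", "mismatch"),
    sequence = c(
      paste0(pad, key1, random_dna(30)),
      paste0(pad, key1, key2),
      paste0(pad, key1, key1),
      paste0(pad, mismatched_key, random_dna(30))
    )
  )
  hits <- locate_fiveprime(reads, idx)
  expect_equal(hits$read_id, "unique")
  expect_equal(hits$offset, 30L)
  expect_equal(hits$intron_id, idx$intron_id[1])
})

test_that("trimming keeps the prefix before the key and applies the 20-nt rule", {
  reads <- tibble::tibble(
    read_id = c("long", "short", "atstart"),
    sequence = c(strrep("A", 100), strrep("A", 40), strrep("A", 30))
  )
  hits <- tibble::tibble(
    read_id = c("long", "short", "atstart"),
    intron_id = "i1",
    offset = c(50L, 12L, 0L)
  )
  trimmed <- trim_for_branchpoint(reads, hits)
  expect_equal(trimmed$read_id, "long")
  expect_equal(nchar(trimmed$prefix), 50L)
  # alternative reading: the removed suffix must be >= 20 nt
  alt <- trim_for_branchpoint(reads, hits, rule = "removed_suffix")
  expect_setequal(alt$read_id, c("long", "short"))
})

test_that("branchpoint calls restrict to the same gene with inverted order", {
  led <- test_ledger(seed = 57, plan = c("NONE", "NONE", "NONE"))
  idx <- build_fiveprime_index(led$introns, led$genome)
  sim <- simulate_lariat_reads(led, "g002_intron", n = 5, seed = 21)
  reads <- sim$reads
  hits <- locate_fiveprime(reads, idx)
  trimmed <- trim_for_branchpoint(reads, hits)
  cands <- align_branch_segment(trimmed, led$genome)
  calls <- select_and_call(cands, hits, idx, led$genes)
  expect_equal(nrow(calls), 5L)
  expect_true(all(calls$gene_id == "g002"))
  expect_true(all(calls$branchpoint == sim$truth$branchpoint))
  # a candidate in the wrong gene is rejected even if it scores well:
  # restrict genes table to exclude g002's span
  genes_wrong <- led$genes[led$genes$gene_id != "g002", ]
  idx_wrong <- dplyr::mutate(idx, gene_id = "g001")
  calls_wrong <- select_and_call(cands, hits, idx_wrong, genes_wrong)
  expect_equal(nrow(calls_wrong), 0L)
})

test_that("noise-free reads are recovered at planted coordinates on both strands", {
  led <- test_ledger(seed = 58, plan = c("NONE", "IR", "NONE", "SINGLE"))
  sims <- lapply(c("g001_intron", "g002_intron"), function(i) {
    simulate_lariat_reads(led, i, n = 25, seed = 13)
  })
  reads <- dplyr::bind_rows(lapply(sims, `[[`, "reads"))
  truth <- dplyr::bind_rows(lapply(sims, `[[`, "truth"))
  lm <- map_lariat_reads(reads, led$genome, led$introns, led$genes)
  expect_equal(nrow(lm$calls), nrow(truth))
  m <- dplyr::inner_join(lm$calls, truth, by = "read_id", suffix = c("", ".t"))
  expect_true(all(m$branchpoint == m$branchpoint.t))
  expect_true(all(m$intron_id == m$intron_id.t))
  # strand coverage: one '+' and one '-' gene
  expect_setequal(unique(m$strand), c("+", "-"))
})

test_that("read sets shrink monotonically across pipeline stages", {
  led <- test_ledger(seed = 59, plan = c("NONE", "NONE"))
  sim <- simulate_lariat_reads(led, "g001_intron", n = 10, seed = 2)
  junk <- tibble::tibble(
    read_id = c("junk1", "junk2"),
    sequence = c(strrep("N", 100), substr(led$genome[[1]], 11, 110))
  )
  lm <- map_lariat_reads(
    dplyr::bind_rows(sim$reads, junk),
    led$genome, led$introns, led$genes
  )
  expect_true(all(diff(lm$stages$reads) <= 0))
  expect_equal(nrow(lm$calls), 10L)
})

test_that("identical inputs give identical outputs", {
  led <- test_ledger(seed = 60, plan = c("NONE", "NONE"))
  sim <- simulate_lariat_reads(led, "g001_intron", n = 8, seed = 5)
  lm1 <- map_lariat_reads(sim$reads, led$genome, led$introns, led$genes)
  lm2 <- map_lariat_reads(sim$reads, led$genome, led$introns, led$genes)
  expect_identical(lm1$calls, lm2$calls)
  expect_identical(lm1$branchpoints, lm2$branchpoints)
})

test_that("quantification normalizes per million and reports fold changes", {
  calls <- tibble::tibble(
    read_id = paste0("r", 1:10), intron_id = "i1", gene_id = "g1",
    chrom = "chr1", strand = "+", branchpoint = 500L,
    mismatches = 0L, indel_len = 0L, score = 80
  )
  q <- lariat_quant(calls, total_mapped = 1e6)
  expect_equal(q$per_million, 10)
  expect_equal(q$n_branchpoints, 1L)
  expect_error(lariat_quant(calls, 0), class = "lariatdsrna_domain_error")

  wt <- tibble::tibble(intron_id = c("i1", "i2"), per_million = c(2, 0))
  ko <- tibble::tibble(intron_id = c("i1", "i2"), per_million = c(86, 0))
  fc <- lariat_fold_change(wt, ko)
  expect_equal(fc$fold_change[fc$intron_id == "i1"], 43)
  expect_equal(fc$flag[fc$intron_id == "i2"], "undefined")
  only_ko <- lariat_fold_change(
    tibble::tibble(intron_id = "i3", per_million = 0),
    tibble::tibble(intron_id = "i3", per_million = 5)
  )
  expect_equal(only_ko$flag, "infinite")
})

test_that("lariat dsRNA site tallies fold called introns and normalize per million", {
  # one called lariat in an intron folding to a single 34-bp stem
  stem <- paste0(strrep("C", 34), "AAAA", strrep("G", 34))
  genome <- c(chr1 = paste0(strrep("A", 50), stem, strrep("A", 50)))
  introns <- tibble::tibble(
    intron_id = "i1", gene_id = "g1", chrom = "chr1",
    start = 50L, end = 50L + nchar(stem), strand = "+"
  )
  calls <- tibble::tibble(
    read_id = "r1", intron_id = "i1", gene_id = "g1", chrom = "chr1",
    strand = "+", branchpoint = 90L, mismatches = 0L, indel_len = 0L, score = 60
  )
  tal <- lariat_dsrna_sites(calls, genome, introns, total_mapped = 1e6)
  expect_equal(tal$per_million[tal$sensor == "PKR"], 1)
  half <- lariat_dsrna_sites(calls, genome, introns, total_mapped = 2e6)
  expect_equal(half$per_million, tal$per_million / 2) # doubling halves
  # two supporting reads double the tally
  calls2 <- dplyr::bind_rows(calls, dplyr::mutate(calls, read_id = "r2"))
  tal2 <- lariat_dsrna_sites(calls2, genome, introns, total_mapped = 1e6)
  expect_equal(tal2$sites, tal$sites * 2L)
})

test_that("synthetic IR Alu introns give nonzero PKR tallies with the built-in folder", {
  led <- test_ledger(seed = 61, plan = c("IR", "NONE"))
  sim <- simulate_lariat_reads(led, "g001_intron", n = 3, seed = 8)
  lm <- map_lariat_reads(sim$reads, led$genome, led$introns, led$genes)
  expect_gt(nrow(lm$calls), 0)
  tal <- lariat_dsrna_sites(lm, led$genome, led$introns, total_mapped = 1e6)
  expect_gt(tal$sites[tal$sensor == "PKR"], 0)
})
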