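test_that("genomes are deterministic under seed and honor the Alu plan", {
  led1 <- make_genome(seed = 5, n_genes = 3, alu_plan = c("IR", "NONE", "SINGLE"),
                      intron_length = 800, intergenic_length = 300)
  led2 <- make_genome(seed = 5, n_genes = 3, alu_plan = c("IR", "NONE", "SINGLE"),
                      intron_length = 800, intergenic_length = 300)
  expect_identical(led1$genome, led2$genome)
  expect_identical(led1$regions, led2$regions)
  expect_equal(nrow(led1$alus), 3L) # 2 for IR + 1 for SINGLE
  # plan all NONE leaves no insertion intervals
  led0 <- make_genome(seed = 6, n_genes = 2, alu_plan = "NONE",
                      intron_length = 400, intergenic_length = 200)
  expect_equal(nrow(led0$alus), 0L)
})

test_that("IR introns contain a perfect-complement consensus pair", {
  led <- make_genome(seed = 7, n_genes = 1, alu_plan = "IR",
                     intron_length = 700, intergenic_length = 200)
  a <- led$alus
  fwd <- a[a$element_strand == "+", ]
  rev <- a[a$element_strand == "-", ]
  seq_fwd <- substr(led$genome[[1]], fwd$start + 1, fwd$end)
  seq_rev <- substr(led$genome[[1]], rev$start + 1, rev$end)
  expect_equal(seq_fwd, alu_consensus())
  expect_equal(seq_rev, revcomp(alu_consensus()))
})

test_that("no 20-mer repeats in an Alu-free genome, in either orientation", {
  led <- make_genome(seed = 8, n_genes = 3, alu_plan = "NONE",
                     intron_length = 600, intergenic_length = 2000)
  expect_length(duplicate_kmer_positions(led$genome), 0L)
})

test_that("infeasible Alu plans are rejected", {
  expect_error(
    make_genome(seed = 1, n_genes = 1, alu_plan = "IR", intron_length = 500),
    class = "lariatdsrna_domain_error"
  )
  expect_error(
    make_genome(seed = 1, n_genes = 1, alu_plan = "WRONG"),
    class = "lariatdsrna_domain_error"
  )
})

test_that("simulated lariat reads follow the junction construction", {
  led <- test_ledger(seed = 91, plan = c("NONE", "NONE"))
  sim <- simulate_lariat_reads(led, "g001_intron", n = 5, seed = 3, read_length = 80)
  expect_equal(nchar(sim$reads$sequence), rep(80L, 5))
  intron <- led$introns[led$introns$intron_id == "g001_intron", ]
  key <- substr(led$genome[[1]], intron$start + 1, intron$start + 20)
  expect_true(all(substr(sim$reads$sequence, 61, 80) == key))
  bp <- sim$truth$branchpoint[1]
  expect_equal(
    substr(sim$reads$sequence[1], 1, 60),
    substr(led$genome[[1]], bp - 60 + 2, bp + 1)
  )
  # noise-free reads are identical; the truth table pins the coordinate
  expect_equal(length(unique(sim$reads$sequence)), 1L)
  expect_true(all(sim$truth$branchpoint >= intron$start & sim$truth$branchpoint < intron$end))
})

test_that("minus-strand reads are reverse-complemented into transcription orientation", {
  led <- test_ledger(seed = 92, plan = c("NONE", "NONE"))
  sim <- simulate_lariat_reads(led, "g002_intron", n = 2, seed = 4)
  intron <- led$introns[led$introns$intron_id == "g002_intron", ]
  expect_equal(intron$strand, "-")
  key <- revcomp(substr(led$genome[[1]], intron$end - 19, intron$end))
  expect_true(all(substr(sim$reads$sequence, 81, 100) == key))
})

test_that("infeasible branchpoint geometry errors out", {
  led <- test_ledger(seed = 93, plan = c("NONE", "NONE"))
  intron <- led$introns[1, ]
  expect_error(
    simulate_lariat_reads(led, "g001_intron",
      branchpoint = intron$start + 10, n = 1
    ),
    class = "lariatdsrna_domain_error"
  )
  expect_error(
    simulate_lariat_reads(led, "nope", n = 1),
    class = "lariatdsrna_domain_error"
  )
})

test_that("count simulation plants enrichment only at IR regions", {
  led <- test_ledger(seed = 94, plan = c("IR", "NONE"))
  counts <- simulate_counts(led, noise = "none", ip_enrichment = 3)
  ir <- counts[counts$category == "IR", ]
  non_ir <- counts[counts$category != "IR", ]
  expect_true(all(ir$count_ip == round(3 * ir$count_total)))
  expect_true(all(non_ir$count_ip == non_ir$count_total))
  expect_equal(unique(ir$planted_enrichment), 3)
  # stochastic counts are reproducible under seed
  c1 <- simulate_counts(led, seed = 10)
  c2 <- simulate_counts(led, seed = 10)
  expect_identical(c1, c2)
})

test_that("ledgers round-trip through their plain-text serialization", {
  led <- test_ledger(seed = 95, plan = c("IR", "SINGLE"))
  dir <- withr::local_tempdir()
  write_ledger(led, dir)
  back <- read_ledger(dir)
  expect_identical(back$genome, led$genome)
  expect_equal(as.data.frame(back$regions), as.data.frame(led$regions))
  expect_equal(as.data.frame(back$introns), as.data.frame(led$introns))
  expect_equal(as.data.frame(back$alus), as.data.frame(led$alus))
  expect_equal(as.data.frame(back$genes), as.data.frame(led$genes))
  expect_equal(back$seed, led$seed)
  expect_equal(back$params$intron_length, led$params$intron_length)
})
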