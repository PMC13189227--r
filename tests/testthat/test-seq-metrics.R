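test_that("gc_content counts G+C over unambiguous bases only", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("ACGTN"), 0.5) # N excluded from both sides
  expect_equal(gc_content(c("GGCC", "acgu")), c(1.0, 0.5))
  expect_error(gc_content(""), class = "lariatdsrna_domain_error")
  expect_error(gc_content("NNN"), class = "lariatdsrna_domain_error")
})

test_that("nt_composition fractions sum to one and T is read as U", {
  comp <- nt_composition(c(x = "AAAATTCC", y = "ACGTNNR"))
  expect_equal(comp$frac_a + comp$frac_c + comp$frac_g + comp$frac_u, c(1, 1))
  expect_equal(comp$frac_u[1], 0.25) # the Ts
  expect_equal(comp$length, c(8L, 4L))
  expect_equal(comp$n_ambiguous, c(0L, 3L))
})

test_that("mbp reproduces the worked example and edge compositions", {
  expect_equal(mbp("AAAATTCC"), 0.5)
  expect_equal(mbp("ACGU"), 1.0)
  expect_equal(mbp("AAAA"), 0.0)
  expect_equal(mbp("AAGG"), 0.0)
  expect_error(mbp(nt_composition("NNNN")), class = "lariatdsrna_domain_error")
})

test_that("matching oracle handles wobble pairs and no-partner cases", {
  expect_equal(mbp_matching_oracle("AAAATTCC"), 0.5) # 2 A-U pairs of 8 bases
  expect_equal(mbp_matching_oracle("UUGG"), 1.0) # two G-U wobble pairs
  expect_equal(mbp_matching_oracle("CCCC"), 0.0)
})

test_that("mbp formula equals the matching oracle on random compositions and is in range", {
  set.seed(404)
  for (i in 1:200) {
    total <- sample(1:60, 1)
    counts <- as.vector(stats::rmultinom(1, total, prob = runif(4)))
    comp <- tibble::tibble(
      frac_a = counts[1] / total, frac_c = counts[2] / total,
      frac_g = counts[3] / total, frac_u = counts[4] / total, length = total
    )
    f <- mbp(comp)
    expect_equal(f, mbp_matching_oracle(comp), tolerance = 1e-12)
    expect_gte(f, 0)
    expect_lte(f, 1)
  }
})

test_that("mbp saturates on self-complement concatenations", {
  set.seed(11)
  for (i in 1:20) {
    s <- random_dna(sample(5:40, 1))
    expect_equal(mbp(paste0(s, revcomp(s))), 1.0)
  }
})

test_that("mbp is asymmetric under reverse complement because wobble is directional", {
  expect_equal(mbp("AAAATTCC"), 0.5)
  expect_equal(mbp(revcomp("AAAATTCC")), 1.0) # GGAATTTT: G-U wobble saturates
  expect_equal(mbp_matching_oracle("GGAATTTT"), 1.0)
})

test_that("shuffles preserve the base multiset and composition metrics", {
  ss <- shuffle_sequence("ACGGUUAC", n = 10, seed = 7)
  expect_length(ss$shuffles, 10)
  base_sorted <- paste(sort(strsplit(ss$original, "")[[1]]), collapse = "")
  for (s in ss$shuffles) {
    expect_equal(paste(sort(strsplit(s, "")[[1]]), collapse = ""), base_sorted)
    expect_equal(gc_content(s), gc_content(ss$original))
    expect_equal(mbp(s), mbp(ss$original))
  }
  expect_equal(shuffle_sequence("AAAA", n = 3, seed = 1)$shuffles, rep("AAAA", 3))
  # reproducible under seed, distinct without
  expect_identical(
    shuffle_sequence("ACGGUUAC", n = 5, seed = 42)$shuffles,
    shuffle_sequence("ACGGUUAC", n = 5, seed = 42)$shuffles
  )
  expect_error(shuffle_sequence("ACGU", n = 0), class = "lariatdsrna_domain_error")
})

test_that("k-mer full-pairing probability follows MBP^k and is monotone", {
  expect_equal(kmer_fully_paired_prob("ACGU", k = 33), 1.0)
  expect_equal(kmer_fully_paired_prob("AAAA", k = 17), 0.0)
  expect_equal(kmer_fully_paired_prob("AAAATTCC", k = 2), 0.25)
  p <- kmer_fully_paired_prob("ACGGAUCCGUA", k = c(17, 22, 33))
  expect_true(all(diff(p) <= 0)) # nonincreasing in k
  # nondecreasing in mbp at fixed k
  comps <- c("AAAAAACC", "AAAATTCC", "ACGUACGU")
  expect_true(all(diff(kmer_fully_paired_prob(comps, k = 17)) >= 0))
  expect_error(kmer_fully_paired_prob("ACGU", k = 0), class = "lariatdsrna_domain_error")
})

test_that("Monte-Carlo k-mer probability agrees with the analytic value for pair draws", {
  # for k = 2 the analytic and draw-based definitions coincide in expectation
  mc <- kmer_fully_paired_prob("AAAATTCC",
    k = 2, method = "montecarlo",
    n_draws = 20000, seed = 5
  )
  expect_equal(mc, 0.25, tolerance = 0.02)
})

test_that("seq_metrics tabulates id, length, gc and mbp per record", {
  tbl <- seq_metrics(c(a = "AAAATTCC", b = "GGCC"))
  expect_equal(tbl$id, c("a", "b"))
  expect_equal(tbl$mbp, c(0.5, 1))
  expect_equal(tbl$gc, c(0.25, 1))
  expect_equal(tbl$length, c(8L, 4L))
})
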