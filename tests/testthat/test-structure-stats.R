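test_that("dot-bracket parsing recovers pairs and rejects malformed input", {
  st <- parse_dotbracket("((..))", "GGAACC")
  expect_equal(st$pairs$i, c(0L, 1L))
  expect_equal(st$pairs$j, c(5L, 4L))
  expect_equal(nrow(parse_dotbracket("......", "ACGUAC")$pairs), 0L)
  expect_error(parse_dotbracket("((.)", "ACGU"), class = "lariatdsrna_format_error")
  expect_error(parse_dotbracket(".).(", "ACGU"), class = "lariatdsrna_format_error")
  expect_error(parse_dotbracket("(..)", "ACGUA"), class = "lariatdsrna_format_error")
  expect_error(parse_dotbracket("(<.>)", "ACGUA"), class = "lariatdsrna_format_error")
})

test_that("stretch extraction splits at any departure from perfect stacking", {
  one <- extract_stretches(parse_dotbracket("((((....))))", "GGGGAAAACCCC"))
  expect_equal(one$length_bp, 4L)
  expect_equal(one$five_prime_start, 0L)
  expect_equal(one$three_prime_end, 11L)

  two <- extract_stretches(parse_dotbracket("((..((....))))", "GGAAGGAAAACCCC"))
  expect_equal(two$length_bp, c(2L, 2L)) # internal loop breaks the run
  expect_equal(two$five_prime_start, c(0L, 4L))

  none <- extract_stretches(parse_dotbracket("....", "ACGU"))
  expect_equal(nrow(none), 0L)

  # single-nt bulge also terminates a stretch
  bulged <- extract_stretches(parse_dotbracket("((.((...))))", "GGAGGAAACCCC"))
  expect_equal(bulged$length_bp, c(2L, 2L))
})

test_that("stretch extraction conserves paired-base totals on folded random sequences", {
  set.seed(99)
  for (i in 1:60) {
    fr <- fold_builtin(random_dna(sample(15:60, 1)))
    st <- extract_stretches(fr$structure)
    expect_equal(
      sum(st$length_bp) * 2L,
      count_paired_chars(fr$structure$dotbracket)
    )
  }
})

test_that("sensor-site counts follow the floor rule per stretch", {
  expect_equal(
    sensor_sites(33)$sites,
    c(1L, 1L, 1L) # floor(33/17), floor(33/22), floor(33/33)
  )
  expect_equal(sensor_sites(c(17, 16))$sites[1], 1L) # OAS1: 1 + 0
  expect_equal(sensor_sites(70)$sites, c(4L, 3L, 2L))
  expect_equal(sensor_sites(numeric(0))$sites, c(0L, 0L, 0L))
  expect_error(
    sensor_sites(10, panel = c(bad = 0)),
    class = "lariatdsrna_domain_error"
  )
})

test_that("sensor-site counts are monotone and superadditive under stretch merging", {
  set.seed(21)
  for (i in 1:50) {
    a <- sample(1:80, 1)
    b <- sample(1:80, 1)
    merged <- sensor_sites(a + b)$sites
    split <- sensor_sites(c(a, b))$sites
    expect_true(all(merged >= split)) # floor superadditivity
    expect_true(all(sensor_sites(a + 1)$sites >= sensor_sites(a)$sites))
  }
})

test_that("normalized MFE divides by length with a domain guard", {
  expect_equal(normalized_mfe(-50, 100), -0.5)
  expect_equal(normalized_mfe(0, 10), 0)
  expect_equal(normalized_mfe(-3, 3), -1)
  expect_error(normalized_mfe(-5, 0), class = "lariatdsrna_domain_error")
})

test_that("built-in folder matches exhaustive structure enumeration on short sequences", {
  set.seed(31)
  for (i in 1:25) {
    s <- random_dna(sample(6:12, 1))
    fr <- fold_builtin(s)
    expect_equal(-fr$mfe, enum_max_pairs(s), info = s)
    # the reported dot-bracket is consistent with the pair count
    expect_equal(count_paired_chars(fr$structure$dotbracket), -2 * fr$mfe)
  }
})

test_that("fold results normalize energy by length and flag positive-energy structures", {
  fr <- fold_builtin("GGGGAAAACCCC")
  expect_equal(fr$normalized_mfe, fr$mfe / 12)
  expect_warning(fold_result("GGAACC", "((..))", mfe = 1), "positive energy")
})

test_that("ensemble deviation is zero for homopolymers and negative for planted inverted repeats", {
  ed0 <- ensemble_deviation("AAAAAAAAAAAA", n = 5, seed = 1)
  expect_equal(ed0$deviation, 0)
  expect_equal(ed0$observed_mfe, mean(ed0$shuffled_mfes))

  set.seed(8)
  s <- random_dna(25)
  ir <- paste0(s, strrep("A", 8), revcomp(s))
  ed <- ensemble_deviation(ir, n = 10, seed = 2)
  expect_lt(ed$deviation, 0)
  expect_equal(ed$deviation, ed$observed_mfe - mean(ed$shuffled_mfes))
})

test_that("folder failures propagate with the offending sequence identified", {
  bad_folder <- function(seq) stop("predictor exploded")
  expect_error(
    ensemble_deviation("ACGUACGU", folder = bad_folder, n = 2, id = "reg7"),
    "reg7"
  )
})

test_that("region sensor-site tables skip over-long regions and count hairpins", {
  seqs <- c(
    hairpin = paste0(strrep("C", 34), "AAAA", strrep("G", 34)),
    unstructured = strrep("A", 40),
    toolong = strrep("A", 120)
  )
  expect_message(
    tbl <- count_sensor_sites_for_regions(seqs, max_length = 100),
    "skipped"
  )
  skipped <- attr(tbl, "skipped")
  expect_equal(skipped$region_id, "toolong")
  expect_equal(skipped$length, 120L)
  expect_false("toolong" %in% tbl$region_id)
  hp <- tbl[tbl$region_id == "hairpin", ]
  expect_equal(hp$sites[hp$sensor == "PKR"], 1L) # 34-bp stem
  expect_equal(hp$sites[hp$sensor == "OAS1"], 2L)
  un <- tbl[tbl$region_id == "unstructured", ]
  expect_equal(sum(un$sites), 0L)
})

test_that("ensemble deviation objects tidy, glance and plot", {
  ed <- ensemble_deviation("GGGGGAAAACCCCC", n = 4, seed = 3)
  td <- tidy(ed)
  expect_equal(nrow(td), 5)
  expect_equal(sum(td$role == "shuffled"), 4)
  gl <- glance(ed)
  expect_equal(gl$deviation, ed$deviation)
  expect_s3_class(autoplot(ed), "ggplot")
})

test_that("Vienna files round-trip fold results", {
  folds <- list(
    r1 = fold_builtin("GGGGAAAACCCC"),
    r2 = fold_builtin("ACGUACGUAAA")
  )
  path <- withr::local_tempfile(fileext = ".vienna")
  write_vienna(folds, path)
  back <- read_vienna(path)
  expect_equal(back$id, c("r1", "r2"))
  expect_equal(back$dotbracket[1], folds$r1$structure$dotbracket)
  expect_equal(back$mfe, c(folds$r1$mfe, folds$r2$mfe))
})
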