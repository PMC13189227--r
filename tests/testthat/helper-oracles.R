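# Independent oracles used across the suite.

# Exhaustive enumeration of all legal non-crossing pair sets over a short RNA
# (min hairpin loop 3, A-U/C-G/G-U pairs); returns the maximum pair count.
# Definitional and memo-free, so it is independent of the package's dynamic
# program.
enum_max_pairs <- function(seq, min_loop = 3) {
  ch <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  ok <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
  }
  rec <- function(idx) {
    if (length(idx) < 2L) return(0L)
    i <- idx[1]
    best <- rec(idx[-1]) # i unpaired
    for (j in idx[-1]) {
      if (j - i > min_loop && ok(ch[i], ch[j])) {
        inner <- idx[idx > i & idx < j]
        outer <- idx[idx > j]
        best <- max(best, 1L + rec(inner) + rec(outer))
      }
    }
    best
  }
  rec(seq_along(ch))
}

# Stack-based count of paired positions in a dot-bracket string.
count_paired_chars <- function(db) {
  ch <- strsplit(db, "")[[1]]
  sum(ch %in% c("(", ")"))
}

# All base-count compositions (nA, nC, nG, nU) with the given total.
composition_grid <- function(total) {
  g <- expand.grid(na = 0:total, nc = 0:total, ng = 0:total)
  g <- g[g$na + g$nc + g$ng <= total, ]
  g$nu <- total - g$na - g$nc - g$ng
  g
}

grid_to_comp_tbl <- function(g) {
  n <- g$na + g$nc + g$ng + g$nu
  tibble::tibble(
    frac_a = g$na / n, frac_c = g$nc / n,
    frac_g = g$ng / n, frac_u = g$nu / n, length = n
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A small deterministic ledger shared by lariat-pipeline tests.
test_ledger <- function(seed = 101, plan = c("NONE", "IR", "NONE", "SINGLE"),
                        intron_length = 800, intergenic = 1500) {
  make_genome(
    seed = seed, n_genes = length(plan), alu_plan = plan,
    intron_length = intron_length, intergenic_length = intergenic
  )
}
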