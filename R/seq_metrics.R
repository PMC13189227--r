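# Composition statistics: GC content, the maximum base pairing (MBP) metric,
# shuffle ensembles, and k-mer full-pairing probabilities.
#
# MBP is a composition-only upper bound on pairing: the maximum fraction of a
# sequence's bases that could be paired given its base counts, allowing A-U,
# C-G and G-U (wobble) pairs. It is computed from proportions by a closed-form
# expression and cross-checked by an explicit matching oracle over base counts.

#' Nucleotide composition of sequences
#'
#' Computes per-sequence base fractions over the unambiguous bases. `T` is
#' treated as `U`; IUPAC ambiguity codes (including `N`) are excluded from both
#' numerator and denominator and reported in `n_ambiguous`.
#'
#' @param seq Character vector of nucleotide sequences.
#' @param id Optional sequence identifiers (defaults to names of `seq` or a
#'   running index).
#' @return A tibble with one row per sequence: `id`, `length` (count of
#'   unambiguous bases), `frac_a`, `frac_c`, `frac_g`, `frac_u`,
#'   `n_ambiguous`. Fractions sum to 1 whenever `length > 0`.
#' @examples
#' nt_composition("AAAATTCC")
#' @export
nt_composition <- function(seq, id = NULL) {
  if (!is.character(seq) || length(seq) == 0L) {
    abort_domain("`seq` must be a non-empty character vector.")
  }
  if (is.null(id)) id <- names(seq) %||% as.character(seq_along(seq))
  rows <- purrr::map2(seq, id, function(s, nm) {
    s <- normalize_rna(s)
    ch <- seq_chars(s)
    counts <- c(
      A = sum(ch == "A"), C = sum(ch == "C"),
      G = sum(ch == "G"), U = sum(ch == "U")
    )
    n <- sum(counts)
    tibble(
      id = nm,
      length = n,
      frac_a = if (n > 0) counts[["A"]] / n else 0,
      frac_c = if (n > 0) counts[["C"]] / n else 0,
      frac_g = if (n > 0) counts[["G"]] / n else 0,
      frac_u = if (n > 0) counts[["U"]] / n else 0,
      n_ambiguous = length(ch) - n
    )
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Accepts either raw sequences or an nt_composition() tibble and returns the
# composition tibble, so every metric can take both.
as_composition <- function(x) {
  if (is.character(x)) {
    return(nt_composition(x))
  }
  if (is.data.frame(x)) {
    needed <- c("frac_a", "frac_c", "frac_g", "frac_u", "length")
    if (!all(needed %in% names(x))) {
      abort_domain("composition table must have columns frac_a, frac_c, frac_g, frac_u, length.")
    }
    return(as_tibble(x))
  }
  abort_domain("`x` must be a character vector of sequences or a composition tibble.")
}

#' GC content
#'
#' Fraction of unambiguous bases that are G or C. Ambiguous bases are excluded
#' from numerator and denominator.
#'
#' @param seq Character vector of sequences over `A,C,G,T,U,N` plus IUPAC codes.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' gc_content(c("GGCC", "ATAT", "ACGTN"))
#' @export
gc_content <- function(seq) {
  if (!is.character(seq) || length(seq) == 0L) {
    abort_domain("`seq` must be a non-empty character vector.")
  }
  purrr::map_dbl(seq, function(s) {
    check_string(s)
    if (nchar(s) == 0L) abort_domain("empty sequence.")
    ch <- seq_chars(normalize_rna(s))
    unamb <- ch[ch %in% c("A", "C", "G", "U")]
    if (length(unamb) == 0L) abort_domain("sequence has no unambiguous bases.")
    sum(unamb %in% c("G", "C")) / length(unamb)
  })
}

#' Maximum base pairing (MBP) metric
#'
#' The maximum proportion of positions that could be paired given a sequence's
#' nucleotide composition, allowing A-U, C-G and G-U wobble pairs. Computed by
#' the closed-form expression over base proportions
#' \deqn{MBP = 1 - [\max(A-U,0) + \max(C-G,0) + |\max(U-A,0) - \max(G-C,0)|]}
#' where `A,C,G,U` are the base proportions. The value is not symmetric under
#' reverse complement: wobble pairing makes G and U interchangeable as partners
#' in a way that depends on which strand's composition is scored (see
#' [mbp_matching_oracle()], which agrees exactly).
#'
#' @param x Character vector of sequences, or a composition tibble from
#'   [nt_composition()].
#' @return Numeric vector of MBP values in `[0, 1]`, one per sequence.
#' @examples
#' mbp("AAAATTCC") # 0.5
#' mbp("ACGU") # 1
#' @seealso [mbp_matching_oracle()] for the count-based matching verifier.
#' @export
mbp <- function(x) {
  comp <- as_composition(x)
  if (any(comp$length == 0)) abort_domain("MBP is undefined for length-0 compositions.")
  a <- comp$frac_a
  c_ <- comp$frac_c
  g <- comp$frac_g
  u <- comp$frac_u
  1 - (pmax(a - u, 0) + pmax(c_ - g, 0) + abs(pmax(u - a, 0) - pmax(g - c_, 0)))
}

#' Matching oracle for the MBP metric
#'
#' Independent verifier of [mbp()]: maximizes the number of disjoint base pairs
#' drawn from the base multiset under the allowed pairings A-U, C-G and G-U, by
#' exhaustive search over the number of wobble pairs. Returns paired bases as a
#' fraction of the (unambiguous) length.
#'
#' @inheritParams mbp
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' mbp_matching_oracle("UUGG") # two G-U wobble pairs: 1
#' @export
mbp_matching_oracle <- function(x) {
  comp <- as_composition(x)
  if (any(comp$length == 0)) abort_domain("undefined for length-0 compositions.")
  purrr::pmap_dbl(
    list(comp$frac_a, comp$frac_c, comp$frac_g, comp$frac_u, comp$length),
    function(a, c_, g, u, n) {
      counts <- round(c(a, c_, g, u) * n)
      max_pairs_from_counts(counts[1], counts[2], counts[3], counts[4]) * 2 / n
    }
  )
}

# Max disjoint pairs over counts with pairings A-U, C-G, G-U: try every
# possible number of wobble pairs and take the best completion.
max_pairs_from_counts <- function(na, nc, ng, nu) {
  x_gu <- 0:min(ng, nu)
  best <- pmin(na, nu - x_gu) + pmin(nc, ng - x_gu) + x_gu
  max(best)
}

#' Shuffle a sequence
#'
#' Generates `n` independent uniform (mononucleotide) permutations of the
#' input. Composition-dependent statistics such as [gc_content()] and [mbp()]
#' are exactly invariant under this shuffle; structure is not, which is what
#' shuffle-ensemble deviations exploit.
#'
#' @param seq A single nucleotide string.
#' @param n Number of shuffles (default 10).
#' @param seed Integer seed for reproducibility (optional).
#' @return A `shuffle_set`: list with `original`, `shuffles` (character vector
#'   of length `n`), and `seed`.
#' @examples
#' shuffle_sequence("ACGU", n = 3, seed = 1)
#' @export
shuffle_sequence <- function(seq, n = 10, seed = NULL) {
  check_string(seq)
  if (nchar(seq) == 0L) abort_domain("`seq` must be non-empty.")
  if (!is.numeric(n) || n < 1) abort_domain("`n` must be >= 1.")
  ch <- seq_chars(seq)
  shuffles <- with_seed(seed, {
    vapply(seq_len(n), function(i) paste(sample(ch), collapse = ""), character(1))
  })
  structure(
    list(original = seq, shuffles = shuffles, seed = seed),
    class = "shuffle_set"
  )
}

#' @export
print.shuffle_set <- function(x, ...) {
  cat("<shuffle_set> ", length(x$shuffles), " shuffles of a ",
    nchar(x$original), "-nt sequence\n",
    sep = ""
  )
  invisible(x)
}

#' Probability that a random k-mer is fully paired
#'
#' Under the composition-only pairing model, the chance that every base of a
#' random k-mer drawn from a sequence's composition can find a partner. The
#' default analytic definition is `MBP^k` (independent positions); a
#' Monte-Carlo alternative draws k bases i.i.d. from the composition and tests
#' whether the draw's own MBP equals 1.
#'
#' @inheritParams mbp
#' @param k k-mer length (>= 1); e.g. 17 (OAS1), 22 (RIG-I), 33 (PKR).
#' @param method `"analytic"` (default, `MBP^k`) or `"montecarlo"`.
#' @param n_draws Number of Monte-Carlo draws (ignored for analytic).
#' @param seed RNG seed for the Monte-Carlo method.
#' @return Numeric vector of probabilities.
#' @examples
#' kmer_fully_paired_prob("AAAATTCC", k = 2) # 0.25
#' @export
kmer_fully_paired_prob <- function(x, k, method = c("analytic", "montecarlo"),
                                   n_draws = 10000, seed = NULL) {
  method <- match.arg(method)
  if (!is.numeric(k) || any(k < 1)) abort_domain("`k` must be >= 1.")
  comp <- as_composition(x)
  if (method == "analytic") {
    return(mbp(comp)^k)
  }
  with_seed(seed, {
    purrr::pmap_dbl(
      list(comp$frac_a, comp$frac_c, comp$frac_g, comp$frac_u),
      function(a, c_, g, u) {
        draws <- sample(c("A", "C", "G", "U"), n_draws * k,
          replace = TRUE, prob = c(a, c_, g, u)
        )
        mat <- matrix(draws, nrow = n_draws)
        fully <- apply(mat, 1, function(km) {
          counts <- c(sum(km == "A"), sum(km == "C"), sum(km == "G"), sum(km == "U"))
          max_pairs_from_counts(counts[1], counts[2], counts[3], counts[4]) * 2 == k
        })
        mean(fully)
      }
    )
  })
}

#' Per-sequence composition metrics table
#'
#' The module's tabular surface: one row per sequence with length, GC content
#' and MBP, ready to write with [write_metrics_tsv()].
#'
#' @param seq Named character vector of sequences (e.g. from [read_fasta()]).
#' @return A tibble: `id`, `length`, `gc`, `mbp`.
#' @export
seq_metrics <- function(seq) {
  comp <- nt_composition(seq)
  tibble(
    id = comp$id,
    length = comp$length + comp$n_ambiguous,
    gc = unname(gc_content(seq)),
    mbp = mbp(comp)
  )
}
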