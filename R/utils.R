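# Shared sequence helpers and input checks.

VALID_BASES <- c("A", "C", "G", "T", "U")

abort_domain <- function(msg) {
  rlang::abort(msg, class = "lariatdsrna_domain_error")
}

abort_format <- function(msg) {
  rlang::abort(msg, class = "lariatdsrna_format_error")
}

check_string <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort_domain(sprintf("`%s` must be a single non-NA string.", what))
  }
  invisible(x)
}

#' Normalize a nucleotide string
#'
#' Uppercases and converts T to U. Used internally so that composition and
#' pairing logic only ever sees the RNA alphabet; user-facing outputs keep the
#' caller's alphabet.
#'
#' @param seq A single nucleotide string.
#' @return The normalized string.
#' @keywords internal
normalize_rna <- function(seq) {
  check_string(seq)
  chartr("Tt", "Uu", toupper(seq))
}

seq_chars <- function(seq) {
  strsplit(seq, "", fixed = TRUE)[[1]]
}

#' Reverse complement of a DNA/RNA string
#'
#' @param seq A single nucleotide string (DNA or RNA alphabet; ambiguity
#'   codes are complemented per IUPAC).
#' @return The reverse complement, in the same alphabet family as the input
#'   (a `U` anywhere in the input selects the RNA alphabet).
#' @examples
#' revcomp("GGAATTTT")
#' @export
revcomp <- function(seq) {
  check_string(seq)
  if (grepl("U", toupper(seq), fixed = TRUE)) {
    as.character(Biostrings::reverseComplement(Biostrings::RNAString(toupper(seq))))
  } else {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
  }
}

#' Draw a random nucleotide sequence
#'
#' @param n Length in bases.
#' @param freqs Named base probabilities over `A,C,G,T` (or `U`); defaults
#'   to uniform.
#' @return A single string of length `n`.
#' @export
random_seq <- function(n, freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (n < 1) abort_domain("`n` must be >= 1.")
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

# local seed scope: runs `expr` under set.seed(seed) without disturbing the
# caller's RNG stream when seed is NULL.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L) abort_domain("`seed` must be a single number.")
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}
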