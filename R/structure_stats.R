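# Secondary-structure statistics: dot-bracket parsing, maximal duplex
# ("dsRNA stretch") extraction, immune sensor-site counts, length-normalized
# MFE, and observed-versus-shuffled ensemble deviations.
#
# Folding is an injected contract: any function mapping a sequence to a fold
# result (dot-bracket + free energy) can be wired in. The built-in folder is a
# deterministic pairing-maximization dynamic program (score -1 per pair) so the
# whole module is exercisable without an external structure predictor;
# production analyses wire an RNAfold-compatible predictor instead.

#' Parse a dot-bracket string
#'
#' Recovers base pairs by stack matching. Only `(`, `)` and `.` are accepted
#' (no pseudoknots).
#'
#' @param db Dot-bracket string.
#' @param seq The folded sequence (same length as `db`).
#' @return A `secondary_structure`: list with `sequence`, `dotbracket`, and
#'   `pairs`, a tibble of 0-based positions `i < j`.
#' @examples
#' parse_dotbracket("((..))", "GGAACC")$pairs
#' @export
parse_dotbracket <- function(db, seq) {
  check_string(db, "db")
  check_string(seq, "seq")
  if (nchar(db) != nchar(seq)) {
    abort_format("dot-bracket and sequence lengths differ.")
  }
  ch <- seq_chars(db)
  if (!all(ch %in% c("(", ")", "."))) {
    abort_format("dot-bracket may contain only '(', ')' and '.'.")
  }
  stack <- integer(0)
  is <- integer(0)
  js <- integer(0)
  for (pos in seq_along(ch)) {
    if (ch[pos] == "(") {
      stack <- c(stack, pos)
    } else if (ch[pos] == ")") {
      if (length(stack) == 0L) abort_format("unbalanced dot-bracket: unmatched ')'.")
      is <- c(is, stack[length(stack)])
      js <- c(js, pos)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0L) abort_format("unbalanced dot-bracket: unmatched '('.")
  ord <- order(is)
  structure(
    list(
      sequence = seq,
      dotbracket = db,
      pairs = tibble(i = is[ord] - 1L, j = js[ord] - 1L)
    ),
    class = "secondary_structure"
  )
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("<secondary_structure> ", nchar(x$sequence), " nt, ",
    nrow(x$pairs), " pairs\n",
    sep = ""
  )
  invisible(x)
}

#' Extract maximal dsRNA stretches
#'
#' Splits a structure into its maximal runs of consecutively stacked pairs.
#' Any departure from perfect stacking -- a bulge on either strand, an internal
#' loop, or a multiloop junction -- terminates a stretch, reflecting the
#' dependence of dsRNA sensors on uninterrupted helical duplex.
#'
#' @param structure A `secondary_structure` from [parse_dotbracket()] or a
#'   folder.
#' @return A tibble ordered by `five_prime_start`: `length_bp` (stacked pairs),
#'   `five_prime_start`, `three_prime_end` (0-based outermost pair positions).
#'   Twice the summed `length_bp` equals the number of paired positions.
#' @examples
#' extract_stretches(parse_dotbracket("((((....))))", "GGGGAAAACCCC"))
#' @export
extract_stretches <- function(structure) {
  stopifnot(inherits(structure, "secondary_structure"))
  p <- dplyr::arrange(structure$pairs, .data$i)
  if (nrow(p) == 0L) {
    return(tibble(
      length_bp = integer(0), five_prime_start = integer(0),
      three_prime_end = integer(0)
    ))
  }
  # a pair continues the current stretch iff it is exactly (i+1, j-1)
  new_run <- c(TRUE, !(diff(p$i) == 1L & diff(p$j) == -1L))
  run_id <- cumsum(new_run)
  p |>
    dplyr::mutate(run = run_id) |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(
      length_bp = dplyr::n(),
      five_prime_start = min(.data$i),
      three_prime_end = max(.data$j),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$five_prime_start) |>
    dplyr::select(-"run") |>
    dplyr::select("length_bp", "five_prime_start", "three_prime_end")
}

#' Default dsRNA sensor panel
#'
#' Minimum activating duplex lengths: OAS1 17 bp, RIG-I 22 bp, PKR 33 bp.
#'
#' @return Named integer vector (sensor name to minimum duplex length in bp).
#' @export
default_sensor_panel <- function() {
  c(OAS1 = 17L, `RIG-I` = 22L, PKR = 33L)
}

#' Sensor-site counts for a set of duplex stretches
#'
#' For each sensor, sums `floor(length_bp / threshold)` over stretches: the
#' number of non-overlapping duplex segments long enough to engage the sensor.
#'
#' @param stretches Tibble from [extract_stretches()], or a numeric vector of
#'   stretch lengths in bp.
#' @param panel Named vector of minimum activating lengths; defaults to
#'   [default_sensor_panel()].
#' @return A tibble: `sensor`, `min_bp`, `sites`.
#' @examples
#' sensor_sites(c(17, 16))
#' @export
sensor_sites <- function(stretches, panel = default_sensor_panel()) {
  if (is.data.frame(stretches)) stretches <- stretches$length_bp
  if (is.null(names(panel)) || any(panel < 1)) {
    abort_domain("`panel` must be a named vector of thresholds >= 1.")
  }
  tibble(
    sensor = names(panel),
    min_bp = as.integer(panel),
    sites = unname(purrr::map_int(panel, function(thr) {
      as.integer(sum(floor(stretches / thr)))
    }))
  )
}

#' Length-normalized minimum free energy
#'
#' @param mfe Free energy in kcal/mol.
#' @param length Region length in nt (>= 1).
#' @return kcal/mol per nucleotide.
#' @export
normalized_mfe <- function(mfe, length) {
  if (any(length < 1)) abort_domain("`length` must be >= 1.")
  mfe / length
}

#' Built-in deterministic folder
#'
#' Pairing-maximization fold (Nussinov-style dynamic program, minimum hairpin
#' loop of 3 nt, G-U wobble allowed) with a surrogate energy of -1 kcal/mol per
#' base pair. Deterministic, dependency-free, and suitable for short sequences
#' (the dynamic program is cubic in length); production analyses should inject
#' an RNAfold-compatible thermodynamic predictor instead.
#'
#' @param seq A single nucleotide string.
#' @param min_loop Minimum number of unpaired bases in a hairpin loop.
#' @return A `fold_result`: list with `structure` (a `secondary_structure`),
#'   `mfe` and `normalized_mfe`.
#' @examples
#' fold_builtin("GGGGAAAACCCC")
#' @export
fold_builtin <- function(seq, min_loop = 3) {
  check_string(seq)
  if (nchar(seq) == 0L) abort_domain("`seq` must be non-empty.")
  rna <- normalize_rna(seq)
  res <- .nussinov_fold(rna, as.integer(min_loop))
  fold_result(seq, res$dotbracket, mfe = -res$n_pairs)
}

#' Construct a fold result
#'
#' Wraps a predicted structure and its energy, computing the length-normalized
#' energy. Use this to adapt any external predictor's output to the folder
#' contract. A positive-pair structure with `mfe > 0` triggers a warning (a
#' physically sensible predictor assigns non-positive energies to paired
#' structures).
#'
#' @param seq Folded sequence.
#' @param dotbracket Predicted dot-bracket string.
#' @param mfe Free energy in kcal/mol.
#' @return A `fold_result`.
#' @export
fold_result <- function(seq, dotbracket, mfe) {
  st <- parse_dotbracket(dotbracket, seq)
  if (nrow(st$pairs) > 0 && mfe > 0) {
    warning("structure has pairs but positive energy; check the predictor.")
  }
  structure(
    list(
      structure = st,
      mfe = mfe,
      normalized_mfe = normalized_mfe(mfe, nchar(seq))
    ),
    class = "fold_result"
  )
}

#' @export
print.fold_result <- function(x, ...) {
  cat("<fold_result> ", nchar(x$structure$sequence), " nt, mfe ", x$mfe,
    " (", signif(x$normalized_mfe, 4), "/nt)\n",
    sep = ""
  )
  invisible(x)
}

#' RNAfold adapter folder
#'
#' Returns a folder function that shells out to an RNAfold-compatible binary
#' (sequence on stdin; dot-bracket line with a trailing `(energy)` on stdout).
#' Only useful where such a binary is installed; tests and examples use
#' [fold_builtin()].
#'
#' @param cmd Path to the RNAfold binary.
#' @param args Extra command-line arguments.
#' @return A function `seq -> fold_result`.
#' @export
rnafold_folder <- function(cmd = "RNAfold", args = c("--noPS")) {
  force(cmd)
  force(args)
  function(seq) {
    out <- system2(cmd, args, stdout = TRUE, input = normalize_rna(seq))
    if (length(out) < 2L) abort_format("unexpected RNAfold output.")
    line <- out[2]
    m <- regmatches(line, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1]]
    if (length(m) != 3L) abort_format("could not parse RNAfold structure line.")
    fold_result(seq, m[2], as.numeric(m[3]))
  }
}

#' Observed-versus-shuffled ensemble deviation
#'
#' Folds a sequence and an ensemble of its mononucleotide shuffles with the
#' same folder, and reports the deviation `observed - mean(shuffled)` in the
#' folder's energy units. More structure than expected from composition alone
#' gives a negative deviation.
#'
#' @param seq A single nucleotide string.
#' @param folder A folder contract (`seq -> fold_result`); default
#'   [fold_builtin()].
#' @param n Ensemble size (default 10 shuffles).
#' @param seed Integer seed for the shuffles.
#' @param normalized Use length-normalized energies (default `FALSE`; the
#'   shuffles have the observed sequence's length, so normalization rescales
#'   but does not reorder deviations).
#' @param id Optional identifier carried into error messages and tidy output.
#' @return An `ensemble_deviation`: list with `id`, `observed_mfe`,
#'   `shuffled_mfes`, `mean_shuffled_mfe`, `deviation`, `n`, `seed`.
#' @examples
#' ensemble_deviation("GGGGGAAAACCCCC", n = 5, seed = 1)
#' @export
ensemble_deviation <- function(seq, folder = fold_builtin, n = 10, seed = NULL,
                               normalized = FALSE, id = NULL) {
  if (n < 1) abort_domain("`n` must be >= 1.")
  pick <- function(fr) if (normalized) fr$normalized_mfe else fr$mfe
  observed <- tryCatch(pick(folder(seq)), error = function(e) {
    abort_domain(sprintf(
      "folder failed on %s: %s", id %||% "observed sequence",
      conditionMessage(e)
    ))
  })
  shuffles <- shuffle_sequence(seq, n = n, seed = seed)$shuffles
  shuffled <- purrr::imap_dbl(shuffles, function(s, k) {
    tryCatch(pick(folder(s)), error = function(e) {
      abort_domain(sprintf(
        "folder failed on shuffle %d of %s: %s", k,
        id %||% "sequence", conditionMessage(e)
      ))
    })
  })
  structure(
    list(
      id = id, observed_mfe = observed, shuffled_mfes = shuffled,
      mean_shuffled_mfe = mean(shuffled),
      deviation = observed - mean(shuffled),
      n = n, seed = seed
    ),
    class = "ensemble_deviation"
  )
}

#' @export
print.ensemble_deviation <- function(x, ...) {
  cat("<ensemble_deviation> observed ", x$observed_mfe, ", mean of ", x$n,
    " shuffles ", signif(x$mean_shuffled_mfe, 5),
    ", deviation ", signif(x$deviation, 5), "\n",
    sep = ""
  )
  invisible(x)
}

#' Sensor-site counts across a set of regions
#'
#' Folds each region once (regions longer than `max_length` are skipped, since
#' structure prediction cost grows steeply with length), extracts duplex
#' stretches, and tallies sensor sites.
#'
#' @param sequences Named character vector of region sequences.
#' @param folder Folder contract; default [fold_builtin()].
#' @param panel Sensor panel; default [default_sensor_panel()].
#' @param max_length Regions longer than this many nt are skipped (default
#'   5000).
#' @return A long tibble: `region_id`, `length`, `mfe`, `normalized_mfe`,
#'   `n_stretches`, `sensor`, `sites`. Skipped regions are reported in the
#'   `"skipped"` attribute (tibble of `region_id`, `length`) and via a message.
#' @export
count_sensor_sites_for_regions <- function(sequences, folder = fold_builtin,
                                           panel = default_sensor_panel(),
                                           max_length = 5000) {
  if (is.null(names(sequences))) names(sequences) <- as.character(seq_along(sequences))
  lens <- nchar(sequences)
  skipped <- tibble(
    region_id = names(sequences)[lens > max_length],
    length = unname(lens[lens > max_length])
  )
  if (nrow(skipped) > 0) {
    message(nrow(skipped), " region(s) longer than ", max_length, " nt skipped.")
  }
  keep <- sequences[lens <= max_length]
  rows <- purrr::imap(keep, function(s, nm) {
    fr <- folder(s)
    stretches <- extract_stretches(fr$structure)
    sites <- sensor_sites(stretches, panel)
    tibble(
      region_id = nm, length = nchar(s), mfe = fr$mfe,
      normalized_mfe = fr$normalized_mfe, n_stretches = nrow(stretches),
      sensor = sites$sensor, sites = sites$sites
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  out
}
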