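# Weighted sense/antisense Alu hybridization trials.
#
# Emulates a mixed pool of transcribed Alu elements: plus- and minus-strand
# members are drawn with probabilities given by their relative representation,
# the sampled pair is hybridized (injected contract; the built-in hybridizer
# maximizes intermolecular complementarity), and the duplex's sensor-site
# counts are tallied across trials.

#' Build a weighted Alu pool
#'
#' @param sequences Named character vector of member sequences.
#' @param counts Per-member read counts (same names/order as `sequences`), or
#'   `NULL` for uniform weights.
#' @return Tibble `id`, `sequence`, `weight`; weights are counts normalized to
#'   sum to 1.
#' @export
alu_pool <- function(sequences, counts = NULL) {
  if (is.null(names(sequences))) names(sequences) <- as.character(seq_along(sequences))
  if (is.null(counts)) counts <- rep(1, length(sequences))
  if (!is.null(names(counts))) counts <- counts[names(sequences)]
  weights <- weights_from_counts(counts)
  tibble(id = names(sequences), sequence = unname(sequences), weight = unname(weights))
}

#' Normalize member counts to sampling weights
#'
#' @param counts Non-negative numeric vector with at least one positive entry.
#' @return Weights summing to 1 (names preserved).
#' @examples
#' weights_from_counts(c(a = 3, b = 1))
#' @export
weights_from_counts <- function(counts) {
  if (any(counts < 0)) abort_domain("counts must be >= 0.")
  total <- sum(counts)
  if (total <= 0) abort_domain("at least one count must be positive.")
  counts / total
}

#' Built-in intermolecular hybridizer
#'
#' Maximizes the number of non-crossing intermolecular base pairs (A-U, C-G,
#' G-U) between two strands by dynamic programming -- a deterministic,
#' dependency-free stand-in for a thermodynamic duplex predictor. No
#' intramolecular pairing is considered. Two exact reverse complements of
#' length L form a single perfect stretch of L pairs.
#'
#' @param seq_plus,seq_minus The two strands (5'->3').
#' @return A `duplex`: list with `pairs` (tibble of 0-based `pos_plus`,
#'   `pos_minus`) and `stretches` (tibble with `length_bp`).
#' @examples
#' hybridize_builtin("ACGU", revcomp("ACGU"))
#' @export
hybridize_builtin <- function(seq_plus, seq_minus) {
  a <- normalize_rna(seq_plus)
  b <- normalize_rna(seq_minus)
  res <- .duplex_hybridize(a, b)
  pairs <- tibble(pos_plus = res$pos_a, pos_minus = res$pos_b)
  structure(
    list(pairs = pairs, stretches = duplex_stretches(pairs)),
    class = "duplex"
  )
}

#' @export
print.duplex <- function(x, ...) {
  cat("<duplex> ", nrow(x$pairs), " intermolecular pairs in ",
    nrow(x$stretches), " stretch(es)\n",
    sep = ""
  )
  invisible(x)
}

#' Maximal stretches of a duplex
#'
#' Consecutively stacked intermolecular pairs: the plus-strand position
#' advances by one while the minus-strand position recedes by one.
#'
#' @param pairs Tibble of `pos_plus` (ascending) and `pos_minus`.
#' @return Tibble `length_bp`, `plus_start`, `minus_end` (0-based).
#' @export
duplex_stretches <- function(pairs) {
  if (nrow(pairs) == 0L) {
    return(tibble(
      length_bp = integer(0), plus_start = integer(0), minus_end = integer(0)
    ))
  }
  p <- dplyr::arrange(pairs, .data$pos_plus)
  new_run <- c(TRUE, !(diff(p$pos_plus) == 1L & diff(p$pos_minus) == -1L))
  p |>
    dplyr::mutate(run = cumsum(new_run)) |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(
      length_bp = dplyr::n(),
      plus_start = min(.data$pos_plus),
      minus_end = max(.data$pos_minus),
      .groups = "drop"
    ) |>
    dplyr::select("length_bp", "plus_start", "minus_end")
}

#' Run weighted Alu-pair hybridization trials
#'
#' `n` independent weighted draws (with replacement) of one plus-pool and one
#' minus-pool member; each sampled pair is hybridized and its per-sensor site
#' counts recorded. Hybridizations are memoized per unique member pair. A
#' failing hybridizer marks the trial failed and excludes it from the summary.
#'
#' @param pool_plus,pool_minus Pool tibbles from [alu_pool()].
#' @param hybridizer Contract `(seq_plus, seq_minus) -> duplex` (default
#'   [hybridize_builtin()]).
#' @param panel Sensor panel (default [default_sensor_panel()]).
#' @param n Number of trials (default 10000).
#' @param seed RNG seed.
#' @return A `hybrid_trials`: list with `trials` (long tibble: `trial`,
#'   `plus_id`, `minus_id`, `failed`, `sensor`, `sites`), `summary` (per
#'   sensor: mean, median, quartiles over successful trials), `n_failed`,
#'   `n`, `seed`.
#' @export
run_hybrid_trials <- function(pool_plus, pool_minus,
                              hybridizer = hybridize_builtin,
                              panel = default_sensor_panel(),
                              n = 10000, seed = NULL) {
  if (n < 1) abort_domain("`n` must be >= 1.")
  draws <- with_seed(seed, {
    tibble(
      trial = seq_len(n),
      plus_id = sample(pool_plus$id, n, replace = TRUE, prob = pool_plus$weight),
      minus_id = sample(pool_minus$id, n, replace = TRUE, prob = pool_minus$weight)
    )
  })
  seq_plus <- setNames(pool_plus$sequence, pool_plus$id)
  seq_minus <- setNames(pool_minus$sequence, pool_minus$id)
  pair_key <- paste(draws$plus_id, draws$minus_id, sep = "\r")
  uniq <- unique(pair_key)
  per_pair <- purrr::map(uniq, function(keyk) {
    ids <- strsplit(keyk, "\r", fixed = TRUE)[[1]]
    dup <- tryCatch(hybridizer(seq_plus[[ids[1]]], seq_minus[[ids[2]]]),
      error = function(e) NULL
    )
    if (is.null(dup)) {
      list(failed = TRUE, sites = rep(NA_integer_, length(panel)))
    } else {
      list(failed = FALSE, sites = sensor_sites(dup$stretches, panel)$sites)
    }
  })
  names(per_pair) <- uniq
  failed <- purrr::map_lgl(per_pair, "failed")[pair_key]
  sites_mat <- do.call(rbind, purrr::map(per_pair, "sites"))[match(pair_key, uniq), , drop = FALSE]
  colnames(sites_mat) <- names(panel)
  trials <- draws |>
    dplyr::mutate(failed = unname(failed)) |>
    dplyr::bind_cols(as_tibble(sites_mat)) |>
    tidyr::pivot_longer(dplyr::all_of(names(panel)),
      names_to = "sensor", values_to = "sites"
    )
  summary <- trials |>
    dplyr::filter(!.data$failed) |>
    dplyr::group_by(.data$sensor) |>
    dplyr::summarise(
      mean = mean(.data$sites),
      median = stats::median(.data$sites),
      q25 = stats::quantile(.data$sites, 0.25),
      q75 = stats::quantile(.data$sites, 0.75),
      .groups = "drop"
    )
  structure(
    list(
      trials = trials, summary = summary,
      n = n, n_failed = sum(failed), seed = seed
    ),
    class = "hybrid_trials"
  )
}

#' @export
print.hybrid_trials <- function(x, ...) {
  cat("<hybrid_trials> ", x$n, " trials (", x$n_failed, " failed)\n", sep = "")
  print(x$summary)
  invisible(x)
}
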