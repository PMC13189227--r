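# broom-style accessors for the package's result objects.

#' Tidy an ensemble deviation
#'
#' @param x An `ensemble_deviation`.
#' @param ... Unused.
#' @return One row per fold: `role` (`"observed"`/`"shuffled"`), `replicate`,
#'   `mfe`.
#' @export
tidy.ensemble_deviation <- function(x, ...) {
  dplyr::bind_rows(
    tibble(role = "observed", replicate = NA_integer_, mfe = x$observed_mfe),
    tibble(
      role = "shuffled", replicate = seq_along(x$shuffled_mfes),
      mfe = x$shuffled_mfes
    )
  )
}

#' @rdname tidy.ensemble_deviation
#' @export
glance.ensemble_deviation <- function(x, ...) {
  tibble(
    observed_mfe = x$observed_mfe,
    mean_shuffled_mfe = x$mean_shuffled_mfe,
    deviation = x$deviation,
    n_shuffles = x$n
  )
}

#' Tidy hybridization trials
#'
#' @param x A `hybrid_trials`.
#' @param ... Unused.
#' @return The long per-trial tibble (`trial`, `plus_id`, `minus_id`,
#'   `failed`, `sensor`, `sites`).
#' @export
tidy.hybrid_trials <- function(x, ...) x$trials

#' @rdname tidy.hybrid_trials
#' @export
glance.hybrid_trials <- function(x, ...) {
  tibble(n_trials = x$n, n_failed = x$n_failed) |>
    dplyr::bind_cols(
      tidyr::pivot_wider(
        dplyr::select(x$summary, "sensor", "mean"),
        names_from = "sensor", values_from = "mean", names_prefix = "mean_"
      )
    )
}

#' Tidy a lariat mapping
#'
#' @param x A `lariat_mapping`.
#' @param ... Unused.
#' @return The per-read calls tibble.
#' @export
tidy.lariat_mapping <- function(x, ...) x$calls

#' @rdname tidy.lariat_mapping
#' @export
glance.lariat_mapping <- function(x, ...) {
  tibble(
    n_input = x$stages$reads[x$stages$stage == "input"],
    n_called = nrow(x$calls),
    n_branchpoints = nrow(x$branchpoints),
    n_introns = dplyr::n_distinct(x$calls$intron_id)
  )
}
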