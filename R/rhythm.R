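#' Count calls per hour-of-day slot
#'
#' Each period is divided into 24 one-hour slots and calls are counted by the
#' hour-of-day of their timestamp (floor to the hour, slots `[h, h + 1)`).
#' Counting is grouped by `owner_id` and, when present, `period`, and every
#' group is completed to the full 24 bins so zero hours appear explicitly.
#'
#' @param records Tibble of call records, optionally carrying a `period`
#'   column from [assign_periods()].
#' @return A tibble with columns `owner_id`, (`period`,) `hour` (0-23),
#'   `n_calls`.
#' @export
count_by_hour <- function(records) {
  records <- validate_cdr(records)
  has_period <- "period" %in% names(records)
  grp <- if (has_period) c("owner_id", "period") else "owner_id"
  records$hour <- as.integer(format(records$timestamp, "%H"))
  counts <- records |>
    dplyr::count(dplyr::across(dplyr::all_of(grp)), .data$hour, name = "n_calls") |>
    tidyr::complete(
      tidyr::nesting(!!!rlang::syms(grp)),
      hour = 0:23,
      fill = list(n_calls = 0L)
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(grp, "hour"))))
  counts
}

#' Normalize hourly counts into a daily rhythm
#'
#' The daily rhythm of one individual in one period is the empirical
#' distribution of their calls over the 24 hour slots:
#' `f(t) = n(t) / sum_t n(t)`. It is the raw empirical fraction — no
#' smoothing and no pseudo-counts — and is undefined when the individual
#' placed no calls in the period.
#'
#' @param counts Numeric vector of 24 non-negative hourly counts
#'   (hours 0-23).
#' @return Numeric vector of 24 fractions summing to 1.
#' @examples
#' compute_rhythm(c(3, rep(0, 11), 1, rep(0, 11)))
#' @export
compute_rhythm <- function(counts) {
  if (length(counts) != 24L || any(counts < 0) || anyNA(counts)) {
    stop_contract("`counts` must be 24 non-negative hourly counts.")
  }
  total <- sum(counts)
  if (total < 1) {
    abort("Cannot compute a daily rhythm from zero calls.",
          class = c("callrhythm_empty_period", "callrhythm_contract_error"))
  }
  counts / total
}

#' Compute daily rhythms for every individual and period
#'
#' Tidy wrapper around [count_by_hour()] and [compute_rhythm()]: one row per
#' `owner_id` x `period` x `hour` with the call count, the fraction `f(t)`,
#' and the period total. Individuals with zero calls in a period simply have
#' no rows for that period; downstream analysis excludes them from that
#' direction mode (a rhythm is undefined there).
#'
#' The returned tibble has class `daily_rhythm` and can be plotted with
#' [autoplot()] or exported with [readr::write_csv()] to re-create rhythm
#' curves externally.
#'
#' @param records Tibble of call records with a `period` column (see
#'   [assign_periods()]).
#' @return A `daily_rhythm` tibble: `owner_id`, `period`, `hour`, `n_calls`,
#'   `fraction`, `total_calls`.
#' @export
daily_rhythms <- function(records) {
  if (!"period" %in% names(records)) {
    stop_contract("`records` must carry a `period` column; run assign_periods() first.")
  }
  rhythms <- count_by_hour(records) |>
    dplyr::group_by(.data$owner_id, .data$period) |>
    dplyr::mutate(
      total_calls = sum(.data$n_calls),
      fraction = .data$n_calls / .data$total_calls
    ) |>
    dplyr::ungroup() |>
    dplyr::relocate("owner_id", "period", "hour", "n_calls", "fraction", "total_calls")
  class(rhythms) <- c("daily_rhythm", class(tibble::tibble()))
  rhythms
}

# Extract one individual's 24-bin fraction vector from a daily_rhythm tibble.
rhythm_profile <- function(rhythms, owner, period) {
  rows <- rhythms[rhythms$owner_id == owner & rhythms$period == period, ]
  if (nrow(rows) != 24L) {
    abort(
      sprintf("No daily rhythm for individual '%s' in period '%s'.", owner, period),
      class = c("callrhythm_missing_profile", "callrhythm_contract_error")
    )
  }
  rows$fraction[order(rows$hour)]
}

#' Plot daily rhythm profiles
#'
#' Step curves of the hourly call fraction `f(t)` by period, one panel per
#' individual.
#'
#' @param object A `daily_rhythm` tibble from [daily_rhythms()].
#' @param owners Optional subset of `owner_id`s to plot.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot daily_rhythm
#' @export
autoplot.daily_rhythm <- function(object, owners = NULL, ...) {
  if (!is.null(owners)) {
    object <- object[object$owner_id %in% owners, ]
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$hour, y = .data$fraction,
                                       colour = .data$period)) +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::facet_wrap(~owner_id) +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6), limits = c(0, 23)) +
    ggplot2::labs(x = "Hour of day", y = "Fraction of calls f(t)",
                  colour = "Period") +
    ggplot2::theme_minimal()
}
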