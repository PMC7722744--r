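#' Define successive observation periods
#'
#' The persistence analysis coarse-grains the observation window into
#' `N_T >= 2` successive time periods. A partition is a tibble with one row
#' per period and columns `period` (label), `start`, `end`; intervals are
#' half-open `[start, end)`, contiguous, and strictly increasing, so every
#' instant inside the window belongs to exactly one period.
#'
#' @param breaks Increasing vector of `N_T + 1` boundary date-times
#'   (`POSIXct`, `Date`, or ISO-8601 strings). Period `k` spans
#'   `[breaks[k], breaks[k + 1])`.
#' @param labels Optional period labels; defaults to `"T1" ... "TN"`.
#' @return A `time_partition` tibble.
#' @examples
#' time_partition(c("2019-01-01", "2019-07-02", "2019-12-31"))
#' @export
time_partition <- function(breaks, labels = NULL) {
  breaks <- to_utc_time(breaks)
  n <- length(breaks) - 1L
  if (n < 2L) {
    stop_config("A partition needs at least 2 periods (3 break points).")
  }
  if (any(diff(as.numeric(breaks)) <= 0)) {
    stop_config("`breaks` must be strictly increasing.")
  }
  if (is.null(labels)) {
    labels <- paste0("T", seq_len(n))
  }
  if (length(labels) != n || anyDuplicated(labels) > 0) {
    stop_config("`labels` must be unique and match the number of periods.")
  }
  structure(
    tibble::tibble(period = labels, start = breaks[-(n + 1L)], end = breaks[-1L]),
    class = c("time_partition", class(tibble::tibble()))
  )
}

to_utc_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (inherits(x, "Date")) {
    return(as.POSIXct(as.character(x), tz = "UTC"))
  }
  out <- suppressWarnings(readr::parse_datetime(as.character(x),
                                                locale = readr::locale(tz = "UTC")))
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    out[bad] <- suppressWarnings(as.POSIXct(as.character(x)[bad], tz = "UTC"))
  }
  if (anyNA(out)) {
    stop_config("Could not parse period boundaries as date-times.")
  }
  out
}

#' Split the observation window into equal periods
#'
#' Convenience constructor: takes the records' observation window (first
#' timestamp to just past the last) and divides it into `n_periods` equal
#' successive periods, e.g. two 6-month halves of a 12-month window.
#'
#' @param records Tibble of call records.
#' @param n_periods Number of equal periods (`>= 2`).
#' @return A [time_partition()] covering every record.
#' @export
equal_partition <- function(records, n_periods = 2) {
  records <- validate_cdr(records)
  if (nrow(records) == 0) {
    stop_input("Cannot derive an observation window from zero records.")
  }
  if (!is_scalar_number(n_periods) || n_periods < 2) {
    stop_config("`n_periods` must be at least 2.")
  }
  lo <- min(records$timestamp)
  hi <- max(records$timestamp) + 1 # half-open: last record must fall inside
  time_partition(lo + (as.numeric(hi) - as.numeric(lo)) * (0:n_periods) / n_periods)
}

#' Assign call records to time periods
#'
#' Adds a `period` column: each record whose timestamp falls in
#' `[start_k, end_k)` gets label `T_k`. Records outside every period are
#' dropped, counted, and reported; the count is attached as attribute
#' `n_dropped`.
#'
#' @param records Tibble of call records.
#' @param partition A [time_partition()].
#' @return The records inside the window, with a `period` factor column whose
#'   levels follow the partition order.
#' @export
assign_periods <- function(records, partition) {
  records <- validate_cdr(records)
  if (!inherits(partition, "time_partition")) {
    stop_config("`partition` must be created with time_partition() or equal_partition().")
  }
  idx <- findInterval(as.numeric(records$timestamp),
                      as.numeric(c(partition$start, partition$end[nrow(partition)])),
                      left.open = FALSE, rightmost.closed = FALSE)
  # findInterval with the combined break vector: idx in 1..N_T means inside
  # period idx (half-open, since rightmost.closed = FALSE puts end_k in k+1)
  inside <- idx >= 1L & idx <= nrow(partition) &
    records$timestamp < partition$end[pmin(pmax(idx, 1L), nrow(partition))]
  n_dropped <- sum(!inside)
  if (n_dropped > 0) {
    inform(sprintf("Dropped %d record(s) outside the partition window.", n_dropped))
  }
  out <- records[inside, ]
  out$period <- factor(partition$period[idx[inside]], levels = partition$period)
  attr(out, "n_dropped") <- n_dropped
  out
}
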