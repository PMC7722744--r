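#' Describe the column layout of a CDR file
#'
#' A call detail record (CDR) export has no universal layout, so reading is
#' driven by a small dialect object: which column holds each field, how
#' direction tokens map onto the two canonical directions, and the delimiter.
#' The default layout is `owner_id, timestamp, direction, peer_id, duration_s`
#' with ISO-8601 timestamps and literal `outgoing` / `incoming` tokens.
#'
#' Timestamps are treated as local civil time exactly as recorded: they are
#' parsed into UTC-labelled `POSIXct` without any time-zone or daylight-saving
#' adjustment, so the hour written in the file is the hour used for binning.
#'
#' @param delim Field delimiter (default `","`).
#' @param owner_id,timestamp,direction,peer_id,duration_s Column names in the
#'   file holding each record field. `peer_id` and `duration_s` are optional:
#'   set to `NULL` if the file lacks them.
#' @param direction_codes Named character vector mapping the canonical
#'   directions to the tokens used in the file, e.g.
#'   `c(outgoing = "out", incoming = "in")`.
#' @param timestamp_format Optional `strptime()` format string; by default
#'   ISO-8601 is parsed with [readr::parse_datetime()].
#' @return A `cdr_dialect` list.
#' @examples
#' cdr_dialect(direction_codes = c(outgoing = "out", incoming = "in"))
#' @export
cdr_dialect <- function(delim = ",",
                        owner_id = "owner_id",
                        timestamp = "timestamp",
                        direction = "direction",
                        peer_id = "peer_id",
                        duration_s = "duration_s",
                        direction_codes = c(outgoing = "outgoing", incoming = "incoming"),
                        timestamp_format = NULL) {
  if (!setequal(names(direction_codes), c("outgoing", "incoming"))) {
    stop_config("`direction_codes` must be named with exactly 'outgoing' and 'incoming'.")
  }
  structure(
    list(
      delim = delim, owner_id = owner_id, timestamp = timestamp,
      direction = direction, peer_id = peer_id, duration_s = duration_s,
      direction_codes = direction_codes, timestamp_format = timestamp_format
    ),
    class = "cdr_dialect"
  )
}

#' Read a CDR event log
#'
#' Reads a delimited text file of call events into a tibble with one row per
#' call and canonical columns `owner_id`, `timestamp`, `direction`, `peer_id`,
#' `duration_s`. Rows whose timestamp or direction cannot be decoded (or with
#' negative duration) are skipped with a warning by default; with
#' `strict = TRUE` the first malformed row is a fatal input error naming the
#' row. The number of skipped rows is attached as attribute `n_skipped`.
#'
#' @param path Path to the delimited file (header required).
#' @param dialect A [cdr_dialect()] describing the layout.
#' @param strict If `TRUE`, malformed rows are fatal instead of skipped.
#' @return A tibble of call records, in file order. `direction` is a factor
#'   with levels `outgoing`, `incoming`.
#' @seealso [write_cdr()], [assign_periods()], [select_direction()]
#' @export
read_cdr <- function(path, dialect = cdr_dialect(), strict = FALSE) {
  if (!inherits(dialect, "cdr_dialect")) {
    stop_config("`dialect` must be created with cdr_dialect().")
  }
  if (!file.exists(path)) {
    stop_input(sprintf("CDR file not found: '%s'.", path))
  }
  raw <- readr::read_delim(
    path,
    delim = dialect$delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  mandatory <- c(dialect$owner_id, dialect$timestamp, dialect$direction)
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    stop_config(sprintf(
      "CDR file '%s' lacks mandatory column(s): %s.",
      path, paste(missing_cols, collapse = ", ")
    ))
  }

  ts_raw <- raw[[dialect$timestamp]]
  # readr's own parse-failure warning is redundant here: unparseable rows are
  # counted and reported (or made fatal) by the malformed-row handling below
  ts <- suppressWarnings(
    if (is.null(dialect$timestamp_format)) {
      readr::parse_datetime(ts_raw, locale = readr::locale(tz = "UTC"))
    } else {
      readr::parse_datetime(ts_raw, format = dialect$timestamp_format,
                            locale = readr::locale(tz = "UTC"))
    }
  )

  codes <- dialect$direction_codes
  dir_canon <- names(codes)[match(raw[[dialect$direction]], codes)]

  bad <- is.na(ts) | is.na(dir_canon) | is.na(raw[[dialect$owner_id]])
  dur <- NULL
  if (!is.null(dialect$duration_s) && dialect$duration_s %in% names(raw)) {
    dur <- suppressWarnings(as.integer(raw[[dialect$duration_s]]))
    bad <- bad | (!is.na(raw[[dialect$duration_s]]) & (is.na(dur) | dur < 0))
  }
  if (any(bad)) {
    rows <- which(bad)
    if (strict) {
      stop_input(sprintf(
        "Malformed CDR row %d in '%s' (unparseable timestamp, direction, or duration).",
        rows[1], path
      ))
    }
    warn(sprintf("Skipped %d malformed CDR row(s) in '%s' (first at row %d).",
                 length(rows), path, rows[1]))
  }

  records <- tibble::tibble(
    owner_id = as.character(raw[[dialect$owner_id]]),
    timestamp = ts,
    direction = factor(dir_canon, levels = c("outgoing", "incoming")),
    peer_id = if (!is.null(dialect$peer_id) && dialect$peer_id %in% names(raw)) {
      as.character(raw[[dialect$peer_id]])
    } else {
      NA_character_
    },
    duration_s = if (is.null(dur)) NA_integer_ else dur
  )[!bad, ]
  attr(records, "n_skipped") <- sum(bad)
  records
}

#' Write call records back to a delimited file
#'
#' Inverse of [read_cdr()]: writes the canonical record tibble using the same
#' dialect (column names, delimiter, direction tokens), so a read/write cycle
#' round-trips.
#'
#' @param records Tibble of call records as returned by [read_cdr()] or
#'   [generate_dataset()].
#' @param path Output file path.
#' @param dialect A [cdr_dialect()].
#' @return `path`, invisibly.
#' @export
write_cdr <- function(records, path, dialect = cdr_dialect()) {
  records <- validate_cdr(records)
  codes <- dialect$direction_codes
  out <- tibble::tibble(
    !!dialect$owner_id := records$owner_id,
    !!dialect$timestamp := format(records$timestamp, "%Y-%m-%dT%H:%M:%S"),
    !!dialect$direction := unname(codes[as.character(records$direction)]),
    !!dialect$peer_id := records$peer_id,
    !!dialect$duration_s := records$duration_s
  )
  readr::write_delim(out, path, delim = dialect$delim, na = "")
  invisible(path)
}

validate_cdr <- function(records) {
  needed <- c("owner_id", "timestamp", "direction")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop_contract(sprintf("Records lack column(s): %s.",
                          paste(missing_cols, collapse = ", ")))
  }
  if (!inherits(records$timestamp, "POSIXct")) {
    stop_contract("`timestamp` must be POSIXct.")
  }
  if (!all(records$direction %in% c("outgoing", "incoming"))) {
    stop_contract("`direction` must be 'outgoing' or 'incoming' for every record.")
  }
  if ("duration_s" %in% names(records) &&
      any(records$duration_s < 0, na.rm = TRUE)) {
    stop_contract("`duration_s` must be non-negative.")
  }
  records
}

#' Keep calls of one direction mode
#'
#' The analysis is run separately for outgoing, incoming, and total call
#' activity. `total` keeps every record; the other two filter by direction,
#' preserving order.
#'
#' @param records Tibble of call records.
#' @param mode One of `"outgoing"`, `"incoming"`, `"total"`.
#' @return The filtered tibble.
#' @export
select_direction <- function(records, mode = c("total", "outgoing", "incoming")) {
  mode <- match.arg(mode)
  records <- validate_cdr(records)
  if (mode == "total") {
    return(records)
  }
  records[records$direction == mode, ]
}
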