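# In-code fixtures: tiny record tibbles and hand-built rhythm tables.

utc <- function(x) as.POSIXct(x, tz = "UTC")

make_records <- function(owner, times, direction = "outgoing",
                         peer = NA_character_, duration = 60L) {
  tibble::tibble(
    owner_id = owner,
    timestamp = utc(times),
    direction = factor(direction, levels = c("outgoing", "incoming")),
    peer_id = peer,
    duration_s = as.integer(duration)
  )
}

# Build a daily_rhythm tibble directly from named lists of 24-bin fraction
# vectors: profiles[[period]][[owner]].
make_rhythms <- function(profiles, total_calls = 100L) {
  rows <- purrr::map_dfr(names(profiles), function(pd) {
    purrr::map_dfr(names(profiles[[pd]]), function(ow) {
      f <- profiles[[pd]][[ow]]
      stopifnot(length(f) == 24, abs(sum(f) - 1) < 1e-9)
      tibble::tibble(
        owner_id = ow, period = pd, hour = 0:23,
        n_calls = as.integer(round(f * total_calls)),
        fraction = f, total_calls = total_calls
      )
    })
  })
  rows$period <- factor(rows$period, levels = names(profiles))
  class(rows) <- c("daily_rhythm", class(tibble::tibble()))
  rows
}

point_mass <- function(hour) {
  f <- rep(0, 24)
  f[hour + 1] <- 1
  f
}

uniform_profile <- function() rep(1 / 24, 24)

# A random valid 24-bin distribution (for property-style loops).
random_profile <- function() {
  g <- rgamma(24, shape = runif(1, 0.3, 3))
  g / sum(g)
}

# Write a small CDR CSV and return its path (cleaned up with the test env).
write_fixture_csv <- function(lines, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = env)
  writeLines(lines, path)
  path
}
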