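#' Configure the synthetic CDR generator
#'
#' Parameters of the generative model behind [generate_dataset()]. The
#' defaults emulate the kind of study the method targets: 26 individuals
#' followed for 12 months split into two 182-day periods, a few hundred calls
#' per individual per period, individual-specific hourly profiles, and a
#' minority of individuals whose profile drifts between periods.
#'
#' @param n_individuals Number of individuals (`>= 2`; default 26).
#' @param n_periods Number of successive periods (`>= 2`; default 2).
#' @param period_days Length of each period in days (default 182, i.e. two
#'   6-month halves of a year).
#' @param mean_calls_per_period Poisson mean of an individual's call volume in
#'   one period (default 300).
#' @param profile_concentration Dirichlet concentration of the individual
#'   hourly profiles around the diurnal template; larger = flatter,
#'   more-alike profiles (default 5).
#' @param drift_fraction Share of individuals whose profile drifts between
#'   periods, i.e. the non-persistent ground truth (default 0.15).
#' @param drift_strength Mixing weight in `[0, 1]` toward a freshly drawn
#'   profile for drifting individuals at each period change; 1 (default)
#'   replaces the profile entirely.
#' @param direction_split Probability a call is outgoing (default 0.5).
#' @param start_date First day of the observation window (default
#'   `"2019-01-01"`).
#' @param seed Integer seed; all generator randomness flows through it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_individuals = 26, n_periods = 2,
                              period_days = 182, mean_calls_per_period = 300,
                              profile_concentration = 5, drift_fraction = 0.15,
                              drift_strength = 1, direction_split = 0.5,
                              start_date = "2019-01-01", seed = 1) {
  if (!is_scalar_number(n_individuals) || n_individuals < 2) {
    stop_config("`n_individuals` must be at least 2.")
  }
  if (!is_scalar_number(n_periods) || n_periods < 2) {
    stop_config("`n_periods` must be at least 2.")
  }
  for (nm in c("period_days", "mean_calls_per_period", "profile_concentration")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v <= 0) {
      stop_config(sprintf("`%s` must be positive.", nm))
    }
  }
  check_probability(drift_fraction, "drift_fraction", open = FALSE)
  check_probability(drift_strength, "drift_strength", open = FALSE)
  check_probability(direction_split, "direction_split", open = FALSE)
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      n_periods = as.integer(n_periods),
      period_days = as.integer(period_days),
      mean_calls_per_period = mean_calls_per_period,
      profile_concentration = profile_concentration,
      drift_fraction = drift_fraction,
      drift_strength = drift_strength,
      direction_split = direction_split,
      start_date = as.Date(start_date),
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Diurnal template for hourly call profiles
#'
#' A fixed 24-bin probability vector giving the population-level shape that
#' individual profiles are drawn around: very little mass overnight
#' (0-6 h, when people rarely phone), a morning ramp, a broad daytime
#' plateau, and an evening taper. Individual profiles are Dirichlet draws
#' centred on this template.
#'
#' @return Numeric vector of 24 probabilities summing to 1.
#' @export
diurnal_template <- function() {
  w <- c(rep(0.1, 7),          # 00-06: night
         0.6, 1.2,             # 07-08: morning ramp
         rep(1.6, 4),          # 09-12: late-morning peak
         rep(1.3, 5),          # 13-17: afternoon plateau
         rep(1.5, 3),          # 18-20: evening peak
         1.0, 0.5, 0.2)        # 21-23: taper
  w / sum(w)
}

#' Draw one individual's base hourly profile
#'
#' Samples a 24-bin probability vector from a Dirichlet distribution with
#' parameter `concentration * 24 * template` (gamma draws, normalized). With
#' the uniform template the draw concentrates around `1/24` per bin as
#' `concentration` grows; with the default [diurnal_template()] it yields
#' realistic, individually distinctive daily rhythms.
#'
#' Uses the current RNG state; seed control belongs to the caller (see
#' [generate_dataset()]).
#'
#' @param concentration Positive Dirichlet concentration.
#' @param template 24-bin probability vector of expected profile shape.
#' @return A 24-bin probability vector.
#' @export
sample_base_profile <- function(concentration = 5, template = diurnal_template()) {
  if (!is_scalar_number(concentration) || concentration <= 0) {
    stop_config("`concentration` must be positive.")
  }
  check_distribution(template, "template")
  if (length(template) != 24L) {
    stop_contract("`template` must have 24 bins.")
  }
  g <- rgamma(24L, shape = concentration * 24 * template, rate = 1)
  g / sum(g)
}

make_owner_ids <- function(n) {
  if (n <= 26L) LETTERS[seq_len(n)] else sprintf("ID%03d", seq_len(n))
}

#' Generate a synthetic CDR dataset with known ground truth
#'
#' Simulates a population of individuals, each with a base hourly calling
#' profile drawn from a Dirichlet law around the diurnal template. In every
#' period an individual places `Poisson(mean_calls_per_period)` calls; each
#' call's hour is sampled from the individual's period profile, its minute
#' uniformly, and its date uniformly within the period; direction is
#' `Bernoulli(direction_split)`. Persistent individuals keep their base
#' profile in every period; drifting individuals move toward a freshly drawn
#' profile at each period change by the mixing weight `drift_strength`
#' (`1` = complete redraw). Exactly `round(n * drift_fraction)` individuals
#' drift, chosen at random.
#'
#' Randomness is a single RNG stream seeded from `config$seed` (draw order:
#' drifting assignment, then per individual: base profile, then per period:
#' fresh profile if drifting, call count, hours, minutes, seconds, dates,
#' directions, peers, durations). The caller's RNG state is restored on exit,
#' so generation is reproducible and side-effect free.
#'
#' @param config A [simulation_config()].
#' @return A `cdr_simulation` list: `records` (a call-record tibble accepted
#'   by the whole pipeline), `truth` (tibble with `owner_id`, `persistent`,
#'   list-columns `profiles` — one 24-bin vector per period — and
#'   `calls_per_period`), and `config`.
#' @examples
#' sim <- generate_dataset(simulation_config(n_individuals = 5, seed = 7))
#' dplyr::count(sim$records, owner_id)
#' @export
generate_dataset <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config")) {
    stop_config("`config` must be created with simulation_config().")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(config$seed)

  n <- config$n_individuals
  owners <- make_owner_ids(n)
  n_drift <- round(n * config$drift_fraction)
  drifting <- owners %in% sample(owners, n_drift)
  peers <- sprintf("P%03d", seq_len(max(10L, 2L * n)))
  period_starts <- config$start_date + (seq_len(config$n_periods) - 1L) * config$period_days

  records <- vector("list", n)
  profiles <- vector("list", n)
  calls <- vector("list", n)
  for (i in seq_len(n)) {
    base <- sample_base_profile(config$profile_concentration)
    prof_k <- vector("list", config$n_periods)
    rec_k <- vector("list", config$n_periods)
    n_k <- integer(config$n_periods)
    current <- base
    for (k in seq_len(config$n_periods)) {
      if (k > 1L && drifting[i] && config$drift_strength > 0) {
        fresh <- sample_base_profile(config$profile_concentration)
        current <- (1 - config$drift_strength) * current +
          config$drift_strength * fresh
        current <- current / sum(current)
      }
      prof_k[[k]] <- current
      m <- rpois(1L, config$mean_calls_per_period)
      n_k[k] <- m
      if (m == 0L) {
        rec_k[[k]] <- NULL
        next
      }
      hour <- sample(0:23, m, replace = TRUE, prob = current)
      minute <- sample(0:59, m, replace = TRUE)
      second <- sample(0:59, m, replace = TRUE)
      day <- sample(0:(config$period_days - 1L), m, replace = TRUE)
      ts <- as.POSIXct(as.character(period_starts[k]), tz = "UTC") +
        day * 86400 + hour * 3600 + minute * 60 + second
      rec_k[[k]] <- tibble::tibble(
        owner_id = owners[i],
        timestamp = ts,
        direction = factor(
          ifelse(runif(m) < config$direction_split, "outgoing", "incoming"),
          levels = c("outgoing", "incoming")
        ),
        peer_id = sample(peers, m, replace = TRUE),
        duration_s = as.integer(round(rexp(m, rate = 1 / 120)))
      )
    }
    profiles[[i]] <- prof_k
    calls[[i]] <- n_k
    records[[i]] <- dplyr::bind_rows(rec_k)
  }

  records <- dplyr::arrange(dplyr::bind_rows(records), .data$owner_id,
                            .data$timestamp)
  truth <- tibble::tibble(
    owner_id = owners,
    persistent = !drifting,
    profiles = profiles,
    calls_per_period = calls
  )
  structure(list(records = records, truth = truth, config = config),
            class = "cdr_simulation")
}

#' Time partition matching a simulation's periods
#'
#' Builds the [time_partition()] whose boundaries are exactly the simulated
#' period boundaries, so no record is dropped and every call lands in the
#' period it was generated in.
#'
#' @param sim A `cdr_simulation` from [generate_dataset()], or a
#'   [simulation_config()].
#' @return A [time_partition()].
#' @export
simulation_partition <- function(sim) {
  config <- if (inherits(sim, "cdr_simulation")) sim$config else sim
  if (!inherits(config, "simulation_config")) {
    stop_config("`sim` must be a cdr_simulation or simulation_config.")
  }
  breaks <- config$start_date + (0:config$n_periods) * config$period_days
  time_partition(breaks)
}

#' Write a simulation to disk
#'
#' Writes the CDR table in the [cdr_dialect()] layout and a ground-truth JSON
#' sidecar (per individual: persistence flag, per-period profiles and
#' realized call counts), so a simulated study round-trips through the file
#' interface.
#'
#' @param sim A `cdr_simulation` from [generate_dataset()].
#' @param cdr_path Output CSV path.
#' @param truth_path Optional output JSON path for the ground truth.
#' @param dialect A [cdr_dialect()].
#' @return `cdr_path`, invisibly.
#' @export
write_simulation <- function(sim, cdr_path, truth_path = NULL,
                             dialect = cdr_dialect()) {
  if (!inherits(sim, "cdr_simulation")) {
    stop_config("`sim` must come from generate_dataset().")
  }
  write_cdr(sim$records, cdr_path, dialect)
  if (!is.null(truth_path)) {
    rlang::check_installed("jsonlite")
    truth <- purrr::map(seq_len(nrow(sim$truth)), function(i) {
      list(
        persistent = sim$truth$persistent[i],
        calls_per_period = sim$truth$calls_per_period[[i]],
        profiles = sim$truth$profiles[[i]]
      )
    })
    names(truth) <- sim$truth$owner_id
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(cdr_path)
}
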