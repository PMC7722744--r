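test_that("simulation_config validates its parameters", {
  cfg <- simulation_config()
  expect_equal(cfg$n_individuals, 26L)
  expect_equal(cfg$n_periods, 2L)
  expect_equal(cfg$period_days, 182L)
  expect_error(simulation_config(n_individuals = 1), class = "callrhythm_config_error")
  expect_error(simulation_config(drift_fraction = 1.2), class = "callrhythm_contract_error")
  expect_error(simulation_config(mean_calls_per_period = 0), class = "callrhythm_config_error")
})

test_that("base profiles are valid distributions that tighten with concentration", {
  withr::local_seed(31)
  draws <- purrr::map(1:50, ~sample_base_profile(5))
  expect_true(all(purrr::map_dbl(draws, sum) - 1 < 1e-12))
  expect_true(all(purrr::map_dbl(draws, min) >= 0))

  uniform <- rep(1 / 24, 24)
  dev <- function(conc) {
    mean(purrr::map_dbl(1:50, ~max(abs(sample_base_profile(conc, uniform) - 1 / 24))))
  }
  loose <- dev(2)
  tight <- dev(2000)
  expect_lt(tight, 0.01)   # near-uniform in the concentration limit
  expect_lt(tight, loose / 5)
})

test_that("generate_dataset is reproducible and leaves the caller's RNG alone", {
  cfg <- simulation_config(n_individuals = 6, seed = 77)
  sim1 <- generate_dataset(cfg)
  set.seed(123)
  before <- .Random.seed
  sim2 <- generate_dataset(cfg)
  expect_identical(before, .Random.seed) # RNG state restored
  expect_identical(sim1$records, sim2$records)
  expect_identical(sim1$truth$persistent, sim2$truth$persistent)

  # and byte-identical on disk
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_simulation(sim1, f1)
  write_simulation(sim2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("generated records feed the pipeline without drops and match the config", {
  cfg <- simulation_config(n_individuals = 10, seed = 41, drift_fraction = 0.2)
  sim <- generate_dataset(cfg)
  expect_s3_class(sim$records, "tbl_df")
  part <- simulation_partition(sim)
  assigned <- assign_periods(sim$records, part)
  expect_equal(attr(assigned, "n_dropped"), 0L)

  # realized counts agree with the per-period tallies in the ground truth
  tallies <- dplyr::count(assigned, owner_id, period)
  for (i in seq_len(nrow(sim$truth))) {
    ow <- sim$truth$owner_id[i]
    expect_equal(
      tallies$n[tallies$owner_id == ow],
      sim$truth$calls_per_period[[i]]
    )
  }
  # exactly round(n * drift_fraction) drifting individuals
  expect_equal(sum(!sim$truth$persistent), 2)
  # every period profile is a distribution
  sums <- purrr::map_dbl(purrr::flatten(sim$truth$profiles), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("total record volume is consistent with the Poisson volume model", {
  # total calls ~ Poisson(n * periods * mean); stay within 4 SD
  cfg <- simulation_config(n_individuals = 26, seed = 53)
  sim <- generate_dataset(cfg)
  lambda <- 26 * 2 * 300
  expect_lt(abs(nrow(sim$records) - lambda), 4 * sqrt(lambda))
})

test_that("simulations round-trip through the file interface with ground truth", {
  sim <- generate_dataset(simulation_config(n_individuals = 4, seed = 19))
  cdr <- withr::local_tempfile(fileext = ".csv")
  truth <- withr::local_tempfile(fileext = ".json")
  write_simulation(sim, cdr, truth)
  back <- read_cdr(cdr)
  expect_equal(nrow(back), nrow(sim$records))
  expect_equal(back$owner_id, sim$records$owner_id)
  expect_equal(back$timestamp, sim$records$timestamp)
  tj <- jsonlite::read_json(truth)
  expect_setequal(names(tj), sim$truth$owner_id)
  expect_equal(
    purrr::map_lgl(tj, "persistent")[sim$truth$owner_id],
    rlang::set_names(sim$truth$persistent, sim$truth$owner_id)
  )
})
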