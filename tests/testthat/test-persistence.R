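test_that("comparison_vector applies the strict success indicator", {
  expect_equal(comparison_vector(0.3, c(0.2, 0.4), c(0.1, 0.5)), c(1L, 0L, 1L, 0L))
  # y below every reference value: no inter distance beats it
  expect_equal(comparison_vector(0.05, c(0.2, 0.4), c(0.1, 0.5)), rep(0L, 4))
  # exact ties are failures under the strict inequality
  expect_equal(comparison_vector(0.3, 0.3, 0.3), c(0L, 0L))
  expect_error(comparison_vector(0.3, numeric(0), numeric(0)),
               class = "callrhythm_contract_error")
  expect_error(comparison_vector(0.3, c(0.1, 0.2), 0.1),
               class = "callrhythm_contract_error")
})

test_that("sign_test_pvalue is exact, monotone, and saturates at 1", {
  # spot grid against an independent pmf summation
  for (n in c(1, 7, 50, 64)) {
    for (q in c(0.25, 0.5, 0.75)) {
      expect_equal(
        sign_test_pvalue(0:n, n, q),
        cumsum(stats::dbinom(0:n, n, q)),
        tolerance = 1e-12
      )
    }
  }
  expect_equal(sign_test_pvalue(50, 50, 0.5), 1)
  expect_equal(sign_test_pvalue(0, 50, 0.5), 0.5^50)
  expect_equal(sign_test_pvalue(1, 50, 0.5), 51 * 0.5^50)
  p <- sign_test_pvalue(0:50, 50, 0.5)
  expect_true(all(diff(p) >= 0))
  expect_error(sign_test_pvalue(-1, 50), class = "callrhythm_contract_error")
  expect_error(sign_test_pvalue(51, 50), class = "callrhythm_contract_error")
  expect_error(sign_test_pvalue(5, 50, q = 1), class = "callrhythm_contract_error")
})

test_that("assess_pair wires dissimilarities into the sign test", {
  # focal individual A keeps its rhythm; everyone else differs strongly
  rhythms <- make_rhythms(list(
    T1 = list(A = point_mass(9), B = uniform_profile(), C = point_mass(3),
              D = point_mass(15)),
    T2 = list(A = point_mass(9), B = uniform_profile(), C = point_mass(4),
              D = point_mass(16))
  ))
  res <- assess_pair(rhythms, "A")
  expect_s3_class(res, "persistence_test")
  expect_equal(res$y, 0)
  expect_equal(res$n_comp, 2 * 4 - 2)
  expect_equal(res$n_plus, 0)
  expect_equal(res$p_value, 0.5^6)
  expect_true(res$persistent)

  g <- glance(res)
  expect_equal(g$individual, "A")
  expect_equal(g$n_plus, 0)
  td <- tidy(res)
  expect_equal(nrow(td), 1 + 6)
  expect_equal(td$comparator_id[1], "self")
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("the verdict is invariant to the divergence log base and to monotone transforms", {
  withr::local_seed(13)
  profs <- function() list(A = random_profile(), B = random_profile(),
                           C = random_profile(), D = random_profile(),
                           E = random_profile())
  rhythms <- make_rhythms(list(T1 = profs(), T2 = profs()))
  for (ow in c("A", "C", "E")) {
    r2 <- assess_pair(rhythms, ow, base = 2)
    re <- assess_pair(rhythms, ow, base = exp(1))
    expect_equal(r2$z, re$z)
    expect_equal(r2$n_plus, re$n_plus)
    expect_equal(r2$p_value, re$p_value)
  }
  # any strictly increasing transform of the dissimilarities leaves z, N+, p alone
  y <- 0.37
  x_a <- c(0.2, 0.5, 0.37, 0.9)
  x_b <- c(0.41, 0.1, 0.8, 0.36)
  g <- function(v) log1p(v)^2
  expect_equal(comparison_vector(y, x_a, x_b),
               comparison_vector(g(y), g(x_a), g(x_b)))
})

test_that("assess_sequence applies the second-level sign test", {
  # focal A stable over 4 periods against 3 distinct comparators:
  # every consecutive pair is persistent, v = (1,1,1), p = 0.5^3
  mk <- function(a_hour) list(A = point_mass(a_hour), B = uniform_profile(),
                              C = point_mass(3), D = point_mass(15))
  rhythms <- make_rhythms(list(T1 = mk(9), T2 = mk(9), T3 = mk(9), T4 = mk(9)))
  st <- assess_sequence(rhythms, "A")
  expect_s3_class(st, "sequence_test")
  expect_equal(st$v, c(1L, 1L, 1L))
  expect_equal(st$p_value, 0.125)
  expect_false(st$trend_persistent) # short sequences have little power
  expect_equal(nrow(tidy(st)), 3)
  expect_equal(glance(st)$n_persistent_pairs, 3)

  # focal drifts to a fresh disjoint hour each period: y = 1 never strictly
  # exceeded by any reference distance, so no pair is persistent
  rhythms2 <- make_rhythms(list(T1 = mk(0), T2 = mk(1), T3 = mk(2), T4 = mk(5)))
  st2 <- assess_sequence(rhythms2, "A")
  expect_equal(sum(st2$v), 0)
  expect_equal(st2$p_value, 1)

  expect_error(assess_sequence(make_rhythms(list(T1 = mk(9), T2 = mk(9))), "A"),
               class = "callrhythm_contract_error")
})

test_that("a fully persistent direction gives p = 0.5^(N_T - 1) in the sequence test", {
  mk <- function() list(A = point_mass(9), B = uniform_profile(),
                        C = point_mass(3), D = point_mass(15))
  periods <- paste0("T", 1:8)
  rhythms <- make_rhythms(stats::setNames(purrr::map(periods, ~mk()), periods))
  st <- assess_sequence(rhythms, "A")
  expect_equal(st$v, rep(1L, 7))
  expect_equal(st$p_value, 0.5^7)
  expect_true(st$trend_persistent)
})

test_that("analyze_population reports every individual per mode and is deterministic", {
  sim <- generate_dataset(simulation_config(n_individuals = 8, seed = 21))
  part <- simulation_partition(sim)
  res1 <- analyze_population(sim$records, part, modes = c("outgoing", "total"))
  res2 <- analyze_population(sim$records, part, modes = c("outgoing", "total"))
  expect_identical(res1, res2)
  expect_equal(nrow(res1), 8 * 2)
  expect_true(all(res1$n_comp == 2 * 8 - 2))
  expect_true(all(res1$persistent == (res1$p_value < 0.05)))
})

test_that("individuals with an empty period are excluded and N_comp shrinks", {
  withr::local_seed(99)
  n_calls <- 40
  owners <- c("A", "B", "C", "D", "E")
  rec <- purrr::map_dfr(owners, function(ow) {
    ts <- utc("2019-01-01") + round(runif(n_calls, 0, 363 * 86400))
    if (ow == "E") ts <- ts[ts < utc("2019-07-02")] # E silent in T2
    make_records(ow, ts, direction = sample(c("outgoing", "incoming"),
                                            length(ts), replace = TRUE))
  })
  part <- time_partition(c("2019-01-01", "2019-07-02", "2019-12-31"))
  res <- suppressMessages(
    analyze_population(rec, part, modes = "total")
  )
  expect_equal(nrow(res), 5)
  e_row <- res[res$individual == "E", ]
  expect_match(e_row$excluded_reason, "no calls")
  expect_true(is.na(e_row$p_value))
  kept <- res[res$individual != "E", ]
  expect_true(all(kept$n_comp == 2 * 4 - 2)) # E removed as comparator too
})

test_that("Benjamini-Hochberg adjustment is available but changes only the verdict column", {
  sim <- generate_dataset(simulation_config(n_individuals = 8, seed = 22))
  part <- simulation_partition(sim)
  plain <- analyze_population(sim$records, part, modes = "total")
  bh <- analyze_population(sim$records, part, modes = "total", adjust = "BH")
  expect_equal(bh$p_value, plain$p_value)
  expect_equal(bh$p_adjusted, stats::p.adjust(plain$p_value, "BH"))
  expect_true(all(bh$p_adjusted >= bh$p_value))
})
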