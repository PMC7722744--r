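#' Compare intra- against inter-individual dissimilarities
#'
#' Builds the binary success vector `z_i`: for each inter-individual
#' dissimilarity `x` (first all of period a, then all of period b), a success
#' (`1`) is recorded when `y_i - x > 0`: the inter-individual dissimilarity is
#' strictly *lower* than the intra-individual one. Exact ties are failures
#' (strict inequality), which is conservative for declaring persistence.
#'
#' @param y Intra-individual dissimilarity `y_i`.
#' @param x_a,x_b Numeric vectors of inter-individual dissimilarities in the
#'   two periods (equal length, non-empty).
#' @return Integer vector of 0/1 of length `length(x_a) + length(x_b)`.
#' @examples
#' comparison_vector(0.3, c(0.2, 0.4), c(0.1, 0.5)) # 1 0 1 0
#' @export
comparison_vector <- function(y, x_a, x_b) {
  if (!is_scalar_number(y) || y < 0) {
    stop_contract("`y` must be a single non-negative dissimilarity.")
  }
  if (length(x_a) == 0 || length(x_b) == 0 || length(x_a) != length(x_b)) {
    stop_contract("`x_a` and `x_b` must be non-empty and of equal length.")
  }
  x <- c(x_a, x_b)
  if (anyNA(x) || any(x < 0)) {
    stop_contract("Inter-individual dissimilarities must be non-negative and non-missing.")
  }
  as.integer(y - x > 0)
}

#' Exact lower-tail binomial p-value for the sign test
#'
#' Under the null hypothesis each of the `N_comp = 2n - 2` comparisons has
#' probability `q` (default 1/2, the median test) of being a success, so the
#' success count is `Binomial(N_comp, q)`. The p-value is the exact lower
#' tail `P(X <= N_plus)`, computed by direct summation of the binomial pmf in
#' log space — no normal approximation. A *small* count of successes (the
#' individual's own rhythm rarely beaten by others') gives a small p-value
#' and supports persistence.
#'
#' @param n_plus Number of successes (vectorized).
#' @param n_comp Number of comparisons.
#' @param q Null success probability, in (0, 1).
#' @return p-value(s) in `[0, 1]`.
#' @examples
#' sign_test_pvalue(0, 50)  # 0.5^50 = 8.88e-16
#' sign_test_pvalue(14, 50) # 1.30e-03
#' @export
sign_test_pvalue <- function(n_plus, n_comp, q = 0.5) {
  if (!is_scalar_number(n_comp) || n_comp < 1 || n_comp != round(n_comp)) {
    stop_contract("`n_comp` must be a positive integer.")
  }
  check_probability(q, "q")
  if (!is.numeric(n_plus) || length(n_plus) < 1 || anyNA(n_plus) ||
      any(n_plus < 0 | n_plus > n_comp | n_plus != round(n_plus))) {
    stop_contract("`n_plus` must be integer(s) in [0, n_comp].")
  }
  vapply(n_plus, function(np) {
    k <- 0:np
    min(sum(exp(lchoose(n_comp, k) + k * log(q) + (n_comp - k) * log1p(-q))), 1)
  }, numeric(1))
}

# Exact upper tail P(X >= s) for X ~ Binomial(n, q), same summation route.
binom_upper_tail <- function(s, n, q = 0.5) {
  if (s <= 0) {
    return(1)
  }
  k <- s:n
  min(sum(exp(lchoose(n, k) + k * log(q) + (n - k) * log1p(-q))), 1)
}

# Individuals usable for a mode: a rhythm (>= 1 call) in every listed period.
included_individuals <- function(rhythms, periods) {
  tab <- unique(rhythms[, c("owner_id", "period")])
  tab <- tab[tab$period %in% periods, ]
  counts <- table(tab$owner_id)
  sort(names(counts)[counts == length(periods)])
}

#' Test the persistence of one individual's rhythm across two periods
#'
#' Runs the full two-period procedure for a focal individual against the
#' population in a `daily_rhythm` tibble: intra-individual dissimilarity
#' `y_i` between the two periods, the `2n - 2` inter-individual
#' dissimilarities (both periods), the comparison vector, and the exact
#' binomial sign test. Individuals without a rhythm in *both* periods are
#' excluded from the population entirely (as focal and comparator), keeping
#' the two periods' reference samples balanced; `n` and `N_comp = 2n - 2`
#' refer to the included population.
#'
#' @param rhythms A `daily_rhythm` tibble covering the population.
#' @param owner Focal individual's `owner_id`.
#' @param periods The two period labels; defaults to the first two levels of
#'   `rhythms$period`.
#' @param q Null success probability (default 1/2).
#' @param alpha Significance level (default 0.05).
#' @param base Logarithm base for the divergence (default 2; the test result
#'   is invariant to this choice).
#' @return A `persistence_test` object; see [tidy()], [glance()],
#'   [autoplot()].
#' @export
assess_pair <- function(rhythms, owner, periods = NULL, q = 0.5, alpha = 0.05,
                        base = 2) {
  check_probability(q, "q")
  check_probability(alpha, "alpha")
  periods <- resolve_periods(rhythms, periods, expected = 2L)
  included <- included_individuals(rhythms, periods)
  if (!(owner %in% included)) {
    abort(
      sprintf("Individual '%s' lacks a rhythm in both periods ('%s', '%s').",
              owner, periods[1], periods[2]),
      class = c("callrhythm_missing_profile", "callrhythm_contract_error")
    )
  }
  if (length(included) < 2) {
    abort("Fewer than 2 individuals have rhythms in both periods.",
          class = c("callrhythm_population_too_small", "callrhythm_contract_error"))
  }
  comparators <- setdiff(included, owner)
  y <- intra_dissimilarity(rhythms, owner, periods[1], periods[2], base = base)
  x_a <- inter_dissimilarities(rhythms, owner, periods[1], comparators, base = base)
  x_b <- inter_dissimilarities(rhythms, owner, periods[2], comparators, base = base)
  z <- comparison_vector(y, x_a$distance, x_b$distance)
  n_plus <- sum(z)
  n_comp <- length(z)
  p_value <- sign_test_pvalue(n_plus, n_comp, q)
  structure(
    list(
      owner_id = owner, periods = periods, y = y,
      inter = dplyr::bind_rows(x_a, x_b), z = z,
      n_plus = n_plus, n_comp = n_comp, n_included = length(included),
      q = q, alpha = alpha, base = base,
      p_value = p_value, persistent = p_value < alpha
    ),
    class = "persistence_test"
  )
}

resolve_periods <- function(rhythms, periods, expected = NULL) {
  all_periods <- if (is.factor(rhythms$period)) {
    levels(rhythms$period)
  } else {
    unique(as.character(rhythms$period))
  }
  if (is.null(periods)) {
    periods <- if (is.null(expected)) all_periods else head(all_periods, expected)
  }
  periods <- as.character(periods)
  if (!all(periods %in% unique(as.character(rhythms$period)))) {
    stop_contract("Some requested periods have no rhythms at all.")
  }
  if (!is.null(expected) && length(periods) != expected) {
    stop_contract(sprintf("Exactly %d periods are required here, got %d.",
                          expected, length(periods)))
  }
  periods
}

#' Trend persistence across more than two successive periods
#'
#' For `N_T >= 3` successive periods, the two-period test is run on each
#' consecutive pair and its outcome is coded as a binary event (1 =
#' significant persistence at `alpha`). A second-level exact sign test on the
#' resulting vector `v` of length `N_T - 1` — upper tail of
#' `Binomial(N_T - 1, 1/2)` at the number of persistence events — asks
#' whether persistent pairs dominate the sequence.
#'
#' @inheritParams assess_pair
#' @param periods Ordered period labels (`>= 3`); defaults to all levels in
#'   order.
#' @return A `sequence_test` object with the per-pair results, `v`, the
#'   sequence p-value, and the `trend_persistent` verdict.
#' @export
assess_sequence <- function(rhythms, owner, periods = NULL, q = 0.5,
                            alpha = 0.05, base = 2) {
  periods <- resolve_periods(rhythms, periods)
  if (length(periods) < 3) {
    stop_contract("assess_sequence() needs at least 3 periods; use assess_pair() for 2.")
  }
  pairs <- purrr::map(seq_len(length(periods) - 1), function(k) {
    assess_pair(rhythms, owner, periods = periods[k:(k + 1)],
                q = q, alpha = alpha, base = base)
  })
  v <- as.integer(purrr::map_lgl(pairs, "persistent"))
  p_value <- binom_upper_tail(sum(v), length(v), 0.5)
  structure(
    list(
      owner_id = owner, periods = periods, per_pair = pairs, v = v,
      q = q, alpha = alpha, p_value = p_value,
      trend_persistent = p_value < alpha
    ),
    class = "sequence_test"
  )
}

#' Run the persistence analysis over a whole population
#'
#' The end-to-end pipeline: for each direction mode, records are filtered,
#' daily rhythms computed per period, individuals without a rhythm in every
#' period excluded (with the reason reported in the output), and each
#' remaining individual tested — with [assess_pair()] when the partition has
#' two periods, or [assess_sequence()] when it has more. Output mirrors the
#' usual results-table layout: one row per individual x mode with the
#' p-value, success count `N+`, and comparison count `N_comp`.
#'
#' @param records Tibble of call records (no `period` column needed).
#' @param partition A [time_partition()]; defaults to splitting the
#'   observation window into two equal periods.
#' @param modes Direction modes to analyze.
#' @param q Null success probability (default 1/2).
#' @param alpha Significance level (default 0.05).
#' @param base Logarithm base for the divergence.
#' @param adjust `"none"` (default; per-individual reporting at `alpha`) or
#'   `"BH"` for Benjamini-Hochberg adjustment within each mode.
#' @return A tibble with columns `individual`, `mode`, `y`, `n_plus`,
#'   `n_comp`, `p_value`, `persistent`, `excluded_reason` (two periods), or
#'   the analogous sequence columns (`n_persistent_pairs`, `n_pairs`) for
#'   longer partitions. Excluded individuals appear with `NA` statistics.
#' @export
analyze_population <- function(records, partition = NULL,
                               modes = c("outgoing", "incoming", "total"),
                               q = 0.5, alpha = 0.05, base = 2,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  modes <- match.arg(modes, several.ok = TRUE)
  records <- validate_cdr(records)
  if (is.null(partition)) {
    partition <- equal_partition(records, 2)
  }
  periods <- partition$period
  all_owners <- sort(unique(records$owner_id))
  two_periods <- length(periods) == 2

  res <- purrr::map_dfr(modes, function(mode) {
    sub <- select_direction(records, mode)
    sub <- assign_periods(sub, partition)
    rhythms <- if (nrow(sub) > 0) daily_rhythms(sub) else NULL
    included <- if (is.null(rhythms)) character(0) else {
      included_individuals(rhythms, periods)
    }
    excluded <- setdiff(all_owners, included)
    if (length(included) < 2) {
      return(tibble::tibble(
        individual = all_owners, mode = mode,
        excluded_reason = "population too small after exclusions"
      ))
    }
    rhythms <- rhythms[rhythms$owner_id %in% included, ]

    if (two_periods) {
      rows <- purrr::map_dfr(included, function(i) {
        glance(assess_pair(rhythms, i, periods = periods, q = q,
                           alpha = alpha, base = base))
      })
      rows <- dplyr::transmute(
        rows,
        individual = .data$individual, mode = mode, y = .data$y,
        n_plus = .data$n_plus, n_comp = .data$n_comp,
        p_value = .data$p_value, persistent = .data$persistent,
        excluded_reason = NA_character_
      )
    } else {
      rows <- purrr::map_dfr(included, function(i) {
        glance(assess_sequence(rhythms, i, periods = periods, q = q,
                               alpha = alpha, base = base))
      })
      rows$mode <- mode
      rows$excluded_reason <- NA_character_
      rows <- dplyr::relocate(rows, "individual", "mode")
    }
    if (adjust == "BH") {
      rows$p_adjusted <- stats::p.adjust(rows$p_value, method = "BH")
      rows$persistent <- rows$p_adjusted < alpha
    }
    if (length(excluded) > 0) {
      rows <- dplyr::bind_rows(
        rows,
        tibble::tibble(individual = excluded, mode = mode,
                       excluded_reason = "no calls in at least one period")
      )
    }
    dplyr::arrange(rows, .data$individual)
  })
  attr(res, "alpha") <- alpha
  attr(res, "q") <- q
  res
}
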