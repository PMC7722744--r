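#' Jensen-Shannon divergence between two hourly distributions
#'
#' The symmetrized, bounded Kullback-Leibler divergence through the mixture
#' `M = (P + Q) / 2`:
#' `JSD(P, Q) = KL(P || M) / 2 + KL(Q || M) / 2`,
#' with the convention `0 * log(0 / m) = 0`. Bins where both distributions are
#' zero contribute nothing. With `base = 2` the divergence lies in `[0, 1]`.
#'
#' @param p,q Probability vectors of equal length (each sums to 1).
#' @param base Logarithm base (`> 1`); default 2, so the value is in bits.
#' @return A single non-negative number.
#' @examples
#' js_divergence(c(0.5, 0.5, rep(0, 22)), c(1, rep(0, 23))) # 0.3112781...
#' @export
js_divergence <- function(p, q, base = 2) {
  check_distribution(p, "p")
  check_distribution(q, "q")
  if (length(p) != length(q)) {
    stop_contract("`p` and `q` must have the same length.")
  }
  if (!is_scalar_number(base) || base <= 1) {
    stop_contract("`base` must be a number > 1.")
  }
  m <- (p + q) / 2
  kl <- function(a) {
    keep <- a > 0
    sum(a[keep] * log(a[keep] / m[keep]))
  }
  (kl(p) + kl(q)) / (2 * log(base))
}

check_distribution <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop_contract(sprintf("`%s` must be a non-negative numeric vector.", name))
  }
  if (abs(sum(x) - 1) > 1e-6) {
    stop_contract(sprintf("`%s` must sum to 1 (got %.8f).", name, sum(x)))
  }
  invisible(x)
}

#' Jensen-Shannon distance between two daily rhythms
#'
#' The square root of [js_divergence()], which is a proper metric on
#' probability distributions (symmetric, zero only for identical
#' distributions, triangle inequality). With `base = 2` it lies in `[0, 1]`.
#' This is the dissimilarity `D` used for both intra- and inter-individual
#' comparisons.
#'
#' @inheritParams js_divergence
#' @return A single number in `[0, 1]` for `base = 2`.
#' @export
rhythm_distance <- function(p, q, base = 2) {
  sqrt(max(js_divergence(p, q, base = base), 0))
}

#' Intra-individual dissimilarity between two periods
#'
#' `y_i = D_self(i, T_a, T_b)`: the Jensen-Shannon distance between one
#' individual's daily rhythms in two (successive) periods. Small values mean
#' the individual kept a similar hourly calling pattern.
#'
#' @param rhythms A `daily_rhythm` tibble from [daily_rhythms()].
#' @param owner Focal individual's `owner_id`.
#' @param period_a,period_b The two period labels.
#' @param base Logarithm base for the divergence (default 2).
#' @return A single distance.
#' @export
intra_dissimilarity <- function(rhythms, owner, period_a, period_b, base = 2) {
  p <- rhythm_profile(rhythms, owner, period_a)
  q <- rhythm_profile(rhythms, owner, period_b)
  rhythm_distance(p, q, base = base)
}

#' Inter-individual dissimilarities within one period
#'
#' `x_{i,j}^{T_k} = D_ref(i, j, T_k)`: the Jensen-Shannon distance between the
#' focal individual's rhythm and every other individual's rhythm within the
#' same period. These `n - 1` values are the reference sample the
#' intra-individual dissimilarity is ranked against.
#'
#' @inheritParams intra_dissimilarity
#' @param period Period label.
#' @param comparators Optional character vector restricting (and ordering) the
#'   comparator individuals; defaults to everyone else with a rhythm in the
#'   period.
#' @return A tibble `focal_id`, `comparator_id`, `period`, `distance`.
#' @export
inter_dissimilarities <- function(rhythms, owner, period, comparators = NULL,
                                  base = 2) {
  present <- unique(rhythms$owner_id[rhythms$period == period])
  if (is.null(comparators)) {
    comparators <- sort(setdiff(present, owner))
  } else {
    comparators <- setdiff(comparators, owner)
  }
  if (!(owner %in% present) || length(comparators) < 1) {
    abort(
      sprintf("Need the focal individual and at least one comparator with a rhythm in period '%s'.", period),
      class = c("callrhythm_population_too_small", "callrhythm_contract_error")
    )
  }
  p <- rhythm_profile(rhythms, owner, period)
  dist <- purrr::map_dbl(
    comparators,
    function(j) rhythm_distance(p, rhythm_profile(rhythms, j, period), base = base)
  )
  tibble::tibble(
    focal_id = owner, comparator_id = comparators,
    period = period, distance = dist
  )
}
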