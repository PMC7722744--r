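#' Tidy the dissimilarities behind a persistence test
#'
#' One row per dissimilarity: the intra-individual value (`comparator_id =
#' "self"`, spanning the two periods) followed by every inter-individual
#' value with its comparison outcome. Suitable as an audit dump of the test.
#'
#' @param x A `persistence_test` from [assess_pair()].
#' @param ... Ignored.
#' @return A tibble `focal_id`, `comparator_id`, `period`, `distance`,
#'   `success`.
#' @method tidy persistence_test
#' @export
tidy.persistence_test <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(
      focal_id = x$owner_id, comparator_id = "self",
      period = paste(x$periods, collapse = "|"),
      distance = x$y, success = NA
    ),
    tibble::tibble(
      focal_id = x$inter$focal_id, comparator_id = x$inter$comparator_id,
      period = as.character(x$inter$period), distance = x$inter$distance,
      success = as.logical(x$z)
    )
  )
}

#' One-row summary of a persistence test
#'
#' @param x A `persistence_test` from [assess_pair()].
#' @param ... Ignored.
#' @return A one-row tibble: `individual`, `y`, `n_plus`, `n_comp`,
#'   `n_included`, `q`, `alpha`, `p_value`, `persistent`.
#' @method glance persistence_test
#' @export
glance.persistence_test <- function(x, ...) {
  tibble::tibble(
    individual = x$owner_id, y = x$y, n_plus = x$n_plus, n_comp = x$n_comp,
    n_included = x$n_included, q = x$q, alpha = x$alpha,
    p_value = x$p_value, persistent = x$persistent
  )
}

#' Tidy the per-pair results of a sequence test
#'
#' @param x A `sequence_test` from [assess_sequence()].
#' @param ... Ignored.
#' @return One row per consecutive period pair with that pair's test summary
#'   and the binary persistence event.
#' @method tidy sequence_test
#' @export
tidy.sequence_test <- function(x, ...) {
  purrr::map_dfr(seq_along(x$per_pair), function(k) {
    g <- glance(x$per_pair[[k]])
    g$pair <- paste(x$per_pair[[k]]$periods, collapse = "|")
    g$event <- x$v[k]
    dplyr::relocate(g, "individual", "pair", "event")
  })
}

#' One-row summary of a sequence test
#'
#' @param x A `sequence_test` from [assess_sequence()].
#' @param ... Ignored.
#' @return A one-row tibble: `individual`, `n_persistent_pairs`, `n_pairs`,
#'   `p_value`, `persistent`.
#' @method glance sequence_test
#' @export
glance.sequence_test <- function(x, ...) {
  tibble::tibble(
    individual = x$owner_id,
    n_persistent_pairs = sum(x$v), n_pairs = length(x$v),
    p_value = x$p_value, persistent = x$trend_persistent
  )
}

#' @export
print.persistence_test <- function(x, ...) {
  cat(sprintf(
    "Persistence sign test: individual '%s', periods %s\n",
    x$owner_id, paste(x$periods, collapse = " vs ")
  ))
  cat(sprintf("  y (intra) = %.4f; N+ = %d of N_comp = %d (q = %g)\n",
              x$y, x$n_plus, x$n_comp, x$q))
  cat(sprintf("  p-value = %s -> %s at alpha = %g\n",
              format_pvalue(x$p_value),
              if (x$persistent) "persistent" else "not persistent", x$alpha))
  invisible(x)
}

#' @export
print.sequence_test <- function(x, ...) {
  cat(sprintf(
    "Sequential persistence test: individual '%s', %d periods\n",
    x$owner_id, length(x$periods)
  ))
  cat(sprintf("  v = [%s]; persistence events: %d of %d pairs\n",
              paste(x$v, collapse = " "), sum(x$v), length(x$v)))
  cat(sprintf("  sequence p-value = %s -> %s at alpha = %g\n",
              format_pvalue(x$p_value),
              if (x$trend_persistent) "trend persistent" else "no persistent trend",
              x$alpha))
  invisible(x)
}

#' Plot a persistence test
#'
#' Histograms of the inter-individual dissimilarities per period with the
#' intra-individual dissimilarity `y_i` as a vertical line: persistence shows
#' as `y_i` sitting in the left tail of both reference samples.
#'
#' @param object A `persistence_test` from [assess_pair()].
#' @param bins Histogram bin count.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot persistence_test
#' @export
autoplot.persistence_test <- function(object, bins = 15, ...) {
  ggplot2::ggplot(object$inter, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey35") +
    ggplot2::geom_vline(xintercept = object$y, colour = "firebrick",
                        linewidth = 0.8) +
    ggplot2::facet_wrap(~period) +
    ggplot2::labs(
      x = "Jensen-Shannon distance", y = "Comparators",
      title = sprintf("Individual %s: y = %.3f, N+ = %d/%d, p = %s",
                      object$owner_id, object$y, object$n_plus, object$n_comp,
                      format_pvalue(object$p_value))
    ) +
    ggplot2::theme_minimal()
}
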