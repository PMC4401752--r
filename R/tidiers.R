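#' Tidy an automaton into a transition table
#'
#' One row per transition: `from`, `symbol`, `to`, plus counts and
#' probabilities where the automaton carries them.
#'
#' @param x A `dsfa`, `freq_automaton` or `dfa`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.dsfa <- function(x, ...) {
  purrr::map_dfr(seq_along(x$p_end), function(i) {
    tr <- x$trans[[i]]
    if (length(tr) == 0) return(NULL)
    tibble(
      from = i, symbol = names(tr), to = unname(tr),
      count = unname(x$counts[[i]][names(tr)]),
      probability = unname(x$probs[[i]][names(tr)])
    )
  })
}

#' @rdname tidy.dsfa
#' @exportS3Method generics::tidy
tidy.freq_automaton <- function(x, ...) {
  purrr::map_dfr(which(x$alive), function(i) {
    tr <- x$trans[[i]]
    if (length(tr) == 0) return(NULL)
    tibble(
      from = i, symbol = names(tr), to = unname(tr),
      count = unname(x$counts[[i]][names(tr)])
    )
  })
}

#' @rdname tidy.dsfa
#' @exportS3Method generics::tidy
tidy.dfa <- function(x, ...) {
  purrr::map_dfr(seq_along(x$accepting), function(i) {
    tr <- x$trans[[i]]
    if (length(tr) == 0) return(NULL)
    tibble(from = i, symbol = names(tr), to = unname(tr))
  })
}

#' One-row model summaries
#'
#' @param x A `dsfa`, `freq_automaton` or `dfa`.
#' @param ... Unused.
#' @return A one-row tibble (state counts, alphabet size, key parameters).
#' @exportS3Method generics::glance
glance.dsfa <- function(x, ...) {
  tibble(
    n_states = length(x$p_end),
    n_transitions = sum(lengths(x$trans)),
    alphabet_size = length(x$alphabet),
    smoothing = x$smoothing,
    alpha = x$meta$alpha %||% NA_real_,
    n_training = x$meta$n_training %||% NA_integer_,
    normalization_residual = stochastic_residual(x)
  )
}

#' @rdname glance.dsfa
#' @exportS3Method generics::glance
glance.freq_automaton <- function(x, ...) {
  tibble(
    n_states = sum(x$alive),
    n_transitions = sum(lengths(x$trans[x$alive])),
    alphabet_size = length(x$alphabet),
    n_training = x$n[x$initial]
  )
}

#' @rdname glance.dsfa
#' @exportS3Method generics::glance
glance.dfa <- function(x, ...) {
  tibble(
    n_states = length(x$accepting),
    n_accepting = sum(x$accepting),
    n_transitions = sum(lengths(x$trans)),
    alphabet_size = length(x$alphabet)
  )
}

#' Plot an ROC sweep
#'
#' Sensitivity against false-positive rate over the threshold grid produced by
#' [roc_points()].
#'
#' @param object A `phosgram_roc` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.phosgram_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$sn)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "False positive rate (1 - Sp)", y = "Sensitivity (Sn)",
      title = "ROC over the decision-threshold grid"
    ) +
    ggplot2::theme_minimal()
}

#' Plot bootstrap metric distributions
#'
#' One boxplot per metric across the bootstrap resamples returned by
#' [bootstrap_evaluate()].
#'
#' @param object A `phosgram_boot` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.phosgram_boot <- function(object, ...) {
  long <- tidyr_pivot(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(
      x = NULL, y = "Value",
      title = "Bootstrap distribution of evaluation metrics"
    ) +
    ggplot2::theme_minimal()
}

# minimal long-format reshape (avoids a tidyr dependency for one call)
tidyr_pivot <- function(object) {
  metrics <- c("precision", "recall", "accuracy", "f_measure", "sn", "sp")
  purrr::map_dfr(metrics, function(m) {
    tibble(resample = object$resample, metric = m, value = object[[m]])
  })
}
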