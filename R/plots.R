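#' Plot a predictive distribution
#'
#' Bar chart of the next-note probability over the pitch alphabet, with
#' pitch names on the x axis.
#'
#' @param object A [pred_dist()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pred_dist <- function(object, ...) {
  df <- tibble::tibble(
    pitch = factor(pitch_name(object$pitch), levels = pitch_name(object$pitch)),
    p = object$p
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pitch, y = .data$p)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(
      x = NULL, y = "p(next pitch)",
      subtitle = sprintf(
        "H = %.2f bits, Hnorm = %.2f",
        entropy_bits(object), normalized_entropy(object)
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot per-note entropy profiles over a corpus
#'
#' @param scores Output of [score_corpus_notes()].
#' @param max_melodies Melodies per style to draw.
#' @return A ggplot object.
#' @export
plot_entropy_profiles <- function(scores, max_melodies = 6) {
  keep <- scores |>
    dplyr::distinct(.data$style, .data$melody_id) |>
    dplyr::group_by(.data$style) |>
    dplyr::slice_head(n = max_melodies) |>
    dplyr::ungroup()
  df <- dplyr::semi_join(scores, keep, by = c("style", "melody_id"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$note_index, y = .data$entropy, group = .data$melody_id
  )) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~style) +
    ggplot2::labs(x = "note position", y = "entropy (bits)") +
    ggplot2::theme_minimal()
}

#' Plot a model-comparison grid
#'
#' Dot plot of the correlation columns per model row.
#'
#' @param comparison A `"model_comparison"` tibble.
#' @param measure One of `"unexp"`, `"inferred"`, `"explicit"`.
#' @return A ggplot object.
#' @export
plot_model_comparison <- function(comparison,
                                  measure = c("unexp", "inferred", "explicit")) {
  measure <- match.arg(measure)
  cols <- grep(paste0("^r_", measure), names(comparison), value = TRUE)
  df <- comparison |>
    dplyr::select("model", dplyr::all_of(cols)) |>
    tidyr::pivot_longer(-"model", names_to = "group", values_to = "r") |>
    dplyr::mutate(group = sub(paste0("r_", measure, "_"), "", .data$group)) |>
    dplyr::filter(!is.na(.data$r))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$r, y = .data$model, colour = .data$group
  )) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("Spearman r (%s)", measure), y = NULL, colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot simulated condition means
#'
#' Bar chart of mean uncertainty by entropy class, complexity and
#' expertise, the figure summarizing the behavioral effects.
#'
#' @param means One element of an `experiment_analysis`'s
#'   `condition_means` (tibble with `group`, `complexity`, `entropy`,
#'   `value`).
#' @param ylab Axis label.
#' @return A ggplot object.
#' @export
plot_condition_means <- function(means, ylab = "mean rating") {
  df <- means |>
    dplyr::group_by(.data$group, .data$complexity, .data$entropy) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = stats::sd(.data$value) / sqrt(dplyr::n()), .groups = "drop"
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$entropy, y = .data$mean, fill = .data$group
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2
    ) +
    ggplot2::facet_wrap(~complexity) +
    ggplot2::labs(x = "entropy class", y = ylab, fill = NULL) +
    ggplot2::theme_minimal()
}
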