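#' Evaluate an expectation model on a stimulus set
#'
#' For every stimulus the model predicts the continuation after the
#' context prefix (with the short-term sub-model exposed to the prefix
#' when active), yielding the full-alphabet entropy, the 9-tone entropy
#' over the probes, both Schmuckler difference scores, and the
#' information content of each probe tone.
#'
#' @param stimuli A `stimulus_set`.
#' @param alphabet Full pitch alphabet (probes outside it are unioned in
#'   per stimulus).
#' @param ltm Trained long-term store (unless STM-only).
#' @param config A [model_config()].
#' @return List with tibbles `per_stimulus` (`stimulus_id`,
#'   `entropy_full`, `entropy_9`, `schmuckler_ic`, `schmuckler_prob`) and
#'   `per_probe` (`stimulus_id`, `probe_pitch`, `p`, `ic`).
#' @export
evaluate_model_on_stimuli <- function(stimuli, alphabet, ltm = NULL,
                                      config = model_config()) {
  res <- purrr::map(seq_len(nrow(stimuli)), function(i) {
    row <- stimuli[i, ]
    probes <- row$probes[[1]]
    k <- key(row$key_tonic, row$key_mode)
    alph <- sort(unique(c(alphabet, probes)))
    d <- predict_next(row$prefix[[1]], k, alph,
      ltm = ltm, stm = stm_for_prefix(row$prefix[[1]], k, config),
      config = config
    )
    d9 <- renormalize_subset(d, probes)
    list(
      per_stimulus = tibble::tibble(
        stimulus_id = row$stimulus_id,
        entropy_full = entropy_bits(d),
        entropy_9 = entropy_bits(d9),
        schmuckler_ic = schmuckler_score(d, "ic"),
        schmuckler_prob = schmuckler_score(d, "probability")
      ),
      per_probe = tibble::tibble(
        stimulus_id = row$stimulus_id,
        probe_pitch = probes,
        p = d$p[match(probes, d$pitch)],
        ic = information_content(d, probes)
      )
    )
  })
  list(
    per_stimulus = purrr::map_dfr(res, "per_stimulus"),
    per_probe = purrr::map_dfr(res, "per_probe")
  )
}

#' Inferred uncertainty for every participant and stimulus
#'
#' @param ratings A `rating_dataset` (see [simulate_listener_ratings()])
#'   or its `unexpectedness` tibble.
#' @param orientation Passed to [inferred_uncertainty()].
#' @return Tibble `participant`, `group`, `stimulus_id`, `inferred`.
#' @export
inferred_uncertainty_table <- function(ratings, orientation = "raw") {
  unexp <- if (inherits(ratings, "rating_dataset")) ratings$unexpectedness else ratings
  unexp |>
    dplyr::group_by(.data$participant, .data$group, .data$stimulus_id) |>
    dplyr::summarise(
      inferred = inferred_uncertainty(.data$rating, orientation),
      .groups = "drop"
    )
}

# per-participant condition means, given per-item values joined to cells
condition_means <- function(df) {
  df |>
    dplyr::group_by(
      .data$participant, .data$group, .data$complexity, .data$entropy
    ) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
}

stimulus_cells <- function(stimuli) {
  tibble::tibble(
    stimulus_id = stimuli$stimulus_id,
    complexity = stimuli$style,
    entropy = stimuli$entropy_class
  )
}

anova_with_exclusion <- function(means, multiplier = 1.5) {
  long <- dplyr::mutate(means,
    condition = paste(.data$complexity, .data$entropy, sep = ":"),
    expertise = .data$group
  )
  excl <- exclude_outliers(
    dplyr::select(long, "participant", "condition", "value"),
    multiplier = multiplier
  )
  kept <- dplyr::filter(long, .data$participant %in% excl$retained)
  list(
    anova = mixed_anova(kept),
    rank_anova = rank_transform_anova(long),
    outliers = excl
  )
}

#' Full behavioral analysis of a rating dataset
#'
#' Computes, for each dependent variable (explicit uncertainty, inferred
#' uncertainty, mean unexpectedness): per-participant condition means,
#' Tukey-fence outlier exclusion, the mixed 2x2x2 ANOVA on the retained
#' participants and the Conover-Iman rank-transform ANOVA on the full
#' data. Also computes Cronbach's alpha (participants as items, stimuli as
#' cases) for explicit uncertainty and unexpectedness, and each
#' participant's entropy-model-fit (explicit and inferred vs. model
#' entropy) and unexpectedness-model-fit (ratings vs. model information
#' content), Fisher-z transformed. Explicit-uncertainty values from
#' contexts a participant reported as familiar are excluded cell-wise.
#'
#' @param stimuli A `stimulus_set`.
#' @param ratings A `rating_dataset`.
#' @param model_eval Output of [evaluate_model_on_stimuli()].
#' @param orientation Orientation for [inferred_uncertainty()].
#' @return A list of class `"experiment_analysis"`.
#' @export
analyze_experiment <- function(stimuli, ratings, model_eval,
                               orientation = "raw") {
  cells <- stimulus_cells(stimuli)
  unexp <- ratings$unexpectedness
  explicit <- dplyr::filter(ratings$explicit, !.data$familiar)

  inferred <- inferred_uncertainty_table(ratings, orientation)
  means <- list(
    explicit = condition_means(dplyr::left_join(
      dplyr::rename(explicit, value = "rating"), cells,
      by = "stimulus_id"
    )),
    inferred = condition_means(dplyr::left_join(
      dplyr::rename(inferred, value = "inferred"), cells,
      by = "stimulus_id"
    )),
    unexpectedness = condition_means(dplyr::left_join(
      dplyr::rename(unexp, value = "rating"), cells,
      by = "stimulus_id"
    ))
  )
  anovas <- purrr::map(means, anova_with_exclusion)

  alpha <- list(
    explicit = cronbach_alpha(rating_matrix(explicit, "rating")),
    unexpectedness = cronbach_alpha(
      rating_matrix(
        dplyr::mutate(unexp,
          stimulus_id = paste(.data$stimulus_id, .data$probe_pitch)
        ),
        "rating"
      )
    )
  )

  per_stim <- model_eval$per_stimulus
  fits <- dplyr::bind_rows(
    fit_by_participant(
      dplyr::left_join(dplyr::rename(explicit, value = "rating"),
        per_stim, by = "stimulus_id"
      ),
      "entropy_full", "explicit"
    ),
    fit_by_participant(
      dplyr::left_join(dplyr::rename(inferred, value = "inferred"),
        per_stim, by = "stimulus_id"
      ),
      "entropy_full", "inferred"
    ),
    fit_by_participant(
      dplyr::left_join(dplyr::rename(unexp, value = "rating"),
        model_eval$per_probe, by = c("stimulus_id", "probe_pitch")
      ),
      "ic", "unexpectedness"
    )
  )
  structure(
    list(
      inferred = inferred, condition_means = means, anovas = anovas,
      cronbach_alpha = alpha, fits = fits, model_eval = model_eval
    ),
    class = "experiment_analysis"
  )
}

rating_matrix <- function(df, value_col) {
  wide <- df |>
    dplyr::select("participant", "stimulus_id", value = dplyr::all_of(value_col)) |>
    tidyr::pivot_wider(names_from = "participant", values_from = "value") |>
    dplyr::select(-"stimulus_id")
  as.matrix(wide[stats::complete.cases(wide), , drop = FALSE])
}

fit_by_participant <- function(df, model_col, measure) {
  df |>
    dplyr::group_by(.data$participant, .data$group) |>
    dplyr::group_modify(function(g, key_) {
      f <- participant_model_fit(g$value, g[[model_col]])
      tibble::tibble(r = f$r, z = f$z, n = f$n)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(measure = measure)
}

#' Model-comparison grid
#'
#' Re-evaluates the stimulus set under every combination of order bound
#' and sub-model configuration, correlating (Spearman) model entropy with
#' mean inferred and explicit uncertainty and model information content
#' with mean unexpectedness, overall and per expertise group. The
#' Schmuckler difference scores (computed from the standard configuration:
#' both sub-models, variable order) and the Implication-Realization
#' regression are included as competitor rows.
#'
#' @param stimuli A `stimulus_set`.
#' @param ratings A `rating_dataset`.
#' @param corpus Training corpus for the long-term sub-models.
#' @param orders Order bounds to cross, e.g. `c(0:4, "variable")`.
#' @param configurations Sub-model configurations to cross.
#' @param base_config Template [model_config()] supplying the remaining
#'   switches.
#' @param include_competitors Add Schmuckler and Implication-Realization
#'   rows.
#' @return A tibble of class `"model_comparison"`, one row per model.
#' @export
model_comparison_grid <- function(stimuli, ratings, corpus,
                                  orders = c(0, 1, 2, 3, 4, "variable"),
                                  configurations = c("stm", "ltm", "both"),
                                  base_config = model_config(),
                                  include_competitors = TRUE) {
  alphabet <- corpus_alphabet(corpus, base_config$alphabet_policy)
  unexp_mean <- mean_by_group(ratings$unexpectedness,
    c("stimulus_id", "probe_pitch"), "rating")
  explicit_mean <- mean_by_group(
    dplyr::filter(ratings$explicit, !.data$familiar),
    "stimulus_id", "rating"
  )
  inferred_mean <- mean_by_group(
    inferred_uncertainty_table(ratings), "stimulus_id", "inferred"
  )

  grid <- tidyr::expand_grid(
    order = as.character(orders), configuration = configurations
  )
  rows <- purrr::pmap_dfr(grid, function(order, configuration) {
    cfg <- model_config(
      order_bound = if (order == "variable") "variable" else as.integer(order),
      configuration = configuration,
      escape_method = base_config$escape_method,
      smoothing = base_config$smoothing,
      update_exclusion = base_config$update_exclusion,
      bias = base_config$bias,
      include_ioi_contour = base_config$include_ioi_contour,
      alphabet_policy = base_config$alphabet_policy
    )
    ltm <- if (configuration != "stm") train_ltm(corpus, cfg)
    ev <- evaluate_model_on_stimuli(stimuli, alphabet, ltm, cfg)
    tibble::tibble(
      model = paste0("ppm_", configuration, "_", order),
      order = order, configuration = configuration,
      corr_cols(ev, unexp_mean, inferred_mean, explicit_mean)
    )
  })
  if (include_competitors) {
    std_cfg <- model_config(
      order_bound = "variable", configuration = "both",
      escape_method = base_config$escape_method,
      smoothing = base_config$smoothing,
      update_exclusion = base_config$update_exclusion,
      bias = base_config$bias,
      include_ioi_contour = base_config$include_ioi_contour,
      alphabet_policy = base_config$alphabet_policy
    )
    ltm <- train_ltm(corpus, std_cfg)
    ev <- evaluate_model_on_stimuli(stimuli, alphabet, ltm, std_cfg)
    rows <- dplyr::bind_rows(
      rows,
      schmuckler_rows(ev, inferred_mean, explicit_mean),
      ir_row(stimuli, unexp_mean)
    )
  }
  structure(rows, class = c("model_comparison", class(tibble::tibble())))
}

mean_by_group <- function(df, keys, value_col) {
  overall <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      value = mean(.data[[value_col]]), .groups = "drop"
    ) |>
    dplyr::mutate(group = "all")
  per_group <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "group")))) |>
    dplyr::summarise(value = mean(.data[[value_col]]), .groups = "drop")
  dplyr::bind_rows(overall, per_group)
}

spearman_by_group <- function(means, model_df, keys, model_col) {
  joined <- dplyr::left_join(means, model_df, by = keys)
  out <- joined |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      r = suppressWarnings(
        stats::cor(.data$value, .data[[model_col]], method = "spearman")
      ),
      .groups = "drop"
    )
  stats::setNames(out$r, out$group)
}

corr_cols <- function(ev, unexp_mean, inferred_mean, explicit_mean) {
  ru <- spearman_by_group(unexp_mean, ev$per_probe,
    c("stimulus_id", "probe_pitch"), "ic")
  ri <- spearman_by_group(inferred_mean, ev$per_stimulus,
    "stimulus_id", "entropy_full")
  re <- spearman_by_group(explicit_mean, ev$per_stimulus,
    "stimulus_id", "entropy_full")
  tibble::tibble(
    r_unexp_all = ru[["all"]],
    r_unexp_musician = ru["musician"],
    r_unexp_nonmusician = ru["nonmusician"],
    r_inferred_all = ri[["all"]],
    r_inferred_musician = ri["musician"],
    r_inferred_nonmusician = ri["nonmusician"],
    r_explicit_all = re[["all"]],
    r_explicit_musician = re["musician"],
    r_explicit_nonmusician = re["nonmusician"]
  )
}

schmuckler_rows <- function(ev, inferred_mean, explicit_mean) {
  purrr::map_dfr(c("schmuckler_ic", "schmuckler_prob"), function(col) {
    ri <- spearman_by_group(inferred_mean, ev$per_stimulus, "stimulus_id", col)
    re <- spearman_by_group(explicit_mean, ev$per_stimulus, "stimulus_id", col)
    tibble::tibble(
      model = col, order = "variable", configuration = "both",
      r_unexp_all = NA_real_, r_unexp_musician = NA_real_,
      r_unexp_nonmusician = NA_real_,
      r_inferred_all = ri[["all"]],
      r_inferred_musician = ri["musician"],
      r_inferred_nonmusician = ri["nonmusician"],
      r_explicit_all = re[["all"]],
      r_explicit_musician = re["musician"],
      r_explicit_nonmusician = re["nonmusician"]
    )
  })
}

ir_row <- function(stimuli, unexp_mean) {
  pred <- ir_predictor_table(stimuli)
  r_for <- function(grp) {
    m <- dplyr::filter(unexp_mean, .data$group == grp)
    joined <- dplyr::left_join(pred, m, by = c("stimulus_id", "probe_pitch"))
    keep <- !is.na(joined$value)
    fit <- fit_ir_regression(
      joined[keep, c("proximity", "pitch_reversal", "tonal_hierarchy")],
      joined$value[keep]
    )
    fit$R
  }
  tibble::tibble(
    model = "ir_regression", order = NA_character_,
    configuration = NA_character_,
    r_unexp_all = r_for("all"),
    r_unexp_musician = r_for("musician"),
    r_unexp_nonmusician = r_for("nonmusician"),
    r_inferred_all = NA_real_, r_inferred_musician = NA_real_,
    r_inferred_nonmusician = NA_real_,
    r_explicit_all = NA_real_, r_explicit_musician = NA_real_,
    r_explicit_nonmusician = NA_real_
  )
}
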