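test_that("grammar specs validate their stochastic structure", {
  expect_error(
    grammar_spec(60:61, matrix(c(0.5, 0.5, 0.6, 0.5), 2, byrow = TRUE)),
    "sum to 1"
  )
  expect_error(
    grammar_spec(60:62, matrix(1 / 3, 2, 2)),
    "square"
  )
  g <- grammar_spec(60:61, matrix(0.5, 2, 2))
  expect_s3_class(g, "grammar_spec")
  expect_error(
    grammar_spec(60:61, matrix(0.5, 2, 2), initial = c(0.9, 0.2)),
    "probability vector"
  )
})

test_that("a permutation grammar cycles deterministically", {
  perm <- matrix(0, 3, 3)
  perm[1, 2] <- perm[2, 3] <- perm[3, 1] <- 1
  spec <- grammar_spec(c(60, 62, 64), perm,
    initial = c(1, 0, 0),
    phrase_range = c(4, 4), seed = 2
  )
  co <- generate_markov_corpus(spec, 3, 9)
  for (m in co$melodies) {
    expect_equal(m$pitch, rep(c(60, 62, 64), 3))
  }
  expect_equal(analytic_chain_entropy(spec), 0)
})

test_that("corpus generation is reproducible and matches the grammar", {
  spec <- recovery_grammar(23)
  c1 <- generate_markov_corpus(spec, 6, 20)
  c2 <- generate_markov_corpus(spec, 6, 20)
  expect_identical(
    purrr::map(c1$melodies, "pitch"),
    purrr::map(c2$melodies, "pitch")
  )
  # empirical bigram frequencies approach the generator rows (1e4 notes)
  big <- generate_markov_corpus(spec, 100, 100)
  idx <- function(p) match(p, spec$alphabet)
  counts <- matrix(0, 5, 5)
  for (m in big$melodies) {
    i <- idx(m$pitch)
    for (j in 2:length(i)) counts[i[j - 1], i[j]] <- counts[i[j - 1], i[j]] + 1
  }
  emp <- counts / rowSums(counts)
  # visitation-weighted mean total variation across conditioning states
  tvs <- rowSums(abs(emp - spec$transition)) / 2
  tv <- sum(tvs * rowSums(counts)) / sum(counts)
  expect_lt(tv, 0.02)
  # styles: isochronous gives unit durations, rhythmic varies them
  expect_true(all(c1$melodies[[1]]$duration == 1))
  rhythmic <- grammar_spec(spec$alphabet, spec$transition,
    style = "rhythmic", seed = 3
  )
  cr <- generate_markov_corpus(rhythmic, 4, 30)
  expect_gt(length(unique(unlist(purrr::map(cr$melodies, "duration")))), 1)
  expect_equal(attr(cr$melodies[[1]], "style"), "complex")
})

test_that("analytic chain entropy matches hand computation", {
  # uniform rows: log2 n
  for (n in c(2, 4)) {
    g <- grammar_spec(seq(60, by = 1, length.out = n), matrix(1 / n, n, n))
    expect_equal(analytic_chain_entropy(g), log2(n))
  }
  # 2-state chain (0.9, 0.1; 0.2, 0.8): pi = (2/3, 1/3) by hand
  g2 <- grammar_spec(c(60, 62), matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE))
  h_rows <- c(
    -(0.9 * log2(0.9) + 0.1 * log2(0.1)),
    -(0.2 * log2(0.2) + 0.8 * log2(0.8))
  )
  expect_equal(
    analytic_chain_entropy(g2),
    2 / 3 * h_rows[1] + 1 / 3 * h_rows[2],
    tolerance = 1e-12
  )
  # reducible chain is rejected
  red <- grammar_spec(c(60, 62), diag(2))
  expect_error(analytic_chain_entropy(red), "reducible")
})

sim_fixture <- function(seed = 5) {
  cfg_pipe <- small_pipeline_config(seed)
  corpora <- generate_study_corpora(cfg_pipe)
  mcfg <- config_to_model_test(cfg_pipe$model)
  ltm <- train_ltm(corpora$training_corpus, mcfg)
  stimuli <- build_stimulus_set(corpora$stimulus_corpus, ltm, mcfg,
    k_per_extreme = cfg_pipe$selection$k_per_extreme,
    per_cell = cfg_pipe$selection$per_cell
  )
  alphabet <- corpus_alphabet(corpora$stimulus_corpus, mcfg$alphabet_policy)
  ev <- evaluate_model_on_stimuli(stimuli, alphabet, ltm, mcfg)
  list(stimuli = stimuli, ev = ev)
}

test_that("noise-free listeners track information content almost perfectly", {
  fx <- sim_fixture()
  quiet <- list(listener_spec("musician", 0, 0))
  ratings <- simulate_listener_ratings(fx$stimuli, fx$ev,
    listeners = quiet,
    n_per_group = 2, seed = 9
  )
  joined <- dplyr::left_join(ratings$unexpectedness, fx$ev$per_probe,
    by = c("stimulus_id", "probe_pitch")
  )
  for (p in unique(joined$participant)) {
    sub <- joined[joined$participant == p, ]
    expect_gte(participant_model_fit(sub$rating, sub$ic)$r, 0.95)
  }
  # full-lapse listeners carry no signal
  noiselike <- list(listener_spec("nonmusician", 0, 1))
  r2 <- simulate_listener_ratings(fx$stimuli, fx$ev,
    listeners = noiselike,
    n_per_group = 20, seed = 10
  )
  j2 <- dplyr::left_join(r2$unexpectedness, fx$ev$per_probe,
    by = c("stimulus_id", "probe_pitch")
  )
  fits <- j2 |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(r = stats::cor(.data$rating, .data$ic))
  expect_lt(abs(mean(fits$r)), 0.1)
})

test_that("lower listener noise yields higher model fit on average", {
  fx <- sim_fixture()
  ratings <- simulate_listener_ratings(fx$stimuli, fx$ev,
    listeners = default_listeners(),
    n_per_group = 10, seed = 11
  )
  joined <- dplyr::left_join(ratings$unexpectedness, fx$ev$per_probe,
    by = c("stimulus_id", "probe_pitch")
  )
  fits <- joined |>
    dplyr::group_by(.data$participant, .data$group) |>
    dplyr::summarise(r = stats::cor(.data$rating, .data$ic), .groups = "drop")
  mean_by_group <- tapply(fits$r, fits$group, mean)
  expect_gt(mean_by_group[["musician"]], mean_by_group[["nonmusician"]])
  # ratings are valid Likert integers and the design is complete
  expect_true(all(ratings$unexpectedness$rating %in% 1:9))
  expect_equal(
    nrow(ratings$unexpectedness),
    20 * nrow(fx$stimuli) * 9
  )
  # reproducibility
  again <- simulate_listener_ratings(fx$stimuli, fx$ev,
    listeners = default_listeners(),
    n_per_group = 10, seed = 11
  )
  expect_identical(ratings$unexpectedness, again$unexpectedness)
})

test_that("rating datasets round-trip through tidy CSVs", {
  fx <- sim_fixture()
  ratings <- simulate_listener_ratings(fx$stimuli, fx$ev,
    n_per_group = 2, seed = 3
  )
  dir <- withr::local_tempdir()
  write_rating_dataset(ratings, dir)
  back <- read_rating_dataset(dir)
  expect_equal(
    as.data.frame(back$unexpectedness),
    as.data.frame(ratings$unexpectedness)
  )
  expect_equal(
    as.data.frame(back$explicit)[, c("participant", "rating")],
    as.data.frame(ratings$explicit)[, c("participant", "rating")]
  )
})

test_that("analysis recovers the entropy effect and expertise ordering across seeds", {
  fx <- sim_fixture()
  cells <- tibble::tibble(
    stimulus_id = fx$stimuli$stimulus_id,
    complexity = fx$stimuli$style,
    entropy = fx$stimuli$entropy_class
  )
  n_rep <- 40
  ok_entropy <- logical(n_rep)
  ok_expertise <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    ratings <- simulate_listener_ratings(fx$stimuli, fx$ev,
      n_per_group = 20, seed = 1000 + i
    )
    inf <- inferred_uncertainty_table(ratings)
    means <- inf |>
      dplyr::left_join(cells, by = "stimulus_id") |>
      dplyr::group_by(.data$participant, .data$group, .data$complexity, .data$entropy) |>
      dplyr::summarise(value = mean(.data$inferred), .groups = "drop") |>
      dplyr::rename(expertise = "group")
    tab <- generics::tidy(mixed_anova(means))
    hi <- mean(means$value[means$entropy == "high"])
    lo <- mean(means$value[means$entropy == "low"])
    ok_entropy[i] <- tab$p.value[tab$effect == "entropy"] < 0.05 && hi > lo
    joined <- dplyr::left_join(ratings$unexpectedness, fx$ev$per_probe,
      by = c("stimulus_id", "probe_pitch")
    )
    fits <- joined |>
      dplyr::group_by(.data$participant, .data$group) |>
      dplyr::summarise(r = stats::cor(.data$rating, .data$ic), .groups = "drop")
    mg <- tapply(fits$r, fits$group, mean)
    ok_expertise[i] <- mg[["musician"]] > mg[["nonmusician"]]
  }
  expect_gte(mean(ok_entropy), 0.95)
  expect_gte(mean(ok_expertise), 0.95)
})
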