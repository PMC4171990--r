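count_of <- function(store, ctx, sym) {
  cnts <- melent:::store_counts(store, ctx)
  if (is.null(cnts) || is.na(cnts[sym])) 0 else unname(cnts[sym])
}

test_that("training counts n-grams per melody without crossing boundaries", {
  st <- ngram_store(1)
  st <- melent:::store_add_sequence(st, c("a", "b", "a", "b", "a"), FALSE)
  expect_equal(count_of(st, "a", "b"), 2)
  expect_equal(count_of(st, "b", "a"), 2)
  expect_equal(count_of(st, character(0), "a"), 3)
  expect_equal(count_of(st, character(0), "b"), 2)

  # order 2 on the same sequence: trigram counts by hand enumeration
  st2 <- ngram_store(2)
  st2 <- melent:::store_add_sequence(st2, c("a", "b", "a", "b", "a"), FALSE)
  expect_equal(count_of(st2, c("a", "b"), "a"), 2)
  expect_equal(count_of(st2, c("b", "a"), "b"), 1)

  # two copies of a melody double every count
  co1 <- corpus(list(toy_melody(c(60, 62, 60), id = "m1")))
  co2 <- corpus(list(
    toy_melody(c(60, 62, 60), id = "m1"),
    toy_melody(c(60, 62, 60), id = "m2")
  ))
  cfg <- model_config(order_bound = 1, update_exclusion = FALSE)
  s1 <- train_ltm(co1, cfg)
  s2 <- train_ltm(co2, cfg)
  k <- estimate_key(co1$melodies[[1]])
  sym <- symbol_for_candidate(60, 62, k)
  expect_equal(
    2 * count_of(s1, derive_viewpoints(co1$melodies[[1]], k)$symbol[1], sym),
    count_of(s2, derive_viewpoints(co1$melodies[[1]], k)$symbol[1], sym)
  )
  expect_error(train_ltm(structure(list(melodies = list()),
    class = "melody_corpus"
  ), cfg), "empty")
})

test_that("an empty store predicts uniformly and counts raise probability", {
  st <- ngram_store()
  p <- ppm_distribution(st, character(0), letters[1:4])
  expect_equal(unname(p), rep(0.25, 4))
  st <- melent:::store_add_event(st, c("a", "b"))
  expect_gt(
    ppm_probability(st, "a", "b", c("a", "b", "c")),
    ppm_probability(st, "a", "c", c("a", "b", "c"))
  )
  expect_gt(ppm_probability(st, "a", "c", c("a", "b", "c")), 0)
  expect_error(ppm_probability(st, "a", "z", c("a", "b")), "alphabet")
})

test_that("smoothed probabilities match the brute-force escape recursion", {
  set.seed(7)
  for (method in c("a", "b", "c", "d")) {
    for (rep in 1:8) {
      n_sym <- sample(2:5, 1)
      alphabet <- letters[1:n_sym]
      train <- sample(alphabet, sample(4:10, 1), replace = TRUE)
      st <- ngram_store()
      st <- melent:::store_add_sequence(st, train, update_exclusion = FALSE)
      cfg <- model_config(escape_method = method, update_exclusion = FALSE)
      for (ctx_len in 0:3) {
        ctx <- if (ctx_len == 0) character(0) else {
          sample(alphabet, ctx_len, replace = TRUE)
        }
        for (sym in alphabet) {
          expect_equal(
            ppm_probability(st, ctx, sym, alphabet, cfg),
            oracle_ppm(train, ctx, sym, alphabet, method),
            tolerance = 1e-12
          )
        }
      }
    }
  }
})

test_that("emitted distributions are strictly positive and sum to one", {
  set.seed(13)
  st <- ngram_store()
  st <- melent:::store_add_sequence(st, sample(letters[1:4], 30, TRUE))
  for (cfg in list(
    model_config(), model_config(order_bound = 2),
    model_config(smoothing = "backoff"),
    model_config(escape_method = "b"),
    model_config(escape_method = "d", smoothing = "backoff")
  )) {
    for (ctx in list(character(0), "a", c("b", "a"), c("d", "d", "d"))) {
      p <- ppm_distribution(st, ctx, letters[1:4], cfg)
      expect_equal(sum(p), 1, tolerance = 1e-9)
      expect_gt(min(p), 0)
    }
  }
})

test_that("STM repetition sharpens predictions monotonically", {
  k <- key(0, "major")
  m <- melody(rep(c(60, 62), 8), 0:15, rep(1, 16))
  cfg <- model_config(configuration = "stm", order_bound = 1)
  preds <- sequence_predictions(m, c(60, 62, 64), config = cfg)
  # P(62 | ... 60) at each odd position (predicting the following 62)
  p_b <- purrr::map_dbl(
    seq(2, 16, by = 2),
    function(i) preds[[i]]$p[preds[[i]]$pitch == 62]
  )
  expect_true(all(diff(p_b) > 0))
  expect_equal(length(preds), nrow(m))
})

test_that("order-0 predictions ignore the context", {
  co <- generate_markov_corpus(recovery_grammar(3), 5, 20)
  cfg <- model_config(order_bound = 0, configuration = "ltm")
  ltm <- train_ltm(co, cfg)
  k <- key(0, "major")
  alph <- corpus_alphabet(co)
  d1 <- predict_next(toy_melody(c(60, 62)), k, alph, ltm = ltm, config = cfg)
  d2 <- predict_next(toy_melody(c(65, 67)), k, alph, ltm = ltm, config = cfg)
  # same interval/degree structure is not required: order 0 uses only
  # zeroth-order symbol frequencies, but symbols differ by prev pitch, so
  # compare against an explicit hand computation instead
  st <- ngram_store(0)
  syms1 <- symbol_for_candidate(62, alph, k)
  for (m in co$melodies) {
    st <- melent:::store_add_sequence(
      st, derive_viewpoints(m, attr(m, "key"))$symbol
    )
  }
  by_hand <- ppm_distribution(st, character(0), syms1, cfg)
  by_hand <- by_hand / sum(by_hand)
  expect_equal(unname(d1$p), unname(by_hand), tolerance = 1e-12)
  expect_equal(sum(d2$p), 1, tolerance = 1e-9)
})

test_that("a trained order-1 model recovers the generating chain", {
  spec <- recovery_grammar(11)
  h_true <- analytic_chain_entropy(spec)
  cfg <- model_config(order_bound = 1, configuration = "ltm")
  alph <- spec$alphabet
  ev <- eigen(t(spec$transition))
  pi_s <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  pi_s <- pi_s / sum(pi_s)
  # conditionals measured from two-note contexts (x, i), weighted by the
  # stationary probability of the context, so the conditioning symbol is a
  # full linked viewpoint symbol as in the bulk of training
  recover <- function(n_events) {
    co <- generate_markov_corpus(spec, ceiling(n_events / 50), 50)
    ltm <- train_ltm(co, cfg)
    kl <- 0
    h_model <- 0
    for (x in seq_along(alph)) {
      for (i in seq_along(alph)) {
        w <- pi_s[x] * spec$transition[x, i]
        if (w == 0) next
        ctx <- melody(c(alph[x], alph[i]), 0:1, c(1, 1))
        d <- predict_next(ctx, spec$key, alph, ltm = ltm, config = cfg)
        q <- d$p[match(alph, d$pitch)]
        p <- spec$transition[i, ]
        kl <- kl + w * sum(p[p > 0] * log2(p[p > 0] / q[p > 0]))
        h_model <- h_model + w * entropy_bits(d)
      }
    }
    list(kl = kl, h = h_model)
  }
  res <- purrr::map(c(100, 1000, 10000), recover)
  kl_by_n <- purrr::map_dbl(res, "kl")
  expect_true(all(diff(kl_by_n) < 0))
  expect_lt(abs(res[[3]]$h - h_true), 0.05)
})

test_that("variable order does not underperform low fixed orders", {
  # raw symbol sequences keep the first-order structure in the context
  # (a linked-viewpoint symbol already encodes its own transition)
  spec <- recovery_grammar(5)
  syms <- letters[1:5]
  gen_seq <- function(n, seed) {
    set.seed(seed)
    idx <- integer(n)
    idx[1] <- sample.int(5, 1)
    for (j in 2:n) idx[j] <- sample.int(5, 1, prob = spec$transition[idx[j - 1], ])
    syms[idx]
  }
  train <- purrr::map(1:100, function(i) gen_seq(40, 20 + i))
  held <- purrr::map(1:20, function(i) gen_seq(20, 500 + i))
  mean_lp <- function(order) {
    cfg <- model_config(order_bound = order, configuration = "ltm")
    st <- ngram_store(cfg$order_bound)
    for (tr in train) {
      st <- melent:::store_add_sequence(st, tr, cfg$update_exclusion)
    }
    lps <- purrr::map(held, function(h) {
      purrr::map_dbl(seq_along(h), function(i) {
        log2(ppm_probability(st, h[seq_len(i - 1)], h[i], syms, cfg))
      })
    })
    mean(unlist(lps))
  }
  lp0 <- mean_lp(0)
  lp1 <- mean_lp(1)
  lp_var <- mean_lp("variable")
  expect_gt(lp1, lp0)
  expect_gt(lp_var, lp0)
})

test_that("n-gram stores persist to JSON and back", {
  st <- ngram_store(2)
  st <- melent:::store_add_sequence(st, c("a", "b", "a", "c", "a", "b"))
  path <- withr::local_tempfile(fileext = ".json")
  write_ngram_store(st, path)
  back <- read_ngram_store(path)
  expect_equal(back$order_bound, 2)
  for (ctx in list(character(0), "a", c("b", "a"))) {
    for (s in c("a", "b", "c")) {
      expect_equal(count_of(back, ctx, s), count_of(st, ctx, s))
    }
  }
  expect_equal(
    ppm_distribution(back, "a", c("a", "b", "c")),
    ppm_distribution(st, "a", c("a", "b", "c"))
  )
})
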