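test_that("inferred uncertainty is the normalized entropy of rating weights", {
  # equal ratings give maximal uncertainty under either orientation
  for (v in c(1, 5, 9)) {
    expect_equal(inferred_uncertainty(rep(v, 9), "raw"), 1)
    expect_equal(inferred_uncertainty(rep(v, 9), "reversed"), 1)
  }
  # hand entropy sum for (9,1,1,...,1) raw: p = (9/17, 1/17 x 8)
  r <- c(9, rep(1, 8))
  p <- c(9 / 17, rep(1 / 17, 8))
  expect_equal(
    inferred_uncertainty(r, "raw"),
    -sum(p * log2(p)) / log2(9)
  )
  # orientations differ whenever ratings are non-constant
  set.seed(4)
  for (i in 1:10) {
    rr <- sample(1:9, 9, TRUE)
    if (length(unique(rr)) > 1) {
      expect_false(
        isTRUE(all.equal(
          inferred_uncertainty(rr, "raw"),
          inferred_uncertainty(rr, "reversed")
        ))
      )
    }
  }
  expect_error(inferred_uncertainty(c(0, rep(5, 8))), "1..9")
})

test_that("Fisher z is monotone and round-trips; fits match hand values", {
  r <- seq(-0.99, 0.99, by = 0.11)
  z <- fisher_z(r)
  expect_true(all(diff(z) > 0))
  expect_equal(tanh(z), r, tolerance = 1e-12)
  # perfect and anti-perfect correlation, with the documented cap
  f1 <- participant_model_fit(1:5, 1:5 * 2 + 3)
  expect_equal(f1$r, 1)
  expect_true(is.finite(f1$z))
  f2 <- participant_model_fit(1:5, -(1:5))
  expect_equal(f2$r, -1)
  # 5-pair hand computation of the covariance ratio
  x <- c(1, 3, 2, 5, 4)
  y <- c(2, 2, 4, 5, 3)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(participant_model_fit(x, y)$r, r_hand, tolerance = 1e-12)
  expect_error(participant_model_fit(rep(1, 5), 1:5), "zero variance")
  expect_error(participant_model_fit(1:2, 1:2), "at least 3")
})

test_that("outlier exclusion applies the fence rule with boundaries retained", {
  d <- tibble::tibble(
    participant = rep(sprintf("p%d", 1:8), each = 2),
    condition = rep(c("a", "b"), 8),
    value = c(5, 5, 5.2, 5, 4.9, 5, 5.1, 5, 4.8, 5, 5.05, 5, 4.95, 5, 5.15, 5)
  )
  expect_length(exclude_outliers(d)$excluded, 0)

  d2 <- d
  d2$value[3] <- 500 # p2 in condition a
  excl <- exclude_outliers(d2)
  expect_equal(excl$excluded, "p2")
  expect_equal(excl$report$condition, "a")
  expect_equal(sort(excl$retained), sort(setdiff(unique(d$participant), "p2")))

  # boundary case: with zero IQR the fences collapse onto the quartiles,
  # values exactly on the fence are retained, strict exceedance excludes
  d3 <- tibble::tibble(
    participant = sprintf("p%d", 1:5),
    condition = "a",
    value = c(0, 0, 0, 0, 10)
  )
  excl3 <- exclude_outliers(d3)
  expect_equal(excl3$excluded, "p5")
  expect_false(any(c("p1", "p2", "p3", "p4") %in% excl3$excluded))
})

test_that("the mixed ANOVA matches the brute-force cell-means decomposition", {
  set.seed(31)
  d <- tidyr::expand_grid(
    participant = sprintf("p%d", 1:6),
    complexity = c("simple", "complex"),
    entropy = c("high", "low")
  )
  d$expertise <- ifelse(d$participant %in% sprintf("p%d", 1:3),
    "musician", "nonmusician"
  )
  d$value <- stats::rnorm(nrow(d)) +
    2 * (d$entropy == "high") + 1 * (d$expertise == "musician")
  fit <- mixed_anova(d)
  tab <- generics::tidy(fit)
  ss <- oracle_mixed_ss(d)
  for (eff in c(
    "expertise", "complexity", "entropy", "expertise:complexity",
    "expertise:entropy", "complexity:entropy",
    "expertise:complexity:entropy"
  )) {
    expect_equal(
      tab$sumsq[tab$effect == eff], ss[[eff]],
      tolerance = 1e-9, info = eff
    )
  }
  # F ratios use the conventional error strata
  expect_equal(
    tab$statistic[tab$effect == "expertise"],
    (ss$expertise / 1) / (ss$err_between / 4),
    tolerance = 1e-9
  )
  expect_equal(
    tab$statistic[tab$effect == "entropy"],
    (ss$entropy / 1) / (ss$err_E / 4),
    tolerance = 1e-9
  )
  # total sum of squares decomposes exactly
  expect_equal(
    sum(tab$sumsq) + ss$err_between + ss$err_C + ss$err_E + ss$err_CE,
    ss$total,
    tolerance = 1e-9
  )
})

test_that("a pure between-group shift loads only on expertise", {
  d <- tidyr::expand_grid(
    participant = sprintf("p%d", 1:8),
    complexity = c("simple", "complex"),
    entropy = c("high", "low")
  )
  d$expertise <- ifelse(d$participant %in% sprintf("p%d", 1:4),
    "musician", "nonmusician"
  )
  base <- rep(c(0.3, -0.1, 0.2, -0.4), 8) # identical within-participant profile
  d$value <- base + ifelse(d$expertise == "musician", 2, 0)
  fit <- generics::tidy(mixed_anova(d))
  expect_gt(fit$sumsq[fit$effect == "expertise"], 10)
  others <- fit$sumsq[fit$effect != "expertise" &
    !(fit$effect %in% c("complexity", "entropy", "complexity:entropy"))]
  expect_true(all(others < 1e-20))
  # flat data: all F vanish
  d$value <- 5
  flat <- generics::tidy(mixed_anova(d))
  expect_true(all(flat$sumsq < 1e-20))
})

test_that("rank-transform ANOVA is invariant to monotone transformations", {
  set.seed(12)
  d <- tidyr::expand_grid(
    participant = sprintf("p%d", 1:6),
    complexity = c("simple", "complex"),
    entropy = c("high", "low")
  )
  d$expertise <- ifelse(d$participant %in% sprintf("p%d", 1:3), "m", "n")
  d$value <- stats::rlnorm(nrow(d))
  t1 <- generics::tidy(rank_transform_anova(d))
  d2 <- dplyr::mutate(d, value = exp(value) + 3)
  t2 <- generics::tidy(rank_transform_anova(d2))
  expect_equal(t1$statistic, t2$statistic, tolerance = 1e-12)
  # midranks over the pooled data sum to N(N+1)/2 even with heavy ties
  ties <- rep(c(1, 1, 2, 2, 3), 4)
  expect_equal(sum(rank(ties, ties.method = "average")), 20 * 21 / 2)
})

test_that("Cronbach's alpha matches the formula and its limits", {
  ident <- matrix(rep(stats::rnorm(20), 3), ncol = 3)
  expect_equal(cronbach_alpha(ident), 1)
  m <- matrix(c(1, 2, 3, 2, 3, 4, 1, 3, 5), ncol = 3)
  k <- 3
  expect_equal(
    cronbach_alpha(m),
    k / (k - 1) * (1 - sum(apply(m, 2, var)) / var(rowSums(m)))
  )
  # independent noise items: alpha near 0 at large n
  set.seed(8)
  noise <- matrix(stats::rnorm(3000), ncol = 3)
  expect_lt(abs(cronbach_alpha(noise)), 0.1)
  expect_error(cronbach_alpha(matrix(1, 4, 1)), "at least 2")
})

test_that("summary t statistics reproduce the reported group comparisons", {
  # musical-training subscale summaries: non-musicians first
  w <- welch_t(13.94, 3.56, 17, 53.12, 7.83, 17)
  expect_equal(w$t, -18.79, tolerance = 0.01)
  expect_equal(w$df, 22.36, tolerance = 0.01)
  # ages: pooled t with 32 df
  p <- pooled_t(26.65, 5.68, 17, 28.94, 6.42, 17)
  expect_equal(abs(p$t), 1.11, tolerance = 0.01)
  expect_equal(p$df, 32)
  # identical summaries give t = 0
  expect_equal(welch_t(5, 1, 10, 5, 1, 10)$t, 0)
  expect_equal(pooled_t(5, 1, 10, 5, 1, 10)$t, 0)
  # 2-vs-2 toy case by hand
  t22 <- pooled_t(1.5, sd(c(1, 2)), 2, 3.5, sd(c(3, 4)), 2)
  sp <- sqrt((0.5 + 0.5) / 2)
  expect_equal(t22$t, (1.5 - 3.5) / (sp * sqrt(1)), tolerance = 1e-12)
  expect_error(welch_t(1, 0, 5, 2, 1, 5), "positive SDs")
})

test_that("the 2x2 chi-square matches the gender comparison and hand cases", {
  # agrees with the printed 0.12 to its two-decimal precision
  expect_lt(abs(chi_square_2x2(matrix(c(9, 8, 8, 9), 2)) - 0.12), 0.005)
  expect_equal(chi_square_2x2(matrix(c(10, 0, 0, 10), 2)), 20)
  # proportional rows give 0
  expect_equal(chi_square_2x2(matrix(c(10, 20, 5, 10), 2)), 0)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("Williams' t matches an independent transcription", {
  expect_equal(williams_t(0.5, 0.5, 0.3, 30)$t, 0)
  # sign symmetry
  a <- williams_t(0.7, 0.4, 0.5, 25)
  b <- williams_t(0.4, 0.7, 0.5, 25)
  expect_equal(a$t, -b$t, tolerance = 1e-12)
  expect_equal(a$df, 22)
  # fixed case against the independently written determinant form
  for (case in list(
    c(0.63, 0.45, 0.52, 24), c(-0.2, 0.35, 0.1, 40),
    c(0.701, 0.569, 0.6, 216)
  )) {
    expect_equal(
      williams_t(case[1], case[2], case[3], case[4])$t,
      oracle_williams(case[1], case[2], case[3], case[4]),
      tolerance = 1e-12
    )
  }
  expect_error(williams_t(0.9, -0.9, 0.9, 20), "positive semi-definite")
})
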