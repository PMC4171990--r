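# Independent oracles used across the suite. These deliberately avoid the
# package's internal code paths: counts are enumerated by brute force and
# the smoothing recursion is written recursively from the definition.

# n-gram counts by direct enumeration over every position
oracle_counts <- function(train, context, symbol) {
  k <- length(context)
  hits <- 0
  for (i in seq_along(train)) {
    if (i - k < 1) next
    ctx_here <- if (k == 0) character(0) else train[(i - k):(i - 1)]
    if (identical(ctx_here, context) && train[i] == symbol) hits <- hits + 1
  }
  hits
}

oracle_escape <- function(cnt, method) {
  n_tot <- sum(cnt)
  t_d <- sum(cnt > 0)
  switch(method,
    a = list(alpha = cnt / (n_tot + 1), gamma = 1 / (n_tot + 1)),
    b = list(alpha = pmax(cnt - 1, 0) / n_tot, gamma = t_d / n_tot),
    c = list(alpha = cnt / (n_tot + t_d), gamma = t_d / (n_tot + t_d)),
    d = list(
      alpha = pmax(2 * cnt - 1, 0) / (2 * n_tot),
      gamma = t_d / (2 * n_tot)
    )
  )
}

# recursive interpolated-smoothing evaluation straight from the definition;
# the starting context is the PPM* choice: the shortest deterministic
# matching context, else the longest matching one
oracle_ppm <- function(train, context, symbol, alphabet, method = "c") {
  counts_at <- function(ctx) {
    vapply(alphabet, function(s) oracle_counts(train, ctx, s), 0)
  }
  matched <- integer(0)
  det <- integer(0)
  for (k in 0:length(context)) {
    ctx <- if (k == 0) character(0) else train_tail(context, k)
    cnt <- counts_at(ctx)
    if (sum(cnt) == 0) next
    matched <- c(matched, k)
    if (sum(cnt > 0) == 1) det <- c(det, k)
  }
  start <- if (length(det) > 0) {
    min(det)
  } else if (length(matched) > 0) {
    max(matched)
  } else {
    0
  }
  rec <- function(ctx) {
    lower <- if (length(ctx) == 0) {
      stats::setNames(rep(1 / length(alphabet), length(alphabet)), alphabet)
    } else {
      rec(ctx[-1])
    }
    cnt <- counts_at(ctx)
    if (sum(cnt) == 0) {
      return(lower)
    }
    eg <- oracle_escape(cnt, method)
    eg$alpha + eg$gamma * lower
  }
  unname(rec(train_tail(context, start))[symbol])
}

train_tail <- function(x, k) if (k == 0) character(0) else x[(length(x) - k + 1):length(x)]

# balanced mixed-design sums of squares from the cell-means decomposition
oracle_mixed_ss <- function(df) {
  m_all <- mean(df$value)
  m_p <- tapply(df$value, df$participant, mean)
  groups <- tapply(as.character(df$expertise), df$participant, unique)
  m_g <- tapply(df$value, df$expertise, mean)
  m_c <- tapply(df$value, df$complexity, mean)
  m_e <- tapply(df$value, df$entropy, mean)
  m_gc <- tapply(df$value, list(df$expertise, df$complexity), mean)
  m_ge <- tapply(df$value, list(df$expertise, df$entropy), mean)
  m_ce <- tapply(df$value, list(df$complexity, df$entropy), mean)
  m_gce <- tapply(df$value, list(df$expertise, df$complexity, df$entropy), mean)
  m_pc <- tapply(df$value, list(df$participant, df$complexity), mean)
  m_pe <- tapply(df$value, list(df$participant, df$entropy), mean)
  p_of <- names(m_p)
  n_g <- table(groups)

  ss_bs <- 4 * sum((m_p - m_all)^2)
  ss_A <- 4 * sum(n_g * (m_g[names(n_g)] - m_all)^2)
  ss_err_between <- ss_bs - ss_A

  ss_C <- sum(2 * length(m_p) * (m_c - m_all)^2)
  ss_AC <- sum(vapply(rownames(m_gc), function(g) {
    sum(2 * n_g[[g]] * (m_gc[g, ] - m_g[[g]] - m_c + m_all)^2)
  }, 0))
  ss_pC <- sum(vapply(p_of, function(p) {
    g <- groups[[p]]
    sum(2 * (m_pc[p, ] - m_p[[p]] - m_gc[g, ] + m_g[[g]])^2)
  }, 0))

  ss_E <- sum(2 * length(m_p) * (m_e - m_all)^2)
  ss_AE <- sum(vapply(rownames(m_ge), function(g) {
    sum(2 * n_g[[g]] * (m_ge[g, ] - m_g[[g]] - m_e + m_all)^2)
  }, 0))
  ss_pE <- sum(vapply(p_of, function(p) {
    g <- groups[[p]]
    sum(2 * (m_pe[p, ] - m_p[[p]] - m_ge[g, ] + m_g[[g]])^2)
  }, 0))

  ss_total <- sum((df$value - m_all)^2)
  ss_CE <- sum(vapply(rownames(m_ce), function(cc) {
    sum(length(m_p) * (m_ce[cc, ] - m_c[[cc]] - m_e + m_all)^2)
  }, 0))
  ss_ACE <- sum(vapply(rownames(m_gce), function(g) {
    out <- 0
    for (cc in colnames(m_gce)) {
      for (ee in dimnames(m_gce)[[3]]) {
        out <- out + n_g[[g]] * (m_gce[g, cc, ee] - m_gc[g, cc] - m_ge[g, ee] -
          m_ce[cc, ee] + m_g[[g]] + m_c[[cc]] + m_e[[ee]] - m_all)^2
      }
    }
    out
  }, 0))
  ss_err_within <- ss_total - ss_bs - ss_C - ss_AC - ss_pC -
    ss_E - ss_AE - ss_pE - ss_CE - ss_ACE
  list(
    expertise = ss_A, complexity = ss_C, entropy = ss_E,
    `expertise:complexity` = ss_AC, `expertise:entropy` = ss_AE,
    `complexity:entropy` = ss_CE,
    `expertise:complexity:entropy` = ss_ACE,
    err_between = ss_err_between, err_C = ss_pC, err_E = ss_pE,
    err_CE = ss_err_within, total = ss_total
  )
}

# independent transcription of the dependent-correlation t statistic
oracle_williams <- function(r12, r13, r23, n) {
  R <- det(matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3, 3))
  rb <- (r12 + r13) / 2
  (r12 - r13) * sqrt(
    ((n - 1) * (1 + r23)) /
      (2 * R * (n - 1) / (n - 3) + rb^2 * (1 - r23)^3)
  )
}

# small deterministic melody fixtures
toy_melody <- function(pitches = c(60, 62, 64, 65, 67),
                       onsets = seq_along(pitches) - 1,
                       durations = rep(1, length(pitches)), ...) {
  melody(pitches, onsets, durations, ...)
}

# fixed 5-state chain used by recovery tests (seeded, moderately peaked)
recovery_grammar <- function(seed = 11) {
  alphabet <- c(60, 62, 64, 65, 67)
  set.seed(seed)
  trans <- matrix(stats::rgamma(25, shape = 0.8), 5, 5)
  trans <- trans / rowSums(trans)
  grammar_spec(alphabet, trans,
    phrase_range = c(6, 10),
    style = "isochronous", seed = seed
  )
}

config_to_model_test <- function(mc) melent:::config_to_model(mc)

# tiny pipeline configuration for fast end-to-end tests
small_pipeline_config <- function(seed = 1) {
  cfg <- default_pipeline_config(seed)
  cfg$training <- list(n_melodies = 12, notes_per_melody = 30)
  cfg$stimulus_corpus <- list(n_melodies = 10, notes_per_melody = 26)
  cfg$selection <- list(k_per_extreme = 10, per_cell = 3, min_context_notes = 8)
  cfg$listeners$n_per_group <- 6
  cfg$comparison <- list(
    orders = c("0", "variable"), configurations = c("ltm", "both")
  )
  cfg
}
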