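#' Inferred uncertainty from one probe-rating profile
#'
#' The normalized entropy of the distribution obtained by normalizing the
#' nine probe ratings to sum to one. With `orientation = "raw"` the
#' unexpectedness ratings themselves are the weights; with `"reversed"`
#' the ratings are flipped (`10 - rating`) so that weights reflect
#' expectedness. Equal ratings give 1 under either orientation.
#'
#' @param ratings Integer ratings on the 1-9 scale, one per probe.
#' @param orientation `"raw"` or `"reversed"`.
#' @return Normalized entropy in `[0, 1]`.
#' @export
inferred_uncertainty <- function(ratings, orientation = c("raw", "reversed")) {
  orientation <- match.arg(orientation)
  if (any(is.na(ratings)) || any(ratings < 1 | ratings > 9)) {
    stop("ratings must lie in 1..9", call. = FALSE)
  }
  w <- if (orientation == "raw") as.numeric(ratings) else 10 - as.numeric(ratings)
  normalized_entropy(w / sum(w))
}

#' Fisher z transform
#'
#' Strictly monotone map `z = atanh(r)`; `r` is clamped away from +/-1 so
#' the transform stays finite (cap |z| about 18.7, i.e. r within 1e-16 of
#' unity).
#'
#' @param r Correlation(s).
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-16), 1 - 1e-16))

#' Per-participant model fit
#'
#' Correlation between a participant's uncertainty (or unexpectedness)
#' series and the model's series over the same items, plus its Fisher z
#' transform for aggregation.
#'
#' @param participant_series,model_series Equal-length numeric vectors
#'   (at least 3 complete pairs).
#' @param method `"pearson"` or `"spearman"`.
#' @return An object of class `"entropy_fit"`: list with `r`, `z`,
#'   `method`, `n`.
#' @export
participant_model_fit <- function(participant_series, model_series,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- stats::complete.cases(participant_series, model_series)
  x <- participant_series[keep]
  y <- model_series[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: a series has zero variance", call. = FALSE)
  }
  r <- stats::cor(x, y, method = method)
  structure(
    list(r = r, z = fisher_z(r), method = method, n = length(x)),
    class = "entropy_fit"
  )
}

#' @export
print.entropy_fit <- function(x, ...) {
  cat("<entropy_fit> r =", format(x$r, digits = 4),
    "(z =", format(x$z, digits = 4), ", n =", x$n, ",", x$method, ")\n")
  invisible(x)
}

#' Exclude outlying participants by the Tukey fence rule
#'
#' A participant is excluded when any of their condition means falls
#' strictly outside `[Q1 - m*IQR, Q3 + m*IQR]`, computed per condition
#' across participants; values exactly on a fence are retained.
#'
#' @param data Long tibble with columns `participant`, `condition`,
#'   `value` (one condition mean per row).
#' @param multiplier Fence multiplier `m`; 1.5 by default.
#' @return List with `retained` (participant ids), `excluded`, and a
#'   `report` tibble naming each exclusion's condition and value.
#' @export
exclude_outliers <- function(data, multiplier = 1.5) {
  stopifnot(all(c("participant", "condition", "value") %in% names(data)))
  fences <- data |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      q1 = stats::quantile(.data$value, 0.25),
      q3 = stats::quantile(.data$value, 0.75),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      lower = .data$q1 - multiplier * (.data$q3 - .data$q1),
      upper = .data$q3 + multiplier * (.data$q3 - .data$q1)
    )
  flagged <- data |>
    dplyr::left_join(fences, by = "condition") |>
    dplyr::filter(.data$value < .data$lower | .data$value > .data$upper)
  report <- dplyr::select(flagged, "participant", "condition", "value", "lower", "upper")
  excluded <- unique(report$participant)
  list(
    retained = setdiff(unique(data$participant), excluded),
    excluded = excluded,
    report = report
  )
}

#' Mixed-design 2x2x2 ANOVA
#'
#' Classical mixed ANOVA with `complexity` and `entropy` as
#' within-participant factors and `expertise` as a between-participant
#' factor, using the conventional error strata
#' (`Error(participant/(complexity*entropy))`). Every participant must
#' contribute all four within cells.
#'
#' @param data Tibble with columns `participant`, `expertise`,
#'   `complexity`, `entropy`, `value` (one row per participant x cell).
#' @return An object of class `"mixed_anova"`; `tidy()` gives the effect
#'   table (effect, df, den_df, sumsq, statistic, p.value).
#' @export
mixed_anova <- function(data) {
  req <- c("participant", "expertise", "complexity", "entropy", "value")
  stopifnot(all(req %in% names(data)))
  cells <- data |>
    dplyr::count(.data$participant, .data$complexity, .data$entropy)
  n_cells <- data |>
    dplyr::count(.data$participant) |>
    dplyr::pull(.data$n)
  if (any(cells$n != 1) || any(n_cells != 4)) {
    stop("each participant needs exactly one value in each of the 4 cells",
      call. = FALSE
    )
  }
  df <- data.frame(
    participant = factor(data$participant),
    expertise = factor(data$expertise),
    complexity = factor(data$complexity),
    entropy = factor(data$entropy),
    value = data$value
  )
  fit <- stats::aov(
    value ~ expertise * complexity * entropy +
      Error(participant / (complexity * entropy)),
    data = df
  )
  tab <- purrr::map_dfr(summary(fit), function(stratum) {
    s <- stratum[[1]]
    eff <- trimws(rownames(s))
    res <- eff == "Residuals"
    if (!any(res) || all(res)) return(tibble::tibble())
    tibble::tibble(
      effect = eff[!res],
      df = s$Df[!res],
      den_df = s$Df[res],
      sumsq = s$`Sum Sq`[!res],
      resid_sumsq = s$`Sum Sq`[res],
      statistic = s$`F value`[!res],
      p.value = s$`Pr(>F)`[!res]
    )
  })
  structure(list(table = tab, fit = fit, data = df), class = "mixed_anova")
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat("<mixed_anova>\n")
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' Rank-transform mixed ANOVA (Conover-Iman)
#'
#' Assigns midranks over the pooled values, then applies [mixed_anova()]
#' to the ranks; a non-parametric check of the parametric analysis.
#'
#' @inheritParams mixed_anova
#' @return A `"mixed_anova"` object fitted to the ranks.
#' @export
rank_transform_anova <- function(data) {
  data$value <- rank(data$value, ties.method = "average")
  mixed_anova(data)
}

#' Cronbach's alpha
#'
#' `k/(k-1) * (1 - sum(item variances) / variance of case totals)`. For
#' inter-individual consistency, participants are the items and stimuli
#' the cases.
#'
#' @param mat Numeric matrix, cases in rows, items in columns.
#' @return Alpha.
#' @export
cronbach_alpha <- function(mat) {
  mat <- as.matrix(mat)
  k <- ncol(mat)
  if (k < 2 || nrow(mat) < 2) stop("need at least 2 items and 2 cases", call. = FALSE)
  total_var <- stats::var(rowSums(mat))
  if (total_var == 0) stop("undefined alpha: zero total variance", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(mat, 2, stats::var)) / total_var)
}

#' Welch's two-sample t from summary statistics
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @return List with `t`, `df` (Welch-Satterthwaite).
#' @examples
#' welch_t(13.94, 3.56, 17, 53.12, 7.83, 17) # t ~ -18.79, df ~ 22.36
#' @export
welch_t <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2 || s1 <= 0 || s2 <= 0) {
    stop("need n >= 2 and positive SDs in both groups", call. = FALSE)
  }
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df)
}

#' Pooled-variance two-sample t from summary statistics
#'
#' @inheritParams welch_t
#' @return List with `t`, `df = n1 + n2 - 2`.
#' @export
pooled_t <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2 || s1 <= 0 || s2 <= 0) {
    stop("need n >= 2 and positive SDs in both groups", call. = FALSE)
  }
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2)
}

#' Pearson chi-square for a 2x2 table
#'
#' @param counts 2x2 matrix of non-negative counts with positive margins.
#' @param continuity_correction Apply Yates' correction (off by default).
#' @return The chi-square statistic (1 df).
#' @export
chi_square_2x2 <- function(counts, continuity_correction = FALSE) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("table has a zero margin", call. = FALSE)
  }
  unname(suppressWarnings(
    stats::chisq.test(counts, correct = continuity_correction)$statistic
  ))
}

#' Williams' t for dependent correlations sharing a variable
#'
#' Tests whether `r12` differs from `r13` when variables 2 and 3 are both
#' correlated with the common variable 1 (Williams' t as given by Steiger,
#' 1980, Eq. 3). `df = n - 3`.
#'
#' @param r12,r13 The two correlations being compared.
#' @param r23 Correlation between the two non-shared variables.
#' @param n Sample size (>= 4).
#' @return List with `t`, `df`.
#' @export
williams_t <- function(r12, r13, r23, n) {
  stopifnot(n >= 4)
  if (any(abs(c(r12, r13, r23)) > 1)) {
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  }
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  if (detR < -1e-12) {
    stop("invalid correlation matrix (not positive semi-definite)", call. = FALSE)
  }
  detR <- max(detR, 0)
  rbar <- (r12 + r13) / 2
  denom <- 2 * detR * (n - 1) / (n - 3) + rbar^2 * (1 - r23)^3
  t <- (r12 - r13) * sqrt((n - 1) * (1 + r23) / denom)
  list(t = t, df = n - 3)
}
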