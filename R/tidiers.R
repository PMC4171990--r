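#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mixed ANOVA
#'
#' @param x A `"mixed_anova"` from [mixed_anova()].
#' @param ... Unused.
#' @return A tibble with one row per effect: `effect`, `df`, `den_df`,
#'   `sumsq`, `statistic`, `p.value`.
#' @exportS3Method generics::tidy
tidy.mixed_anova <- function(x, ...) {
  dplyr::select(
    x$table, "effect", "df", "den_df", "sumsq", "statistic", "p.value"
  )
}

#' @rdname tidy.mixed_anova
#' @exportS3Method generics::glance
glance.mixed_anova <- function(x, ...) {
  tibble::tibble(
    n_participants = length(unique(x$data$participant)),
    n_cells = nrow(x$data),
    total_sumsq = sum(x$table$sumsq) + sum(unique(x$table$resid_sumsq))
  )
}

#' Tidy an entropy-model-fit
#'
#' @param x An `"entropy_fit"` from [participant_model_fit()].
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.entropy_fit <- function(x, ...) {
  tibble::tibble(
    estimate = x$r, fisher_z = x$z, method = x$method, n = x$n
  )
}

#' @rdname tidy.entropy_fit
#' @exportS3Method generics::glance
glance.entropy_fit <- function(x, ...) {
  tibble::tibble(r = x$r, z = x$z, n = x$n)
}

#' Tidy an Implication-Realization regression fit
#'
#' @param x An `"ir_fit"` from [fit_ir_regression()].
#' @param ... Unused.
#' @return One row per coefficient.
#' @exportS3Method generics::tidy
tidy.ir_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients)
  )
}

#' @rdname tidy.ir_fit
#' @exportS3Method generics::glance
glance.ir_fit <- function(x, ...) {
  tibble::tibble(r = x$R, r.squared = x$R^2, n = x$n)
}
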