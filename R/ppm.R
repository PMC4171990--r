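#' Model configuration
#'
#' Bundles the tunable parameters of the expectation model: the order
#' bound on context length (`0:4` or `"variable"` for a PPM*-style
#' longest-match strategy), which sub-models are active, the PPM escape
#' method, interpolated vs. backoff smoothing, update exclusion during
#' training, the entropy-weighting bias `b` used when combining the
#' long- and short-term distributions, whether the linked viewpoint
#' includes IOI contour, and the pitch-alphabet policy.
#'
#' @param order_bound `"variable"` or a non-negative integer (max context
#'   length in notes).
#' @param configuration `"both"`, `"ltm"` or `"stm"`.
#' @param escape_method PPM escape method, one of `"a"`, `"b"`, `"c"`,
#'   `"d"`. Method C is the default.
#' @param smoothing `"interpolated"` (default) or `"backoff"`.
#' @param update_exclusion Logical; stop propagating a count to shorter
#'   contexts once the symbol was already seen at a longer one.
#' @param bias Non-negative entropy-weighting exponent `b`; `0` weights the
#'   two sub-models equally.
#' @param include_ioi_contour Logical; add the IOI-contour component to
#'   the linked viewpoint (used for melodies carrying rhythm).
#' @param alphabet_policy `"corpus"` or `"chromatic_span"`; see
#'   [corpus_alphabet()].
#' @return A list of class `"model_config"`.
#' @export
model_config <- function(order_bound = "variable",
                         configuration = c("both", "ltm", "stm"),
                         escape_method = c("c", "a", "b", "d"),
                         smoothing = c("interpolated", "backoff"),
                         update_exclusion = TRUE,
                         bias = 1,
                         include_ioi_contour = FALSE,
                         alphabet_policy = c("corpus", "chromatic_span")) {
  configuration <- match.arg(configuration)
  escape_method <- match.arg(escape_method)
  smoothing <- match.arg(smoothing)
  alphabet_policy <- match.arg(alphabet_policy)
  if (identical(order_bound, "variable")) {
    order_bound <- Inf
  } else {
    order_bound <- as.numeric(order_bound)
    if (is.na(order_bound) || order_bound < 0) {
      stop("order_bound must be 'variable' or a non-negative integer",
        call. = FALSE
      )
    }
  }
  stopifnot(bias >= 0)
  structure(
    list(
      order_bound = order_bound, configuration = configuration,
      escape_method = escape_method, smoothing = smoothing,
      update_exclusion = update_exclusion, bias = bias,
      include_ioi_contour = include_ioi_contour,
      alphabet_policy = alphabet_policy
    ),
    class = "model_config"
  )
}

#' Create an empty n-gram store
#'
#' The trainable state of one sub-model: counts of (context, next symbol)
#' pairs for all context lengths up to the order bound (unbounded for the
#' variable-order strategy).
#'
#' @param order_bound Max context length stored; `Inf` for variable order.
#' @return An object of class `"ngram_store"`.
#' @export
ngram_store <- function(order_bound = Inf) {
  structure(
    list(counts = new.env(parent = emptyenv()), order_bound = order_bound,
         n_events = 0L),
    class = "ngram_store"
  )
}

#' @export
print.ngram_store <- function(x, ...) {
  cat("<ngram_store> order bound ",
    if (is.infinite(x$order_bound)) "variable" else x$order_bound,
    ", ", length(ls(x$counts)), " contexts, ", x$n_events,
    " events seen\n",
    sep = ""
  )
  invisible(x)
}

# "#"-prefixed so the empty context has a legal environment key
ctx_key <- function(syms) paste0("#", paste(syms, collapse = " "))

# Record one event: syms[length(syms)] observed after the preceding
# symbols. Counts are added for the longest context first; with update
# exclusion, propagation to shorter contexts stops at the first context
# that had already seen the symbol.
store_add_event <- function(store, syms, update_exclusion = TRUE) {
  i <- length(syms)
  sym <- syms[i]
  max_len <- min(store$order_bound, i - 1)
  for (k in max_len:0) {
    ck <- if (k == 0) ctx_key(character(0)) else ctx_key(syms[(i - k):(i - 1)])
    cnts <- store$counts[[ck]]
    prior <- if (is.null(cnts)) 0 else cnts[sym]
    if (is.null(cnts)) cnts <- numeric(0)
    if (is.na(prior) || length(prior) == 0) prior <- 0
    cnts[sym] <- prior + 1
    store$counts[[ck]] <- cnts
    if (update_exclusion && prior > 0) break
  }
  store$n_events <- store$n_events + 1L
  store
}

store_add_sequence <- function(store, syms, update_exclusion = TRUE) {
  for (i in seq_along(syms)) {
    store <- store_add_event(store, syms[seq_len(i)], update_exclusion)
  }
  store
}

store_counts <- function(store, context_syms) {
  store$counts[[ctx_key(context_syms)]]
}

#' Train the long-term sub-model on a corpus
#'
#' Derives the linked viewpoint sequence of every melody (restarting at
#' each melody, so no contexts cross melody boundaries) and accumulates
#' n-gram counts up to the configured order bound. Scale degrees use each
#' melody's notated key when present, otherwise the key estimated by
#' [estimate_key()].
#'
#' @param corpus A [corpus()].
#' @param config A [model_config()].
#' @return A trained [ngram_store()].
#' @export
train_ltm <- function(corpus, config = model_config()) {
  stopifnot(inherits(corpus, "melody_corpus"), inherits(config, "model_config"))
  if (length(corpus$melodies) == 0) stop("corpus is empty", call. = FALSE)
  store <- ngram_store(config$order_bound)
  for (m in corpus$melodies) {
    k <- melody_key(m) %||% estimate_key(m)
    syms <- derive_viewpoints(m, k, config$include_ioi_contour)$symbol
    store <- store_add_sequence(store, syms, config$update_exclusion)
  }
  store
}

# escape-method coefficients over counts restricted to the query alphabet
ppm_alpha_gamma <- function(cnt, method) {
  n_tot <- sum(cnt)
  t_distinct <- sum(cnt > 0)
  switch(method,
    a = list(alpha = cnt / (n_tot + 1), gamma = 1 / (n_tot + 1)),
    b = list(alpha = pmax(cnt - 1, 0) / n_tot, gamma = t_distinct / n_tot),
    c = list(
      alpha = cnt / (n_tot + t_distinct),
      gamma = t_distinct / (n_tot + t_distinct)
    ),
    d = list(
      alpha = pmax(2 * cnt - 1, 0) / (2 * n_tot),
      gamma = t_distinct / (2 * n_tot)
    )
  )
}

#' Smoothed predictive distribution over a symbol alphabet
#'
#' Evaluates the PPM-style smoothing recursion: starting from the longest
#' stored context suffix within the effective order bound, maximum-
#' likelihood estimates at each context length are blended with the escape
#' mass passed down to shorter contexts, terminating in a uniform
#' 1/|alphabet| floor. Every symbol therefore receives strictly positive
#' probability and the distribution sums to one over the alphabet.
#'
#' @param store An [ngram_store()].
#' @param context Character vector of context symbols (may be empty).
#' @param alphabet Character vector of candidate symbols.
#' @param config A [model_config()]; the escape method, smoothing style and
#'   order bound are honored.
#' @return Named numeric vector of probabilities over `alphabet`.
#' @export
ppm_distribution <- function(store, context, alphabet,
                             config = model_config()) {
  stopifnot(inherits(store, "ngram_store"))
  if (length(alphabet) == 0) stop("alphabet must be non-empty", call. = FALSE)
  if (anyDuplicated(alphabet)) stop("alphabet symbols must be distinct", call. = FALSE)
  n_a <- length(alphabet)
  start <- min(length(context), config$order_bound, store$order_bound)
  if (is.infinite(start)) start <- length(context)
  if (!is.finite(config$order_bound)) {
    # variable order: the shortest deterministic matching context, else the
    # longest matching context (naive longest-match is overconfident)
    matched <- integer(0)
    det <- integer(0)
    for (k in 0:start) {
      ctx <- if (k == 0) character(0) else utils::tail(context, k)
      cnts <- store_counts(store, ctx)
      if (is.null(cnts) || sum(cnts) == 0) next
      matched <- c(matched, k)
      if (sum(cnts > 0) == 1) det <- c(det, k)
    }
    if (length(matched) > 0) {
      start <- if (length(det) > 0) min(det) else max(matched)
    } else {
      start <- 0
    }
  }
  p <- stats::setNames(rep(1 / n_a, n_a), alphabet)
  for (k in 0:start) {
    ctx <- if (k == 0) character(0) else utils::tail(context, k)
    cnts <- store_counts(store, ctx)
    if (is.null(cnts)) next
    cnt <- stats::setNames(rep(0, n_a), alphabet)
    common <- intersect(names(cnts), alphabet)
    cnt[common] <- cnts[common]
    if (sum(cnt) == 0) next
    ag <- ppm_alpha_gamma(cnt, config$escape_method)
    if (config$smoothing == "interpolated") {
      p <- ag$alpha + ag$gamma * p
    } else {
      unseen <- ag$alpha == 0
      if (any(unseen)) {
        esc <- 1 - sum(ag$alpha[!unseen])
        p_new <- ag$alpha
        p_new[unseen] <- esc * p[unseen] / sum(p[unseen])
        p <- p_new
      } else {
        p <- ag$alpha / sum(ag$alpha)
      }
    }
  }
  p
}

#' Smoothed probability of one symbol
#'
#' @inheritParams ppm_distribution
#' @param symbol The symbol whose conditional probability is wanted; must
#'   be a member of `alphabet`.
#' @return A single probability in (0, 1].
#' @export
ppm_probability <- function(store, context, symbol, alphabet,
                            config = model_config()) {
  if (!symbol %in% alphabet) {
    stop("symbol is not in the evaluation alphabet", call. = FALSE)
  }
  unname(ppm_distribution(store, context, alphabet, config)[symbol])
}

#' Persist / restore a trained n-gram store
#'
#' Serializes counts, order bound and format version as JSON.
#'
#' @param store An [ngram_store()].
#' @param path JSON file path.
#' @return `path` invisibly / the restored store.
#' @export
write_ngram_store <- function(store, path) {
  keys <- ls(store$counts)
  jsonlite::write_json(
    list(
      format = "melent-ngram-1",
      order_bound = if (is.infinite(store$order_bound)) "variable" else store$order_bound,
      n_events = store$n_events,
      counts = stats::setNames(
        lapply(keys, function(k) as.list(store$counts[[k]])), keys
      )
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_ngram_store
#' @export
read_ngram_store <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "melent-ngram-1")) {
    stop("not a melent n-gram store: ", path, call. = FALSE)
  }
  ob <- if (identical(obj$order_bound, "variable")) Inf else as.numeric(obj$order_bound)
  store <- ngram_store(ob)
  store$n_events <- as.integer(obj$n_events)
  for (k in names(obj$counts)) {
    store$counts[[k]] <- unlist(obj$counts[[k]])
  }
  store
}
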