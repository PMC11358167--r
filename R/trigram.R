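#' Train a trigram (second-order Markov) word model
#'
#' Tabulates trigram, bigram and unigram counts over every utterance of a
#' single-language corpus. Counts never cross an utterance boundary: each
#' utterance restarts its context, and no sentence-start padding is used, so
#' the first word of an utterance is scored from its unigram relative
#' frequency and the second from the bigram relative frequency (genuinely
#' reduced context). Probabilities are maximum-likelihood count ratios with
#' no smoothing, which is exact when scoring the training corpus itself since
#' every scored event then has count >= 1.
#'
#' Training deliberately uses the full cleaned corpus, including utterances
#' that the length/duration filter later removes: filtering happens only
#' after probabilities are computed.
#'
#' @param corpus A cleaned `conv_corpus` with a single language label.
#' @param log_base 2 (surprisal in bits, default) or `exp(1)` (nats).
#' @return A `trigram_model` object.
#' @export
train_trigram_model <- function(corpus, log_base = 2) {
  if (nrow(corpus) == 0) stop("cannot train on an empty corpus", call. = FALSE)
  if (length(unique(corpus$language)) > 1) {
    stop("corpus contains several languages; train one model per language",
         call. = FALSE)
  }
  if (!log_base %in% c(2, exp(1))) stop("log_base must be 2 or exp(1)", call. = FALSE)
  toks <- token_table(corpus)
  uni <- toks[, list(n = .N), by = "w"]
  big <- toks[!is.na(toks$w1), list(n = .N), by = c("w1", "w")]
  big_ctx <- big[, list(n_ctx = sum(n)), by = "w1"]
  tri <- toks[!is.na(toks$w2), list(n = .N), by = c("w2", "w1", "w")]
  tri_ctx <- tri[, list(n_ctx = sum(n)), by = c("w2", "w1")]
  data.table::setkeyv(uni, "w")
  data.table::setkeyv(big, c("w1", "w"))
  data.table::setkeyv(big_ctx, "w1")
  data.table::setkeyv(tri, c("w2", "w1", "w"))
  data.table::setkeyv(tri_ctx, c("w2", "w1"))
  structure(list(language = corpus$language[1],
                 log_base = log_base,
                 n_tokens = nrow(toks),
                 vocab = sort(uni$w),
                 uni = uni, big = big, big_ctx = big_ctx,
                 tri = tri, tri_ctx = tri_ctx),
            class = "trigram_model")
}

# long token table with per-utterance lagged contexts
token_table <- function(corpus) {
  n_tok <- lengths(corpus$tokens)
  dt <- data.table::data.table(
    utterance_id = rep(corpus$utterance_id, n_tok),
    position = unlist(lapply(n_tok, seq_len), use.names = FALSE),
    w = unlist(corpus$tokens, use.names = FALSE)
  )
  dt[, c("w1", "w2") := list(data.table::shift(w, 1L), data.table::shift(w, 2L)),
     by = "utterance_id"]
  dt
}

#' @export
print.trigram_model <- function(x, ...) {
  cat(sprintf("<trigram_model> language: %s | %d tokens, %d word types, %d trigram contexts | log base %s\n",
              x$language, x$n_tokens, length(x$vocab), nrow(x$tri_ctx),
              if (x$log_base == 2) "2 (bits)" else "e (nats)"))
  invisible(x)
}

#' Conditional trigram probability
#'
#' Maximum-likelihood estimate `count(w2, w1, w) / count(w2, w1)`. For events
#' never seen in training the default policy is to raise an error (scoring
#' the training corpus never triggers it); `on_unseen = "inf"` instead
#' returns probability 0, i.e. an infinite-surprisal sentinel, for held-out
#' scoring.
#'
#' @param model A `trigram_model`.
#' @param w2,w1 The two context words (w at positions i-2, i-1).
#' @param w The continuation word. All three may be vectors of equal length.
#' @param on_unseen `"error"` (default) or `"inf"`.
#' @return Probabilities in (0, 1], or 0 where unseen under `"inf"`.
#' @export
conditional_probability <- function(model, w2, w1, w, on_unseen = c("error", "inf")) {
  on_unseen <- match.arg(on_unseen)
  q <- data.table::data.table(w2 = as.character(w2), w1 = as.character(w1),
                              w = as.character(w))
  n <- model$tri[q, on = c("w2", "w1", "w")]$n
  n_ctx <- model$tri_ctx[q, on = c("w2", "w1")]$n_ctx
  p <- n / n_ctx
  miss <- is.na(n) | is.na(n_ctx)
  if (any(miss)) {
    if (on_unseen == "error") {
      stop("unseen trigram: (", q$w2[miss][1], ", ", q$w1[miss][1], ", ",
           q$w[miss][1], ")", call. = FALSE)
    }
    p[miss] <- 0
  }
  p
}

#' Per-word surprisal for one utterance
#'
#' Word i (1-based) at position >= 3 is scored as
#' `-log P(w_i | w_{i-2}, w_{i-1})` under the trigram model; position 1 is
#' scored from the unigram relative frequency and position 2 from the bigram
#' relative frequency. The first two values are flagged
#' `context_complete = FALSE` because they rest on less context than a full
#' trigram, and downstream half statistics exclude them from first-half
#' means.
#'
#' @param model A `trigram_model`.
#' @param tokens Character vector of tokens, or a one-row `conv_corpus`.
#' @param on_unseen Unseen-event policy, see [conditional_probability()];
#'   under `"inf"` unseen events give `Inf` surprisal.
#' @return A tibble with `position`, `token`, `surprisal` (in the model's log
#'   base) and `context_complete`.
#' @export
utterance_surprisal <- function(model, tokens, on_unseen = c("error", "inf")) {
  on_unseen <- match.arg(on_unseen)
  if (inherits(tokens, "data.frame")) {
    stopifnot(nrow(tokens) == 1)
    tokens <- tokens$tokens[[1]]
  }
  n <- length(tokens)
  p <- numeric(n)
  p[1] <- model$uni[list(w = tokens[1]), on = "w"]$n / model$n_tokens
  if (n >= 2) {
    p[2] <- model$big[list(w1 = tokens[1], w = tokens[2]), on = c("w1", "w")]$n /
      model$big_ctx[list(w1 = tokens[1]), on = "w1"]$n_ctx
  }
  if (n >= 3) {
    idx <- 3:n
    p[idx] <- conditional_probability(model, tokens[idx - 2], tokens[idx - 1],
                                      tokens[idx], on_unseen = on_unseen)
  }
  if (anyNA(p) || any(p == 0)) {
    if (on_unseen == "error") {
      stop("unseen event at position ", which(is.na(p) | p == 0)[1], call. = FALSE)
    }
    p[is.na(p)] <- 0
  }
  tibble::tibble(position = seq_len(n), token = tokens,
                 surprisal = -log(p, base = model$log_base),
                 context_complete = seq_len(n) > 2)
}

#' Score every token of a corpus under a trigram model
#'
#' Vectorized equivalent of [utterance_surprisal()] over all utterances,
#' returned as one long table.
#'
#' @inheritParams utterance_surprisal
#' @param corpus A `conv_corpus` scoreable under `model` (same language).
#' @return A tibble with `utterance_id`, `position`, `token`, `surprisal`,
#'   `context_complete`.
#' @export
score_corpus <- function(corpus, model, on_unseen = c("error", "inf")) {
  on_unseen <- match.arg(on_unseen)
  toks <- token_table(corpus)
  p <- rep(NA_real_, nrow(toks))
  i1 <- which(toks$position == 1L)
  i2 <- which(toks$position == 2L)
  i3 <- which(toks$position >= 3L)
  p[i1] <- model$uni[toks[i1], on = "w"]$n / model$n_tokens
  if (length(i2)) {
    p[i2] <- model$big[toks[i2], on = c("w1", "w")]$n /
      model$big_ctx[toks[i2], on = "w1"]$n_ctx
  }
  if (length(i3)) {
    n <- model$tri[toks[i3], on = c("w2", "w1", "w")]$n
    n_ctx <- model$tri_ctx[toks[i3], on = c("w2", "w1")]$n_ctx
    p[i3] <- n / n_ctx
  }
  if (anyNA(p)) {
    if (on_unseen == "error") {
      bad <- which(is.na(p))[1]
      stop("unseen event: token '", toks$w[bad], "' at position ", toks$position[bad],
           " of ", toks$utterance_id[bad], call. = FALSE)
    }
    p[is.na(p)] <- 0
  }
  tibble::tibble(utterance_id = toks$utterance_id, position = toks$position,
                 token = toks$w, surprisal = -log(p, base = model$log_base),
                 context_complete = toks$position > 2L)
}

#' Serialize a trigram model to versioned JSON
#'
#' Counts are written with deterministically ordered keys so identical models
#' hash identically. [read_trigram_model()] restores an equivalent model.
#'
#' @param model A `trigram_model`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_trigram_model <- function(model, path) {
  pack <- function(dt, keys) {
    dt <- data.table::copy(dt)
    data.table::setorderv(dt, keys)
    dt[]
  }
  obj <- list(
    format = "convload-trigram-model",
    version = 1L,
    language = model$language,
    log_base = if (model$log_base == 2) "2" else "e",
    n_tokens = model$n_tokens,
    unigrams = pack(model$uni, "w"),
    bigrams = pack(model$big, c("w1", "w")),
    trigrams = pack(model$tri, c("w2", "w1", "w"))
  )
  jsonlite::write_json(obj, path, dataframe = "columns", auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized trigram model
#'
#' @param path Path written by [write_trigram_model()].
#' @return A `trigram_model`.
#' @export
read_trigram_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "convload-trigram-model")) {
    stop("not a convload trigram model file: ", path, call. = FALSE)
  }
  uni <- data.table::as.data.table(obj$unigrams)
  big <- data.table::as.data.table(obj$bigrams)
  tri <- data.table::as.data.table(obj$trigrams)
  big_ctx <- big[, list(n_ctx = sum(n)), by = "w1"]
  tri_ctx <- tri[, list(n_ctx = sum(n)), by = c("w2", "w1")]
  data.table::setkeyv(uni, "w")
  data.table::setkeyv(big, c("w1", "w"))
  data.table::setkeyv(big_ctx, "w1")
  data.table::setkeyv(tri, c("w2", "w1", "w"))
  data.table::setkeyv(tri_ctx, c("w2", "w1"))
  structure(list(language = obj$language,
                 log_base = if (identical(obj$log_base, "2")) 2 else exp(1),
                 n_tokens = obj$n_tokens,
                 vocab = sort(uni$w),
                 uni = uni, big = big, big_ctx = big_ctx,
                 tri = tri, tri_ctx = tri_ctx),
            class = "trigram_model")
}
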