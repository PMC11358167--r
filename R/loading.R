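#' Exclude short utterances
#'
#' Keeps utterances with at least `min_tokens` lexical tokens AND a duration
#' of at least `min_duration_ms`. The exclusion rule is strict ("fewer than
#' eight tokens" / "less than 600 ms"), so boundary utterances of exactly 8
#' tokens or exactly 600 ms survive. Applied after model training: the
#' trigram model sees the full cleaned corpus, the half statistics only this
#' subset. Filtering is idempotent and order-preserving.
#'
#' @param corpus A cleaned `conv_corpus`.
#' @param min_tokens Minimum token count (default 8).
#' @param min_duration_ms Minimum duration in milliseconds (default 600).
#' @return The surviving `conv_corpus`; attributes `n_before` and `n_after`
#'   report the counts.
#' @export
filter_utterances <- function(corpus, min_tokens = 8, min_duration_ms = 600) {
  n_tok <- lengths(corpus$tokens)
  dur <- corpus$end_ms - corpus$start_ms
  keep <- n_tok >= min_tokens & dur >= min_duration_ms
  out <- corpus[keep, ]
  attr(out, "n_before") <- nrow(corpus)
  attr(out, "n_after") <- sum(keep)
  out
}

#' Split an utterance into first and last halves
#'
#' A simple count-based split: the first half is tokens `1..floor(n/2)`, the
#' last half `floor(n/2)+1..n`, so a 10-word utterance splits 5/5 and an
#' 8-word utterance has words 1-4 in the first half and 5-8 in the last. For
#' odd n the extra token goes to the last half, keeping the last half's start
#' where the even anchors place it. Requires n >= 8 so that each half mean
#' rests on at least two full-context trigrams.
#'
#' @param n_words Number of tokens in the utterance.
#' @return A list with integer index vectors `first` and `last`.
#' @export
split_halves <- function(n_words) {
  if (n_words < 8) {
    stop("split_halves requires at least 8 tokens (got ", n_words,
         "); apply filter_utterances() first", call. = FALSE)
  }
  k <- floor(n_words / 2)
  list(first = seq_len(k), last = seq.int(k + 1L, n_words))
}

#' Per-utterance half means and the loading statistic
#'
#' The first-half mean excludes positions 1-2 (scored with reduced context,
#' not proper trigrams); the last-half mean uses every last-half position.
#' `surprisal_diff` is last minus first: positive values indicate
#' back-loading, negative front-loading. Any non-finite surprisal in scope
#' flags the utterance (`ok = FALSE`) instead of raising; flagged rows are
#' excluded from aggregation downstream.
#'
#' @param surprisal Numeric vector of per-token surprisal values.
#' @param split Halves from [split_halves()] (defaults to the split implied
#'   by `length(surprisal)`).
#' @return A one-row tibble: `n_words`, `mean_first`, `mean_last`, `diff`,
#'   `ok`.
#' @export
compute_half_stats <- function(surprisal, split = split_halves(length(surprisal))) {
  first_idx <- setdiff(split$first, 1:2)
  vals_first <- surprisal[first_idx]
  vals_last <- surprisal[split$last]
  ok <- all(is.finite(vals_first)) && all(is.finite(vals_last))
  m_first <- if (ok) mean(vals_first) else NA_real_
  m_last <- if (ok) mean(vals_last) else NA_real_
  tibble::tibble(n_words = length(surprisal),
                 mean_first = m_first, mean_last = m_last,
                 diff = m_last - m_first, ok = ok)
}

#' Loading table: one row of half statistics per utterance
#'
#' Scores the filtered corpus under its trigram model(s) and computes
#' [compute_half_stats()] per utterance. Row order follows the corpus, so
#' reruns on identical inputs are identical.
#'
#' @param corpus A filtered `conv_corpus` (every utterance >= 8 tokens).
#' @param model A `trigram_model`, or a named list of models keyed by
#'   language for multi-language corpora. Models must be trained on the full
#'   cleaned corpus, not the filtered subset.
#' @param on_unseen Unseen-event policy; under `"inf"`, utterances touching
#'   an unseen event are flagged `ok = FALSE` and dropped from model fits.
#' @return A tibble with `language`, `conversation_id`, `dyad`, `speaker`,
#'   `utterance_id`, `n_words`, `mean_first`, `mean_last`, `diff`, `ok`.
#' @export
corpus_loading_table <- function(corpus, model, on_unseen = c("error", "inf")) {
  on_unseen <- match.arg(on_unseen)
  if (any(lengths(corpus$tokens) < 8)) {
    stop("corpus contains utterances with fewer than 8 tokens; ",
         "apply filter_utterances() first", call. = FALSE)
  }
  scored <- score_corpus_multi(corpus, model, on_unseen)
  dt <- data.table::as.data.table(scored)
  n_by_utt <- dt[, list(n_words = max(position)), by = "utterance_id"]
  dt <- merge(dt, n_by_utt, by = "utterance_id", sort = FALSE)
  dt[, "half" := ifelse(dt$position > floor(dt$n_words / 2), "last", "first")]
  dt <- dt[!(dt$half == "first" & dt$position <= 2L), ]
  hm <- dt[, list(m = mean(surprisal), finite = all(is.finite(surprisal))),
           by = c("utterance_id", "half")]
  wide <- data.table::dcast(hm, utterance_id ~ half, value.var = c("m", "finite"))
  res <- tibble::tibble(
    language = corpus$language,
    conversation_id = corpus$conversation_id,
    dyad = corpus$dyad_id,
    speaker = corpus$speaker,
    utterance_id = corpus$utterance_id,
    n_words = lengths(corpus$tokens)
  )
  ord <- match(res$utterance_id, wide$utterance_id)
  res$mean_first <- wide$m_first[ord]
  res$mean_last <- wide$m_last[ord]
  res$diff <- res$mean_last - res$mean_first
  res$ok <- wide$finite_first[ord] & wide$finite_last[ord] & is.finite(res$diff)
  res
}

# score a possibly multi-language corpus with one model per language
score_corpus_multi <- function(corpus, model, on_unseen) {
  if (inherits(model, "trigram_model")) {
    langs <- unique(corpus$language)
    if (length(langs) > 1) {
      stop("multi-language corpus needs a named list of models", call. = FALSE)
    }
    return(score_corpus(corpus, model, on_unseen))
  }
  langs <- unique(corpus$language)
  miss <- setdiff(langs, names(model))
  if (length(miss) > 0) stop("no model supplied for language: ", miss[1], call. = FALSE)
  parts <- lapply(langs, function(lg) {
    score_corpus(corpus[corpus$language == lg, ], model[[lg]], on_unseen)
  })
  dplyr::bind_rows(parts)
}

#' Long-format loading table
#'
#' Pivots a loading table to one row per utterance half (the shape consumed
#' by [lrt_half_effect()]).
#'
#' @param loading A table from [corpus_loading_table()].
#' @return A tibble with `half` in `{first, last}` and `surprisal` columns.
#' @export
loading_long <- function(loading) {
  loading <- loading[loading$ok, ]
  long <- tidyr::pivot_longer(
    loading[, c("language", "conversation_id", "dyad", "speaker", "utterance_id",
                "n_words", "mean_first", "mean_last")],
    cols = c("mean_first", "mean_last"),
    names_to = "half", names_prefix = "mean_", values_to = "surprisal")
  long$half <- factor(long$half, levels = c("first", "last"))
  long
}
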