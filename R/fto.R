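#' Floor transfer offsets for one conversation
#'
#' A floor transfer offset (FTO) is the signed time between the end of one
#' speaker's utterance and the start of the other speaker's next utterance;
#' negative values indicate overlap. Utterances are paired as adjacent in
#' start-time order; adjacencies by the same speaker yield no transition.
#' Unordered input is sorted internally with a notice.
#'
#' @param conv A `conv_corpus` slice holding one conversation.
#' @return A tibble of transitions: `conversation_id`, `prev_utterance_id`,
#'   `next_utterance_id`, `prev_speaker`, `next_speaker`, `fto_ms`,
#'   `n_words_prev`, `n_words_next`.
#' @export
compute_ftos <- function(conv) {
  if (length(unique(conv$conversation_id)) > 1) {
    stop("compute_ftos() expects a single conversation; see fto_table()",
         call. = FALSE)
  }
  if (is.unsorted(conv$start_ms)) {
    message("utterances not in start-time order; sorting")
    conv <- conv[order(conv$start_ms), ]
  }
  n <- nrow(conv)
  if (n < 2) {
    return(tibble::tibble(conversation_id = character(), prev_utterance_id = character(),
                          next_utterance_id = character(), prev_speaker = character(),
                          next_speaker = character(), fto_ms = integer(),
                          n_words_prev = integer(), n_words_next = integer()))
  }
  i <- seq_len(n - 1)
  change <- conv$speaker[i] != conv$speaker[i + 1]
  i <- i[change]
  tibble::tibble(
    conversation_id = conv$conversation_id[i],
    prev_utterance_id = conv$utterance_id[i],
    next_utterance_id = conv$utterance_id[i + 1],
    prev_speaker = conv$speaker[i],
    next_speaker = conv$speaker[i + 1],
    fto_ms = conv$start_ms[i + 1] - conv$end_ms[i],
    n_words_prev = lengths(conv$tokens)[i],
    n_words_next = lengths(conv$tokens)[i + 1]
  )
}

#' FTO table across a corpus
#'
#' All speaker transitions in every conversation, joined with the language's
#' loading-group label and, where the utterances survived filtering, the
#' half-mean surprisals of the utterance preceding the transition (the turn
#' being responded to) and of the following utterance.
#'
#' @param corpus A `conv_corpus` with timings (typically unfiltered: FTOs are
#'   defined for every transition, not only long utterances).
#' @param loading Optional [corpus_loading_table()]; supplies `mean_first` /
#'   `mean_last` for the previous (`mean_first`, `mean_last`) and next
#'   (`next_mean_first`, `next_mean_last`) utterance where available, and the
#'   derived loading group when `loading_group` is `NULL`.
#' @param loading_group Named character vector `language -> {"back","front"}`
#'   overriding derivation from `loading`.
#' @return A tibble with `language`, `loading_group`, `conversation_id`,
#'   `dyad`, `prev_speaker`, `next_speaker`, `fto_ms`, `n_words` (of the
#'   previous utterance), `n_words_next`, `mean_first`, `mean_last`,
#'   `next_mean_first`, `next_mean_last`.
#' @export
fto_table <- function(corpus, loading = NULL, loading_group = NULL) {
  parts <- lapply(split(seq_len(nrow(corpus)), corpus$conversation_id),
                  function(idx) compute_ftos(corpus[idx, ]))
  out <- dplyr::bind_rows(parts)
  if (nrow(out) == 0) return(out)
  idx <- match(out$prev_utterance_id, corpus$utterance_id)
  out$language <- corpus$language[idx]
  out$dyad <- corpus$dyad_id[idx]
  if (is.null(loading_group) && !is.null(loading)) {
    mdiff <- tapply(loading$diff[loading$ok], loading$language[loading$ok], mean)
    loading_group <- stats::setNames(as.character(ifelse(mdiff > 0, "back", "front")),
                                     names(mdiff))
  }
  out$loading_group <- if (is.null(loading_group)) NA_character_
                       else unname(loading_group[out$language])
  if (!is.null(loading)) {
    ip <- match(out$prev_utterance_id, loading$utterance_id)
    im <- match(out$next_utterance_id, loading$utterance_id)
    out$mean_first <- loading$mean_first[ip]
    out$mean_last <- loading$mean_last[ip]
    out$next_mean_first <- loading$mean_first[im]
    out$next_mean_last <- loading$mean_last[im]
  } else {
    out$mean_first <- out$mean_last <- NA_real_
    out$next_mean_first <- out$next_mean_last <- NA_real_
  }
  out$n_words <- out$n_words_prev
  out <- out[order(out$language, out$conversation_id), ]
  out[, c("language", "loading_group", "conversation_id", "dyad",
          "prev_utterance_id", "next_utterance_id", "prev_speaker", "next_speaker",
          "fto_ms", "n_words", "n_words_next",
          "mean_first", "mean_last", "next_mean_first", "next_mean_last")]
}
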