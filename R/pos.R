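#' Attach universal POS tags to a corpus
#'
#' Tagging is a pluggable interface: `tagger` maps a token vector to an
#' equal-length vector of universal POS labels (one most-probable tag per
#' word). Utterances that already carry tags (e.g. synthetic ground truth)
#' pass through unchanged unless `retag = TRUE`.
#'
#' @param corpus A `conv_corpus`.
#' @param tagger `function(tokens) -> character` of the same length, or
#'   `NULL` when every utterance is already tagged.
#' @param retag Re-tag utterances that already have tags (default `FALSE`).
#' @return The corpus with a complete `tags` column.
#' @export
tag_corpus <- function(corpus, tagger = NULL, retag = FALSE) {
  need <- if (retag) rep(TRUE, nrow(corpus)) else lengths(corpus$tags) == 0
  if (!any(need)) return(corpus)
  if (is.null(tagger)) {
    stop(sum(need), " utterances lack tags and no tagger was supplied", call. = FALSE)
  }
  tags <- corpus$tags
  for (i in which(need)) {
    tg <- tagger(corpus$tokens[[i]])
    if (length(tg) != length(corpus$tokens[[i]])) {
      stop("tagger returned ", length(tg), " tags for ",
           length(corpus$tokens[[i]]), " tokens (utterance ",
           corpus$utterance_id[i], ")", call. = FALSE)
    }
    tags[[i]] <- as.character(tg)
  }
  corpus$tags <- tags
  corpus
}

#' Per-half rate and mean surprisal of one grammatical unit
#'
#' For each utterance half, the unit's rate is its occurrence count divided
#' by the number of words in that half (so three verbs among seven words
#' give 3/7 = 0.429); `rate_denominator = "utterance"` instead divides by the
#' utterance's total word count. The unit's mean surprisal averages the
#' surprisal of the unit's tokens in that half, excluding positions 1-2
#' (reduced context) from the average although their tags still count toward
#' the rate; it is `NA` when the unit is absent from the half.
#'
#' @param tags Character vector of universal POS labels.
#' @param surprisal Aligned numeric surprisal values.
#' @param unit POS label, e.g. `"NOUN"` or `"VERB"`.
#' @param split Halves from [split_halves()].
#' @param rate_denominator `"half"` (default, the worked-example convention)
#'   or `"utterance"`.
#' @return A two-row tibble (`half` = first, last) with `n_unit`,
#'   `n_words_half`, `rate`, `mean_unit_surprisal`.
#' @export
unit_half_stats <- function(tags, surprisal, unit,
                            split = split_halves(length(tags)),
                            rate_denominator = c("half", "utterance")) {
  rate_denominator <- match.arg(rate_denominator)
  stopifnot(length(tags) == length(surprisal))
  one <- function(idx, half) {
    is_unit <- tags[idx] == unit
    n_unit <- sum(is_unit)
    denom <- if (rate_denominator == "half") length(idx) else length(tags)
    s_idx <- idx[is_unit & idx > 2]
    tibble::tibble(half = half, unit = unit, n_unit = n_unit,
                   n_words_half = length(idx), rate = n_unit / denom,
                   mean_unit_surprisal = if (length(s_idx) == 0) NA_real_
                   else mean(surprisal[s_idx]))
  }
  dplyr::bind_rows(one(split$first, "first"), one(split$last, "last"))
}

#' Unit statistics table for NOUN and VERB
#'
#' Two rows (first/last half) per unit per utterance, joined with the
#' language's loading-group label: either supplied explicitly or derived as
#' the sign of the language's mean surprisal difference (positive = back).
#'
#' @param corpus A filtered, tagged `conv_corpus`.
#' @param model A `trigram_model` or named list of models per language.
#' @param units POS labels to tabulate (default NOUN and VERB).
#' @param rate_denominator See [unit_half_stats()].
#' @param loading_group Named character vector `language -> {"back","front"}`,
#'   or `NULL` to derive from the data.
#' @param loading Optional precomputed [corpus_loading_table()] (avoids
#'   rescoring and is required if `loading_group` is `NULL`... it is computed
#'   when missing).
#' @param on_unseen Unseen-event policy for scoring.
#' @return A tibble with one row per utterance x half x unit:
#'   `language`, `dyad`, `speaker`, `utterance_id`, `half`, `unit`,
#'   `n_unit`, `n_words_half`, `rate`, `mean_unit_surprisal`,
#'   `loading_group`.
#' @export
unit_stats_table <- function(corpus, model, units = c("NOUN", "VERB"),
                             rate_denominator = c("half", "utterance"),
                             loading_group = NULL, loading = NULL,
                             on_unseen = c("error", "inf")) {
  rate_denominator <- match.arg(rate_denominator)
  on_unseen <- match.arg(on_unseen)
  if (any(lengths(corpus$tags) == 0)) {
    stop("corpus has untagged utterances; run tag_corpus() first", call. = FALSE)
  }
  if (is.null(loading)) loading <- corpus_loading_table(corpus, model, on_unseen)
  if (is.null(loading_group)) {
    mdiff <- tapply(loading$diff[loading$ok], loading$language[loading$ok], mean)
    loading_group <- stats::setNames(as.character(ifelse(mdiff > 0, "back", "front")),
                                     names(mdiff))
  }
  # score_corpus keeps tokens in corpus row order, so per-token metadata can
  # be attached by replication rather than joins
  n_tok <- lengths(corpus$tokens)
  ord <- order(match(corpus$language, unique(corpus$language)))  # multi-lang scoring groups by language
  corpus <- corpus[ord, ]
  n_tok <- n_tok[ord]
  scored <- score_corpus_multi(corpus, model, on_unseen)
  dt <- data.table::as.data.table(scored)
  stopifnot(identical(dt$utterance_id, rep(corpus$utterance_id, n_tok)))
  dt[, "n_words" := rep(n_tok, n_tok)]
  dt[, "tag" := unlist(corpus$tags, use.names = FALSE)]
  dt[, "half" := ifelse(dt$position > floor(dt$n_words / 2), "last", "first")]
  half_sizes <- dt[, list(n_words_half = .N), by = c("utterance_id", "half")]
  rows <- list()
  for (u in units) {
    agg <- dt[, list(
      n_unit = sum(tag == u),
      mean_unit_surprisal = {
        sel <- tag == u & position > 2L
        if (any(sel)) mean(surprisal[sel]) else NA_real_
      }
    ), by = c("utterance_id", "half")]
    agg <- merge(agg, half_sizes, by = c("utterance_id", "half"), sort = FALSE)
    agg[, "unit" := u]
    rows[[u]] <- agg
  }
  out <- data.table::rbindlist(rows)
  denom <- if (rate_denominator == "half") out$n_words_half
           else lengths(corpus$tokens)[match(out$utterance_id, corpus$utterance_id)]
  out[, "rate" := out$n_unit / denom]
  res <- tibble::as_tibble(out)
  idx <- match(res$utterance_id, corpus$utterance_id)
  res$language <- corpus$language[idx]
  res$dyad <- corpus$dyad_id[idx]
  res$speaker <- corpus$speaker[idx]
  res$loading_group <- unname(loading_group[res$language])
  res <- res[order(match(res$utterance_id, corpus$utterance_id), res$unit, res$half), ]
  res[, c("language", "dyad", "speaker", "utterance_id", "half", "unit",
          "n_unit", "n_words_half", "rate", "mean_unit_surprisal", "loading_group")]
}
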