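#' Default filled-pause lexicons
#'
#' Filled-pause inventories are language-specific; these small defaults cover
#' the six study languages and can be replaced or extended per run. The
#' English list carries the canonical "uh", "hm", "ah" plus common variants.
#' An unknown language falls back to the English list.
#'
#' @param language Language label (case-insensitive).
#' @return Character vector of filler forms (lowercase).
#' @export
default_fillers <- function(language = "english") {
  lex <- list(
    english  = c("uh", "hm", "ah", "um", "mm", "mhm", "uhhuh"),
    german   = c("\u00e4h", "\u00e4hm", "hm", "mhm", "\u00f6h"),
    spanish  = c("eh", "em", "mm", "ah", "este"),
    arabic   = c("ah", "eh", "mm", "yaani"),
    japanese = c("ano", "eto", "un", "ee", "maa"),
    mandarin = c("en", "uh", "um", "nage", "zhege")
  )
  key <- tolower(language)
  if (key %in% names(lex)) lex[[key]] else lex$english
}

#' Default non-lexeme annotation patterns
#'
#' Regular expressions matching transcript markup that is not a spoken word:
#' bracketed event annotations (laughter, noise), angle/curly-brace markup,
#' and ampersand-prefixed non-lexemes. Markup conventions vary by corpus, so
#' the set is configurable wherever it is consumed.
#'
#' @return Character vector of regular expressions.
#' @export
default_annotation_patterns <- function() {
  c("^\\[.*\\]$", "^<.*>$", "^\\{.*\\}$", "^&")
}

#' Clean one utterance's token sequence
#'
#' Removes punctuation-only tokens (no letter or digit under Unicode
#' categories, so intra-word apostrophes and hyphens survive), tokens matching
#' any annotation pattern, and filled pauses, then optionally lowercases the
#' survivors. Tags aligned to removed tokens are removed with them; surviving
#' tokens keep their relative order and (apart from case folding) their exact
#' strings. Cleaning is idempotent.
#'
#' @param tokens Character vector of tokens.
#' @param tags Optional aligned character vector of POS tags.
#' @param filler_lexicon Filled-pause forms (compared lowercase).
#' @param annotation_patterns Regular expressions for non-lexeme markup.
#' @param lowercase Lowercase surviving tokens (default `TRUE`).
#' @return A list with `tokens`, `tags` (possibly `NULL`) and `empty`
#'   (`TRUE` when every token was removed; such utterances are excluded
#'   downstream rather than raising an error).
#' @export
clean_utterance <- function(tokens, tags = NULL,
                            filler_lexicon = default_fillers(),
                            annotation_patterns = default_annotation_patterns(),
                            lowercase = TRUE) {
  if (!is.null(tags) && length(tags) != length(tokens)) {
    stop(length(tags), " tags for ", length(tokens), " tokens", call. = FALSE)
  }
  drop <- !grepl("[\\p{L}\\p{N}]", tokens, perl = TRUE)
  for (pat in annotation_patterns) {
    drop <- drop | grepl(pat, tokens, perl = TRUE)
  }
  drop <- drop | tolower(tokens) %in% tolower(filler_lexicon)
  kept <- tokens[!drop]
  if (lowercase) kept <- tolower(kept)
  list(tokens = kept,
       tags = if (is.null(tags)) NULL else tags[!drop],
       empty = length(kept) == 0)
}

#' Clean every utterance in a corpus
#'
#' Applies [clean_utterance()] per row, using the per-language default filler
#' lexicon unless one is supplied. Utterances left empty by cleaning are
#' flagged and dropped (with a count recorded in the `n_dropped_empty`
#' attribute), not raised as errors.
#'
#' @param corpus A `conv_corpus`.
#' @param filler_lexicon Character vector used for every language, or `NULL`
#'   to take [default_fillers()] per utterance language.
#' @param annotation_patterns See [default_annotation_patterns()].
#' @param lowercase Lowercase surviving tokens (default `TRUE`).
#' @return A cleaned `conv_corpus`; attributes `n_dropped_empty` and
#'   `n_utterances_in` record what was removed.
#' @export
clean_corpus <- function(corpus, filler_lexicon = NULL,
                         annotation_patterns = default_annotation_patterns(),
                         lowercase = TRUE) {
  n_in <- nrow(corpus)
  fill_for <- function(lang) {
    if (is.null(filler_lexicon)) default_fillers(lang) else filler_lexicon
  }
  cleaned <- lapply(seq_len(n_in), function(i) {
    clean_utterance(corpus$tokens[[i]], corpus$tags[[i]],
                    filler_lexicon = fill_for(corpus$language[i]),
                    annotation_patterns = annotation_patterns,
                    lowercase = lowercase)
  })
  empty <- vapply(cleaned, `[[`, TRUE, "empty")
  out <- corpus[!empty, ]
  out$tokens <- lapply(cleaned[!empty], `[[`, "tokens")
  out$tags <- lapply(cleaned[!empty], `[[`, "tags")
  out <- conv_corpus(out, validate = FALSE)
  attr(out, "n_utterances_in") <- n_in
  attr(out, "n_dropped_empty") <- sum(empty)
  out
}
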