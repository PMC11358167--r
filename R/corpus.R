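#' Construct a conversational corpus
#'
#' A corpus is a tibble with one row per utterance, carrying speaker
#' attribution, millisecond timing relative to conversation start, and the
#' utterance's token sequence (optionally with aligned universal POS tags).
#' Utterances are grouped into conversations by `conversation_id`; each
#' conversation is a dyadic exchange between exactly two speakers.
#'
#' @param utterances A data frame with columns `conversation_id`, `dyad_id`,
#'   `speaker`, `start_ms`, `end_ms`, and `tokens` (a list of character
#'   vectors, or a character vector of single-space-separated tokens).
#'   Optional columns: `language`, `utterance_id`, `tags` (list of character
#'   vectors aligned to `tokens`, or space-separated strings).
#' @param language Language label applied when the `language` column is
#'   absent.
#' @param validate Run full invariant checks (default `TRUE`).
#' @return A `conv_corpus` tibble, sorted by language, conversation and start
#'   time.
#' @export
conv_corpus <- function(utterances, language = NULL, validate = TRUE) {
  utt <- tibble::as_tibble(utterances)
  required <- c("conversation_id", "dyad_id", "speaker", "start_ms", "end_ms", "tokens")
  missing_cols <- setdiff(required, names(utt))
  if (length(missing_cols) > 0) {
    stop("corpus is missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"language" %in% names(utt)) {
    utt$language <- if (is.null(language)) "corpus" else as.character(language)
  }
  if (is.character(utt$tokens)) {
    utt$tokens <- strsplit(utt$tokens, " ", fixed = TRUE)
  }
  if (!"tags" %in% names(utt)) {
    utt$tags <- list(NULL)
  } else if (is.character(utt$tags)) {
    utt$tags <- lapply(utt$tags, function(x) {
      if (is.na(x) || !nzchar(x)) NULL else strsplit(x, " ", fixed = TRUE)[[1]]
    })
  }
  utt$conversation_id <- as.character(utt$conversation_id)
  utt$dyad_id <- as.character(utt$dyad_id)
  utt$speaker <- as.character(utt$speaker)
  utt$start_ms <- as.integer(utt$start_ms)
  utt$end_ms <- as.integer(utt$end_ms)
  if (!"utterance_id" %in% names(utt)) {
    utt$utterance_id <- make_utterance_ids(utt$conversation_id)
  }
  utt <- utt[order(utt$language, utt$conversation_id, utt$start_ms, utt$utterance_id), ]
  utt <- utt[, c("language", "conversation_id", "dyad_id", "speaker", "utterance_id",
                 "start_ms", "end_ms", "tokens", "tags")]
  out <- structure(utt, class = c("conv_corpus", class(tibble::tibble())))
  if (validate) validate_corpus(out)
  out
}

make_utterance_ids <- function(conversation_id) {
  idx <- stats::ave(seq_along(conversation_id), conversation_id, FUN = seq_along)
  sprintf("%s_u%03d", conversation_id, idx)
}

#' Validate corpus invariants
#'
#' Checks timing order, non-empty token sequences, tag alignment, unique
#' utterance ids, and that every conversation involves exactly two speakers.
#'
#' @param corpus A `conv_corpus`.
#' @return The corpus, invisibly; errors describe the first offending record.
#' @export
validate_corpus <- function(corpus) {
  bad_time <- which(corpus$end_ms < corpus$start_ms)
  if (length(bad_time) > 0) {
    stop("utterance ", corpus$utterance_id[bad_time[1]], ": end_ms < start_ms",
         call. = FALSE)
  }
  n_tok <- lengths(corpus$tokens)
  if (any(n_tok == 0)) {
    stop("utterance ", corpus$utterance_id[which(n_tok == 0)[1]], ": empty token sequence",
         call. = FALSE)
  }
  n_tag <- lengths(corpus$tags)
  bad_tag <- which(n_tag > 0 & n_tag != n_tok)
  if (length(bad_tag) > 0) {
    stop("utterance ", corpus$utterance_id[bad_tag[1]], ": ", n_tag[bad_tag[1]],
         " tags for ", n_tok[bad_tag[1]], " tokens", call. = FALSE)
  }
  if (anyDuplicated(corpus$utterance_id)) {
    stop("duplicate utterance_id: ",
         corpus$utterance_id[duplicated(corpus$utterance_id)][1], call. = FALSE)
  }
  spk <- tapply(corpus$speaker, corpus$conversation_id, function(s) length(unique(s)))
  if (any(spk > 2)) {
    stop("conversation ", names(spk)[which(spk > 2)[1]],
         " has more than two speakers; corpora must be dyadic", call. = FALSE)
  }
  invisible(corpus)
}

#' @export
print.conv_corpus <- function(x, ...) {
  langs <- unique(x$language)
  cat(sprintf("<conv_corpus> %d utterances, %d conversations, %d dyads, %s\n",
              nrow(x), length(unique(x$conversation_id)), length(unique(x$dyad_id)),
              if (length(langs) == 1) paste0("language: ", langs)
              else paste0(length(langs), " languages")))
  NextMethod()
}

#' Read a corpus from TSV or JSONL
#'
#' The TSV dialect is UTF-8 with a header row and columns `conversation_id`,
#' `dyad_id`, `speaker`, `start_ms`, `end_ms` (integer milliseconds from
#' conversation start), `tokens` (single-space-separated), plus optional
#' `tags` (space-separated universal POS labels), `language` and
#' `utterance_id`. The JSONL dialect has one utterance object per line with
#' the same fields (`tokens`/`tags` may be arrays or space-separated strings).
#'
#' @param path File to read.
#' @param dialect `"tsv"` or `"jsonl"`; default guessed from the extension.
#' @param language Language label used when the file has no `language` column.
#' @return A validated [conv_corpus()].
#' @export
read_corpus <- function(path, dialect = c("auto", "tsv", "jsonl"), language = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "tsv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "tsv") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    if (length(lines) == 0 || !nzchar(lines[1])) stop("empty input file: ", path, call. = FALSE)
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    body <- lines[-1]
    body <- body[nzchar(body)]
    if (length(body) == 0) stop("empty input: ", path, " has a header but no records", call. = FALSE)
    fields <- strsplit(body, "\t", fixed = TRUE)
    n_f <- lengths(fields)
    bad <- which(n_f != length(header))
    if (length(bad) > 0) {
      stop("malformed record at line ", bad[1] + 1L, ": expected ",
           length(header), " fields, found ", n_f[bad[1]], call. = FALSE)
    }
    mat <- do.call(rbind, fields)
    colnames(mat) <- header
    df <- tibble::as_tibble(mat)
    for (col in c("start_ms", "end_ms")) {
      if (!col %in% names(df)) stop("missing required column: ", col, call. = FALSE)
      val <- suppressWarnings(as.integer(df[[col]]))
      if (anyNA(val)) {
        stop("malformed record at line ", which(is.na(val))[1] + 1L,
             ": non-integer ", col, call. = FALSE)
      }
      df[[col]] <- val
    }
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) stop("empty input file: ", path, call. = FALSE)
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) stop("malformed record at line ", i, ": ",
                                               conditionMessage(e), call. = FALSE))
      rec
    })
    df <- tibble::tibble(
      conversation_id = vapply(recs, function(r) as.character(r$conversation_id %||% NA), ""),
      dyad_id = vapply(recs, function(r) as.character(r$dyad_id %||% NA), ""),
      speaker = vapply(recs, function(r) as.character(r$speaker %||% NA), ""),
      start_ms = vapply(recs, function(r) as.integer(r$start_ms %||% NA), 1L),
      end_ms = vapply(recs, function(r) as.integer(r$end_ms %||% NA), 1L),
      tokens = lapply(recs, function(r) {
        tk <- r$tokens
        if (is.character(tk) && length(tk) == 1) strsplit(tk, " ", fixed = TRUE)[[1]]
        else as.character(tk)
      }),
      tags = lapply(recs, function(r) {
        tg <- r$tags
        if (is.null(tg)) return(NULL)
        if (is.character(tg) && length(tg) == 1) strsplit(tg, " ", fixed = TRUE)[[1]]
        else as.character(tg)
      })
    )
    if ("language" %in% names(recs[[1]])) {
      df$language <- vapply(recs, function(r) as.character(r$language %||% NA), "")
    }
    if ("utterance_id" %in% names(recs[[1]])) {
      df$utterance_id <- vapply(recs, function(r) as.character(r$utterance_id %||% NA), "")
    }
  }
  conv_corpus(df, language = language)
}

#' Write a corpus to TSV or JSONL
#'
#' The emitted file round-trips through [read_corpus()] with identical token
#' sequences, timings and identifiers. Records are written grouped by
#' language and conversation in start-time order, so output is deterministic.
#'
#' @param corpus A `conv_corpus`.
#' @param path Output file.
#' @param dialect `"tsv"` or `"jsonl"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, dialect = c("auto", "tsv", "jsonl")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "tsv"
  }
  has_ws <- vapply(corpus$tokens, function(tk) any(grepl("[ \t\n]", tk)), TRUE)
  if (any(has_ws)) {
    stop("utterance ", corpus$utterance_id[which(has_ws)[1]],
         " contains whitespace inside a token; cannot serialize", call. = FALSE)
  }
  has_tags <- any(lengths(corpus$tags) > 0)
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  if (dialect == "tsv") {
    cols <- c("language", "conversation_id", "dyad_id", "speaker", "utterance_id",
              "start_ms", "end_ms", "tokens", if (has_tags) "tags")
    rows <- vapply(seq_len(nrow(corpus)), function(i) {
      vals <- c(corpus$language[i], corpus$conversation_id[i], corpus$dyad_id[i],
                corpus$speaker[i], corpus$utterance_id[i],
                corpus$start_ms[i], corpus$end_ms[i],
                paste(corpus$tokens[[i]], collapse = " "),
                if (has_tags) paste(corpus$tags[[i]], collapse = " "))
      paste(vals, collapse = "\t")
    }, "")
    writeLines(c(paste(cols, collapse = "\t"), rows), con, useBytes = FALSE)
  } else {
    rows <- vapply(seq_len(nrow(corpus)), function(i) {
      rec <- list(language = corpus$language[i],
                  conversation_id = corpus$conversation_id[i],
                  dyad_id = corpus$dyad_id[i],
                  speaker = corpus$speaker[i],
                  utterance_id = corpus$utterance_id[i],
                  start_ms = corpus$start_ms[i],
                  end_ms = corpus$end_ms[i],
                  tokens = as.list(corpus$tokens[[i]]))
      if (length(corpus$tags[[i]]) > 0) rec$tags <- as.list(corpus$tags[[i]])
      jsonlite::toJSON(rec, auto_unbox = TRUE)
    }, "")
    writeLines(rows, con)
  }
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
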