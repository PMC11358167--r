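# Hand-built corpora used across test files.

# a corpus from explicit token strings; times default to 1 s per utterance
toy_corpus <- function(token_strings, speakers = NULL, start_ms = NULL,
                       end_ms = NULL, language = "toy",
                       conversation_id = "conv1", dyad_id = "dyad1",
                       tags = NULL) {
  n <- length(token_strings)
  if (is.null(speakers)) speakers <- rep(c("A", "B"), length.out = n)
  if (is.null(start_ms)) start_ms <- seq(0, by = 2000, length.out = n)
  if (is.null(end_ms)) end_ms <- start_ms + 1000
  df <- tibble::tibble(conversation_id = conversation_id, dyad_id = dyad_id,
                       speaker = speakers, start_ms = start_ms, end_ms = end_ms,
                       tokens = token_strings)
  if (!is.null(tags)) df$tags <- tags
  conv_corpus(df, language = language)
}

# independent brute-force n-gram tally: nested loops and named vectors only,
# no shared code with the package internals
brute_force_counts <- function(token_lists) {
  uni <- numeric(0); big <- numeric(0); tri <- numeric(0)
  big_ctx <- numeric(0); tri_ctx <- numeric(0)
  bump <- function(tab, key) {
    tab[key] <- if (is.na(tab[key])) 1 else tab[key] + 1
    tab
  }
  for (toks in token_lists) {
    for (i in seq_along(toks)) {
      uni <- bump(uni, toks[i])
      if (i >= 2) {
        big <- bump(big, paste(toks[i - 1], toks[i]))
        big_ctx <- bump(big_ctx, toks[i - 1])
      }
      if (i >= 3) {
        tri <- bump(tri, paste(toks[i - 2], toks[i - 1], toks[i]))
        tri_ctx <- bump(tri_ctx, paste(toks[i - 2], toks[i - 1]))
      }
    }
  }
  list(uni = uni, big = big, tri = tri, big_ctx = big_ctx, tri_ctx = tri_ctx,
       n_tokens = sum(uni))
}

# brute-force surprisal of one utterance from the tally above
brute_force_surprisal <- function(counts, toks, base = 2) {
  n <- length(toks)
  p <- numeric(n)
  p[1] <- counts$uni[toks[1]] / counts$n_tokens
  if (n >= 2) p[2] <- counts$big[paste(toks[1], toks[2])] / counts$big_ctx[toks[1]]
  if (n >= 3) {
    for (i in 3:n) {
      p[i] <- counts$tri[paste(toks[i - 2], toks[i - 1], toks[i])] /
        counts$tri_ctx[paste(toks[i - 2], toks[i - 1])]
    }
  }
  -log(unname(p), base = base)
}
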