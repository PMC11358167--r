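zipf_weights <- function(exponent, support) {
  p <- seq_len(support)^(-exponent)
  p / sum(p)
}

entropy_bits <- function(p) -sum(p * log2(p))

# solve for the Zipf exponent whose truncated distribution has the target
# entropy (entropy is strictly decreasing in the exponent)
solve_zipf_exponent <- function(target_bits, support) {
  h_max <- log2(support)
  if (target_bits > h_max - 1e-9) return(NA_real_)
  if (target_bits <= entropy_bits(zipf_weights(30, support))) return(30)
  stats::uniroot(function(a) entropy_bits(zipf_weights(a, support)) - target_bits,
                 c(0, 30), tol = 1e-10)$root
}

#' Configuration for the synthetic dialogue generator
#'
#' The generator emits dyadic conversations with alternating speakers.
#' Words are drawn from two context-conditional families over a Zipfian
#' vocabulary: each family is a Zipf-weighted distribution over the top
#' `context_support` offsets from a context-dependent shift (taken modulo
#' `context_modulus`, which gives genuine trigram dependence while keeping
#' contexts frequent enough for maximum-likelihood recovery). The sparse
#' family uses `zipf_exponent`; the dense family's exponent is solved so its
#' entropy exceeds the sparse family's by `delta_bits`, which makes
#' `delta_bits` the expected per-word true-surprisal gap between the dense
#' and sparse halves. The dense half is the last half under
#' `loading_mode = "back"`, the first under `"front"`, and neither under
#' `"flat"`.
#'
#' POS tags are drawn position-dependently: in the dense half the NOUN and
#' VERB probabilities are each raised by `pos_enrichment` (other categories
#' rescaled). Durations are `n_words / words_per_second`; inter-turn gaps
#' are Gaussian with the configured FTO mean and SD (negative draws produce
#' overlaps). Optional filler injection exercises the cleaning stage:
#' fillers carry the INTJ tag and are not part of the generating process, so
#' ground truth aligns with the cleaned corpus.
#'
#' @param language Language label.
#' @param n_dyads,conversations_per_dyad,utterances_per_conversation Corpus
#'   shape (defaults 50 x 2 x 20 = 2,000 utterances).
#' @param length_min,length_max,length_shape Utterance lengths are
#'   `length_min + Binomial(length_max - length_min, length_shape)`, chosen
#'   to straddle the 8-token analysis threshold (defaults 4..18, mean ~11).
#' @param vocab_size Vocabulary size (>= 50).
#' @param zipf_exponent Sparse-family Zipf exponent (default 1.6).
#' @param context_support Continuations per context (default 16); bounds the
#'   feasible `delta_bits` at `log2(context_support)` minus the sparse
#'   family's entropy.
#' @param context_modulus Number of distinct context shifts (default 4).
#' @param loading_mode `"flat"`, `"front"` or `"back"`.
#' @param delta_bits Target expected true-surprisal gap (bits, >= 0).
#' @param pos_enrichment Added NOUN and VERB probability in the dense half.
#' @param pos_jitter_sd Between-speaker heterogeneity in noun/verb usage:
#'   a dyad-level plus speaker-level Gaussian deviation (SDs `pos_jitter_sd`
#'   and half of it, clamped to +/-0.08) added to each speaker's NOUN and
#'   VERB probabilities in both halves, so rate targets hold in expectation
#'   while speakers differ - giving the rate models' random intercepts real
#'   variance.
#' @param entropy_jitter_sd Between-speaker heterogeneity: each speaker's
#'   sparse-family entropy is the base entropy plus a dyad-level and a
#'   speaker-level Gaussian deviation (SDs `entropy_jitter_sd` and half of
#'   it), with the dense family always `delta_bits` above that speaker's
#'   sparse family - so the expected half gap stays exactly `delta_bits`
#'   while dyads and speakers differ in overall predictability, giving the
#'   dyad/speaker random intercepts of the analysis models real variance.
#' @param fto_mean_ms,fto_sd_ms Inter-turn gap distribution (ms).
#' @param fto_dyad_sd_ms Between-dyad SD of the FTO mean (ms).
#' @param words_per_second Speech-rate constant for durations.
#' @param filler_rate Per-slot probability of injecting a filled pause.
#' @param seed Integer seed; identical configs and seeds reproduce the
#'   corpus exactly.
#' @return A `generator_config` list with the two calibrated families
#'   attached.
#' @export
generator_config <- function(language = "synth",
                             n_dyads = 50,
                             conversations_per_dyad = 2,
                             utterances_per_conversation = 20,
                             length_min = 4, length_max = 18, length_shape = 0.5,
                             vocab_size = 100,
                             zipf_exponent = 1.6,
                             context_support = 16,
                             context_modulus = 4,
                             loading_mode = c("flat", "front", "back"),
                             delta_bits = 0,
                             pos_enrichment = 0,
                             pos_jitter_sd = 0.02,
                             entropy_jitter_sd = 0.08,
                             fto_mean_ms = 200, fto_sd_ms = 150,
                             fto_dyad_sd_ms = 30,
                             words_per_second = 3,
                             filler_rate = 0,
                             seed = 1) {
  loading_mode <- match.arg(loading_mode)
  stopifnot(n_dyads >= 1, conversations_per_dyad >= 1,
            utterances_per_conversation >= 1,
            length_min >= 1, length_max >= length_min,
            length_shape > 0, length_shape < 1,
            vocab_size >= 50, context_support >= 2,
            context_support <= vocab_size,
            context_modulus >= 1, delta_bits >= 0,
            pos_enrichment >= 0, words_per_second > 0,
            pos_jitter_sd >= 0, entropy_jitter_sd >= 0, fto_dyad_sd_ms >= 0,
            filler_rate >= 0, filler_rate < 1)
  p_sparse <- zipf_weights(zipf_exponent, context_support)
  h_sparse <- entropy_bits(p_sparse)
  a_dense <- solve_zipf_exponent(h_sparse + delta_bits, context_support)
  if (is.na(a_dense)) {
    stop(sprintf(paste0("delta_bits = %.3f is not reachable: the dense family ",
                        "can add at most %.3f bits over the sparse family ",
                        "(support %d, sparse entropy %.3f bits)"),
                 delta_bits, log2(context_support) - h_sparse,
                 context_support, h_sparse), call. = FALSE)
  }
  p_dense <- zipf_weights(a_dense, context_support)
  base_pos <- c(NOUN = 0.21, VERB = 0.13, PRON = 0.12, ADP = 0.10, DET = 0.09,
                ADV = 0.08, ADJ = 0.07, AUX = 0.05, CCONJ = 0.04, SCONJ = 0.03,
                PART = 0.03, NUM = 0.02, INTJ = 0.03)
  if (2 * pos_enrichment >= 1 - base_pos[["NOUN"]] - base_pos[["VERB"]]) {
    stop("pos_enrichment too large for the base POS distribution", call. = FALSE)
  }
  structure(list(language = language, n_dyads = n_dyads,
                 conversations_per_dyad = conversations_per_dyad,
                 utterances_per_conversation = utterances_per_conversation,
                 length_min = as.integer(length_min),
                 length_max = as.integer(length_max),
                 length_shape = length_shape,
                 vocab_size = as.integer(vocab_size),
                 zipf_exponent = zipf_exponent,
                 context_support = as.integer(context_support),
                 context_modulus = as.integer(context_modulus),
                 loading_mode = loading_mode, delta_bits = delta_bits,
                 pos_enrichment = pos_enrichment,
                 pos_jitter_sd = pos_jitter_sd,
                 entropy_jitter_sd = entropy_jitter_sd,
                 fto_mean_ms = fto_mean_ms, fto_sd_ms = fto_sd_ms,
                 fto_dyad_sd_ms = fto_dyad_sd_ms,
                 words_per_second = words_per_second,
                 filler_rate = filler_rate, seed = as.integer(seed),
                 p_sparse = p_sparse, p_dense = p_dense,
                 base_pos = base_pos),
            class = "generator_config")
}

pos_probs <- function(config, dense, nv_shift = 0) {
  p <- config$base_pos
  e <- (if (dense) config$pos_enrichment else 0) + nv_shift
  nv <- c("NOUN", "VERB")
  other <- setdiff(names(p), nv)
  p[other] <- p[other] * (1 - sum(p[nv]) - 2 * e) / sum(p[other])
  p[nv] <- p[nv] + e
  p
}

#' Generate a synthetic dialogue corpus with ground truth
#'
#' See [generator_config()] for the generating process. Returns both the
#' corpus and the generator-side ground truth: each token's true surprisal
#' (`-log2` of its generating probability given its realized context), its
#' POS label, the utterance's loading mode, and the FTO parameters used.
#'
#' @param config A [generator_config()].
#' @return A list of class `synthetic_corpus`: `corpus` (a [conv_corpus()]),
#'   `truth` (tibble keyed by `utterance_id` with list-columns
#'   `true_surprisal` and `tags` aligned to the cleaned tokens, plus
#'   `loading_mode`, `fto_mean_ms`, `fto_sd_ms`), and `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  n_conv <- config$n_dyads * config$conversations_per_dyad
  n_utt <- n_conv * config$utterances_per_conversation
  dyad <- rep(sprintf("%s_d%03d", config$language, seq_len(config$n_dyads)),
              each = config$conversations_per_dyad * config$utterances_per_conversation)
  conv_no <- rep(rep(seq_len(config$conversations_per_dyad),
                     each = config$utterances_per_conversation), config$n_dyads)
  conv <- sprintf("%s_c%d", dyad, conv_no)
  utt_in_conv <- rep(seq_len(config$utterances_per_conversation), n_conv)
  speaker <- paste0(dyad, "_", ifelse(utt_in_conv %% 2 == 1, "A", "B"))

  len <- config$length_min +
    stats::rbinom(n_utt, config$length_max - config$length_min, config$length_shape)
  maxlen <- max(len)
  V <- config$vocab_size
  m <- config$context_modulus
  s <- config$context_support

  # cell masks: which matrix cells hold a token, and which are in the dense
  # half (positions past floor(n/2) for back-loading, up to it for front)
  split_at <- floor(len / 2)
  pos_grid <- matrix(rep(seq_len(maxlen), each = n_utt), n_utt, maxlen)
  ACT <- pos_grid <= len
  DENSE <- switch(config$loading_mode,
                  back = ACT & pos_grid > split_at,
                  front = ACT & pos_grid <= split_at,
                  flat = ACT & FALSE)

  # per-speaker families: sparse entropy = base + dyad + speaker deviations,
  # dense entropy exactly delta_bits above, so the expected half gap is
  # delta_bits for every speaker while speakers differ in predictability
  spk_levels <- unique(speaker)
  spk_dyad <- sub("_[AB]$", "", spk_levels)
  h_base <- entropy_bits(config$p_sparse)
  j <- config$entropy_jitter_sd
  dyad_dev <- stats::setNames(stats::rnorm(length(unique(spk_dyad)), 0, j),
                              unique(spk_dyad))
  h_spk <- h_base + dyad_dev[spk_dyad] + stats::rnorm(length(spk_levels), 0, j / 2)
  h_spk <- pmin(pmax(h_spk, 0.3), log2(s) - config$delta_bits - 0.02)
  fam_sparse <- lapply(h_spk, function(h) zipf_weights(solve_zipf_exponent(h, s), s))
  fam_dense <- lapply(h_spk, function(h) {
    zipf_weights(solve_zipf_exponent(h + config$delta_bits, s), s)
  })

  # offsets and true surprisal are iid given (speaker, family): draw per
  # speaker and family in one vectorized call each
  OFF <- matrix(NA_integer_, n_utt, maxlen)
  TS <- matrix(NA_real_, n_utt, maxlen)
  spk_idx <- match(speaker, spk_levels)
  SPK <- matrix(spk_idx, n_utt, maxlen)
  for (k in seq_along(spk_levels)) {
    for (fam in c("sparse", "dense")) {
      p_fam <- if (fam == "dense") fam_dense[[k]] else fam_sparse[[k]]
      cells <- which(ACT & SPK == k & (DENSE == (fam == "dense")))
      if (length(cells) == 0) next
      off <- sample.int(s, length(cells), replace = TRUE, prob = p_fam) - 1L
      OFF[cells] <- off
      TS[cells] <- -log2(p_fam[off + 1L])
    }
  }

  # realize words: shift from the two preceding words (uniform at position 1
  # so the context process is stationary across positions)
  W <- matrix(NA_integer_, n_utt, maxlen)
  for (p in seq_len(maxlen)) {
    act <- which(len >= p)
    shift <- if (p == 1) sample.int(m, n_utt, replace = TRUE) - 1L
             else if (p == 2) W[, 1] %% m
             else (W[, p - 2L] + W[, p - 1L]) %% m
    W[cbind(act, p)] <- (shift[act] + OFF[cbind(act, p)]) %% V
  }

  tokens <- lapply(seq_len(n_utt), function(i) sprintf("w%03d", W[i, seq_len(len[i])] + 1L))
  true_surprisal <- lapply(seq_len(n_utt), function(i) TS[i, seq_len(len[i])])

  # POS tags, enriched for NOUN/VERB in the dense half, with a per-speaker
  # usage deviation shared by both halves
  nv_dev <- dyad_dev_pos <- stats::setNames(
    stats::rnorm(length(unique(spk_dyad)), 0, config$pos_jitter_sd),
    unique(spk_dyad))
  nv_dev <- dyad_dev_pos[spk_dyad] +
    stats::rnorm(length(spk_levels), 0, config$pos_jitter_sd / 2)
  nv_dev <- pmin(pmax(nv_dev, -0.08), 0.08)
  p_dense_pos <- lapply(nv_dev, function(d) pos_probs(config, TRUE, d))
  p_sparse_pos <- lapply(nv_dev, function(d) pos_probs(config, FALSE, d))
  labs <- names(config$base_pos)
  tags <- lapply(seq_len(n_utt), function(i) {
    dense <- DENSE[i, seq_len(len[i])]
    tg <- character(len[i])
    k <- spk_idx[i]
    if (any(dense)) tg[dense] <- sample(labs, sum(dense), TRUE, p_dense_pos[[k]])
    if (any(!dense)) tg[!dense] <- sample(labs, sum(!dense), TRUE, p_sparse_pos[[k]])
    tg
  })

  # timings: duration from speech rate, inter-turn gaps from the FTO law
  # with a dyad-level offset on the mean
  dur <- as.integer(round(len / config$words_per_second * 1000))
  dyad_fto <- stats::setNames(stats::rnorm(config$n_dyads, 0, config$fto_dyad_sd_ms),
                              unique(dyad))
  gap <- as.integer(round(stats::rnorm(n_utt, config$fto_mean_ms + dyad_fto[dyad],
                                       config$fto_sd_ms)))
  start <- integer(n_utt)
  end <- integer(n_utt)
  for (ci in split(seq_len(n_utt), conv)) {
    t0 <- 0L
    for (i in ci) {
      start[i] <- t0
      end[i] <- t0 + dur[i]
      t0 <- end[i] + gap[i]
    }
  }

  # optional filled-pause injection (ground truth stays aligned with the
  # cleaned tokens, so cleaning recovers the generating sequence exactly)
  out_tokens <- tokens
  out_tags <- tags
  if (config$filler_rate > 0) {
    fillers <- default_fillers("english")[1:3]
    for (i in seq_len(n_utt)) {
      ins <- which(stats::runif(len[i]) < config$filler_rate)
      if (length(ins) > 0) {
        tk <- tokens[[i]]; tg <- tags[[i]]
        for (j in rev(ins)) {
          tk <- append(tk, sample(fillers, 1), after = j)
          tg <- append(tg, "INTJ", after = j)
        }
        out_tokens[[i]] <- tk
        out_tags[[i]] <- tg
      }
    }
  }

  corpus <- conv_corpus(tibble::tibble(
    language = config$language, conversation_id = conv, dyad_id = dyad,
    speaker = speaker, start_ms = start, end_ms = end,
    tokens = out_tokens, tags = out_tags,
    utterance_id = sprintf("%s_u%03d", conv, utt_in_conv)
  ), validate = FALSE)

  truth <- tibble::tibble(
    utterance_id = corpus$utterance_id,
    loading_mode = config$loading_mode,
    true_surprisal = true_surprisal[match(corpus$utterance_id,
                                          sprintf("%s_u%03d", conv, utt_in_conv))],
    tags = tags[match(corpus$utterance_id, sprintf("%s_u%03d", conv, utt_in_conv))],
    fto_mean_ms = config$fto_mean_ms,
    fto_sd_ms = config$fto_sd_ms
  )
  structure(list(corpus = corpus, truth = truth, config = config),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus> %s: %d utterances, loading %s (delta %.2f bits), seed %d\n",
              x$config$language, nrow(x$corpus), x$config$loading_mode,
              x$config$delta_bits, x$config$seed))
  invisible(x)
}

#' Ground-truth surprisal for one utterance
#'
#' @param truth The `truth` element of a [generate_corpus()] result (or the
#'   result itself).
#' @param utterance_id An utterance id from the generated corpus.
#' @return Numeric vector of per-token true surprisal in bits.
#' @export
true_surprisal <- function(truth, utterance_id) {
  if (inherits(truth, "synthetic_corpus")) truth <- truth$truth
  i <- match(utterance_id, truth$utterance_id)
  if (is.na(i)) stop("unknown utterance: ", utterance_id, call. = FALSE)
  truth$true_surprisal[[i]]
}

#' Standard synthetic fixtures
#'
#' * `tiny`: one flat language, 2 dyads x 8 utterances (oracle-sized).
#' * `reference`: the calibrated six-language suite - three back-loaded
#'   languages (delta = +0.5 bits, FTO mean 300 ms) and three front-loaded
#'   (delta = -0.5 bits, FTO mean 200 ms), 2,000 utterances (50 dyads) each,
#'   NOUN/VERB enrichment 0.08 in the dense half.
#' * `null`: six flat languages, no surprisal gap, no enrichment, common
#'   FTO mean (250 ms), 800 utterances (40 dyads) each.
#'
#' @param name `"tiny"`, `"reference"` or `"null"`.
#' @param seed Master seed; per-language seeds are derived deterministically.
#' @param n_dyads,utterances_per_conversation Optional size overrides for
#'   the multi-language fixtures.
#' @return For `tiny`, a `synthetic_corpus`; otherwise a list with combined
#'   `corpus`, `truth`, per-language `configs`, and the condition map
#'   `loading_group`.
#' @export
make_fixture <- function(name = c("tiny", "reference", "null"), seed = 1,
                         n_dyads = NULL, utterances_per_conversation = NULL) {
  name <- match.arg(name)
  if (name == "tiny") {
    return(generate_corpus(generator_config(
      language = "tiny", n_dyads = 2, conversations_per_dyad = 1,
      utterances_per_conversation = 8, length_min = 4, length_max = 12,
      loading_mode = "flat", seed = seed)))
  }
  if (name == "reference") {
    modes <- c(back1 = "back", back2 = "back", back3 = "back",
               front1 = "front", front2 = "front", front3 = "front")
    delta <- 0.5; enrich <- 0.08
    fto <- c(back = 300, front = 200)
    nd <- n_dyads %||% 50
    upc <- utterances_per_conversation %||% 20
  } else {
    modes <- stats::setNames(rep("flat", 6), paste0("null", 1:6))
    delta <- 0; enrich <- 0
    fto <- c(flat = 250, back = 250, front = 250)
    nd <- n_dyads %||% 40
    upc <- utterances_per_conversation %||% 20
  }
  sims <- lapply(seq_along(modes), function(k) {
    generate_corpus(generator_config(
      language = names(modes)[k], loading_mode = modes[[k]],
      delta_bits = delta, pos_enrichment = enrich,
      fto_mean_ms = fto[[modes[[k]]]],
      n_dyads = nd, conversations_per_dyad = if (name == "reference") 2 else 1,
      utterances_per_conversation = upc,
      seed = seed * 101 + k))
  })
  list(corpus = conv_corpus(dplyr::bind_rows(lapply(sims, `[[`, "corpus")),
                            validate = FALSE),
       truth = dplyr::bind_rows(lapply(sims, `[[`, "truth")),
       configs = lapply(sims, `[[`, "config"),
       loading_group = stats::setNames(
         ifelse(unname(modes) == "flat", NA_character_, unname(modes)),
         names(modes)))
}
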