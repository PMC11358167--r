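test_that("identical configs and seeds reproduce the corpus exactly", {
  cfg <- generator_config(language = "g", n_dyads = 5, seed = 77,
                          loading_mode = "back", delta_bits = 0.8,
                          pos_enrichment = 0.05, filler_rate = 0.05)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a$corpus, b$corpus)
  expect_identical(a$truth, b$truth)
  c2 <- generate_corpus(generator_config(language = "g", n_dyads = 5, seed = 78,
                                         loading_mode = "back", delta_bits = 0.8))
  expect_false(identical(a$corpus$tokens, c2$corpus$tokens))
})

test_that("generated corpora satisfy the corpus invariants and survive cleaning", {
  fx <- generate_corpus(generator_config(language = "g", n_dyads = 6, seed = 3,
                                         loading_mode = "front", delta_bits = 0.5))
  expect_silent(validate_corpus(fx$corpus))
  expect_true(all(vapply(split(fx$corpus$speaker, fx$corpus$conversation_id),
                         function(s) length(unique(s)) == 2, TRUE)))
  cleaned <- clean_corpus(fx$corpus)
  expect_identical(cleaned$tokens, fx$corpus$tokens)
  expect_equal(attr(cleaned, "n_dropped_empty"), 0)

  # with filler injection, cleaning recovers the truth-aligned sequence
  fx2 <- generate_corpus(generator_config(language = "g", n_dyads = 6, seed = 3,
                                          loading_mode = "front", delta_bits = 0.5,
                                          filler_rate = 0.08))
  expect_gt(sum(lengths(fx2$corpus$tokens)), sum(lengths(fx$corpus$tokens)))
  cleaned2 <- clean_corpus(fx2$corpus)
  expect_identical(cleaned2$tokens, fx$corpus$tokens)
  expect_identical(cleaned2$tags, fx2$truth$tags[match(cleaned2$utterance_id,
                                                       fx2$truth$utterance_id)])
})

test_that("true surprisal matches the generating families in closed form", {
  # jitter off so the two base families are the exact generating laws
  cfg <- generator_config(language = "g", n_dyads = 4, seed = 11,
                          loading_mode = "back", delta_bits = 1,
                          entropy_jitter_sd = 0)
  fx <- generate_corpus(cfg)
  # every true surprisal is one of the two families' point surprisals
  allowed <- sort(unique(round(c(-log2(cfg$p_sparse), -log2(cfg$p_dense)), 6)))
  ts <- round(unlist(fx$truth$true_surprisal), 6)
  expect_true(all(ts %in% allowed))
  expect_true(all(ts >= 0))
  # accessor returns the aligned vector and rejects foreign utterances
  id <- fx$corpus$utterance_id[4]
  expect_length(true_surprisal(fx, id), length(fx$corpus$tokens[[4]]))
  expect_error(true_surprisal(fx, "nope"), "unknown")
})

test_that("delta_bits calibration matches the analytic entropy gap", {
  cfg <- generator_config(delta_bits = 0.7)
  h <- function(p) -sum(p * log2(p))
  expect_equal(h(cfg$p_dense) - h(cfg$p_sparse), 0.7, tolerance = 1e-8)
  # infeasible targets fail with the feasible maximum named
  expect_error(generator_config(delta_bits = 3.5, context_support = 16),
               "at most")
})

test_that("the empirical true-surprisal gap tracks the configured delta", {
  for (mode in c("back", "front", "flat")) {
    fx <- generate_corpus(generator_config(language = "g", n_dyads = 25,
                                           utterances_per_conversation = 20,
                                           loading_mode = mode,
                                           delta_bits = if (mode == "flat") 0 else 1,
                                           seed = 5))
    flt <- filter_utterances(fx$corpus)
    ts <- fx$truth$true_surprisal[match(flt$utterance_id, fx$truth$utterance_id)]
    diffs <- vapply(ts, function(v) compute_half_stats(v)$diff, 0)
    expected <- switch(mode, back = 1, front = -1, flat = 0)
    expect_equal(mean(diffs), expected, tolerance = 0.2)
  }
})

test_that("fixtures have the documented shapes", {
  tiny <- make_fixture("tiny", seed = 1)
  expect_lte(nrow(tiny$corpus), 20)
  ref <- make_fixture("reference", seed = 1, n_dyads = 2)
  expect_setequal(unique(ref$corpus$language),
                  c("back1", "back2", "back3", "front1", "front2", "front3"))
  expect_equal(unname(ref$loading_group[c("back1", "front3")]), c("back", "front"))
  nul <- make_fixture("null", seed = 1, n_dyads = 2)
  expect_true(all(vapply(nul$configs, function(cf) cf$delta_bits == 0, TRUE)))
  expect_equal(length(unique(vapply(nul$configs, function(cf) cf$fto_mean_ms, 0))), 1)
})
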