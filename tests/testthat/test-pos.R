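test_that("unit rates follow the per-half worked example", {
  # 7 words in a half, 3 of them verbs -> rate 3/7
  tags <- c("NOUN", "DET", "VERB", "VERB", "ADV", "VERB", "NOUN",
            "PRON", "NOUN", "DET", "NOUN", "ADJ", "NOUN", "CCONJ")
  surp <- c(5, 4, 2, 4, 1, 3, 2, 1, 6, 1, 2, 3, 4, 1)
  us <- unit_half_stats(tags, surp, "VERB")
  expect_equal(us$n_words_half, c(7, 7))
  expect_equal(us$rate[us$half == "first"], 3 / 7)
  expect_equal(round(us$rate[us$half == "first"], 3), 0.429)
  expect_equal(us$rate[us$half == "last"], 0)
  # unit absent from a half -> no unit surprisal
  expect_true(is.na(us$mean_unit_surprisal[us$half == "last"]))
  # first-half unit surprisal averages the verbs at positions 3, 4, 6 only
  expect_equal(us$mean_unit_surprisal[us$half == "first"], mean(c(2, 4, 3)))

  # positions 1-2 count toward the rate but not the surprisal mean
  tags2 <- c("VERB", "VERB", "DET", "NOUN", "PRON", "VERB", "NOUN", "ADV")
  surp2 <- c(10, 10, 1, 1, 1, 2, 1, 1)
  us2 <- unit_half_stats(tags2, surp2, "VERB")
  expect_equal(us2$rate, c(2 / 4, 1 / 4))
  expect_true(is.na(us2$mean_unit_surprisal[1]))  # only reduced-context verbs
  expect_equal(us2$mean_unit_surprisal[2], 2)

  # per-utterance denominator variant
  us3 <- unit_half_stats(tags2, surp2, "VERB", rate_denominator = "utterance")
  expect_equal(us3$rate, c(2 / 8, 1 / 8))
})

test_that("per-half rates over all labels sum to one", {
  fx <- generate_corpus(generator_config(language = "g", n_dyads = 3,
                                         utterances_per_conversation = 8,
                                         pos_enrichment = 0.05,
                                         loading_mode = "back", delta_bits = 0.5,
                                         seed = 21))
  i <- which(lengths(fx$corpus$tokens) >= 8)[1]
  tags <- fx$corpus$tags[[i]]
  surp <- rep(1, length(tags))
  rates <- vapply(unique(tags), function(u) unit_half_stats(tags, surp, u)$rate,
                  c(0, 0))
  expect_equal(rowSums(rates), c(1, 1))
})

test_that("tagging is pluggable and validates alignment", {
  cc <- toy_corpus(c("a b c", "d e f"))
  expect_error(tag_corpus(cc), "no tagger")
  tagged <- tag_corpus(cc, tagger = function(toks) rep("NOUN", length(toks)))
  expect_equal(tagged$tags[[1]], c("NOUN", "NOUN", "NOUN"))
  # already-tagged corpora pass through unchanged
  expect_identical(tag_corpus(tagged, tagger = function(toks) rep("X", length(toks))),
                   tagged)
  expect_error(tag_corpus(cc, tagger = function(toks) "NOUN"), "alignment|returned")
})

test_that("the unit table has two rows per unit per half and matches a recount", {
  fx <- generate_corpus(generator_config(language = "g", n_dyads = 4,
                                         utterances_per_conversation = 10,
                                         pos_enrichment = 0.08,
                                         loading_mode = "back", delta_bits = 0.5,
                                         seed = 31))
  m <- train_trigram_model(fx$corpus)
  flt <- filter_utterances(fx$corpus)
  ut <- unit_stats_table(flt, m, loading_group = c(g = "back"))
  expect_equal(nrow(ut), 4 * nrow(flt))
  expect_identical(ut, unit_stats_table(flt, m, loading_group = c(g = "back")))
  expect_true(all(ut$loading_group == "back"))
  expect_true(all(ut$rate >= 0 & ut$rate <= 1))
  expect_true(all(is.na(ut$mean_unit_surprisal) == (ut$n_unit == 0 |
    mapply(function(id, h, u) {
      i <- match(id, flt$utterance_id)
      tg <- flt$tags[[i]]; sp <- split_halves(length(tg))
      idx <- if (h == "first") sp$first else sp$last
      !any(tg[idx] == u & idx > 2)
    }, ut$utterance_id, ut$half, ut$unit))))

  # cross-check every row against the single-utterance computation
  for (i in seq_len(min(5, nrow(flt)))) {
    toks <- flt$tokens[[i]]
    s <- utterance_surprisal(m, toks)$surprisal
    for (u in c("NOUN", "VERB")) {
      ref <- unit_half_stats(flt$tags[[i]], s, u)
      got <- ut[ut$utterance_id == flt$utterance_id[i] & ut$unit == u, ]
      expect_equal(got$rate, ref$rate)
      expect_equal(got$n_unit, ref$n_unit)
      expect_equal(got$mean_unit_surprisal, ref$mean_unit_surprisal)
    }
  }
})

test_that("configured noun/verb enrichment shows up in last-half rates", {
  fx <- generate_corpus(generator_config(language = "g", n_dyads = 25,
                                         utterances_per_conversation = 20,
                                         pos_enrichment = 0.08,
                                         loading_mode = "back", delta_bits = 0.5,
                                         seed = 41))
  m <- train_trigram_model(fx$corpus)
  flt <- filter_utterances(fx$corpus)
  ut <- unit_stats_table(flt, m, loading_group = c(g = "back"))
  mean_rate <- tapply(ut$rate, list(ut$half, ut$unit), mean)
  # dense (last) half should be enriched for both units by about 0.08
  expect_gt(mean_rate["last", "NOUN"], mean_rate["first", "NOUN"] + 0.04)
  expect_gt(mean_rate["last", "VERB"], mean_rate["first", "VERB"] + 0.04)
  # realized rates near the configured targets
  expect_equal(unname(mean_rate["first", "NOUN"]), 0.21, tolerance = 0.1)
  expect_equal(unname(mean_rate["last", "NOUN"]), 0.29, tolerance = 0.1)
})
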