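make_lang <- function(lang, mode, delta = 0.5, n_dyads = 15, fto = 250,
                      seed = 1, enrich = 0) {
  generate_corpus(generator_config(language = lang, loading_mode = mode,
                                   delta_bits = delta, n_dyads = n_dyads,
                                   utterances_per_conversation = 20,
                                   pos_enrichment = enrich,
                                   fto_mean_ms = fto, seed = seed))
}

lang_loading <- function(fx) {
  m <- train_trigram_model(fx$corpus)
  corpus_loading_table(filter_utterances(fx$corpus), m)
}

test_that("the half-effect LRT recovers injected loading with the right sign", {
  lt_back <- lang_loading(make_lang("b", "back", seed = 101))
  res <- lrt_half_effect(lt_back)
  expect_s3_class(res, "model_comparison")
  expect_gte(res$chisq, 0)
  expect_equal(res$df, 1)
  expect_equal(res$alpha_used, 0.008)
  expect_true(res$significant)
  est <- res$estimates$estimate[grepl("^half", res$estimates$term)]
  expect_gt(est, 0)

  lt_front <- lang_loading(make_lang("f", "front", seed = 102))
  res_f <- lrt_half_effect(lt_front)
  expect_true(res_f$significant)
  expect_lt(res_f$estimates$estimate[grepl("^half", res_f$estimates$term)], 0)
})

test_that("degenerate single-dyad data fails loudly instead of dropping effects", {
  fx <- generate_corpus(generator_config(language = "g", n_dyads = 1, seed = 5))
  lt <- lang_loading(fx)
  expect_error(lrt_half_effect(lt), "dyad")
})

test_that("cross-language contrasts separate the loading groups under Tukey", {
  sims <- list(make_lang("b1", "back", seed = 201), make_lang("b2", "back", seed = 202),
               make_lang("f1", "front", seed = 203), make_lang("f2", "front", seed = 204))
  models <- lapply(sims, function(fx) train_trigram_model(fx$corpus))
  names(models) <- vapply(sims, function(fx) fx$config$language, "")
  corpus <- conv_corpus(dplyr::bind_rows(lapply(sims, `[[`, "corpus")),
                        validate = FALSE)
  lt <- corpus_loading_table(filter_utterances(corpus), models)
  res <- cross_language_model(lt)
  expect_true(res$comparison$significant)
  expect_equal(res$comparison$df, 3)
  expect_equal(nrow(res$contrasts), choose(4, 2))
  expect_true(all(res$contrasts$adjusted_p >= 0 & res$contrasts$adjusted_p <= 1))
  cross <- grepl("^b\\d - f\\d$|^f\\d - b\\d$", res$contrasts$contrast)
  expect_true(all(res$contrasts$adjusted_p[cross] < 0.05))
  expect_true(all(res$contrasts$adjusted_p[!cross] > 0.05))
  # back-loaded languages have the larger surprisal difference
  expect_true(all(res$contrasts$estimate[cross][grepl("^b", res$contrasts$contrast[cross])] > 0))
})

ref_unit_table <- function(seed = 301, n_dyads = 8) {
  langs <- list(c("b1", "back"), c("b2", "back"), c("f1", "front"), c("f2", "front"))
  sims <- lapply(seq_along(langs), function(k) {
    make_lang(langs[[k]][1], langs[[k]][2], n_dyads = n_dyads,
              seed = seed + k, enrich = 0.08)
  })
  models <- lapply(sims, function(fx) train_trigram_model(fx$corpus))
  names(models) <- vapply(sims, function(fx) fx$config$language, "")
  corpus <- conv_corpus(dplyr::bind_rows(lapply(sims, `[[`, "corpus")),
                        validate = FALSE)
  flt <- filter_utterances(corpus)
  groups <- c(b1 = "back", b2 = "back", f1 = "front", f2 = "front")
  lt <- corpus_loading_table(flt, models)
  list(unit = unit_stats_table(flt, models, loading_group = groups, loading = lt),
       loading = lt)
}

test_that("the unit surprisal model finds the loading-by-half interaction", {
  ut <- ref_unit_table()$unit
  res <- unit_surprisal_model(ut)
  expect_s3_class(res, "model_comparison")
  expect_equal(nrow(res$steps), 5)
  expect_true(res$significant)  # interactions beat main effects
  lh <- res$estimates[res$estimates$term ==
    "Front Loaded > Back Loaded x Utterance Half (Last > First)", ]
  expect_equal(nrow(lh), 1)
  # front-loaded languages have the lower last-half unit surprisal
  expect_lt(lh$estimate, 0)
  expect_gt(abs(lh$estimate / lh$se), 2)
})

test_that("the beta-family rate model finds the loading-by-half interaction", {
  ut <- ref_unit_table()$unit
  res <- unit_rate_model(ut)
  expect_true(res$significant)
  expect_gte(res$chisq, 0)
  lh <- res$estimates[res$estimates$term ==
    "Front Loaded > Back Loaded x Utterance Half (Last > First)", ]
  expect_lt(lh$estimate, 0)
})

test_that("rates at the boundary are squeezed strictly inside (0, 1)", {
  ut <- ref_unit_table()$unit
  n <- nrow(ut)
  y <- (ut$rate * (n - 1) + 0.5) / n
  expect_true(any(ut$rate == 0))
  expect_true(all(y > 0 & y < 1))
})

test_that("sum coding gives zero column sums on balanced factors", {
  dat <- expand.grid(unit = c("NOUN", "VERB"), loading_group = c("back", "front"),
                     half = c("first", "last"), stringsAsFactors = FALSE)
  dat <- convload:::code_unit_factors(dat)
  mm <- stats::model.matrix(~ unit * loading_group * half, dat)
  expect_true(all(abs(colSums(mm[, -1])) < 1e-12))
})

simulate_diff_data <- function(n_dyads = 30, per_dyad = 40, seed = 11,
                               interaction = FALSE) {
  set.seed(seed)
  n <- n_dyads * per_dyad
  dyad <- rep(sprintf("d%02d", seq_len(n_dyads)), each = per_dyad)
  speaker <- paste0(dyad, rep(c("A", "B"), length.out = n))
  re <- rep(stats::rnorm(n_dyads, 0, 0.2), each = per_dyad)
  dat <- tibble::tibble(
    dyad = dyad, speaker = speaker,
    utterance_id = sprintf("u%05d", seq_len(n)),
    unit = sample(c("NOUN", "VERB"), n, TRUE),
    loading_group = sample(c("back", "front"), n, TRUE),
    half = sample(c("first", "last"), n, TRUE),
    rate = stats::runif(n, 0, 0.5),
    mean_unit_surprisal = stats::rnorm(n, 3, 1)
  )
  half_num <- ifelse(dat$half == "last", 1, -1)
  dat$diff <- 0.3 * dat$rate - 0.2 * dat$mean_unit_surprisal + re +
    (if (interaction) 0.35 * half_num * dat$mean_unit_surprisal else 0) +
    stats::rnorm(n, 0, 0.5)
  dat
}

test_that("backwards selection prunes absent interactions and keeps real ones", {
  dat <- simulate_diff_data()
  loading <- tibble::tibble(utterance_id = dat$utterance_id, diff = dat$diff)
  res <- backwards_select(dat, loading)
  expect_s3_class(res, "model_comparison")
  expect_true(res$significant)  # main effects carry real signal vs. base
  # every non-significant removal left the term out of the final model, and
  # the search stopped at the first significant one
  removed <- res$steps$term[res$steps$removed]
  expect_gt(length(removed), 0)
  expect_false(any(vapply(gsub(":", ".*", removed), function(pat) {
    any(grepl(pat, gsub(" x ", ":", res$estimates$term), ignore.case = TRUE))
  }, TRUE)))
  sig_steps <- which(!res$steps$removed)
  expect_true(length(sig_steps) == 0 || identical(sig_steps, nrow(res$steps)))
  # the real main effects survive selection
  expect_true(any(grepl("^rate$", res$estimates$term)))
  expect_true(any(grepl("^surprisal$", res$estimates$term)))
  # deterministic removal order
  res2 <- backwards_select(dat, loading)
  expect_identical(res$steps, res2$steps)

  dat_i <- simulate_diff_data(interaction = TRUE, seed = 12)
  loading_i <- tibble::tibble(utterance_id = dat_i$utterance_id, diff = dat_i$diff)
  res_i <- backwards_select(dat_i, loading_i)
  expect_true(any(grepl("surprisal x Utterance Half|Utterance Half.*surprisal",
                        res_i$estimates$term) |
                  grepl("surprisal:half|half:surprisal", res_i$estimates$term)))
})

test_that("FTO models detect a group shift and ignore unrelated surprisal", {
  b <- make_lang("b1", "back", fto = 300, seed = 401, n_dyads = 20)
  f <- make_lang("f1", "front", fto = 200, seed = 402, n_dyads = 20)
  models <- list(b1 = train_trigram_model(b$corpus),
                 f1 = train_trigram_model(f$corpus))
  corpus <- conv_corpus(dplyr::bind_rows(b$corpus, f$corpus), validate = FALSE)
  lt <- corpus_loading_table(filter_utterances(corpus), models)
  ft <- fto_table(corpus, loading = lt,
                  loading_group = c(b1 = "back", f1 = "front"))
  res <- fto_model(ft)
  expect_true(res$group$significant)
  expect_equal(res$group$back_minus_front_ms, 100, tolerance = 0.25)
  # treatment coding: the front-loaded coefficient is negative (shorter FTOs)
  fr <- res$group$estimates[res$group$estimates$term == "loading_groupfront", ]
  expect_lt(fr$estimate, 0)
  # FTO was generated independently of surprisal
  expect_equal(res$surprisal$df, 2)
  expect_false(res$surprisal$significant)
})
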