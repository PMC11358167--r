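#' Pipeline configuration
#'
#' Exactly one of `input` (paths to transcript files) or `generator` (a list
#' of [generator_config()]s, or a fixture name understood by
#' [make_fixture()]) must be given.
#'
#' @param input Character vector of transcript paths (TSV/JSONL dialect).
#' @param dialect Transcript dialect for `input`.
#' @param generator List of generator configs, or `"reference"` / `"null"` /
#'   `"tiny"`.
#' @param min_tokens,min_duration_ms Exclusion thresholds (defaults 8 / 600).
#' @param log_base Surprisal log base: 2 (bits) or `exp(1)` (nats).
#' @param rate_denominator `"half"` or `"utterance"`, see [unit_half_stats()].
#' @param alpha Base significance level; the per-language tests use
#'   `alpha / n_languages` (Bonferroni).
#' @param lowercase,filler_lexicon,annotation_patterns Cleaning options, see
#'   [clean_corpus()].
#' @param loading_group Optional named `language -> {"back","front"}` map;
#'   derived from the per-language half-effect estimates when `NULL`.
#' @param outdir Output directory for the report bundle, or `NULL` to skip
#'   writing.
#' @param seed Seed for any generator randomness.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, dialect = "auto", generator = NULL,
                            min_tokens = 8, min_duration_ms = 600,
                            log_base = 2, rate_denominator = "half",
                            alpha = 0.05, lowercase = TRUE,
                            filler_lexicon = NULL,
                            annotation_patterns = default_annotation_patterns(),
                            loading_group = NULL, outdir = NULL, seed = 1) {
  if (is.null(input) == is.null(generator)) {
    stop("supply exactly one of `input` or `generator`", call. = FALSE)
  }
  stopifnot(min_tokens > 0, min_duration_ms > 0, alpha > 0, alpha < 1)
  structure(list(input = input, dialect = dialect, generator = generator,
                 min_tokens = min_tokens, min_duration_ms = min_duration_ms,
                 log_base = log_base, rate_denominator = rate_denominator,
                 alpha = alpha, lowercase = lowercase,
                 filler_lexicon = filler_lexicon,
                 annotation_patterns = annotation_patterns,
                 loading_group = loading_group,
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Generate or ingest -> clean -> train per-language trigram models (on the
#' full cleaned corpora) -> filter short utterances -> loading, unit and FTO
#' tables -> per-language half-effect LRTs (Bonferroni-corrected), the
#' cross-language model with Tukey contrasts, the unit surprisal and rate
#' models, and the FTO models -> report bundle. When `outdir` is set, writes
#' `loading_table.csv`, `unit_stats.csv`, `fto_table.csv`,
#' `inference_report.csv` and `manifest.json` (stage counts, thresholds,
#' seed and versions); reruns with the same config and seed are identical.
#'
#' @param config A [pipeline_config()].
#' @return A list bundle: `corpus` (filtered), `models`, `loading`,
#'   `unit_stats`, `fto`, `per_language` (list of [model_comparison]),
#'   `cross_language`, `unit_surprisal`, `unit_rate`, `fto_models`,
#'   `loading_group`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  counts <- list()

  if (!is.null(config$input)) {
    corpus <- dplyr::bind_rows(lapply(config$input, read_corpus,
                                      dialect = config$dialect))
    corpus <- conv_corpus(corpus)
  } else if (is.character(config$generator)) {
    fx <- make_fixture(config$generator, seed = config$seed)
    corpus <- if (inherits(fx, "synthetic_corpus")) fx$corpus else fx$corpus
  } else {
    sims <- lapply(config$generator, function(gc) generate_corpus(gc))
    corpus <- conv_corpus(dplyr::bind_rows(lapply(sims, `[[`, "corpus")),
                          validate = FALSE)
  }
  counts$utterances_raw <- nrow(corpus)

  corpus <- clean_corpus(corpus, filler_lexicon = config$filler_lexicon,
                         annotation_patterns = config$annotation_patterns,
                         lowercase = config$lowercase)
  counts$utterances_cleaned <- nrow(corpus)

  langs <- unique(corpus$language)
  models <- lapply(stats::setNames(langs, langs), function(lg) {
    train_trigram_model(corpus[corpus$language == lg, ], log_base = config$log_base)
  })

  filtered <- filter_utterances(corpus, config$min_tokens, config$min_duration_ms)
  counts$utterances_filtered <- nrow(filtered)

  loading <- corpus_loading_table(filtered, models)
  counts$loading_rows <- nrow(loading)

  alpha_lang <- config$alpha / length(langs)
  per_language <- lapply(stats::setNames(langs, langs), function(lg) {
    lrt_half_effect(loading[loading$language == lg, ], alpha = alpha_lang)
  })

  loading_group <- config$loading_group
  if (is.null(loading_group)) {
    est <- vapply(per_language, function(m) {
      e <- m$estimates
      e$estimate[grepl("^half", e$term)][1]
    }, 0)
    loading_group <- stats::setNames(ifelse(est > 0, "back", "front"), langs)
  }

  cross <- if (length(langs) >= 2) cross_language_model(loading, alpha = config$alpha)
           else NULL

  have_tags <- all(lengths(filtered$tags) > 0)
  unit_stats <- NULL; unit_surp <- NULL; unit_rate <- NULL
  if (have_tags && nrow(filtered) > 0) {
    unit_stats <- unit_stats_table(filtered, models,
                                   rate_denominator = config$rate_denominator,
                                   loading_group = loading_group,
                                   loading = loading)
    counts$unit_rows <- nrow(unit_stats)
    if (length(unique(stats::na.omit(unname(loading_group)))) >= 2) {
      unit_surp <- unit_surprisal_model(unit_stats, alpha = config$alpha)
      unit_rate <- unit_rate_model(unit_stats, alpha = config$alpha)
    }
  }

  fto <- fto_table(corpus, loading = loading, loading_group = loading_group)
  counts$fto_rows <- nrow(fto)
  fto_models <- if (length(unique(stats::na.omit(fto$loading_group))) >= 2) {
    fto_model(fto, alpha = config$alpha)
  } else NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("convload")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    thresholds = list(min_tokens = config$min_tokens,
                      min_duration_ms = config$min_duration_ms),
    log_base = if (config$log_base == 2) "2" else "e",
    rate_denominator = config$rate_denominator,
    alpha = config$alpha, alpha_per_language = alpha_lang,
    languages = as.list(loading_group),
    counts = counts
  )

  bundle <- list(corpus = filtered, models = models, loading = loading,
                 unit_stats = unit_stats, fto = fto,
                 per_language = per_language, cross_language = cross,
                 unit_surprisal = unit_surp, unit_rate = unit_rate,
                 fto_models = fto_models, loading_group = loading_group,
                 manifest = manifest)
  if (!is.null(config$outdir)) write_bundle(bundle, config$outdir)
  invisible(bundle)
}

comparison_rows <- function(analysis, cmp) {
  if (is.null(cmp)) return(NULL)
  head_row <- tibble::tibble(analysis = analysis, term = "(model comparison)",
                             chisq = cmp$chisq, df = cmp$df, p = cmp$p_value,
                             estimate = NA_real_, se = NA_real_, t = NA_real_,
                             alpha = cmp$alpha_used)
  est <- cmp$estimates
  est_rows <- tibble::tibble(analysis = analysis, term = est$term,
                             chisq = NA_real_, df = NA_integer_, p = NA_real_,
                             estimate = est$estimate, se = est$se, t = est$t,
                             alpha = cmp$alpha_used)
  dplyr::bind_rows(head_row, est_rows)
}

write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  csv <- function(df, name) {
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  }
  loading_out <- bundle$loading[, c("language", "dyad", "speaker", "utterance_id",
                                    "n_words", "mean_first", "mean_last", "diff")]
  csv(loading_out, "loading_table.csv")
  if (!is.null(bundle$unit_stats)) csv(bundle$unit_stats, "unit_stats.csv")
  fto_out <- bundle$fto[, c("language", "loading_group", "conversation_id",
                            "prev_speaker", "next_speaker", "fto_ms", "n_words",
                            "mean_first", "mean_last")]
  csv(fto_out, "fto_table.csv")
  rows <- c(
    lapply(names(bundle$per_language), function(lg) {
      comparison_rows(paste0("half effect: ", lg), bundle$per_language[[lg]])
    }),
    list(if (!is.null(bundle$cross_language))
           comparison_rows("cross-language", bundle$cross_language$comparison),
         if (!is.null(bundle$cross_language))
           tibble::tibble(analysis = "cross-language contrasts",
                          term = bundle$cross_language$contrasts$contrast,
                          chisq = NA_real_, df = NA_integer_,
                          p = bundle$cross_language$contrasts$adjusted_p,
                          estimate = bundle$cross_language$contrasts$estimate,
                          se = bundle$cross_language$contrasts$se,
                          t = bundle$cross_language$contrasts$z_ratio,
                          alpha = 0.05),
         comparison_rows("unit surprisal", bundle$unit_surprisal),
         comparison_rows("unit rate", bundle$unit_rate),
         if (!is.null(bundle$fto_models))
           comparison_rows("FTO: loading group", bundle$fto_models$group),
         if (!is.null(bundle$fto_models))
           comparison_rows("FTO: surprisal", bundle$fto_models$surprisal))
  )
  report <- dplyr::bind_rows(Filter(Negate(is.null), rows))
  csv(report, "inference_report.csv")
  jsonlite::write_json(bundle$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
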