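#' @title Mixed-model comparison results
#' @description Container returned by the inference functions: a
#' likelihood-ratio test between nested mixed models fitted by maximum
#' likelihood on identical data, the full model's fixed-effect estimates,
#' and the significance threshold the decision used.
#' @name model_comparison
NULL

new_model_comparison <- function(label, chisq, df, p_value, estimates,
                                 alpha_used, converged = TRUE, note = NULL,
                                 steps = NULL) {
  structure(list(label = label, chisq = chisq, df = df, p_value = p_value,
                 estimates = estimates, alpha_used = alpha_used,
                 significant = !is.na(p_value) && p_value < alpha_used,
                 converged = converged, note = note, steps = steps),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %s\n", x$label))
  cat(sprintf("  chisq(%d) = %.3f, p = %.4g (alpha = %.4g)%s%s\n",
              x$df, x$chisq, x$p_value, x$alpha_used,
              if (x$significant) " *" else "",
              if (x$converged) "" else " [convergence issues]"))
  if (!is.null(x$estimates) && nrow(x$estimates) > 0) {
    print(as.data.frame(x$estimates), digits = 4, row.names = FALSE)
  }
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

lmer_control <- function() {
  lme4::lmerControl(calc.derivs = FALSE, check.conv.singular = "ignore")
}

fit_lmer <- function(formula, data) {
  withCallingHandlers(
    lme4::lmer(formula, data = data, REML = FALSE, control = lmer_control()),
    message = function(m) invokeRestart("muffleMessage"),
    warning = function(w) invokeRestart("muffleWarning")
  )
}

lmer_ok <- function(fit) {
  !lme4::isSingular(fit, tol = 1e-5) &&
    length(fit@optinfo$conv$lme4$messages %||% character()) == 0
}

fixef_table <- function(fit) {
  if (inherits(fit, "glmmTMB")) {
    co <- summary(fit)$coefficients$cond
    tibble::tibble(term = rownames(co), estimate = co[, 1], se = co[, 2],
                   t = co[, 3])
  } else {
    co <- summary(fit)$coefficients
    tibble::tibble(term = rownames(co), estimate = co[, 1], se = co[, 2],
                   t = co[, 3])
  }
}

lrt <- function(m0, m1) {
  an <- stats::anova(m0, m1)
  list(chisq = an$Chisq[2], df = an$Df[2], p = an$`Pr(>Chisq)`[2])
}

check_grouping <- function(data, what = "dyad") {
  n_dyads <- length(unique(data[[what]]))
  if (n_dyads < 2) {
    stop("only ", n_dyads, " ", what,
         " present; random-intercept models need at least two (refusing to ",
         "silently drop the random effect)", call. = FALSE)
  }
}

#' Per-language utterance-half effect (LRT)
#'
#' The main model comparison: a null linear mixed model with per-half mean
#' surprisal as response, number of words as fixed effect and nested random
#' intercepts for speaker within dyad, against the same model plus utterance
#' half (first/last). Both fits use maximum likelihood; the LRT has 1 df.
#' The half estimate is the last-minus-first difference, so positive values
#' mean back-loading. Across six languages a Bonferroni-corrected threshold
#' of 0.05/6 = 0.008 is the conventional `alpha`.
#'
#' @param loading A [corpus_loading_table()] (or its [loading_long()] form)
#'   for one language.
#' @param alpha Significance threshold recorded with the decision
#'   (default 0.008).
#' @return A [model_comparison] with the half fixed-effect estimate.
#' @export
lrt_half_effect <- function(loading, alpha = 0.008) {
  long <- if ("half" %in% names(loading)) loading else loading_long(loading)
  if (length(unique(long$language)) > 1) {
    stop("lrt_half_effect() fits one language at a time", call. = FALSE)
  }
  check_grouping(long)
  m0 <- fit_lmer(surprisal ~ n_words + (1 | dyad / speaker), long)
  m1 <- fit_lmer(surprisal ~ n_words + half + (1 | dyad / speaker), long)
  res <- lrt(m0, m1)
  new_model_comparison(
    label = paste0("utterance half effect (", long$language[1], ")"),
    chisq = res$chisq, df = res$df, p_value = res$p,
    estimates = fixef_table(m1), alpha_used = alpha,
    converged = lmer_ok(m0) && lmer_ok(m1))
}

#' Cross-language model of the surprisal difference
#'
#' Tests whether the per-utterance surprisal difference (last minus first
#' half) differs between languages: a base model with centered number of
#' words and nested dyad/speaker intercepts against the same model plus
#' language (LRT with k-1 df), followed by all pairwise language contrasts
#' with Tukey adjustment (asymptotic z ratios).
#'
#' @param loading A multi-language [corpus_loading_table()].
#' @param alpha Threshold for the language LRT (default 0.05).
#' @return A list: `comparison` ([model_comparison]) and `contrasts`, a
#'   tibble with `contrast`, `estimate`, `se`, `z_ratio`, `adjusted_p`.
#' @export
cross_language_model <- function(loading, alpha = 0.05) {
  data <- loading[loading$ok, ]
  if (length(unique(data$language)) < 2) {
    stop("cross_language_model() needs at least two languages", call. = FALSE)
  }
  check_grouping(data)
  data$n_words_c <- data$n_words - mean(data$n_words)
  data$language <- factor(data$language)
  m0 <- fit_lmer(diff ~ n_words_c + (1 | dyad / speaker), data)
  m1 <- fit_lmer(diff ~ n_words_c + language + (1 | dyad / speaker), data)
  res <- lrt(m0, m1)
  emm <- emmeans::emmeans(m1, "language", lmer.df = "asymptotic")
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise", adjust = "tukey"))
  contrasts <- tibble::tibble(contrast = prs$contrast, estimate = prs$estimate,
                              se = prs$SE, z_ratio = prs$z.ratio,
                              adjusted_p = prs$p.value)
  comparison <- new_model_comparison(
    label = "language effect on surprisal difference",
    chisq = res$chisq, df = res$df, p_value = res$p,
    estimates = fixef_table(m1), alpha_used = alpha,
    converged = lmer_ok(m0) && lmer_ok(m1))
  list(comparison = comparison, contrasts = contrasts)
}

# sum-code the three unit-table factors; levels chosen so the coded column
# is +1 for VERB, +1 for front, +1 for last (paper-style contrast labels)
code_unit_factors <- function(data) {
  data$unit <- factor(data$unit, levels = c("VERB", "NOUN"))
  data$loading_group <- factor(data$loading_group, levels = c("front", "back"))
  data$half <- factor(data$half, levels = c("last", "first"))
  stats::contrasts(data$unit) <- stats::contr.sum(2)
  stats::contrasts(data$loading_group) <- stats::contr.sum(2)
  stats::contrasts(data$half) <- stats::contr.sum(2)
  data
}

relabel_unit_terms <- function(tab) {
  map <- c("unit1" = "Grammatical Unit (Verb > Noun)",
           "loading_group1" = "Front Loaded > Back Loaded",
           "half1" = "Utterance Half (Last > First)")
  pretty <- function(term) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    parts <- ifelse(parts %in% names(map), map[parts], parts)
    paste(parts, collapse = " x ")
  }
  tab$term <- vapply(tab$term, pretty, "")
  tab
}

#' Stepwise mixed model for unit surprisal
#'
#' Response: per-half mean surprisal of a grammatical unit. The three
#' sum-coded predictors (grammatical unit, front/back loading group,
#' utterance half) are added step-wise, each addition tested by LRT, then
#' the two-way and three-way interactions. The reported comparison is the
#' interaction structure against the main-effects model; estimates come from
#' the full factorial model.
#'
#' @param unit_table A [unit_stats_table()] spanning both loading groups.
#' @param alpha Threshold per step (default 0.05).
#' @return A [model_comparison]; `$steps` records each addition's LRT.
#' @export
unit_surprisal_model <- function(unit_table, alpha = 0.05) {
  data <- unit_table[!is.na(unit_table$mean_unit_surprisal), ]
  if (length(unique(data$loading_group)) < 2) {
    stop("unit_surprisal_model() needs both loading groups", call. = FALSE)
  }
  check_grouping(data)
  data <- code_unit_factors(data)
  data$y <- data$mean_unit_surprisal
  rhs <- c("unit", "loading_group", "half",
           "unit:loading_group + unit:half + loading_group:half",
           "unit:loading_group:half")
  labels <- c("grammatical unit", "loading group", "utterance half",
              "two-way interactions", "three-way interaction")
  fits <- list(fit_lmer(y ~ (1 | dyad / speaker), data))
  steps <- vector("list", length(rhs))
  terms_so_far <- character()
  for (k in seq_along(rhs)) {
    terms_so_far <- c(terms_so_far, rhs[k])
    f <- stats::as.formula(paste("y ~", paste(terms_so_far, collapse = " + "),
                                 "+ (1 | dyad / speaker)"))
    fits[[k + 1]] <- fit_lmer(f, data)
    r <- lrt(fits[[k]], fits[[k + 1]])
    steps[[k]] <- tibble::tibble(step = labels[k], chisq = r$chisq, df = r$df,
                                 p = r$p, significant = r$p < alpha)
  }
  steps <- dplyr::bind_rows(steps)
  full <- fits[[length(fits)]]
  main <- fits[[4]]
  res <- lrt(main, full)
  new_model_comparison(
    label = "unit surprisal: interaction structure vs. main effects",
    chisq = res$chisq, df = res$df, p_value = res$p,
    estimates = relabel_unit_terms(fixef_table(full)),
    alpha_used = alpha, converged = lmer_ok(full), steps = steps)
}

#' Beta-family mixed model for unit rates
#'
#' Rates are proportions in [0, 1], so they are squeezed into the open
#' interval with the standard `(y * (n - 1) + 0.5) / n` transform and fitted
#' with a beta-family mixed model (logit link) using the same sum-coded
#' predictors as [unit_surprisal_model()]. The reported LRT compares the
#' full factorial model against the main-effects model.
#'
#' @param unit_table A [unit_stats_table()] spanning both loading groups.
#' @param alpha Threshold (default 0.05).
#' @return A [model_comparison] (estimates on the logit scale).
#' @export
unit_rate_model <- function(unit_table, alpha = 0.05) {
  data <- unit_table
  if (length(unique(data$loading_group)) < 2) {
    stop("unit_rate_model() needs both loading groups", call. = FALSE)
  }
  check_grouping(data)
  data <- code_unit_factors(data)
  n <- nrow(data)
  data$y <- (data$rate * (n - 1) + 0.5) / n
  quiet_tmb <- function(expr) {
    withCallingHandlers(expr, warning = function(w) invokeRestart("muffleWarning"))
  }
  m0 <- quiet_tmb(glmmTMB::glmmTMB(
    y ~ unit + loading_group + half + (1 | dyad / speaker),
    data = data, family = glmmTMB::beta_family()))
  m1 <- quiet_tmb(glmmTMB::glmmTMB(
    y ~ unit * loading_group * half + (1 | dyad / speaker),
    data = data, family = glmmTMB::beta_family()))
  an <- stats::anova(m0, m1)
  new_model_comparison(
    label = "unit rate (beta family): interaction structure vs. main effects",
    chisq = an$Chisq[2], df = an$`Chi Df`[2], p_value = an$`Pr(>Chisq)`[2],
    estimates = relabel_unit_terms(fixef_table(m1)), alpha_used = alpha,
    converged = isTRUE(m1$sdr$pdHess))
}

#' Backwards model selection for the surprisal-difference model
#'
#' Starts from the full model: surprisal difference as response; rate, unit
#' surprisal, utterance half and grammatical unit as fixed factors with all
#' two-, three- and four-way interactions; nested dyad/speaker intercepts.
#' At each step the removable term (respecting marginality) whose removal
#' least decreases the log-likelihood per degree of freedom is dropped and
#' the removal tested by LRT against the retaining model: a non-significant
#' comparison leaves the term out; the first significant comparison stops
#' the search. The reported comparison is the final model against the
#' random-effects-only base model.
#'
#' @param unit_table A [unit_stats_table()] spanning both loading groups.
#' @param loading The matching [corpus_loading_table()] supplying each
#'   utterance's surprisal difference.
#' @param alpha Threshold per removal test (default 0.05).
#' @return A [model_comparison]; `$steps` records the removal path.
#' @export
backwards_select <- function(unit_table, loading, alpha = 0.05) {
  data <- unit_table[!is.na(unit_table$mean_unit_surprisal), ]
  data$diff <- loading$diff[match(data$utterance_id, loading$utterance_id)]
  data <- data[!is.na(data$diff), ]
  check_grouping(data)
  data <- code_unit_factors(data)
  data$surprisal <- data$mean_unit_surprisal
  current <- stats::formula(diff ~ rate * surprisal * half * unit + (1 | dyad / speaker))
  fit_cur <- fit_lmer(current, data)
  base <- fit_lmer(diff ~ (1 | dyad / speaker), data)
  removal_log <- list()
  repeat {
    fixed_part <- lme4::nobars(current)
    scope <- stats::drop.scope(fixed_part)
    if (length(scope) == 0) break
    cand <- lapply(scope, function(tm) {
      f <- stats::update(current, stats::as.formula(paste(". ~ . -", tm)))
      fit <- tryCatch(fit_lmer(f, data), error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      list(term = tm, formula = f, fit = fit,
           ll_per_df = (stats::logLik(fit_cur) - stats::logLik(fit)) /
             (attr(stats::logLik(fit_cur), "df") - attr(stats::logLik(fit), "df")))
    })
    cand <- Filter(Negate(is.null), cand)
    if (length(cand) == 0) break
    drops <- vapply(cand, function(x) as.numeric(x$ll_per_df), 0)
    pick <- cand[[which.min(drops)]]
    r <- lrt(pick$fit, fit_cur)
    removal_log[[length(removal_log) + 1]] <- tibble::tibble(
      term = pick$term, chisq = r$chisq, df = r$df, p = r$p,
      removed = r$p >= alpha)
    if (r$p >= alpha) {
      current <- pick$formula
      fit_cur <- pick$fit
    } else break
  }
  res <- lrt(base, fit_cur)
  new_model_comparison(
    label = "surprisal difference: final backwards-selected model vs. base",
    chisq = res$chisq, df = res$df, p_value = res$p,
    estimates = relabel_unit_terms(fixef_table(fit_cur)), alpha_used = alpha,
    converged = lmer_ok(fit_cur),
    steps = if (length(removal_log)) dplyr::bind_rows(removal_log) else NULL)
}

#' FTO mixed models
#'
#' Two comparisons on the floor-transfer-offset table. First, the loading
#' group test: FTO as response, number of words as fixed effect and dyad as
#' random intercept, against the same model plus loading group
#' (treatment-coded with back-loaded = 0, front-loaded = 1, so a negative
#' estimate means back-loaded languages have longer FTOs). Second, the
#' surprisal test: the base model plus the mean surprisal of the first and
#' last halves of the preceding utterance (LRT with 2 df), fitted on the
#' transitions where those means exist.
#'
#' @param fto A [fto_table()] with loading groups.
#' @param alpha Threshold (default 0.05).
#' @return A list of two [model_comparison]s: `group` and `surprisal`; the
#'   `group` element also carries `back_minus_front_ms`, the fitted FTO
#'   excess of back-loaded over front-loaded languages.
#' @export
fto_model <- function(fto, alpha = 0.05) {
  data <- fto[!is.na(fto$loading_group), ]
  if (length(unique(data$loading_group)) < 2) {
    stop("fto_model() needs both loading groups", call. = FALSE)
  }
  check_grouping(data)
  data$loading_group <- factor(data$loading_group, levels = c("back", "front"))
  m0 <- fit_lmer(fto_ms ~ n_words + (1 | dyad), data)
  m1 <- fit_lmer(fto_ms ~ n_words + loading_group + (1 | dyad), data)
  r1 <- lrt(m0, m1)
  group <- new_model_comparison(
    label = "FTO: loading group", chisq = r1$chisq, df = r1$df, p_value = r1$p,
    estimates = fixef_table(m1), alpha_used = alpha,
    converged = lmer_ok(m0) && lmer_ok(m1))
  group$back_minus_front_ms <- -unname(lme4::fixef(m1)["loading_groupfront"])
  sub <- data[!is.na(data$mean_first) & !is.na(data$mean_last), ]
  if (nrow(sub) > 0 && length(unique(sub$dyad)) >= 2) {
    s0 <- fit_lmer(fto_ms ~ n_words + (1 | dyad), sub)
    s1 <- fit_lmer(fto_ms ~ n_words + mean_first + mean_last + (1 | dyad), sub)
    r2 <- lrt(s0, s1)
    surp <- new_model_comparison(
      label = "FTO: half-mean surprisal of preceding utterance",
      chisq = r2$chisq, df = r2$df, p_value = r2$p,
      estimates = fixef_table(s1), alpha_used = alpha,
      converged = lmer_ok(s0) && lmer_ok(s1))
  } else {
    surp <- NULL
  }
  list(group = group, surprisal = surp)
}
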