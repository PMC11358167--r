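---
title: "Measuring utterance-level information loading in conversation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring utterance-level information loading in conversation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(convload)
```

## The question and the statistic

Speakers in conversation produce words one at a time, and listeners process
them while planning their own next turn. A natural question is whether the
information carried by an utterance is spread evenly over its words or
concentrated early (front-loading) or late (back-loading), and whether whole
languages differ systematically in this respect.

convload operationalizes "information" as trigram surprisal. For each
corpus a second-order Markov model is tabulated over the cleaned
transcripts, and every word receives

$$s(w_i) = -\log_2 P(w_i \mid w_{i-2}, w_{i-1})$$

with maximum-likelihood probabilities (raw count ratios). The per-utterance
loading statistic is

$$\Delta = \bar{s}_{\text{last half}} - \bar{s}_{\text{first half}},$$

where halves come from a simple count-based split (a 10-word utterance
splits 5/5; for odd lengths the extra word joins the last half, which keeps
the last half starting at word 5 for the canonical 8-word case). Positive
$\Delta$ means back-loading.

Several details matter and are fixed throughout:

* **No smoothing, no padding.** The model scores the same corpus it was
  trained on, so every scored event has count $\ge 1$ and unsmoothed ratios
  are exact. There are no sentence-start symbols: word 1 is scored from its
  unigram relative frequency and word 2 from a bigram ratio, and both are
  flagged as reduced-context. Held-out scoring is possible only by opting
  into an explicit unseen-event policy (`on_unseen = "inf"`), which flags
  affected utterances rather than silently imputing.
* **First two words are excluded from first-half means.** They are not
  proper trigrams, and including them would bias the first half upward.
* **Short utterances are excluded after training.** Utterances with fewer
  than 8 tokens or shorter than 600 ms are dropped from the analysis (but
  still inform the counts). Both thresholds are inclusive at the boundary:
  exactly 8 tokens or exactly 600 ms survives. The 8-token floor guarantees
  at least two complete trigrams per half.
* **Log base.** Surprisal defaults to bits (`log_base = 2`); nats are
  available and differ by the exact factor $\ln 2$, so no sign-level
  conclusion depends on the base.
* **Case folding.** Tokens are lowercased during cleaning (configurable
  off); otherwise sentence-initial capitalization would split trigram
  counts. Punctuation-only tokens (no Unicode letter or digit, so in-word
  apostrophes and hyphens survive), configurable annotation markup, and
  per-language filled-pause lexicons are removed before any counting.

## The inference stage

The statistical workflow mirrors standard mixed-model practice (lme4 /
glmmTMB / emmeans supply the estimation; this package owns the formulas,
codings and decision rules):

* **Per-language half effect.** Null model: per-half mean surprisal ~
  number of words + (1 | dyad/speaker); alternative adds utterance half.
  Both fitted by maximum likelihood, compared by a 1-df likelihood-ratio
  test. With six languages the conventional threshold is Bonferroni-lowered
  to $0.05/6 = 0.008$. Random slopes are omitted by default (they
  characteristically produce singular fits at these scales); a degenerate
  single-dyad input errors loudly rather than silently dropping the random
  effect.
* **Cross-language model.** $\Delta$ ~ centered word count + language +
  (1 | dyad/speaker) against the model without language, then all pairwise
  language contrasts with Tukey adjustment, reported as asymptotic
  z-ratios.
* **Unit (NOUN/VERB) models.** Per utterance half, each unit's rate is its
  count divided by the words in that half — the worked-example convention
  (3 verbs among 7 words = 0.429). The prose alternative, dividing by the
  utterance's total word count, is available via
  `rate_denominator = "utterance"` but is not the default because the
  numeric example is unambiguous. Reduced-context words count toward rates
  but not toward unit surprisal means, for consistency with the main
  analysis. Surprisal models are linear mixed models with sum-coded unit,
  loading group and half (stepwise additions, each tested by LRT); rate
  models use a beta-family mixed model on rates squeezed into the open
  interval by $(y(n-1)+0.5)/n$, the standard transform for proportions
  containing exact zeros.
* **Backwards selection.** For the model relating $\Delta$ to rate, unit
  surprisal, half and unit (all interactions), terms are removed
  lowest-contribution-first, where contribution is operationalized as
  log-likelihood change per degree of freedom — the criterion is stated
  qualitatively in the literature this follows, and this is the documented
  interpretation here. Each removal is tested by LRT; the first significant
  removal stops the search, and the final model is compared against the
  random-effects-only base. Note the stop-at-first-significant rule means
  a spurious early hit can freeze remaining interactions in place; this is
  faithful to the procedure rather than an optimality claim.
* **Turn timing.** The floor transfer offset (FTO) of a transition is the
  next utterance's start minus the previous utterance's end (negative =
  overlap), computed for adjacent utterances by different speakers in
  start-time order; same-speaker adjacencies yield no transition, and each
  adjacency in a multi-utterance turn is treated independently (the
  handling of multi-unit turns is not specified by the source analyses, so
  the simplest convention is used and documented). The FTO model uses dyad
  intercepts and treatment coding with back-loaded as reference, so the
  "front" coefficient is negative when back-loaded languages have longer
  offsets. A second comparison adds the preceding utterance's two half
  means (the turn being responded to — the hypothesis concerns responding
  to information placement); outlier trimming at ±2 SD exists for plotting
  conventions only and is never applied in analysis.

## What the synthetic generator emulates

Real multi-language conversational corpora are licensed and cannot ship
with the package, so every stage is exercised on generated dialogue with
known ground truth.

Each language is a set of dyads; conversations alternate strictly between
the dyad's two speakers. Utterance lengths are
`length_min + Binomial(length_max - length_min, length_shape)` (defaults
4-18, mean about 11, straddling the 8-token filter the way the real
post-cleaning distributions do). Words come from two context-conditional
families over a Zipfian vocabulary: the context pair determines a shift
(modulo `context_modulus = 4`, with the position-1 shift drawn uniformly so
the process is stationary across positions), and the word is the shift plus
a Zipf-weighted offset among the top `context_support = 16` candidates.
Because the conditional distribution given any context is one of two known
distributions, every token's true surprisal is available in closed form,
and the expected gap between the dense and sparse halves is exactly the
entropy difference of the two families. `delta_bits` is calibrated by
solving for the dense family's exponent; infeasible targets (beyond
`log2(context_support)` minus the sparse entropy) raise an error naming the
feasible maximum.

The small context modulus and truncated support are deliberate: they keep
trigram contexts frequent enough that the unsmoothed maximum-likelihood
model can actually recover the generating surprisal at desk scale
(correlation about 0.93 at 5,000 utterances, improving monotonically with
corpus size). A full-vocabulary rotation scheme was tried first and
abandoned: it makes word marginals near-uniform, contexts near-unique, and
maximum-likelihood surprisal estimates uninformative.

POS tags are drawn from a fixed universal-POS distribution,
position-dependently: in the dense half the NOUN and VERB probabilities are
each raised by `pos_enrichment` with other labels rescaled. Tags are
ground truth, standing in for the pluggable tagger interface used on real
data. Durations are `n_words / words_per_second` (3 words/s); inter-turn
gaps are Gaussian with per-condition mean and SD 150 ms, so overlaps
(negative FTOs) occur naturally.

Because the analysis models assume dyad and speaker random-intercept
variance, the generator supplies it: each speaker's sparse-family entropy
carries a dyad-level plus speaker-level Gaussian deviation (the dense
family stays exactly `delta_bits` above that speaker's sparse family, so
the configured gap holds for every speaker), each speaker's NOUN/VERB
probabilities carry an analogous usage deviation, and each dyad's FTO mean
is offset by a Gaussian draw (SD 30 ms). All deviations are mean-zero, so
the configured targets hold in expectation; without them, every
random-intercept variance would be estimated at zero and the mixed models
would be degenerate by construction.

The reference conditions used by the tests: three back-loaded languages
(`delta_bits = 0.5`, FTO mean 300 ms) and three front-loaded ones
(`delta_bits = 0.5` front, 200 ms), 50 dyads x 2 conversations x 20
utterances = 2,000 utterances per language, `pos_enrichment = 0.08`. The
null fixture sets every effect to zero.

What the generator does **not** emulate: morphology, syntax, word order in
any linguistic sense, backchannels, questions, or the retroactive-
modification phenomena relevant to incremental languages. Passing tests
show the pipeline recovers known structure of this kind; they do not show
that any particular natural language is front- or back-loaded.

## Numerical and scale choices

Analyses in the test-suite and acceptance script run at deliberately
modest sizes chosen to make their claims at desk scale: recovery claims
use 5,000 utterances (where the correlation criterion is defined), the
sign-recovery sweep uses 20 seeds of the six-language reference suite, the
type-I calibration uses 400 null datasets of 40 dyads x 20 utterances, and
the FTO recovery uses about 20,000 transitions (where the +100 ms
injection is recoverable within +/-20 ms). Model fits disable costly
derivative checks (`calc.derivs = FALSE`); singular-fit detection is
retained and reported through the `converged` flag.

## A minimal run

```{r example, eval = FALSE}
gens <- list(
  generator_config(language = "bk", loading_mode = "back",  delta_bits = 0.5,
                   pos_enrichment = 0.08, fto_mean_ms = 300, seed = 11),
  generator_config(language = "fr", loading_mode = "front", delta_bits = 0.5,
                   pos_enrichment = 0.08, fto_mean_ms = 200, seed = 12)
)
bundle <- run_pipeline(pipeline_config(generator = gens, outdir = "out"))
bundle$loading_group          # bk classified "back", fr "front"
bundle$per_language$bk        # chisq, p, half estimate
bundle$fto_models$group       # fitted FTO gap between the groups
```

## Known limitations

* Maximum-likelihood surprisal on training data is downward-biased for
  high-entropy contexts (observed events have count >= 1), so estimated
  loading gaps are attenuated relative to the generating `delta_bits`; all
  sign-level inferences are unaffected.
* The two-half summary cannot distinguish monotone gradients from
  mid-utterance peaks; position-by-position curve shapes are out of scope.
* The TSV/JSONL dialect is this package's own; parsers for CHAT/CLAN or
  LDC markup are intentionally not provided.
* The per-language non-lexeme annotation inventories of real corpora are
  not guessed; the annotation pattern list is configuration.
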