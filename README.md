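# convload

Utterance-level information distribution in conversational corpora.

## The problem

In dialogue, words arrive one at a time while the listener is already
planning a reply. Whether an utterance's information is *front-loaded*
(more informative words early) or *back-loaded* (more informative words
late) may therefore matter for comprehension and turn-taking, and languages
may differ systematically in which pattern they favour. convload is for
researchers in computational psycholinguistics who have time-aligned,
speaker-attributed transcripts of dyadic conversation and want to quantify
and test this.

## The statistic and the models

For each corpus a trigram (second-order Markov) word model is tabulated
over the cleaned transcripts, with maximum-likelihood probabilities and no
cross-utterance context. Each word's surprisal is

    s(w_i) = -log2 P(w_i | w_{i-2}, w_{i-1})   [bits]

with words 1 and 2 of an utterance scored from unigram/bigram relative
frequencies and flagged as reduced-context. After excluding utterances
with fewer than 8 tokens or shorter than 600 ms, each utterance is split
in half by word count (10 words: 5 + 5; the first two words are excluded
from the first-half mean), and the loading statistic is

    Δ = mean surprisal(last half) − mean surprisal(first half)

Positive Δ = back-loading. Inference is by likelihood-ratio tests between
nested mixed-effects models (maximum likelihood, dyad/speaker nested random
intercepts): a per-language utterance-half effect at a Bonferroni-corrected
threshold (0.05/6 = 0.008 for six languages), a cross-language model with
Tukey-adjusted pairwise contrasts, noun/verb rate and surprisal models
(sum-coded predictors; beta-family mixed model for rates), backwards model
selection for the surprisal-difference model, and a floor-transfer-offset
(FTO) model relating turn-transition timing to front/back loading.

Real cross-linguistic telephone corpora of this kind are licensed and not
bundled; the package ships a synthetic dialogue generator with closed-form
ground-truth surprisal, controllable loading (`delta_bits`), noun/verb
enrichment and FTO structure, so the entire pipeline is testable offline.

## Worked example

Generate one back-loaded and one front-loaded synthetic language and run
the full pipeline:

```r
library(convload)
gens <- list(
  generator_config(language = "bk", loading_mode = "back",  delta_bits = 0.5,
                   pos_enrichment = 0.08, fto_mean_ms = 300, seed = 11),
  generator_config(language = "fr", loading_mode = "front", delta_bits = 0.5,
                   pos_enrichment = 0.08, fto_mean_ms = 200, seed = 12)
)
bundle <- run_pipeline(pipeline_config(generator = gens))
bundle$loading_group
#>      bk      fr
#>  "back" "front"
bundle$per_language$bk
#> <model_comparison> utterance half effect (bk)
#>   chisq(1) = 238.141, p = 1e-53 (alpha = 0.025) *
#>         term estimate       se       t
#>  (Intercept)  2.42938 0.079659 30.4973
#>      n_words  0.00428 0.006952  0.6157
#>     halflast  0.37873 0.024158 15.6772
bundle$fto_models$group
#> <model_comparison> FTO: loading group
#>   chisq(1) = 90.300, p = 2.047e-21 (alpha = 0.05) *
#>                term estimate     se        t
#>         (Intercept) 303.4802 15.574  19.4858
#>             n_words  -0.6733  1.326  -0.5077
#>  loading_groupfront -91.7915  7.579 -12.1114
```

Reading the output: language `bk` was generated back-loaded, and the
half-effect model finds last-half surprisal about 0.38 bits above the
first half (`halflast`), significant at the Bonferroni-corrected threshold,
so the pipeline classifies it "back". The FTO model is treatment-coded
with back-loaded as reference: the `loading_groupfront` estimate of
−92 ms says front-loaded transitions are about 92 ms shorter — recovering
the injected 100 ms gap (300 vs 200 ms) to within sampling error. The
per-utterance table behind all of this:

```r
head(bundle$loading[, c("language", "utterance_id", "n_words",
                        "mean_first", "mean_last", "diff")], 4)
#> # A tibble: 4 × 6
#>   language utterance_id    n_words mean_first mean_last   diff
#> 1 bk       bk_d001_c1_u001      10       1.72      2.52  0.801
#> 2 bk       bk_d001_c1_u003      11       2.54      1.48 -1.06
#> 3 bk       bk_d001_c1_u005       8       1.06      3.39  2.33
#> 4 bk       bk_d001_c1_u006      14       2.49      3.16  0.664
```

With an `outdir` set, `run_pipeline()` also writes `loading_table.csv`,
`unit_stats.csv`, `fto_table.csv`, `inference_report.csv` and
`manifest.json` (stage counts, thresholds, seed). Transcript files in the
package's TSV/JSONL dialect can be analysed the same way via
`pipeline_config(input = ...)`; a thin command-line wrapper lives at
`inst/cli/convload.R`. The methods vignette
(`vignettes/information-loading.Rmd`) documents the model, the generator
and every numerical convention.

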