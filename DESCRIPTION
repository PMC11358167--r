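Package: convload
Title: Utterance-Level Information Distribution in Conversational Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how information is distributed within spoken
    utterances in time-aligned, speaker-attributed conversational transcripts.
    Trains per-corpus trigram (second-order Markov) word models, computes
    per-word surprisal and the per-utterance front-/back-loading statistic
    (mean surprisal of the last half minus the first half), relates loading to
    part-of-speech composition and to turn-transition timing (floor transfer
    offsets), and runs the associated mixed-effects model comparisons via
    likelihood-ratio tests. Includes a synthetic dialogue-corpus generator
    with closed-form ground-truth surprisal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    tibble,
    tidyr,
    jsonlite,
    lme4,
    glmmTMB,
    emmeans,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
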