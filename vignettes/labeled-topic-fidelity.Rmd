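---
title: "Labeled topic models for MI fidelity coding: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Labeled topic models for MI fidelity coding: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fidelity evaluation of motivational interviewing (MI) rests on behavioral
coding: human raters assign Motivational Interviewing Skills Code (MISC)
labels — open/closed questions, simple/complex reflections, affirmations,
and so on — to the talk turns of a session transcript. `mitopics` models
that coding process statistically so that codes can be generated for new
sessions from text alone, and provides the agreement statistics needed to
judge whether machine codes are usable where human codes are the standard.

The unit of analysis throughout is the **talk turn** (one speaker's
uninterrupted span). Human coders traditionally work at the finer utterance
grain; the model does not attempt utterance segmentation, and a turn's label
set is simply the set of codes any rater assigned anywhere in the turn.
Multi-rater annotations are fused by **set union** before training: a turn
coded A+B, B+C, and D by three raters trains with labels {A, B, C, D},
treating rater disagreement as uncertainty about content rather than
adjudicating it. Only codes present in at least 2% of talk turns are
modeled (an inclusive threshold: a code at exactly 2% is retained).

## Model

A topic is a multinomial over the vocabulary; a turn is a mixture over a
*constrained* set of topics. Three topic groups exist:

* one topic per retained code — tied to the supervision;
* one topic per intervention study — absorbing study-specific vocabulary
  (a study on 21st-birthday drinking is full of "birthday"; one on marijuana
  of "smoke");
* `n_background` free topics — absorbing generic conversational language.

In training, a turn's tokens may only be assigned to the topics of its
fused codes, its study's topic, and the background topics. This is the
standard labeled-LDA constraint, extended by the study and background
groups. Without those extra groups, high-frequency study words would have to
be explained by the code topics, contaminating them; the package's ablation
test (`test-acceptance.R`) verifies on study-confounded synthetic data that
removing them never improves any code's held-out AUC.

Inference is collapsed Gibbs sampling. With symmetric priors
`alpha` on the per-turn mixture θ and `beta` on the topic-word rows φ, a
token with word *w* in turn *d* is reassigned with probability proportional
to `(n_dt + alpha) * (n_tw + beta) / (n_t + V beta)` over the turn's
admissible topics. After `burn_in` sweeps, every `sample_lag`-th sweep
contributes a sample of `(n_tw + beta) / (n_t + V beta)` to the estimate
φ̂, which is the average over retained samples.

Held-out sessions are scored by **fold-in**: φ̂ is frozen (no test-set
leakage into the topic-word distributions) and only the turn's topic counts
are resampled, now admitting *all* code topics. The estimate
`θ̂[d, t]` averages `(n_dt + alpha) / (n_d + |allowed| alpha)` over retained
samples; a turn with no tokens therefore reports the uniform prior over its
admissible topics. The **score** of code *c* on a turn is `θ̂` at *c*'s
topic — the posterior mean share of the turn's tokens attributed to that
code's language. It lives in [0, 1] and is used directly for ROC analysis.

θ is placed at the talk-turn level, not the session level: predictions are
needed per talk turn, and session summaries are derived downstream as
tallies. Whether patient codes (change/sustain talk) share the model with
therapist codes is configurable (`restrict_codes_by_speaker`); the default
fits a single model to all codes.

### Defaults and what they mean

| parameter | default | role |
|---|---|---|
| `alpha` | 0.1 | sparsity of per-turn topic mixtures; small values expect a turn to be dominated by few topics |
| `beta` | 0.01 | smoothing of topic-word rows; small values give sharp, interpretable topics |
| `n_background` | 10 | capacity for non-code, non-study language |
| `n_iterations` / `burn_in` / `sample_lag` | 1000 / 500 / 10 | 50 retained φ̂ samples; tiny-corpus oracle tests show this is far past mixing for corpora of this size |
| phrase `min_doc_freq` | 10 turns | bigrams/trigrams seen in at least this many turns become single vocabulary terms |

All are exposed; every CLI run writes them to a manifest.

## Tokenization and vocabulary

Text is lowercased; punctuation is stripped except apostrophes and hyphens
*inside* words (`you're`, `twenty-first`); numerals are kept; transcription
artifacts such as spelled-out acronyms stay as separate single-letter
tokens. Contiguous bigrams and trigrams above the document-frequency
threshold are admitted as terms and matched greedily left-to-right, longest
first, so each source word is consumed exactly once and token counts remain
well defined for the sampler. Stop words are **not** removed — question and
reflection language is made of function words ("what do you", "sounds
like"), so removal would destroy the signal.

In cross-validation the vocabulary and phrase table are rebuilt from each
training fold only; held-out terms outside the training vocabulary carry no
information under the trained φ̂ and are dropped. The model artifact stores
a vocabulary hash and refuses to score a corpus tokenized under a different
vocabulary.

## Evaluation stack

* **ROC/AUC** per code, over all pooled held-out turns, truth = union of
  raters. AUC uses the rank (Mann–Whitney) statistic with ties counted 1/2,
  which equals the trapezoidal area under the threshold-swept curve; tests
  verify both identities and cross-check against pair enumeration and pROC.
* **Cohen's κ** per code on binary presence/absence per turn (a single
  multiclass κ cannot represent multi-label turns).
  Restricted to sessions with two or more raters so rater–rater and
  model–rater agreement are estimated on the same turns. The model's
  continuous scores are binarized at the threshold whose positive fraction
  best matches the *average single-rater* marking rate for that code; the
  union rate would overshoot every individual rater's margin and bias the
  comparison. Ties at the cut break toward fewer positives.
* **ICC** on per-session code tallies, Shrout–Fleiss ICC(2,1): two-way
  random effects, absolute agreement, single measure. Absolute agreement is
  deliberate — a coder (or model) that systematically over-counts should be
  penalized. The model's tally is the count of turns whose binarized
  prediction is positive, putting it on the same count scale as rater
  tallies; summing raw θ̂ shares would total token shares, not turns, and
  sit systematically below any rater's count. The expected-count variant
  remains available via `session_tallies()` on raw scores.
* **Proficiency indices** per session — reflection-to-question ratio,
  % open questions, % complex reflections — computed from tallies for each
  rater and for the model, compared by the same ICC. Zero denominators
  yield `NA`, never an error.
* **Confusion pairs**: on turns where the model's top-1 code is outside the
  turn's truth set, the most frequently substituted code per true code
  (ties all reported; the full histogram is attached as an attribute).

Argmax and top-term ties break by inventory/vocabulary order for exact
reproducibility.

## The synthetic corpus generator

Real MISC-coded transcripts are confidential, so validation runs on corpora
drawn from the model's own generative process with known ground truth. The
generator emulates the structure of the original 148-session addiction
corpus at desk scale (see `addiction_corpus_summary()`): five studies with
proportional session counts (default 50 sessions), ~40 turns per session
and ~34 tokens per turn (negative binomial, matching the corpus's ~33.5
words/turn), a 2,000-term vocabulary, 12 MISC codes with non-uniform
prevalences all above the 2% retention threshold, three raters with
independent per-code errors (15% misses, 1% spurious additions), and 21% of
sessions coded by all three raters — the real corpus's coding design.

Two choices deserve comment:

* **Per-class θ concentrations.** The configuration gives each admissible
  topic a concentration by class (`code` 1.5, `study` 0.5, `background` 0.1
  each), so an annotated turn devotes roughly half its tokens to its code's
  language. A single small symmetric α would frequently produce annotated
  turns containing *no* code language, which is not how rater-visible codes
  behave.
* **Language difficulty calibration.** `topic_sharpness` (0.10) controls
  lexical overlap between topics. It is set, together with the code
  concentration, so that the fitted model lands in the qualitative regime
  observed on real transcripts: strong held-out ranking of true codes, yet
  turn-level reliability *below* that of the human raters, with session
  tallies agreeing better than individual turns. With near-disjoint topics
  the model becomes essentially perfect and inverts that ordering, which
  would make the test bed uninformative about the method's real failure
  modes.

What the generator does **not** emulate: natural-language realism (terms
are abstract `w0001`-style ids), correlated rater errors, turn-order
dependence, utterance-level structure, and speaker-specific language.
Passing the recovery tests therefore demonstrates correctness of the
inference and evaluation machinery under the model's own assumptions — not
performance on real clinical language.

## Validation problem sizes

The test suite validates at three scales: exact-enumeration oracles on
corpora with at most 64 assignment configurations (training) and at most
three turns of three tokens (fold-in, against brute-force posterior
enumeration, within 0.02); statistical cross-checks on 50-element random
fixtures (AUC vs pair enumeration, ICC vs `aov()` mean squares); and the
full pipeline on the default 50-session corpus under 10-fold
cross-validation, plus a 100-session study-confounded corpus for the
ablation comparison (the larger n keeps per-code AUC differences above
Monte-Carlo noise). The full suite runs in minutes on one CPU.

## Degenerate inputs and numerical conventions

* Empty turns infer the uniform mixture over admissible topics.
* In the ablated (codes-only) model, turns with no labels admit no topic
  and are dropped from training sweeps; they are still scored at predict
  time.
* Topics never visited in training report the uniform prior row
  `beta / (V beta)`.
* `kappa` with both raters constant and identical is 1; constant and
  opposite gives 0 (p_o = p_e = 0); ICC with zero between-session variance
  is an error rather than a silent 0/0.
* Gibbs randomness comes from R's RNG (`unif_rand` in compiled code), so a
  seed fixes every result bit-for-bit; cross-validation derives per-fold
  seeds as `seed + fold`, and all derived seeds stay within 32-bit range.

## Known limitations

* Turn order is ignored; distinguishing simple from complex reflections
  often needs the preceding patient turn, which this model cannot see.
* The θ-share score is a ranking score, not a calibrated probability of
  code presence; binarization is prevalence-matched rather than
  probability-thresholded.
* Kappa/ICC comparisons ride on the multiply-coded subset (21% of
  sessions); at desk scale that is ~10 sessions, so per-code ICCs carry
  substantial sampling error.
* The ICC variant and the binarization rule are conventions chosen here
  (and configurable), not facts about the original coding study.
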