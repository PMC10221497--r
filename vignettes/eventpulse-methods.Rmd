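---
title: "Measuring an event's impact on social-media engagement, sentiment, and expressed trust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring an event's impact on social-media engagement, sentiment, and expressed trust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(eventpulse)
```

## The problem

An abrupt public event — here, the May 2022 leak of a draft court decision
restricting abortion access — can change not only how much people discuss
clinicians and the privacy of health information, but how they feel about
them and whether the words they use carry connotations of trust or
mistrust. `eventpulse` packages the full measurement chain for such a
question on a corpus of short timestamped posts: topic-filtered selection
of on-topic posts, ordinal sentiment aggregation into daily series, a
Bayesian structural time-series counterfactual for the engagement and
sentiment changes, an antonym-anchored semantic-axis reading of trust
connotations in word embeddings, and sentiment-stratified TF-IDF term
volumes with exemplar-post selection.

Because real platform corpora cannot be redistributed (and scraping is out
of scope), the package ships a seeded synthetic-corpus generator with
planted ground truth. Every stage is validated by recovering what was
planted, by exact agreement with brute-force oracles, or by closed-form
expectations.

## Study window and ingestion

The analysis window is split at a boundary date: posts dated on or before
the boundary (UTC calendar date; the day-binning timezone is a package
convention, since none is standard) are "pre", later posts through the end
date are "post". The default window is 2020-01-01 through 2022-10-17 with
the boundary at 2022-05-01, matching the studied event.

Deduplication keys on whitespace-collapsed lowercased text, keeping first
occurrences in input order; record ids play no role (duplicate posts on
these platforms are retweet-like verbatim copies under fresh ids).
Tokenization lowercases, strips URLs, replaces user mentions by a
placeholder token, keeps hashtag words without the sign, splits on
non-alphanumerics, and keeps tokens of length two or more plus the
whitelisted domain terms "ob" and "phi". Stop-word removal is optional and
intended only for topic modeling and TF-IDF; embedding training sees the
unfiltered token sequence.

## Topic filtering

`fit_lda()` is a collapsed Gibbs sampler for latent Dirichlet allocation.
Topic-word and document-topic distributions are post-burn-in averaged
counts with Dirichlet smoothing; sweeps visit documents and tokens in fixed
order from one seeded RNG stream, so fits are exactly reproducible.
Defaults follow common practice (`alpha = 50/K`, `beta = 0.01`, 1,000
sweeps, 200 burn-in). One caveat matters for short posts: the
document-topic prior acts as `alpha` pseudo-tokens per topic, so with
`alpha = 50/K` a 15-token post can never reach 95% membership in one
topic. Pipelines that filter short posts at a 0.95 threshold should use a
small prior: the attainable single-topic membership of an `L`-token post is
`(L + alpha) / (L + K * alpha)`, so the demo uses `alpha = 0.01`, which also
pulls ambiguous tokens (sentiment markers, planted anchor words) toward the
post's dominant topic instead of letting them leak membership to unselected
topics.

Held-out posts are scored by fold-in: their token assignments are Gibbs
sampled with the topic-word distribution frozen. For training documents the
stored mixture is used directly (re-inference would add noise without
information). Filtering keeps a post when its membership summed over the
operator-selected topics reaches the threshold (default 0.95, the studied
inclusion rule). Topic selection itself is an operator decision;
`select_topics_by_terms()` offers a reproducible surrogate for the
inspect-the-top-terms step, and the pipeline records the selection in its
manifest.

## Sentiment and daily series

Sentiment classification is a pluggable contract: any function mapping a
character vector to an `n x 3` row-stochastic matrix over (negative,
neutral, positive). The transformer model used in the original study is
external trained weights, so the shipping default is a marker-lexicon
classifier that is exact on synthetic corpora by construction; the
analysis logic downstream of the contract is what this package reproduces.
Labels are the argmax with ties resolved toward neutral then negative
(conservative: ambiguity moves scores toward the center), then encoded
negative = 0, neutral = 0.5, positive = 1.

Daily sentiment is the mean encoded score per day; daily engagement is the
number of distinct users posting per day (a user active on several days
counts once per day). Days without posts get engagement 0; sentiment on
empty days is linearly interpolated between neighbors because the
counterfactual model needs a regular grid and a mean-sentiment value of 0
would be a data artifact, not an observation.

## The counterfactual model

Both daily series are modeled with the Bayesian local level model

y_t = mu_t + eps_t, eps_t ~ N(0, s2_obs);  mu_{t+1} = mu_t + eta_t, eta_t ~ N(0, s2_level),

fit to the pre-period only. No covariate or seasonal components are used:
the studied analysis names no control series, so the counterfactual must
come from the pre-period dynamics alone. The Gibbs sampler alternates a
forward-filter backward-sampling draw of the level path with conjugate
inverse-gamma draws of both variances; split-R-hat on both variances is
reported. Four chains of 2,500 sweeps with 500 burn-in are the defaults;
the calibration studies in the test suite use two chains of 1,500 (the
posterior for this two-parameter model is simple and mixes quickly, and the
studies repeat the fit hundreds of times).

Priors are weakly informative inverse-gamma with shape 0.01 and rate
`0.01 * var(y)`. The rate is scaled by the sample variance deliberately: an
inverse-gamma rate bounds the smallest variance the prior tolerates
(density carries a factor `exp(-rate/x)`), so a fixed rate of 0.01 would
silently forbid level variances below about 1e-3 — exactly the region the
likelihood favors for a flat sentiment series on the [0, 1] scale — and
inflate long-horizon predictive intervals. On unit-variance data the
default reduces to IG(0.01, 0.01).

Engagement counts are modeled on the `log1p` scale (Poisson-like
heteroscedasticity) and every posterior-predictive draw is back-transformed
before effects are computed, so all reported effects live on the original
scale; sentiment is modeled on its raw [0, 1] scale. The counterfactual
propagates each retained draw's final level through the random walk with
observation noise; effects per draw are the post-period mean difference
(absolute) and the percentage difference of totals (relative), with
central credible intervals and a one-sided posterior tail-area probability
using the add-one estimator (so p is never exactly zero and is floored at
1/(draws+1)). For count-like series, draws with nonpositive counterfactual
totals are rejected and counted.

Test-suite calibration under these choices: across 100 simulated series
with a planted threefold post-period step (300 pre days, 150 post days),
the 95% relative-effect interval covers the true +200% in at least 90; on
200 null series the tail-area probability falls below 0.05 in at most 7%.
The null rate runs conservative (typically 2-5%) because predictive
uncertainty about the boundary level and the variances widens the interval
relative to the true sampling distribution — the cost of refusing to
pretend the parameters are known.

## The trust dimension

Skip-gram with negative sampling is trained from scratch, single-threaded,
with a linearly decaying learning rate, negatives drawn from the
unigram^0.75 distribution, a dynamic window, and optional frequency
subsampling — deterministic given the seed. One model is trained per
period: the per-period scores are what the analysis reports, and
within-model projection avoids cross-model vector alignment entirely
(cosine against an axis built inside the same space is invariant to the
arbitrary rotations separating two independently trained models).

The trust axis is built from seven fixed antonym pairs ("trust"/"mistrust",
"trustworthy"/"untrustworthy", ...). Each pair difference (positive minus
negative vector) is unit-normalized before averaging so no single pair
dominates, and the mean is renormalized. A term's score is the cosine of
its center-word vector with this axis; out-of-vocabulary terms are reported
as missing, never given a default score. Pre/post deltas are defined only
where both scores exist — mirroring the studied handling of terms absent
from one period entirely.

Embeddings in the pipeline are trained on the deduplicated, period-labeled
corpus rather than the topic-filtered subset: the filter's purpose is to
isolate the on-topic series, while the embedding needs the full discourse
so that both anchor poles stay attested in both periods. (The studied
analysis is ambiguous on this point; the choice is recorded here.)

Default training settings are 100 dimensions, window 5, 5 negatives,
5 epochs, minimum count 5, subsampling 1e-3. On the small-vocabulary
synthetic corpora the demo and tests use 50 dimensions and disable
subsampling (with a vocabulary of ~100 types every word exceeds the 1e-3
frequency threshold, and subsampling would only discard data).

## Term volumes and exemplars

TF-IDF uses raw term frequency and unsmoothed `idf = ln(N/df)`: the variant
is pinned so the implementation can be tested for exact equality with a
brute-force double loop, including the edge case of a term present in every
document (idf exactly 0). Volumes count, per term, period, and sentiment
polarity (argmax label; neutral posts belong to neither polarity), the
posts whose token set contains the term, and are standardized to z-scores
within each polarity panel; an all-equal panel maps to zeros rather than
0/0. Exemplar posts for a term are those at or above the 0.95 quantile of
the term's TF-IDF weight among posts containing it (ties at the cut kept —
the studied "weighted threshold" is not defined precisely, and a quantile
with kept ties is monotone and scale-free), excluding posts containing
URLs as a proxy for headline/link posts.

## The synthetic corpus

`generate_corpus()` draws, for each day, a Poisson number of unique users
(intensity stepped by a multiplier at the boundary); each user posts
`1 + Poisson(tweets_per_user - 1)` times. Posts sample tokens from a
planted topic vocabulary (five default topics: policy/legality, health
privacy, an off-topic confounder, and positive- and negative-trust talk
topics that keep both anchor poles attested), carry exactly one sentiment
marker token from the planted label's set, and receive anchor-word
insertions near target terms per the trust directives. A configurable
fraction of posts is re-emitted verbatim under a fresh id. One RNG stream
seeded once drives everything, in fixed order.

Defaults emulate the studied conditions where they are known: the window
dates; an engagement step of 6.77 (the studied +576.86% in unique daily
users); sentiment probabilities (0.32, 0.48, 0.20) pre and
(0.45, 0.40, 0.15) post, whose expected encoded scores are 0.44 and 0.35
(the studied expected-vs-observed daily sentiment); and trust directives
that flip initially-positive clinician terms negative after the boundary.
Daily intensity is a desk-scale choice (the studied corpus has millions of
posts): 20-30 users/day keeps a laptop run in minutes while leaving
Poisson noise far from dominating a 6.77-fold step. The demo pipeline uses
20 users/day over the full window (~55,000 posts), LDA with 5 topics and
200 sweeps, and 3-epoch embeddings, and completes in a few minutes on one
CPU.

What the generator does not emulate: natural language (posts are bags of
planted tokens), user-level behavior across days, network structure,
retweet counts, and the gradual (rather than step) decay of real attention
spikes. Passing recovery tests therefore demonstrates that the estimators
recover planted structure of the kind the analysis assumes — not that the
pipeline is robust to the full messiness of platform text; the pluggable
classifier contract and explicit topic selection are the designed seams
for real-data substitutions.

## Numerical and degenerate-input conventions

* Probability vectors are validated to sum to 1 within 1e-9 (generator) and
  1e-8 (classifier outputs, LDA rows).
* A constant pre-period series triggers a degenerate-fit warning and
  variance draws floored at a small positive constant; the counterfactual
  is then flat at the constant.
* Documents with no in-vocabulary tokens score uniformly over topics and
  are flagged; terms out of vocabulary project to missing, not zero.
* `top_terms()` breaks weight ties lexicographically so serialized output
  is stable.
* Argmax sentiment ties resolve toward neutral, then negative.
* Per-stage seeds are the pipeline's global seed plus fixed offsets, so any
  stage can be rerun in isolation with identical results.

## Known limitations

The local-level counterfactual carries no seasonality or covariates; weekly
cycles in real engagement series will widen its intervals rather than be
explained. The lexicon classifier is a contract default, not a sentiment
model for natural text. Embedding scores carry no uncertainty in the
studied analysis; the test suite adds bootstrap-style stability checks over
seeds, but the reported scores remain point estimates. TF-IDF exemplar
selection reproduces the mechanical filter only — the studied manual
thematic review of exemplars is out of scope.
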