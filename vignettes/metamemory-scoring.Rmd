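---
title: "Scoring and clustering metamemory betting data with metabet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and clustering metamemory betting data with metabet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabet)
```

## The task and the data model

metabet analyses a judgment-of-learning (JOL) task in which a participant
studies R rounds of W words (defaults 5 x 12) and, after seeing each word,
places a bet between 0 and `bet_max` (default 10) points on recalling it at
the end of the round. Recalled words add their bet to the participant's
running score; forgotten words subtract it. The trial-level record is one row
per word event: participant, round, list position, bet, and a binary recall
outcome.

A bet of 0 is a legitimate wager, never a missing-data code; missing cells
are absent rows. Because the clustering stages need complete feature vectors,
`as_mm_series()` applies listwise deletion: a participant missing any of the
R x W cells is excluded from all analyses and reported in the dropped list.

## The scores

**mBrier.** The package's central statistic is a hybrid
calibration/resolution score. The bets of one round are first transformed by
`ranked_jols()`:

1. items bet 0 are excluded from ranking and assigned the value 0;
2. the remaining bets receive ascending fractional ranks, tied bets sharing
   the mean of their positional ranks;
3. ranks are divided by the *maximum assigned rank*, so the largest (possibly
   tied) bets map to exactly 1.

The mBrier score is then the mean squared deviation between recall accuracy
and the transformed bets, averaged over **all** n items of the round
(zero-bet items stay in the denominator):

$$\mathrm{mBrier} = \frac{1}{n}\sum_{i=1}^{n}(acc_i - Rjol_i)^2 .$$

Three numerical choices deserve emphasis, because plausible alternatives give
different numbers:

* *Average ranks for ties.* Dense or minimum ranking changes the score
  whenever bets tie; fractional average ranks are what reproduces the
  package's worked examples (e.g. the 0.183 round, whose two tied top bets
  make the maximum assigned rank 11.5).
* *Scaling by the maximum assigned rank, not by the count of nonzero bets.*
  Scaling by the count m would give 0.170 instead of 0.183 on the same
  round, and the top tied bets would no longer reach 1.
* *Full-n denominator.* Zero-bet items contribute $(acc_i - 0)^2$; an
  all-zero-bet round is still defined and equals the proportion recalled.

Because steps 1–3 use only the ordering of the positive bets, mBrier is
invariant under any strictly increasing remapping of the positive bet values:
a risk-averse participant betting 2s and 4s and a bold one betting 1s and 10s
receive identical scores whenever their orderings agree. This is the property
that distinguishes mBrier from the classical Brier score and the package's
test suite asserts it on randomly generated rounds.

**Brier.** `brier_score()` treats the bet as a recall probability. The
forecast can be normalised by the participant's own largest bet in the round
(`observed_max`, the default) or by the nominal scale maximum (`scale_max`).
The default is `observed_max` because it is the convention under which the
package's worked examples (0.23 / 0.09) reproduce; the two conventions
coincide whenever a participant uses the full scale and diverge for
compressed-scale betting (the 0.23 round scores 0.157 under `scale_max`).

**Gamma.** `gk_gamma()` counts concordant and discordant item pairs after
discarding every pair tied on either the bet or the outcome and returns
$(N_s - N_d)/(N_s + N_d)$. It is `NA` exactly when no pair survives — in
particular whenever all bets are equal or all outcomes are equal. This
happens often on 12-item rounds; the scoring aggregate therefore skips
undefined rounds rather than imputing, and reports `n_gamma_defined`
alongside the mean.

**Discrimination.** No canonical formula exists for this construct; the
package operationalises it as the mean bet on recalled items minus the mean
bet on forgotten items, `NA` when either set is empty. This is a deliberate
artifact choice, documented here so users know the number is not comparable
across packages that define discrimination differently.

**Aggregation.** Per-participant aggregates are the arithmetic means of the
per-round scores (points are summed), matching per-list reporting
conventions. A pooled mode that scores the concatenated R x W items once is
available (`aggregate = "pooled"`) but non-default: pooling mixes rounds with
different recall baselines into one ranking and is not how per-list summary
tables are usually built.

## Clustering

`mm_cluster()` runs agglomerative hierarchical clustering with the
complete-linkage criterion on either the 60-dimensional flattened bet
vectors (betting-strategy clusters) or the R-dimensional per-round mBrier
vectors (trajectory clusters). Design choices:

* *Euclidean distance on raw features.* All bets live on the same 0–10
  scale; column standardization would shrink exactly the low-variance
  vs high-variance contrast the strategy clusters are meant to expose.
* *Flattening order* is round-major (round 1 positions 1–12, then round 2,
  …). Any fixed order yields the same distances; this one is documented and
  stable.
* *Backbone.* The merge sequence is computed by `stats::hclust`; the test
  suite verifies topology and merge heights against an independent
  brute-force agglomerator on random instances, along with merge-height
  monotonicity, nestedness of cuts, and invariance to row permutation.
  Ties between candidate merges are resolved by `hclust`'s internal order;
  on continuous feature data exact ties have probability zero, and integer
  bet vectors in 60 dimensions make them vanishingly rare.
* *Cut labels* are renumbered by decreasing cluster size (ties by smallest
  member index), so "cluster 1" is reproducibly the largest. Cluster
  identity across analyses should be matched by profile shape
  (`cluster_profile()` returns per-cluster columnwise means and SDs — the
  content of the usual radar graphs), not by index.
* The default cuts are k = 2 and k = 3, the two coarsest non-trivial
  partitions; any k is available. The package deliberately offers no
  automatic k selection (silhouette, gap statistic): the intended use is
  inspecting fixed coarse cuts.

## Group comparisons

`chi_square_independence()` (Pearson, no Yates correction by default — the
correction is a flag, since 2 x 2 defaults differ across software),
`fisher_exact()` (full enumeration of tables with the observed margins,
summing probabilities of tables no more probable than the observed one; a
complexity guard diverts genuinely large tables to the chi-square test),
`t_test_groups()` (pooled variance by default, so df = n1 + n2 − 2, with
Cohen's d on the pooled SD), `anova_oneway()` with eta-squared, and
`tukey_hsd()` (studentized-range adjusted p). The chi-square warns when any
expected count drops below 5, the usual trigger for switching to the exact
test. No multiple-testing correction is applied across the analysis suite;
users running many comparisons should correct downstream.

## The synthetic cohort generator

No raw behavioural data ships with the package, so `simulate_mm_cohort()`
generates trial-level cohorts with the structure the analysis assumes, and
`mm_fixture()` provides calibrated presets. The generative model, per
participant:

* an **archetype** drawn from the group's mixture over three betting
  strategies: `low_flat` (low bets, low variance), `high_variable` (high
  bets, high variance), and `cyclical` (bets start high at the top of each
  round and decline, with the amplitude growing over rounds);
* a **personal ceiling** drawn uniformly from `scale_compression` (default
  6–10), emulating risk-averse participants who never touch the top of the
  scale — exactly the behaviour the rank transform is designed to absorb;
* a **capacity** draw (logit scale) around the group mean; per item, recall
  is Bernoulli with probability
  `plogis(capacity + primacy_slope*(position-1) + memorability_sd*z)`,
  where z ~ N(0,1) is the item's latent memorability and the negative
  primacy slope makes early list positions easier;
* a **bet signal** `rho*z + sqrt(1-rho^2)*noise`: `coupling_rho` is the
  single knob controlling how much the bets know about recall, with one
  meaning across archetypes because the signal is shaped (level, gain,
  round trend, cyclical profile) only afterwards, then clipped to the
  personal ceiling and rounded.

Recall draws use a uniform threshold (`u < p`) rather than `rbinom`, so
raising capacity under common random numbers raises recall pointwise — the
monotonicity properties in the test suite hold deterministically, not just
in expectation.

The default ("paperlike") preset encodes the study conditions the package
targets: 79 older adults (OA) and 138 young adults (YA). The group capacity
logits (−0.55 OA, +0.44 YA) were chosen analytically, via the
logistic-normal mean approximation, to put expected recall near 3.7 (OA) and
6.0 (YA) words per 12-word list, and the archetype mixtures and bet levels
put mean bets near 4 with OA slightly below YA; tests verify these summaries
by simulation with a ±0.5-word tolerance in expectation over seeds. These
are preset parameter choices verified after the fact, not numbers fitted by
optimization; exact moment-matching is a non-goal. Under these conditions
the cohorts reproduce the qualitative structure the analysis expects: OAs
recall fewer words and score worse (higher) on mBrier, OAs are
overrepresented in the worse mBrier-trajectory cluster, the
cyclical archetype attains the best mBrier (its front-loaded bets track the
primacy gradient), mBrier correlates negatively with gamma, and a nonzero
fraction of rounds has undefined gamma.

Other presets: `separable_k2`/`separable_k3` plant archetypes with mean-bet
gaps of 6 points and tight variances so strategy clustering recovers the
planted labels essentially perfectly (adjusted Rand index 1 at n = 200) —
these are recovery benchmarks, not realistic cohorts; `degenerate_gamma`
plants bet-perseverating participants (zero bet variance) to stress the
undefined-gamma code paths.

What the generator does **not** emulate: word-level lexical effects
(frequency, valence, imageability), response times, spelling errors,
within-participant strategy switching, and any dependence between the
personal ceiling and capacity. Passing recovery tests on synthetic cohorts
therefore shows the pipeline is correct and sensitive under the planted
model; it does not validate the psychological interpretation of clusters
found in real data. Whether a cyclical bettor is proactively minimising
effort or compensating for accurately-perceived weak memory is not a
question the generator takes a stance on: amplitude and coupling are
independent knobs.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on generated data:
full-size cohorts (217 participants, 13 020 trials) for the group-level
checks, 200-participant cohorts for recovery, 1000-round sweeps for the
scale-invariance and gamma-oracle properties, and 100 random instances of
n ≤ 8 points for the clustering oracle — sizes chosen so each property is
exercised convincingly while the whole suite stays fast. All randomness
flows through a single integer seed per simulation (`set.seed`, R's default
Mersenne-Twister), so identical configurations give byte-identical cohorts
across platforms.

## Known limitations

* mBrier inherits rank coarseness: on rounds with few distinct bet values it
  takes few distinct values, and an all-tied round collapses to the
  proportion forgotten.
* Gamma aggregation over defined rounds only introduces selection (rounds
  with extreme recall are dropped); `n_gamma_defined` should accompany any
  gamma-based comparison.
* Fisher's exact enumeration is intended for small contingency tables
  (clusters x age groups); use the chi-square test for large ones.
* Cluster labels are stable only within one fitted tree; comparing cluster
  "1" across datasets requires profile matching.
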