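# metabet

Scoring and clustering of metamemory betting-task data.

## The problem

In judgment-of-learning (JOL) "betting" tasks a participant studies rounds of
words and wagers 0–10 points on recalling each one; recalled words add the
bet to their score, forgotten words subtract it. Researchers want to know how
well those bets track actual memory — but participants use the rating scale
differently (a cautious bettor may live between 0 and 5, a bold one between 0
and 10), and the two classical accuracy measures each break down here:

* the **Brier score** (calibration), `mean((f_i - acc_i)^2)` with the bet
  taken as a recall probability `f_i`, penalises scale compression even when
  the *ordering* of bets is perfect;
* **Goodman–Kruskal gamma** (resolution), `(Ns - Nd)/(Ns + Nd)` over
  concordant/discordant item pairs, discards every tied pair and is
  undefined whenever all bets or all outcomes coincide — which happens
  constantly on short rounds.

metabet implements the **modified Brier score (mBrier)**, a hybrid of the
two: zero bets are excluded and mapped to 0, the remaining bets get
fractional (average-of-ties) ascending ranks divided by the maximum assigned
rank — so the top bets map to exactly 1 — and the score is

```
mBrier = (1/n) * sum_i (acc_i - Rjol_i)^2,     Rjol = scaled ranked bet
```

over all n items of a round. Lower is better. Because only the bet ordering
enters, mBrier is invariant to any strictly increasing remapping of a
participant's positive bets: two participants who order their bets
identically get identical scores regardless of which part of the scale they
use, yet — unlike gamma — mBrier is defined for flat-betting rounds and
grades *how wrong* miscalibrated bets were, not just their direction.

Around the score, the package provides the full analysis pipeline for an
aging-study design (older vs young adults): trial-table I/O with listwise
deletion, per-round and aggregate scoring (mBrier, Brier, gamma,
discrimination, raw points), complete-linkage hierarchical clustering of
60-dim betting-strategy vectors and 5-dim mBrier trajectories with
dendrogram (JSON/Newick) export, cluster-composition and score-comparison
statistics (chi-square, exact-enumeration Fisher, pooled t with Cohen's d,
one-way ANOVA with Tukey HSD), and a calibrated synthetic cohort generator
so everything is testable without raw behavioural data.

## Worked example

One round from a well-calibrated participant — high bets on the three
recalled words, low bets elsewhere, with tied top bets:

```r
library(metabet)
bets <- c(10, 10, 3, 3, 3, 1, 1, 1, 1, 2, 1, 1)
acc  <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0)

mbrier(bets, acc)                # 0.1832073
brier_score(bets, acc)           # 0.06416667  (observed-max normalization)
gk_gamma(bets, acc)              # 1
discrimination_score(bets, acc)  # 6.111111
mm_points(bets, acc)             # 9
```

The mBrier of 0.183 reflects good but imperfect monitoring (the recalled
word bet at 3 ranks below several forgotten 3s is penalised); gamma saturates
at 1 because every surviving pair is concordant, hiding that imperfection.

A full synthetic cohort through the pipeline:

```r
cohort <- mm_fixture("paperlike", seed = 1)   # 79 OA + 138 YA, 5 x 12 trials
series <- as_mm_series(cohort$trials)          # listwise-complete matrices
scores <- mm_score(series)
summary(scores)
#> Per-group summary (means per round/list; SDs across participants):
#>   OA     n= 79  bets 3.68 (1.21)  recalled 3.65 (1.22)  mBrier 0.36 (0.06)
#>   YA     n=138  bets 4.22 (1.26)  recalled 5.94 (1.75)  mBrier 0.32 (0.05)
#> Rounds with undefined gamma: 1.3%

mm_cluster(series, feature = "bets", k = c(2, 3))
#> mm_clust: complete-linkage tree over 217 participants (bets features, d=60)
#>   k=2 sizes: 128, 89
#>   k=3 sizes: 128, 71, 18

p <- scores$participants
t_test_groups(p$agg_mbrier[p$age_group == "OA"],
              p$agg_mbrier[p$age_group == "YA"])
#> t(215) = 5.404, p < 0.001, d = 0.762
```

The planted age gap shows up exactly as designed: older adults recall fewer
words per list (3.65 vs 5.94), bet about as much as young adults, and score
significantly worse (higher) on mBrier.

There is also a command-line interface (`inst/scripts/metabet`, a thin
launcher over `mm_cli()`):

```sh
Rscript inst/scripts/metabet run-all --preset paperlike --seed 42 --out results/run
```

which writes trials, truth, score tables, dendrograms, cluster assignments,
profiles, test results and a run manifest.

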