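Package: metabet
Title: Scoring and Clustering of Metamemory Betting-Task Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing judgment-of-learning "betting" tasks in which
    participants wager 0-10 points on recalling each studied word. Implements
    the rank-based modified Brier score (mBrier), a hybrid
    calibration/resolution statistic that is invariant to individual
    differences in rating-scale usage, alongside the classical Brier score,
    Goodman-Kruskal gamma, discrimination, and raw betting points. Provides
    complete-linkage hierarchical clustering of betting-strategy vectors and
    per-round mBrier trajectories, group-composition and score-comparison
    statistics (chi-square, Fisher's exact, t-tests, one-way ANOVA with Tukey
    HSD), and a synthetic cohort generator emulating an aging study (older and
    young adult groups, betting-strategy archetypes, serial-position effects,
    judgment-recall coupling) so the full pipeline is testable without raw
    behavioural data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
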