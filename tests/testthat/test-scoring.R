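test_that("ranked JOL transform handles ties, zeros and the top rank", {
  # fractional average ranks divided by the maximum assigned rank (11.5 here)
  expect_equal(ranked_jols(TABLE1_B$bets),
               c(11.5, 11.5, 9, 9, 9, 3.5, 3.5, 3.5, 3.5, 7, 3.5, 3.5) / 11.5)
  expect_equal(ranked_jols(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(ranked_jols(c(0, 5)), c(0, 1))
  # tied largest bets map to exactly 1
  expect_equal(max(ranked_jols(c(7, 7, 2))), 1)
  # monotone non-decreasing in the bet value, zeros fixed at 0
  set.seed(41)
  for (i in 1:200) {
    b <- random_round()$bets
    r <- ranked_jols(b)
    expect_true(all(r[b == 0] == 0))
    expect_true(all(diff(r[order(b)]) >= -1e-12))
  }
})

test_that("mBrier reproduces the worked vignette rounds", {
  expect_equal(round(mbrier(TABLE1_A$bets, TABLE1_A$acc), 3), 0.585)
  expect_equal(round(mbrier(TABLE1_B$bets, TABLE1_B$acc), 3), 0.183)
  expect_equal(round(mbrier(TABLE3_E$bets, TABLE3_E$acc), 2), 0.18)
  expect_equal(mbrier(TABLE3_E$bets, TABLE3_E$acc),
               mbrier(TABLE3_F$bets, TABLE3_F$acc))
  # equal bets, all recalled: ranked value 1 everywhere, perfect score
  expect_equal(mbrier(rep(4, 10), rep(1, 10)), 0)
  # all-zero bets: defined, equals the proportion recalled
  expect_equal(mbrier(rep(0, 10), c(rep(1, 3), rep(0, 7))), 0.3)
})

test_that("mBrier is permutation-invariant and bounded, Brier bounded", {
  set.seed(42)
  for (i in 1:200) {
    r <- random_round()
    m <- mbrier(r$bets, r$acc)
    expect_gte(m, 0); expect_lte(m, 1)
    b <- brier_score(r$bets, r$acc)
    expect_gte(b, 0); expect_lte(b, 1)
    perm <- sample(length(r$bets))
    expect_equal(mbrier(r$bets[perm], r$acc[perm]), m)
  }
})

test_that("Brier normalizations match the vignette and disagree on scale use", {
  expect_equal(round(brier_score(TABLE3_E$bets, TABLE3_E$acc, "observed_max"), 2), 0.23)
  expect_equal(round(brier_score(TABLE3_F$bets, TABLE3_F$acc, "observed_max"), 2), 0.09)
  expect_equal(round(brier_score(TABLE3_F$bets, TABLE3_F$acc, "scale_max"), 2), 0.09)
  # under scale_max the compressed-scale participant E scores differently
  expect_false(isTRUE(all.equal(brier_score(TABLE3_E$bets, TABLE3_E$acc, "scale_max"),
                                brier_score(TABLE3_E$bets, TABLE3_E$acc, "observed_max"))))
  # exact forecasts give 0
  expect_equal(brier_score(c(10, 0, 10), c(1, 0, 1), "scale_max"), 0)
  expect_error(brier_score(c(1, 2), c(1, 0, 1)), "length")
})

test_that("gamma matches single-pair logic and is missing when all pairs tie", {
  expect_equal(gk_gamma(c(1, 2), c(0, 1)), 1)
  expect_equal(gk_gamma(c(2, 1), c(0, 1)), -1)
  expect_true(is.na(gk_gamma(c(1, 2, 3), c(1, 1, 1))))
  expect_true(is.na(gk_gamma(c(4, 4, 4), c(0, 1, 0))))
  expect_equal(gk_gamma(TABLE1_A$bets, TABLE1_A$acc), 1)
  expect_equal(gk_gamma(TABLE1_B$bets, TABLE1_B$acc), 1)
  expect_equal(gk_gamma(TABLE2_C$bets, TABLE2_C$acc), -1)
  expect_equal(gk_gamma(TABLE2_D$bets, TABLE2_D$acc), -1)
})

test_that("gamma is NA exactly when every pair is discarded", {
  set.seed(43)
  for (i in 1:300) {
    r <- random_round(n = sample(2:12, 1))
    any_pair <- length(unique(r$bets)) > 1 && length(unique(r$acc)) > 1 &&
      !is.na(oracle_gamma(r$bets, r$acc))
    expect_equal(is.na(gk_gamma(r$bets, r$acc)), !any_pair)
  }
})

test_that("discrimination is the recalled/forgotten mean-bet gap", {
  expect_equal(discrimination_score(c(10, 1), c(1, 0)), 9)
  expect_true(is.na(discrimination_score(c(3, 5), c(0, 0))))
  expect_equal(discrimination_score(TABLE1_B$bets, TABLE1_B$acc),
               mean(c(10, 10, 3)) - mean(c(3, 3, 1, 1, 1, 1, 2, 1, 1)))
})

test_that("raw points add recalled bets and subtract forgotten ones", {
  expect_equal(mm_points(TABLE1_A$bets, TABLE1_A$acc), -35L)
  expect_equal(mm_points(rep(0, 12), rbinom(12, 1, 0.5)), 0L)
  b <- c(3, 7, 2); expect_equal(mm_points(b, rep(1, 3)), as.integer(sum(b)))
})

test_that("participant scoring aggregates per-round values as documented", {
  # five identical rounds replicating the Table-1 Participant-B round
  df <- do.call(rbind, lapply(1:5, function(r) {
    d <- one_round_trials_df("B", TABLE1_B$bets, TABLE1_B$acc); d$round <- r; d
  }))
  series <- as_mm_series(df, R = 5, W = 12)
  sc <- mm_score(series)
  p <- sc$participants
  expect_equal(round(p$agg_mbrier, 3), 0.183)
  expect_equal(p$n_gamma_defined, 5L)
  expect_equal(p$agg_gamma, 1)
  expect_equal(p$agg_points, 5L * mm_points(TABLE1_B$bets, TABLE1_B$acc))
  expect_equal(p$agg_mbrier, mean(sc$rounds$mbrier))

  # constant bets in every round: gamma never defined
  df2 <- do.call(rbind, lapply(1:5, function(r) {
    d <- one_round_trials_df("P", rep(6L, 12), rep(c(1L, 0L), 6)); d$round <- r; d
  }))
  p2 <- mm_score(as_mm_series(df2, 5, 12))$participants
  expect_true(is.na(p2$agg_gamma))
  expect_equal(p2$n_gamma_defined, 0L)

  # perfect top-rank betting: max bet on recalled items, 0 elsewhere
  df3 <- do.call(rbind, lapply(1:5, function(r) {
    d <- one_round_trials_df("Q", c(rep(10L, 4), rep(0L, 8)),
                             c(rep(1L, 4), rep(0L, 8))); d$round <- r; d
  }))
  expect_equal(mm_score(as_mm_series(df3, 5, 12))$participants$agg_mbrier, 0)
})

test_that("pooled aggregation scores the concatenated items", {
  cohort <- mm_fixture("paperlike", n = c(OA = 3, YA = 3), seed = 9)
  series <- as_mm_series(cohort$trials)
  sc <- mm_score(series, aggregate = "pooled")
  p1 <- series[[1]]
  expect_equal(sc$participants$agg_mbrier[1],
               mbrier(as.vector(t(p1$bets)), as.vector(t(p1$recalls))))
})

test_that("long-format score table covers every metric and aggregate rows", {
  cohort <- mm_fixture("paperlike", n = c(OA = 2, YA = 2), seed = 3)
  sc <- mm_score(as_mm_series(cohort$trials))
  long <- mm_scores_long(sc)
  expect_true(all(c("mbrier", "gamma", "mm_points") %in% long$metric))
  expect_true("all" %in% long$round)
  agg <- long[long$round == "all" & long$metric == "mbrier", ]
  expect_equal(sort(agg$value), sort(sc$participants$agg_mbrier))
})
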