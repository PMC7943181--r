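test_that("chi-square matches the 2x2 closed form and degenerate rules", {
  t0 <- chi_square_independence(matrix(c(10, 10, 10, 10), 2))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)

  tab <- matrix(c(20, 10, 10, 20), 2)
  t1 <- chi_square_independence(tab)
  closed <- 60 * (20 * 20 - 10 * 10)^2 / (30 * 30 * 30 * 30)
  expect_equal(t1$statistic, closed, tolerance = 1e-12)
  expect_equal(t1$df, 1)

  t2 <- expect_silent(chi_square_independence(matrix(c(28, 0, 0, 28), 2)))
  expect_equal(t2$statistic, 56)

  expect_warning(chi_square_independence(matrix(c(2, 1, 3, 2), 2)),
                 "fisher_exact")
  expect_error(chi_square_independence(matrix(c(5, 5, 0, 0), 2)), "degenerate")

  # invariance under row/column permutation on a random 3x2 table
  set.seed(21)
  tab3 <- matrix(rpois(6, 20), 3, 2)
  expect_equal(chi_square_independence(tab3)$statistic,
               chi_square_independence(tab3[c(3, 1, 2), c(2, 1)])$statistic)

  # closed form holds on random 2x2 tables
  for (i in 1:20) {
    t22 <- matrix(rpois(4, 15) + 1, 2)
    a <- t22[1, 1]; b <- t22[1, 2]; c <- t22[2, 1]; d <- t22[2, 2]; n <- sum(t22)
    cf <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(chi_square_independence(t22)$statistic, cf, tolerance = 1e-10)
  }
})

test_that("Yates correction is available for 2x2 tables", {
  tab <- matrix(c(12, 5, 6, 14), 2)
  expect_lt(chi_square_independence(tab, correction = TRUE)$statistic,
            chi_square_independence(tab, correction = FALSE)$statistic)
})

test_that("Fisher's exact enumeration reproduces the hypergeometric example", {
  # margins (2,2)/(2,2): three tables with probabilities 1/6, 4/6, 1/6
  t1 <- fisher_exact(matrix(c(2, 0, 0, 2), 2))
  expect_equal(t1$p_value, 2 / 6, tolerance = 1e-12)
  expect_error(fisher_exact(matrix(c(3, 2, 0, 0), 2, byrow = TRUE)),
               "degenerate")
})

test_that("Fisher's exact agrees with the reference implementation", {
  set.seed(22)
  shapes <- list(c(2, 2), c(2, 3), c(3, 3))
  for (i in 1:30) {
    sh <- shapes[[sample(3, 1)]]
    repeat {
      tab <- matrix(rpois(prod(sh), 3), sh[1], sh[2])
      if (sum(tab) <= 30 && all(rowSums(tab) > 0) && all(colSums(tab) > 0)) break
    }
    expect_equal(fisher_exact(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-8,
                 info = paste(tab, collapse = ","))
  }
})

test_that("enumeration guard rejects oversized tables", {
  big <- matrix(500L, 4, 4)
  expect_error(fisher_exact(big, guard = 1000), "chi_square")
})

test_that("t-test: pooled df, Cohen's d, antisymmetry, degenerate input", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 4)
  t0 <- t_test_groups(x, y)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$effect_size, 0)
  expect_equal(t0$df, length(x) + length(y) - 2)

  a <- rnorm(10, 1); b <- rnorm(12)
  tf <- t_test_groups(a, b); tr <- t_test_groups(b, a)
  expect_equal(tf$statistic, -tr$statistic)
  expect_equal(tf$effect_size, -tr$effect_size)

  # direct-arithmetic d for the worked pair
  t1 <- t_test_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t1$effect_size, (2 - 5) / 1)

  tw <- t_test_groups(a, b, welch = TRUE)
  expect_false(isTRUE(all.equal(tw$df, 20)))

  expect_error(t_test_groups(c(1, 1), c(1, 1)), "variance")
  expect_error(t_test_groups(1, c(1, 2)), "n >= 2")
})

test_that("two-group ANOVA F equals the squared pooled t", {
  set.seed(23)
  for (i in 1:10) {
    x <- rnorm(8, 0.3); y <- rnorm(11)
    f <- anova_oneway(list(x = x, y = y))
    t2 <- t_test_groups(x, y)$statistic^2
    expect_equal(f$statistic, t2, tolerance = 1e-10)
    expect_equal(f$df, c(1, 17))
  }
  near0 <- anova_oneway(list(a = c(1, 2, 3), b = c(2, 1, 3), c = c(3, 2, 1)))
  expect_equal(near0$statistic, 0, tolerance = 1e-12)
  expect_error(anova_oneway(list(a = c(1, 1), b = c(2, 2))), "variance")
  expect_error(anova_oneway(list(a = c(1, 2))), "2 groups")
})

test_that("Tukey HSD flags planted gaps and dominates unadjusted p", {
  set.seed(24)
  g <- list(a = rnorm(40, 0, 0.5), b = rnorm(40, 0, 0.5), c = rnorm(40, 2, 0.5))
  tk <- tukey_hsd(g)
  expect_equal(nrow(tk), 3)
  expect_true(all(tk$p_adj >= 0 & tk$p_adj <= 1))
  sig <- tk$p_adj < 0.001
  names(sig) <- tk$pair
  expect_false(sig[["b-a"]])
  expect_true(sig[["c-a"]] && sig[["c-b"]])
  # adjusted p is never below the unadjusted pairwise p on the same
  # (all-groups) error term
  for (i in 1:20) {
    g2 <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10))
    tk2 <- tukey_hsd(g2)
    mse <- sum(vapply(g2, function(v) sum((v - mean(v))^2), 0)) / (30 - 3)
    for (pr in tk2$pair) {
      nm <- strsplit(pr, "-")[[1]]
      tstat <- (mean(g2[[nm[1]]]) - mean(g2[[nm[2]]])) / sqrt(mse * (1/10 + 1/10))
      p_un <- 2 * stats::pt(-abs(tstat), df = 30 - 3)
      expect_gte(tk2$p_adj[tk2$pair == pr] + 1e-8, p_un)
    }
  }
})

test_that("group x round tables reduce correctly on tiny cohorts", {
  df <- do.call(rbind, lapply(1:5, function(r) {
    d <- one_round_trials_df("solo", TABLE1_B$bets, TABLE1_B$acc); d$round <- r; d
  }))
  sc <- mm_score(as_mm_series(df, 5, 12))
  tab <- group_round_table(sc)
  expect_equal(dim(tab$mean), c(1, 5))
  expect_equal(unname(tab$mean[1, ]), sc$rounds$mbrier)

  # two identical participants: SD 0 in every cell
  df2 <- df; df2$participant_id <- "twin"
  sc2 <- mm_score(as_mm_series(rbind(df, df2), 5, 12))
  tab2 <- group_round_table(sc2)
  expect_equal(unname(tab2$sd[1, ]), rep(0, 5))

  expect_error(group_round_table(sc2, grouping = c(solo = "g1")), "cover")
  expect_error(group_round_table(sc2, metric = "nope"), "unknown metric")
})

test_that("cluster composition cross-tabulates assignments by group", {
  cohort <- mm_fixture("separable_k2", n = c(OA = 10, YA = 10), seed = 8)
  series <- as_mm_series(cohort$trials)
  a <- mm_cluster(series, feature = "bets", k = 2)$assignments$k2
  grp <- setNames(cohort$truth$age_group, cohort$truth$participant_id)
  tab <- cluster_composition(a, grp)
  expect_equal(sum(tab), 20)
  expect_equal(unname(colSums(tab)), c(10, 10))
  expect_error(cluster_composition(a, grp[-1]), "cover")
})
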