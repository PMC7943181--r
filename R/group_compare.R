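mm_test <- function(method, statistic, df, p_value, effect_size = NA_real_,
                    effect_name = NA_character_, ...) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, effect_size = effect_size,
                 effect_name = effect_name, ...),
            class = "mm_test")
}

#' @export
print.mm_test <- function(x, ...) {
  dfstr <- if (all(is.na(x$df))) "" else
    sprintf("(%s)", paste(format(x$df, digits = 4), collapse = ","))
  pstr <- if (is.na(x$p_value)) "p = NA"
          else if (x$p_value < 0.001) "p < 0.001"
          else sprintf("p = %.4g", x$p_value)
  eff <- if (!is.na(x$effect_size))
    sprintf(", %s = %.3g", x$effect_name, x$effect_size) else ""
  stat <- if (is.na(x$statistic)) "" else sprintf(" = %.4g", x$statistic)
  cat(sprintf("%s%s%s, %s%s\n", x$method, dfstr, stat, pstr, eff))
  invisible(x)
}

check_contingency <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != floor(tab))) stop("counts must be non-negative integers")
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("need at least a 2 x 2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: a row or column margin is zero")
  tab
}

#' Chi-square test of independence
#'
#' Pearson chi-square on an r x c contingency table (clusters x age groups in
#' the intended use), with expected counts from the margins and
#' df = (r-1)(c-1). The Yates continuity correction for 2 x 2 tables is off
#' by default and available by flag. A warning is raised when any expected
#' count falls below 5, the usual trigger for preferring
#' \code{\link{fisher_exact}}.
#'
#' @param tab non-negative integer matrix, at least 2 x 2, with positive
#'   margins.
#' @param correction apply the Yates correction (2 x 2 only)?
#' @return an \code{mm_test} with the statistic, df, p-value and Cramer's V.
#' @export
chi_square_independence <- function(tab, correction = FALSE) {
  tab <- check_contingency(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5))
    warning("expected cell count below 5; consider fisher_exact()")
  res <- suppressWarnings(stats::chisq.test(tab, correct = correction))
  v <- sqrt(unname(res$statistic) / (sum(tab) * (min(dim(tab)) - 1)))
  mm_test(method = "chi-square", statistic = unname(res$statistic),
          df = unname(res$parameter), p_value = res$p.value,
          effect_size = v, effect_name = "Cramer's V",
          expected = expected)
}

#' Fisher's exact test for r x c tables
#'
#' Two-sided exact test by full enumeration: all tables with the observed
#' margins are generated recursively, each is assigned its multivariate
#' hypergeometric probability, and the p-value sums the probabilities of
#' tables no more probable than the observed one. Intended for the small
#' cluster x age-group tables of this analysis (at most a few hundred
#' participants); an enumeration guard refuses tables whose lattice is too
#' large and suggests the chi-square test instead.
#'
#' @param tab non-negative integer matrix with positive margins.
#' @param guard maximum number of tables to enumerate (default 1e7).
#' @return an \code{mm_test} with the p-value (no test statistic).
#' @export
fisher_exact <- function(tab, guard = 1e7) {
  tab <- check_contingency(tab)
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  # loose upper bound on the number of tables in the lattice
  bound <- prod(pmin(matrix(rs, length(rs), length(cs)),
                     matrix(cs, length(rs), length(cs), byrow = TRUE))[
                       seq_len(length(rs) - 1), seq_len(length(cs) - 1)] + 1)
  if (bound > guard)
    stop("table too large for exact enumeration (bound ", format(bound),
         " > guard); use chi_square_independence()")
  log_const <- sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(N)
  logp_obs <- log_const - sum(lfactorial(tab))
  total <- 0
  count <- 0L
  r <- nrow(tab); cc <- ncol(tab)
  cells <- matrix(0L, r, cc)
  recurse <- function(i, j, row_left, col_left) {
    if (count > guard) stop("enumeration guard exceeded; use chi_square_independence()")
    if (i == r) {            # last row forced by column margins
      cells[r, ] <<- col_left
      count <<- count + 1L
      lp <- log_const - sum(lfactorial(cells))
      if (lp <= logp_obs + 1e-7) total <<- total + exp(lp)
      return()
    }
    if (j == cc) {           # last column of a row forced by row margin
      if (row_left > col_left[cc]) return()
      cells[i, cc] <<- row_left
      recurse(i + 1L, 1L, rs[i + 1L], {cl <- col_left; cl[cc] <- cl[cc] - row_left; cl})
      return()
    }
    for (v in 0:min(row_left, col_left[j])) {
      cells[i, j] <<- v
      recurse(i, j + 1L, row_left - v, {cl <- col_left; cl[j] <- cl[j] - v; cl})
    }
  }
  recurse(1L, 1L, rs[1], cs)
  mm_test(method = "Fisher's exact test", statistic = NA_real_, df = NA_real_,
          p_value = min(1, total))
}

#' Two-sample t-test with Cohen's d
#'
#' Pooled-variance t by default (matching df = n1 + n2 - 2 reporting
#' conventions); Welch's unequal-variance form by flag. Cohen's d always uses
#' the pooled SD.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param welch use the Welch statistic instead of pooled variance?
#' @return an \code{mm_test} including Cohen's d.
#' @export
t_test_groups <- function(x, y, welch = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs n >= 2")
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 == 0) stop("zero variance in both groups")
  res <- stats::t.test(x, y, var.equal = !welch)
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  mm_test(method = if (welch) "Welch t" else "t",
          statistic = unname(res$statistic), df = unname(res$parameter),
          p_value = res$p.value, effect_size = d, effect_name = "d")
}

groups_to_df <- function(groups) {
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  data.frame(value = unlist(groups, use.names = FALSE),
             grp = factor(rep(names(groups), lengths(groups))))
}

#' One-way ANOVA
#'
#' F = MS_between / MS_within with df (k-1, N-k) plus eta-squared.
#'
#' @param groups a (preferably named) list of numeric vectors, >= 2 groups
#'   with n >= 2 each.
#' @return an \code{mm_test} including eta-squared.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) < 2))
    stop("need >= 2 groups with n >= 2 each")
  df <- groups_to_df(groups)
  if (all(vapply(groups, stats::var, 0) == 0))
    stop("zero within-group variance everywhere")
  fit <- stats::aov(value ~ grp, data = df)
  s <- summary(fit)[[1]]
  eta2 <- s["grp", "Sum Sq"] / sum(s[, "Sum Sq"])
  mm_test(method = "one-way ANOVA F", statistic = s["grp", "F value"],
          df = c(s["grp", "Df"], s["Residuals", "Df"]),
          p_value = s["grp", "Pr(>F)"],
          effect_size = eta2, effect_name = "eta^2", fit = fit)
}

#' Tukey HSD post-hoc comparisons
#'
#' All pairwise mean differences with family-wise adjusted p-values from the
#' studentized-range distribution.
#'
#' @inheritParams anova_oneway
#' @return a data frame: pair, diff, lwr, upr, p_adj.
#' @export
tukey_hsd <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) < 2))
    stop("need >= 2 groups with n >= 2 each")
  df <- groups_to_df(groups)
  tk <- stats::TukeyHSD(stats::aov(value ~ grp, data = df))$grp
  data.frame(pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Group x round descriptive table
#'
#' Per-group, per-round means and SDs of a score (default mBrier): the
#' numerical surface behind group-trajectory displays.
#'
#' @param scores an \code{mm_scores} object.
#' @param grouping named vector mapping participant_id to a group label;
#'   defaults to the age groups stored in \code{scores}. Must cover every
#'   scored participant.
#' @param metric a per-round score column (mbrier, brier, gamma,
#'   discrimination, mm_points, n_recalled, mean_bet).
#' @return list with group x round matrices \code{mean} and \code{sd}.
#' @export
group_round_table <- function(scores, grouping = NULL, metric = "mbrier") {
  stopifnot(inherits(scores, "mm_scores"))
  r <- scores$rounds
  if (!metric %in% names(r)) stop("unknown metric: ", metric)
  if (is.null(grouping))
    grouping <- stats::setNames(scores$participants$age_group,
                                scores$participants$participant_id)
  unknown <- setdiff(r$participant_id, names(grouping))
  if (length(unknown))
    stop("grouping does not cover participant(s): ",
         paste(utils::head(unknown, 3), collapse = ", "))
  g <- grouping[r$participant_id]
  levels_g <- sort(unique(g))
  rounds <- sort(unique(r$round))
  mk <- function(f) {
    m <- vapply(rounds, function(rd) vapply(levels_g, function(gg)
      f(r[[metric]][g == gg & r$round == rd]), 0), numeric(length(levels_g)))
    m <- matrix(m, nrow = length(levels_g),
                dimnames = list(levels_g, paste0("round", rounds)))
    m
  }
  list(mean = mk(function(v) mean(v, na.rm = TRUE)),
       sd = mk(function(v) if (sum(!is.na(v)) < 2) 0 else stats::sd(v, na.rm = TRUE)))
}

#' Cluster x group contingency table
#'
#' Cross-tabulates a cluster assignment against a participant grouping (age
#' group, by default, when given an \code{mm_scores} or named vector).
#'
#' @param assignment an \code{mm_assignment} (from \code{\link{mm_cut}} or
#'   inside \code{\link{mm_cluster}}).
#' @param grouping named vector participant_id -> group label.
#' @return an integer matrix (clusters x groups).
#' @export
cluster_composition <- function(assignment, grouping) {
  stopifnot(inherits(assignment, "mm_assignment"))
  ids <- names(assignment$labels)
  if (!all(ids %in% names(grouping)))
    stop("grouping does not cover all clustered participants")
  tab <- table(cluster = assignment$labels, group = grouping[ids])
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  m
}
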