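#' Rank-transform judgments of learning
#'
#' The transform underlying the modified Brier score. Zero bets are excluded
#' from ranking and mapped to 0. The remaining (nonzero) bets receive
#' ascending fractional ranks (tied bets share the mean of their positional
#' ranks), which are then divided by the maximum assigned rank so the largest
#' bet(s) map to exactly 1. The result is a pseudo-probability in [0, 1] that
#' depends only on the ordering of a participant's bets, not on which part of
#' the 0--10 scale they use.
#'
#' @param bets non-negative integer vector of bets/JOLs for one round.
#' @return numeric vector in [0, 1], same length as \code{bets}; all zeros
#'   when every bet is zero.
#' @examples
#' ranked_jols(c(10, 10, 3, 3, 3, 1, 1, 1, 1, 2, 1, 1))
#' ranked_jols(c(0, 5))  # 0, 1
#' @export
ranked_jols <- function(bets) {
  if (length(bets) < 1) stop("empty bet vector")
  if (any(is.na(bets)) || any(bets < 0)) stop("bets must be non-negative")
  r <- numeric(length(bets))
  nz <- bets > 0
  if (any(nz)) {
    rk <- rank(bets[nz], ties.method = "average")
    r[nz] <- rk / max(rk)
  }
  r
}

#' Modified Brier score (mBrier)
#'
#' Mean squared deviation between recall accuracy and the rank-transformed
#' bets (\code{\link{ranked_jols}}); the hybrid calibration/resolution score.
#' Zero-bet items enter the mean with a transformed value of 0, and the
#' denominator is the full item count n. Range [0, 1]; lower is better.
#' Because the rank transform discards bet magnitudes, mBrier is invariant to
#' any strictly increasing remapping of a participant's positive bet values
#' (two participants with the same bet ordering but different scale usage
#' receive identical scores).
#'
#' @param bets non-negative integer vector.
#' @param acc binary recall vector (0/1), same length.
#' @return a single number in [0, 1].
#' @examples
#' # the two Table-1 style profiles: near-uniform high bets vs graded bets
#' mbrier(c(10,10,10,10,10,10,5,10,10,10,10,10), c(1,1,1,1,0,0,0,0,0,0,0,0))  # 0.585
#' mbrier(c(10,10,3,3,3,1,1,1,1,2,1,1),          c(1,1,1,0,0,0,0,0,0,0,0,0))  # 0.183
#' @export
mbrier <- function(bets, acc) {
  check_round(bets, acc)
  mean((acc - ranked_jols(bets))^2)
}

#' Classical Brier score
#'
#' Mean squared deviation between recall accuracy and the bets taken as
#' probabilities of recall. Two normalizations of the bet into a forecast
#' probability f are offered: \code{"observed_max"} divides by the
#' participant's largest bet in the round (f = bet / max(bets)), so the score
#' reflects how each participant used their own range; \code{"scale_max"}
#' divides by the nominal scale maximum (f = bet / bet_max). The default is
#' \code{observed_max}. Unlike mBrier, either Brier variant is sensitive to
#' scale usage: compressing all bets into the lower half of the scale changes
#' the score even when the ordering is unchanged.
#'
#' @param bets non-negative integer vector.
#' @param acc binary recall vector, same length.
#' @param normalization \code{"observed_max"} or \code{"scale_max"}.
#' @param bet_max nominal scale maximum (used by \code{scale_max}).
#' @return a single number in [0, 1].
#' @export
brier_score <- function(bets, acc,
                        normalization = c("observed_max", "scale_max"),
                        bet_max = 10) {
  check_round(bets, acc)
  normalization <- match.arg(normalization)
  denom <- if (normalization == "observed_max") max(bets) else bet_max
  f <- if (denom > 0) bets / denom else rep(0, length(bets))
  mean((f - acc)^2)
}

#' Goodman-Kruskal gamma
#'
#' Rank correlation between bets and recall over all unordered item pairs.
#' A pair is concordant when the item with the higher bet was recalled and
#' the other was not, discordant when the item with the higher bet was the
#' one forgotten; pairs tied on either the bet or the accuracy are discarded.
#' Gamma = (Ns - Nd) / (Ns + Nd). Returns \code{NA} when no pair survives --
#' in particular whenever all bets are equal or all accuracies are equal,
#' which is why gamma is frequently non-computable on short rounds.
#'
#' @param bets non-negative integer vector (length >= 2).
#' @param acc binary recall vector, same length.
#' @return a number in [-1, 1], or \code{NA_real_} when undefined.
#' @export
gk_gamma <- function(bets, acc) {
  check_round(bets, acc)
  if (length(bets) < 2) stop("gamma needs at least 2 items")
  db <- sign(outer(bets, bets, "-"))
  da <- sign(outer(acc, acc, "-"))
  prod <- (db * da)[upper.tri(db)]
  ns <- sum(prod > 0)
  nd <- sum(prod < 0)
  if (ns + nd == 0) return(NA_real_)
  (ns - nd) / (ns + nd)
}

#' Discrimination score
#'
#' Difference between the mean bet on recalled items and the mean bet on
#' forgotten items. Positive values indicate higher confidence on items that
#' were subsequently recalled. Undefined (\code{NA}) when a round has no
#' recalled or no forgotten items. This mean-difference form is the package's
#' operationalisation of the discrimination construct.
#'
#' @inheritParams gk_gamma
#' @return a number, or \code{NA_real_} when one of the outcome classes is
#'   empty.
#' @export
discrimination_score <- function(bets, acc) {
  check_round(bets, acc)
  if (!any(acc == 1) || !any(acc == 0)) return(NA_real_)
  mean(bets[acc == 1]) - mean(bets[acc == 0])
}

#' Raw betting-task points (MM score)
#'
#' The score shown to participants: each recalled word adds its bet, each
#' forgotten word subtracts it.
#'
#' @inheritParams gk_gamma
#' @return an integer: sum of bet * (2*acc - 1).
#' @export
mm_points <- function(bets, acc) {
  check_round(bets, acc)
  as.integer(sum(bets * (2 * acc - 1)))
}

check_round <- function(bets, acc) {
  if (length(bets) != length(acc))
    stop("bets and acc must have equal length (", length(bets),
         " vs ", length(acc), ")")
  if (any(is.na(bets)) || any(is.na(acc)))
    stop("missing values in bets/acc; complete rounds are required")
  if (!all(acc %in% c(0, 1))) stop("acc must be binary 0/1")
  if (any(bets < 0)) stop("bets must be non-negative")
  invisible(TRUE)
}

score_one_round <- function(bets, acc, normalization, bet_max) {
  data.frame(
    mbrier = mbrier(bets, acc),
    brier = brier_score(bets, acc, normalization, bet_max),
    gamma = gk_gamma(bets, acc),
    discrimination = discrimination_score(bets, acc),
    mm_points = mm_points(bets, acc),
    n_recalled = as.integer(sum(acc)),
    mean_bet = mean(bets)
  )
}

#' Score a cohort of participants
#'
#' Computes every per-round score (mBrier, Brier, gamma, discrimination, raw
#' points, words recalled, mean bet) and the per-participant aggregates.
#' Rounds are scored independently; aggregates are the arithmetic mean of the
#' per-round values (points are summed). Gamma aggregation skips undefined
#' rounds rather than imputing, and \code{n_gamma_defined} reports how many
#' rounds were computable for each participant. With
#' \code{aggregate = "pooled"} the aggregate mBrier/Brier/gamma are instead
#' computed once over the concatenated R*W items (non-default; round-wise
#' averaging matches the usual per-list reporting).
#'
#' @param series an \code{mm_series} object (see \code{\link{as_mm_series}}).
#' @param brier_norm normalization passed to \code{\link{brier_score}}.
#' @param aggregate \code{"by_round"} (default) or \code{"pooled"}.
#' @return an object of class \code{mm_scores}: list with data frames
#'   \code{rounds} (participant x round) and \code{participants}
#'   (aggregates), plus the scoring options used.
#' @export
mm_score <- function(series, brier_norm = c("observed_max", "scale_max"),
                     aggregate = c("by_round", "pooled")) {
  stopifnot(inherits(series, "mm_series"))
  brier_norm <- match.arg(brier_norm)
  aggregate <- match.arg(aggregate)
  R <- attr(series, "R"); W <- attr(series, "W")
  bet_max <- attr(series, "bet_max")

  rounds <- do.call(rbind, lapply(series, function(p) {
    per <- do.call(rbind, lapply(seq_len(R), function(r)
      score_one_round(p$bets[r, ], p$recalls[r, ], brier_norm, bet_max)))
    cbind(data.frame(participant_id = p$participant_id,
                     age_group = p$age_group, round = seq_len(R),
                     stringsAsFactors = FALSE), per)
  }))
  rownames(rounds) <- NULL

  participants <- do.call(rbind, lapply(series, function(p) {
    rr <- rounds[rounds$participant_id == p$participant_id, ]
    gdef <- !is.na(rr$gamma)
    if (aggregate == "pooled") {
      b <- as.vector(t(p$bets)); a <- as.vector(t(p$recalls))
      agg_mbrier <- mbrier(b, a)
      agg_brier <- brier_score(b, a, brier_norm, bet_max)
      agg_gamma <- gk_gamma(b, a)
    } else {
      agg_mbrier <- mean(rr$mbrier)
      agg_brier <- mean(rr$brier)
      agg_gamma <- if (any(gdef)) mean(rr$gamma[gdef]) else NA_real_
    }
    data.frame(participant_id = p$participant_id, age_group = p$age_group,
               agg_mbrier = agg_mbrier, agg_brier = agg_brier,
               agg_gamma = agg_gamma, n_gamma_defined = sum(gdef),
               agg_points = sum(rr$mm_points),
               agg_recalled = mean(rr$n_recalled),
               mean_bet = mean(rr$mean_bet),
               stringsAsFactors = FALSE)
  }))
  rownames(participants) <- NULL

  structure(list(rounds = rounds, participants = participants,
                 R = R, W = W, brier_norm = brier_norm,
                 aggregate = aggregate),
            class = "mm_scores")
}

#' @export
print.mm_scores <- function(x, ...) {
  cat(sprintf("mm_scores: %d participants x %d rounds (Brier: %s, aggregation: %s)\n",
              nrow(x$participants), x$R, x$brier_norm, x$aggregate))
  cat(sprintf("  mean mBrier %.3f, mean recalled/round %.2f, undefined-gamma rounds %.1f%%\n",
              mean(x$participants$agg_mbrier),
              mean(x$participants$agg_recalled),
              100 * mean(is.na(x$rounds$gamma))))
  invisible(x)
}

#' @export
summary.mm_scores <- function(object, ...) {
  p <- object$participants
  out <- do.call(rbind, lapply(split(p, p$age_group), function(g)
    data.frame(age_group = g$age_group[1], n = nrow(g),
               mean_bet = mean(g$mean_bet), sd_bet = stats::sd(g$mean_bet),
               recalled = mean(g$agg_recalled), sd_recalled = stats::sd(g$agg_recalled),
               mbrier = mean(g$agg_mbrier), sd_mbrier = stats::sd(g$agg_mbrier),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  structure(list(by_group = out,
                 undefined_gamma_fraction = mean(is.na(object$rounds$gamma))),
            class = "summary.mm_scores")
}

#' @export
print.summary.mm_scores <- function(x, ...) {
  cat("Per-group summary (means per round/list; SDs across participants):\n")
  df <- x$by_group
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-6s n=%3d  bets %.2f (%.2f)  recalled %.2f (%.2f)  mBrier %.2f (%.2f)\n",
                df$age_group[i], df$n[i], df$mean_bet[i], df$sd_bet[i],
                df$recalled[i], df$sd_recalled[i], df$mbrier[i], df$sd_mbrier[i]))
  cat(sprintf("Rounds with undefined gamma: %.1f%%\n",
              100 * x$undefined_gamma_fraction))
  invisible(x)
}

#' @export
plot.mm_scores <- function(x, metric = "mbrier", ...) {
  tab <- group_round_table(x, metric = metric)
  matplot(t(tab$mean), type = "b", pch = 19, lty = 1,
          xlab = "round", ylab = paste("mean", metric), ...)
  legend("topright", legend = rownames(tab$mean),
         col = seq_len(nrow(tab$mean)), lty = 1, pch = 19, bty = "n")
  invisible(x)
}

#' @export
as.data.frame.mm_scores <- function(x, ...) x$participants

# n x R matrix of per-round mBrier, the trajectory feature for clustering
mbrier_matrix <- function(scores) {
  stopifnot(inherits(scores, "mm_scores"))
  r <- scores$rounds
  ids <- unique(r$participant_id)
  X <- t(vapply(ids, function(id)
    r$mbrier[r$participant_id == id][order(r$round[r$participant_id == id])],
    numeric(scores$R)))
  rownames(X) <- ids
  X
}

#' Long-format score table
#'
#' Per-round scores in (participant, round, metric, value) long form, plus
#' aggregate rows with \code{round = "all"}; convenient for external plotting
#' tools and the score-file interface.
#'
#' @param scores an \code{mm_scores} object.
#' @return a data frame with columns participant_id, round, metric, value.
#' @export
mm_scores_long <- function(scores) {
  stopifnot(inherits(scores, "mm_scores"))
  metrics <- c("mbrier", "brier", "gamma", "discrimination", "mm_points",
               "n_recalled", "mean_bet")
  r <- scores$rounds
  long_r <- do.call(rbind, lapply(metrics, function(m)
    data.frame(participant_id = r$participant_id, round = as.character(r$round),
               metric = m, value = r[[m]], stringsAsFactors = FALSE)))
  p <- scores$participants
  aggs <- c(mbrier = "agg_mbrier", brier = "agg_brier", gamma = "agg_gamma",
            mm_points = "agg_points", n_recalled = "agg_recalled",
            mean_bet = "mean_bet")
  long_a <- do.call(rbind, lapply(names(aggs), function(m)
    data.frame(participant_id = p$participant_id, round = "all",
               metric = m, value = p[[aggs[m]]], stringsAsFactors = FALSE)))
  rbind(long_r, long_a)
}
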