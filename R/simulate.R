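#' Configuration for the synthetic cohort generator
#'
#' Collects every knob of the generative model behind
#' \code{\link{simulate_mm_cohort}} and validates it. The defaults are the
#' "paperlike" study conditions: 79 older adults (OA) and 138 young adults
#' (YA), 5 rounds of 12 words, bets 0--10, a planted age gap in recall
#' capacity, three betting-strategy archetypes, and a moderate coupling
#' between item memorability and the bet signal.
#'
#' @param n_per_group named integer vector of participants per age group
#'   (default \code{c(OA = 79, YA = 138)}).
#' @param R,W rounds and words per round (defaults 5 and 12).
#' @param bet_max nominal scale maximum (default 10).
#' @param archetype_mix named list, one probability vector per group over the
#'   archetypes \code{low_flat}, \code{high_variable}, \code{cyclical}.
#' @param capacity named numeric, logit-scale recall propensity per group.
#' @param capacity_sd SD of the per-participant capacity draw.
#' @param primacy_slope per-position logit decrement (<= 0): earlier list
#'   positions are easier to recall.
#' @param memorability_sd weight of the latent per-item memorability z in the
#'   recall logit.
#' @param coupling_rho correlation in [0, 1] between z and the bet signal;
#'   0 means bets carry no information about recall (expected gamma ~ 0).
#' @param bet_level_mu,bet_level_sd named numeric per archetype: mean bet
#'   level and gain applied to the unit-variance bet signal.
#' @param bet_noise_sd extra white noise added to every bet before rounding.
#' @param cyclical_amplitude peak-to-center amplitude of the within-round
#'   declining bet profile of the cyclical archetype; the profile's amplitude
#'   grows over rounds.
#' @param round_trend named numeric per archetype: additive bet drift per
#'   round (negative = bets decline over rounds).
#' @param scale_compression length-2 range (low, high) from which each
#'   participant's personal bet ceiling is drawn uniformly; emulates
#'   risk-averse participants who never use the top of the scale.
#' @param seed integer RNG seed.
#' @return a validated object of class \code{mm_sim_config}.
#' @export
mm_sim_config <- function(n_per_group = c(OA = 79, YA = 138),
                          R = 5, W = 12, bet_max = 10,
                          archetype_mix = list(
                            OA = c(low_flat = 0.45, high_variable = 0.35, cyclical = 0.20),
                            YA = c(low_flat = 0.35, high_variable = 0.45, cyclical = 0.20)),
                          capacity = c(OA = -0.55, YA = 0.44),
                          capacity_sd = 0.6,
                          primacy_slope = -0.08,
                          memorability_sd = 1,
                          coupling_rho = 0.45,
                          bet_level_mu = c(low_flat = 2.5, high_variable = 6.5, cyclical = 4.5),
                          bet_level_sd = c(low_flat = 0.6, high_variable = 3.0, cyclical = 1.6),
                          bet_noise_sd = 0.4,
                          cyclical_amplitude = 3.5,
                          round_trend = c(low_flat = 0, high_variable = -0.3, cyclical = 0),
                          scale_compression = c(6, 10),
                          seed = 1L) {
  cfg <- structure(list(n_per_group = n_per_group, R = R, W = W,
                        bet_max = bet_max, archetype_mix = archetype_mix,
                        capacity = capacity, capacity_sd = capacity_sd,
                        primacy_slope = primacy_slope,
                        memorability_sd = memorability_sd,
                        coupling_rho = coupling_rho,
                        bet_level_mu = bet_level_mu,
                        bet_level_sd = bet_level_sd,
                        bet_noise_sd = bet_noise_sd,
                        cyclical_amplitude = cyclical_amplitude,
                        round_trend = round_trend,
                        scale_compression = scale_compression,
                        seed = as.integer(seed)),
                   class = "mm_sim_config")
  validate_sim_config(cfg)
  cfg
}

ARCHETYPES <- c("low_flat", "high_variable", "cyclical")

validate_sim_config <- function(cfg) {
  bad <- character()
  note <- function(msg) bad <<- c(bad, msg)
  if (is.null(names(cfg$n_per_group)) || any(cfg$n_per_group < 1))
    note("n_per_group must be a named vector of counts >= 1")
  if (cfg$R < 1 || cfg$W < 1) note("R and W must be >= 1")
  if (cfg$bet_max < 1) note("bet_max must be >= 1")
  for (g in names(cfg$n_per_group)) {
    mix <- cfg$archetype_mix[[g]]
    if (is.null(mix) || !all(ARCHETYPES %in% names(mix)) ||
        abs(sum(mix) - 1) > 1e-8 || any(mix < 0))
      note(sprintf("archetype_mix$%s must be probabilities over %s summing to 1",
                   g, paste(ARCHETYPES, collapse = "/")))
    if (!g %in% names(cfg$capacity))
      note(sprintf("capacity is missing group %s", g))
  }
  if (cfg$coupling_rho < 0 || cfg$coupling_rho > 1)
    note("coupling_rho must lie in [0, 1]")
  if (cfg$primacy_slope > 0) note("primacy_slope must be <= 0")
  for (f in c("bet_level_mu", "bet_level_sd", "round_trend"))
    if (!all(ARCHETYPES %in% names(cfg[[f]])))
      note(paste(f, "must name every archetype"))
  if (length(cfg$scale_compression) != 2 ||
      cfg$scale_compression[1] > cfg$scale_compression[2] ||
      cfg$scale_compression[2] > cfg$bet_max || cfg$scale_compression[1] < 1)
    note("scale_compression must be (low, high) with 1 <= low <= high <= bet_max")
  if (length(bad))
    stop("invalid simulation config:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  invisible(cfg)
}

# within-round declining bet profile for the cyclical archetype; amplitude
# grows across rounds so the cycles become more pronounced late in the task
cyclical_shape <- function(cfg, rnd, pos) {
  growth <- if (cfg$R > 1) 0.6 + 0.4 * (rnd - 1) / (cfg$R - 1) else 1
  span <- if (cfg$W > 1) 1 - 2 * (pos - 1) / (cfg$W - 1) else 0
  cfg$cyclical_amplitude * growth * span
}

#' Simulate a trial-level betting-task cohort
#'
#' Generative model, per participant: an archetype is drawn from the group's
#' mixture, a personal bet ceiling from the scale-compression range, and a
#' recall capacity from a normal around the group's logit-scale mean. For
#' each of the R*W items a latent memorability z ~ N(0,1) is drawn; recall is
#' a Bernoulli draw (via a uniform threshold, so capacity is pointwise
#' monotone under common random numbers) with success probability
#' plogis(capacity + primacy_slope*(position-1) + memorability_sd*z). The bet
#' signal rho*z + sqrt(1-rho^2)*noise is shaped by the archetype's level,
#' gain, round trend and (for the cyclical archetype) within-round declining
#' profile, clipped to [0, ceiling] and rounded to an integer bet.
#'
#' @param config an \code{\link{mm_sim_config}}.
#' @param seed optional override of \code{config$seed}.
#' @return an object of class \code{mm_cohort}: list with \code{trials} (a
#'   valid trial-record data frame), \code{truth} (participant_id, age_group,
#'   archetype, capacity, ceiling) and the \code{config}.
#' @export
simulate_mm_cohort <- function(config = mm_sim_config(), seed = NULL) {
  stopifnot(inherits(config, "mm_sim_config"))
  validate_sim_config(config)
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  R <- config$R; W <- config$W
  rho <- config$coupling_rho
  trials <- vector("list", sum(config$n_per_group))
  truth <- vector("list", sum(config$n_per_group))
  idx <- 0L
  for (grp in names(config$n_per_group)) {
    for (i in seq_len(config$n_per_group[[grp]])) {
      idx <- idx + 1L
      id <- sprintf("%s%03d", grp, i)
      arch <- sample(ARCHETYPES, 1, prob = config$archetype_mix[[grp]][ARCHETYPES])
      ceiling_i <- stats::runif(1, config$scale_compression[1],
                                config$scale_compression[2])
      cap <- stats::rnorm(1, config$capacity[[grp]], config$capacity_sd)
      rnd <- rep(seq_len(R), each = W)
      pos <- rep(seq_len(W), times = R)
      z <- stats::rnorm(R * W)
      p_rec <- stats::plogis(cap + config$primacy_slope * (pos - 1) +
                               config$memorability_sd * z)
      rec <- as.integer(stats::runif(R * W) < p_rec)
      s <- rho * z + sqrt(1 - rho^2) * stats::rnorm(R * W)
      shape <- config$bet_level_mu[[arch]] +
        config$round_trend[[arch]] * (rnd - 1) +
        if (arch == "cyclical") cyclical_shape(config, rnd, pos) else 0
      braw <- shape + config$bet_level_sd[[arch]] * s +
        stats::rnorm(R * W, 0, config$bet_noise_sd)
      bet <- pmin(pmax(as.integer(round(braw)), 0L),
                  as.integer(floor(ceiling_i)), config$bet_max)
      trials[[idx]] <- data.frame(
        participant_id = id, age_group = grp,
        list_version = if (idx %% 2 == 0) "A" else "B",
        round = rnd, position = pos,
        word = sprintf("w%d_%02d", rnd, pos),
        bet = bet, recalled = rec, stringsAsFactors = FALSE)
      truth[[idx]] <- data.frame(participant_id = id, age_group = grp,
                                 archetype = arch, capacity = cap,
                                 ceiling = ceiling_i, stringsAsFactors = FALSE)
    }
  }
  trials <- do.call(rbind, trials)
  attr(trials, "bet_max") <- config$bet_max
  class(trials) <- c("mm_trials", "data.frame")
  structure(list(trials = trials, truth = do.call(rbind, truth),
                 config = config),
            class = "mm_cohort")
}

#' @export
print.mm_cohort <- function(x, ...) {
  cat(sprintf("mm_cohort: %d participants (%s), %d x %d trials each, seed %d\n",
              nrow(x$truth),
              paste(sprintf("%s=%d", names(x$config$n_per_group),
                            x$config$n_per_group), collapse = ", "),
              x$config$R, x$config$W, x$config$seed))
  print(table(x$truth$age_group, x$truth$archetype))
  invisible(x)
}

#' Named cohort presets
#'
#' Ready-made simulation profiles:
#' \describe{
#'   \item{paperlike}{the default study conditions (79 OA + 138 YA) with the
#'     planted age gap in recall capacity, mixed archetypes and moderate
#'     judgment-recall coupling; cohort summaries land near the reference
#'     group means (OA ~3.7 and YA ~6.0 words recalled per list).}
#'   \item{separable_k2}{two archetypes (low_flat vs high_variable) with a
#'     mean-bet gap >= 4 points and tight within-archetype variance, so
#'     strategy clustering at k = 2 recovers the planted labels
#'     near-perfectly.}
#'   \item{separable_k3}{three well-separated archetypes (adds a
#'     high-amplitude cyclical group) for k = 3 recovery.}
#'   \item{degenerate_gamma}{includes bet-perseverating participants (zero
#'     bet variance) so a substantial fraction of rounds has undefined
#'     gamma.}
#' }
#'
#' @param profile preset name.
#' @param n optional named per-group sizes overriding the preset default.
#' @param seed RNG seed.
#' @return an \code{mm_cohort} (see \code{\link{simulate_mm_cohort}}).
#' @export
mm_fixture <- function(profile = c("paperlike", "separable_k2",
                                   "separable_k3", "degenerate_gamma"),
                       n = NULL, seed = 1L) {
  if (!is.character(profile) || !profile[1] %in%
      c("paperlike", "separable_k2", "separable_k3", "degenerate_gamma"))
    stop("unknown preset '", profile[1], "'; available: paperlike, ",
         "separable_k2, separable_k3, degenerate_gamma")
  profile <- match.arg(profile)
  cfg <- switch(profile,
    paperlike = mm_sim_config(seed = seed),
    separable_k2 = mm_sim_config(
      n_per_group = c(OA = 100, YA = 100),
      archetype_mix = list(
        OA = c(low_flat = 0.5, high_variable = 0.5, cyclical = 0),
        YA = c(low_flat = 0.5, high_variable = 0.5, cyclical = 0)),
      bet_level_mu = c(low_flat = 2, high_variable = 8, cyclical = 5),
      bet_level_sd = c(low_flat = 0.5, high_variable = 1.0, cyclical = 1),
      bet_noise_sd = 0.3, round_trend = c(low_flat = 0, high_variable = 0,
                                          cyclical = 0),
      scale_compression = c(10, 10), seed = seed),
    separable_k3 = mm_sim_config(
      n_per_group = c(OA = 100, YA = 100),
      archetype_mix = list(
        OA = c(low_flat = 1/3, high_variable = 1/3, cyclical = 1/3),
        YA = c(low_flat = 1/3, high_variable = 1/3, cyclical = 1/3)),
      bet_level_mu = c(low_flat = 1.5, high_variable = 8.5, cyclical = 5),
      bet_level_sd = c(low_flat = 0.5, high_variable = 1.0, cyclical = 0.8),
      bet_noise_sd = 0.3, cyclical_amplitude = 4.5,
      round_trend = c(low_flat = 0, high_variable = 0, cyclical = 0),
      scale_compression = c(10, 10), seed = seed),
    degenerate_gamma = mm_sim_config(
      n_per_group = c(OA = 40, YA = 40),
      archetype_mix = list(
        OA = c(low_flat = 0.6, high_variable = 0.4, cyclical = 0),
        YA = c(low_flat = 0.6, high_variable = 0.4, cyclical = 0)),
      bet_level_sd = c(low_flat = 0, high_variable = 3, cyclical = 1),
      bet_noise_sd = 0, seed = seed))
  if (!is.null(n)) {
    cfg$n_per_group[names(n)] <- n
    validate_sim_config(cfg)
  }
  simulate_mm_cohort(cfg)
}

#' Write a simulated cohort to disk
#'
#' Emits the standard trials CSV plus the planted-truth CSV.
#'
#' @param cohort an \code{mm_cohort}.
#' @param dir output directory (created if needed).
#' @return the two file paths, invisibly.
#' @export
write_mm_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mm_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tf <- file.path(dir, "trials.csv"); uf <- file.path(dir, "truth.csv")
  write_mm_table(cohort$trials, tf)
  write_mm_table(cohort$truth, uf)
  invisible(c(trials = tf, truth = uf))
}
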