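#' metabet: scoring and clustering of metamemory betting-task data
#'
#' Analysis tools for judgment-of-learning (JOL) "betting" tasks: participants
#' study short word lists and wager 0--10 points on later recalling each word.
#' The package implements the rank-based modified Brier score (mBrier), a
#' hybrid calibration/resolution statistic invariant to individual differences
#' in rating-scale usage, together with the classical Brier score,
#' Goodman-Kruskal gamma, discrimination and raw betting points; hierarchical
#' complete-linkage clustering of betting-strategy vectors and per-round
#' mBrier trajectories; group-composition and score-comparison statistics; and
#' a synthetic cohort generator for an older-adult/young-adult study design.
#'
#' @section Typical workflow:
#' \enumerate{
#'   \item \code{\link{read_mm_trials}} or \code{\link{simulate_mm_cohort}}
#'   \item \code{\link{as_mm_series}} (listwise-complete participant matrices)
#'   \item \code{\link{mm_score}} (per-round and aggregate scores)
#'   \item \code{\link{mm_cluster}} (strategy and trajectory clusters)
#'   \item \code{\link{chi_square_independence}}, \code{\link{t_test_groups}},
#'     \code{\link{anova_oneway}} etc. for group comparisons
#' }
#'
#' @keywords internal
#' @importFrom graphics matplot legend
#' @importFrom stats dist hclust cutree as.dist
"_PACKAGE"

# canonical trial-table column order
MM_TRIAL_COLUMNS <- c("participant_id", "age_group", "list_version",
                      "round", "position", "word", "bet", "recalled")
MM_REQUIRED_COLUMNS <- c("participant_id", "round", "position", "bet", "recalled")

#' Read a trial-level betting-task table
#'
#' Reads a delimited file with one row per word event (participant x round x
#' list position), validates it against the trial-record contract and returns
#' a data frame in canonical column order. Required columns:
#' \code{participant_id}, \code{round}, \code{position}, \code{bet},
#' \code{recalled}; optional columns \code{age_group}, \code{list_version} and
#' \code{word} are carried through (filled with \code{"other"}/\code{"unknown"}
#' /\code{NA} when absent). Files with different headers can be ingested by
#' supplying a \code{schema} mapping.
#'
#' @param path path to a delimited text file with a header row.
#' @param schema optional named character vector mapping canonical names to
#'   the file's column names, e.g. \code{c(participant_id = "subj")}.
#' @param bet_max maximum legal bet (default 10).
#' @param sep field separator (default comma).
#' @param quiet suppress the row-count message.
#' @return a data frame of validated trial records (class \code{mm_trials}),
#'   with attribute \code{bet_max}.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' cohort <- mm_fixture("paperlike", n = c(OA = 3, YA = 3), seed = 1)
#' write_mm_table(cohort$trials, f)
#' trials <- read_mm_trials(f)
#' nrow(trials)  # 6 participants x 5 rounds x 12 words
#' @export
read_mm_trials <- function(path, schema = NULL, bet_max = 10, sep = ",",
                           quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", encoding = "UTF-8")
  if (!is.null(schema)) {
    bad <- setdiff(unname(schema), names(raw))
    if (length(bad))
      stop("schema maps to columns absent from file: ",
           paste(bad, collapse = ", "))
    idx <- match(unname(schema), names(raw))
    names(raw)[idx] <- names(schema)
  }
  missing_req <- setdiff(MM_REQUIRED_COLUMNS, names(raw))
  if (length(missing_req))
    stop("missing required column(s): ", paste(missing_req, collapse = ", "))

  df <- data.frame(
    participant_id = as.character(raw$participant_id),
    age_group      = if ("age_group" %in% names(raw)) as.character(raw$age_group) else "other",
    list_version   = if ("list_version" %in% names(raw)) as.character(raw$list_version) else "unknown",
    round          = suppressWarnings(as.integer(raw$round)),
    position       = suppressWarnings(as.integer(raw$position)),
    word           = if ("word" %in% names(raw)) as.character(raw$word) else NA_character_,
    bet            = suppressWarnings(as.numeric(raw$bet)),
    recalled       = suppressWarnings(as.numeric(raw$recalled)),
    stringsAsFactors = FALSE
  )
  validate_mm_trials(df, bet_max = bet_max)
  df$bet <- as.integer(df$bet)
  df$recalled <- as.integer(df$recalled)
  if (!quiet) message(sprintf("read %d trial records for %d participant(s) from %s",
                              nrow(df), length(unique(df$participant_id)), path))
  attr(df, "bet_max") <- bet_max
  class(df) <- c("mm_trials", "data.frame")
  df
}

# validate trial records against the contract; errors cite the offending row
validate_mm_trials <- function(df, bet_max = 10) {
  fail_rows <- function(ok, what) {
    if (any(!ok)) {
      rows <- which(!ok)
      stop(sprintf("invalid %s on row %s%s", what,
                   paste(utils::head(rows, 5), collapse = ", "),
                   if (length(rows) > 5) sprintf(" (and %d more)", length(rows) - 5) else ""),
           call. = FALSE)
    }
  }
  fail_rows(!is.na(df$round) & df$round >= 1 & df$round == floor(df$round),
            "round (must be integer >= 1)")
  fail_rows(!is.na(df$position) & df$position >= 1 & df$position == floor(df$position),
            "position (must be integer >= 1)")
  fail_rows(!is.na(df$bet) & df$bet == floor(df$bet) & df$bet >= 0 & df$bet <= bet_max,
            sprintf("bet (must be integer in [0, %d])", bet_max))
  fail_rows(!is.na(df$recalled) & df$recalled %in% c(0, 1),
            "recalled (must be 0 or 1)")
  key <- paste(df$participant_id, df$round, df$position, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate (participant, round, position) record(s), first at row ",
         which(dup)[1], call. = FALSE)
  invisible(df)
}

#' Write a delimited table
#'
#' Writes any non-empty data frame as comma-separated text with a header,
#' re-readable losslessly (UTF-8; no row names). Companion of
#' \code{\link{read_mm_trials}} for the round-trip property.
#'
#' @param rows a non-empty data frame.
#' @param path output path.
#' @export
write_mm_table <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0)
    stop("refusing to write an empty table")
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  utils::write.csv(as.data.frame(rows), con, row.names = FALSE)
  invisible(path)
}

#' Assemble complete per-participant bet/recall matrices
#'
#' Converts trial records into one R x W bet matrix and one R x W recall
#' matrix per participant (rows = rounds, columns = list positions).
#' Participants with any missing cell are dropped entirely (listwise
#' deletion), because the downstream clustering requires full feature
#' vectors; the dropped participants are listed in the \code{dropped}
#' attribute.
#'
#' @param trials a trial-record data frame (from \code{\link{read_mm_trials}}
#'   or \code{\link{simulate_mm_cohort}}).
#' @param R number of rounds (default 5).
#' @param W words per round (default 12).
#' @return an object of class \code{mm_series}: a list with one element per
#'   complete participant (\code{participant_id}, \code{age_group},
#'   \code{bets}, \code{recalls}), attributes \code{R}, \code{W},
#'   \code{bet_max} and \code{dropped} (data frame of excluded participants
#'   with their record counts).
#' @export
as_mm_series <- function(trials, R = 5, W = 12) {
  stopifnot(R >= 1, W >= 1)
  df <- as.data.frame(trials)
  ids <- unique(df$participant_id)
  out <- list()
  dropped <- data.frame(participant_id = character(), n_records = integer(),
                        stringsAsFactors = FALSE)
  for (id in ids) {
    sub <- df[df$participant_id == id & df$round <= R & df$position <= W, ]
    complete <- nrow(sub) == R * W &&
      !anyDuplicated(paste(sub$round, sub$position))
    if (!complete) {
      dropped <- rbind(dropped, data.frame(participant_id = id,
                                           n_records = nrow(sub),
                                           stringsAsFactors = FALSE))
      next
    }
    bets <- matrix(NA_integer_, R, W)
    recalls <- matrix(NA_integer_, R, W)
    bets[cbind(sub$round, sub$position)] <- sub$bet
    recalls[cbind(sub$round, sub$position)] <- sub$recalled
    out[[id]] <- list(participant_id = id,
                      age_group = sub$age_group[1],
                      bets = bets, recalls = recalls)
  }
  if (length(out) == 0)
    stop("no participant has complete ", R, " x ", W, " data")
  structure(out, class = "mm_series", R = R, W = W,
            bet_max = attr(trials, "bet_max") %||% 10L,
            dropped = dropped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mm_series <- function(x, ...) {
  cat(sprintf("mm_series: %d participants, %d rounds x %d words (%d dropped)\n",
              length(x), attr(x, "R"), attr(x, "W"), nrow(attr(x, "dropped"))))
  tab <- table(vapply(x, `[[`, "", "age_group"))
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Flatten bet matrices into strategy vectors
#'
#' Stacks each participant's bets into one row of length R*W in round-major
#' order (round 1 positions 1..W, then round 2, ...). This is the feature
#' matrix used for betting-strategy clustering. The order is an artifact
#' convention (clustering is invariant to any fixed coordinate order) but is
#' documented and stable.
#'
#' @param series an \code{mm_series} object.
#' @return an n x (R*W) integer matrix with participant ids as row names.
#' @export
flatten_bets <- function(series) {
  stopifnot(inherits(series, "mm_series"))
  X <- t(vapply(series, function(p) as.vector(t(p$bets)),
                numeric(attr(series, "R") * attr(series, "W"))))
  rownames(X) <- vapply(series, `[[`, "", "participant_id")
  X
}

# recall matrices, flattened the same way (used by summaries)
flatten_recalls <- function(series) {
  X <- t(vapply(series, function(p) as.vector(t(p$recalls)),
                numeric(attr(series, "R") * attr(series, "W"))))
  rownames(X) <- vapply(series, `[[`, "", "participant_id")
  X
}

series_age_groups <- function(series) {
  stats::setNames(vapply(series, `[[`, "", "age_group"),
                  vapply(series, `[[`, "", "participant_id"))
}
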