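# Pseudo-randomized trial schedules for the prosocial effort task.
#
# Design constraints reproduced by the generator:
#   * every consecutive non-overlapping block of 5 trials contains each
#     effort level exactly once (so the block-mean effort is exactly 3);
#   * the same recipient never occurs more than 4 times in a row;
#   * exactly n_per_recipient trials per recipient (default 75 + 75 = 150);
#   * within each recipient, each (effort_level, work_shocks) cell of the
#     5 x 5 offer grid appears n_per_recipient/25 times.

MAX_RECIPIENT_RUN <- 4L
REST_SHOCKS <- 6L
PENALTY_SHOCKS <- 10L

max_run_length <- function(x) max(rle(as.character(x))$lengths)

#' Generate a pseudo-randomized trial schedule
#'
#' Effort levels are laid out as consecutive mini-blocks of five, each a
#' uniformly random permutation of levels 1..5. Recipients (self/other) are
#' assigned balanced within each effort level and resampled until no
#' recipient occurs more than four times consecutively. Work-offer shock
#' counts (1..5) are then allocated in balance within each recipient x
#' effort cell.
#'
#' @param n_per_recipient Trials per recipient; must be a positive multiple
#'   of 25 so the 5 x 5 effort-by-shock grid balances (default 75).
#' @param seed Integer RNG seed; regeneration with the same seed is
#'   bit-identical.
#' @param max_attempts Bound on rejection-sampling attempts for the
#'   recipient-run constraint.
#' @return An `ep_schedule`: a data frame with one row per trial and columns
#'   `index` (0-based position), `recipient`, `effort_level`, `effort_pct`
#'   (40-80, percent of maximum voluntary contraction), `work_shocks`,
#'   `rest_shocks` (always 6) and `penalty_shocks` (always 10).
#' @examples
#' sched <- generate_schedule(75, seed = 1)
#' nrow(sched)                 # 150
#' table(sched$recipient)      # 75 self, 75 other
#' @export
generate_schedule <- function(n_per_recipient = 75, seed = NULL,
                              max_attempts = 10000) {
  abort_if(!is_count(n_per_recipient) || n_per_recipient %% 25 != 0,
           "n_per_recipient must be a positive multiple of 25 ",
           "(so that all 25 effort-by-shock cells balance); got ",
           n_per_recipient)
  if (!is.null(seed)) set.seed(seed)
  n_total <- 2L * n_per_recipient
  n_blocks <- n_total %/% 5L

  effort <- as.integer(unlist(lapply(seq_len(n_blocks), function(b) sample(5L))))

  # balanced recipient assignment within each effort level, rejected until
  # the run-length constraint holds
  per_level <- n_total %/% 5L          # occurrences of each effort level
  recipient <- NULL
  for (attempt in seq_len(max_attempts)) {
    r <- character(n_total)
    for (lev in 1:5) {
      idx <- which(effort == lev)
      r[idx] <- sample(rep(c("self", "other"), each = per_level %/% 2L))
    }
    if (max_run_length(r) <= MAX_RECIPIENT_RUN) {
      recipient <- r
      break
    }
  }
  abort_if(is.null(recipient),
           "could not satisfy the recipient run-length constraint in ",
           max_attempts, " attempts")

  # balanced shock allocation within recipient x effort cells
  work_shocks <- integer(n_total)
  copies <- n_per_recipient %/% 25L
  for (rec in c("self", "other")) {
    for (lev in 1:5) {
      idx <- which(recipient == rec & effort == lev)
      work_shocks[idx] <- sample(rep(1:5, copies))
    }
  }

  out <- data.frame(
    index = 0:(n_total - 1L),
    recipient = recipient,
    effort_level = effort,
    effort_pct = 30L + 10L * effort,
    work_shocks = work_shocks,
    rest_shocks = REST_SHOCKS,
    penalty_shocks = PENALTY_SHOCKS,
    stringsAsFactors = FALSE)
  attr(out, "n_per_recipient") <- as.integer(n_per_recipient)
  attr(out, "seed") <- seed
  class(out) <- c("ep_schedule", "data.frame")
  out
}

#' Validate a trial schedule against the design constraints
#'
#' Never throws on rule violations; returns a character report instead
#' (empty when the schedule is valid). Malformed input (missing columns)
#' is an error.
#'
#' @param schedule A data frame with the [generate_schedule()] columns.
#' @return Character vector of violated constraints, each naming the rule
#'   and the offending trial indices; `character(0)` if all hold.
#' @export
validate_schedule <- function(schedule) {
  need <- c("index", "recipient", "effort_level", "work_shocks", "rest_shocks")
  abort_if(!is.data.frame(schedule) || nrow(schedule) == 0,
           "schedule must be a non-empty data frame")
  abort_if(!all(need %in% names(schedule)),
           "schedule must have columns: ", paste(need, collapse = ", "))
  report <- character(0)
  n <- nrow(schedule)

  bad <- which(!schedule$effort_level %in% 1:5)
  if (length(bad)) report <- c(report, paste0(
    "effort_level outside 1..5 at trials: ", paste(bad, collapse = ", ")))
  bad <- which(!schedule$work_shocks %in% 1:5)
  if (length(bad)) report <- c(report, paste0(
    "work_shocks outside 1..5 at trials: ", paste(bad, collapse = ", ")))
  bad <- which(schedule$work_shocks >= schedule$rest_shocks)
  if (length(bad)) report <- c(report, paste0(
    "work_shocks not below rest_shocks at trials: ", paste(bad, collapse = ", ")))
  bad <- which(schedule$rest_shocks != REST_SHOCKS)
  if (length(bad)) report <- c(report, paste0(
    "rest_shocks != 6 at trials: ", paste(bad, collapse = ", ")))

  counts <- table(schedule$recipient)
  if (length(counts) != 2 || length(unique(counts)) != 1) {
    report <- c(report, paste0(
      "recipient split is not balanced self/other: ",
      paste(names(counts), counts, sep = "=", collapse = ", ")))
  }

  if (n %% 5 == 0) {
    blocks <- split(schedule$effort_level, rep(seq_len(n %/% 5), each = 5))
    bad_blocks <- which(!vapply(blocks, function(b) setequal(b, 1:5), logical(1)))
    if (length(bad_blocks)) report <- c(report, paste0(
      "mini-block of 5 is not a permutation of effort levels 1..5 ",
      "at blocks: ", paste(bad_blocks, collapse = ", ")))
  } else {
    report <- c(report, paste0("length ", n, " is not a multiple of 5 ",
                               "(mini-block structure impossible)"))
  }

  runs <- rle(as.character(schedule$recipient))
  if (any(runs$lengths > MAX_RECIPIENT_RUN)) {
    ends <- cumsum(runs$lengths)
    long <- which(runs$lengths > MAX_RECIPIENT_RUN)
    report <- c(report, paste0(
      "recipient run longer than ", MAX_RECIPIENT_RUN,
      " ending at trials: ", paste(ends[long], collapse = ", ")))
  }

  for (rec in unique(schedule$recipient)) {
    sub <- schedule[schedule$recipient == rec, ]
    eff_tab <- table(factor(sub$effort_level, levels = 1:5))
    shk_tab <- table(factor(sub$work_shocks, levels = 1:5))
    if (length(unique(as.integer(eff_tab))) != 1) report <- c(report, paste0(
      "effort levels not balanced within recipient '", rec, "'"))
    if (length(unique(as.integer(shk_tab))) != 1) report <- c(report, paste0(
      "shock levels not balanced within recipient '", rec, "'"))
  }
  report
}

#' Write / read a schedule as CSV
#'
#' The exported CSV uses 1-based trial numbering (`trial` column); the
#' in-memory object keeps the 0-based `index`.
#'
#' @param schedule An `ep_schedule`.
#' @param path File path.
#' @return `write_schedule` returns `path` invisibly; `read_schedule`
#'   returns an `ep_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  out <- data.frame(trial = schedule$index + 1L,
                    schedule[c("recipient", "effort_level", "effort_pct",
                               "work_shocks", "rest_shocks")])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial", "recipient", "effort_level", "work_shocks", "rest_shocks")
  abort_if(!all(need %in% names(raw)),
           "schedule CSV must have columns: ", paste(need, collapse = ", "))
  out <- data.frame(
    index = raw$trial - 1L,
    recipient = raw$recipient,
    effort_level = as.integer(raw$effort_level),
    effort_pct = if ("effort_pct" %in% names(raw)) as.integer(raw$effort_pct)
                 else 30L + 10L * as.integer(raw$effort_level),
    work_shocks = as.integer(raw$work_shocks),
    rest_shocks = as.integer(raw$rest_shocks),
    penalty_shocks = PENALTY_SHOCKS,
    stringsAsFactors = FALSE)
  class(out) <- c("ep_schedule", "data.frame")
  out
}
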