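#' Trial-level session logs
#'
#' A session log is the package's central behavioral data structure: one row
#' per trial, concatenated across sessions for one subject (real or
#' synthetic). Columns are fixed:
#'
#' * `trial_index`: integer >= 0, strictly increasing across the whole log.
#' * `session_id`: integer >= 0, non-decreasing.
#' * `tone`: `"A"` or `"B"` (the high- and low-risk cues).
#' * `action`: `"pull"` or `"non_pull"`.
#' * `reward`: 0/1, water delivered.
#' * `punishment`: 0/1, the *physical* punishment event (air-puff). In the
#'   omission task this column is always 0; the model's punishment indicator
#'   (pull without water) is derived, not stored
#'   (see [derivePunishmentIndicator()]).
#' * `early_pull`: 0/1, lever pulled before the go cue. Early-pull trials are
#'   excluded from all modelling.
#'
#' A trial without a pull can deliver neither water nor an air-puff, so
#' `action == "non_pull"` forces `reward == 0` and `punishment == 0`.
#'
#' @param trials data.frame with the columns above.
#' @param task_label `"air_puff"` or `"omission"`.
#' @return An object of class `session_log`: the validated data.frame with a
#'   `task_label` attribute.
#' @examples
#' log <- sessionLog(data.frame(
#'   trial_index = 0:2, session_id = 0L, tone = c("A", "B", "B"),
#'   action = c("non_pull", "pull", "pull"), reward = c(0L, 1L, 1L),
#'   punishment = 0L, early_pull = 0L), task_label = "omission")
#' nTrials(log)
#' @export
sessionLog <- function(trials, task_label = c("air_puff", "omission")) {
  task_label <- match.arg(task_label)
  trials <- as.data.frame(trials)
  missing_cols <- setdiff(log_columns(), names(trials))
  if (length(missing_cols)) {
    stop("session log is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  trials <- trials[log_columns()]
  trials$trial_index <- as.integer(trials$trial_index)
  trials$session_id <- as.integer(trials$session_id)
  trials$tone <- as.character(trials$tone)
  trials$action <- as.character(trials$action)
  trials$reward <- as.integer(trials$reward)
  trials$punishment <- as.integer(trials$punishment)
  trials$early_pull <- as.integer(trials$early_pull)
  rownames(trials) <- NULL
  validate_session_log(trials)
  structure(trials, task_label = task_label,
            class = c("session_log", "data.frame"))
}

log_columns <- function() {
  c("trial_index", "session_id", "tone", "action", "reward", "punishment",
    "early_pull")
}

validate_session_log <- function(trials) {
  n <- nrow(trials)
  if (n == 0L) return(invisible(TRUE))
  if (anyNA(trials)) stop("session log contains missing values")
  if (!all(trials$tone %in% c("A", "B"))) {
    stop("tone must be 'A' or 'B'")
  }
  if (!all(trials$action %in% c("pull", "non_pull"))) {
    stop("action must be 'pull' or 'non_pull'")
  }
  if (!all(trials$reward %in% 0:1) || !all(trials$punishment %in% 0:1) ||
      !all(trials$early_pull %in% 0:1)) {
    stop("reward, punishment and early_pull must be 0/1")
  }
  bad <- trials$action == "non_pull" & (trials$reward == 1L | trials$punishment == 1L)
  if (any(bad)) {
    stop("invariant violation at trial_index ",
         trials$trial_index[which(bad)[1L]],
         ": a non-pull trial cannot deliver reward or punishment")
  }
  if (n > 1L) {
    if (any(diff(trials$trial_index) <= 0L)) {
      stop("trial_index must be strictly increasing")
    }
    if (any(diff(trials$session_id) < 0L)) {
      stop("session_id must be non-decreasing")
    }
  }
  invisible(TRUE)
}

#' @rdname sessionLog
#' @param log A `session_log`.
#' @export
taskLabel <- function(log) attr(log, "task_label")

#' @rdname sessionLog
#' @export
nTrials <- function(log) nrow(log)

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> %d trials, %d session(s), task '%s'\n",
              nrow(x), length(unique(x$session_id)), taskLabel(x)))
  if (nrow(x)) print(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more trials\n")
  invisible(x)
}

# Subsetting keeps the class and task label so filtered logs stay logs.
#' @export
`[.session_log` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(log_columns() %in% names(out))) {
    rownames(out) <- NULL
    structure(out, task_label = attr(x, "task_label"),
              class = c("session_log", "data.frame"))
  } else out
}

#' Read and write trial logs
#'
#' Trial logs interchange as UTF-8 CSV with a header row naming the exact
#' `session_log` columns (booleans as 0/1), or as a JSON mirror with fields
#' `task_label` and `trials`. Reading validates every invariant; a malformed
#' row fails with its line number.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @param task_label Task the log comes from (CSV carries no task field).
#' @return `readTrials()` returns a [sessionLog()]; `writeTrials()` returns
#'   `path` invisibly.
#' @export
readTrials <- function(path, format = c("auto", "csv", "json"),
                       task_label = c("air_puff", "omission")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.null(obj$task_label)) task_label <- obj$task_label
    trials <- as.data.frame(obj$trials)
    if (!nrow(trials)) trials <- empty_trials()
    return(sessionLog(trials, task_label = match.arg(task_label,
                                                     c("air_puff", "omission"))))
  }
  task_label <- match.arg(task_label)
  trials <- read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(trials) && !length(setdiff(log_columns(), names(trials)))) {
    trials <- empty_trials()
  }
  check_parsed_rows(trials, path)
  sessionLog(trials, task_label = task_label)
}

# Per-row numeric checks reported with the file line (header is line 1).
check_parsed_rows <- function(trials, path) {
  for (col in c("trial_index", "session_id", "reward", "punishment", "early_pull")) {
    if (!col %in% names(trials)) next
    v <- suppressWarnings(as.numeric(trials[[col]]))
    bad <- which(is.na(v) | v != floor(v))
    if (length(bad)) {
      stop(sprintf("parse error in %s line %d: column '%s' is not an integer",
                   path, bad[1L] + 1L, col))
    }
  }
  invisible(TRUE)
}

empty_trials <- function() {
  data.frame(trial_index = integer(), session_id = integer(),
             tone = character(), action = character(), reward = integer(),
             punishment = integer(), early_pull = integer(),
             stringsAsFactors = FALSE)
}

#' @rdname readTrials
#' @param log A [sessionLog()].
#' @export
writeTrials <- function(log, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    jsonlite::write_json(
      list(task_label = taskLabel(log), trials = as.data.frame(log)),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(as.data.frame(log), path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Behavioral preprocessing
#'
#' `excludeEarlyPulls()` drops trials in which the lever was pulled before the
#' go cue; these trials enter neither the behavioral summaries nor the
#' modelling. `truncateAtRewardFraction()` implements the within-session
#' motivation guard: each session is kept only from its first trial to the
#' last trial before the cumulative rewarded-trial count reaches
#' `ceiling(fraction * planned_rewards)`; if a session never reaches the
#' threshold it is kept whole.
#'
#' @param log A [sessionLog()].
#' @param planned_rewards The session's programmed total reward count (a
#'   rig-side configuration value; it cannot be inferred from the log).
#' @param fraction Fraction of the planned rewards at which to cut, in (0, 1].
#' @return A filtered [sessionLog()].
#' @export
excludeEarlyPulls <- function(log) {
  log[log$early_pull == 0L, ]
}

#' @rdname excludeEarlyPulls
#' @export
truncateAtRewardFraction <- function(log, planned_rewards, fraction = 0.6) {
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0 ||
      fraction > 1) {
    stop("fraction must be in (0, 1]")
  }
  if (!is.numeric(planned_rewards) || planned_rewards <= 0) {
    stop("planned_rewards must be a positive integer")
  }
  threshold <- ceiling(fraction * planned_rewards)
  keep <- unlist(lapply(split(seq_len(nrow(log)), log$session_id), function(idx) {
    cum <- cumsum(log$reward[idx])
    idx[cum < threshold]
  }), use.names = FALSE)
  log[sort(keep), ]
}

#' Behavioral summaries
#'
#' `leverPullRate()` is the number of pull trials divided by the number of
#' trials of the requested tone, after early-pull exclusion.
#' `movingAverageChoice()` returns the `window`-trial moving average of the
#' 0/1 pull choice for one tone's trial sequence; the first `window - 1`
#' positions average over the available prefix so the output aligns 1:1 with
#' trials. `thresholdSessionsMet()` applies the learning criterion: tone-A
#' pull rate strictly below 0.5 and tone-B strictly above 0.5 in two
#' consecutive sessions.
#'
#' @param log A [sessionLog()].
#' @param tone `"A"` or `"B"`.
#' @return `leverPullRate()`: a proportion in \[0, 1\].
#' @export
leverPullRate <- function(log, tone = c("A", "B")) {
  tone <- match.arg(tone)
  log <- excludeEarlyPulls(log)
  sel <- log$tone == tone
  if (!any(sel)) stop("no tone-", tone, " trials: lever-pull rate undefined")
  mean(log$action[sel] == "pull")
}

#' @rdname leverPullRate
#' @param window Moving-average window length (trials), >= 1.
#' @export
movingAverageChoice <- function(log, tone = c("A", "B"), window = 10L) {
  tone <- match.arg(tone)
  log <- excludeEarlyPulls(log)
  x <- as.integer(log$action[log$tone == tone] == "pull")
  movingAverage(x, window)
}

#' @rdname leverPullRate
#' @param x Numeric vector (typically 0/1 choices).
#' @export
movingAverage <- function(x, window = 10L) {
  if (!is.numeric(window) || length(window) != 1L || window < 1) {
    stop("window must be a positive integer")
  }
  window <- as.integer(window)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  cs <- cumsum(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - window + 1L)
    out[i] <- (cs[i] - if (lo > 1L) cs[lo - 1L] else 0) / (i - lo + 1L)
  }
  out
}

#' @rdname leverPullRate
#' @param per_session_rates A two-column matrix or data.frame of per-session
#'   (tone A, tone B) lever-pull rates, in session order.
#' @return `thresholdSessionsMet()`: a list with `met` (logical) and `index`
#'   (1-based index of the second qualifying session, or `NA`).
#' @export
thresholdSessionsMet <- function(per_session_rates) {
  rates <- as.matrix(per_session_rates)
  if (nrow(rates) < 1L || ncol(rates) != 2L) {
    stop("per_session_rates must have at least one row and two columns")
  }
  ok <- rates[, 1L] < 0.5 & rates[, 2L] > 0.5
  if (length(ok) >= 2L) {
    both <- which(ok[-1L] & ok[-length(ok)])
    if (length(both)) {
      return(list(met = TRUE, index = both[1L] + 1L))
    }
  }
  list(met = FALSE, index = NA_integer_)
}
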