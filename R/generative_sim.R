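#' Generative (posterior-predictive) simulation of choice behavior
#'
#' Replays the subject's actual tone order and, per replicate, draws each
#' trial's action from the model's current pull probability. Outcomes are
#' coupled to the real session: when the simulated and actual actions are
#' both pulls, the recorded reward and punishment indicators are replayed;
#' when the simulation pulls but the animal did not, the outcome is drawn
#' from the task's programmed probabilities; a simulated non-pull yields no
#' outcome. Values then update exactly as during fitting.
#'
#' Each replicate's binary choice sequence is scored against the actual
#' binary choices by RMSE, and the per-replicate RMSEs are averaged; the
#' per-trial mean simulated choice across replicates is also returned.
#'
#' @param log A [sessionLog()] (early pulls excluded) supplying the tone
#'   order, actual actions and actual outcomes.
#' @param cfg The [taskConfig()] the session was run under; its `task_label`
#'   must match the log's.
#' @param params An [rlParams()].
#' @param spec Optional [modelSpec()] for parameter/spec consistency checks.
#' @param initial_state Initial [qState()].
#' @param n_reps Number of simulation replicates (study procedure: 1,000).
#' @param seed Integer seed; the simulation is deterministic given it.
#' @param keep_reps If `TRUE`, also return the per-replicate 0/1 choice
#'   matrix (`n_reps` x trials).
#' @param pred_mode `"binary"` (default): RMSE computed per replicate on
#'   binary choices, then averaged across replicates. `"mean"`: a single
#'   RMSE of the replicate-averaged choice probability against the binary
#'   actual choices.
#' @return An object of class `sim_result`: list with `mean_choice` (per
#'   trial), `rmse_per_rep`, `rmse` (scalar summary per `pred_mode`),
#'   `n_reps`, `seed`, and optionally `reps`.
#' @export
simulateChoices <- function(log, cfg, params, spec = NULL,
                            initial_state = qState(), n_reps = 1000L,
                            seed = NULL, keep_reps = FALSE,
                            pred_mode = c("binary", "mean")) {
  pred_mode <- match.arg(pred_mode)
  if (!is.null(spec)) checkParamsMatchSpec(params, spec)
  if (!identical(cfg$task_label, taskLabel(log))) {
    stop("task_config label '", cfg$task_label,
         "' does not match the log's task '", taskLabel(log), "'")
  }
  if (nrow(log) == 0L) stop("cannot simulate an empty log")
  enc <- encode_log(log)
  res <- with_seed(seed,
    cpp_simulate(enc$tone, enc$action, enc$reward, enc$punish,
                 par_vec(params),
                 as.numeric(initial_state$q_pull),
                 as.numeric(initial_state$q_non_pull),
                 as.numeric(cfg$reward_prob), as.numeric(cfg$punish_prob),
                 as.integer(cfg$task_label == "omission"),
                 as.integer(n_reps), as.integer(keep_reps)))
  summary_rmse <- if (pred_mode == "binary") {
    mean(res$rmse_rep)
  } else {
    rmse(enc$action, res$mean_choice)
  }
  structure(list(mean_choice = res$mean_choice, rmse_per_rep = res$rmse_rep,
                 rmse = summary_rmse, n_reps = as.integer(n_reps),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 pred_mode = pred_mode,
                 reps = if (keep_reps) res$reps else NULL),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d trials x %d reps: mean RMSE = %.4f (%s mode)\n",
              length(x$mean_choice), x$n_reps, x$rmse, x$pred_mode))
  invisible(x)
}

#' Root-mean-square error between choice sequences
#'
#' `sqrt(mean((predicted - actual)^2))` over all trials of both tones.
#'
#' @param actual,predicted Equal-length numeric vectors (typically 0/1).
#' @return Non-negative scalar.
#' @examples
#' rmse(c(1, 0, 1, 1), c(1, 1, 1, 0))  # sqrt(2/4)
#' @export
rmse <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("actual and predicted must have the same length")
  }
  if (length(actual) == 0L) stop("rmse needs at least one trial")
  sqrt(mean((predicted - actual)^2))
}

# Bin counts used for subject-averaged display, proportional to the tone
# presentation probabilities of each task.
bin_counts <- function(task_label, tone) {
  counts <- list(air_puff = c(A = 10L, B = 40L),
                 omission = c(A = 20L, B = 30L))
  counts[[task_label]][[tone]]
}

#' Bin-averaged choice summaries
#'
#' Averages a per-trial sequence (actual or simulated choice for one tone)
#' into a fixed number of near-equal bins, enabling averaging across
#' subjects with different trial counts. Bin counts follow the tasks' tone
#' presentation probabilities: air-puff task, 10 bins for tone A and 40 for
#' tone B; omission task, 20 for tone A and 30 for tone B. When the trial
#' count is not a multiple of the bin count, leading bins take one extra
#' trial.
#'
#' @param values Per-trial numeric vector for one tone.
#' @param task_label `"air_puff"` or `"omission"`.
#' @param tone `"A"` or `"B"`.
#' @param n_bins Override the task-derived bin count.
#' @return Numeric vector of bin means.
#' @export
binAverageChoices <- function(values, task_label = c("air_puff", "omission"),
                              tone = c("A", "B"), n_bins = NULL) {
  task_label <- match.arg(task_label)
  tone <- match.arg(tone)
  if (is.null(n_bins)) n_bins <- bin_counts(task_label, tone)
  n <- length(values)
  if (n < n_bins) {
    stop("cannot form ", n_bins, " bins from ", n, " trials")
  }
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  idx <- rep(seq_len(n_bins), times = sizes)
  as.numeric(tapply(values, idx, mean))
}
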