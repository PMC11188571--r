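#' Task environment configuration
#'
#' The two-tone lever-pull tasks are defined by four constants: the tone-A
#' presentation probability and, per tone, the probability that a pull is
#' rewarded with water and the probability that it triggers a physical
#' punishment (air-puff). Two presets reproduce the study designs:
#'
#' * `air_puff`: tone A presented 20% of trials; a pull is rewarded with
#'   probability 1 under either tone; an air-puff follows a pull with
#'   probability 0.9 (tone A) or 0.1 (tone B).
#' * `omission`: tone A presented 40% of trials; a pull is rewarded with
#'   probability 0.1 (tone A) or 0.9 (tone B); no air-puff is ever delivered.
#'
#' A trial without a pull delivers neither water nor an air-puff.
#'
#' @param task_label `"air_puff"` or `"omission"`.
#' @param p_toneA Probability of presenting tone A on a trial.
#' @param reward_prob Named numeric `c(A = , B = )`: P(water | pull, tone).
#' @param punish_prob Named numeric `c(A = , B = )`: P(air-puff | pull, tone).
#' @return An object of class `task_config`.
#' @examples
#' cfg <- taskPreset("air_puff")
#' cfg$punish_prob
#' @export
taskConfig <- function(task_label = c("air_puff", "omission"), p_toneA,
                       reward_prob, punish_prob) {
  task_label <- match.arg(task_label)
  stopifnot(length(p_toneA) == 1L, p_toneA >= 0, p_toneA <= 1)
  reward_prob <- unlist(reward_prob)[c("A", "B")]
  punish_prob <- unlist(punish_prob)[c("A", "B")]
  if (anyNA(reward_prob) || anyNA(punish_prob)) {
    stop("reward_prob and punish_prob must be named with tones 'A' and 'B'")
  }
  if (any(reward_prob < 0 | reward_prob > 1) ||
      any(punish_prob < 0 | punish_prob > 1)) {
    stop("all outcome probabilities must lie in [0, 1]")
  }
  if (task_label == "omission" && any(punish_prob > 0)) {
    stop("the omission task never delivers a physical punishment")
  }
  structure(list(task_label = task_label, p_toneA = as.numeric(p_toneA),
                 reward_prob = reward_prob, punish_prob = punish_prob),
            class = "task_config")
}

#' @rdname taskConfig
#' @export
taskPreset <- function(task_label = c("air_puff", "omission")) {
  task_label <- match.arg(task_label)
  if (task_label == "air_puff") {
    taskConfig("air_puff", p_toneA = 0.2,
               reward_prob = c(A = 1.0, B = 1.0),
               punish_prob = c(A = 0.9, B = 0.1))
  } else {
    taskConfig("omission", p_toneA = 0.4,
               reward_prob = c(A = 0.1, B = 0.9),
               punish_prob = c(A = 0.0, B = 0.0))
  }
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf("<task_config> %s: P(tone A) = %.2f\n", x$task_label, x$p_toneA))
  cat(sprintf("  reward | pull: A %.2f, B %.2f\n",
              x$reward_prob[["A"]], x$reward_prob[["B"]]))
  cat(sprintf("  punish | pull: A %.2f, B %.2f\n",
              x$punish_prob[["A"]], x$punish_prob[["B"]]))
  invisible(x)
}

#' Sample from a task environment
#'
#' `drawTone()` draws tone identities i.i.d. with `P(A) = p_toneA`.
#' `generateSessionSchedule()` is its fixed-length, seedable form: the tone
#' schedules it returns are reused verbatim across simulations, mirroring how
#' generative simulations replay the subject's actual tone order.
#' `resolveOutcome()` resolves one trial's physical outcome given the action:
#' a non-pull yields neither event; a pull draws reward and punishment
#' independently from the tone's probabilities.
#'
#' @param cfg A [taskConfig()].
#' @param n Number of tones to draw.
#' @return `drawTone()`: character vector of `"A"`/`"B"`.
#' @export
drawTone <- function(cfg, n = 1L) {
  ifelse(runif(n) < cfg$p_toneA, "A", "B")
}

#' @rdname drawTone
#' @param n_trials Schedule length, >= 1.
#' @param seed Optional integer seed; the schedule is a pure function of it.
#' @export
generateSessionSchedule <- function(cfg, n_trials, seed = NULL) {
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1) {
    stop("n_trials must be a positive integer")
  }
  with_seed(seed, drawTone(cfg, as.integer(n_trials)))
}

#' @rdname drawTone
#' @param tone `"A"` or `"B"`.
#' @param action `"pull"` or `"non_pull"`.
#' @return `resolveOutcome()`: list with binary `reward` and `punishment`.
#' @export
resolveOutcome <- function(cfg, tone, action = c("pull", "non_pull")) {
  action <- match.arg(action)
  tone <- match.arg(tone, c("A", "B"))
  if (action == "non_pull") {
    return(list(reward = 0L, punishment = 0L))
  }
  list(reward = as.integer(runif(1L) < cfg$reward_prob[[tone]]),
       punishment = as.integer(runif(1L) < cfg$punish_prob[[tone]]))
}
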