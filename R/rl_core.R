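#' The forgetting Q-learning model family
#'
#' All model variants share the same update skeleton over four latent action
#' values, one (pull, non-pull) pair per tone. On a pull of tone x with
#' reward indicator r and punishment indicator p:
#' \deqn{Q_{x,pull} \leftarrow Q_{x,pull} +
#'       \alpha_l(\kappa_r r - \kappa_p p - Q_{x,pull})}
#' \deqn{Q_{x,non} \leftarrow (1-\alpha_f) Q_{x,non}}
#' and on a non-pull:
#' \deqn{Q_{x,pull} \leftarrow (1-\alpha_f) Q_{x,pull}}
#' \deqn{Q_{x,non} \leftarrow Q_{x,non} + \alpha_l(\psi - Q_{x,non})}
#' The other tone's pair is untouched. The pull probability is the sigmoid of
#' \eqn{Q_{x,pull} - Q_{x,non}} (no temperature parameter).
#'
#' `kappa_r` (reward value) and `alpha_l` (learning rate) are present in
#' every variant; the punishment weight `kappa_p`, the covert non-pull reward
#' `psi` (saving term) and the forgetting rate `alpha_f` are toggled on or
#' off, giving exactly seven variants: `simple`, `punishment`, `saving`,
#' `forgetting`, `P-F`, `S-F`, `P-S-F`. A disabled parameter is fixed at 0,
#' which collapses the update rules to the reduced model.
#'
#' @param name One of `simple`, `punishment`, `saving`, `forgetting`, `P-F`,
#'   `S-F`, `P-S-F`.
#' @return `modelSpec()`: an object of class `model_spec` with logical flags
#'   `use_punishment`, `use_saving`, `use_forgetting`, the `name`, and `K`,
#'   the free-parameter count (2 + number of enabled flags).
#' @examples
#' modelSpec("P-S-F")$K   # 5
#' modelSpec("S-F")$K     # 4
#' @export
modelSpec <- function(name = c("simple", "punishment", "saving", "forgetting",
                               "P-F", "S-F", "P-S-F")) {
  # exact names only: no partial matching of variant identifiers
  if (length(name) > 1L) name <- name[1L]
  if (!is.character(name) || !name %in% modelNames()) {
    stop("unknown model name '", name, "'; the seven variants are: ",
         paste(modelNames(), collapse = ", "))
  }
  flags <- switch(name,
    "simple"     = c(FALSE, FALSE, FALSE),
    "punishment" = c(TRUE,  FALSE, FALSE),
    "saving"     = c(FALSE, TRUE,  FALSE),
    "forgetting" = c(FALSE, FALSE, TRUE),
    "P-F"        = c(TRUE,  FALSE, TRUE),
    "S-F"        = c(FALSE, TRUE,  TRUE),
    "P-S-F"      = c(TRUE,  TRUE,  TRUE))
  structure(list(name = name, use_punishment = flags[1L],
                 use_saving = flags[2L], use_forgetting = flags[3L],
                 K = 2L + sum(flags)),
            class = "model_spec")
}

#' @rdname modelSpec
#' @export
modelNames <- function() {
  c("simple", "punishment", "saving", "forgetting", "P-F", "S-F", "P-S-F")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (K = %d free parameters)\n", x$name, x$K))
  cat(sprintf("  punishment kappa_p: %s, saving psi: %s, forgetting alpha_f: %s\n",
              x$use_punishment, x$use_saving, x$use_forgetting))
  invisible(x)
}

#' @rdname modelSpec
#' @param alpha_l Learning rate, in \[0, 1\].
#' @param alpha_f Forgetting rate, in \[0, 1\] (0 disables forgetting).
#' @param kappa_r Reward value (subjective goodness of water), >= 0.
#' @param kappa_p Punishment weight (aversion strength), >= 0.
#' @param psi Covert reward for withholding the pull (saving term), >= 0.
#' @return `rlParams()`: a named numeric vector of class `rl_params` in the
#'   canonical order `alpha_l, alpha_f, kappa_r, kappa_p, psi`.
#' @export
rlParams <- function(alpha_l, kappa_r, alpha_f = 0, kappa_p = 0, psi = 0) {
  p <- c(alpha_l = as.numeric(alpha_l), alpha_f = as.numeric(alpha_f),
         kappa_r = as.numeric(kappa_r), kappa_p = as.numeric(kappa_p),
         psi = as.numeric(psi))
  if (anyNA(p)) stop("parameters must be numeric")
  if (p[["alpha_l"]] < 0 || p[["alpha_l"]] > 1 ||
      p[["alpha_f"]] < 0 || p[["alpha_f"]] > 1) {
    stop("alpha_l and alpha_f must lie in [0, 1]")
  }
  if (p[["kappa_r"]] < 0 || p[["kappa_p"]] < 0 || p[["psi"]] < 0) {
    stop("kappa_r, kappa_p and psi must be non-negative")
  }
  structure(p, class = "rl_params")
}

#' @export
print.rl_params <- function(x, ...) {
  cat("<rl_params>", paste(sprintf("%s = %.4g", names(x), unclass(x)),
                           collapse = ", "), "\n")
  invisible(x)
}

paramNames <- function() c("alpha_l", "alpha_f", "kappa_r", "kappa_p", "psi")

# Parameters free under a model spec, in canonical order.
freeParamNames <- function(spec) {
  nm <- c("alpha_l",
          if (spec$use_forgetting) "alpha_f",
          "kappa_r",
          if (spec$use_punishment) "kappa_p",
          if (spec$use_saving) "psi")
  intersect(paramNames(), nm)
}

# Check that disabled parameters are 0 for the given spec.
checkParamsMatchSpec <- function(params, spec) {
  fixed <- setdiff(paramNames(), freeParamNames(spec))
  off <- fixed[unclass(params)[fixed] != 0]
  if (length(off)) {
    stop("parameters disabled under model '", spec$name,
         "' must be 0: ", paste(off, collapse = ", "))
  }
  invisible(TRUE)
}

#' Latent action values
#'
#' A `q_state` holds the four latent values: Q(pull) and Q(non-pull) for each
#' tone. The all-zero state is the value-neutral start used for fitting.
#'
#' @param q_pull,q_non_pull Named numeric `c(A = , B = )`.
#' @return An object of class `q_state`.
#' @export
qState <- function(q_pull = c(A = 0, B = 0), q_non_pull = c(A = 0, B = 0)) {
  q_pull <- unlist(q_pull)[c("A", "B")]
  q_non_pull <- unlist(q_non_pull)[c("A", "B")]
  if (anyNA(q_pull) || anyNA(q_non_pull) ||
      any(!is.finite(c(q_pull, q_non_pull)))) {
    stop("q_state values must be finite and named with tones 'A' and 'B'")
  }
  structure(list(q_pull = q_pull, q_non_pull = q_non_pull), class = "q_state")
}

#' @export
print.q_state <- function(x, ...) {
  cat(sprintf("<q_state> pull: A %.4g, B %.4g | non-pull: A %.4g, B %.4g\n",
              x$q_pull[["A"]], x$q_pull[["B"]],
              x$q_non_pull[["A"]], x$q_non_pull[["B"]]))
  invisible(x)
}

#' Model punishment indicator
#'
#' The environment only emits physical events (water, air-puff); the model's
#' punishment indicator p_x(t) is task-dependent. In the air-puff task it is
#' the air-puff itself (on pull trials). In the omission task it is 1 exactly
#' when the lever was pulled but no water was delivered — reward omission is
#' treated as the punishing event. A non-pull trial always has p = 0.
#'
#' @param task_label `"air_puff"` or `"omission"`.
#' @param action `"pull"` or `"non_pull"` (vectorised).
#' @param reward Binary reward indicator (vectorised).
#' @param physical_punishment Binary air-puff indicator (vectorised).
#' @return Integer 0/1 vector.
#' @export
derivePunishmentIndicator <- function(task_label = c("air_puff", "omission"),
                                      action, reward, physical_punishment) {
  task_label <- match.arg(task_label)
  pull <- action == "pull"
  if (task_label == "air_puff") {
    as.integer(pull & physical_punishment == 1L)
  } else {
    as.integer(pull & reward == 0L)
  }
}

#' Single-trial model primitives
#'
#' `updateQ()` applies one trial's value update to a [qState()];
#' `choiceProbability()` is the sigmoidal pull probability for the presented
#' tone; `steadyStateQ()` returns the fixed point of the expected-value
#' updates when the outcome indicators are held at constant expectations
#' `R_x = reward_prob[x]`, `P_x = punish_prob[x]`:
#' `Q(pull) = kappa_r R_x - kappa_p P_x` and `Q(non-pull) = psi`. These are
#' the steady-state initial values used by the perturbation analysis in the
#' air-puff task.
#'
#' @param state A [qState()].
#' @param tone `"A"` or `"B"`.
#' @param action `"pull"` or `"non_pull"`.
#' @param r,p Binary reward and (derived) punishment indicators.
#' @param params An [rlParams()].
#' @return `updateQ()`: the updated [qState()].
#' @export
updateQ <- function(state, tone, action = c("pull", "non_pull"), r, p, params) {
  tone <- match.arg(tone, c("A", "B"))
  action <- match.arg(action)
  al <- params[["alpha_l"]]; af <- params[["alpha_f"]]
  kr <- params[["kappa_r"]]; kp <- params[["kappa_p"]]; psi <- params[["psi"]]
  if (action == "pull") {
    state$q_pull[[tone]] <- state$q_pull[[tone]] +
      al * (kr * r - kp * p - state$q_pull[[tone]])
    state$q_non_pull[[tone]] <- (1 - af) * state$q_non_pull[[tone]]
  } else {
    state$q_pull[[tone]] <- (1 - af) * state$q_pull[[tone]]
    state$q_non_pull[[tone]] <- state$q_non_pull[[tone]] +
      al * (psi - state$q_non_pull[[tone]])
  }
  state
}

#' @rdname updateQ
#' @export
choiceProbability <- function(state, tone) {
  tone <- match.arg(tone, c("A", "B"))
  stats::plogis(state$q_pull[[tone]] - state$q_non_pull[[tone]])
}

#' @rdname updateQ
#' @param cfg A [taskConfig()] providing the expected outcome probabilities.
#' @export
steadyStateQ <- function(params, cfg) {
  qState(q_pull = c(A = params[["kappa_r"]] * cfg$reward_prob[["A"]] -
                        params[["kappa_p"]] * cfg$punish_prob[["A"]],
                    B = params[["kappa_r"]] * cfg$reward_prob[["B"]] -
                        params[["kappa_p"]] * cfg$punish_prob[["B"]]),
         q_non_pull = c(A = params[["psi"]], B = params[["psi"]]))
}

# --- internal: log <-> integer encoding for the C++ kernels ----------------

# Returns list(tone, action, reward, punish) as integer vectors with the
# model punishment indicator already derived; early pulls must be excluded
# upstream of modelling, enforced here.
encode_log <- function(log) {
  if (any(log$early_pull == 1L)) {
    stop("log contains early-pull trials; apply excludeEarlyPulls() first")
  }
  list(tone = as.integer(log$tone == "B"),
       action = as.integer(log$action == "pull"),
       reward = log$reward,
       punish = derivePunishmentIndicator(taskLabel(log), log$action,
                                          log$reward, log$punishment))
}

par_vec <- function(params) as.numeric(unclass(params)[paramNames()])
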