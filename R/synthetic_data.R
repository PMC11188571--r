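#' Synthetic ground-truth agents
#'
#' An `agent_spec` bundles a model variant, a ground-truth parameter set
#' respecting it (disabled parameters 0), and an initial value state; a
#' `scenario_config` describes the sessions to simulate. Together they drive
#' [generateAgentLog()], which produces behavioral logs with known latent
#' trajectories for recovery testing.
#'
#' @param spec A [modelSpec()] (or its name).
#' @param params An [rlParams()] consistent with `spec`.
#' @param initial_state Initial [qState()].
#' @param label Free-text label carried through to outputs.
#' @return `agentSpec()`: an object of class `agent_spec`.
#' @export
agentSpec <- function(spec, params, initial_state = qState(), label = "") {
  if (!inherits(spec, "model_spec")) spec <- modelSpec(spec)
  checkParamsMatchSpec(params, spec)
  structure(list(spec = spec, params = params, initial_state = initial_state,
                 label = label),
            class = "agent_spec")
}

#' @rdname agentSpec
#' @param cfg A [taskConfig()].
#' @param n_sessions,trials_per_session Session structure, both >= 1.
#' @param seed Integer seed governing tones, actions and outcomes.
#' @param perturbed_params Optional [rlParams()] replacing the agent's
#'   parameters from `perturb_from_session` (1-based) onward, emulating an
#'   acute manipulation such as regional inactivation.
#' @param perturb_from_session First session index the perturbation applies
#'   to.
#' @export
scenarioConfig <- function(cfg, n_sessions = 1L, trials_per_session, seed = 1L,
                           perturbed_params = NULL,
                           perturb_from_session = NULL) {
  if (n_sessions < 1L || trials_per_session < 1L) {
    stop("n_sessions and trials_per_session must be >= 1")
  }
  if (!is.null(perturbed_params) && is.null(perturb_from_session)) {
    perturb_from_session <- n_sessions
  }
  structure(list(cfg = cfg, n_sessions = as.integer(n_sessions),
                 trials_per_session = as.integer(trials_per_session),
                 seed = as.integer(seed), perturbed_params = perturbed_params,
                 perturb_from_session = perturb_from_session),
            class = "scenario_config")
}

#' Reference ground-truth parameter regimes
#'
#' Documented constants used as default generating parameters in recovery
#' tests, one per model variant. Each variant is paired with the task in
#' which its parameters are statistically identifiable: variants carrying
#' the punishment weight live in the air-puff task, where the per-tone
#' air-puff probabilities (0.9 vs 0.1) separate `kappa_p` from the other
#' value offsets, while the remaining variants live in the omission task,
#' where stochastic rewards keep the values fluctuating and informative
#' about the learning rate. (In the omission task the punishment indicator
#' is the complement of reward, so `kappa_p` shifts both tones' pull values
#' by the same constant and is nearly collinear with `psi`; punishment
#' variants are therefore not probed there.) Within each task the
#' magnitudes follow the qualitative regime of trained animals — reward
#' value of a few units, a punishment weight large enough to suppress
#' pulling under the high-risk tone, a saving term around one unit — sized
#' so that maximum-likelihood recovery from a five-thousand-trial log has
#' useful precision for every free parameter.
#'
#' @param model Model variant name.
#' @return List with `params` ([rlParams()]) and `task` (preset label).
#' @export
referenceAgent <- function(model = modelNames()) {
  model <- match.arg(model)
  switch(model,
    "simple"     = list(params = rlParams(alpha_l = 0.2, kappa_r = 3),
                        task = "omission"),
    "punishment" = list(params = rlParams(alpha_l = 0.3, kappa_r = 2,
                                          kappa_p = 5),
                        task = "air_puff"),
    "saving"     = list(params = rlParams(alpha_l = 0.2, kappa_r = 2, psi = 1),
                        task = "omission"),
    "forgetting" = list(params = rlParams(alpha_l = 0.2, kappa_r = 3,
                                          alpha_f = 0.1),
                        task = "omission"),
    "P-F"        = list(params = rlParams(alpha_l = 0.3, kappa_r = 2,
                                          alpha_f = 0.1, kappa_p = 4),
                        task = "air_puff"),
    "S-F"        = list(params = rlParams(alpha_l = 0.2, kappa_r = 4,
                                          alpha_f = 0.1, psi = 1.5),
                        task = "omission"),
    "P-S-F"      = list(params = rlParams(alpha_l = 0.3, kappa_r = 3,
                                          alpha_f = 0.1, kappa_p = 4,
                                          psi = 1.5),
                        task = "air_puff"))
}

#' Simulate a ground-truth agent
#'
#' Walks the agent forward through the scenario: per trial, a tone is drawn
#' from the task, the pull probability follows the sigmoidal choice rule,
#' the action is sampled, the physical outcome is resolved by the task, the
#' model punishment indicator is derived, and the values update. Latent
#' value and probability trajectories are returned alongside the log so
#' recovery tests can compare against ground truth. Q-values carry over
#' across session boundaries (sessions are concatenated, as in fitting).
#' Early pulls are never generated. Deterministic given the scenario seed.
#'
#' @param scenario A [scenarioConfig()].
#' @param agent An [agentSpec()].
#' @return List with `log` (a [sessionLog()] of physical events),
#'   `p_trajectory`, `q_trajectory` (matrix `qA_pull, qB_pull, qA_non,
#'   qB_non`), `punish_indicator` (the model's p_x(t)), and `agent`.
#' @export
generateAgentLog <- function(scenario, agent) {
  cfg <- scenario$cfg
  n_per <- scenario$trials_per_session
  n_sessions <- scenario$n_sessions
  switch_at <- if (is.null(scenario$perturbed_params)) NULL else
    scenario$perturb_from_session
  omission <- as.integer(cfg$task_label == "omission")

  tones_int <- integer(0)
  session_id <- integer(0)
  for (s in seq_len(n_sessions)) {
    sched <- generateSessionSchedule(cfg, n_per,
                                     seed = derive_seed(scenario$seed, s))
    tones_int <- c(tones_int, as.integer(sched == "B"))
    session_id <- c(session_id, rep.int(s - 1L, n_per))
  }

  run_chunk <- function(tones, params, q0p, q0n) {
    cpp_generate_agent(tones, par_vec(params), q0p, q0n,
                       as.numeric(cfg$reward_prob),
                       as.numeric(cfg$punish_prob), omission)
  }

  with_seed(derive_seed(scenario$seed, 0L), {
    q0p <- as.numeric(agent$initial_state$q_pull)
    q0n <- as.numeric(agent$initial_state$q_non_pull)
    if (is.null(switch_at) || switch_at > n_sessions) {
      res <- run_chunk(tones_int, agent$params, q0p, q0n)
    } else {
      n_pre <- (switch_at - 1L) * n_per
      if (n_pre > 0L) {
        pre <- run_chunk(tones_int[seq_len(n_pre)], agent$params, q0p, q0n)
        q_last <- pre$q[n_pre, ]
        post <- run_chunk(tones_int[-seq_len(n_pre)],
                          scenario$perturbed_params,
                          q_last[1:2], q_last[3:4])
        res <- Map(function(a, b) {
          if (is.matrix(a)) rbind(a, b) else c(a, b)
        }, pre, post)
      } else {
        res <- run_chunk(tones_int, scenario$perturbed_params, q0p, q0n)
      }
    }
    n <- length(tones_int)
    log <- sessionLog(data.frame(
      trial_index = 0:(n - 1L), session_id = session_id,
      tone = ifelse(tones_int == 1L, "B", "A"),
      action = ifelse(res$action == 1L, "pull", "non_pull"),
      reward = res$reward, punishment = res$punish_phys,
      early_pull = 0L), task_label = cfg$task_label)
    q_traj <- res$q
    colnames(q_traj) <- c("qA_pull", "qB_pull", "qA_non", "qB_non")
    list(log = log, p_trajectory = res$p_pull, q_trajectory = q_traj,
         punish_indicator = res$punish_ind, agent = agent)
  })
}

#' Matched baseline/perturbed session pair
#'
#' Generates two sessions sharing identical tone schedules (and identical
#' underlying random draws, so the pair differs only through the parameter
#' change): a baseline session with the agent's own parameters and a
#' perturbed session with `perturbed` substituted. This is the synthetic
#' stand-in for a vehicle-control session versus an inactivation session.
#'
#' @inheritParams generateAgentLog
#' @param perturbed [rlParams()] for the perturbed session; must respect the
#'   agent's model spec.
#' @return List with `baseline` and `perturbed`, each a [generateAgentLog()]
#'   result.
#' @export
generateInactivationPair <- function(scenario, agent, perturbed) {
  checkParamsMatchSpec(perturbed, agent$spec)
  baseline <- generateAgentLog(scenario, agent)
  agent_perturbed <- agentSpec(agent$spec, perturbed,
                               initial_state = agent$initial_state,
                               label = paste0(agent$label, " (perturbed)"))
  perturbed_run <- generateAgentLog(scenario, agent_perturbed)
  list(baseline = baseline, perturbed = perturbed_run)
}
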