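#' End-to-end reproducible pipeline
#'
#' Runs the whole analysis from a YAML configuration: synthesize a
#' ground-truth agent log, fit and compare model variants, score the best
#' model generatively, and (optionally) run the perturbation attribution on
#' a matched baseline/perturbed session pair. Every artifact is written as
#' JSON (tables additionally as CSV) together with a run manifest recording
#' the config snapshot, seeds, package version and output paths. All
#' randomness flows from the config seed, so re-running the same config
#' reproduces every numeric output exactly.
#'
#' Config keys (see `system.file("extdata", "demo_config.yaml", package =
#' "forgetq")` for a worked example): `task` (preset name), `agent` (model
#' plus parameter values), `scenario` (`n_sessions`, `trials_per_session`),
#' `models` (variants to compare), `fitting$n_restarts`,
#' `simulation$n_reps`, optional `perturbation` (`perturbed` parameter
#' overrides, `n_reps`, `mode`), and `seed`.
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest as a list.
#' @export
runPipeline <- function(config, out_dir) {
  cfg_list <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else config
  cfg_list <- validate_pipeline_config(cfg_list)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg_list$seed
  task_cfg <- taskPreset(cfg_list$task)

  agent <- agentSpec(modelSpec(cfg_list$agent$model),
                     config_params(cfg_list$agent),
                     label = "pipeline ground truth")
  scenario <- scenarioConfig(task_cfg,
                             n_sessions = cfg_list$scenario$n_sessions,
                             trials_per_session = cfg_list$scenario$trials_per_session,
                             seed = derive_seed(seed, 1L))
  truth <- generateAgentLog(scenario, agent)
  log <- truth$log
  paths <- list(trials = file.path(out_dir, "trials.csv"),
                ground_truth = file.path(out_dir, "ground_truth.json"),
                comparison_json = file.path(out_dir, "model_comparison.json"),
                comparison_csv = file.path(out_dir, "model_comparison.csv"),
                simulation = file.path(out_dir, "simulation.json"),
                manifest = file.path(out_dir, "manifest.json"))
  writeTrials(log, paths$trials)
  write_json_artifact(list(model = agent$spec$name,
                           params = as.list(unclass(agent$params))),
                      paths$ground_truth)

  comparison <- compareModels(log, n_restarts = cfg_list$fitting$n_restarts,
                              seed = derive_seed(seed, 2L),
                              models = cfg_list$models)
  write.csv(comparison$table, paths$comparison_csv, row.names = FALSE,
            quote = FALSE)
  write_json_artifact(list(
    best_by_aic = comparison$best_by_aic,
    best_by_bic = comparison$best_by_bic,
    models = lapply(comparison$fits, function(f) {
      list(params = as.list(unclass(f$params)),
           log_likelihood_max = f$log_likelihood_max, aic = f$aic,
           bic = f$bic, n_trials_fit = f$n_trials_fit)
    })), paths$comparison_json)

  best_fit <- comparison$fits[[comparison$best_by_aic]]
  sim <- simulateChoices(log, task_cfg, best_fit$params,
                         n_reps = cfg_list$simulation$n_reps,
                         seed = derive_seed(seed, 3L))
  write_json_artifact(list(model = comparison$best_by_aic, rmse = sim$rmse,
                           n_reps = sim$n_reps,
                           mean_choice = sim$mean_choice),
                      paths$simulation)

  perturb_summary <- NULL
  if (!is.null(cfg_list$perturbation)) {
    pcfg <- cfg_list$perturbation
    perturbed <- config_params(modifyList(cfg_list$agent, pcfg$perturbed))
    pair <- generateInactivationPair(scenario, agent, perturbed)
    post_log <- pair$perturbed$log
    pr <- identifyInjectionParameter(
      post_log, task_cfg, best_fit$params, best_fit$spec,
      initial_q_mode = pcfg$mode,
      initial_state = last_q_state(best_fit),
      n_reps = pcfg$n_reps, seed = derive_seed(seed, 4L))
    paths$perturbation <- file.path(out_dir, "perturbation.json")
    perturb_summary <- list(
      injection_related_parameter = pr$injection_related_parameter,
      baseline_rmse = pr$baseline_rmse,
      per_parameter = pr$per_parameter)
    write_json_artifact(perturb_summary, paths$perturbation)
  }

  manifest <- list(command = "runPipeline",
                   package_version = as.character(utils::packageVersion("forgetq")),
                   config = cfg_list, seed = seed,
                   outputs = unlist(paths, use.names = TRUE),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"))
  write_json_artifact(manifest, paths$manifest)
  invisible(manifest)
}

# Extract the last per-trial Q-state of a fit as the carryover initial state.
last_q_state <- function(fit) {
  q <- fit$q_trajectory[nrow(fit$q_trajectory), ]
  qState(q_pull = c(A = q[["qA_pull"]], B = q[["qB_pull"]]),
         q_non_pull = c(A = q[["qA_non"]], B = q[["qB_non"]]))
}

config_params <- function(agent_cfg) {
  keep <- intersect(names(agent_cfg), paramNames())
  vals <- agent_cfg[keep]
  do.call(rlParams, vals)
}

validate_pipeline_config <- function(cfg) {
  req <- function(ok, path, msg) {
    if (!ok) stop("config error at '", path, "': ", msg)
  }
  req(is.list(cfg), "", "config must be a mapping")
  req(!is.null(cfg$task), "task", "missing")
  req(cfg$task %in% c("air_puff", "omission"), "task",
      paste0("unknown task '", cfg$task, "'"))
  req(is.list(cfg$agent) && !is.null(cfg$agent$model), "agent.model", "missing")
  req(cfg$agent$model %in% modelNames(), "agent.model",
      paste0("unknown model '", cfg$agent$model, "'"))
  req(!is.null(cfg$scenario$trials_per_session), "scenario.trials_per_session",
      "missing")
  cfg$scenario$n_sessions <- cfg$scenario$n_sessions %||% 1L
  cfg$models <- cfg$models %||% modelNames()
  bad <- setdiff(cfg$models, modelNames())
  req(!length(bad), "models", paste0("unknown model '", bad[1L], "'"))
  cfg$fitting <- cfg$fitting %||% list()
  cfg$fitting$n_restarts <- cfg$fitting$n_restarts %||% 100L
  cfg$simulation <- cfg$simulation %||% list()
  cfg$simulation$n_reps <- cfg$simulation$n_reps %||% 1000L
  cfg$seed <- cfg$seed %||% 1L
  if (!is.null(cfg$perturbation)) {
    req(is.list(cfg$perturbation$perturbed), "perturbation.perturbed",
        "must map parameter names to values")
    bad <- setdiff(names(cfg$perturbation$perturbed), paramNames())
    req(!length(bad), "perturbation.perturbed",
        paste0("unknown parameter '", bad[1L], "'"))
    cfg$perturbation$n_reps <- cfg$perturbation$n_reps %||% 200L
    cfg$perturbation$mode <- cfg$perturbation$mode %||% "carryover"
    req(cfg$perturbation$mode %in% c("carryover", "steady_state"),
        "perturbation.mode", "must be 'carryover' or 'steady_state'")
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
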