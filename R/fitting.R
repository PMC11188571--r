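#' Negative log-likelihood of a choice sequence
#'
#' The likelihood of a trial is the model's pull probability if the lever was
#' pulled and its complement otherwise; trials are processed in log order,
#' each tone updating its own value pair. The total is accumulated in log
#' space, and each per-trial probability is clamped to
#' `[eps, 1 - eps]` so the objective stays finite at parameter bounds.
#'
#' @param log A [sessionLog()] with early pulls already excluded.
#' @param params An [rlParams()].
#' @param spec Optional [modelSpec()]; if given, parameters disabled under
#'   the spec must be 0.
#' @param initial_state Initial [qState()]; all-zero by default.
#' @param eps Probability clamp, default `1e-12`.
#' @return The scalar negative log-likelihood (0 for an empty log).
#' @export
negativeLogLikelihood <- function(log, params, spec = NULL,
                                  initial_state = qState(), eps = 1e-12) {
  if (!is.null(spec)) checkParamsMatchSpec(params, spec)
  if (nrow(log) == 0L) return(0)
  enc <- encode_log(log)
  cpp_nll(enc$tone, enc$action, enc$reward, enc$punish, par_vec(params),
          as.numeric(initial_state$q_pull), as.numeric(initial_state$q_non_pull),
          eps)
}

# Optimization bounds. The learning/forgetting rates are kept strictly inside
# (0, 1); the outcome weights share the [0, 20] ceiling that the perturbation
# grid search uses.
param_bounds <- function() {
  list(lower = c(alpha_l = 1e-6, alpha_f = 1e-6, kappa_r = 0, kappa_p = 0,
                 psi = 0),
       upper = c(alpha_l = 1 - 1e-6, alpha_f = 1 - 1e-6, kappa_r = 20,
                 kappa_p = 20, psi = 20))
}

#' Information criteria
#'
#' `AIC = -2 log L_max + 2K` and `BIC = -2 log L_max + K log T_n`, with `K`
#' the number of free parameters and `T_n` the number of trials fitted.
#'
#' @param log_likelihood_max Maximized log-likelihood (<= 0).
#' @param K Number of free parameters.
#' @param T_n Number of trials used for fitting, >= 1.
#' @return Named list with `aic` and `bic`.
#' @export
informationCriteria <- function(log_likelihood_max, K, T_n) {
  if (T_n < 1) stop("T_n must be >= 1")
  list(aic = -2 * log_likelihood_max + 2 * K,
       bic = -2 * log_likelihood_max + K * log(T_n))
}

#' Maximum-likelihood model fitting
#'
#' Fits one model variant to a trial log by bounded local optimization
#' (`L-BFGS-B`) from `n_restarts` uniform-random starting points inside the
#' parameter bounds, keeping the best local optimum. The default restart
#' count matches the study procedure (5,000); smaller counts are adequate for
#' the model family's low-dimensional, well-behaved likelihood surfaces and
#' are used throughout the test suite (100).
#'
#' @inheritParams negativeLogLikelihood
#' @param spec A [modelSpec()].
#' @param n_restarts Number of random restarts, >= 1.
#' @param seed Integer seed making the restart draw (and hence the fit)
#'   deterministic.
#' @return An object of class `fit_result`: list with `spec`, `params`
#'   (full [rlParams()], disabled entries 0), `log_likelihood_max`,
#'   `n_trials_fit`, `aic`, `bic`, `n_restarts`, `n_converged`, `seed`,
#'   `p_trajectory` (per-trial pull probability) and `q_trajectory`
#'   (per-trial value matrix with columns `qA_pull, qB_pull, qA_non, qB_non`).
#' @export
fitModel <- function(log, spec, n_restarts = 5000L, seed = NULL,
                     initial_state = qState()) {
  if (!inherits(spec, "model_spec")) spec <- modelSpec(spec)
  if (!is.numeric(n_restarts) || n_restarts < 1) {
    stop("n_restarts must be a positive integer")
  }
  if (nrow(log) == 0L) stop("cannot fit an empty log")
  if (any(log$early_pull == 1L)) log <- excludeEarlyPulls(log)
  enc <- encode_log(log)
  free <- freeParamNames(spec)
  idx <- match(free, paramNames())
  b <- param_bounds()
  lower <- b$lower[free]; upper <- b$upper[free]
  q0p <- as.numeric(initial_state$q_pull)
  q0n <- as.numeric(initial_state$q_non_pull)

  # Objective and exact gradient share one likelihood pass; optim() asks for
  # them separately, so the last evaluation is cached.
  cache <- new.env(parent = emptyenv())
  eval_nll <- function(theta) {
    if (!is.null(cache$theta) && identical(theta, cache$theta)) return(cache$res)
    full <- numeric(5L)
    full[idx] <- theta
    res <- cpp_nll_grad(enc$tone, enc$action, enc$reward, enc$punish, full,
                        q0p, q0n, 1e-12)
    cache$theta <- theta
    cache$res <- res
    res
  }
  objective <- function(theta) eval_nll(theta)$nll
  gradient <- function(theta) eval_nll(theta)$grad[idx]

  with_seed(seed, {
    starts <- matrix(runif(n_restarts * length(free), rep(lower, each = n_restarts),
                           rep(upper, each = n_restarts)),
                     nrow = n_restarts)
    best <- NULL
    n_converged <- 0L
    failures <- character(0)
    # Two-stage search: every restart runs a bounded local optimization at a
    # coarse tolerance; the best optimum is then polished at full precision.
    for (i in seq_len(n_restarts)) {
      fit <- tryCatch(
        optim(starts[i, ], objective, gradient, method = "L-BFGS-B",
              lower = lower, upper = upper,
              control = list(maxit = 200L, factr = 1e9)),
        error = function(e) e)
      if (inherits(fit, "error")) {
        failures <- c(failures, conditionMessage(fit))
        next
      }
      n_converged <- n_converged + 1L
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (is.null(best)) {
      stop("all ", n_restarts, " restarts failed; first error: ",
           utils::head(failures, 1L))
    }
    polished <- tryCatch(
      optim(best$par, objective, gradient, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 1000L, factr = 1e7)),
      error = function(e) NULL)
    if (!is.null(polished) && polished$value <= best$value) best <- polished
    full <- numeric(5L); names(full) <- paramNames()
    full[idx] <- best$par
    params <- do.call(rlParams, as.list(full)[c("alpha_l", "kappa_r", "alpha_f",
                                                "kappa_p", "psi")])
    traj <- cpp_trajectory(enc$tone, enc$action, enc$reward, enc$punish,
                           par_vec(params), q0p, q0n, 1e-12)
    colnames(traj$q) <- c("qA_pull", "qB_pull", "qA_non", "qB_non")
    ic <- informationCriteria(-best$value, spec$K, nrow(log))
    structure(list(spec = spec, params = params,
                   log_likelihood_max = -best$value,
                   n_trials_fit = nrow(log), aic = ic$aic, bic = ic$bic,
                   n_restarts = as.integer(n_restarts),
                   n_converged = n_converged,
                   seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                   p_trajectory = traj$p_pull, q_trajectory = traj$q),
              class = "fit_result")
  })
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> model %s: logL = %.3f over %d trials\n",
              x$spec$name, x$log_likelihood_max, x$n_trials_fit))
  cat(sprintf("  AIC = %.2f, BIC = %.2f (%d/%d restarts converged)\n",
              x$aic, x$bic, x$n_converged, x$n_restarts))
  print(x$params)
  invisible(x)
}

#' Fit and compare the full model family
#'
#' Fits all seven model variants to one log and compares them by AIC and BIC.
#' Scores are also z-scored across the seven models (mean 0, sd 1), the form
#' used to display scores across subjects. The best model is the argmin of
#' the raw score; exact ties resolve to the earlier model in the canonical
#' order (`simple`, `punishment`, `saving`, `forgetting`, `P-F`, `S-F`,
#' `P-S-F`).
#'
#' @inheritParams fitModel
#' @param models Character vector of model names to include (default all 7).
#' @return An object of class `model_comparison`: list with `fits` (named
#'   list of [fitModel()] results), `table` (data.frame of logL, K, AIC,
#'   BIC, z-scored AIC/BIC), `best_by_aic`, `best_by_bic`.
#' @export
compareModels <- function(log, n_restarts = 5000L, seed = NULL,
                          initial_state = qState(), models = modelNames()) {
  models <- match.arg(models, modelNames(), several.ok = TRUE)
  fits <- list()
  errors <- character(0)
  for (i in seq_along(models)) {
    sub_seed <- if (is.null(seed)) NULL else derive_seed(seed, i)
    f <- tryCatch(fitModel(log, modelSpec(models[i]), n_restarts = n_restarts,
                           seed = sub_seed, initial_state = initial_state),
                  error = function(e) e)
    if (inherits(f, "error")) {
      errors <- c(errors, paste0(models[i], ": ", conditionMessage(f)))
    } else {
      fits[[models[i]]] <- f
    }
  }
  if (length(fits) < 2L) {
    stop("model comparison needs at least two successful fits; errors: ",
         paste(errors, collapse = "; "))
  }
  aic <- vapply(fits, `[[`, numeric(1L), "aic")
  bic <- vapply(fits, `[[`, numeric(1L), "bic")
  zs <- function(x) if (length(x) > 1L && sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  tab <- data.frame(model = names(fits),
                    K = vapply(fits, function(f) f$spec$K, integer(1L)),
                    logL = vapply(fits, `[[`, numeric(1L), "log_likelihood_max"),
                    aic = aic, bic = bic,
                    z_aic = zs(aic), z_bic = zs(bic),
                    row.names = NULL)
  structure(list(fits = fits, table = tab,
                 best_by_aic = names(fits)[which.min(aic)],
                 best_by_bic = names(fits)[which.min(bic)],
                 errors = errors),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  print(x$table, digits = 4)
  cat(sprintf("best by AIC: %s | best by BIC: %s\n",
              x$best_by_aic, x$best_by_bic))
  invisible(x)
}
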