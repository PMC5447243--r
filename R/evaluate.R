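# Prediction for new samples, fit metrics, clock phases, response curves
# and model-recovery summaries.

#' Predict expression for new samples
#'
#' Rebuilds the design matrix at the requested samples, applying the scale
#' specs stored at training time to the age and response columns, and
#' returns the noise-free model mean `X beta`.
#'
#' @param model a `fieldfit_gene`.
#' @param samples sample table (`time`, `age`, `genotype`).
#' @param ws [weather_series()] covering the prediction window plus the
#'   model's memory period (ignored for models without a response term).
#' @return Numeric vector of predictions on the training scale.
#' @export
predict_expression <- function(model, samples, ws = NULL) {
  stopifnot(inherits(model, "fieldfit_gene"))
  if (is.null(model$scale_specs)) stop("model carries no scale specs")
  rp <- model$response_params
  if (!is.null(rp) && is.null(ws)) {
    stop("model responds to '", rp$factor, "': weather series required")
  }
  ws_int <- if (is.null(rp)) NULL else get_integration_weather(ws, model$step)
  X <- build_design_matrix(samples$time, samples$age, samples$genotype,
                           ws_int, rp, scale_specs = model$scale_specs)
  as.numeric(X$values %*% model$coefficients)
}

#' Coefficient of determination
#'
#' `1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)`.
#'
#' @param obs observed values (not constant, length >= 2).
#' @param pred predicted values.
#' @return Scalar R-squared (<= 1; negative when worse than the mean).
#' @export
r_squared <- function(obs, pred) {
  stopifnot(length(obs) == length(pred), length(obs) >= 2L)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot < 1e-300) stop("observed values are constant")
  1 - sum((obs - pred)^2) / ss_tot
}

#' Clock phase of a fitted model
#'
#' Recovers the time of day (hours) at which the fitted circadian
#' component peaks, as the argument of `beta_cos + i * beta_sin` mapped to
#' `[0, 24)`.
#'
#' @param model a `fieldfit_gene`, or a coefficient vector with
#'   `clock_cos` / `clock_sin` entries.
#' @return Phase in hours.
#' @export
phase_of <- function(model) {
  beta <- if (inherits(model, "fieldfit_gene")) model$coefficients else model
  bc <- beta[["clock_cos"]]; bs <- beta[["clock_sin"]]
  if (bc == 0 && bs == 0) stop("clock coefficients are both zero")
  (atan2(bs, bc) * 24 / (2 * pi)) %% 24
}

# Shortest circular distance between two phases, in hours (in [0, 12]).
circular_phase_error <- function(a, b) {
  d <- abs(a - b) %% 24
  pmin(d, 24 - d)
}

#' Reconstructed response curve
#'
#' Evaluates the fitted steady-state response to the environmental factor:
#' `beta_r * max(0, tanh(rho * exp(gamma_f) * (T - theta))) * sqrt(exp(-2*gamma_f) + 1)`
#' over a grid of factor values.
#'
#' @param model a `fieldfit_gene` with a response term.
#' @param T_grid factor values at which to evaluate.
#' @return Numeric vector of responses.
#' @export
response_curve <- function(model, T_grid) {
  stopifnot(inherits(model, "fieldfit_gene"))
  rp <- model$response_params
  if (is.null(rp)) stop("model has no response term")
  beta_r <- model$coefficients[["response"]]
  beta_r * response_fn(T_grid - rp$threshold_theta, rp$gamma_f, rp$sign_rho)
}

# Non-zero penalized-group pattern of a coefficient vector. Coefficients
# below a small absolute tolerance are treated as zero (solver-boundary
# values are not structure).
nonzero_groups <- function(beta, tol = 1e-7) {
  groups <- design_groups()
  names(groups)[vapply(groups, function(idx) any(abs(beta[idx]) > tol),
                       logical(1L))]
}

#' Model-recovery summary against a truth library
#'
#' Compares fitted models to their generative truth: structure match is
#' exact equality of the non-zero penalized-group patterns (the sign of
#' the response coefficient is not compared, as dose-independent responses
#' above and below the threshold differ only by a constant); the factor
#' confusion table crosses true versus selected factor (including
#' `"none"`); circular phase errors are reported for genes whose truth and
#' fit both carry a clock.
#'
#' @param fit a `fieldfit_fit` (or list of `fieldfit_gene`).
#' @param truth a [truth_library()] with matching gene ids.
#' @return Object of class `recovery_summary`: `per_gene` data frame,
#'   `confusion` table, `n_variable`, `n_variable_matched`, `n_constant`,
#'   `n_constant_correct`, `phase_errors`.
#' @export
recovery_summary <- function(fit, truth) {
  models <- if (inherits(fit, "fieldfit_fit")) fit$models else fit
  ids <- vapply(truth, `[[`, "", "gene_id")
  mids <- vapply(models, `[[`, "", "gene_id")
  if (!all(ids %in% mids)) stop("gene ids in truth not all present in fit")
  models <- models[match(ids, mids)]
  rows <- lapply(seq_along(truth), function(i) {
    e <- truth[[i]]
    m <- models[[i]]
    fitted_pat <- nonzero_groups(m$coefficients)
    true_fac <- if (!is.null(e$response)) e$response$rp$factor else "none"
    phase_err <- NA_real_
    if ("clock" %in% e$structure && "clock" %in% fitted_pat) {
      phase_err <- circular_phase_error(phase_of(m), e$clock$phase)
    }
    data.frame(
      gene_id = e$gene_id,
      variable = length(e$structure) > 0L,
      match = setequal(fitted_pat, e$structure),
      true_factor = true_fac,
      selected_factor = m$factor,
      phase_error = phase_err,
      stringsAsFactors = FALSE
    )
  })
  per_gene <- do.call(rbind, rows)
  facs <- c(weather_attributes(), "none")
  confusion <- table(
    true = factor(per_gene$true_factor, levels = facs),
    selected = factor(per_gene$selected_factor, levels = facs)
  )
  structure(
    list(
      per_gene = per_gene,
      confusion = confusion,
      n_variable = sum(per_gene$variable),
      n_variable_matched = sum(per_gene$match & per_gene$variable),
      n_constant = sum(!per_gene$variable),
      n_constant_correct = sum(per_gene$match & !per_gene$variable),
      phase_errors = per_gene$phase_error[!is.na(per_gene$phase_error)]
    ),
    class = "recovery_summary"
  )
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf(
    "<recovery_summary> variable: %d/%d structures recovered; constant: %d/%d\n",
    x$n_variable_matched, x$n_variable, x$n_constant_correct, x$n_constant))
  if (length(x$phase_errors)) {
    cat(sprintf("  clock phase error: median %.2f h (n=%d)\n",
                stats::median(x$phase_errors), length(x$phase_errors)))
  }
  invisible(x)
}
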