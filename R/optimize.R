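# Per-gene two-step optimization (grid search, then Nelder-Mead) of the
# environmental-response parameters and factor choice, the full per-gene
# fitting pipeline, and cluster-based warm starting.

#' Grid specification for the initial parameter search
#'
#' Default spans cover the dose-dependent to dose-independent regimes
#' (`gamma_f`), the no-gate / cosine-gate / rectangular-gate regimes
#' (`gamma_g`, `theta_g`), memory periods from 1 h to 3 days, thresholds at
#' the deciles of the observed factor, gate phases every 4 h, and both
#' response signs.
#'
#' @param period_p memory periods (hours).
#' @param theta_quantiles threshold quantiles in (0,1), mapped to
#'   factor-specific values over the training window.
#' @param gamma_f,gamma_g,theta_g,psi,signs candidate values.
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(period_p = c(1, 3, 6, 12, 24, 48, 72),
                      theta_quantiles = seq(0.1, 0.9, by = 0.1),
                      gamma_f = c(-4, 0, 4),
                      gamma_g = c(-2, 2, 6),
                      theta_g = c(-1.5, -0.5, 0, 0.5, 0.9),
                      psi = c(0, 4, 8, 12, 16, 20),
                      signs = c(1, -1)) {
  stopifnot(length(period_p) > 0, length(theta_quantiles) > 0,
            length(gamma_f) > 0, length(gamma_g) > 0, length(theta_g) > 0,
            length(psi) > 0, length(signs) > 0)
  structure(list(period_p = period_p, theta_quantiles = theta_quantiles,
                 gamma_f = gamma_f, gamma_g = gamma_g, theta_g = theta_g,
                 psi = psi, signs = signs),
            class = "grid_spec")
}

grid_size <- function(grid) {
  prod(vapply(grid, length, integer(1L)))
}

#' Fitting options
#'
#' @param factors candidate weather attributes, searched in the given order.
#' @param grid a [grid_spec()].
#' @param step integration step for the environmental-response sums,
#'   seconds (default 600: 10-minute block means of the station record).
#' @param nm_maxit,nm_reltol Nelder-Mead iteration cap and relative
#'   convergence tolerance.
#' @param nlambda,lambda_min_ratio regularization path layout.
#' @param tol group-lasso convergence tolerance.
#' @return A `fit_options` list.
#' @export
fit_options <- function(factors = weather_attributes(), grid = grid_spec(),
                        step = 600, nm_maxit = 500L, nm_reltol = 1e-6,
                        nlambda = 50L, lambda_min_ratio = 1e-4, tol = 1e-8) {
  structure(list(factors = factors, grid = grid, step = step,
                 nm_maxit = nm_maxit, nm_reltol = nm_reltol,
                 nlambda = nlambda, lambda_min_ratio = lambda_min_ratio,
                 tol = tol),
            class = "fit_options")
}

# Expand a grid_spec into the full parameter table for one factor, in
# lexicographic order of the grid_spec fields (period_p slowest, signs
# fastest). theta quantiles are resolved against the factor's values over
# the training window.
expand_grid_table <- function(grid, theta_values) {
  combos <- expand.grid(sign_rho = grid$signs, psi = grid$psi,
                        theta_g = grid$theta_g, gamma_g = grid$gamma_g,
                        gamma_f = grid$gamma_f,
                        threshold_theta = theta_values,
                        period_p = grid$period_p,
                        KEEP.OUT.ATTRS = FALSE)
  # expand.grid varies the first column fastest; reorder columns for clarity
  combos[, c("period_p", "threshold_theta", "gamma_f", "gamma_g",
             "theta_g", "psi", "sign_rho")]
}

# Raw (unscaled) response features for every grid point of one factor:
# a (grid points) x N matrix in the enumeration order of expand_grid_table.
# The inner combos share the gate*response product on the weather grid; the
# memory periods reuse its cumulative sum.
grid_features <- function(ws, sample_times, factor, grid) {
  sample_times <- as_time(sample_times)
  p_max <- max(grid$period_p)
  check_weather_coverage(ws, min(sample_times) - p_max * 3600,
                         max(sample_times))
  wvals <- ws$values[[factor]]
  if (is.null(wvals)) stop("weather series has no attribute '", factor, "'")
  wt <- as.numeric(ws$time)
  st <- as.numeric(sample_times)
  tod <- time_of_day(ws$time)
  # thresholds: deciles of the factor over the training window
  in_window <- wt >= min(st) - p_max * 3600 - 1e-6 & wt <= max(st) + 1e-6
  theta_values <- unname(stats::quantile(wvals[in_window],
                                         probs = grid$theta_quantiles))
  eps <- 1e-6
  hi <- findInterval(st + eps, wt)
  if (any(hi == 0)) stop("insufficient weather coverage")
  lo <- lapply(grid$period_p,
               function(p) findInterval(st - p * 3600 - eps, wt))
  n <- length(st)
  nP <- length(grid$period_p)
  # combos excluding period, slowest-varying first: theta, gf, gg, tg, psi, sign
  inner <- expand.grid(sign_rho = grid$signs, psi = grid$psi,
                       theta_g = grid$theta_g, gamma_g = grid$gamma_g,
                       gamma_f = grid$gamma_f, threshold_theta = theta_values,
                       KEEP.OUT.ATTRS = FALSE)
  C <- nrow(inner)
  gates <- list()
  for (gg in grid$gamma_g) for (tg in grid$theta_g) for (ps in grid$psi) {
    gates[[paste(gg, tg, ps)]] <- gate_on_grid(ws, ps, gg, tg)
  }
  resps <- list()
  for (th in theta_values) for (gf in grid$gamma_f) for (sg in grid$signs) {
    resps[[paste(th, gf, sg)]] <- response_fn(wvals - th, gf, sg)
  }
  F <- matrix(0, nP * C, n)
  vals <- matrix(0, nP, n)
  for (ci in seq_len(C)) {
    cmb <- inner[ci, ]
    v <- gates[[paste(cmb$gamma_g, cmb$theta_g, cmb$psi)]] *
      resps[[paste(cmb$threshold_theta, cmb$gamma_f, cmb$sign_rho)]]
    cs <- c(0, cumsum(v))
    for (pi in seq_len(nP)) {
      vals[pi, ] <- cs[hi + 1L] - cs[lo[[pi]] + 1L]
    }
    F[(seq_len(nP) - 1L) * C + ci, ] <- vals
  }
  params <- expand_grid_table(grid, theta_values)
  list(features = F, params = params, factor = factor)
}

# Fixed design columns (everything except the response columns), with
# degenerate columns removed; used by the grid WLS sweep.
fixed_design <- function(samples) {
  d <- scale_unit_range(samples$age)$scaled
  cb <- clock_basis(samples$time)
  X0 <- cbind(intercept = rep(1, nrow(samples)), age = d,
              clock_cos = cb[, 1L], clock_sin = cb[, 2L],
              age_clock_cos = d * cb[, 1L], age_clock_sin = d * cb[, 2L],
              genotype = as.numeric(samples$genotype))
  keep <- !degenerate_columns(X0)
  list(X0 = X0[, keep, drop = FALSE], d = d)
}

#' Grid search over environmental-response parameters and factors
#'
#' For every candidate factor and grid point, builds the design matrix,
#' fits weighted least squares, and records the weighted mean squared
#' error; returns the global minimizer. Ties are broken by enumeration
#' order: factors in the order given, grid points in lexicographic order
#' of the [grid_spec()] fields. Deterministic.
#'
#' @param y expression vector (length N >= 10).
#' @param w positive observation weights, or `NULL`.
#' @param samples sample table: data frame with columns `time`, `age`,
#'   `genotype` (and optionally `sample_id`).
#' @param ws [weather_series()] at the integration cadence.
#' @param factors candidate weather attribute names.
#' @param grid a [grid_spec()].
#' @param cache optional environment for reusing per-factor feature
#'   matrices across genes fitted against the same samples and weather.
#' @return List: `response_params`, `factor`, `beta_tilde` (pilot WLS
#'   coefficients at the winning setting), `mse`.
#' @export
grid_search <- function(y, w = NULL, samples, ws, factors = weather_attributes(),
                        grid = grid_spec(), cache = NULL) {
  n <- nrow(samples)
  stopifnot(length(y) == n, n >= 10L)
  if (is.null(w)) w <- rep(1, n)
  fd <- fixed_design(samples)
  best <- NULL
  for (fac in factors) {
    gf <- if (!is.null(cache) && !is.null(cache[[fac]])) {
      cache[[fac]]
    } else {
      out <- grid_features(ws, samples$time, fac, grid)
      if (!is.null(cache)) cache[[fac]] <- out
      out
    }
    mse <- .grid_wls_mse(gf$features, fd$X0, fd$d, y, w)
    i <- which(mse <= min(mse) + 1e-12 * (1 + abs(min(mse))))[1L]
    if (is.null(best) || mse[i] < best$mse * (1 - 1e-12) - 1e-15) {
      mk_rp <- function(j) {
        p <- gf$params[j, ]
        response_params(
          period_p = p$period_p, threshold_theta = p$threshold_theta,
          gamma_f = p$gamma_f, gamma_g = p$gamma_g, theta_g = p$theta_g,
          psi = p$psi, sign_rho = p$sign_rho, factor = fac)
      }
      best <- list(response_params = mk_rp(i), factor = fac, mse = mse[i])
    }
  }
  X <- build_design_matrix(samples$time, samples$age, samples$genotype,
                           ws, best$response_params)
  best$beta_tilde <- wls_fit(X, y, w)
  best
}

# Transform between response_params and unconstrained Nelder-Mead
# coordinates: p via log, psi wrapped mod 24, gammas clamped to [-10, 10].
rp_to_par <- function(rp) {
  c(log(rp$period_p), rp$threshold_theta, rp$gamma_f, rp$gamma_g,
    rp$theta_g, rp$psi)
}

par_to_rp <- function(par, template, p_max = Inf) {
  response_params(
    period_p = min(exp(par[1L]), p_max),
    threshold_theta = par[2L],
    gamma_f = max(-10, min(10, par[3L])),
    gamma_g = max(-10, min(10, par[4L])),
    theta_g = par[5L],
    psi = par[6L] %% 24,
    sign_rho = template$sign_rho,
    factor = template$factor
  )
}

#' Nelder-Mead refinement of environmental-response parameters
#'
#' Polishes the grid-search winner by Nelder-Mead in transformed
#' coordinates (log memory period, gate phase modulo 24 h, shape
#' parameters clamped to `[-10, 10]`); the response sign and factor stay
#' fixed. The returned parameters never have a worse objective than the
#' initial ones.
#'
#' @param init a [response_params()] starting point.
#' @param objective function mapping a `response_params` to the weighted
#'   MSE after a pilot WLS fit; must be finite at `init`.
#' @param maxit,reltol Nelder-Mead controls.
#' @param p_max upper bound for the memory period (hours), from weather
#'   coverage.
#' @return Refined `response_params` with attribute `"objective"`.
#' @export
refine_nelder_mead <- function(init, objective, maxit = 500L, reltol = 1e-6,
                               p_max = Inf) {
  f0 <- objective(init)
  if (!is.finite(f0)) stop("objective not finite at the initial parameters")
  obj_par <- function(par) {
    v <- objective(par_to_rp(par, init, p_max))
    if (!is.finite(v)) .Machine$double.xmax else v
  }
  opt <- stats::optim(rp_to_par(init), obj_par, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
  if (opt$value <= f0) {
    out <- par_to_rp(opt$par, init, p_max)
    attr(out, "objective") <- opt$value
  } else {
    out <- init
    attr(out, "objective") <- f0
  }
  out
}

# Run the penalized-selection tail of the pipeline: pilot WLS, adaptive
# weights, group-lasso path with approximate LOO-CV, 1-SE selection.
fit_selection <- function(X, y, w, options) {
  beta_tilde <- wls_fit(X, y, w)
  zeta <- adaptive_weights(beta_tilde)
  path <- group_lasso_path(X, y, w, zeta, nlambda = options$nlambda,
                           lambda_min_ratio = options$lambda_min_ratio,
                           tol = options$tol)
  lam <- select_lambda(path)
  i <- which(path$lambdas == lam)[1L]
  list(beta_tilde = beta_tilde, zeta = zeta, path = path,
       lambda = lam, beta = path$coefficients[i, ],
       cv_error = path$cv_error[i], cv_se = path$cv_se[i])
}

#' Fit the field-transcriptome model for one gene
#'
#' The full per-gene pipeline: grid search over environmental-response
#' parameters and factors, Nelder-Mead refinement, pilot weighted least
#' squares, adaptive group-lasso path with approximate leave-one-out CV,
#' and 1-SE penalty selection. If the selected model has zero response and
#' age x response coefficients the factor is `"none"`; if every penalized
#' group is zero the gene is called constant.
#'
#' @param y expression vector on the log2 (or log-cpm) scale.
#' @param w per-sample precision weights, or `NULL` for unweighted.
#' @param samples sample table (`time`, `age`, `genotype`).
#' @param ws [weather_series()]; resampled internally to `options$step`.
#' @param options a [fit_options()].
#' @param gene_id gene identifier stored in the result.
#' @param init optional warm start: a `response_params` whose factor is
#'   used instead of running the grid search (cluster-based fitting), or
#'   `NULL` within a warm start to force a no-response fit.
#' @param cache optional environment shared across genes (feature matrices
#'   and the resampled weather).
#' @return Object of class `fieldfit_gene`.
#' @export
fit_gene <- function(y, w = NULL, samples, ws, options = fit_options(),
                     gene_id = "gene", init, cache = NULL) {
  n <- nrow(samples)
  stopifnot(length(y) == n)
  if (!is.null(w)) stopifnot(length(w) == n, all(w > 0))
  ws_int <- get_integration_weather(ws, options$step, cache)
  p_max <- (min(as.numeric(as_time(samples$time))) -
              as.numeric(ws_int$time[1L])) / 3600
  warm <- !missing(init)
  obj <- function(rp) {
    X <- build_design_matrix(samples$time, samples$age, samples$genotype,
                             ws_int, rp)
    beta <- wls_fit(X, y, w)
    e <- y - X$values %*% beta
    ww <- if (is.null(w)) rep(1, n) else w
    sum(ww * e^2) / n
  }
  if (!warm) {
    gs <- grid_search(y, w, samples, ws_int, factors = options$factors,
                      grid = options$grid, cache = cache)
    if (!is.null(cache)) {
      cache$n_grid_search <- (cache$n_grid_search %||% 0L) + 1L
    }
    rp0 <- gs$response_params
  } else {
    rp0 <- init
  }
  rp <- if (is.null(rp0)) NULL else {
    refine_nelder_mead(rp0, obj, maxit = options$nm_maxit,
                       reltol = options$nm_reltol, p_max = p_max)
  }
  X <- build_design_matrix(samples$time, samples$age, samples$genotype,
                           ws_int, rp)
  sel <- fit_selection(X, y, w, options)
  beta <- sel$beta
  has_response <- beta[["response"]] != 0 || beta[["age_response"]] != 0
  penalized_zero <- all(beta[-1L] == 0)
  fitted_vals <- as.numeric(X$values %*% beta)
  ww <- if (is.null(w)) rep(1, n) else w
  structure(
    list(
      gene_id = gene_id,
      response_params = if (has_response) rp else NULL,
      factor = if (has_response) rp$factor else "none",
      coefficients = beta,
      scale_specs = X$scale_specs,
      selected_lambda = sel$lambda,
      cv_error = sel$cv_error,
      cv_se = sel$cv_se,
      beta_tilde = sel$beta_tilde,
      constant = penalized_zero,
      weights_used = !is.null(w),
      step = options$step,
      mse_train = sum(ww * (y - fitted_vals)^2) / n,
      fitted = fitted_vals,
      y = as.numeric(y)
    ),
    class = "fieldfit_gene"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

get_integration_weather <- function(ws, step, cache = NULL) {
  if (!is.null(cache) && !is.null(cache$.ws_int) &&
      isTRUE(all.equal(cache$.ws_step, step))) {
    return(cache$.ws_int)
  }
  out <- if (ws$cadence == step) ws else resample_weather(ws, step)
  if (!is.null(cache)) {
    cache$.ws_int <- out
    cache$.ws_step <- step
  }
  out
}

#' Fit every gene of an expression matrix independently
#'
#' Runs the full [fit_gene()] pipeline per gene (grid search and all),
#' sharing the per-factor grid feature matrices across genes.
#'
#' @param Y gene x sample matrix (rownames = gene ids) of log2 expression
#'   or log-cpm values.
#' @param w gene x sample matrix of precision weights, or `NULL`.
#' @param samples,ws,options as in [fit_gene()].
#' @param verbose print per-gene progress.
#' @return Object of class `fieldfit_fit`.
#' @export
fit_genes <- function(Y, w = NULL, samples, ws, options = fit_options(),
                      verbose = FALSE) {
  Y <- as.matrix(Y)
  ids <- rownames(Y) %||% paste0("gene", seq_len(nrow(Y)))
  cache <- new.env(parent = emptyenv())
  cache$n_grid_search <- 0L
  models <- vector("list", nrow(Y))
  for (i in seq_len(nrow(Y))) {
    wi <- if (is.null(w)) NULL else w[i, ]
    models[[i]] <- fit_gene(Y[i, ], wi, samples, ws, options,
                            gene_id = ids[i], cache = cache)
    if (verbose) {
      message(sprintf("fit %s: factor=%s lambda=%.3g", ids[i],
                      models[[i]]$factor, models[[i]]$selected_lambda))
    }
  }
  names(models) <- ids
  structure(
    list(models = models, cluster = NULL,
         diagnostics = list(n_grid_search = cache$n_grid_search)),
    class = "fieldfit_fit"
  )
}

#' Affinity-propagation clustering
#'
#' Frey-Dueck affinity propagation on the rows of a data matrix, with
#' similarity the negative Euclidean distance, the median off-diagonal
#' similarity as the shared preference, and damped message updates.
#'
#' @param X data matrix (items x features).
#' @param damping message damping in (0.5, 1) (default 0.9).
#' @param max_iter maximum iterations.
#' @param conv_iter iterations with an unchanged exemplar set required to
#'   declare convergence.
#' @param preference shared preference; default median off-diagonal
#'   similarity.
#' @return List: `exemplars` (row indices), `assignment` (exemplar index
#'   per row), `converged` (logical).
#' @export
affinity_propagation <- function(X, damping = 0.9, max_iter = 1000L,
                                 conv_iter = 50L, preference = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n == 1L) return(list(exemplars = 1L, assignment = 1L, converged = TRUE))
  S <- -as.matrix(stats::dist(X))
  if (is.null(preference)) {
    preference <- stats::median(S[upper.tri(S)])
  }
  diag(S) <- preference
  # tiny deterministic jitter breaks exact symmetry ties
  set_jitter <- 1e-10 * (abs(preference) + 1)
  S <- S + set_jitter * matrix(seq_len(n * n) %% 7, n, n) / 7
  R <- A <- matrix(0, n, n)
  last <- NULL
  stable <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    AS <- A + S
    first <- apply(AS, 1L, max)
    which_first <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), which_first)] <- -Inf
    second <- apply(AS2, 1L, max)
    Rmax <- S - first
    Rmax[cbind(seq_len(n), which_first)] <-
      S[cbind(seq_len(n), which_first)] - second
    R <- damping * R + (1 - damping) * Rmax
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    colsum <- rep(colSums(Rp), each = n)
    Anew <- matrix(colsum, n, n) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(R) + diag(A) > 0)
    if (identical(ex, last)) stable <- stable + 1L else stable <- 0L
    last <- ex
    if (stable >= conv_iter && length(ex) > 0L) {
      converged <- TRUE
      break
    }
  }
  if (length(last) == 0L) {
    last <- which.max(rowSums(S))
    converged <- FALSE
  }
  assignment <- last[max.col(S[, last, drop = FALSE], ties.method = "first")]
  assignment[last] <- last
  list(exemplars = last, assignment = assignment, converged = converged)
}

#' Cluster-based fitting with warm starts
#'
#' Clusters z-scored expression patterns by [affinity_propagation()], runs
#' the full pipeline (grid search included) on each cluster exemplar only,
#' and fits the remaining genes by Nelder-Mead refinement warm-started
#' from their exemplar's environmental-response parameters (factor
#' inherited), followed by the usual penalized selection. Falls back to
#' full per-gene fits with a warning if clustering fails to converge.
#'
#' @inheritParams fit_genes
#' @return A `fieldfit_fit` whose `cluster` field records the exemplars
#'   and assignments.
#' @export
cluster_fit <- function(Y, w = NULL, samples, ws, options = fit_options(),
                        verbose = FALSE) {
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) >= 2L)
  ids <- rownames(Y) %||% paste0("gene", seq_len(nrow(Y)))
  Z <- t(scale(t(Y)))
  Z[!is.finite(Z)] <- 0
  ap <- affinity_propagation(Z)
  if (!ap$converged) {
    warning("affinity propagation did not converge; falling back to full per-gene fits")
    return(fit_genes(Y, w, samples, ws, options, verbose))
  }
  cache <- new.env(parent = emptyenv())
  cache$n_grid_search <- 0L
  models <- vector("list", nrow(Y))
  for (e in ap$exemplars) {
    we <- if (is.null(w)) NULL else w[e, ]
    models[[e]] <- fit_gene(Y[e, ], we, samples, ws, options,
                            gene_id = ids[e], cache = cache)
  }
  for (i in seq_len(nrow(Y))) {
    if (i %in% ap$exemplars) next
    ex_model <- models[[ap$assignment[i]]]
    init <- ex_model$response_params
    if (is.null(init)) {
      # constant/clock-only exemplar: members fitted without a response term
      init <- NULL
    }
    wi <- if (is.null(w)) NULL else w[i, ]
    models[[i]] <- fit_gene(Y[i, ], wi, samples, ws, options,
                            gene_id = ids[i], init = init, cache = cache)
  }
  names(models) <- ids
  structure(
    list(models = models,
         cluster = list(exemplars = ids[ap$exemplars],
                        assignment = stats::setNames(ids[ap$assignment], ids)),
         diagnostics = list(n_grid_search = cache$n_grid_search)),
    class = "fieldfit_fit"
  )
}
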