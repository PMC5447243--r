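# Weighted least squares, adaptive group lasso, approximate LOO-CV and
# lambda selection.

as_design_values <- function(X) {
  if (inherits(X, "design_matrix")) X$values else as.matrix(X)
}

# Columns with (numerically) zero variance that are not the intercept
# carry no information and are dropped from fits (coefficient 0).
degenerate_columns <- function(X) {
  rng <- apply(X, 2L, function(v) max(v) - min(v))
  deg <- rng < 1e-12
  if ("intercept" %in% colnames(X)) deg[colnames(X) == "intercept"] <- FALSE
  deg
}

#' Weighted least squares fit
#'
#' Minimizes `sum(w * (y - X beta)^2)`. Degenerate (constant) columns are
#' dropped with coefficient zero; remaining rank deficiency is resolved by
#' pivoting, with a warning, again assigning zero to aliased columns.
#'
#' @param X design matrix (a `design_matrix` or plain numeric matrix).
#' @param y response vector.
#' @param w positive observation weights (default all 1).
#' @return Named coefficient vector, one entry per column of `X`.
#' @export
wls_fit <- function(X, y, w = NULL) {
  X <- as_design_values(X)
  n <- nrow(X)
  if (is.null(w)) w <- rep(1, n)
  stopifnot(length(y) == n, length(w) == n, all(w > 0))
  beta <- stats::setNames(numeric(ncol(X)), colnames(X))
  keep <- !degenerate_columns(X)
  fit <- stats::lm.wfit(X[, keep, drop = FALSE], y, w)
  cf <- fit$coefficients
  if (anyNA(cf)) {
    warning("rank-deficient design: aliased columns set to zero")
    cf[is.na(cf)] <- 0
  }
  beta[keep] <- cf
  beta
}

#' Adaptive group-lasso penalty weights
#'
#' Derives per-group penalty weights from a pilot (unpenalized) WLS fit:
#' `1/beta^2` for the age and genotype singletons, `7/beta^2` for the
#' environmental response and the age x response interaction (the response
#' carries seven nonlinear parameters, so it is penalized seven-fold), and
#' `1/(beta_cos^2 + beta_sin^2)` for each cos/sin pair. A zero pilot
#' coefficient yields an infinite weight, which removes the group.
#'
#' @param beta_tilde pilot coefficient 9-vector from [wls_fit()] on the
#'   full design (ordered as [build_design_matrix()] columns).
#' @return Named numeric vector of group weights (class `penalty_weights`):
#'   `age`, `clock`, `response`, `age_clock`, `age_response`, `genotype`.
#' @export
adaptive_weights <- function(beta_tilde) {
  stopifnot(length(beta_tilde) == 9L)
  b <- unname(beta_tilde)
  inv <- function(x) if (x < .Machine$double.xmin) Inf else 1 / x
  w <- c(
    age          = inv(b[2L]^2),
    clock        = inv(b[3L]^2 + b[4L]^2),
    response     = 7 * inv(b[5L]^2),
    age_clock    = inv(b[6L]^2 + b[7L]^2),
    age_response = 7 * inv(b[8L]^2),
    genotype     = inv(b[9L]^2)
  )
  structure(w, class = "penalty_weights")
}

# Largest-eigenvalue Lipschitz constants per group block of A = 2 X'WX.
group_lipschitz <- function(A, groups) {
  vapply(groups, function(idx) {
    blk <- A[idx, idx, drop = FALSE]
    if (length(idx) == 1L) blk[1L, 1L] else max(eigen(blk, symmetric = TRUE,
                                                      only.values = TRUE)$values)
  }, numeric(1L))
}

#' Adaptive group-lasso fit at a single penalty
#'
#' Minimizes
#' `sum(w * (y - X beta)^2) + lambda * sum(zeta_g * ||beta_g||_2)`
#' over the 9 design coefficients, with the intercept unpenalized, the
#' cos/sin pairs penalized as Euclidean-norm groups, and the remaining
#' covariates as singletons. Solved by block coordinate descent with
#' group-wise proximal (soft-thresholding) updates; convergence requires
#' both a maximum coefficient change and a block-KKT residual below `tol`.
#' Groups with infinite weight (or degenerate columns) are excluded.
#'
#' @param X design matrix (N x 9).
#' @param y response vector.
#' @param w positive weights (default 1).
#' @param zeta [adaptive_weights()] vector.
#' @param lambda penalty strength, >= 0.
#' @param beta_init optional warm start.
#' @param tol convergence tolerance (default 1e-8).
#' @param max_iter maximum sweeps (default 10000).
#' @return Named coefficient 9-vector.
#' @export
group_lasso_fit <- function(X, y, w = NULL, zeta, lambda,
                            beta_init = NULL, tol = 1e-8, max_iter = 10000L) {
  X <- as_design_values(X)
  n <- nrow(X)
  if (is.null(w)) w <- rep(1, n)
  stopifnot(lambda >= 0, all(w > 0))
  groups <- design_groups()
  stopifnot(all(names(groups) %in% names(zeta)))
  deg <- degenerate_columns(X)
  excluded <- vapply(names(groups), function(g) {
    !is.finite(zeta[[g]]) || any(deg[groups[[g]]])
  }, logical(1L))
  A <- 2 * crossprod(X, w * X)
  b <- 2 * crossprod(X, w * y)[, 1L]
  beta <- if (is.null(beta_init)) numeric(9L) else as.numeric(beta_init)
  beta[unlist(groups[excluded])] <- 0
  Lg <- group_lipschitz(A, groups)
  act_groups <- names(groups)[!excluded]
  iter <- 0L
  repeat {
    # block coordinate descent with group-wise proximal updates until the
    # coefficient change stalls, then an active-set Newton polish drives
    # the stationarity residual to the tolerance
    sweeps <- 0L
    repeat {
      iter <- iter + 1L
      sweeps <- sweeps + 1L
      delta <- 0
      new0 <- (b[1L] - sum(A[1L, -1L] * beta[-1L])) / A[1L, 1L]
      delta <- max(delta, abs(new0 - beta[1L]))
      beta[1L] <- new0
      for (g in act_groups) {
        idx <- groups[[g]]
        grad <- A[idx, , drop = FALSE] %*% beta - b[idx]
        z <- beta[idx] - grad / Lg[[g]]
        zn <- sqrt(sum(z^2))
        newb <- if (zn > 0) z * max(0, 1 - lambda * zeta[[g]] / (Lg[[g]] * zn))
        else z * 0
        delta <- max(delta, max(abs(newb - beta[idx])))
        beta[idx] <- newb
      }
      # hand the slow tail to the Newton polish once progress stalls
      if (delta < tol || sweeps >= 100L || iter >= max_iter) break
    }
    beta <- newton_polish(A, b, beta, zeta, lambda, groups, act_groups)
    kkt <- kkt_residual(A, b, beta, zeta, lambda, groups, excluded)
    if (kkt < tol) break
    if (iter >= max_iter) {
      stop(sprintf(
        "group lasso did not converge in %d iterations (KKT residual %.3g)",
        max_iter, kkt))
    }
  }
  stats::setNames(beta, colnames(X))
}

# Newton iterations on the stationarity system restricted to the current
# active set (intercept always active). Each step is accepted only if it
# decreases the penalized objective (backtracking halving); groups whose
# norm collapses are dropped to zero, and coordinate descent resumes if
# the KKT conditions are still violated.
newton_polish <- function(A, b, beta, zeta, lambda, groups, act_groups,
                          max_newton = 50L) {
  qval <- function(bb) {
    pen <- 0
    for (g in act_groups) {
      nrm <- sqrt(sum(bb[groups[[g]]]^2))
      if (nrm > 0) pen <- pen + zeta[[g]] * nrm
    }
    0.5 * sum(bb * (A %*% bb)) - sum(b * bb) + lambda * pen
  }
  q0 <- qval(beta)
  for (nit in seq_len(max_newton)) {
    active <- act_groups[vapply(act_groups,
                                function(g) any(beta[groups[[g]]] != 0),
                                logical(1L))]
    idx <- c(1L, unlist(groups[active], use.names = FALSE))
    Fi <- (A %*% beta - b)[idx]
    J <- A[idx, idx, drop = FALSE]
    pos <- 1L
    degenerate <- FALSE
    for (g in active) {
      gi <- groups[[g]]
      k <- length(gi)
      rows <- pos + seq_len(k)
      bg <- beta[gi]
      nrm <- sqrt(sum(bg^2))
      if (nrm < 1e-10) { degenerate <- TRUE; break }
      Fi[rows] <- Fi[rows] + lambda * zeta[[g]] * bg / nrm
      J[rows, rows] <- J[rows, rows] +
        lambda * zeta[[g]] * (diag(k) / nrm - tcrossprod(bg) / nrm^3)
      pos <- pos + k
    }
    if (degenerate) break
    if (max(abs(Fi)) < 1e-12) break
    step <- tryCatch(solve(J, Fi), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    accepted <- FALSE
    scale <- 1
    for (bt in 1:20) {
      newb <- beta
      newb[idx] <- beta[idx] - scale * step
      # a group driven through zero is dropped rather than stepped across
      for (g in active) {
        gi <- groups[[g]]
        if (sqrt(sum(newb[gi]^2)) < 1e-12 ||
            (length(gi) == 1L && sign(newb[gi]) * sign(beta[gi]) < 0 &&
             abs(beta[gi]) > 0)) {
          newb[gi] <- 0
        }
      }
      q1 <- qval(newb)
      if (q1 <= q0 + 1e-14 * (abs(q0) + 1)) {
        accepted <- TRUE
        break
      }
      scale <- scale / 2
    }
    if (!accepted) break
    if (max(abs(newb - beta)) < 1e-14) {
      beta <- newb
      break
    }
    beta <- newb
    q0 <- q1
  }
  beta
}

#' Block KKT residual of a group-lasso solution
#'
#' Maximum violation of the stationarity conditions of the penalized
#' objective: zero intercept gradient; for active groups
#' `grad + lambda * zeta * beta/||beta|| = 0`; for inactive groups
#' `||grad|| <= lambda * zeta`.
#'
#' @inheritParams group_lasso_fit
#' @param beta candidate coefficient vector.
#' @return Scalar residual (0 at an exact solution).
#' @export
kkt_check <- function(X, y, w = NULL, zeta, lambda, beta) {
  X <- as_design_values(X)
  if (is.null(w)) w <- rep(1, nrow(X))
  groups <- design_groups()
  deg <- degenerate_columns(X)
  excluded <- vapply(names(groups), function(g) {
    !is.finite(zeta[[g]]) || any(deg[groups[[g]]])
  }, logical(1L))
  A <- 2 * crossprod(X, w * X)
  b <- 2 * crossprod(X, w * y)[, 1L]
  kkt_residual(A, b, beta, zeta, lambda, groups, excluded)
}

kkt_residual <- function(A, b, beta, zeta, lambda, groups, excluded) {
  grad <- A %*% beta - b
  res <- abs(grad[1L])
  for (g in names(groups)[!excluded]) {
    idx <- groups[[g]]
    gn <- beta[idx]
    if (sqrt(sum(gn^2)) > 0) {
      res <- max(res, max(abs(grad[idx] + lambda * zeta[[g]] * gn / sqrt(sum(gn^2)))))
    } else {
      res <- max(res, max(0, sqrt(sum(grad[idx]^2)) - lambda * zeta[[g]]))
    }
  }
  res
}

# Smallest lambda at which every penalized (finite-weight) group is zero,
# from the intercept-only residual.
lambda_max <- function(X, y, w, zeta) {
  X <- as_design_values(X)
  groups <- design_groups()
  deg <- degenerate_columns(X)
  mu <- sum(w * y) / sum(w)
  r0 <- y - mu
  lmax <- 0
  for (g in names(groups)) {
    if (!is.finite(zeta[[g]]) || any(deg[groups[[g]]])) next
    gnorm <- sqrt(sum((2 * crossprod(X[, groups[[g]], drop = FALSE], w * r0))^2))
    lmax <- max(lmax, gnorm / zeta[[g]])
  }
  lmax
}

#' Approximate leave-one-out cross-validation error
#'
#' Given the active-set design (columns with non-zero coefficients,
#' intercept included) and the fitted coefficients, approximates the
#' leave-one-out CV error and its standard error from a single fit: each
#' per-sample squared residual is inflated by `(1 + x_j' chi x_j)^2`, where
#' `chi` combines the active-set Gram inverse with the sample's leverage;
#' algebraically the inflation equals `1/(1 - h_j)^2` with `h_j` the
#' leverage. The CV error is the mean of the inflated squared residuals
#' over samples and the standard error is their standard deviation divided
#' by `sqrt(N)`. With observation weights the weighted leverage and
#' weighted squared residuals are used.
#'
#' @param X_active N x k active-set design matrix, full column rank, k < N.
#' @param y response vector.
#' @param beta fitted coefficients for the active columns.
#' @param w optional positive weights.
#' @return List with `cv_error` and `cv_se`.
#' @export
approx_loocv <- function(X_active, y, beta, w = NULL) {
  X <- as_design_values(X_active)
  n <- nrow(X)
  if (is.null(w)) w <- rep(1, n)
  stopifnot(n > ncol(X))
  A <- crossprod(X, w * X)
  Ai <- tryCatch(solve(A), error = function(e) stop("active set is rank deficient"))
  h <- w * rowSums((X %*% Ai) * X)
  if (any(h >= 1 - 1e-10)) stop("leverage >= 1: exact LOO undefined")
  e <- y - X %*% as.numeric(beta)
  vals <- w * (e / (1 - h))^2
  list(cv_error = mean(vals), cv_se = stats::sd(vals) / sqrt(n))
}

#' Fit the adaptive group-lasso regularization path
#'
#' Fits [group_lasso_fit()] along a decreasing log-spaced sequence of 50
#' penalties from the analytic `lambda_max` (all penalized groups zero)
#' down to `1e-4 * lambda_max`, warm-starting each fit from the previous
#' one, and computes the approximate LOO-CV error at each penalty using
#' that penalty's active set (intercept always included).
#'
#' @inheritParams group_lasso_fit
#' @param nlambda number of penalties (default 50).
#' @param lambda_min_ratio ratio of smallest to largest penalty.
#' @return Object of class `reg_path`: `lambdas`, `coefficients`
#'   (nlambda x 9), `cv_error`, `cv_se`, `n_active_groups`.
#' @export
group_lasso_path <- function(X, y, w = NULL, zeta, nlambda = 50L,
                             lambda_min_ratio = 1e-4, tol = 1e-8) {
  X <- as_design_values(X)
  n <- nrow(X)
  if (is.null(w)) w <- rep(1, n)
  lmax <- lambda_max(X, y, w, zeta)
  if (lmax <= 0) {
    # every penalized group excluded or residual exactly zero: intercept only
    lambdas <- 0
  } else {
    # small margin keeps the boundary group strictly inactive at the start
    lmax <- lmax * (1 + 1e-6)
    lambdas <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                       length.out = nlambda))
  }
  groups <- design_groups()
  coefs <- matrix(0, length(lambdas), 9L,
                  dimnames = list(NULL, colnames(X)))
  cv_error <- cv_se <- numeric(length(lambdas))
  nact <- integer(length(lambdas))
  beta <- NULL
  for (i in seq_along(lambdas)) {
    beta <- group_lasso_fit(X, y, w, zeta, lambdas[i], beta_init = beta,
                            tol = tol)
    coefs[i, ] <- beta
    active_cols <- c(1L, which(beta[-1L] != 0) + 1L)
    # the leave-one-out identity underlying the approximation holds for the
    # least-squares fit on the active submodel, so the CV error is computed
    # from the active-set WLS refit rather than the shrunk coefficients
    Xa <- X[, active_cols, drop = FALSE]
    beta_ref <- wls_fit(Xa, y, w)
    cv <- approx_loocv(Xa, y, beta_ref, w)
    cv_error[i] <- cv$cv_error
    cv_se[i] <- cv$cv_se
    nact[i] <- sum(vapply(groups, function(idx) any(beta[idx] != 0), logical(1L)))
  }
  structure(
    list(lambdas = lambdas, coefficients = coefs, cv_error = cv_error,
         cv_se = cv_se, n_active_groups = nact),
    class = "reg_path"
  )
}

#' Select the penalty by the 1-SE rule
#'
#' Returns the largest penalty whose CV error is below the minimum CV error
#' plus the standard error at the minimizer.
#'
#' @param path a `reg_path` from [group_lasso_path()].
#' @return Selected lambda (scalar).
#' @export
select_lambda <- function(path) {
  stopifnot(inherits(path, "reg_path"), length(path$lambdas) > 0L)
  imin <- which.min(path$cv_error)
  thr <- path$cv_error[imin] + path$cv_se[imin]
  max(path$lambdas[path$cv_error < thr])
}

#' @export
print.reg_path <- function(x, ...) {
  cat(sprintf("<reg_path> %d lambdas in [%.3g, %.3g], min CV error %.4g\n",
              length(x$lambdas), min(x$lambdas), max(x$lambdas),
              min(x$cv_error)))
  invisible(x)
}
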