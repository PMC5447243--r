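# WLS, adaptive weights, group lasso, approximate LOO-CV, lambda selection.

# A well-conditioned 9-column design in the package's column layout.
random_design <- function(n, seed = 1) {
  set.seed(seed)
  d <- scale_unit_range(seq_len(n) / n)$scaled
  ang <- 2 * pi * (seq_len(n) %% 24) / 24
  r <- scale_unit_range(rnorm(n))$scaled
  g <- rep(c(0, 1), length.out = n)
  cbind(intercept = rep(1, n), age = d, clock_cos = cos(ang),
        clock_sin = sin(ang), response = r,
        age_clock_cos = d * cos(ang), age_clock_sin = d * sin(ang),
        age_response = d * r, genotype = g)
}

test_that("wls_fit recovers exact coefficients and obeys weighting identities", {
  X <- random_design(40, seed = 2)
  beta0 <- c(2, 1, -0.5, 0.3, 0.8, 0.1, -0.2, 0.4, -0.6)
  y <- as.numeric(X %*% beta0)
  expect_equal(unname(wls_fit(X, y)), beta0, tolerance = 1e-10)
  set.seed(3)
  y <- y + rnorm(40, 0, 0.5)
  expect_equal(wls_fit(X, y, rep(2, 40)), wls_fit(X, y), tolerance = 1e-10)
  # doubling a sample's weight is the same as duplicating the row
  w <- rep(1, 40); w[7] <- 2
  Xd <- rbind(X, X[7, ]); yd <- c(y, y[7])
  expect_equal(wls_fit(X, y, w), wls_fit(Xd, yd), tolerance = 1e-10)
})

test_that("wls_fit drops degenerate columns with zero coefficients", {
  X <- random_design(30, seed = 4)
  X[, "genotype"] <- 0
  y <- as.numeric(X %*% rep(1, 9)) # genotype contributes nothing
  beta <- wls_fit(X, y)
  expect_equal(unname(beta["genotype"]), 0)
  expect_equal(as.numeric(X %*% beta), y, tolerance = 1e-10)
})

test_that("adaptive_weights implements the stated group formulas", {
  z <- adaptive_weights(rep(1, 9))
  expect_equal(unclass(z)[c("age", "genotype")], c(age = 1, genotype = 1))
  expect_equal(unname(z[["response"]]), 7)
  expect_equal(unname(z[["age_response"]]), 7)
  expect_equal(unname(z[["clock"]]), 1 / 2)
  expect_equal(unname(z[["age_clock"]]), 1 / 2)
  bz <- rep(1, 9); bz[5] <- 0
  expect_equal(adaptive_weights(bz)[["response"]], Inf)
  b <- c(1, 0.5, 1.5, -2, 0.7, 0.2, 0.3, -0.4, 1.1)
  expect_equal(unclass(adaptive_weights(2 * b)), unclass(adaptive_weights(b)) / 4,
               tolerance = 1e-12)
})

test_that("group_lasso_fit reduces to WLS at lambda 0 and to the intercept at large lambda", {
  X <- random_design(60, seed = 5)
  set.seed(6)
  y <- as.numeric(X %*% c(3, 1, 0.6, -0.4, 0, 0, 0, 0, 0.5)) + rnorm(60, 0, 0.3)
  w <- runif(60, 0.5, 2)
  zeta <- adaptive_weights(wls_fit(X, y, w))
  expect_equal(group_lasso_fit(X, y, w, zeta, 0), wls_fit(X, y, w),
               tolerance = 1e-8)
  lmax <- fieldfit:::lambda_max(X, y, w, zeta)
  big <- group_lasso_fit(X, y, w, zeta, 10 * lmax)
  expect_equal(unname(big[1]), sum(w * y) / sum(w), tolerance = 1e-10)
  expect_true(all(big[-1] == 0))
})

test_that("group_lasso_fit matches an independent proximal-gradient oracle", {
  X <- random_design(50, seed = 7)
  set.seed(8)
  y <- as.numeric(X %*% c(2, 0.8, 1, -0.5, 0.6, 0, 0, 0, 0)) + rnorm(50, 0, 0.4)
  w <- rep(1, 50)
  zeta <- adaptive_weights(wls_fit(X, y, w))
  for (lam in c(0.05, 0.5, 3) * fieldfit:::lambda_max(X, y, w, zeta)) {
    fit <- group_lasso_fit(X, y, w, zeta, lam)
    oracle <- prox_gradient_oracle(X, y, w, zeta, lam)
    expect_equal(gl_objective(X, y, w, zeta, lam, fit),
                 gl_objective(X, y, w, zeta, lam, oracle), tolerance = 1e-8)
    expect_equal(unname(fit), unname(oracle), tolerance = 1e-5)
    expect_lt(kkt_check(X, y, w, zeta, lam, fit), 1e-8)
  }
})

test_that("clock pairs enter and leave together along the path", {
  X <- random_design(80, seed = 9)
  set.seed(10)
  y <- as.numeric(X %*% c(1, 0, 1.2, 0.9, 0, 0.4, -0.3, 0, 0)) + rnorm(80, 0, 0.5)
  zeta <- adaptive_weights(wls_fit(X, y))
  path <- group_lasso_path(X, y, NULL, zeta)
  cz <- path$coefficients[, "clock_cos"] == 0
  sz <- path$coefficients[, "clock_sin"] == 0
  expect_equal(cz, sz)
  dz <- path$coefficients[, "age_clock_cos"] == 0
  ez <- path$coefficients[, "age_clock_sin"] == 0
  expect_equal(dz, ez)
  # the number of active groups does not increase with lambda (ties allowed)
  expect_true(all(diff(path$n_active_groups) >= 0)) # lambdas are decreasing
})

test_that("approx_loocv reproduces the intercept-only closed form and brute-force refits", {
  set.seed(11)
  y <- rnorm(25, 3, 1)
  n <- length(y)
  cv <- approx_loocv(matrix(1, n, 1, dimnames = list(NULL, "intercept")),
                     y, mean(y))
  expect_equal(cv$cv_error, sum((y - mean(y))^2) * (n / (n - 1))^2 / n,
               tolerance = 1e-12)
  # zero residuals give (0, 0)
  X <- random_design(30, seed = 12)[, 1:4]
  yy <- as.numeric(X %*% c(1, 2, 3, 4))
  z <- approx_loocv(X, yy, c(1, 2, 3, 4))
  expect_equal(z$cv_error, 0)
  expect_equal(z$cv_se, 0)
})

test_that("approximate LOO-CV is within tolerance of exact refit LOO", {
  set.seed(13)
  worst30 <- 0
  for (k in 1:50) {
    n <- 30
    X <- cbind(intercept = rep(1, n), a = rnorm(n), b = rnorm(n), c = rnorm(n))
    y <- as.numeric(X %*% rnorm(4)) + rnorm(n, 0, 0.7)
    beta <- wls_fit(X, y)
    a <- approx_loocv(X, y, beta)
    b <- brute_loocv(X, y)
    worst30 <- max(worst30, abs(a$cv_error / b$cv_error - 1))
  }
  expect_lt(worst30, 0.05)
  n <- 200
  X <- cbind(intercept = rep(1, n), a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- as.numeric(X %*% rnorm(4)) + rnorm(n, 0, 0.7)
  a <- approx_loocv(X, y, wls_fit(X, y))
  b <- brute_loocv(X, y)
  expect_lt(abs(a$cv_error / b$cv_error - 1), 0.01)
  # weighted variant agrees with weighted refits
  w <- runif(n, 0.5, 2)
  aw <- approx_loocv(X, y, wls_fit(X, y, w), w)
  bw <- brute_loocv(X, y, w)
  expect_lt(abs(aw$cv_error / bw$cv_error - 1), 0.01)
})

test_that("select_lambda applies the 1-SE rule", {
  mk <- function(lambdas, cv, se) {
    structure(list(lambdas = lambdas, cv_error = cv,
                   cv_se = se, n_active_groups = integer(length(lambdas))),
              class = "reg_path")
  }
  expect_equal(select_lambda(mk(c(4, 3, 2, 1), rep(2, 4), rep(0.5, 4))), 4)
  expect_equal(select_lambda(mk(c(4, 3, 2, 1), c(1, 2, 3, 4), rep(1e-9, 4))), 4)
  expect_equal(select_lambda(mk(c(4, 3, 2, 1), c(4, 3, 2, 1), rep(1e-9, 4))), 1)
  expect_equal(select_lambda(mk(c(4, 3, 2, 1), c(5, 3, 2, 4), c(1, 1, 1.5, 1))), 3)
})

test_that("the selected model excludes irrelevant singletons on sparse truths", {
  # clock-only truth at N = 180, noise sd 0.3: age / response / genotype /
  # interaction singleton groups should be excluded in >= 90% of replicates
  n <- 180
  X <- random_design(n, seed = 14)
  excl <- 0L
  set.seed(15)
  for (k in 1:50) {
    y <- as.numeric(X %*% c(4, 0, 1, -0.7, 0, 0, 0, 0, 0)) + rnorm(n, 0, 0.3)
    zeta <- adaptive_weights(wls_fit(X, y))
    path <- group_lasso_path(X, y, NULL, zeta)
    beta <- path$coefficients[which(path$lambdas == select_lambda(path))[1], ]
    if (all(beta[c("age", "response", "age_response", "genotype")] == 0)) {
      excl <- excl + 1L
    }
  }
  expect_gte(excl, 45L)
})
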