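# Grid search, Nelder-Mead refinement, the per-gene pipeline, and
# cluster-based warm starting.

make_bench <- function(seed = 30) {
  ws <- synth_weather("2008-06-01", "2008-09-19", step = 600, seed = seed)
  samples <- sampling_design("4h", 2008)
  list(ws = ws, samples = samples)
}

test_that("grid_search is deterministic and breaks ties toward the first grid point", {
  b <- make_bench()
  y <- rep(5, 180) # constant: every setting ties at MSE ~ 0
  gs <- grid_search(y, NULL, b$samples, b$ws, factors = "temperature",
                    grid = test_grid())
  g <- test_grid()
  rp <- gs$response_params
  expect_equal(rp$period_p, g$period_p[1])
  expect_equal(rp$gamma_f, g$gamma_f[1])
  expect_equal(rp$gamma_g, g$gamma_g[1])
  expect_equal(rp$theta_g, g$theta_g[1])
  expect_equal(rp$psi, g$psi[1])
  expect_equal(rp$sign_rho, g$signs[1])
  gs2 <- grid_search(y, NULL, b$samples, b$ws, factors = "temperature",
                     grid = test_grid())
  expect_identical(gs$response_params, gs2$response_params)
})

test_that("grid_search finds a generating grid point on noiseless data", {
  b <- make_bench()
  g <- test_grid()
  cache <- new.env(parent = emptyenv())
  # resolve the actual threshold value the grid will use
  gf <- fieldfit:::grid_features(b$ws, b$samples$time, "temperature", g)
  target <- gf$params[200, ] # an arbitrary interior grid point
  rp_true <- response_params(target$period_p, target$threshold_theta,
                             target$gamma_f, target$gamma_g, target$theta_g,
                             target$psi, target$sign_rho, "temperature")
  r <- scale_unit_range(env_response_feature(b$ws, b$samples$time, rp_true))$scaled
  y <- 5 + 2 * r
  gs <- grid_search(y, NULL, b$samples, b$ws, factors = "temperature",
                    grid = g, cache = cache)
  expect_lt(gs$mse, 1e-10)
})

test_that("grid_search selects the generating factor over a noise factor", {
  b <- make_bench()
  g <- test_grid()
  cache <- new.env(parent = emptyenv())
  rp <- response_params(12, 27, -4, 6, -2, 0, 1, "temperature")
  r <- scale_unit_range(env_response_feature(b$ws, b$samples$time, rp))$scaled
  hits <- 0L
  set.seed(31)
  for (k in 1:20) {
    y <- 5 + 2 * r + rnorm(180, 0, 0.2)
    gs <- grid_search(y, NULL, b$samples, b$ws,
                      factors = c("wind", "temperature"), grid = g,
                      cache = cache)
    if (gs$factor == "temperature") hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("refine_nelder_mead improves smooth objectives and never returns worse", {
  # quadratic bowl in (theta, gamma_f)
  obj <- function(rp) (rp$threshold_theta - 26)^2 + (rp$gamma_f - 1)^2
  init <- response_params(6, 24, -2, 0, 0, 12, 1, "temperature")
  out <- refine_nelder_mead(init, obj, maxit = 2000L, reltol = 1e-10)
  expect_lt(abs(out$threshold_theta - 26), 1e-3)
  expect_lt(abs(out$gamma_f - 1), 1e-3)
  expect_lte(attr(out, "objective"), obj(init))
  at_opt <- response_params(6, 26, 1, 0, 0, 12, 1, "temperature")
  out2 <- refine_nelder_mead(at_opt, obj)
  expect_lte(attr(out2, "objective"), obj(at_opt) + 1e-12)
  expect_error(refine_nelder_mead(init, function(rp) NaN), "not finite")
})

test_that("fit_gene recovers a noiseless clock gene exactly", {
  b <- make_bench()
  tod <- (as.numeric(b$samples$time) %% 86400) / 3600
  y <- 5 + 2 * cos(2 * pi * (tod - 8) / 24)
  m <- fit_gene(y, NULL, b$samples, b$ws,
                fit_options(factors = "temperature", grid = test_grid()),
                gene_id = "clock8")
  expect_equal(sort(fieldfit:::nonzero_groups(coef(m))), "clock")
  expect_lt(abs(phase_of(m) - 8), 0.1)
  expect_equal(m$factor, "none")
  expect_null(m$response_params)
  expect_false(m$constant)
  # deterministic given data and options
  m2 <- fit_gene(y, NULL, b$samples, b$ws,
                 fit_options(factors = "temperature", grid = test_grid()),
                 gene_id = "clock8")
  expect_identical(coef(m), coef(m2))
  # training weighted MSE no worse than the constant model's
  expect_lte(m$mse_train, mean((y - mean(y))^2))
})

test_that("fit_gene calls most iid-noise genes constant", {
  b <- make_bench()
  opts <- fit_options(factors = "temperature", grid = test_grid())
  cache <- new.env(parent = emptyenv())
  set.seed(32)
  n_const <- 0L
  for (k in 1:25) {
    y <- rnorm(180, 5, 0.5)
    m <- suppressWarnings(fit_gene(y, NULL, b$samples, b$ws, opts,
                                   cache = cache))
    if (m$constant) n_const <- n_const + 1L
  }
  expect_gte(n_const, 20L) # >= 80%
})

test_that("fit_gene recovers a temperature-response gene from the truth library", {
  b <- make_bench()
  tl <- truth_library(seed = 33)
  i <- which(vapply(tl, function(e) identical(e$structure, "response"),
                    logical(1)))[1]
  sig <- truth_signals(tl[i], b$samples, b$ws)
  counts <- nb_counts(tl[i], b$samples, b$ws, seed = 34)
  y <- log2(counts[1, ] + 0.5)
  m <- suppressWarnings(fit_gene(y, NULL, b$samples, b$ws,
                                 fit_options(factors = "temperature"),
                                 gene_id = tl[[i]]$gene_id))
  expect_equal(m$factor, "temperature")
  expect_true("response" %in% fieldfit:::nonzero_groups(coef(m)))
})

test_that("affinity propagation recovers separable clusters and collapses duplicates", {
  set.seed(35)
  X <- rbind(matrix(rnorm(10 * 20, 0, 0.2), 10),
             matrix(rnorm(10 * 20, 5, 0.2), 10))
  ap <- affinity_propagation(X)
  expect_true(ap$converged)
  expect_equal(length(ap$exemplars), 2L)
  expect_equal(length(unique(ap$assignment[1:10])), 1L)
  expect_equal(length(unique(ap$assignment[11:20])), 1L)
  expect_false(ap$assignment[1] == ap$assignment[11])
  dup <- rbind(c(1, 2, 3), c(1, 2, 3))
  apd <- affinity_propagation(dup)
  expect_equal(length(unique(apd$assignment)), 1L)
})

test_that("cluster_fit assigns duplicated genes to one cluster with matching models", {
  b <- make_bench()
  tod <- (as.numeric(b$samples$time) %% 86400) / 3600
  set.seed(36)
  y <- 5 + 1.5 * cos(2 * pi * (tod - 10) / 24) + rnorm(180, 0, 0.2)
  Y <- rbind(g1 = y, g2 = y, g3 = 7 + rnorm(180, 0, 0.2))
  fit <- suppressWarnings(cluster_fit(Y, NULL, b$samples, b$ws,
                                      fit_options(factors = "temperature",
                                                  grid = test_grid())))
  expect_equal(fit$cluster$assignment[["g1"]], fit$cluster$assignment[["g2"]])
  expect_equal(coef(fit$models$g1), coef(fit$models$g2), tolerance = 1e-6)
  expect_equal(fit$diagnostics$n_grid_search, length(fit$cluster$exemplars))
})
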