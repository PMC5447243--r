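# File formats and workflow commands tying the modules together.

#' Read an expression or count matrix (TSV, genes as rows)
#'
#' First column `gene_id`, remaining columns one per sample.
#'
#' @param path TSV file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write an expression or count matrix (TSV, genes as rows)
#'
#' @param m matrix with gene rownames.
#' @param path output path.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample attribute table
#'
#' CSV with columns `sample_id`, `time` (ISO-8601), `age` (days after
#' transplanting) and `genotype` (0/1).
#'
#' @param path CSV file.
#' @return Data frame with parsed `time`.
#' @export
read_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "age", "genotype")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample table lacks column(s): ",
                         paste(miss, collapse = ", "))
  df$time <- as_time(df$time)
  if (!all(df$genotype %in% c(0, 1))) stop("genotype values must be 0 or 1")
  df
}

#' Write a sample attribute table
#' @param samples sample table.
#' @param path output CSV path.
#' @export
write_samples <- function(samples, path) {
  out <- samples
  out$time <- format(out$time, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

gene_model_to_list <- function(m) {
  list(
    gene_id = m$gene_id,
    factor = m$factor,
    response_params = if (is.null(m$response_params)) NULL else
      unclass(m$response_params),
    coefficients = as.list(m$coefficients),
    scale_specs = lapply(m$scale_specs, unclass),
    selected_lambda = m$selected_lambda,
    cv_error = m$cv_error,
    weights_used = m$weights_used,
    step = m$step
  )
}

#' Serialize fitted models to JSON-lines
#'
#' One JSON record per gene (id, factor, response parameters, coefficients
#' keyed by column role, scale specs, selected penalty, CV error).
#'
#' @param fit a `fieldfit_fit` or list of `fieldfit_gene`.
#' @param path output path.
#' @export
write_models <- function(fit, path) {
  models <- if (inherits(fit, "fieldfit_fit")) fit$models else fit
  con <- file(path, "w")
  on.exit(close(con))
  for (m in models) {
    writeLines(jsonlite::toJSON(gene_model_to_list(m), auto_unbox = TRUE,
                                digits = NA, null = "null"), con)
  }
  invisible(path)
}

#' Read fitted models from JSON-lines
#'
#' Restores the fields needed for prediction; fitted values and the
#' training response are not serialized.
#'
#' @param path JSON-lines file from [write_models()].
#' @return List of `fieldfit_gene` objects.
#' @export
read_models <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    rp <- NULL
    if (!is.null(x$response_params) && length(x$response_params)) {
      p <- x$response_params
      rp <- response_params(p$period_p, p$threshold_theta, p$gamma_f,
                            p$gamma_g, p$theta_g, p$psi, p$sign_rho, p$factor)
    }
    specs <- lapply(x$scale_specs, function(s) {
      structure(list(offset = s$offset, scale = s$scale,
                     degenerate = isTRUE(s$degenerate)), class = "scale_spec")
    })
    beta <- unlist(x$coefficients)
    structure(
      list(gene_id = x$gene_id, response_params = rp, factor = x$factor,
           coefficients = beta[design_roles()], scale_specs = specs,
           selected_lambda = x$selected_lambda, cv_error = x$cv_error,
           constant = all(beta[-1L] == 0),
           weights_used = isTRUE(x$weights_used), step = x$step,
           mse_train = NA_real_, fitted = NULL, y = NULL),
      class = "fieldfit_gene")
  })
}

#' Simulate a benchmark data set to disk
#'
#' Runs [simulate_benchmark()] and writes counts TSV, sample attribute
#' CSV, weather CSV and truth JSON under `out_dir`.
#'
#' @param out_dir output directory (created if needed).
#' @inheritParams simulate_benchmark
#' @return Invisibly, the list from [simulate_benchmark()].
#' @export
cmd_simulate <- function(out_dir, design_id = "4h", year = 2008,
                         constant_genes = 200L, seed = 1L, ws = NULL,
                         step = 600) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_benchmark(design_id, year, constant_genes, seed, ws, step)
  write_expression(sim$counts, file.path(out_dir, "counts.tsv"))
  write_samples(sim$samples[c("sample_id", "time", "age", "genotype")],
                file.path(out_dir, "samples.csv"))
  write_weather(sim$weather, file.path(out_dir, "weather.csv"))
  truth_json <- lapply(sim$truth, function(e) {
    e$response$rp <- if (!is.null(e$response)) unclass(e$response$rp)
    e
  })
  jsonlite::write_json(truth_json, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(sim)
}

#' Fit models for a data set on disk
#'
#' Reads the expression/count matrix, sample table and weather CSV, fits
#' every gene (full or cluster-based optimization) and writes the models
#' as JSON-lines. Count data (`kind = "rnaseq"`) is converted to log-cpm
#' with voom-style precision weights first; microarray data is used as-is,
#' unweighted.
#'
#' @param expression_path,samples_path,weather_path input files.
#' @param out_path output JSON-lines path.
#' @param kind `"microarray"` (log2 intensities) or `"rnaseq"` (counts).
#' @param cluster use cluster-based optimization.
#' @param options a [fit_options()].
#' @return The `fieldfit_fit`, invisibly.
#' @export
cmd_fit <- function(expression_path, samples_path, weather_path, out_path,
                    kind = c("microarray", "rnaseq"), cluster = FALSE,
                    options = fit_options()) {
  kind <- match.arg(kind)
  Y <- read_expression(expression_path)
  samples <- read_samples(samples_path)
  if (!identical(colnames(Y), samples$sample_id)) {
    stop("sample ids of the expression matrix and attribute table differ")
  }
  ws <- load_weather(weather_path)
  w <- NULL
  if (kind == "rnaseq") {
    vw <- voom_weights(Y, samples$time)
    Y <- vw$log_cpm
    w <- vw$weights
  }
  fit <- if (cluster) cluster_fit(Y, w, samples, ws, options)
  else fit_genes(Y, w, samples, ws, options)
  write_models(fit, out_path)
  invisible(fit)
}

#' Predict expression for new samples from serialized models
#'
#' @param models_path JSON-lines models file.
#' @param samples_path sample attribute CSV.
#' @param weather_path weather CSV (needed if any model has a response).
#' @param out_path output TSV of gene x sample predictions.
#' @return The prediction matrix, invisibly.
#' @export
cmd_predict <- function(models_path, samples_path, weather_path = NULL,
                        out_path = NULL) {
  models <- read_models(models_path)
  samples <- read_samples(samples_path)
  ws <- if (!is.null(weather_path)) load_weather(weather_path) else NULL
  for (m in models) {
    if (!is.null(m$response_params) &&
        (is.null(ws) || !m$response_params$factor %in% names(ws$values))) {
      stop("weather attribute '", m$response_params$factor,
           "' required by model ", m$gene_id, " is unavailable")
    }
  }
  out <- t(vapply(models, predict_expression, numeric(nrow(samples)),
                  samples = samples, ws = ws))
  rownames(out) <- vapply(models, `[[`, "", "gene_id")
  colnames(out) <- samples$sample_id
  if (!is.null(out_path)) write_expression(out, out_path)
  invisible(out)
}

#' Read a run configuration file
#'
#' YAML (or JSON) configuration mapping onto [fit_options()] plus workflow
#' flags. Recognized keys: `factors`, `step`, `nm_maxit`, `nm_reltol`,
#' `nlambda`, `lambda_min_ratio`, `tol`, `grid` (a mapping of
#' [grid_spec()] arguments), `cluster` (logical), `kind`
#' (microarray/rnaseq) and `seed`. Unspecified keys keep their defaults.
#'
#' @param path YAML or JSON file.
#' @return List with `options` (a [fit_options()]), `cluster`, `kind`,
#'   `seed`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("[.]json$", path)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configuration requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  }
  grid <- if (is.null(cfg$grid)) grid_spec() else do.call(grid_spec, cfg$grid)
  opt_args <- cfg[intersect(names(cfg), c("factors", "step", "nm_maxit",
                                          "nm_reltol", "nlambda",
                                          "lambda_min_ratio", "tol"))]
  opt_args$grid <- grid
  list(
    options = do.call(fit_options, opt_args),
    cluster = isTRUE(cfg$cluster),
    kind = cfg$kind %||% "microarray",
    seed = cfg$seed %||% 1L
  )
}
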