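# S3 methods for fitted gene models and model collections.

#' @export
print.fieldfit_gene <- function(x, ...) {
  cat(sprintf("<fieldfit_gene> %s: %s\n", x$gene_id,
              if (x$constant) "constant model" else
                paste("groups:", paste(nonzero_groups(x$coefficients),
                                       collapse = ", "))))
  cat(sprintf("  factor: %s | lambda* = %.4g | CV error = %.4g\n",
              x$factor, x$selected_lambda, x$cv_error))
  invisible(x)
}

#' @export
summary.fieldfit_gene <- function(object, ...) {
  x <- object
  cat(sprintf("Gene %s (%sweighted fit, N = %d)\n", x$gene_id,
              if (x$weights_used) "" else "un", length(x$y)))
  cat(sprintf("  training weighted MSE: %.4g | CV error: %.4g (+/- %.2g)\n",
              x$mse_train, x$cv_error, x$cv_se))
  cat("  coefficients:\n")
  print(round(x$coefficients, 5))
  if (!is.null(x$response_params)) print(x$response_params)
  clk <- x$coefficients[c("clock_cos", "clock_sin")]
  if (any(clk != 0)) {
    cat(sprintf("  clock phase: %.2f h (amplitude %.3g)\n",
                phase_of(x), sqrt(sum(clk^2))))
  }
  invisible(x)
}

#' @export
coef.fieldfit_gene <- function(object, ...) object$coefficients

#' @export
fitted.fieldfit_gene <- function(object, ...) object$fitted

#' @export
residuals.fieldfit_gene <- function(object, ...) object$y - object$fitted

#' @export
predict.fieldfit_gene <- function(object, samples = NULL, ws = NULL, ...) {
  if (is.null(samples)) return(object$fitted)
  predict_expression(object, samples, ws)
}

#' Plot a fitted gene model
#'
#' Two panels: observed versus fitted expression over sampling time, and
#' (when the model has a response term) the reconstructed response curve
#' over the factor's range.
#'
#' @param x a `fieldfit_gene`.
#' @param samples optional sample table used for the time axis.
#' @param ... passed to `plot`.
#' @export
plot.fieldfit_gene <- function(x, samples = NULL, ...) {
  has_resp <- !is.null(x$response_params)
  op <- graphics::par(mfrow = c(1L, if (has_resp) 2L else 1L))
  on.exit(graphics::par(op))
  idx <- seq_along(x$y)
  xaxis <- if (!is.null(samples)) as_time(samples$time) else idx
  graphics::plot(xaxis, x$y, pch = 16, cex = 0.6, col = "grey40",
                 xlab = if (is.null(samples)) "sample" else "time",
                 ylab = "expression (log2)",
                 main = x$gene_id, ...)
  graphics::points(xaxis, x$fitted, pch = 16, cex = 0.6, col = "firebrick")
  graphics::legend("topright", legend = c("observed", "fitted"),
                   col = c("grey40", "firebrick"), pch = 16, bty = "n")
  if (has_resp) {
    th <- x$response_params$threshold_theta
    grid <- seq(th - 10, th + 10, length.out = 200L)
    graphics::plot(grid, response_curve(x, grid), type = "l",
                   xlab = x$response_params$factor, ylab = "response",
                   main = sprintf("response (%s)", x$factor))
    graphics::abline(v = th, lty = 2, col = "grey60")
  }
  invisible(x)
}

#' @export
print.fieldfit_fit <- function(x, ...) {
  n <- length(x$models)
  ncon <- sum(vapply(x$models, `[[`, logical(1L), "constant"))
  cat(sprintf("<fieldfit_fit> %d genes (%d constant)\n", n, ncon))
  if (!is.null(x$cluster)) {
    cat(sprintf("  cluster-based fit: %d exemplars\n",
                length(x$cluster$exemplars)))
  }
  invisible(x)
}

#' @export
summary.fieldfit_fit <- function(object, ...) {
  facs <- vapply(object$models, `[[`, "", "factor")
  cat(sprintf("Fitted models for %d genes\n", length(object$models)))
  print(table(factor = facs))
  cv <- vapply(object$models, `[[`, numeric(1L), "cv_error")
  cat(sprintf("CV error: median %.4g (range %.4g - %.4g)\n",
              stats::median(cv), min(cv), max(cv)))
  invisible(object)
}

#' @export
coef.fieldfit_fit <- function(object, ...) {
  t(vapply(object$models, `[[`, numeric(9L), "coefficients"))
}

#' @export
predict.fieldfit_fit <- function(object, samples = NULL, ws = NULL, ...) {
  if (is.null(samples)) {
    return(t(vapply(object$models, fitted, numeric(length(object$models[[1L]]$y)))))
  }
  out <- t(vapply(object$models, predict_expression,
                  numeric(nrow(samples)), samples = samples, ws = ws))
  colnames(out) <- samples$sample_id
  out
}
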