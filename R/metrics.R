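# Prediction-error metrics and normal fits of error distributions.

#' Prediction-error metrics
#'
#' Mean absolute error, root-mean-square error and the Pearson correlation
#' between predictions and reference values. With fewer than two points or
#' zero variance in either vector the correlation is undefined and reported
#' as `NA` with `pearson_defined = FALSE`; MAE and RMSE are still returned.
#'
#' @param pred Numeric vector of predictions.
#' @param ref Numeric vector of reference values, same length.
#' @return An object of class `metrics_report`: list with `mae`, `rmse`
#'   (property units), `pearson_r`, `r_squared` (unitless), `n` and
#'   `pearson_defined`.
#' @export
error_metrics <- function(pred, ref) {
  if (length(pred) != length(ref)) {
    stop("pred and ref lengths differ (", length(pred), " vs ", length(ref), ")")
  }
  if (length(pred) == 0) stop("need at least one value")
  d <- pred - ref
  mae <- mean(abs(d))
  rmse <- sqrt(mean(d^2))
  defined <- length(pred) >= 2 &&
    stats::sd(pred) > 0 && stats::sd(ref) > 0
  r <- if (defined) stats::cor(pred, ref) else NA_real_
  structure(list(mae = mae, rmse = rmse, pearson_r = r,
                 r_squared = if (defined) r^2 else NA_real_,
                 n = length(pred), pearson_defined = defined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 6, ...) {
  cat(sprintf("n = %d  MAE = %.*g  RMSE = %.*g  r = %s  r^2 = %s\n",
              x$n, digits, x$mae, digits, x$rmse,
              if (x$pearson_defined) sprintf("%.*g", digits, x$pearson_r) else "undefined",
              if (x$pearson_defined) sprintf("%.*g", digits, x$r_squared) else "undefined"))
  invisible(x)
}

#' Format metrics reports as a summary table
#'
#' @param reports Named list of `metrics_report` objects (e.g. per element).
#' @return A data.frame with one row per report.
#' @export
metrics_table <- function(reports) {
  do.call(rbind, lapply(names(reports), function(nm) {
    m <- reports[[nm]]
    data.frame(group = nm, n = m$n, mae = m$mae, rmse = m$rmse,
               pearson_r = m$pearson_r, r_squared = m$r_squared,
               stringsAsFactors = FALSE)
  }))
}

#' Maximum-likelihood normal fit of an error sample
#'
#' Returns the parameters of the normal distribution fitted to a sample of
#' prediction errors: the sample mean and, under the default
#' maximum-likelihood convention, the population (1/n) standard deviation.
#' The per-element defaults shipped with the package were obtained from
#' fits of this kind to validation-set errors.
#'
#' @param errors Numeric vector of errors, length >= 2.
#' @param sd_convention `"ml"` (1/n, default) or `"unbiased"` (1/(n-1)).
#' @return Named numeric vector `c(mu = ..., sigma = ...)`.
#' @export
fit_error_distribution <- function(errors, sd_convention = c("ml", "unbiased")) {
  sd_convention <- match.arg(sd_convention)
  n <- length(errors)
  if (n < 2) stop("need at least 2 errors to fit a distribution")
  mu <- mean(errors)
  ss <- sum((errors - mu)^2)
  sigma <- sqrt(ss / if (sd_convention == "ml") n else n - 1)
  c(mu = mu, sigma = sigma)
}

#' Binned counts of an error distribution
#'
#' Histogram export for plotting error distributions alongside their
#' normal fits.
#'
#' @param errors Numeric vector of errors.
#' @param breaks Number of bins or a break vector (passed to [hist()]).
#' @return A data.frame with columns `mid`, `count`, `density`.
#' @export
error_histogram <- function(errors, breaks = 50) {
  h <- graphics::hist(errors, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, count = h$counts, density = h$density)
}
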