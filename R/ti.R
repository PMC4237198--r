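#' Per-lambda derivative series for thermodynamic integration
#'
#' @param lambdas strictly increasing coupling-parameter grid with first
#'   value 0 and last value 1
#' @param values per-lambda ensemble averages of dH/dlambda, kJ/mol
#' @param errors optional per-lambda statistical errors, kJ/mol
#' @param configs optional list (one element per lambda) of lists of
#'   \code{solute_structure} configuration snapshots
#' @return object of class \code{lambda_series}
#' @export
lambda_series <- function(lambdas, values, errors = NULL, configs = NULL) {
  stopifnot(length(lambdas) == length(values),
            all(diff(lambdas) > 0),
            abs(lambdas[1]) < 1e-12,
            abs(lambdas[length(lambdas)] - 1) < 1e-12)
  if (!is.null(errors)) stopifnot(length(errors) == length(values),
                                  all(errors >= 0))
  if (!is.null(configs)) stopifnot(length(configs) == length(lambdas))
  structure(list(lambdas = as.numeric(lambdas), values = as.numeric(values),
                 errors = errors, configs = configs),
            class = "lambda_series")
}

#' @export
print.lambda_series <- function(x, ...) {
  cat(sprintf("<lambda_series> %d points on [0,1], trapezoid integral %.4f kJ/mol\n",
              length(x$lambdas), sum(trapezoid_weights(x$lambdas) * x$values)))
  invisible(x)
}

trapezoid_weights <- function(lambdas) {
  n <- length(lambdas)
  if (n < 2) stop("need at least 2 lambda points")
  dl <- diff(lambdas)
  w <- numeric(n)
  w[1] <- dl[1] / 2
  w[n] <- dl[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dl[-(n - 1)] + dl[-1]) / 2
  w
}

#' Trapezoidal thermodynamic integration
#'
#' Integrates per-lambda ensemble averages of dH/dlambda over the coupling
#' parameter with the trapezoidal rule.  The statistical error is the
#' trapezoidal combination of the per-lambda errors (errors integrate like
#' the values; they are combined in quadrature since block-averaged
#' per-lambda estimates are independent).
#'
#' @param series a \code{lambda_series}
#' @return object of class \code{ti_result} with fields \code{value},
#'   \code{error}, \code{n_lambda}, \code{method}
#' @export
#' @examples
#' trapezoid_ti(synth_lambda_series(-100))$value  # -100
trapezoid_ti <- function(series) {
  stopifnot(inherits(series, "lambda_series"))
  w <- trapezoid_weights(series$lambdas)
  value <- sum(w * series$values)
  error <- if (is.null(series$errors)) NA_real_
           else sqrt(sum((w * series$errors)^2))
  structure(list(value = value, error = error,
                 n_lambda = length(series$lambdas), method = "trapezoid"),
            class = "ti_result")
}

#' @export
print.ti_result <- function(x, ...) {
  cat(sprintf("<ti_result> %.4f %s kJ/mol (%s, %d lambda points)\n", x$value,
              if (is.na(x$error)) "" else sprintf("+/- %.4f", x$error),
              x$method, x$n_lambda))
  invisible(x)
}

#' Block-averaging statistical error of a correlated time series
#'
#' Standard error of block means for a schedule of block sizes (powers of
#' two).  As blocks grow, the estimate rises and plateaus once the block
#' length exceeds the correlation time; the plateau value (first window
#' where successive estimates agree within 5 percent) is returned, or the
#' largest-block estimate if no plateau is detected.
#'
#' @param samples numeric time series
#' @param min_blocks smallest number of blocks to retain (default 4)
#' @param plateau_rtol relative change defining the plateau (default 0.05)
#' @return standard-error estimate (same units as \code{samples})
#' @export
block_average_error <- function(samples, min_blocks = 4,
                                plateau_rtol = 0.05) {
  n <- length(samples)
  if (n < 16) stop("need at least 16 samples for block averaging")
  if (stats::sd(samples) == 0) return(0)
  sizes <- 2^(0:floor(log2(n / min_blocks)))
  est <- vapply(sizes, function(b) {
    nb <- n %/% b
    bm <- colMeans(matrix(samples[seq_len(nb * b)], nrow = b))
    stats::sd(bm) / sqrt(nb)
  }, numeric(1))
  for (k in seq_along(est)[-1]) {
    if (abs(est[k] - est[k - 1]) <= plateau_rtol * est[k]) return(est[k])
  }
  est[length(est)]
}
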