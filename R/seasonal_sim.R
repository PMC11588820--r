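#' Specification of a simulated seasonal abundance curve
#'
#' @param k_max Number of time units in the series, integer `>= 2`.
#' @param N Initial (mean) population size, positive. Visualisation only:
#'   no power or sample-size output depends on it.
#' @param noise Seasonal noise variance (count squared), `>= 0`. Set to 0 to
#'   see the noiseless seasonal signal.
#' @param seed Integer random seed; the same seed and parameters reproduce
#'   the identical curve.
#' @return An object of class `seasonal_curve_spec`.
#' @export
seasonal_curve_spec <- function(k_max, N, noise, seed) {
  check_count(k_max, "k_max", min = 2)
  check_scalar(N, "N")
  if (N <= 0) stop("'N' must be > 0", call. = FALSE)
  check_scalar(noise, "noise")
  if (noise < 0) stop("'noise' must be >= 0", call. = FALSE)
  check_count(seed, "seed", min = 0)
  structure(list(k_max = k_max, N = N, noise = noise, seed = as.integer(seed)),
            class = "seasonal_curve_spec")
}

#' Simulate a seasonal population curve
#'
#' Draws one realisation of a stationary Gaussian process of length `k_max`
#' with mean `N`, marginal variance `noise`, and lag-`l` correlation
#' `rho^(l^theta)` (the lag-generalised dampened AR law), truncated at zero
#' since populations are counts. The curve is a visual elicitation aid for
#' choosing `rho` and `theta` — larger `rho` smooths the series, larger
#' `theta` roughens it — not an inference engine; nothing computed from it
#' feeds the power analysis.
#'
#' The correlation matrix is factored by Cholesky with an escalating
#' diagonal jitter (1e-10 to 1e-4 of the marginal variance) when it is
#' numerically semi-definite; if every jitter fails a numerical error with
#' diagnostics is raised.
#'
#' @param spec A [seasonal_curve_spec()].
#' @param model A [seasonal_model()].
#' @return A `seasonal_curve` data frame with columns `time` (1..k_max) and
#'   `population` (non-negative).
#' @examples
#' curve <- simulate_seasonal_curve(
#'   seasonal_curve_spec(k_max = 30, N = 100, noise = 2, seed = 2),
#'   seasonal_model(rho = 0.5, theta = 1))
#' head(curve)
#' @export
simulate_seasonal_curve <- function(spec, model) {
  stopifnot(inherits(spec, "seasonal_curve_spec"),
            inherits(model, "seasonal_model"))
  kk <- spec$k_max
  if (spec$noise == 0) {
    out <- data.frame(time = seq_len(kk), population = rep(spec$N, kk))
    class(out) <- c("seasonal_curve", "data.frame")
    return(out)
  }
  lags <- abs(outer(seq_len(kk), seq_len(kk), "-"))
  corr <- matrix(lag_correlation(model, as.vector(lags)), kk, kk)
  cov <- spec$noise * corr
  cf <- NULL
  for (jit in c(0, 10^seq(-10, -4))) {
    cf <- tryCatch(chol(cov + diag(jit * spec$noise, kk)),
                   error = function(e) NULL)
    if (!is.null(cf)) break
  }
  if (is.null(cf)) {
    stop("seasonal correlation matrix is not positive definite even after ",
         "jitter (rho = ", model$rho, ", theta = ", model$theta,
         ", k_max = ", kk, ")", call. = FALSE)
  }
  # seed the draw without disturbing the caller's RNG stream
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  z <- stats::rnorm(kk)
  values <- pmax(0, spec$N + drop(crossprod(cf, z)))
  out <- data.frame(time = seq_len(kk), population = values)
  class(out) <- c("seasonal_curve", "data.frame")
  out
}
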