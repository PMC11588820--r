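#' Dampened autoregressive seasonal correlation model
#'
#' Constructs the two-parameter correlation law used throughout the package:
#' the correlation between two measurements separated by a lag `l` (in survey
#' time units) is `rho^(l^theta)`. `rho` is the base seasonal correlation
#' between successive values; `theta` dampens (`theta > 1`) or stretches
#' (`theta < 1`) the decay with increasing lag. `theta = 0` gives compound
#' symmetry: every pair of measurements correlates at `rho`, which is how a
#' directly estimated autocorrelation-function (ACF) value is entered.
#'
#' @param rho Seasonal correlation, a single number in `[0, 1)`. `rho = 1`
#'   is rejected rather than clamped.
#' @param theta Dampening exponent, a single non-negative number.
#'
#' @return An object of class `seasonal_model` with elements `rho` and
#'   `theta`.
#' @examples
#' m <- seasonal_model(rho = 0.5, theta = 1)
#' dampened_ar_correlation(m, k = 3) # 0.25
#' @seealso [dampened_ar_correlation()], [lag_correlation()]
#' @export
seasonal_model <- function(rho, theta) {
  check_scalar(rho, "rho")
  check_scalar(theta, "theta")
  if (rho < 0 || rho >= 1) {
    stop("'rho' must satisfy 0 <= rho < 1 (got ", format(rho), ")",
         call. = FALSE)
  }
  if (theta < 0) {
    stop("'theta' must be >= 0 (got ", format(theta), ")", call. = FALSE)
  }
  structure(list(rho = rho, theta = theta), class = "seasonal_model")
}

#' @export
print.seasonal_model <- function(x, ...) {
  cat("Dampened AR seasonal correlation: rho =", format(x$rho),
      ", theta =", format(x$theta), "\n")
  invisible(x)
}

#' Correlation among k repeated measurements
#'
#' Evaluates the dampened autoregressive law at the lag spanned by a design
#' with `k` repeated measurements, `rho^((k - 1)^theta)`. A single
#' measurement (`k = 1`) has no between-measurement correlation and returns
#' 1 by the lag-0 convention; the repeated-measures sample-size formula
#' multiplies it by `(k - 1) = 0`, so the convention is inert there.
#'
#' @param model A [seasonal_model()].
#' @param k Number of repeated measurements, an integer `>= 1` (vectorised).
#'
#' @return Correlation value(s) in `[0, 1]`.
#' @examples
#' dampened_ar_correlation(seasonal_model(0.7, 0.5), k = 10) # 0.7^3
#' # ACF mode: theta = 0 returns rho for any k >= 2
#' dampened_ar_correlation(seasonal_model(0.2, 0), k = 7)
#' @export
dampened_ar_correlation <- function(model, k) {
  stopifnot(inherits(model, "seasonal_model"))
  check_count(k, "k", min = 1)
  lag_correlation(model, k - 1)
}

#' Correlation at an arbitrary lag
#'
#' The lag-generalised form `rho^(l^theta)` for any non-negative real lag
#' `l`, used by the design optimiser (where the lag is the spacing between
#' visits) and by the seasonal curve simulator (integer lags of the
#' stationary process). `l = 0` returns 1 regardless of `theta` (lag-0
#' correlation), and `theta = 0` with `l > 0` returns `rho`.
#'
#' @param model A [seasonal_model()].
#' @param lag Non-negative lag(s) in survey time units; need not be integer.
#'
#' @return Correlation value(s) in `[0, 1]`.
#' @export
lag_correlation <- function(model, lag) {
  stopifnot(inherits(model, "seasonal_model"))
  if (!is.numeric(lag) || any(!is.finite(lag)) || any(lag < 0)) {
    stop("'lag' must be finite and >= 0", call. = FALSE)
  }
  out <- model$rho^(lag^model$theta)
  # 0^0 = 1 in R would give rho at lag 0; pin the lag-0 convention instead
  out[lag == 0] <- 1
  out
}

# --- input checking helpers (shared across modules) -------------------------

check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("'", name, "' must be a single finite number", call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < min) ||
      any(x != floor(x))) {
    stop("'", name, "' must be integer-valued and >= ", min, call. = FALSE)
  }
  invisible(x)
}
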