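#' Study specification for a surveillance power analysis
#'
#' Bundles every design parameter the closed-form sample sizes and the
#' optimiser consume: the minimum detectable difference (as a percentage of
#' the expected catch), the standard deviation(s) of the effect, the expected
#' per-trap catch(es), the amount of between-location clustering, and the
#' error rates.
#'
#' With two species the comparison is powered on the mean of the two standard
#' deviations and the mean of the two expected catches, so the effect size
#' stays comparable between one- and two-species designs.
#'
#' @param x Minimum detectable difference in percent (e.g. `20` for a 20%
#'   change in the expected catch). Must be positive.
#' @param sd_effect_1 Standard deviation of the effect for species 1, in
#'   count units. Positive.
#' @param m_1 Expected mosquitoes per location per measurement for species 1;
#'   integer `>= 1`.
#' @param rho_c Between-location clustering (intra-cluster correlation) in
#'   `[0, 1]`.
#' @param alpha Significance level; one of 0.1, 0.05, 0.025, 0.001.
#' @param power Target power `1 - beta`, in (0, 1).
#' @param n_species 1 or 2.
#' @param sd_effect_2,m_2 Species 2 values, required when `n_species = 2`.
#'
#' @return An object of class `study_spec`. Derived fields: `sd_eff` and
#'   `m_eff` (species means), and `delta = (x/100) * m_eff`, the absolute
#'   detectable difference in count units.
#' @examples
#' study_spec(x = 20, sd_effect_1 = 3, m_1 = 15, rho_c = 0.2,
#'            alpha = 0.05, power = 0.8)
#' @export
study_spec <- function(x, sd_effect_1, m_1, rho_c, alpha, power,
                       n_species = 1, sd_effect_2 = NULL, m_2 = NULL) {
  check_scalar(x, "x")
  if (x <= 0) stop("'x' (effect size, %) must be > 0", call. = FALSE)
  check_scalar(sd_effect_1, "sd_effect_1")
  if (sd_effect_1 <= 0) stop("'sd_effect_1' must be > 0", call. = FALSE)
  check_count(m_1, "m_1", min = 1)
  check_scalar(rho_c, "rho_c")
  if (rho_c < 0 || rho_c > 1) {
    stop("'rho_c' must lie in [0, 1]", call. = FALSE)
  }
  check_alpha(alpha)
  check_scalar(power, "power")
  if (power <= 0 || power >= 1) stop("'power' must be in (0, 1)", call. = FALSE)
  if (!n_species %in% c(1L, 2L)) {
    stop("'n_species' must be 1 or 2", call. = FALSE)
  }
  if (n_species == 2L) {
    if (is.null(sd_effect_2) || is.null(m_2)) {
      stop("two-species designs need 'sd_effect_2' and 'm_2'", call. = FALSE)
    }
    check_scalar(sd_effect_2, "sd_effect_2")
    if (sd_effect_2 <= 0) stop("'sd_effect_2' must be > 0", call. = FALSE)
    check_count(m_2, "m_2", min = 1)
  }
  sd_eff <- if (n_species == 2L) mean(c(sd_effect_1, sd_effect_2)) else sd_effect_1
  m_eff  <- if (n_species == 2L) mean(c(m_1, m_2)) else m_1
  structure(list(
    x = x, sd_effect_1 = sd_effect_1, sd_effect_2 = sd_effect_2,
    m_1 = m_1, m_2 = m_2, n_species = as.integer(n_species),
    rho_c = rho_c, alpha = alpha, power = power,
    sd_eff = sd_eff, m_eff = m_eff, delta = (x / 100) * m_eff
  ), class = "study_spec")
}

#' @export
print.study_spec <- function(x, ...) {
  cat("Surveillance study specification\n")
  cat("  effect size x:", x$x, "% -> absolute difference",
      format(x$delta), "per trap-visit\n")
  cat("  species:", x$n_species, " m:", x$m_1,
      if (x$n_species == 2L) paste0("/ ", x$m_2), " sd:", x$sd_effect_1,
      if (x$n_species == 2L) paste0("/ ", x$sd_effect_2), "\n")
  cat("  clustering rho_c:", x$rho_c, " alpha:", x$alpha,
      " power:", x$power, "\n")
  invisible(x)
}

#' Variance components of a clustered repeated-measures outcome
#'
#' @param sigma_b2 Between-sample-unit effect variance.
#' @param sigma2 Repeated-measurement error variance.
#' @param tau2 Between-cluster (location) variance.
#' @param sigma_T2 Total outcome variance; defaults to `tau2 + sigma2`
#'   (between-cluster plus within-cluster variance).
#'
#' @return An object of class `variance_components`.
#' @export
variance_components <- function(sigma_b2 = 0, sigma2 = 0, tau2 = 0,
                                sigma_T2 = NULL) {
  for (nm in c("sigma_b2", "sigma2", "tau2")) {
    v <- get(nm)
    check_scalar(v, nm)
    if (v < 0) stop("'", nm, "' must be >= 0", call. = FALSE)
  }
  if (is.null(sigma_T2)) sigma_T2 <- tau2 + sigma2
  check_scalar(sigma_T2, "sigma_T2")
  if (sigma_T2 < 0) stop("'sigma_T2' must be >= 0", call. = FALSE)
  if (tau2 > sigma_T2 + 1e-12) {
    stop("'tau2' cannot exceed 'sigma_T2'", call. = FALSE)
  }
  structure(list(sigma_b2 = sigma_b2, sigma2 = sigma2,
                 tau2 = tau2, sigma_T2 = sigma_T2),
            class = "variance_components")
}

#' Taylor's power law parameters
#'
#' The variance--mean relationship `variance = a * mean^b` describing the
#' spatial aggregation of a natural population. `b = 1` (with `a = 1`)
#' corresponds to a random, Poisson-distributed population; `b > 1` to
#' aggregation.
#'
#' @param a Scaling factor, positive.
#' @param b Aggregation exponent.
#' @param xbar Sample mean abundance, positive.
#' @return An object of class `taylor_params`.
#' @export
taylor_params <- function(a, b, xbar) {
  check_scalar(a, "a"); check_scalar(b, "b"); check_scalar(xbar, "xbar")
  if (a <= 0) stop("'a' must be > 0", call. = FALSE)
  if (xbar <= 0) stop("'xbar' must be > 0", call. = FALSE)
  structure(list(a = a, b = b, xbar = xbar), class = "taylor_params")
}

# sum of the two standard-normal percentiles entering every power formula
zq2 <- function(alpha, power) (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2

check_alpha <- function(alpha) {
  levels <- c(0.1, 0.05, 0.025, 0.001)
  check_scalar(alpha, "alpha")
  if (!any(abs(alpha - levels) < 1e-12)) {
    stop("'alpha' must be one of 0.1, 0.05, 0.025, 0.001", call. = FALSE)
  }
  invisible(alpha)
}

#' Classic t-test sample size
#'
#' The historical precision-based sample size `n = (t / (Z_alpha * x))^2`
#' for a standardized effect `x`, where `t` is the two-sided critical t
#' value at the chosen type-I level and `Z_alpha` the half-width standard
#' normal percentile. The t quantile's degrees of freedom depend on `n`
#' itself; the circularity is resolved as the smallest integer `n >= 2`
#' satisfying `n >= c * (t_{df(n)} / (Z_alpha * x))^2` (a naive fixed-point
#' iteration oscillates for large effects). The one-sample form uses
#' `c = 1, df = n - 1`; the two-sample, two-tailed variant (used for the
#' "total sampling for independent data" summary) uses `c = 2,
#' df = 2(n - 1)` and returns the per-group size.
#'
#' @param x_std Standardized effect size (difference / SD), positive.
#' @param alpha Significance level (0.1, 0.05, 0.025 or 0.001).
#' @param two_sample If `TRUE`, the per-group two-sample size.
#' @param max_n Search cap; exceeding it raises a convergence error.
#'
#' @return Integer sample size `>= 2`.
#' @examples
#' sample_size_ttest(0.5, 0.05)
#' @export
sample_size_ttest <- function(x_std, alpha, two_sample = FALSE, max_n = 1e7) {
  check_scalar(x_std, "x_std")
  if (x_std <= 0) stop("'x_std' must be > 0", call. = FALSE)
  check_alpha(alpha)
  mult <- if (two_sample) 2 else 1
  dfn <- if (two_sample) function(n) 2 * (n - 1) else function(n) n - 1
  za <- stats::qnorm(1 - alpha / 2)
  g <- function(n) mult * (stats::qt(1 - alpha / 2, dfn(n)) / (za * x_std))^2
  # g() is decreasing in n, so the minimal n with n >= g(n) is well defined;
  # walk from the normal approximation, then settle locally.
  n <- max(2, ceiling(mult / x_std^2))
  for (i in 1:100) {
    if (n >= g(n)) {
      while (n > 2 && (n - 1) >= g(n - 1)) n <- n - 1
      return(as.integer(n))
    }
    n_next <- min(ceiling(g(n)), max_n)
    if (n_next <= n) n_next <- n + 1
    n <- n_next
    if (n >= max_n) break
  }
  stop("sample_size_ttest did not converge within 100 iterations",
       call. = FALSE)
}

#' Taylor's power law sample size
#'
#' Scales the classic t-test sample size by the aggregation factor
#' `a * xbar^(b - 2)`: `n = a * xbar^(b - 2) * (t / (Z_alpha * x))^2`. With
#' `b = 2` the abundance cancels; with `a = 1, b = 1` (Poisson-random
#' spatial pattern, variance equal to the mean) it reduces to
#' `(1 / xbar) * (t / (Z_alpha * x))^2`. The circular t quantile is resolved
#' exactly as in [sample_size_ttest()].
#'
#' @param taylor A [taylor_params()].
#' @inheritParams sample_size_ttest
#' @return Integer sample size `>= 2`.
#' @export
sample_size_taylor <- function(taylor, x_std, alpha, max_n = 1e7) {
  stopifnot(inherits(taylor, "taylor_params"))
  check_scalar(x_std, "x_std")
  if (x_std <= 0) stop("'x_std' must be > 0", call. = FALSE)
  check_alpha(alpha)
  fac <- taylor$a * taylor$xbar^(taylor$b - 2)
  za <- stats::qnorm(1 - alpha / 2)
  g <- function(n) fac * (stats::qt(1 - alpha / 2, n - 1) / (za * x_std))^2
  n <- max(2, ceiling(fac / x_std^2))
  for (i in 1:100) {
    if (n >= g(n)) {
      while (n > 2 && (n - 1) >= g(n - 1)) n <- n - 1
      return(as.integer(n))
    }
    n_next <- min(ceiling(g(n)), max_n)
    if (n_next <= n) n_next <- n + 1
    n <- n_next
    if (n >= max_n) break
  }
  stop("sample_size_taylor did not converge within 100 iterations",
       call. = FALSE)
}

#' Repeated-measures (seasonal) sample size
#'
#' Number of sample units (locations) per group needed to detect an absolute
#' difference `x_abs` with `k` temporally correlated repeated measurements:
#'
#' `n = (2 / x_abs^2) * (sigma_b2 + (sigma2 / k) * (1 + (k - 1) * rho_delta))
#'      * (Z_{alpha/2} + Z_beta)^2`
#'
#' rounded up, with a floor of 2. At `k = 1` it reduces to the classic
#' two-sample normal formula; at `rho_delta = 0, sigma_b2 = 0` the required
#' size is inversely proportional to `k`.
#'
#' @param x_abs Detectable difference in outcome (count) units, positive.
#' @param vc A [variance_components()]; uses `sigma_b2` and `sigma2`.
#' @param k Number of repeated measurements, integer `>= 1`.
#' @param rho_delta Correlation among the repeated measurements, in `[0, 1]`.
#' @param alpha Significance level.
#' @param power Target power in (0, 1).
#' @param adjust If `TRUE`, pass the raw (unrounded) size through
#'   [small_sample_adjustment()] with `k` groups (requires `k >= 2`).
#'
#' @return Integer sample size `>= 2`.
#' @examples
#' vc <- variance_components(sigma_b2 = 1, sigma2 = 1)
#' sample_size_seasonal(1, vc, k = 4, rho_delta = 0.5,
#'                      alpha = 0.05, power = 0.8) # 26
#' @export
sample_size_seasonal <- function(x_abs, vc, k, rho_delta, alpha, power,
                                 adjust = FALSE) {
  check_scalar(x_abs, "x_abs")
  if (x_abs <= 0) stop("'x_abs' must be > 0", call. = FALSE)
  stopifnot(inherits(vc, "variance_components"))
  check_count(k, "k", min = 1)
  check_scalar(rho_delta, "rho_delta")
  if (rho_delta < 0 || rho_delta > 1) {
    stop("'rho_delta' must lie in [0, 1]", call. = FALSE)
  }
  check_alpha(alpha)
  check_scalar(power, "power")
  if (power <= 0 || power >= 1) stop("'power' must be in (0, 1)", call. = FALSE)
  raw <- (2 / x_abs^2) *
    (vc$sigma_b2 + (vc$sigma2 / k) * (1 + (k - 1) * rho_delta)) *
    zq2(alpha, power)
  if (raw > 1e9) {
    stop("required sample size exceeds 1e9; the effect is too small for ",
         "these variances", call. = FALSE)
  }
  if (adjust) {
    return(small_sample_adjustment(raw, k = k, alpha = alpha, power = power))
  }
  as.integer(max(2, ceiling(raw)))
}

#' Variance inflation factor (design effect) of clustered sampling
#'
#' `1 + (m - 1) * rho_c`: the factor by which the variance of an estimate is
#' inflated when `m` correlated units are sampled in each cluster instead of
#' `m` independent units.
#'
#' @param m Units per cluster, integer `>= 1`.
#' @param rho_c Intra-cluster correlation in `[0, 1]`.
#' @return Inflation factor `>= 1`.
#' @export
variance_inflation_factor <- function(m, rho_c) {
  check_count(m, "m", min = 1)
  check_scalar(rho_c, "rho_c")
  if (rho_c < 0 || rho_c > 1) stop("'rho_c' must lie in [0, 1]", call. = FALSE)
  1 + (m - 1) * rho_c
}

#' Intra-cluster correlation from variance components
#'
#' `rho_c = tau2 / sigma_T2`: the proportion of total outcome variance
#' attributable to differences between locations. 0 means all variation is
#' within locations (units independent within a location); 1 means units
#' within a location are identical.
#'
#' @param vc A [variance_components()]; uses `tau2` and `sigma_T2`.
#' @return Intra-cluster correlation in `[0, 1]`.
#' @export
intra_cluster_correlation <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  if (vc$sigma_T2 <= 0) {
    stop("degenerate variance: 'sigma_T2' must be > 0", call. = FALSE)
  }
  vc$tau2 / vc$sigma_T2
}

#' Cluster (number of locations) sample size
#'
#' Number of clusters (locations) per group needed to detect `x_abs` when
#' each cluster contributes `m` correlated units:
#'
#' `n_c = (2 / x_abs^2) * sigma_T2 * (1 + (m - 1) * rho_c)
#'        * (Z_{alpha/2} + Z_beta)^2`
#'
#' rounded up, floored at 2. The full sample size is `n_c * m`.
#'
#' @param x_abs Detectable difference in outcome units, positive.
#' @param sigma_T2 Total outcome variance, positive.
#' @param m Units per cluster, integer `>= 1`.
#' @param rho_c Intra-cluster correlation in `[0, 1]`.
#' @param alpha Significance level.
#' @param power Target power in (0, 1).
#' @return Integer number of clusters `>= 2`.
#' @examples
#' sample_size_cluster(1, 1, m = 15, rho_c = 0.2,
#'                     alpha = 0.05, power = 0.8) # 60
#' @export
sample_size_cluster <- function(x_abs, sigma_T2, m, rho_c, alpha, power) {
  check_scalar(x_abs, "x_abs")
  if (x_abs <= 0) stop("'x_abs' must be > 0", call. = FALSE)
  check_scalar(sigma_T2, "sigma_T2")
  if (sigma_T2 <= 0) stop("'sigma_T2' must be > 0", call. = FALSE)
  check_alpha(alpha)
  check_scalar(power, "power")
  if (power <= 0 || power >= 1) stop("'power' must be in (0, 1)", call. = FALSE)
  raw <- (2 / x_abs^2) * sigma_T2 * variance_inflation_factor(m, rho_c) *
    zq2(alpha, power)
  if (raw > 1e9) {
    stop("required number of clusters exceeds 1e9; the effect is too small ",
         "for these variances", call. = FALSE)
  }
  as.integer(max(2, ceiling(raw)))
}

#' Exact noncentral-F small-sample adjustment
#'
#' Adjusts a normal-approximation sample size for the case where the error
#' variance is estimated rather than known, using the exact distribution of
#' the one-way design test statistic. The effect size implied by the raw
#' size `n_raw` gives the noncentrality `lambda(n) = (n / n_raw) *
#' (Z_{alpha/2} + Z_beta)^2`; the test statistic is F with `k - 1` and
#' `k (n - 1)` degrees of freedom. The adjusted size is the smallest integer
#' `n >= 2` whose exact power reaches the target. It is not guaranteed to be
#' `>= ceiling(n_raw)`, but converges to it as `n_raw` grows (the F limit is
#' normal).
#'
#' @param n_raw Real-valued unadjusted sample size, positive.
#' @param k Number of groups (or repeated measurements treated as groups),
#'   integer `>= 2` (the F numerator has `k - 1` degrees of freedom).
#' @param alpha Significance level.
#' @param power Target power in (0, 1).
#' @param max_n Bounded-search cap; exceeding it raises a convergence error.
#' @return Adjusted integer sample size `>= 2`.
#' @export
small_sample_adjustment <- function(n_raw, k, alpha, power, max_n = 1e6) {
  check_scalar(n_raw, "n_raw")
  if (n_raw <= 0) stop("'n_raw' must be > 0", call. = FALSE)
  check_count(k, "k", min = 2)
  check_alpha(alpha)
  check_scalar(power, "power")
  if (power <= 0 || power >= 1) stop("'power' must be in (0, 1)", call. = FALSE)
  z2 <- zq2(alpha, power)
  pow_at <- function(n) {
    df1 <- k - 1
    df2 <- k * (n - 1)
    lambda <- (n / n_raw) * z2
    crit <- stats::qf(1 - alpha, df1, df2)
    stats::pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
  }
  # exact power is increasing in n: bracket upward then walk back
  n <- 2
  while (n < max_n && pow_at(n) < power) {
    n <- if (n < ceiling(n_raw)) ceiling(n_raw) else n * 2
  }
  if (pow_at(n) < power) {
    stop("small_sample_adjustment: no n <= ", max_n,
         " reaches the target power", call. = FALSE)
  }
  while (n > 2 && pow_at(n - 1) >= power) n <- n - 1
  as.integer(n)
}

#' Variance ratio of a correlated repeated-measures test
#'
#' Ratio of the variance of the test with `k` correlated repeated
#' measurements to the variance of an independent two-means test:
#'
#' `VR = (sigma_b2 + (sigma2 / k) * (1 + (k - 1) * rho_delta)) /
#'       (sigma_b2 + sigma2)`
#'
#' `1 - VR` is the variance reduction bought by the repeated measurements.
#' `k = 1` or `rho_delta = 1` give `VR = 1` (no reduction).
#'
#' @inheritParams sample_size_seasonal
#' @return The variance ratio, positive.
#' @export
variance_ratio <- function(vc, k, rho_delta) {
  stopifnot(inherits(vc, "variance_components"))
  check_count(k, "k", min = 1)
  check_scalar(rho_delta, "rho_delta")
  tot <- vc$sigma_b2 + vc$sigma2
  if (tot <= 0) {
    stop("degenerate variance: 'sigma_b2 + sigma2' must be > 0", call. = FALSE)
  }
  (vc$sigma_b2 + (vc$sigma2 / k) * (1 + (k - 1) * rho_delta)) / tot
}
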