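#' Between-visit lag of k visits within the survey horizon
#'
#' When `k` repeated visits are spread evenly over the seasonal design
#' horizon, the time difference between successive visits shrinks as `k`
#' grows. The horizon spans the `k_max + 1` time-unit boundaries of the
#' season and the lag is expressed on the sub-unit grid (quarter time
#' units, e.g. weeks when the survey unit is a month):
#' `lag = 4 * (k_max + 1) / k`. The dampened AR law evaluated at this lag
#' gives the correlation between successive measurements of a `k`-visit
#' design; denser visit schedules are more strongly correlated.
#'
#' @param k Number of repeated measurements, integer `>= 1` (vectorised).
#' @param k_max Seasonal length in survey time units, integer `>= 1`.
#' @return Positive lag(s) in sub-unit steps.
#' @export
visit_lag <- function(k, k_max) {
  check_count(k, "k", min = 1)
  check_count(k_max, "k_max", min = 1)
  4 * (k_max + 1) / k
}

# variance components the optimiser feeds to the repeated-measures formula:
# sigma_b^2 = sigma^2 = sd^2 * (1 - rho_c / 2), the mean of the total (sd^2)
# and within-location ((1 - rho_c) sd^2) variance; calibrated against the
# published design grid (see the methods vignette).
optimizer_vc <- function(spec) {
  s2 <- spec$sd_eff^2 * (1 - spec$rho_c / 2)
  variance_components(sigma_b2 = s2, sigma2 = s2)
}

# Eq-4 locations for each k on the 1..2*k_max grid, at an arbitrary power
seasonal_locations <- function(spec, model, k_max, power = spec$power) {
  vc <- optimizer_vc(spec)
  ks <- seq_len(2 * k_max)
  vapply(ks, function(k) {
    rd <- lag_correlation(model, visit_lag(k, k_max))
    tryCatch(
      sample_size_seasonal(spec$delta, vc, k, rd, spec$alpha, power),
      error = function(e) NA_integer_)
  }, integer(1))
}

# cluster-side matching target: full sample size n_c * m, with the paired
# design effect 1 + rho_c (two compared conditions per location)
cluster_target <- function(spec) {
  n_c <- sample_size_cluster(spec$delta, spec$sd_eff^2, m = 2,
                             rho_c = spec$rho_c,
                             alpha = spec$alpha, power = spec$power)
  list(n_c = n_c, target = n_c * spec$m_eff)
}

#' Optimal number of repeated measurements and locations
#'
#' Grid search over `k = 1 ... 2 * k_max` repeated measurements (sub-unit
#' visit frequencies are allowed, hence the doubled grid). For each `k` the
#' repeated-measures formula gives the locations `n(k)` required under the
#' seasonal correlation at that visit spacing; the cluster formula gives the
#' `k`-independent full sample size `n_c * m`. The optimum is the `k`
#' (searched from `k = 2`; a single visit cannot express seasonality)
#' minimising `|n(k) * k - n_c * m|`, ties broken towards the smallest `k`.
#' The reported number of locations is the smallest that reaches the
#' cluster-mandated full sample with `k*` visits, `ceiling(n_c * m / k*)`.
#'
#' @param spec A [study_spec()].
#' @param model A [seasonal_model()].
#' @param k_max Seasonal length in survey time units, integer `>= 1`.
#' @param cap Feasibility cap on total mosquitoes (`n(k) * k * m`); grid
#'   points above it are discarded and an all-infeasible grid is an error.
#'
#' @return A `design_point` list: `k`, `n_locations`, `effort`
#'   (`k * n_locations`), `objective` (the minimised matching gap), `n_c`,
#'   `target` (`n_c * m`), and the per-`k` grid as attribute `"grid"`.
#' @examples
#' spec <- study_spec(x = 20, sd_effect_1 = 3, m_1 = 15, rho_c = 0.2,
#'                    alpha = 0.05, power = 0.8)
#' optimize_design(spec, seasonal_model(0.1, 1), k_max = 10)
#' @export
optimize_design <- function(spec, model, k_max, cap = 1e6) {
  stopifnot(inherits(spec, "study_spec"), inherits(model, "seasonal_model"))
  check_count(k_max, "k_max", min = 1)
  nk <- seasonal_locations(spec, model, k_max)
  ks <- seq_len(2 * k_max)
  feasible <- !is.na(nk) & ks >= 2 & nk * ks * spec$m_eff <= cap
  if (!any(feasible)) {
    stop("infeasible design: every grid point exceeds the cap of ",
         format(cap), " mosquitoes", call. = FALSE)
  }
  ct <- cluster_target(spec)
  obj <- abs(nk * ks - ct$target)
  obj[!feasible] <- Inf
  k_star <- ks[which.min(obj)] # which.min takes the first = smallest k on ties
  n_star <- max(2L, as.integer(ceiling(ct$target / k_star)))
  out <- structure(list(
    k = k_star,
    n_locations = n_star,
    effort = k_star * n_star,
    objective = min(obj),
    n_c = ct$n_c,
    target = ct$target
  ), class = "design_point")
  attr(out, "grid") <- data.frame(k = ks, n_locations = nk,
                                  product = nk * ks, feasible = feasible)
  out
}

#' @export
print.design_point <- function(x, ...) {
  cat("Optimal surveillance design\n")
  cat("  repeated measurements k* :", x$k, "\n")
  cat("  locations n*             :", x$n_locations, "\n")
  cat("  sampling effort k* x n*  :", x$effort, "\n")
  cat("  cluster full sample n_c*m:", format(x$target), "\n")
  invisible(x)
}

#' Optimal locations across power levels and visit numbers
#'
#' The downloadable design table: for each power level (the eight standard
#' levels 60, 65, ..., 95 per cent plus the user's target, if different) and
#' each number of repeated measurements `k` on the `1 ... 2 * k_max` grid,
#' the number of locations required by the repeated-measures formula at
#' that `k`'s visit spacing.
#'
#' @inheritParams optimize_design
#' @return A `design_table` data frame: first column `power_percent`, then
#'   one integer column `k<j>` per grid point.
#' @export
power_sweep <- function(spec, model, k_max) {
  stopifnot(inherits(spec, "study_spec"), inherits(model, "seasonal_model"))
  check_count(k_max, "k_max", min = 1)
  default_levels <- seq(60, 95, by = 5)
  levels <- sort(unique(c(default_levels, 100 * spec$power)))
  cells <- t(vapply(levels,
                    function(p) seasonal_locations(spec, model, k_max,
                                                   power = p / 100),
                    integer(2 * k_max)))
  out <- data.frame(power_percent = levels, cells)
  names(out) <- c("power_percent", paste0("k", seq_len(2 * k_max)))
  class(out) <- c("design_table", "data.frame")
  out
}

#' Summary of the optimal design and its sampling totals
#'
#' Packages the optimal design with the total number of mosquitoes it
#' collects and the total required if every measurement were treated as
#' independent, plus the variance ratio of the correlated repeated-measures
#' test at the optimum.
#'
#' Totals: the correlated/clustered design collects
#' `n* x k* x m` mosquitoes. The independent baseline is the classic
#' two-sample normal sample size `n2 = 2 (sd / delta)^2 (Z_{alpha/2} +
#' Z_beta)^2` locations per group (the `k = 1` limit of the
#' repeated-measures formula); without the pooling of `m` units per
#' location-visit that the clustered analysis provides, each of the two
#' groups needs `n2 * m` independent measurement events of `m` mosquitoes:
#' `total_independent = 2 * n2 * m^2` (kept unrounded, as the ratio is the
#' quantity of interest). None of these quantities depends on the initial
#' population size `N` or on the random seed, which only affect the
#' visualised seasonal curve.
#'
#' @inheritParams optimize_design
#' @return A `design_summary` list: `optimal_k`, `optimal_n_locations`,
#'   `effort`, `total_sampling_correlated`, `total_sampling_independent`,
#'   `sampling_ratio_percent`, `variance_ratio`, `rho_delta_opt`.
#' @examples
#' spec <- study_spec(x = 20, sd_effect_1 = 3, m_1 = 15, rho_c = 0.2,
#'                    alpha = 0.05, power = 0.8)
#' summarize_design(spec, seasonal_model(rho = 0.2, theta = 0.1), k_max = 10)
#' @export
summarize_design <- function(spec, model, k_max, cap = 1e6) {
  opt <- optimize_design(spec, model, k_max, cap = cap)
  rd_opt <- lag_correlation(model, visit_lag(opt$k, k_max))
  vr <- variance_ratio(optimizer_vc(spec), opt$k, rd_opt)
  n2_raw <- 2 * (spec$sd_eff / spec$delta)^2 * zq2(spec$alpha, spec$power)
  total_corr <- opt$k * opt$n_locations * spec$m_eff
  total_indep <- 2 * n2_raw * spec$m_eff^2
  structure(list(
    optimal_k = opt$k,
    optimal_n_locations = opt$n_locations,
    effort = opt$effort,
    total_sampling_correlated = total_corr,
    total_sampling_independent = total_indep,
    sampling_ratio_percent = 100 * total_corr / total_indep,
    variance_ratio = vr,
    rho_delta_opt = rd_opt,
    design = opt
  ), class = "design_summary")
}

#' @export
print.design_summary <- function(x, ...) {
  cat("Power analysis summary\n")
  cat("  optimal repeated measurements :", x$optimal_k, "\n")
  cat("  optimal number of locations   :", x$optimal_n_locations, "\n")
  cat("  total sampling (correlated)   :",
      format(round(x$total_sampling_correlated)), "mosquitoes\n")
  cat("  total sampling (independent)  :",
      format(round(x$total_sampling_independent)), "mosquitoes\n")
  cat("  correlated / independent      :",
      sprintf("%.1f%%", x$sampling_ratio_percent), "\n")
  cat("  variance ratio (VR)           :",
      sprintf("%.3f (1 - VR = %.3f)", x$variance_ratio,
              1 - x$variance_ratio), "\n")
  invisible(x)
}
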