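# Independent brute-force oracles: direct scans over candidate sizes using
# base quantile functions only, kept free of the package's search logic.

oracle_ttest <- function(x, alpha, two_sample = FALSE) {
  za <- qnorm(1 - alpha / 2)
  mult <- if (two_sample) 2 else 1
  for (n in 2:100000) {
    df <- if (two_sample) 2 * (n - 1) else n - 1
    if (n >= mult * (qt(1 - alpha / 2, df) / (za * x))^2) return(n)
  }
  stop("oracle_ttest ran out of candidates")
}

oracle_taylor <- function(a, b, xbar, x, alpha) {
  za <- qnorm(1 - alpha / 2)
  fac <- a * xbar^(b - 2)
  for (n in 2:100000) {
    if (n >= fac * (qt(1 - alpha / 2, n - 1) / (za * x))^2) return(n)
  }
  stop("oracle_taylor ran out of candidates")
}

oracle_adjustment <- function(n_raw, k, alpha, power, n_max = 100000) {
  z2 <- (qnorm(1 - alpha / 2) + qnorm(power))^2
  for (n in 2:n_max) {
    df2 <- k * (n - 1)
    pw <- pf(qf(1 - alpha, k - 1, df2), k - 1, df2,
             ncp = (n / n_raw) * z2, lower.tail = FALSE)
    if (pw >= power) return(n)
  }
  stop("oracle_adjustment ran out of candidates")
}

# full-grid design search written from the primitive formulas, independent
# of optimize_design's code path
oracle_optimum <- function(x, sd, m, rho_c, alpha, power, rho, theta, k_max) {
  delta <- (x / 100) * m
  z2 <- (qnorm(1 - alpha / 2) + qnorm(power))^2
  s2 <- sd^2 * (1 - rho_c / 2)
  ks <- 1:(2 * k_max)
  nk <- sapply(ks, function(k) {
    lag <- 4 * (k_max + 1) / k
    rd <- if (lag == 0) 1 else rho^(lag^theta)
    max(2, ceiling((2 / delta^2) * (s2 + (s2 / k) * (1 + (k - 1) * rd)) * z2))
  })
  n_c <- max(2, ceiling((2 / delta^2) * sd^2 * (1 + rho_c) * z2))
  target <- n_c * m
  obj <- abs(nk * ks - target)
  obj[ks < 2] <- Inf
  k_star <- ks[which.min(obj)]
  list(k = k_star, n = max(2, ceiling(target / k_star)),
       objective = min(obj), target = target)
}

# Table 1 of the published worked examples: optimal designs on the
# (rho, theta) grid with rho_c = 0.2, power = 0.8, x = 20%, alpha = 0.05,
# one species, m = 15, sd = 3, k_max = 10.
published_design_grid <- function() {
  read.table(text = "
0.1 1.00 19 15 285
0.2 1.00 18 16 288
0.3 1.00 18 16 288
0.4 1.00 17 17 289
0.5 1.00 16 18 288
0.6 1.00 15 19 285
0.7 1.00 14 21 294
0.8 1.00 13 22 286
0.9 1.00 12 24 288
0.5 0.50 15 19 285
0.5 0.75 15 19 285
0.5 1.00 16 18 288
0.5 1.25 17 17 289
0.5 1.50 18 16 288
0.5 1.75 18 16 288
0.5 2.00 18 16 288
0.5 2.25 18 16 288
0.5 2.50 19 15 285
", col.names = c("rho", "theta", "k", "n_locations", "effort"))
}

reference_spec <- function(...) {
  args <- utils::modifyList(
    list(x = 20, sd_effect_1 = 3, m_1 = 15, rho_c = 0.2,
         alpha = 0.05, power = 0.8),
    list(...))
  do.call(study_spec, args)
}
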