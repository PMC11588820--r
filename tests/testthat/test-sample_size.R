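test_that("t-test sample size matches the brute-force oracle", {
  grid <- expand.grid(x = c(0.1, 0.25, 0.5, 1, 2, 5),
                      alpha = c(0.1, 0.05, 0.025, 0.001),
                      two = c(FALSE, TRUE))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_identical(
      sample_size_ttest(g$x, g$alpha, two_sample = g$two),
      as.integer(oracle_ttest(g$x, g$alpha, g$two)),
      label = sprintf("ttest(x=%g, alpha=%g, two=%s)", g$x, g$alpha, g$two))
  }
  # frozen values from the oracle
  expect_identical(sample_size_ttest(1, 0.05), 4L)
  expect_identical(sample_size_ttest(0.2, 0.05, two_sample = TRUE), 52L)
})

test_that("t-test size scales as 1/x^2 in the large-n limit and clamps at 2", {
  n1 <- sample_size_ttest(0.1, 0.05)   # 103
  n2 <- sample_size_ttest(0.05, 0.05)  # 403
  expect_identical(n1, 103L)
  expect_identical(n2, 403L)
  expect_lt(abs(n2 / n1 - 4), 0.1)
  expect_identical(sample_size_ttest(50, 0.05), 2L)
})

test_that("Taylor's power law size scales the t-test core", {
  # b = 2: abundance cancels; a = 1 recovers the t-test size exactly
  for (xbar in c(1, 10, 400)) {
    expect_identical(sample_size_taylor(taylor_params(1, 2, xbar), 0.5, 0.05),
                     sample_size_ttest(0.5, 0.05))
  }
  # Poisson-random population: a = 1, b = 1 gives the 1/xbar scaling
  expect_identical(sample_size_taylor(taylor_params(1, 1, 10), 0.5, 0.05),
                   as.integer(oracle_taylor(1, 1, 10, 0.5, 0.05)))
  # frozen derived case
  expect_identical(sample_size_taylor(taylor_params(2, 1.5, 25), 0.5, 0.05), 5L)
  expect_error(taylor_params(2, 1.5, -1), "xbar")
})

test_that("seasonal repeated-measures size matches direct evaluation", {
  vc <- variance_components(sigma_b2 = 1, sigma2 = 1)
  expect_identical(
    sample_size_seasonal(1, vc, k = 4, rho_delta = 0.5,
                         alpha = 0.05, power = 0.8),
    26L) # 2 * [1 + 0.25 * (1 + 3 * 0.5)] * (1.959964 + 0.841621)^2 = 25.51
  # k = 1 limit: the classic two-sample normal formula
  z2 <- (qnorm(0.975) + qnorm(0.8))^2
  for (s in c(0.5, 1, 3)) {
    vc1 <- variance_components(sigma_b2 = 0, sigma2 = s^2)
    expect_identical(
      sample_size_seasonal(1, vc1, k = 1, rho_delta = 0, alpha = 0.05,
                           power = 0.8),
      as.integer(max(2, ceiling(2 * s^2 * z2))))
  }
  # sigma_b2 = 0, rho = 0: exact 1/k scaling of the unrounded size
  raw_k <- function(k) 2 * (100 / k) * z2
  expect_equal(raw_k(2) / raw_k(4), 2)
  n2 <- sample_size_seasonal(1, variance_components(0, 100), 2, 0, 0.05, 0.8)
  n4 <- sample_size_seasonal(1, variance_components(0, 100), 4, 0, 0.05, 0.8)
  expect_lte(abs(n2 - 2 * n4), 2) # ceiling slack only
})

test_that("seasonal size is monotone in its drivers", {
  base <- list(x = 1, k = 6, rd = 0.3, a = 0.05, p = 0.8)
  n_of <- function(sb, s2, k = base$k, rd = base$rd, x = base$x)
    sample_size_seasonal(x, variance_components(sb, s2), k, rd, base$a, base$p)
  expect_true(all(diff(sapply(c(0, 1, 2, 4), n_of, s2 = 1)) >= 0))    # sigma_b2
  expect_true(all(diff(sapply(c(1, 2, 4, 8), n_of, sb = 1)) >= 0))    # sigma2
  expect_true(all(diff(sapply(c(0, 0.3, 0.7, 1),
                              function(r) n_of(1, 4, rd = r))) >= 0)) # rho
  expect_true(all(diff(sapply(c(1, 2, 4, 8),
                              function(k) n_of(1, 4, k = k))) <= 0))  # k
  expect_true(all(diff(sapply(c(0.5, 1, 2),
                              function(x) n_of(1, 4, x = x))) <= 0))  # x
})

test_that("VIF and ICC behave per definition", {
  expect_identical(variance_inflation_factor(1, 0.9), 1)
  expect_identical(variance_inflation_factor(15, 0), 1)
  expect_equal(variance_inflation_factor(15, 0.2), 3.8)
  expect_equal(intra_cluster_correlation(variance_components(tau2 = 0, sigma2 = 5)), 0)
  expect_equal(intra_cluster_correlation(variance_components(tau2 = 3, sigma2 = 0)), 1)
  expect_equal(intra_cluster_correlation(
    variance_components(tau2 = 2, sigma2 = 6)), 0.25)
  expect_error(intra_cluster_correlation(variance_components(0, 0, 0)),
               "sigma_T2")
  expect_error(variance_components(tau2 = 2, sigma2 = 1, sigma_T2 = 1), "tau2")
})

test_that("cluster size matches direct evaluation and is monotone", {
  expect_identical(
    sample_size_cluster(1, 1, m = 15, rho_c = 0.2, alpha = 0.05, power = 0.8),
    60L) # ceiling(2 * 3.8 * 7.84888) = ceiling(59.65)
  # rho_c = 0, m = 1: identical to the seasonal formula's k = 1 limit
  expect_identical(
    sample_size_cluster(1, 4, m = 1, rho_c = 0, alpha = 0.05, power = 0.8),
    sample_size_seasonal(1, variance_components(0, 4), 1, 0, 0.05, 0.8))
  n_of <- function(m, rc) sample_size_cluster(1, 1, m, rc, 0.05, 0.8)
  expect_true(all(diff(sapply(c(1, 5, 15, 40), n_of, rc = 0.3)) >= 0))
  expect_true(all(diff(sapply(c(0, 0.2, 0.6, 1), function(r) n_of(10, r))) >= 0))
})

test_that("small-sample adjustment agrees with the brute-force scan", {
  grid <- expand.grid(n_raw = c(3.2, 10, 25.7, 80), k = c(2, 3, 4, 8),
                      alpha = c(0.1, 0.05), power = c(0.8, 0.9))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_identical(
      small_sample_adjustment(g$n_raw, g$k, g$alpha, g$power),
      as.integer(oracle_adjustment(g$n_raw, g$k, g$alpha, g$power)),
      label = sprintf("adjustment(n_raw=%g, k=%d, alpha=%g, power=%g)",
                      g$n_raw, g$k, g$alpha, g$power))
  }
  # frozen values
  expect_identical(small_sample_adjustment(10, 2, 0.05, 0.8), 12L)
  expect_identical(small_sample_adjustment(10, 4, 0.05, 0.8), 15L)
})

test_that("adjustment approaches the raw size for large n and is monotone", {
  for (n_raw in c(200, 250, 600)) {
    expect_lte(abs(small_sample_adjustment(n_raw, 2, 0.05, 0.8) -
                     ceiling(n_raw)), 1)
  }
  expect_lte(small_sample_adjustment(10, 2, 0.1, 0.8),
             small_sample_adjustment(10, 2, 0.05, 0.8))
  expect_lte(small_sample_adjustment(10, 2, 0.05, 0.8),
             small_sample_adjustment(10, 2, 0.05, 0.9))
})

test_that("variance ratio covers its limiting cases", {
  vc <- variance_components(sigma_b2 = 2, sigma2 = 3)
  expect_equal(variance_ratio(vc, 1, 0.7), 1)
  for (k in c(2, 5, 9)) expect_equal(variance_ratio(vc, k, 1), 1)
  expect_equal(variance_ratio(variance_components(0, 1), 4, 0), 0.25)
  expect_error(variance_ratio(variance_components(0, 0), 3, 0.5), "degenerate")
})

test_that("study_spec validates and derives effective quantities", {
  s <- reference_spec()
  expect_equal(s$delta, 3)      # 20% of 15
  expect_equal(s$sd_eff, 3)
  s2 <- reference_spec(n_species = 2, sd_effect_2 = 5, m_2 = 25)
  expect_equal(s2$sd_eff, 4)    # mean of the two standard deviations
  expect_equal(s2$m_eff, 20)
  expect_error(reference_spec(alpha = 0.07), "alpha")
  expect_error(reference_spec(rho_c = 1.2), "rho_c")
  expect_error(reference_spec(x = -5), "x")
  expect_error(reference_spec(m_1 = 0.5), "m_1")
  expect_error(study_spec(20, 3, 15, 0.2, 0.05, 0.8, n_species = 2),
               "sd_effect_2")
})
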