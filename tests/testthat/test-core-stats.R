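# Statistical core: mixture LOD->p conversion, inverse-normal transform,
# Liptak combination, permutation Phi.

test_that("lod_to_pvalue follows the boundary-mixture null", {
  # frozen from the closed-form oracle 1 - pnorm(sqrt(2*ln10*lod))
  expect_equal(lod_to_pvalue(0.82), 0.0260, tolerance = 0.0005 / 0.0260)
  expect_equal(lod_to_pvalue(0.53), 0.0591, tolerance = 0.0005 / 0.0591)
  # point-mass convention: statistic 0 has tail probability 1
  expect_identical(lod_to_pvalue(0), 1)
  expect_identical(lod_to_pvalue(-0.4), 1)
  # strictly decreasing and bounded by 0.5 on lod > 0
  grid <- seq(0.01, 10, length.out = 500)
  p <- lod_to_pvalue(grid)
  expect_true(all(diff(p) < 0))
  expect_true(all(p <= 0.5))
  expect_error(lod_to_pvalue(Inf), class = "linkassoc_invalid_input")
  expect_error(lod_to_pvalue(NA_real_), class = "linkassoc_invalid_input")
})

test_that("pvalue_to_z is the upper-tail normal quantile with a 1e-12 clamp", {
  expect_identical(pvalue_to_z(0.5), 0)
  # frozen from the numeric root of pnorm(z) = 0.9863
  expect_equal(pvalue_to_z(0.0137), 2.206, tolerance = 0.002 / 2.206)
  # p = 1 hits the clamp: qnorm(1e-12)
  expect_equal(pvalue_to_z(1), -7.034, tolerance = 0.01 / 7.034)
  p <- c(0.9, 0.5, 0.1, 0.001)
  expect_true(all(diff(pvalue_to_z(p)) > 0))
  expect_error(pvalue_to_z(0), class = "linkassoc_invalid_input")
  expect_error(pvalue_to_z(1.5), class = "linkassoc_invalid_input")
})

test_that("mixture identity: z_from_lod equals sqrt(2 ln10 lod) on (0, 10]", {
  grid <- seq(0.01, 10, length.out = 1000)
  expect_true(all(abs(z_from_lod(grid) - sqrt(2 * log(10) * grid)) < 1e-6))
  expect_equal(z_from_lod(0.82), 1.9433, tolerance = 0.001 / 1.9433)
  expect_equal(z_from_lod(1 / (2 * log(10))), 1, tolerance = 1e-9)
  # lod <= 0 returns the clamped minimum (z of p = 1)
  expect_equal(z_from_lod(-1), pvalue_to_z(1))
})

test_that("liptak_combine matches its closed form and the worked example", {
  r0 <- liptak_combine(0, 0)
  expect_equal(r0$zc, 0)
  expect_equal(r0$p_combined, 0.5)
  # worked causal-gene example: LOD 0.82 with association p 0.0137
  r <- liptak_combine(z_from_lod(0.82), pvalue_to_z(0.0137))
  expect_gt(r$p_combined, 0.00166)
  expect_lt(r$p_combined, 0.00168)
  # identity Phi, equal inputs: zc = z * sqrt(2) exactly
  z <- c(-1.3, 0, 0.7, 4.2)
  expect_equal(liptak_combine(z, z)$zc, z * sqrt(2), tolerance = 1e-12)
  # perfect correlation: combining a statistic with itself returns it
  expect_equal(liptak_combine(z, z, phi_matrix(1))$zc, z, tolerance = 1e-12)
  expect_error(liptak_combine(1, 1, phi_matrix(-1)),
               class = "linkassoc_degenerate_correlation")
  expect_error(liptak_combine(1, 1, matrix(c(2, 0, 0, 1), 2)),
               class = "linkassoc_invalid_input")
})

test_that("estimate_phi is the Pearson correlation of the permutation columns", {
  x <- rnorm(50)
  expect_equal(estimate_phi(tibble::tibble(z1 = x, z2 = x))[1, 2], 1)
  expect_equal(estimate_phi(tibble::tibble(z1 = x, z2 = -x))[1, 2], -1)
  set.seed(42)
  perm <- tibble::tibble(z1 = rnorm(10000), z2 = rnorm(10000))
  expect_lt(abs(estimate_phi(perm)[1, 2]), 0.03)
  expect_error(estimate_phi(tibble::tibble(z1 = rep(1, 5), z2 = rnorm(5))),
               class = "linkassoc_degenerate_permutation")
  expect_error(estimate_phi(tibble::tibble(z1 = 1, z2 = 2)),
               class = "linkassoc_invalid_input")
})

test_that("build_permutation_matrix evaluates both statistics on one permutation", {
  pheno <- rnorm(40)
  # permutation-invariant statistic: all rows identical, Phi degenerate
  pm <- build_permutation_matrix(pheno, mean, mean, n_perms = 5, seed = 1)
  expect_equal(nrow(pm), 5L)
  expect_true(all(pm$z1 == pm$z1[1]) && all(pm$z2 == pm$z2[1]))
  expect_error(estimate_phi(pm), class = "linkassoc_degenerate_permutation")
  # statistics of the same permutation are correlated; reproducible by seed
  s <- function(x) sum(x[1:10])
  pm1 <- build_permutation_matrix(pheno, s, function(x) sum(x[1:20]),
                                  n_perms = 200, seed = 7)
  pm2 <- build_permutation_matrix(pheno, s, function(x) sum(x[1:20]),
                                  n_perms = 200, seed = 7)
  expect_identical(pm1, pm2)
  expect_gt(estimate_phi(pm1)[1, 2], 0.3)
  expect_error(
    build_permutation_matrix(pheno, function(x) NaN, mean, n_perms = 2, seed = 1),
    class = "linkassoc_computation_error"
  )
})

test_that("combined p-values are uniform under the independent null", {
  set.seed(2024)
  p <- liptak_combine(rnorm(10000), rnorm(10000))$p_combined
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
  frac <- mean(p < 0.001)
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.001) / 10000
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
})

test_that("estimated Phi restores calibration under correlated nulls", {
  set.seed(99)
  rho <- 0.5
  n <- 10000
  z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  b1 <- rnorm(n); b2 <- rho * b1 + sqrt(1 - rho^2) * rnorm(n)
  phi_hat <- estimate_phi(tibble::tibble(z1 = b1, z2 = b2))
  p_corr <- liptak_combine(z1, z2, phi_hat)$p_combined
  p_id <- liptak_combine(z1, z2)$p_combined
  bounds <- qbinom(c(0.005, 0.995), n, 0.05) / n
  expect_gte(mean(p_corr < 0.05), bounds[1])
  expect_lte(mean(p_corr < 0.05), bounds[2])
  # ignoring the correlation inflates the rejection rate
  expect_gt(mean(p_id < 0.05), bounds[2])
})
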