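test_that("profile SD is the sample standard deviation with n-1", {
  expect_equal(profile_sd(c(0.5, 0, 0.5, 0, 0.5, 0)), sqrt(0.375 / 5))
  expect_gt(profile_sd(c(0.5, 0, 0.5, 0, 0.5, 0)), 0.21)  # passes filter
  expect_equal(profile_sd(rep(0.3, 6)), 0)
  expect_equal(profile_sd(3 * c(0.5, 0, 0.5, 0, 0.5, 0)),
               3 * profile_sd(c(0.5, 0, 0.5, 0, 0.5, 0)))
  expect_true(is.na(profile_sd(c(1, 2, NA, 4, 5, 6))))
})

test_that("template correlation hits the exact endpoints", {
  v <- ideal_pattern(r = 2, s = -1)
  expect_equal(steady_state_R(v, v), 1)
  expect_equal(steady_state_R(rep(c(-1, 2), 3), v), -1)
  expect_true(is.na(steady_state_R(rep(1, 6))))      # zero variance
  expect_true(is.na(steady_state_R(c(1, NA, 1, 0, 1, 0))))
})

test_that("closed form equals brute-force Pearson for any valid pattern", {
  withr::with_seed(14, {
    for (k in 1:200) {
      x <- rnorm(6)
      rs <- sort(rnorm(2), decreasing = sample(c(TRUE, FALSE), 1))
      v <- ideal_pattern(rs[1], rs[2])
      expect_equal(steady_state_R(x, v),
                   cor(x, v), tolerance = 1e-12)
      expect_equal(steady_state_R(x, v, method = "pearson"), cor(x, v))
    }
    # affine changes of the pattern never change R
    x <- rnorm(6)
    expect_equal(steady_state_R(x, ideal_pattern(1, 0)),
                 steady_state_R(x, ideal_pattern(2 * 1 + 3, 2 * 0 + 3)))
    # positive rescaling of the profile never changes R
    expect_equal(steady_state_R(2.7 * x), steady_state_R(x),
                 tolerance = 1e-12)
  })
})

test_that("analytic null density is correct for the six-point design", {
  expect_equal(analytic_null_density(0), 0.75)
  expect_equal(analytic_null_density(c(-1, 1)), c(0, 0))
  expect_equal(analytic_null_density(0.5), 0.75 * (1 - 0.25))
  expect_equal(integrate(analytic_null_density, -1, 1)$value, 1,
               tolerance = 1e-8)
  expect_error(analytic_null_density(1.2), "supported")
  # CDF closed form matches the n = 6 polynomial and the density integral
  r <- seq(-1, 1, by = 0.25)
  expect_equal(analytic_null_cdf(r), 0.75 * (r - r^3 / 3) + 0.5,
               tolerance = 1e-12)
  expect_equal(analytic_null_cdf(0.6, n = 8),
               integrate(analytic_null_density, -1, 0.6, n = 8)$value,
               tolerance = 1e-7)
})

test_that("simulated null matches the analytic family for several lengths", {
  for (n in c(5, 6, 8)) {
    nm <- simulate_null(5e4, seed = 100 + n, n = n)
    ks <- suppressWarnings(
      ks.test(nm$draws, function(q) analytic_null_cdf(q, n = n))$statistic
    )
    expect_lt(ks, 0.01)
    expect_lt(abs(mean(nm$draws)), 0.01)   # symmetry
  }
})

test_that("permutation null agrees with the exchangeable analytic density", {
  nm <- simulate_null(3e4, seed = 5, mode = "permutation",
                      profile = c(1.3, -0.2, 0.8, 0.1, 2.0, -1.1))
  # discrete support (720 permutations) but same symmetric shape
  expect_lt(abs(mean(nm$draws)), 0.02)
  expect_lt(abs(mean(abs(nm$draws) > 0.75) - nm$tail_prob), 1e-12)
  expect_error(simulate_null(10, mode = "permutation", profile = rep(1, 6)),
               "non-constant")
})

test_that("classification applies both strict thresholds", {
  mk <- function(x) {
    p <- data.frame(gene_id = "G0001", t(setNames(x, paste0("x", 1:6))),
                    t(setNames(rep(0.01, 6), paste0("se", 1:6))),
                    gamma_hat = 0, sigma_hat = 0.01, gamma_estimable = TRUE,
                    singular = FALSE, df_residual = 4L, n_slides = 16L)
    p
  }
  # SD exactly at the filter boundary -> none (strict >)
  x_boundary <- c(0.5, 0, 0.5, 0, 0.5, 0) * 0.21 / sqrt(0.375 / 5)
  expect_equal(profile_sd(x_boundary), 0.21)
  expect_equal(
    as.character(classify_steady_state(mk(x_boundary),
                                       sd_min = profile_sd(x_boundary))$label),
    "none")
  # slightly above the SD boundary, perfect pattern -> up
  calls <- classify_steady_state(mk(x_boundary * 1.01))
  expect_equal(as.character(calls$label), "up")
  expect_equal(calls$R, 1)
  # mirrored pattern -> down
  expect_equal(
    as.character(classify_steady_state(mk(-x_boundary * 1.01))$label),
    "down")
  # R exactly at the threshold -> none (strict >); just under -> up
  x_part <- c(1, 0, 1, 0, 0, 1)
  r_exact <- steady_state_R(x_part)
  expect_equal(r_exact, 1 / 3, tolerance = 1e-12)
  expect_equal(
    as.character(classify_steady_state(mk(x_part),
                                       r_threshold = r_exact)$label),
    "none")
  expect_equal(
    as.character(classify_steady_state(mk(x_part),
                                       r_threshold = r_exact - 1e-9)$label),
    "up")
  # singular profiles are skipped, not classified
  p <- mk(c(1, 0, 1, 0, 1, 0))
  p$x3 <- NA
  p$singular <- TRUE
  calls <- suppressMessages(classify_steady_state(p))
  expect_false(calls$scored)
  expect_equal(as.character(calls$label), "none")
})

test_that("power rises with effect size and falls with noise", {
  sim_power <- function(a, sigma, n = 300, seed = 50) {
    withr::with_seed(seed, {
      hits <- 0L
      for (i in seq_len(n)) {
        x <- a * c(1, 0, 1, 0, 1, 0) + rnorm(6, 0, sigma)
        r <- steady_state_R(x)
        if (profile_sd(x) > 0.21 && !is.na(r) && r > 0.75) hits <- hits + 1L
      }
      hits / n
    })
  }
  expect_lte(sim_power(0.25, 0.1), sim_power(0.5, 0.1))
  expect_lte(sim_power(0.5, 0.25), sim_power(0.5, 0.1))
  expect_gt(sim_power(0.5, 0.05), 0.95)
})

test_that("directional consistency counts signs, zeros set aside", {
  all_up <- matrix(abs(rnorm(56)) + 0.1, nrow = 7)  # 7 genes x 8 points
  res <- directional_consistency(all_up, "up")
  expect_equal(res$n_matching, 56)
  expect_equal(res$fraction, 1)

  # constructed grid with 35 positives of 56
  vals <- c(rep(1, 35), rep(-1, 21))
  grid <- matrix(vals, nrow = 7)
  res <- directional_consistency(grid, "up")
  expect_equal(res$n_matching, 35)
  expect_equal(res$fraction, 0.625)

  flipped <- directional_consistency(-grid, "down")
  expect_equal(flipped$n_matching, 35)

  with_zero <- directional_consistency(matrix(c(1, 0, -1, 2), 2), "up")
  expect_equal(with_zero$n_zero, 1)
  expect_equal(with_zero$n_matching, 2)
  empty <- directional_consistency(matrix(numeric(0), 0, 6), "up")
  expect_true(is.na(empty$fraction))
})

test_that("cross-platform correlation behaves like Pearson with guards", {
  x <- c(0.2, -1.1, 0.5, 1.4, -0.3)
  expect_equal(crossplatform_correlation(x, x), 1)
  expect_equal(crossplatform_correlation(x, -x), -1)
  withr::with_seed(2, {
    a <- rnorm(20); b <- rnorm(20)
    expect_equal(crossplatform_correlation(a, b), cor(a, b),
                 tolerance = 1e-12)
  })
  expect_error(crossplatform_correlation(1:4, 1:3), "equal length")
  expect_error(crossplatform_correlation(c(1, NA, 3), c(1, 2, 3)),
               "3 complete pairs")
  expect_warning(r <- crossplatform_correlation(rep(1, 5), rnorm(5)),
                 "degenerate")
  expect_true(is.na(r))
})
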