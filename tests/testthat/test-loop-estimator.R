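test_that("the full 16-slide system identifies dye bias and all 11 levels", {
  d <- default_loop_design()
  nonmock <- d$slide_id[d$role != "mock"]
  sys <- build_gene_system(gene_ratio_stub(nonmock), d)
  expect_equal(nrow(sys$X), 16)
  expect_equal(ncol(sys$X), 12)       # gamma + 11 free lambda
  expect_equal(qr(sys$X)$rank, 12)
  prof <- estimate_profile(sys)
  expect_false(prof$singular)
  expect_true(prof$gamma_estimable)
})

test_that("dye-swapped pairs contribute mirrored equations", {
  d <- default_loop_design()
  sys <- build_gene_system(gene_ratio_stub(c(1L, 14L)), d)  # C1>UV1 + swap
  expect_equal(unname(sys$X[, "gamma"]), c(1, 1))
  lam_cols <- setdiff(colnames(sys$X), "gamma")
  expect_equal(sys$X[1, lam_cols], -sys$X[2, lam_cols])
})

test_that("a single-slide gene estimates one contrast, flags the rest", {
  d <- default_loop_design()
  sys <- build_gene_system(gene_ratio_stub(1L), d)  # slide 1: C1 -> UV1
  prof <- estimate_profile(sys)
  expect_true(prof$singular)
  expect_false(prof$gamma_estimable)   # no cycle: dye bias dropped
  expect_false(is.na(prof$x1))
  expect_true(all(is.na(prof[paste0("x", 2:6)])))
  expect_equal(prof$n_slides, 1L)
})

test_that("the mock slide is excluded from estimation", {
  d <- default_loop_design()
  sys <- build_gene_system(gene_ratio_stub(c(1L, 17L)), d)
  expect_equal(nrow(sys$X), 1)
  # zero available slides -> empty system, singular gene
  empty <- build_gene_system(gene_ratio_stub(17L), d)
  prof <- estimate_profile(empty)
  expect_true(prof$singular)
  expect_true(all(is.na(prof[paste0("x", 1:6)])))
})

test_that("noise-free profiles recover generator truth to machine precision", {
  cfg <- clean_config(n_genes = c(steady_up = 5, steady_down = 5,
                                  cumulative_up = 5, flat = 5))
  d <- default_loop_design()
  truth <- make_truth(cfg)
  prof <- estimate_profiles(raw_slide_means(simulate_slides(truth, d, cfg)),
                            d)
  xt <- true_contrasts(truth)[prof$gene_id, ]
  xh <- as.matrix(prof[, paste0("x", 1:6)])
  expect_lt(max(abs(xh - xt)), 1e-9)
  expect_lt(max(abs(prof$gamma_hat -
                      truth$gamma[match(prof$gene_id, truth$gene_id)])),
            1e-9)
  expect_equal(count_nonsingular(prof), nrow(prof))
  # zero residual -> sigma_hat ~ 0
  expect_lt(max(prof$sigma_hat), 1e-9)
})

test_that("removing all slides touching UV3 breaks exactly contrast 3", {
  cfg <- clean_config(n_genes = c(steady_up = 2))
  d <- default_loop_design()
  spots <- simulate_slides(make_truth(cfg), d, cfg)
  touches <- d$slide_id[d$cy3_sample == "UV3" | d$cy5_sample == "UV3"]
  ratios <- raw_slide_means(spots)
  prof <- estimate_profiles(ratios[!ratios$slide_id %in% touches, ], d)
  expect_true(all(prof$singular))
  expect_true(all(is.na(prof$x3)))
  xt <- true_contrasts(make_truth(cfg))[prof$gene_id, ]
  other <- paste0("x", c(1, 2, 4, 5, 6))
  expect_lt(max(abs(as.matrix(prof[, other]) - xt[, c(1, 2, 4, 5, 6)])),
            1e-9)
})

test_that("contrasts are invariant to a constant shift of all true levels", {
  cfg <- clean_config(n_genes = c(steady_up = 3))
  d <- default_loop_design()
  truth <- make_truth(cfg)
  shifted <- truth
  lam_cols <- paste0("lambda_", loop_samples())
  shifted[, lam_cols] <- shifted[, lam_cols] + 1.7
  a <- estimate_profiles(raw_slide_means(simulate_slides(truth, d, cfg)), d)
  b <- estimate_profiles(raw_slide_means(simulate_slides(shifted, d, cfg)),
                         d)
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("relabelling both channels negates dye bias, not contrasts", {
  cfg <- clean_config(n_genes = c(steady_up = 3), dye_bias = c(0.1, 0.3))
  d <- default_loop_design()
  spots <- simulate_slides(make_truth(cfg), d, cfg)
  ratios <- raw_slide_means(spots)
  a <- estimate_profiles(ratios, d)

  swapped_design <- d
  swapped_design$cy3_sample <- d$cy5_sample
  swapped_design$cy5_sample <- d$cy3_sample
  swapped_ratios <- ratios
  swapped_ratios$m <- -ratios$m     # the scanned ratio inverts
  b <- estimate_profiles(swapped_ratios, swapped_design)
  expect_equal(as.matrix(b[, paste0("x", 1:6)]),
               as.matrix(a[, paste0("x", 1:6)]), tolerance = 1e-9)
  expect_equal(b$gamma_hat, -a$gamma_hat, tolerance = 1e-9)
})

test_that("noisy estimation is unbiased with calibrated standard errors", {
  n <- 120
  cfg <- generator_config(n_genes = c(steady_up = n), effect_size = 0.5,
                          noise_sd = c(0.1, 0.1), defective_spot_rate = 0,
                          block_bias_sd = 0, block_trend_sd = 0, seed = 33)
  d <- default_loop_design()
  truth <- make_truth(cfg)
  prof <- estimate_profiles(raw_slide_means(simulate_slides(truth, d, cfg)),
                            d)
  xt <- true_contrasts(truth)[prof$gene_id, ]
  err <- as.matrix(prof[, paste0("x", 1:6)]) - xt
  se <- as.matrix(prof[, paste0("se", 1:6)])
  for (i in 1:6) {
    # mean error within 3 SE of the mean
    expect_lt(abs(mean(err[, i])), 3 * sqrt(mean(se[, i]^2) / n))
    # spread matches reported SE within 25% (n = 120 genes)
    expect_lt(abs(sd(err[, i]) / sqrt(mean(se[, i]^2)) - 1), 0.25)
  }
})

test_that("singular flags agree with the graph-connectivity oracle", {
  d <- default_loop_design()
  nonmock <- d$slide_id[d$role != "mock"]
  withr::with_seed(7, {
    for (trial in 1:60) {
      keep <- nonmock[runif(16) > 0.35]
      oracle <- connectivity_oracle(keep, d)
      prof <- estimate_profile(build_gene_system(gene_ratio_stub(keep), d))
      est <- !is.na(as.numeric(prof[paste0("x", 1:6)]))
      expect_identical(est, unname(oracle))
      expect_identical(prof$singular, !all(oracle))
    }
  })
})
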