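test_that("spline weights follow the clamp-and-normalize contract", {
  tp <- seq(0, 390, by = 30)
  cx <- c(0.2, 0.4, 0.6, 0.8) * 390
  expect_equal(cx, c(78, 156, 234, 312))

  # constant positive spline -> uniform weights over the 14-point grid
  w <- spline_weights(cx, rep(0.3, 4), tp)
  expect_equal(w, rep(1 / 14, 14))

  # matches the independent four-point cubic oracle after clamp+normalize
  y <- c(0.1, 0.9, 0.3, 0.2)
  w <- spline_weights(cx, y, tp)
  ref <- pmax(lagrange_cubic(cx, y, tp), 0)
  expect_equal(w, ref / sum(ref), tolerance = 1e-10)

  # simplex invariants for arbitrary ordinates
  set.seed(4)
  for (i in 1:20) {
    w <- spline_weights(cx, rnorm(4), tp)
    expect_true(all(w >= 0 & w <= 1))
    expect_equal(sum(w), 1, tolerance = 1e-9)
  }

  expect_error(spline_weights(cx, c(-1, -1, -1, -1), tp), "degenerate")
  expect_error(spline_weights(c(78, 78, 234, 312), y, tp), "duplicate")
})

test_that("virtual profiles are the weighted column sums of the series", {
  cyc <- make_cycle_series(n_genes = 50, seed = 2)$series
  # unit weight on one timepoint returns that column
  w <- rep(0, 14); w[5] <- 1
  expect_equal(virtual_profile(cyc, w), cyc$values[, 5])
  # uniform weights on row-centered series -> near-zero profile
  cen <- cyc$values - rowMeans(cyc$values)
  rownames(cen) <- rownames(cyc$values)
  cs <- cycle_series(cen, cyc$timepoints_min, cyc$cycle_duration_min)
  expect_lt(max(abs(virtual_profile(cs, rep(1 / 14, 14)))), 1e-12)
  # random weights match per-gene brute-force summation
  set.seed(6)
  w <- runif(14); w <- w / sum(w)
  brute <- apply(cyc$values, 1, function(row) sum(row * w))
  expect_equal(virtual_profile(cyc, w), brute, tolerance = 1e-12)
  expect_error(virtual_profile(cyc, w[-1]), "timepoints")
})

test_that("deconvolution reaches the planted optimum on noiseless mixtures", {
  cyc <- make_cycle_series(n_genes = 200, seed = 7)
  mix <- make_mixture_target(cyc$series, c(0.1, 0.9, 0.3, 0.2), seed = 7)
  fit <- fit_deconvolution(cyc$series, mix$target,
                           deconvolution_config(seed = 7))
  expect_gte(fit$correlation, 0.999)
  expect_true(all(fit$weights >= 0 & fit$weights <= 1))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_gte(fit$n_restarts_used, 10)
})

test_that("deconvolution identifies planted weights when the dictionary has full rank", {
  # with harmonically rich trajectories the series matrix is full-rank and
  # the mixture weights are identifiable: recovery and restart agreement
  cyc <- make_cycle_series(n_genes = 200, n_harmonics = 3, seed = 7)
  mix <- make_mixture_target(cyc$series, c(0.1, 0.9, 0.3, 0.2), seed = 7)
  fit <- fit_deconvolution(cyc$series, mix$target,
                           deconvolution_config(seed = 7))
  expect_gte(fit$correlation, 0.999)
  expect_gte(cor(fit$weights, mix$truth$weights), 0.99)
  expect_true(fit$converged)
  sdr <- sd(fit$top3_correlations) / abs(mean(fit$top3_correlations))
  expect_lte(sdr, 0.01)
  expect_gte(fit$top3_weight_min_pairwise_r, 0.95)

  # single-phase limit: a column of the series itself concentrates weight
  # on its own timepoint (cycle longer than the sampled window so that no
  # column is identically zero except t = 0)
  cyc2 <- make_cycle_series(n_genes = 200, n_harmonics = 3,
                            cycle_duration_min = 420, seed = 7)
  target <- setNames(cyc2$series$values[, 6], rownames(cyc2$series$values))
  fit1 <- fit_deconvolution(cyc2$series, target,
                            deconvolution_config(seed = 11))
  expect_identical(unname(which.max(fit1$weights)), 6L)
})

test_that("noisy mixtures are still deconvolved with high correlation", {
  cyc <- make_cycle_series(n_genes = 200, seed = 7)
  mix <- make_mixture_target(cyc$series, c(0.1, 0.9, 0.3, 0.2),
                             noise_sd = 0.2, seed = 7)
  fit <- fit_deconvolution(cyc$series, mix$target,
                           deconvolution_config(seed = 7))
  expect_gte(fit$correlation, 0.95)
})

test_that("the correlation objective is affine-invariant in the target", {
  cyc <- make_cycle_series(n_genes = 100, seed = 5)
  mix <- make_mixture_target(cyc$series, c(0.5, 0.2, 0.8, 0.1), seed = 5)
  cfg <- deconvolution_config(seed = 3)
  f1 <- fit_deconvolution(cyc$series, mix$target, cfg)
  f2 <- fit_deconvolution(cyc$series, 2.5 * mix$target + 0.7, cfg)
  expect_equal(f1$correlation, f2$correlation, tolerance = 1e-9)
  expect_equal(f1$weights, f2$weights, tolerance = 1e-6)
})

test_that("deconvolution is deterministic under a fixed seed", {
  cyc <- make_cycle_series(n_genes = 60, seed = 2)
  mix <- make_mixture_target(cyc$series, c(0.3, 0.6, 0.2, 0.4), seed = 2)
  cfg <- deconvolution_config(seed = 17)
  f1 <- fit_deconvolution(cyc$series, mix$target, cfg)
  f2 <- fit_deconvolution(cyc$series, mix$target, cfg)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$correlation, f2$correlation)
  expect_identical(f1$control_y, f2$control_y)
})

test_that("gene-label randomization collapses the fit towards zero", {
  cyc <- make_cycle_series(n_genes = 200, seed = 1)
  mix <- make_mixture_target(cyc$series, c(0.1, 0.9, 0.3, 0.2), seed = 7)
  cfg <- deconvolution_config(seed = 7)
  ctrl <- randomize_gene_labels_control(cyc$series, mix$target, 10, cfg)
  expect_length(ctrl$correlations, 10)
  expect_lte(ctrl$mean_abs_r, 0.15)
  expect_error(
    randomize_gene_labels_control(cyc$series, mix$target, 0, cfg),
    "n_randomizations"
  )
})

test_that("matrix randomization collapses the fit and is reproducible", {
  cyc <- make_cycle_series(n_genes = 200, seed = 1)
  mix <- make_mixture_target(cyc$series, c(0.1, 0.9, 0.3, 0.2), seed = 7)
  cfg <- deconvolution_config(seed = 7)
  ctrl <- randomize_matrix_control(cyc$series, mix$target, 10, cfg)
  expect_length(ctrl$correlations, 10)
  expect_lte(ctrl$mean_abs_r, 0.15)
  # identical seed reproduces the control exactly
  ctrl2 <- randomize_matrix_control(cyc$series, mix$target, 10, cfg)
  expect_identical(ctrl2$correlations, ctrl$correlations)
})

test_that("split-half cross-validation generalizes on synthetic mixtures", {
  cyc <- make_cycle_series(n_genes = 400, seed = 7)
  mix <- make_mixture_target(cyc$series, c(0.1, 0.9, 0.3, 0.2), seed = 7)
  cfg <- deconvolution_config(seed = 7)
  cv <- cross_validate(cyc$series, mix$target, 5, cfg)
  expect_equal(nrow(cv), 5)
  expect_gte(attr(cv, "mean_test_r"), 0.99)
  full <- fit_deconvolution(cyc$series, mix$target, cfg)
  expect_lte(abs(attr(cv, "mean_test_r") - full$correlation), 0.05)

  # single split is deterministic given the seed
  cv1a <- cross_validate(cyc$series, mix$target, 1, cfg)
  cv1b <- cross_validate(cyc$series, mix$target, 1, cfg)
  expect_identical(cv1a$test_r, cv1b$test_r)
})

test_that("deconvolution configuration validates its fields", {
  expect_error(deconvolution_config(min_restarts = 2))
  expect_error(deconvolution_config(control_x_fractions = c(0.4, 0.2, 0.6, 0.8)))
  expect_error(deconvolution_config(control_x_fractions = c(0, 0.4, 0.6, 0.8)))
  cfg <- deconvolution_config()
  expect_s3_class(cfg, "deconvolution_config")
  expect_equal(cfg$control_x_fractions, c(0.2, 0.4, 0.6, 0.8))
})
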