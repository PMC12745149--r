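# GRE -> SSFP bias model: PCA basis, PLSR map, correction, LOO validation.

make_pairs <- function(tpl, n, bias, bias_noise = 0, noise = 0.25,
                       pose = FALSE, seed = 13) {
  simulate_protocol_pairs(n = n, template = tpl, bias_field = bias,
                          bias_noise_sd = bias_noise, noise_sd = noise,
                          pose_jitter = pose, seed = seed)
}

test_that("identical protocols learn the identity score map", {
  tpl <- fixture_template()
  pr <- make_pairs(tpl, 12, field_zero(tpl), bias_noise = 0, noise = 0.3)
  bm <- fit_bias_model(pr, variance_keep = 1, n_plsr = NULL)
  bm <- fit_bias_model(pr, variance_keep = 1, n_plsr = bm$k)
  expect_lt(max(abs(bm$plsr$coef - diag(bm$k))), 1e-6)
  expect_lt(max(abs(bm$plsr$intercept)), 1e-6)
})

test_that("the PCA basis is orthonormal and reconstructs training shapes", {
  tpl <- fixture_template()
  pr <- make_pairs(tpl, 10, default_protocol_bias(tpl), bias_noise = 0.2)
  bm <- fit_bias_model(pr, variance_keep = 1, n_plsr = 2)
  gram <- bm$basis %*% t(bm$basis)
  expect_lt(max(abs(gram - diag(nrow(gram)))), 1e-8)
  expect_lte(bm$k, bm$n_training - 1)
  # full-variance basis reconstructs the aligned training shapes
  g <- gpa_align(pr$gre, tpl)
  xc <- sweep(g$aligned, 2, bm$gre_mean)
  recon <- xc %*% t(bm$basis) %*% bm$basis
  rel <- sqrt(sum((recon - xc)^2)) / sqrt(sum(xc^2))
  expect_lt(rel, 1e-8)
})

test_that("a constant bias field is recovered exactly on noiseless pairs", {
  tpl <- fixture_template()
  cfield <- default_protocol_bias(tpl)
  pr <- make_pairs(tpl, 15, cfield, bias_noise = 0, noise = 0)
  bm <- fit_bias_model(pr, variance_keep = 1, n_plsr = NULL)

  # a fresh GRE shape inside the modeled subspace
  v_new <- bm$gre_mean + 0.5 * field_scale(tpl, 0.03) +
    0.3 * field_wall_thickness(tpl, 1)
  corrected <- lvtrajectory:::correct_vector(bm, v_new)
  # the mean protocol offset carries c in full (in- and out-of-basis parts)
  expect_lt(max(abs((corrected - v_new) - cfield)), 1e-6)
})

test_that("identity model leaves shapes unchanged and guards protocols", {
  tpl <- fixture_template()
  pr <- make_pairs(tpl, 12, field_zero(tpl), bias_noise = 0, noise = 0.3)
  bm <- fit_bias_model(pr, variance_keep = 1, n_plsr = NULL)
  bm <- fit_bias_model(pr, variance_keep = 1, n_plsr = bm$k)
  sh <- vector_to_shape(pr$gre[3, ], tpl, protocol = "GRE")
  out <- apply_bias_correction(bm, sh)
  expect_lt(max(abs(shape_to_vector(out) - pr$gre[3, ])), 1e-8)
  expect_identical(out$protocol, "SSFP")
  # double correction is refused
  expect_error(apply_bias_correction(bm, out), "double-correct")
})

test_that("correction moves EDV toward the paired SSFP value", {
  tpl <- fixture_template()
  pr <- make_pairs(tpl, 40, default_protocol_bias(tpl), bias_noise = 0.15,
                   noise = 0.3, pose = TRUE, seed = 23)
  bm <- fit_bias_model(pr, variance_keep = 0.99, n_plsr = 4)
  errs <- vapply(1:10, function(i) {
    sh <- vector_to_shape(pr$gre[i, ], tpl, protocol = "GRE")
    corr <- apply_bias_correction(bm, sh)
    truth <- derived_measures(vector_to_shape(pr$ssfp[i, ], tpl))$EDV
    c(abs(derived_measures(corr)$EDV - truth),
      abs(derived_measures(sh)$EDV - truth))
  }, numeric(2))
  expect_lt(mean(errs[1, ]), 0.5 * mean(errs[2, ]))
})

test_that("n_plsr larger than the basis is rejected", {
  tpl <- fixture_template()
  pr <- make_pairs(tpl, 8, default_protocol_bias(tpl), bias_noise = 0.2)
  expect_error(fit_bias_model(pr, variance_keep = 0.95, n_plsr = 50),
               "cannot exceed")
})

test_that("zero-noise constant bias gives near-zero LOO errors", {
  tpl <- fixture_template()
  pr <- make_pairs(tpl, 10, default_protocol_bias(tpl), bias_noise = 0,
                   noise = 0)
  loo <- loo_validate(pr, variance_keep = 1, n_plsr = 3)
  expect_lt(loo$means$surface_error, 1e-3)
  expect_gt(loo$means$surface_error_uncorrected, 0.5)
})

test_that("pure-noise bias does not make correction worse than the noise floor", {
  tpl <- fixture_template()
  sdn <- 0.2
  pr <- make_pairs(tpl, 12, field_zero(tpl), bias_noise = sdn, noise = 0.3,
                   seed = 29)
  loo <- loo_validate(pr, variance_keep = 0.95, n_plsr = 2)
  # uncorrected error is the pairwise noise floor ~ E||eps||
  floor <- sdn * sqrt(2 / pi) * 2  # crude upper scale of the 3D noise mean
  expect_lt(loo$means$surface_error,
            loo$means$surface_error_uncorrected + floor)
})

test_that("LOO improves surface error on planted-bias pairs", {
  tpl <- fixture_template()
  pr <- make_pairs(tpl, 14, default_protocol_bias(tpl), bias_noise = 0.15,
                   noise = 0.3, pose = TRUE, seed = 37)
  loo <- loo_validate(pr, variance_keep = 0.99, n_plsr = 4)
  expect_lt(loo$means$surface_error, loo$means$surface_error_uncorrected)
  expect_equal(nrow(loo$cases), 14)
})
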