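# Mode regression, remodeling-mode reconstruction, SEM masking, regional
# maps.

small_cohort_scores <- function(tpl, n = 80, seed = 44) {
  co <- simulate_cohort(sim_config(template = tpl, n_subjects = n,
                                   seed = seed, noise_sd = 0.2))
  tr <- compute_trajectories(co, align = FALSE)
  at <- build_atlas(tr)
  list(cohort = co, atlas = at, scores = project_scores(at, tr))
}

test_that("exact linear effects are recovered exactly", {
  tpl <- fixture_template()
  co <- simulate_cohort(sim_config(template = tpl, n_subjects = 40,
                                   seed = 31, noise_sd = 0.2))
  pres <- factor_presence(co$covariates)
  dia <- as.numeric(pres$diabetes[pres$exam == "followup"])
  # scores constructed as 2 * diabetes on component 1, 0 elsewhere, no noise
  scores <- tibble::tibble(subject_id = co$subjects$subject_id,
                           score_1 = 2 * dia,
                           score_2 = rep(0, 40))
  fit <- fit_mode_regression(scores, co$covariates)
  expect_equal(unname(fit$coefficients["diabetes", 1]), 2, tolerance = 1e-8)
  others <- setdiff(rownames(fit$coefficients), "diabetes")
  expect_lt(max(abs(fit$coefficients[others, 1])), 1e-8)
  expect_lt(max(abs(fit$coefficients[, 2])), 1e-8)
})

test_that("null scores give null-calibrated t statistics", {
  tpl <- fixture_template()
  co <- simulate_cohort(sim_config(template = tpl, n_subjects = 150,
                                   seed = 32, noise_sd = 0.2))
  set.seed(77)
  pvals <- unlist(lapply(1:20, function(r) {
    scores <- tibble::tibble(subject_id = co$subjects$subject_id,
                             score_1 = rnorm(150), score_2 = rnorm(150),
                             score_3 = rnorm(150))
    fit <- fit_mode_regression(scores, co$covariates)
    t_stat <- fit$coefficients / fit$se
    2 * stats::pt(-abs(t_stat), df = fit$n - nrow(fit$coefficients) - 1)
  }))
  frac <- mean(pvals < 0.05)
  expect_lt(abs(frac - 0.05), 0.02)
})

test_that("planted effects with correlated predictors are recovered within 2 SE", {
  tpl <- fixture_template()
  n <- 200
  set.seed(55)
  co <- simulate_cohort(sim_config(template = tpl, n_subjects = n,
                                   seed = 33, noise_sd = 0.2))
  pres <- factor_presence(co$covariates)
  pf <- pres[pres$exam == "followup", ]
  x1 <- as.numeric(pf$diabetes)
  # second predictor correlated with the first (r ~ 0.5)
  x2 <- as.numeric(pf$statins)
  scores <- tibble::tibble(subject_id = co$subjects$subject_id,
                           score_1 = 1.5 * x1 - 0.8 * x2 + rnorm(n, 0, 0.5),
                           score_2 = 0.7 * x2 + rnorm(n, 0, 0.5))
  fit <- fit_mode_regression(scores, co$covariates)
  expect_lt(abs(fit$coefficients["diabetes", 1] - 1.5),
            2 * fit$se["diabetes", 1])
  expect_lt(abs(fit$coefficients["statins", 1] + 0.8),
            2 * fit$se["statins", 1])
  expect_lt(abs(fit$coefficients["statins", 2] - 0.7),
            2 * fit$se["statins", 2])
})

test_that("rank-deficient designs are rejected with the offending column", {
  tpl <- fixture_template()
  co <- simulate_cohort(sim_config(template = tpl, n_subjects = 40,
                                   seed = 34, noise_sd = 0.2))
  cv <- co$covariates
  cv$ldl <- cv$hdl          # perfectly collinear
  scores <- tibble::tibble(subject_id = co$subjects$subject_id,
                           score_1 = rnorm(40))
  expect_error(fit_mode_regression(scores, cv, standardize = FALSE),
               "collinear")
})

test_that("zero coefficient rows reconstruct a zero mode", {
  tpl <- fixture_template()
  fx <- small_cohort_scores(tpl, n = 50, seed = 35)
  fit <- fit_mode_regression(fx$scores, fx$cohort$covariates)
  fit$coefficients["smoking", ] <- 0
  md <- reconstruct_mode(fit, fx$atlas, "smoking")
  expect_equal(max(abs(md$displacement)), 0)
  expect_equal(max(abs(md$measure_deltas$delta_pct)), 0)
  expect_equal(md$regional_thickening_delta, rep(0, 17))
})

test_that("mode displacement is linear in delta and matches the predicted-shape oracle", {
  tpl <- fixture_template()
  fx <- small_cohort_scores(tpl, n = 60, seed = 36)
  fit <- fit_mode_regression(fx$scores, fx$cohort$covariates)
  m1 <- reconstruct_mode(fit, fx$atlas, "diabetes", delta = 1)
  m3 <- reconstruct_mode(fit, fx$atlas, "diabetes", delta = 3)
  expect_equal(m3$displacement, 3 * m1$displacement, tolerance = 1e-10)

  # oracle: difference of predicted transported shapes at factor 1 vs 0
  at <- fx$atlas
  m <- ncol(fit$coefficients)
  b <- fit$coefficients["diabetes", ]
  pred_shape <- function(x_dia) {
    z <- fit$intercept + b * x_dia      # all other predictors at reference
    at$mean_trajectory +
      as.vector((z * at$score_sd[seq_len(m)]) %*% at$components)
  }
  oracle <- pred_shape(1) - pred_shape(0)
  expect_lt(max(abs(m1$displacement - oracle)), 1e-6)
})

test_that("unknown factors are rejected", {
  tpl <- fixture_template()
  fx <- small_cohort_scores(tpl, n = 50, seed = 37)
  fit <- fit_mode_regression(fx$scores, fx$cohort$covariates)
  expect_error(reconstruct_mode(fit, fx$atlas, "nonsense"), "unknown factor")
})

test_that("SEM masking follows the elementwise comparison oracle", {
  flt <- sem_filter(c(2, 0.3, -1.5), sd = c(0.4, 0.4, 0.4) * sqrt(25), n = 25)
  expect_identical(flt$shown, c(TRUE, FALSE, TRUE))
  expect_equal(flt$masked_value, c(2, NA, -1.5))
  expect_error(sem_filter(1, 1, 1), "n > 1")

  # Table-3-style matrix against a brute-force comparison
  set.seed(9)
  vals <- matrix(rnorm(4 * 9, 0, 2), 4)
  sems <- c(0.4, 0.6, 0.3, 0.2, 0.4, 0.3, 0.5, 0.5, 0.1)
  for (r in 1:4) {
    flt <- sem_filter(vals[r, ], sd = sems * sqrt(100), n = 100)
    expect_identical(flt$shown, abs(vals[r, ]) > sems)
  }
})

test_that("a planted mid-anterior concentric field maps to segments 7/13", {
  tpl <- fixture_template()
  fx <- small_cohort_scores(tpl, n = 40, seed = 38)
  at <- fx$atlas
  bump <- field_wall_thickness(tpl, 1.5, modulate = function(theta, h) {
    exp(-((((theta + pi) %% (2 * pi)) - pi) / 0.5)^2) *
      exp(-((h - 0.45) / 0.2)^2)
  })
  md <- structure(list(displacement = bump), class = "remodeling_mode")
  reg <- regional_mode_map(md, at)
  top <- reg$segment[order(-abs(reg$thickening_delta))][1:2]
  expect_true(all(top %in% c(7L, 13L, 1L, 14L)))
  expect_true(any(top %in% c(7L, 13L)))
})

test_that("a uniform wall-thickness increase thickens all 17 segments alike", {
  tpl <- fixture_template()
  fx <- small_cohort_scores(tpl, n = 40, seed = 39)
  md <- structure(list(displacement = field_wall_thickness(tpl, 1,
                                                           frames = c(ED = 0, ES = 1))),
                  class = "remodeling_mode")
  reg <- regional_mode_map(md, fx$atlas)
  expect_gt(min(reg$thickening_delta), 0)
  expect_lt(diff(range(reg$thickening_delta)),
            0.35 * mean(reg$thickening_delta))
})
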