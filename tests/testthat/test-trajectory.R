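# Trajectories, linear-shift transport, atlas PCA, z-scores.

zero_change_cohort <- function(tpl, n = 8, seed = 3) {
  simulate_cohort(sim_config(template = tpl, n_subjects = n, seed = seed,
                             noise_sd = 0, aging_drift = field_zero(tpl),
                             trajectory_modes = list(), effect_modes = list()))
}

test_that("identical exams give exactly zero displacements", {
  tpl <- fixture_template()
  co <- zero_change_cohort(tpl)
  tr <- compute_trajectories(co, align = FALSE)
  expect_true(all(tr$displacement == 0))
  expect_equal(tr$transported,
               matrix(tr$mean_baseline, nrow(tr$transported),
                      ncol(tr$transported), byrow = TRUE))
})

test_that("transport is the exact linear-shift identity", {
  tpl <- fixture_template()
  co <- simulate_cohort(sim_config(template = tpl, n_subjects = 10, seed = 5,
                                   noise_sd = 0.3))
  tr <- compute_trajectories(co, align = FALSE)
  # invariant: transported - mean_baseline == displacement, to machine
  # precision
  expect_lt(max(abs(sweep(tr$transported, 2, tr$mean_baseline) -
                      tr$displacement)), 1e-10)
  # a subject whose baseline equals the mean baseline transports to its
  # own follow-up: solve b1 = mean(b1, others)
  co2 <- co
  co2$baseline[1, ] <- colSums(co$baseline[-1, ]) / 9
  tr2 <- compute_trajectories(co2, align = FALSE)
  expect_equal(tr2$transported[1, ], unname(co2$followup[1, ]),
               tolerance = 1e-12)
})

test_that("a planted uniform drift is recovered exactly at zero noise", {
  tpl <- fixture_template()
  drift <- default_aging_drift(tpl)
  co <- simulate_cohort(sim_config(template = tpl, n_subjects = 6, seed = 8,
                                   noise_sd = 0, aging_drift = drift,
                                   trajectory_modes = list(),
                                   effect_modes = list()))
  tr <- compute_trajectories(co, align = FALSE)
  for (i in 1:6) expect_equal(tr$displacement[i, ], drift, tolerance = 1e-10)
  expect_lt(max(apply(tr$displacement, 2, stats::var)), 1e-20)
})

test_that("a single planted mode is recovered as the first component", {
  tpl <- fixture_template()
  f <- field_wall_thickness(tpl, 1)
  co <- simulate_cohort(sim_config(
    template = tpl, n_subjects = 40, seed = 9, noise_sd = 0,
    aging_drift = field_zero(tpl),
    trajectory_modes = list(planted = list(field = f, sd = 1)),
    effect_modes = list()))
  at <- build_atlas(compute_trajectories(co, align = FALSE))
  cosine <- sum(at$components[1, ] * f) / sqrt(sum(f^2))
  expect_gt(abs(cosine), 0.999)
  expect_gt(at$variance_ratio[1], 0.999)
})

test_that("two orthogonal planted modes recover a 4:1 variance ratio", {
  tpl <- fixture_template()
  f1 <- field_wall_thickness(tpl, 1)
  f2 <- field_long_stretch(tpl, 0.03)
  f2 <- f2 - f1 * sum(f1 * f2) / sum(f1^2)      # orthogonalize
  f1 <- f1 / sqrt(sum(f1^2)); f2 <- f2 / sqrt(sum(f2^2))
  co <- simulate_cohort(sim_config(
    template = tpl, n_subjects = 500, seed = 10, noise_sd = 0,
    aging_drift = field_zero(tpl),
    trajectory_modes = list(a = list(field = 2 * f1, sd = 1),
                            b = list(field = f2, sd = 1)),
    effect_modes = list()))
  at <- build_atlas(compute_trajectories(co, align = FALSE))
  ratio <- at$variance[1] / at$variance[2]
  expect_gt(ratio, 4 * 0.8)
  expect_lt(ratio, 4 * 1.2)
})

test_that("isotropic noise gives an approximately flat spectrum", {
  # the near-flat spectrum needs the d >> n regime of the full template
  tpl <- fixture_template(781)
  co <- simulate_cohort(sim_config(
    template = tpl, n_subjects = 200, seed = 12, noise_sd = 0.3,
    aging_drift = field_zero(tpl), trajectory_modes = list(),
    effect_modes = list()))
  at <- build_atlas(compute_trajectories(co, align = FALSE))
  vr <- at$variance_ratio
  expect_lt(max(vr) / min(vr[vr > 1e-12]), 3)
})

test_that("training z-scores have mean 0 and SD 1 and reconstruct shapes", {
  tpl <- fixture_template()
  co <- simulate_cohort(sim_config(template = tpl, n_subjects = 25,
                                   seed = 14, noise_sd = 0.3))
  tr <- compute_trajectories(co, align = FALSE)
  at <- build_atlas(tr)
  sc <- project_scores(at, tr)
  z <- as.matrix(sc[, -1])
  expect_lt(max(abs(colMeans(z))), 1e-8)
  expect_lt(max(abs(apply(z, 2, stats::sd) - 1)), 1e-6)
  # full-rank reconstruction of a training shape
  rec <- reconstruct_shape(at, z[7, ])
  rel <- sqrt(sum((rec - tr$transported[7, ])^2)) /
    sqrt(sum(tr$transported[7, ]^2))
  expect_lt(rel, 1e-6)
  # the mean trajectory itself scores zero everywhere
  z0 <- project_scores(at, matrix(at$mean_trajectory, 1))
  expect_lt(max(abs(as.matrix(z0[, -1]))), 1e-8)
  # mean + 1 score_sd along component 1 scores (1, 0, ..., 0)
  v1 <- at$mean_trajectory + at$score_sd[1] * at$components[1, ]
  z1 <- as.matrix(project_scores(at, matrix(v1, 1))[, -1])
  expect_equal(unname(z1[1, 1]), 1, tolerance = 1e-8)
  expect_lt(max(abs(z1[1, -1])), 1e-8)
})

test_that("scores are invariant to a tenfold baseline variance inflation", {
  tpl <- fixture_template()
  cfg <- sim_config(template = tpl, n_subjects = 20, seed = 16,
                    noise_sd = 0)
  co <- simulate_cohort(cfg)
  tr1 <- compute_trajectories(co, align = FALSE)
  at1 <- build_atlas(tr1)
  # zero-noise cohorts have low-rank trajectories: score the leading
  # non-degenerate components only
  sc1 <- project_scores(at1, tr1, n_components = 4)

  # inflate cross-sectional spread x10 while keeping displacements fixed
  co2 <- co
  mean_b <- colMeans(co$baseline)
  infl <- sweep(sweep(co$baseline, 2, mean_b) * 10, 2, mean_b, `+`)
  disp <- co$followup - co$baseline
  co2$baseline <- infl
  co2$followup <- infl + disp
  tr2 <- compute_trajectories(co2, align = FALSE)
  at2 <- build_atlas(tr2)
  sc2 <- project_scores(at2, tr2, n_components = 4)
  expect_lt(max(abs(as.matrix(sc1[, -1]) - as.matrix(sc2[, -1]))), 1e-6)
})

test_that("adding a constant field to all follow-ups shifts only the mean", {
  tpl <- fixture_template()
  co <- simulate_cohort(sim_config(template = tpl, n_subjects = 15,
                                   seed = 18, noise_sd = 0.2))
  tr1 <- compute_trajectories(co, align = FALSE)
  at <- build_atlas(tr1)
  co2 <- co
  cfield <- field_scale(tpl, 0.01)
  co2$followup <- sweep(co$followup, 2, cfield, `+`)
  tr2 <- compute_trajectories(co2, align = FALSE)
  # centered scores against the same atlas components are unchanged
  s1 <- sweep(tr1$transported, 2, colMeans(tr1$transported)) %*%
    t(at$components)
  s2 <- sweep(tr2$transported, 2, colMeans(tr2$transported)) %*%
    t(at$components)
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("atlas needs at least 3 trajectories and GRE needs a bias model", {
  tpl <- fixture_template()
  co <- zero_change_cohort(tpl, n = 2, seed = 20)
  tr <- compute_trajectories(co, align = FALSE)
  expect_error(build_atlas(tr), "at least 3")
  co$protocol[["baseline"]] <- "GRE"
  expect_error(compute_trajectories(co, align = FALSE), "bias model")
})

test_that("subjects with an incomplete exam are skipped with a message", {
  tpl <- fixture_template()
  co <- zero_change_cohort(tpl, n = 6, seed = 22)
  co$followup[2, 5] <- NA
  expect_message(tr <- compute_trajectories(co, align = FALSE), "skipping")
  expect_equal(nrow(tr$displacement), 5)
  expect_false("S0002" %in% tr$subjects$subject_id)
})
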