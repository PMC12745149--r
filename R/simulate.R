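# Synthetic cohort generator: emulates the statistical structure the
# downstream analysis assumes (baseline shape variation, aging drift,
# covariate-driven effect modes, noise, paired-protocol bias, covariate
# tables with realistic prevalences) so every stage is testable without any
# restricted data.

#' Simulation configuration
#'
#' Bundles everything [simulate_cohort()] needs.  All displacement fields are
#' length `2 * P * 3` vectors on the template (see `field_*()` builders).
#'
#' @param template an `lv_shape`, usually from [lv_template()].
#' @param n_subjects number of subjects (>= 2).
#' @param seed integer seed; the cohort is a deterministic function of the
#'   configuration.
#' @param baseline_modes list of `list(field, sd)` cross-sectional modes.
#' @param aging_drift shared drift field per decade.
#' @param trajectory_modes list of `list(field, sd)` subject-random
#'   longitudinal modes.
#' @param effect_modes named list of per-risk-factor displacement fields
#'   (applied once when the factor is present at follow-up).
#' @param noise_sd per-coordinate measurement noise SD (mm), applied
#'   independently at both exams.
#' @param interval_years exam interval; drift scales as `interval / 10`.
#' @param protocol baseline protocol label, `"SSFP"` (already harmonised) or
#'   `"GRE"`.
#' @param covariates covariate-distribution settings, see
#'   [covariate_defaults()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(template = lv_template(), n_subjects = 100, seed = 1,
                       baseline_modes = default_baseline_modes(template),
                       aging_drift = default_aging_drift(template),
                       trajectory_modes = default_trajectory_modes(template),
                       effect_modes = default_effect_modes(template),
                       noise_sd = 0.4, interval_years = 10,
                       protocol = c("SSFP", "GRE"),
                       covariates = covariate_defaults()) {
  protocol <- match.arg(protocol)
  if (n_subjects < 2) stop("n_subjects must be at least 2")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  d <- 2L * template$topology$n_points * 3L
  chk <- function(f, what) {
    if (length(f) != d) {
      stop(what, " has length ", length(f), ", expected 2*P*3 = ", d)
    }
  }
  chk(aging_drift, "aging_drift")
  for (m in c(baseline_modes, trajectory_modes)) {
    chk(m$field, "a mode field")
    if (m$sd < 0) stop("mode SDs must be nonnegative")
  }
  for (nm in names(effect_modes)) chk(effect_modes[[nm]], paste0("effect_modes$", nm))
  structure(list(template = template, n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed), baseline_modes = baseline_modes,
                 aging_drift = aging_drift,
                 trajectory_modes = trajectory_modes,
                 effect_modes = effect_modes, noise_sd = noise_sd,
                 interval_years = interval_years, protocol = protocol,
                 covariates = covariates),
            class = "sim_config")
}

#' Default covariate-distribution settings
#'
#' Marginal distributions and baseline-to-follow-up transitions emulating a
#' multi-ethnic population cohort re-examined after a decade: mean age ~60 y,
#' 54 percent female, four race/ethnicity groups, and binary-condition
#' prevalences rising between exams (medication use, diagnosed hypertension,
#' impaired fasting glucose / diabetes), with smoking declining.  Transitions
#' are one-step: monotone conditions gain incident cases with the probability
#' that reproduces the follow-up prevalence; smokers quit, none start.
#'
#' @return A list of distribution parameters consumed by the generator.
#' @export
covariate_defaults <- function() {
  list(
    age = list(mean = 59.6, sd = 9.4, min = 45, max = 84),
    female = 0.543,
    race = c(white = 0.415, asian = 0.134, african_american = 0.245,
             hispanic = 0.206),
    height = list(male = c(175, 7), female = c(161, 7)),
    bmi = list(mean = 27.7, sd = 4.8, delta_mean = 0.1, delta_sd = 2.0,
               min = 16, max = 55),
    sbp = list(base = c(123.3, 20), follow_mean = 123.3, ar = 0.6, innov = 16),
    dbp = list(base = c(71.8, 10.1), follow_mean = 68.3, ar = 0.6, innov = 8),
    total_chol = list(base = c(194.8, 35), follow_mean = 184.4, ar = 0.6,
                      innov = 28),
    ldl = list(base = c(117.8, 30.9), follow_mean = 106.8, ar = 0.6,
               innov = 25),
    hdl = list(base = c(51.6, 15.4), follow_mean = 56.1, ar = 0.7, innov = 11),
    triglycerides = list(meanlog = log(110), sdlog = 0.45, ar = 0.7),
    smoker = c(base = 0.105, follow = 0.071),
    htn_med = c(base = 0.312, follow = 0.528),
    statin = c(base = 0.134, follow = 0.351),
    htn_dx = c(base = 0.378, follow = 0.571),
    # diabetes severity: normal / impaired fasting glucose / untreated /
    # treated, quantile-coupled so severity never decreases
    diabetes = list(base = c(normal = 0.809, ifg = 0.116, untreated = 0.013,
                             treated = 0.062),
                    follow = c(normal = 0.620, ifg = 0.211, untreated = 0.018,
                               treated = 0.151))
  )
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

# covariate table: one row per subject x exam
simulate_covariates <- function(n, cv, interval_years) {
  id <- sprintf("S%04d", seq_len(n))
  age0 <- rtrunc_norm(n, cv$age$mean, cv$age$sd, cv$age$min, cv$age$max)
  female <- stats::runif(n) < cv$female
  sex <- ifelse(female, "female", "male")
  race <- sample(names(cv$race), n, replace = TRUE, prob = cv$race)
  hm <- cv$height[["male"]]; hf <- cv$height[["female"]]
  height <- ifelse(female, stats::rnorm(n, hf[1], hf[2]),
                   stats::rnorm(n, hm[1], hm[2]))
  bmi0 <- rtrunc_norm(n, cv$bmi$mean, cv$bmi$sd, cv$bmi$min, cv$bmi$max)
  bmi1 <- pmin(pmax(bmi0 + stats::rnorm(n, cv$bmi$delta_mean, cv$bmi$delta_sd),
                    cv$bmi$min), cv$bmi$max)

  ar1 <- function(spec) {
    x0 <- stats::rnorm(n, spec$base[1], spec$base[2])
    x1 <- spec$follow_mean + spec$ar * (x0 - spec$base[1]) +
      stats::rnorm(n, 0, spec$innov)
    list(x0, x1)
  }
  sbp <- ar1(cv$sbp); dbp <- ar1(cv$dbp); tc <- ar1(cv$total_chol)
  ldl <- ar1(cv$ldl); hdl <- ar1(cv$hdl)
  ltg0 <- stats::rnorm(n, cv$triglycerides$meanlog, cv$triglycerides$sdlog)
  ltg1 <- cv$triglycerides$meanlog + cv$triglycerides$ar *
    (ltg0 - cv$triglycerides$meanlog) +
    stats::rnorm(n, 0, cv$triglycerides$sdlog *
                   sqrt(1 - cv$triglycerides$ar^2))
  trig0 <- exp(ltg0); trig1 <- exp(ltg1)

  monotone_flag <- function(pr) {
    base <- stats::runif(n) < pr[["base"]]
    inc <- (pr[["follow"]] - pr[["base"]]) / (1 - pr[["base"]])
    follow <- base | (stats::runif(n) < inc)
    list(base, follow)
  }
  med <- monotone_flag(cv$htn_med)
  sta <- monotone_flag(cv$statin)
  dxh <- monotone_flag(cv$htn_dx)
  smoke0 <- stats::runif(n) < cv$smoker[["base"]]
  quit_p <- (cv$smoker[["base"]] - cv$smoker[["follow"]]) / cv$smoker[["base"]]
  smoke1 <- smoke0 & (stats::runif(n) >= quit_p)

  lev <- names(cv$diabetes$base)
  u <- stats::runif(n)
  cutlev <- function(p) lev[findInterval(u, cumsum(p), left.open = TRUE) + 1L]
  dia0 <- cutlev(cv$diabetes$base)
  dia1 <- cutlev(cv$diabetes$follow)

  bsa <- function(h_cm, bmi) {
    w <- bmi * (h_cm / 100)^2
    0.007184 * h_cm^0.725 * w^0.425
  }
  one_exam <- function(exam, age, bmi, sbp, dbp, tc, ldl, hdl, trig, smoke,
                       med, sta, dxh, dia) {
    tibble::tibble(subject_id = id, exam = exam, age = age, sex = sex,
                   race = race, height = height, bmi = bmi,
                   sbp = sbp, dbp = dbp, total_chol = tc, ldl = ldl,
                   hdl = hdl, triglycerides = trig, smoker = smoke,
                   diabetes_status = dia, htn_dx = dxh, htn_med = med,
                   statin = sta, bsa = bsa(height, bmi))
  }
  dplyr::bind_rows(
    one_exam("baseline", age0, bmi0, sbp[[1]], dbp[[1]], tc[[1]], ldl[[1]],
             hdl[[1]], trig0, smoke0, med[[1]], sta[[1]], dxh[[1]], dia0),
    one_exam("followup", age0 + interval_years, bmi1, sbp[[2]], dbp[[2]],
             tc[[2]], ldl[[2]], hdl[[2]], trig1, smoke1, med[[2]], sta[[2]],
             dxh[[2]], dia1)
  ) |> dplyr::arrange(.data$subject_id, .data$exam)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a longitudinal LV shape cohort
#'
#' Draws per-subject baseline shapes (template + cross-sectional modes +
#' noise), follow-up shapes (baseline + aging drift scaled by the exam
#' interval + subject-random trajectory modes + risk-factor effect fields for
#' factors present at follow-up + noise), and a covariate table.  The planted
#' truth (mode scores, effect fields, presence indicators) is returned so
#' parameter-recovery tests can compare estimates against it; the pipeline
#' itself never reads it.
#'
#' @param config a [sim_config()].
#' @return An `lv_cohort`: template, subject table, `baseline` and `followup`
#'   flattened-shape matrices, protocol labels, covariate tibble, `truth`
#'   list and the config.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tpl <- config$template
  n <- config$n_subjects
  d <- 2L * tpl$topology$n_points * 3L
  with_seed(config$seed, {
    covariates <- simulate_covariates(n, config$covariates,
                                      config$interval_years)
    pres <- factor_presence(covariates)
    pres_follow <- pres[pres$exam == "followup", , drop = FALSE]

    tv <- shape_to_vector(tpl)
    nb <- length(config$baseline_modes)
    b_scores <- matrix(stats::rnorm(n * max(nb, 1)), n)[, seq_len(nb),
                                                        drop = FALSE]
    b_scores <- sweep(b_scores, 2,
                      vapply(config$baseline_modes, `[[`, numeric(1), "sd"),
                      `*`)
    b_fields <- do.call(rbind, lapply(config$baseline_modes, `[[`, "field"))
    baseline <- matrix(tv, n, d, byrow = TRUE)
    if (nb > 0) baseline <- baseline + b_scores %*% b_fields
    baseline <- baseline +
      matrix(stats::rnorm(n * d, 0, config$noise_sd), n, d)

    nt <- length(config$trajectory_modes)
    t_scores <- matrix(stats::rnorm(n * max(nt, 1)), n)[, seq_len(nt),
                                                        drop = FALSE]
    t_scores <- sweep(t_scores, 2,
                      vapply(config$trajectory_modes, `[[`, numeric(1), "sd"),
                      `*`)
    t_fields <- do.call(rbind, lapply(config$trajectory_modes, `[[`, "field"))

    factors <- names(config$effect_modes)
    x <- if (length(factors)) {
      m <- sapply(factors, function(f) as.numeric(pres_follow[[f]]))
      matrix(m, nrow = n, dimnames = list(NULL, factors))
    } else matrix(0, n, 0)
    e_fields <- if (length(factors)) {
      do.call(rbind, config$effect_modes)
    } else matrix(0, 0, d)

    followup <- baseline +
      matrix(config$aging_drift * config$interval_years / 10, n, d,
             byrow = TRUE)
    if (nt > 0) followup <- followup + t_scores %*% t_fields
    if (length(factors)) followup <- followup + x %*% e_fields
    followup <- followup +
      matrix(stats::rnorm(n * d, 0, config$noise_sd), n, d)

    structure(list(
      template = tpl,
      subjects = tibble::tibble(subject_id = sprintf("S%04d", seq_len(n))),
      baseline = baseline, followup = followup,
      protocol = c(baseline = config$protocol, followup = "SSFP"),
      covariates = covariates,
      truth = list(baseline_scores = b_scores, trajectory_scores = t_scores,
                   effect_fields = e_fields, presence = x,
                   aging_drift = config$aging_drift,
                   trajectory_fields = t_fields),
      config = config
    ), class = "lv_cohort")
  })
}

#' @export
print.lv_cohort <- function(x, ...) {
  cat("<lv_cohort> ", nrow(x$subjects), " subjects x 2 exams, P = ",
      x$template$topology$n_points, " points, baseline protocol ",
      x$protocol[["baseline"]], "\n", sep = "")
  invisible(x)
}

#' Extract one subject's shape from a cohort
#'
#' @param cohort an `lv_cohort`.
#' @param i subject index or id.
#' @param exam `"baseline"` or `"followup"`.
#' @return An `lv_shape`.
#' @export
cohort_shape <- function(cohort, i, exam = c("baseline", "followup")) {
  exam <- match.arg(exam)
  if (is.character(i)) i <- match(i, cohort$subjects$subject_id)
  vector_to_shape(cohort[[exam]][i, ], cohort$template,
                  subject_id = cohort$subjects$subject_id[i], exam = exam,
                  protocol = cohort$protocol[[exam]])
}

# small random rigid pose (rotation angle_sd degrees, translation trans_sd mm)
random_pose <- function(angle_sd = 3, trans_sd = 2) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- stats::rnorm(1, 0, angle_sd) * pi / 180
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  list(R = R, t = stats::rnorm(3, 0, trans_sd), s = 1)
}

#' Simulate paired GRE/SSFP acquisitions
#'
#' Each subject is the template plus cross-sectional modes and noise; the GRE
#' shape is the subject (optionally in a jittered scanner pose shared by the
#' pair) and the SSFP shape adds the planted protocol-bias field plus bias
#' noise.  The default bias enlarges the cavity and thins the wall, the
#' documented direction of the SSFP-GRE difference.
#'
#' @param n number of pairs (>= 3).
#' @param template an `lv_shape`.
#' @param bias_field displacement field added to SSFP shapes.
#' @param bias_noise_sd per-coordinate SD of the pairwise bias noise (mm).
#' @param baseline_modes cross-sectional modes for subject variation.
#' @param noise_sd per-coordinate subject-shape noise (mm).
#' @param pose_jitter apply a small random rigid pose per pair.
#' @param seed integer seed.
#' @return An `lv_protocol_pairs` object with `gre` and `ssfp` matrices.
#' @export
simulate_protocol_pairs <- function(n = 500, template = lv_template(),
                                    bias_field = default_protocol_bias(template),
                                    bias_noise_sd = 0.3,
                                    baseline_modes = default_baseline_modes(template),
                                    noise_sd = 0.3, pose_jitter = TRUE,
                                    seed = 1) {
  if (n < 3) stop("need at least 3 pairs")
  d <- 2L * template$topology$n_points * 3L
  if (length(bias_field) != d) stop("bias_field has the wrong length")
  p <- template$topology$n_points
  with_seed(seed, {
    tv <- shape_to_vector(template)
    nb <- length(baseline_modes)
    scores <- matrix(stats::rnorm(n * max(nb, 1)), n)[, seq_len(nb),
                                                      drop = FALSE]
    scores <- sweep(scores, 2,
                    vapply(baseline_modes, `[[`, numeric(1), "sd"), `*`)
    fields <- do.call(rbind, lapply(baseline_modes, `[[`, "field"))
    subj <- matrix(tv, n, d, byrow = TRUE)
    if (nb > 0) subj <- subj + scores %*% fields
    subj <- subj + matrix(stats::rnorm(n * d, 0, noise_sd), n, d)
    ssfp <- subj + matrix(bias_field, n, d, byrow = TRUE) +
      matrix(stats::rnorm(n * d, 0, bias_noise_sd), n, d)
    gre <- subj
    if (pose_jitter) {
      for (i in seq_len(n)) {
        tf <- random_pose()
        gre[i, ] <- transform_vector(gre[i, ], tf, p)
        ssfp[i, ] <- transform_vector(ssfp[i, ], tf, p)
      }
    }
    structure(list(template = template, gre = gre, ssfp = ssfp,
                   subjects = tibble::tibble(
                     subject_id = sprintf("P%04d", seq_len(n))),
                   truth = list(bias_field = bias_field,
                                bias_noise_sd = bias_noise_sd)),
              class = "lv_protocol_pairs")
  })
}

#' @export
print.lv_protocol_pairs <- function(x, ...) {
  cat("<lv_protocol_pairs> ", nrow(x$gre), " GRE/SSFP pairs, P = ",
      x$template$topology$n_points, " points\n", sep = "")
  invisible(x)
}
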