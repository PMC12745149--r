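# Multivariate regression of trajectory scores on covariates, per-factor
# remodeling-mode reconstruction, derived-measure deltas with SEM masking,
# and AHA 17-segment regional thickening maps.

mode_predictors_continuous <- c("age_baseline", "delta_bsa", "sbp", "dbp",
                                "bmi", "hdl", "ldl")
mode_predictors_binary <- c("race_asian", "race_african_american",
                            "race_hispanic", "smoking", "sex_female",
                            "diabetes", "statins", "htn_medication")

# design matrix in the conventional predictor order; continuous predictors
# optionally standardized (coefficients then per SD)
mode_design <- function(covariates, standardize = TRUE) {
  base <- covariates[covariates$exam == "baseline", ]
  fol <- covariates[covariates$exam == "followup", ]
  stopifnot(identical(base$subject_id, fol$subject_id))
  pres <- factor_presence(covariates)
  pf <- pres[pres$exam == "followup", ]
  stopifnot(identical(pf$subject_id, base$subject_id))

  x <- cbind(
    age_baseline = base$age,
    delta_bsa = fol$bsa - base$bsa,
    sbp = fol$sbp, dbp = fol$dbp, bmi = fol$bmi, hdl = fol$hdl,
    ldl = fol$ldl,
    race_asian = as.numeric(base$race == "asian"),
    race_african_american = as.numeric(base$race == "african_american"),
    race_hispanic = as.numeric(base$race == "hispanic"),
    smoking = as.numeric(pf$smoking),
    sex_female = as.numeric(base$sex == "female"),
    diabetes = as.numeric(pf$diabetes),
    statins = as.numeric(pf$statins),
    htn_medication = as.numeric(pf$htn_medication)
  )
  scale_info <- tibble::tibble(predictor = colnames(x),
                               center = 0, scale = 1,
                               type = ifelse(colnames(x) %in%
                                               mode_predictors_continuous,
                                             "continuous", "binary"))
  if (standardize) {
    for (v in mode_predictors_continuous) {
      mu <- mean(x[, v]); sd <- stats::sd(x[, v])
      if (sd < 1e-12) sd <- 1
      x[, v] <- (x[, v] - mu) / sd
      scale_info$center[scale_info$predictor == v] <- mu
      scale_info$scale[scale_info$predictor == v] <- sd
    }
  }
  list(x = x, subject_id = base$subject_id, scale_info = scale_info)
}

#' Regress trajectory scores on covariates and risk factors
#'
#' Ordinary least squares fitted independently per atlas component
#' (equivalently multivariate OLS with the shared design): responses are the
#' z-scored trajectory scores, predictors are baseline age, BSA change,
#' follow-up SBP, DBP, BMI, HDL and LDL (standardized by default, so their
#' coefficients are per SD), race/ethnicity dummies against the white
#' reference, smoking, sex, diabetes, statin use and hypertension-medication
#' use.
#'
#' @param scores tibble from [project_scores()].
#' @param covariates covariate tibble for both exams.
#' @param standardize standardize continuous predictors.
#' @return A `mode_regression`: coefficient and standard-error matrices
#'   (predictor x component, z-score units), scaling metadata and `n`.
#' @export
fit_mode_regression <- function(scores, covariates, standardize = TRUE) {
  des <- mode_design(covariates, standardize)
  ord <- match(des$subject_id, scores$subject_id)
  if (anyNA(ord)) stop("scores are missing for some covariate subjects")
  y <- as.matrix(scores[ord, grep("^score_", names(scores)), drop = FALSE])
  n <- nrow(y)
  if (n <= ncol(des$x) + 1) {
    stop("need more subjects (", n, ") than predictors (", ncol(des$x), ")")
  }
  x1 <- cbind(`(Intercept)` = 1, des$x)
  qr_x <- qr(x1)
  if (qr_x$rank < ncol(x1)) {
    dropped <- colnames(x1)[qr_x$pivot[seq(qr_x$rank + 1L, ncol(x1))]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qr_x, y)
  resid <- y - x1 %*% beta
  sigma2 <- colSums(resid^2) / (n - ncol(x1))
  xtx_inv_diag <- diag(chol2inv(qr.R(qr_x)))
  se <- sqrt(outer(xtx_inv_diag, sigma2))
  dimnames(se) <- dimnames(beta)
  structure(list(coefficients = beta[-1, , drop = FALSE],
                 intercept = beta[1, ],
                 se = se[-1, , drop = FALSE],
                 scale_info = des$scale_info, n = n,
                 standardized = standardize),
            class = "mode_regression")
}

#' @export
print.mode_regression <- function(x, ...) {
  cat("<mode_regression> ", nrow(x$coefficients), " predictors x ",
      ncol(x$coefficients), " components, n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.mode_regression <- function(x, ...) {
  co <- x$coefficients
  tibble::tibble(
    predictor = rep(rownames(co), ncol(co)),
    component = rep(seq_len(ncol(co)), each = nrow(co)),
    estimate = as.vector(co),
    std_error = as.vector(x$se),
    statistic = as.vector(co / x$se),
    p_value = 2 * stats::pt(-abs(as.vector(co / x$se)),
                            df = x$n - nrow(co) - 1L)
  )
}

#' @export
glance.mode_regression <- function(x, ...) {
  tibble::tibble(n = x$n, n_predictors = nrow(x$coefficients),
                 n_components = ncol(x$coefficients),
                 standardized = x$standardized)
}

#' Standard-error-of-mean filter
#'
#' Masks entries whose magnitude does not exceed the standard error of the
#' mean change, `SEM = sd / sqrt(n)`: the reporting convention for
#' per-measure remodeling deltas.
#'
#' @param values numeric vector of deltas.
#' @param sd per-measure SD of the underlying per-subject changes (recycled).
#' @param n number of subjects (> 1).
#' @return A tibble with `value`, `sem`, `shown` and `masked_value` (`NA`
#'   where masked).
#' @export
sem_filter <- function(values, sd, n) {
  if (n <= 1) stop("SEM needs n > 1")
  sem <- sd / sqrt(n)
  shown <- abs(values) > sem
  tibble::tibble(value = values, sem = sem, shown = shown,
                 masked_value = ifelse(shown, values, NA_real_))
}

# scalar derived measures used for mode deltas
mode_measure_names <- c("EDV", "ESV", "mass", "EF", "MVR", "SphVi_ED",
                        "SphVi_ES", "LS", "RWT_ED", "septal_WT",
                        "inferolateral_WT")

scalar_measures <- function(v, template) {
  m <- derived_measures(vector_to_shape(v, template))
  unlist(m[1, mode_measure_names])
}

#' Reconstruct a risk-factor remodeling mode
#'
#' The factor's displacement field is its coefficient row mapped back
#' through the atlas, `sum_m beta[factor, m] * score_sd_m * component_m`,
#' scaled by `delta` predictor units (all other predictors at reference) —
#' the partition of the factor's independent contribution to the trajectory.
#' Derived-measure deltas apply the mean trajectory with and without the
#' mode to the mean baseline shape and express the difference as percent of
#' the baseline value; regional deltas difference the AHA 17-segment
#' thickening.
#'
#' @param fit a [fit_mode_regression()] result.
#' @param atlas the `trajectory_atlas` the scores came from.
#' @param factor predictor name (row of the coefficient matrix).
#' @param delta contrast in predictor units (binary factors: 1 = present vs
#'   absent; standardized continuous predictors: 1 = +1 SD).
#' @param sem optional named vector of per-measure SEMs for masking.
#' @return A `remodeling_mode`: `displacement` field (mm), `measure_deltas`
#'   tibble (percent, with SEM mask when provided) and
#'   `regional_thickening_delta` (17 values, percentage points).
#' @export
reconstruct_mode <- function(fit, atlas, factor, delta = 1, sem = NULL) {
  if (!factor %in% rownames(fit$coefficients)) {
    stop("unknown factor '", factor, "'; available: ",
         paste(rownames(fit$coefficients), collapse = ", "))
  }
  m <- min(ncol(fit$coefficients), nrow(atlas$components))
  b <- fit$coefficients[factor, seq_len(m)]
  displacement <- as.vector((b * atlas$score_sd[seq_len(m)]) %*%
                              atlas$components[seq_len(m), , drop = FALSE]) *
    delta

  tpl <- atlas$template
  base_v <- atlas$mean_baseline
  ref_v <- atlas$mean_trajectory
  mode_v <- ref_v + displacement

  m_base <- scalar_measures(base_v, tpl)
  m_ref <- scalar_measures(ref_v, tpl)
  m_mode <- scalar_measures(mode_v, tpl)
  pct <- 100 * (m_mode - m_ref) / m_base

  deltas <- tibble::tibble(measure = mode_measure_names,
                           delta_pct = as.numeric(pct))
  if (!is.null(sem)) {
    sem_v <- sem[deltas$measure]
    deltas$sem <- as.numeric(sem_v)
    deltas$shown <- abs(deltas$delta_pct) > deltas$sem
    deltas$masked_value <- ifelse(deltas$shown, deltas$delta_pct, NA_real_)
  }

  regional <- regional_thickening_delta(displacement, atlas)

  structure(list(factor = factor, delta = delta,
                 displacement = displacement,
                 measure_deltas = deltas,
                 regional_thickening_delta = regional,
                 atlas_components_used = m),
            class = "remodeling_mode")
}

#' @export
print.remodeling_mode <- function(x, ...) {
  cat("<remodeling_mode> ", x$factor, " (delta = ", x$delta, "), |field| = ",
      round(sqrt(sum(x$displacement^2)), 2), " mm\n", sep = "")
  print(as.data.frame(x$measure_deltas), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.remodeling_mode <- function(x, ...) x$measure_deltas

# 17-segment thickening change (percentage points) of adding `displacement`
# on top of the mean trajectory
regional_thickening_delta <- function(displacement, atlas) {
  tpl <- atlas$template
  ref <- derived_measures(vector_to_shape(atlas$mean_trajectory, tpl))
  mod <- derived_measures(vector_to_shape(atlas$mean_trajectory + displacement,
                                          tpl))
  mod$regional_thickening[[1]] - ref$regional_thickening[[1]]
}

#' Regional AHA-17 map of a remodeling mode
#'
#' Wall thickening per AHA segment computed on the mean transported shape
#' with and without the mode's displacement field; the difference is the
#' mode's regional thickening effect in percentage points.
#'
#' @param mode a `remodeling_mode`.
#' @param atlas the `trajectory_atlas`.
#' @return A tibble with `segment` (1-17) and `thickening_delta`.
#' @export
regional_mode_map <- function(mode, atlas) {
  tibble::tibble(segment = 1:17,
                 thickening_delta =
                   regional_thickening_delta(mode$displacement, atlas))
}

#' @export
autoplot.remodeling_mode <- function(object, ...) {
  df <- tibble::tibble(segment = factor(1:17),
                       delta = object$regional_thickening_delta)
  ggplot2::ggplot(df, ggplot2::aes(.data$segment, .data$delta)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(title = paste("Regional thickening change:", object$factor),
                  x = "AHA segment",
                  y = "thickening change (percentage points)") +
    ggplot2::theme_minimal()
}

#' Per-measure SEM of the mean longitudinal change
#'
#' From a two-exam derived-measures table, computes each measure's
#' per-subject percent change relative to baseline and returns the standard
#' error of its mean — the masking threshold used when reporting mode
#' deltas.
#'
#' @param measures tibble from [cohort_measures()] (both exams).
#' @return Named numeric vector of SEMs (percent units).
#' @export
measure_change_sem <- function(measures) {
  wide <- measures |>
    dplyr::select("subject_id", "exam", dplyr::all_of(mode_measure_names)) |>
    tidyr::pivot_wider(names_from = "exam",
                       values_from = dplyr::all_of(mode_measure_names))
  vapply(mode_measure_names, function(mn) {
    b <- wide[[paste0(mn, "_baseline")]]
    f <- wide[[paste0(mn, "_followup")]]
    pct <- 100 * (f - b) / b
    stats::sd(pct) / sqrt(length(pct))
  }, numeric(1))
}
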