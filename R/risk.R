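# Binary risk-factor definitions, balanced accuracy, and the Atlas vs
# Mass-Volume penalized logistic-regression comparison under stratified
# repeated cross-validation with nested randomized hyperparameter search.

risk_factor_names <- c("obesity", "high_cholesterol", "hypertension",
                       "smoking", "diabetes", "htn_medication", "statins")

#' Per-exam risk-factor presence
#'
#' Applies the categorical risk-factor definitions to a covariate table:
#' obesity is BMI > 30 kg/m2; hypertension is a hypertension diagnosis or
#' elevated clinic blood pressure (SBP > 140 mmHg combined with DBP > 90 by
#' default, `htn_bp_rule = "or"` accepts either); high cholesterol combines
#' total cholesterol > 240 mg/dl, LDL > 160, HDL < 40 and triglycerides >
#' 150 (`chol_rule = "any"` by default, `"all"` requires every threshold);
#' diabetes is physician-diagnosed diabetes or impaired fasting glucose;
#' smoking, hypertension medication and statin use are carried directly.
#'
#' @param covariates covariate tibble (one row per subject and exam) with the
#'   columns produced by [simulate_cohort()] / read by [read_covariates()].
#' @param chol_rule combine the four lipid thresholds with `"any"` or
#'   `"all"`.
#' @param htn_bp_rule combine the SBP/DBP thresholds with `"and"` (as
#'   conventionally printed) or `"or"`.
#' @return A tibble with `subject_id`, `exam` and one logical column per
#'   factor.
#' @export
factor_presence <- function(covariates, chol_rule = c("any", "all"),
                            htn_bp_rule = c("and", "or")) {
  chol_rule <- match.arg(chol_rule)
  htn_bp_rule <- match.arg(htn_bp_rule)
  cv <- covariates
  chol_parts <- cbind(cv$total_chol > 240, cv$ldl > 160, cv$hdl < 40,
                      cv$triglycerides > 150)
  chol <- if (chol_rule == "any") rowSums(chol_parts) > 0 else
    rowSums(chol_parts) == ncol(chol_parts)
  bp <- if (htn_bp_rule == "and") cv$sbp > 140 & cv$dbp > 90 else
    cv$sbp > 140 | cv$dbp > 90
  tibble::tibble(
    subject_id = cv$subject_id, exam = cv$exam,
    obesity = cv$bmi > 30,
    high_cholesterol = chol,
    hypertension = cv$htn_dx | bp,
    smoking = cv$smoker,
    diabetes = cv$diabetes_status != "normal",
    htn_medication = cv$htn_med,
    statins = cv$statin
  )
}

#' Derive binary risk-factor labels from a covariate table
#'
#' A subject is labelled `positive` for a factor if it is present at
#' follow-up, `negative` if absent at both exams, and `excluded` otherwise
#' (present at baseline but resolved by follow-up, or missing data).
#'
#' @inheritParams factor_presence
#' @return A tibble with `subject_id`, `factor` and `label`
#'   (`positive` / `negative` / `excluded`).
#' @export
derive_risk_labels <- function(covariates, chol_rule = c("any", "all"),
                               htn_bp_rule = c("and", "or")) {
  pres <- factor_presence(covariates, chol_rule, htn_bp_rule)
  long <- tidyr::pivot_longer(pres, -c("subject_id", "exam"),
                              names_to = "factor", values_to = "present")
  wide <- tidyr::pivot_wider(long, names_from = "exam",
                             values_from = "present")
  dplyr::transmute(
    wide, .data$subject_id, .data$factor,
    label = dplyr::case_when(
      is.na(.data$followup) | is.na(.data$baseline) ~ "excluded",
      .data$followup ~ "positive",
      !.data$baseline & !.data$followup ~ "negative",
      TRUE ~ "excluded"
    )
  )
}

#' Balanced accuracy
#'
#' The mean of per-class recalls; 1 is perfect discrimination, 0.5 is chance
#' for a constant classifier on two classes, and the value is invariant to
#' relabelling the classes.
#'
#' @param labels true class labels (two classes must be present).
#' @param predictions predicted labels, same length.
#' @return Balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stop("labels and predictions must have the same length")
  }
  classes <- unique(labels)
  if (length(classes) < 2) {
    stop("balanced accuracy needs both classes present in the labels")
  }
  mean(vapply(classes, function(cl) {
    mean(predictions[labels == cl] == cl)
  }, numeric(1)))
}

# deterministic stratified split: test_frac of each class to the test set
stratified_split <- function(y, test_frac, seed) {
  with_seed(seed, {
    test <- logical(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      n_test <- max(1L, round(length(idx) * test_frac))
      test[sample(idx, n_test)] <- TRUE
    }
    test
  })
}

# stratified k folds (vector of fold ids)
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# fit elastic-net logistic regression at one (alpha, lambda) and predict
# classes on new data; class-balanced observation weights so the fit targets
# balanced accuracy
enet_predict <- function(x_train, y_train, x_test, alpha, lambda) {
  w <- 1 / (table(y_train)[as.character(y_train)] * length(unique(y_train)))
  fit <- glmnet::glmnet(x_train, y_train, family = "binomial",
                        alpha = alpha, lambda = lambda,
                        weights = as.numeric(w) * length(y_train),
                        standardize = FALSE)
  as.integer(stats::predict(fit, x_test, type = "response")[, 1] > 0.5)
}

# randomized hyperparameter search: n_iter draws of (alpha, lambda),
# evaluated by k-fold stratified CV balanced accuracy on the training set
tune_enet <- function(x, y, n_iter, k_inner, seed,
                      alpha_grid = seq(0, 1, by = 0.1),
                      lambda_range = c(1e-4, 1e2)) {
  draws <- with_seed(seed, {
    tibble::tibble(
      alpha = sample(alpha_grid, n_iter, replace = TRUE),
      lambda = exp(stats::runif(n_iter, log(lambda_range[1]),
                                log(lambda_range[2])))
    )
  })
  fold <- stratified_folds(y, k_inner, seed + 1L)
  scores <- vapply(seq_len(n_iter), function(j) {
    bas <- vapply(seq_len(k_inner), function(f) {
      tr <- fold != f
      if (length(unique(y[!tr])) < 2) return(NA_real_)
      pred <- enet_predict(x[tr, , drop = FALSE], y[tr],
                           x[!tr, , drop = FALSE],
                           draws$alpha[j], draws$lambda[j])
      balanced_accuracy(y[!tr], pred)
    }, numeric(1))
    mean(bas, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(scores)
  list(alpha = draws$alpha[best], lambda = draws$lambda[best],
       inner_score = scores[best])
}

scale_train_test <- function(x_train, x_test) {
  mu <- colMeans(x_train)
  sd <- apply(x_train, 2, stats::sd)
  sd[sd < 1e-12] <- 1
  list(train = sweep(sweep(x_train, 2, mu), 2, sd, `/`),
       test = sweep(sweep(x_test, 2, mu), 2, sd, `/`))
}

# evaluate one feature set for one response over the repeated splits
cv_one_model <- function(x, y, n_splits, test_frac, n_iter, k_inner, seed) {
  purrr::map_dfr(seq_len(n_splits), function(s) {
    split_seed <- seed + 1000L * s
    test <- stratified_split(y, test_frac, split_seed)
    sc <- scale_train_test(x[!test, , drop = FALSE], x[test, , drop = FALSE])
    tuned <- tune_enet(sc$train, y[!test], n_iter, k_inner, split_seed + 1L)
    pred <- enet_predict(sc$train, y[!test], sc$test, tuned$alpha,
                         tuned$lambda)
    tibble::tibble(fold = s, balanced_accuracy =
                     balanced_accuracy(y[test], pred),
                   alpha = tuned$alpha, lambda = tuned$lambda)
  })
}

#' Compare Atlas and Mass-Volume risk models
#'
#' For each binary risk factor (and optionally sex as a response), fits
#' elastic-net logistic regressions on two feature sets — atlas trajectory
#' scores truncated at the components covering `variance_keep` of the
#' trajectory variance, versus longitudinal changes in EDV, ESV, mass and EF
#' — both adjusted for sex and baseline age (age only when sex is the
#' response).  Evaluation uses `n_splits` stratified 80/20 shuffle-splits
#' with seeds shared between the two models, hyperparameters tuned per split
#' by randomized search (`n_iter` draws of the elastic-net mixing parameter
#' on \{0, 0.1, ..., 1\} and log-uniform regularization strength) over an
#' inner stratified 5-fold CV maximizing balanced accuracy.  Models are
#' compared by a paired two-sided t-test on the fold-wise balanced
#' accuracies, Bonferroni-corrected across responses.
#'
#' @param scores tibble of atlas z-scores (`subject_id`, `score_1`, ...),
#'   from [project_scores()].
#' @param atlas the [build_atlas()] result (for the variance truncation).
#' @param measures derived-measures tibble for both exams
#'   ([cohort_measures()]).
#' @param labels risk labels from [derive_risk_labels()].
#' @param covariates covariate tibble (sex and baseline age adjusters).
#' @param factors which responses to evaluate (default: the seven risk
#'   factors plus `"sex"`).
#' @param variance_keep atlas-score truncation fraction (default 0.99).
#' @param n_splits,test_frac repeated stratified shuffle-splits.
#' @param n_iter randomized-search draws per split.
#' @param k_inner inner CV folds.
#' @param min_n,min_class minimum labelled subjects / per-class counts; a
#'   factor failing them is skipped with a message.
#' @param seed master seed; all fold seeds derive from it.
#' @return An object of class `cv_comparison` with `folds` (per fold and
#'   model) and `summary` (per response: mean, SD, raw and
#'   Bonferroni-adjusted p-value) tibbles.
#' @export
cv_compare <- function(scores, atlas, measures, labels, covariates,
                       factors = c(risk_factor_names, "sex"),
                       variance_keep = 0.99, n_splits = 10, test_frac = 0.2,
                       n_iter = 50, k_inner = 5, min_n = 40, min_class = 10,
                       seed = 1) {
  base_cov <- covariates[covariates$exam == "baseline",
                         c("subject_id", "age", "sex")]
  n_keep <- components_for_variance(atlas, variance_keep)
  score_cols <- paste0("score_", seq_len(n_keep))
  sc <- scores[, c("subject_id", score_cols)]

  mw <- measures |>
    dplyr::select("subject_id", "exam", "EDV", "ESV", "mass", "EF") |>
    tidyr::pivot_wider(names_from = "exam",
                       values_from = c("EDV", "ESV", "mass", "EF"))
  mv <- dplyr::transmute(
    mw, .data$subject_id,
    dEDV = .data$EDV_followup - .data$EDV_baseline,
    dESV = .data$ESV_followup - .data$ESV_baseline,
    dmass = .data$mass_followup - .data$mass_baseline,
    dEF = .data$EF_followup - .data$EF_baseline
  )

  folds_out <- list()
  summary_out <- list()
  for (fct in factors) {
    if (fct == "sex") {
      dat <- dplyr::inner_join(base_cov, sc, by = "subject_id") |>
        dplyr::inner_join(mv, by = "subject_id")
      y <- as.integer(dat$sex == "female")
      adj <- cbind(age = dat$age)
    } else {
      lab <- labels[labels$factor == fct & labels$label != "excluded", ]
      dat <- dplyr::inner_join(lab, base_cov, by = "subject_id") |>
        dplyr::inner_join(sc, by = "subject_id") |>
        dplyr::inner_join(mv, by = "subject_id")
      y <- as.integer(dat$label == "positive")
      adj <- cbind(age = dat$age, sex = as.integer(dat$sex == "female"))
    }
    if (length(y) < min_n || min(table(y)) < min_class) {
      message("skipping ", fct, ": too few labelled subjects (",
              length(y), " total, smallest class ",
              if (length(y)) min(table(y)) else 0, ")")
      next
    }
    x_atlas <- cbind(as.matrix(dat[, score_cols]), adj)
    x_mv <- cbind(as.matrix(dat[, c("dEDV", "dESV", "dmass", "dEF")]), adj)

    res <- purrr::map_dfr(
      list(Atlas = x_atlas, `Mass-Volume` = x_mv),
      function(x) cv_one_model(x, y, n_splits, test_frac, n_iter, k_inner,
                               seed),
      .id = "model"
    )
    res$factor <- fct
    folds_out[[fct]] <- res

    ba_a <- res$balanced_accuracy[res$model == "Atlas"]
    ba_m <- res$balanced_accuracy[res$model == "Mass-Volume"]
    p <- if (stats::sd(ba_a - ba_m) < 1e-12) 1 else
      stats::t.test(ba_a, ba_m, paired = TRUE)$p.value
    summary_out[[fct]] <- tibble::tibble(
      factor = fct,
      mean_atlas = mean(ba_a), sd_atlas = stats::sd(ba_a),
      mean_mv = mean(ba_m), sd_mv = stats::sd(ba_m),
      diff = mean(ba_a - ba_m), p_raw = p
    )
  }
  summary <- dplyr::bind_rows(summary_out)
  if (nrow(summary)) {
    summary$p_bonferroni <- pmin(summary$p_raw * length(factors), 1)
  }
  structure(list(folds = dplyr::bind_rows(folds_out), summary = summary,
                 n_components = n_keep, n_splits = n_splits, seed = seed),
            class = "cv_comparison")
}

#' @export
print.cv_comparison <- function(x, ...) {
  cat("<cv_comparison> ", x$n_splits, " stratified 80/20 splits, ",
      x$n_components, " atlas components\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.cv_comparison <- function(x, ...) x$folds

#' @export
glance.cv_comparison <- function(x, ...) x$summary

#' @export
autoplot.cv_comparison <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(x = .data$factor, y = .data$balanced_accuracy,
                               fill = .data$model)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = NULL, y = "balanced accuracy (test folds)",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
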