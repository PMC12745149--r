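# Risk-factor labels, balanced accuracy, stratified CV machinery.

cov_row <- function(subject_id, exam, bmi = 25, sbp = 120, dbp = 75,
                    tc = 180, ldl = 100, hdl = 50, trig = 120,
                    smoker = FALSE, dia = "normal", htn_dx = FALSE,
                    htn_med = FALSE, statin = FALSE) {
  tibble::tibble(subject_id = subject_id, exam = exam, age = 60,
                 sex = "female", race = "white", height = 165, bmi = bmi,
                 sbp = sbp, dbp = dbp, total_chol = tc, ldl = ldl,
                 hdl = hdl, triglycerides = trig, smoker = smoker,
                 diabetes_status = dia, htn_dx = htn_dx, htn_med = htn_med,
                 statin = statin, bsa = 1.8)
}

label_of <- function(labels, id, fct) {
  labels$label[labels$subject_id == id & labels$factor == fct]
}

test_that("risk labels follow the positive / negative / excluded rule", {
  cv <- dplyr::bind_rows(
    cov_row("A", "baseline", bmi = 28), cov_row("A", "followup", bmi = 31),
    cov_row("B", "baseline", bmi = 28), cov_row("B", "followup", bmi = 28),
    cov_row("C", "baseline", bmi = 32), cov_row("C", "followup", bmi = 27),
    cov_row("D", "baseline", smoker = TRUE),
    cov_row("D", "followup", smoker = FALSE)
  )
  lab <- derive_risk_labels(cv)
  expect_identical(label_of(lab, "A", "obesity"), "positive")
  expect_identical(label_of(lab, "B", "obesity"), "negative")
  # present at baseline, resolved at follow-up: neither definition applies
  expect_identical(label_of(lab, "C", "obesity"), "excluded")
  expect_identical(label_of(lab, "D", "smoking"), "excluded")
})

test_that("hypertension and cholesterol rule variants enumerate correctly", {
  mk <- function(sbp, dbp, htn_dx = FALSE) {
    dplyr::bind_rows(cov_row("X", "baseline"),
                     cov_row("X", "followup", sbp = sbp, dbp = dbp,
                             htn_dx = htn_dx))
  }
  # conjunction rule (printed form): both thresholds needed
  expect_identical(label_of(derive_risk_labels(mk(150, 95)), "X",
                            "hypertension"), "positive")
  expect_identical(label_of(derive_risk_labels(mk(150, 80)), "X",
                            "hypertension"), "negative")
  # OR variant flips the divergent case
  expect_identical(label_of(derive_risk_labels(mk(150, 80),
                                               htn_bp_rule = "or"),
                            "X", "hypertension"), "positive")
  # diagnosis alone is positive under both rules
  expect_identical(label_of(derive_risk_labels(mk(120, 70, htn_dx = TRUE)),
                            "X", "hypertension"), "positive")

  # cholesterol: one elevated lipid is enough under "any", not under "all"
  cvc <- dplyr::bind_rows(cov_row("Y", "baseline"),
                          cov_row("Y", "followup", ldl = 170))
  expect_identical(label_of(derive_risk_labels(cvc), "Y",
                            "high_cholesterol"), "positive")
  expect_identical(label_of(derive_risk_labels(cvc, chol_rule = "all"),
                            "Y", "high_cholesterol"), "negative")
  all_high <- dplyr::bind_rows(
    cov_row("Z", "baseline"),
    cov_row("Z", "followup", tc = 250, ldl = 170, hdl = 35, trig = 160))
  expect_identical(label_of(derive_risk_labels(all_high, chol_rule = "all"),
                            "Z", "high_cholesterol"), "positive")
})

test_that("diabetes covers diagnosis and impaired fasting glucose", {
  for (st in c("ifg", "untreated", "treated")) {
    cv <- dplyr::bind_rows(cov_row("W", "baseline"),
                           cov_row("W", "followup", dia = st))
    expect_identical(label_of(derive_risk_labels(cv), "W", "diabetes"),
                     "positive")
  }
})

test_that("balanced accuracy equals the mean of per-class recalls", {
  expect_equal(balanced_accuracy(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  # constant predictor: recalls 1 and 0
  expect_equal(balanced_accuracy(c(1, 1, 1, 0, 0), c(1, 1, 1, 1, 1)), 0.5)
  # TP=3 FN=1 TN=2 FP=2 -> (3/4 + 2/4) / 2
  labels <- c(rep(1, 4), rep(0, 4))
  preds <- c(1, 1, 1, 0, 1, 1, 0, 0)
  expect_equal(balanced_accuracy(labels, preds), 0.625)
  # invariant under class relabeling
  expect_equal(balanced_accuracy(1 - labels, 1 - preds), 0.625)
  expect_error(balanced_accuracy(c(1, 1), c(1, 0)), "both classes")
})

test_that("balanced accuracy matches recall arithmetic on enumerated tables", {
  set.seed(5)
  for (rep in 1:20) {
    tp <- sample(1:6, 1); fn <- sample(1:6, 1)
    tn <- sample(1:6, 1); fp <- sample(1:6, 1)
    labels <- c(rep(1, tp + fn), rep(0, tn + fp))
    preds <- c(rep(1, tp), rep(0, fn), rep(0, tn), rep(1, fp))
    expect_equal(balanced_accuracy(labels, preds),
                 (tp / (tp + fn) + tn / (tn + fp)) / 2)
  }
})

test_that("stratified splits preserve class proportions and are deterministic", {
  y <- c(rep(1, 30), rep(0, 70))
  s1 <- lvtrajectory:::stratified_split(y, 0.2, seed = 7)
  s2 <- lvtrajectory:::stratified_split(y, 0.2, seed = 7)
  expect_identical(s1, s2)
  expect_equal(sum(s1), 20)
  expect_equal(sum(y[s1] == 1), 6)   # 30% positives in the test fold

  f <- lvtrajectory:::stratified_folds(y, 5, seed = 3)
  for (k in 1:5) {
    expect_equal(sum(y[f == k] == 1), 6)
    expect_equal(sum(f == k), 20)
  }
})

test_that("cohort flow arithmetic reproduces sequential exclusions", {
  fl <- cohort_flow(2981, c(events = 46, failures = 414))
  expect_equal(fl$n_remaining, c(2981, 2935, 2521))
  expect_error(cohort_flow(10, c(a = 20)), "exceed")
  expect_error(cohort_flow(10, c(a = -1)), "nonnegative")
})
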