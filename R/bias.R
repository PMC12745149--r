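# Cross-protocol (GRE -> SSFP) shape-bias correction: GPA alignment, PCA on
# the GRE shapes, PLSR from GRE scores to SSFP scores, leave-one-out
# validation.

# explicit linear map (coef, intercept) of a fitted PLS regression:
# yhat = x %*% coef + intercept
plsr_linear_map <- function(x, y, ncomp) {
  colnames(x) <- paste0("g", seq_len(ncol(x)))
  colnames(y) <- paste0("s", seq_len(ncol(y)))
  fit <- mixOmics::pls(x, y, ncomp = ncomp, mode = "regression",
                       scale = FALSE)
  probe <- rbind(0, diag(ncol(x)))
  colnames(probe) <- colnames(x)
  pred <- stats::predict(fit, probe)$predict[, , ncomp, drop = FALSE]
  pred <- matrix(pred, nrow = nrow(probe))
  intercept <- pred[1, ]
  coef <- sweep(pred[-1, , drop = FALSE], 2, intercept)
  list(coef = coef, intercept = intercept, ncomp = ncomp)
}

# leave-one-out selection of the PLSR component count over 2..min(max_comp, K)
select_n_plsr <- function(s_gre, s_ssfp, max_comp = 20) {
  k <- ncol(s_gre)
  n <- nrow(s_gre)
  grid <- seq(2L, min(max_comp, k, n - 2L))
  if (length(grid) < 1) return(min(k, n - 2L))
  colnames(s_gre) <- paste0("g", seq_len(k))
  colnames(s_ssfp) <- paste0("s", seq_len(k))
  ncomp_max <- max(grid)
  err <- matrix(NA_real_, n, length(grid))
  for (i in seq_len(n)) {
    fit <- mixOmics::pls(s_gre[-i, , drop = FALSE],
                         s_ssfp[-i, , drop = FALSE],
                         ncomp = ncomp_max, mode = "regression",
                         scale = FALSE)
    pred <- stats::predict(fit, s_gre[i, , drop = FALSE])$predict
    for (j in seq_along(grid)) {
      err[i, j] <- sum((pred[1, , grid[j]] - s_ssfp[i, ])^2)
    }
  }
  grid[which.min(colMeans(err))]
}

#' Fit the GRE-to-SSFP shape-bias model
#'
#' GPA-aligns the GRE shapes of the training pairs (applying each pair's GRE
#' transform to its SSFP shape so pairs stay in register), builds a PCA basis
#' on the aligned GRE shape vectors retaining `variance_keep` of the
#' variance, scores both protocols in that basis (each centered on its own
#' protocol mean, so the mean protocol offset is carried explicitly), and
#' fits a PLSR map from GRE scores to SSFP scores.
#'
#' @param pairs an `lv_protocol_pairs` object (>= 3 pairs).
#' @param variance_keep PCA variance fraction retained for the bias basis.
#' @param n_plsr number of PLSR latent components; `NULL` selects by
#'   leave-one-out error over 2..min(20, K).
#' @return A `bias_model`: GPA reference ED shape, GRE mean vector,
#'   orthonormal `basis` (K x 2*P*3) with per-component variance, the PLSR
#'   coefficient map, and metadata.
#' @export
fit_bias_model <- function(pairs, variance_keep = 0.95, n_plsr = NULL,
                           .clamp_n_plsr = FALSE) {
  stopifnot(inherits(pairs, "lv_protocol_pairs"))
  n <- nrow(pairs$gre)
  if (n < 3) stop("bias-model fitting needs at least 3 pairs")
  tpl <- pairs$template
  p <- tpl$topology$n_points

  g <- gpa_align(pairs$gre, tpl)
  ssfp_al <- do.call(rbind, lapply(seq_len(n), function(i) {
    transform_vector(pairs$ssfp[i, ], g$transforms[[i]], p)
  }))

  gre_mean <- colMeans(g$aligned)
  xc <- sweep(g$aligned, 2, gre_mean)
  sv <- svd(xc, nu = 0)
  var_all <- sv$d^2 / (n - 1)
  ratio <- var_all / sum(var_all)
  k <- which(cumsum(ratio) >= variance_keep - 1e-12)[1]
  k <- min(k, n - 1L)
  basis <- t(sv$v[, seq_len(k), drop = FALSE])

  ssfp_mean <- colMeans(ssfp_al)
  s_gre <- xc %*% t(basis)
  s_ssfp <- sweep(ssfp_al, 2, ssfp_mean) %*% t(basis)

  if (is.null(n_plsr)) n_plsr <- select_n_plsr(s_gre, s_ssfp)
  if (.clamp_n_plsr) n_plsr <- min(n_plsr, k)
  if (n_plsr > k) {
    stop("n_plsr (", n_plsr, ") cannot exceed the basis size K = ", k)
  }
  map <- plsr_linear_map(s_gre, s_ssfp, n_plsr)

  structure(list(gpa_reference = g$mean_ed, gre_mean = gre_mean,
                 ssfp_mean = ssfp_mean,
                 basis = basis, variance = var_all[seq_len(k)],
                 plsr = map, n_plsr = n_plsr, k = k,
                 variance_keep = variance_keep, n_training = n,
                 template = tpl),
            class = "bias_model")
}

#' @export
print.bias_model <- function(x, ...) {
  cat("<bias_model> K = ", x$k, " PCA components (",
      round(100 * x$variance_keep), "% variance), ", x$n_plsr,
      " PLSR components, trained on ", x$n_training, " pairs\n", sep = "")
  invisible(x)
}

# correct a flattened GRE shape vector (protocol checks live in the
# lv_shape-level wrapper)
correct_vector <- function(model, v) {
  p <- model$template$topology$n_points
  ed <- matrix(v[seq_len(3L * p)], ncol = 3L, byrow = TRUE)
  tf <- kabsch_transform(ed, model$gpa_reference)
  va <- transform_vector(v, tf, p)
  centered <- va - model$gre_mean
  s <- as.vector(model$basis %*% centered)
  resid <- centered - as.vector(s %*% model$basis)
  s2 <- as.vector(s %*% model$plsr$coef) + model$plsr$intercept
  v2 <- model$ssfp_mean + as.vector(s2 %*% model$basis) + resid
  transform_vector(v2, invert_transform(tf), p)
}

#' Apply the bias correction to a GRE shape
#'
#' Aligns the shape to the model's GPA reference, maps its PCA scores with
#' the fitted PLSR, reconstructs around the SSFP training mean (so the mean
#' protocol offset — including any component outside the basis — is applied)
#' while preserving the shape's out-of-basis residual (subject-specific
#' detail outside the modeled subspace is untouched), and returns the result
#' in the original pose flagged as SSFP-equivalent.  Applying the correction to an SSFP shape is
#' an error, guarding against double correction.
#'
#' @param model a `bias_model`.
#' @param shape an `lv_shape` with protocol `"GRE"`.
#' @return The corrected `lv_shape` (protocol `"SSFP"`).
#' @export
apply_bias_correction <- function(model, shape) {
  stopifnot(inherits(model, "bias_model"), inherits(shape, "lv_shape"))
  if (!identical(shape$protocol, "GRE")) {
    stop("bias correction applies to GRE shapes only (got protocol ",
         shape$protocol, "); refusing to double-correct")
  }
  v2 <- correct_vector(model, shape_to_vector(shape))
  out <- vector_to_shape(v2, shape, subject_id = shape$subject_id,
                         exam = shape$exam, protocol = "SSFP")
  out$bias_corrected <- TRUE
  out
}

# mean per-point distance between two flattened shapes (both frames), mm
surface_distance <- function(v1, v2) {
  d <- matrix(v1 - v2, ncol = 3L, byrow = TRUE)
  mean(sqrt(rowSums(d^2)))
}

#' Leave-one-out validation of the bias correction
#'
#' For each pair, fits the bias model on the remaining pairs, corrects the
#' held-out GRE shape and compares it with its true SSFP shape: mean surface
#' distance (mm, both frames) and absolute errors in EDV, ESV and mass, each
#' also reported for the uncorrected GRE shape.  The PLSR component count is
#' chosen once (or passed) and held fixed across folds.
#'
#' @param pairs an `lv_protocol_pairs` object (>= 4 pairs).
#' @param variance_keep PCA variance fraction for each fold's basis.
#' @param n_plsr PLSR components; `NULL` selects once on the full data.
#' @return A `loo_validation` object with `cases` (per held-out pair) and
#'   `means` tibbles.
#' @export
loo_validate <- function(pairs, variance_keep = 0.95, n_plsr = NULL) {
  stopifnot(inherits(pairs, "lv_protocol_pairs"))
  n <- nrow(pairs$gre)
  if (n < 4) stop("leave-one-out validation needs at least 4 pairs")
  tpl <- pairs$template

  if (is.null(n_plsr)) {
    n_plsr <- fit_bias_model(pairs, variance_keep)$n_plsr
  }
  measures3 <- function(v) {
    m <- derived_measures(vector_to_shape(v, tpl))
    c(EDV = m$EDV, ESV = m$ESV, mass = m$mass)
  }
  cases <- purrr::map_dfr(seq_len(n), function(i) {
    sub <- structure(list(template = tpl,
                          gre = pairs$gre[-i, , drop = FALSE],
                          ssfp = pairs$ssfp[-i, , drop = FALSE],
                          subjects = pairs$subjects[-i, , drop = FALSE],
                          truth = pairs$truth),
                     class = "lv_protocol_pairs")
    model <- fit_bias_model(sub, variance_keep,
                            n_plsr = min(n_plsr, n - 2L),
                            .clamp_n_plsr = TRUE)
    corr <- correct_vector(model, pairs$gre[i, ])
    truth <- pairs$ssfp[i, ]
    m_true <- measures3(truth)
    m_corr <- measures3(corr)
    m_raw <- measures3(pairs$gre[i, ])
    tibble::tibble(
      case = i,
      surface_error = surface_distance(corr, truth),
      surface_error_uncorrected = surface_distance(pairs$gre[i, ], truth),
      dEDV = abs(m_corr[["EDV"]] - m_true[["EDV"]]),
      dEDV_uncorrected = abs(m_raw[["EDV"]] - m_true[["EDV"]]),
      dESV = abs(m_corr[["ESV"]] - m_true[["ESV"]]),
      dESV_uncorrected = abs(m_raw[["ESV"]] - m_true[["ESV"]]),
      dmass = abs(m_corr[["mass"]] - m_true[["mass"]]),
      dmass_uncorrected = abs(m_raw[["mass"]] - m_true[["mass"]])
    )
  })
  means <- dplyr::summarise(cases, dplyr::across(-"case", mean))
  structure(list(cases = cases, means = means, n_plsr = n_plsr,
                 variance_keep = variance_keep),
            class = "loo_validation")
}

#' @export
print.loo_validation <- function(x, ...) {
  cat("<loo_validation> ", nrow(x$cases), " folds, ", x$n_plsr,
      " PLSR components\n", sep = "")
  print(as.data.frame(x$means), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.loo_validation <- function(x, ...) x$cases

#' @export
glance.loo_validation <- function(x, ...) x$means
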