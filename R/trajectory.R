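# Per-subject remodeling trajectories, linear-shift parallel transport onto
# the mean baseline shape, the trajectory PCA atlas, and z-scored scores.

#' Compute transported remodeling trajectories
#'
#' A subject's remodeling trajectory is the follow-up minus baseline
#' displacement of every shape point.  Baselines acquired with GRE are first
#' corrected to their SSFP equivalents (`bias_model`).  With `align = TRUE`
#' all baselines are GPA-aligned to compute the mean baseline shape and each
#' follow-up inherits its subject's baseline transform, so the difference
#' reflects remodeling, not pose; with `align = FALSE` shapes are taken as
#' already pose-standardised (the synthetic generator's default frame).
#' The trajectory is transported to the common reference by linear shift:
#' `transported = mean_baseline + displacement`, exactly additive, which
#' removes cross-sectional baseline variation from downstream analysis.
#'
#' @param cohort an `lv_cohort`.
#' @param bias_model a [fit_bias_model()] result; required when the baseline
#'   protocol is GRE.
#' @param align GPA-align baselines (default `TRUE`).
#' @return An `lv_trajectories` object: `displacement` and `transported`
#'   matrices (n x 2*P*3), `mean_baseline`, subject table and template.
#' @export
compute_trajectories <- function(cohort, bias_model = NULL, align = TRUE) {
  tpl <- cohort$template
  p <- tpl$topology$n_points
  baseline <- cohort$baseline
  followup <- cohort$followup

  keep <- stats::complete.cases(baseline) & stats::complete.cases(followup)
  if (!all(keep)) {
    message("skipping ", sum(!keep),
            " subject(s) with a missing or incomplete exam")
    baseline <- baseline[keep, , drop = FALSE]
    followup <- followup[keep, , drop = FALSE]
  }
  subjects <- cohort$subjects[keep, , drop = FALSE]
  if (nrow(baseline) < 2) stop("need at least 2 complete subjects")

  corrected <- FALSE
  if (identical(cohort$protocol[["baseline"]], "GRE")) {
    if (is.null(bias_model)) {
      stop("baseline protocol is GRE: a bias model is required")
    }
    baseline <- t(apply(baseline, 1, function(v) correct_vector(bias_model, v)))
    corrected <- TRUE
  }

  if (align) {
    g <- gpa_align(baseline, tpl)
    followup <- do.call(rbind, lapply(seq_len(nrow(followup)), function(i) {
      transform_vector(followup[i, ], g$transforms[[i]], p)
    }))
    baseline <- g$aligned
  }
  mean_baseline <- colMeans(baseline)
  displacement <- followup - baseline
  transported <- sweep(displacement, 2, mean_baseline, `+`)

  structure(list(displacement = displacement, transported = transported,
                 mean_baseline = mean_baseline, subjects = subjects,
                 template = tpl, aligned = align,
                 bias_corrected = corrected),
            class = "lv_trajectories")
}

#' @export
print.lv_trajectories <- function(x, ...) {
  cat("<lv_trajectories> ", nrow(x$displacement), " subjects, ",
      if (x$aligned) "GPA-aligned" else "template frame",
      if (x$bias_corrected) ", bias-corrected baselines" else "", "\n",
      sep = "")
  invisible(x)
}

# deterministic component sign: largest-magnitude loading positive
fix_signs <- function(components) {
  flip <- apply(components, 1, function(v) sign(v[which.max(abs(v))]))
  components * flip
}

#' Build the longitudinal shape-change atlas
#'
#' PCA of the transported trajectory shapes (equivalently of the
#' displacements, up to the constant reference).  Components are sorted by
#' decreasing variance with a deterministic sign convention (the
#' largest-magnitude loading of each component is positive); the per
#' component training-score standard deviations are kept for z-scoring.
#'
#' @param trajectories an `lv_trajectories` object (>= 3 subjects).
#' @return A `trajectory_atlas`: `mean_baseline`, `mean_trajectory` (mean
#'   transported shape), `components` (M x 2*P*3, orthonormal rows),
#'   `variance`, `variance_ratio`, `score_sd`, `n_subjects`, `template`.
#' @export
build_atlas <- function(trajectories) {
  stopifnot(inherits(trajectories, "lv_trajectories"))
  x <- trajectories$transported
  n <- nrow(x)
  if (n < 3) stop("atlas construction needs at least 3 trajectories")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc, nu = 0)
  m <- min(n - 1L, ncol(x))
  comps <- fix_signs(t(sv$v[, seq_len(m), drop = FALSE]))
  variance <- sv$d[seq_len(m)]^2 / (n - 1)
  structure(list(
    mean_baseline = trajectories$mean_baseline,
    mean_trajectory = mu,
    components = comps,
    variance = variance,
    variance_ratio = variance / sum(variance),
    score_sd = sv$d[seq_len(m)] / sqrt(n - 1),
    n_subjects = n,
    template = trajectories$template
  ), class = "trajectory_atlas")
}

#' @export
print.trajectory_atlas <- function(x, ...) {
  k <- min(5L, length(x$variance_ratio))
  cat("<trajectory_atlas> ", x$n_subjects, " subjects, ",
      nrow(x$components), " components; leading variance fractions: ",
      paste(sprintf("%.1f%%", 100 * x$variance_ratio[seq_len(k)]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of components covering a variance fraction
#'
#' @param atlas a `trajectory_atlas`.
#' @param fraction target cumulative explained-variance fraction.
#' @return The smallest component count whose cumulative variance ratio
#'   reaches `fraction`.
#' @export
components_for_variance <- function(atlas, fraction = 0.99) {
  which(cumsum(atlas$variance_ratio) >= fraction - 1e-12)[1]
}

#' Project trajectories onto the atlas as z-scores
#'
#' `score_m = <transported - mean_trajectory, component_m> / score_sd_m`.
#' On the training set, scores have mean 0 and SD 1 per component.
#' Components with zero training variance are degenerate: their scores are
#' set to 0 with a warning.
#'
#' @param atlas a `trajectory_atlas`.
#' @param trajectories an `lv_trajectories` object, or a matrix/vector of
#'   transported shapes.
#' @param n_components number of leading components to score (default all).
#' @return A tibble with `subject_id` and `score_1 ... score_M`.
#' @export
project_scores <- function(atlas, trajectories,
                           n_components = nrow(atlas$components)) {
  if (inherits(trajectories, "lv_trajectories")) {
    x <- trajectories$transported
    ids <- trajectories$subjects$subject_id
  } else {
    x <- if (is.matrix(trajectories)) trajectories else
      matrix(trajectories, nrow = 1)
    ids <- sprintf("S%04d", seq_len(nrow(x)))
  }
  if (ncol(x) != ncol(atlas$components)) {
    stop("trajectory length does not match the atlas")
  }
  m <- n_components
  comps <- atlas$components[seq_len(m), , drop = FALSE]
  raw <- sweep(x, 2, atlas$mean_trajectory) %*% t(comps)
  sds <- atlas$score_sd[seq_len(m)]
  degenerate <- sds < 1e-12
  if (any(degenerate)) {
    warning(sum(degenerate),
            " degenerate component(s) with zero training variance; ",
            "scores set to 0")
    sds[degenerate] <- Inf
  }
  z <- sweep(raw, 2, sds, `/`)
  colnames(z) <- paste0("score_", seq_len(m))
  dplyr::bind_cols(tibble::tibble(subject_id = ids), tibble::as_tibble(z))
}

#' Reconstruct a transported shape from atlas scores
#'
#' `mean_trajectory + sum(score_m * score_sd_m * component_m)`; with all
#' components this inverts [project_scores()] for training shapes.
#'
#' @param atlas a `trajectory_atlas`.
#' @param scores numeric vector of z-scores (length <= M).
#' @return A flattened transported shape vector.
#' @export
reconstruct_shape <- function(atlas, scores) {
  m <- length(scores)
  atlas$mean_trajectory +
    as.vector((scores * atlas$score_sd[seq_len(m)]) %*%
                atlas$components[seq_len(m), , drop = FALSE])
}

#' @export
tidy.trajectory_atlas <- function(x, ...) {
  tibble::tibble(component = seq_along(x$variance),
                 variance = x$variance,
                 variance_ratio = x$variance_ratio,
                 cumulative = cumsum(x$variance_ratio),
                 score_sd = x$score_sd)
}

#' @export
glance.trajectory_atlas <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects,
                 n_components = nrow(x$components),
                 n_99 = components_for_variance(x, 0.99),
                 total_variance = sum(x$variance))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.trajectory_atlas <- function(object, n_components = 20, ...) {
  df <- tidy(object)
  df <- df[seq_len(min(n_components, nrow(df))), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$component, .data$variance_ratio)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative), colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative), size = 0.8) +
    ggplot2::labs(x = "trajectory component",
                  y = "explained variance fraction") +
    ggplot2::theme_minimal()
}
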