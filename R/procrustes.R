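# Rigid / similarity alignment of corresponding point sets and generalized
# Procrustes analysis (GPA) over a set of shapes.

# least-squares transform mapping A onto B (row-vector convention:
# fitted = s * A %*% R + t).  Kabsch with reflection guard.
kabsch_transform <- function(A, B, mode = c("rigid", "similarity")) {
  mode <- match.arg(mode)
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  sv <- svd(crossprod(Ac, Bc))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
    stop("degenerate point set: rank < 3, rotation is not identifiable")
  }
  sgn <- sign(det(sv$u %*% t(sv$v)))
  S <- diag(c(1, 1, sgn))
  R <- sv$u %*% S %*% t(sv$v)
  s <- if (mode == "similarity") {
    sum(sv$d * c(1, 1, sgn)) / sum(Ac^2)
  } else 1
  t_vec <- cb - s * as.vector(ca %*% R)
  list(R = R, t = t_vec, s = s)
}

apply_transform <- function(A, tf) {
  sweep(tf$s * A %*% tf$R, 2, tf$t, `+`)
}

invert_transform <- function(tf) {
  Rinv <- t(tf$R)
  list(R = Rinv, t = -as.vector(tf$t %*% Rinv) / tf$s, s = 1 / tf$s)
}

# split a flattened shape vector into its ED / ES point matrices
vec_frames <- function(v, p) {
  list(ED = matrix(v[seq_len(3L * p)], ncol = 3L, byrow = TRUE),
       ES = matrix(v[3L * p + seq_len(3L * p)], ncol = 3L, byrow = TRUE))
}

frames_vec <- function(fr) c(t(fr$ED), t(fr$ES))

# transform a flattened shape: the same spatial transform on both frames
transform_vector <- function(v, tf, p) {
  fr <- vec_frames(v, p)
  frames_vec(list(ED = apply_transform(fr$ED, tf),
                  ES = apply_transform(fr$ES, tf)))
}

#' Generalized Procrustes alignment of LV shapes
#'
#' Iteratively aligns each shape's ED frame to the evolving mean ED shape by
#' a least-squares rigid (default) or similarity transform, applying the same
#' transform to the ES frame so that contraction-related differences are
#' retained.  Iterates until the mean ED shape changes by less than `tol`
#' (mm, max absolute coordinate) or `max_iter` iterations.
#'
#' @param x an n x (2*P*3) matrix of flattened shapes ([shape_to_vector()]
#'   order), or a list of `lv_shape` objects.
#' @param template an `lv_shape` providing P when `x` is a matrix.
#' @param mode `"rigid"` (no scaling; size is a remodeling signal) or
#'   `"similarity"`.
#' @param tol convergence tolerance on the mean ED shape (mm).
#' @param max_iter maximum number of GPA iterations.
#' @return A list with `aligned` (n x d matrix), `mean` (d vector, mean of
#'   the aligned shapes), `mean_ed` (P x 3), per-shape `transforms`,
#'   `iterations` and the final `objective` (sum of squared ED distances to
#'   the mean).
#' @export
gpa_align <- function(x, template = NULL, mode = c("rigid", "similarity"),
                      tol = 1e-6, max_iter = 100) {
  mode <- match.arg(mode)
  if (is.list(x) && !is.matrix(x)) {
    if (length(x) < 2) stop("GPA needs at least 2 shapes")
    template <- x[[1]]
    x <- do.call(rbind, lapply(x, shape_to_vector))
  }
  if (is.null(template)) stop("template is required when x is a matrix")
  if (nrow(x) < 2) stop("GPA needs at least 2 shapes")
  p <- template$topology$n_points
  n <- nrow(x)

  ed_of <- function(v) matrix(v[seq_len(3L * p)], ncol = 3L, byrow = TRUE)
  mean_ed <- ed_of(colMeans(x))
  mean_ed <- sweep(mean_ed, 2, colMeans(mean_ed))
  aligned <- x
  transforms <- vector("list", n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      tf <- kabsch_transform(ed_of(x[i, ]), mean_ed, mode)
      transforms[[i]] <- tf
      aligned[i, ] <- transform_vector(x[i, ], tf, p)
    }
    new_mean <- ed_of(colMeans(aligned))
    new_mean <- sweep(new_mean, 2, colMeans(new_mean))
    delta <- max(abs(new_mean - mean_ed))
    mean_ed <- new_mean
    if (delta < tol || iter >= max_iter) break
  }
  obj <- sum(vapply(seq_len(n), function(i) {
    sum((ed_of(aligned[i, ]) - mean_ed)^2)
  }, numeric(1)))
  list(aligned = aligned, mean = colMeans(aligned), mean_ed = mean_ed,
       transforms = transforms, iterations = iter, objective = obj,
       mode = mode)
}
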