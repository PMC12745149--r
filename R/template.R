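#' LV shape objects
#'
#' An `lv_shape` holds one exam's left-ventricular geometry as two frames
#' (end-diastole `ED`, end-systole `ES`) of `P` corresponding 3D points (mm),
#' together with the shared triangulation (endocardial and epicardial
#' surfaces, each closed by a basal cap) and anatomical landmarks.  Point
#' correspondence across frames, exams and subjects is by template order, so
#' all shape algebra reduces to arithmetic on flattened coordinate vectors
#' (see [shape_to_vector()]).
#'
#' @param ed,es P x 3 numeric matrices of point coordinates (mm).
#' @param topology topology list as built by [lv_template()].
#' @param landmarks landmark list as built by [lv_template()].
#' @param subject_id subject identifier.
#' @param exam `"baseline"` or `"followup"`.
#' @param protocol acquisition protocol, `"GRE"` or `"SSFP"`.
#' @return An object of class `lv_shape`.
#' @export
lv_shape <- function(ed, es, topology, landmarks,
                     subject_id = "subject", exam = "baseline",
                     protocol = "SSFP") {
  stopifnot(is.matrix(ed), is.matrix(es), ncol(ed) == 3, ncol(es) == 3)
  if (nrow(ed) != nrow(es)) {
    stop("ED and ES frames must have identical point counts")
  }
  if (nrow(ed) != topology$n_points) {
    stop("point count does not match topology (expected ",
         topology$n_points, ", got ", nrow(ed), ")")
  }
  structure(
    list(subject_id = subject_id, exam = exam, protocol = protocol,
         points = list(ED = ed, ES = es),
         topology = topology, landmarks = landmarks),
    class = "lv_shape"
  )
}

#' @export
print.lv_shape <- function(x, ...) {
  cat("<lv_shape> ", x$subject_id, " [", x$exam, ", ", x$protocol, "]  P = ",
      x$topology$n_points, " points per frame\n", sep = "")
  invisible(x)
}

# pick a ring grid (n_phi rings of n_theta points) so that
# 2 + n_phi * n_theta is as close to p_per_surface as possible with an
# approximately 2:1 circumferential:longitudinal aspect.
choose_grid <- function(p_per_surface) {
  for (m in seq(p_per_surface - 2L, max(p_per_surface - 30L, 24L))) {
    divs <- which(m %% seq_len(m) == 0L)
    cand <- divs[divs >= 8L & m %/% divs >= 3L]
    if (length(cand)) {
      n_theta <- cand[which.min(abs(cand - 2 * m / cand))]
      return(list(n_theta = as.integer(n_theta),
                  n_phi = as.integer(m %/% n_theta)))
    }
  }
  stop("cannot build a ring grid for p_per_surface = ", p_per_surface)
}

# points of one truncated-spheroid surface in template pose.
# axes = (a, b, c) semi-axes; long axis +z, apex at z = -c, truncation
# (basal) plane at z = z_base.  Order: apex, rings apex->base, base center.
spheroid_surface <- function(axes, z_base, n_theta, n_phi) {
  a <- axes[1]; b <- axes[2]; cc <- axes[3]
  if (z_base >= cc) {
    stop("basal plane (z = ", z_base, ") must lie below the long semi-axis (",
         cc, " mm)")
  }
  phi_base <- acos(z_base / cc)
  phi <- pi - seq_len(n_phi) * (pi - phi_base) / n_phi
  theta <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  rings <- do.call(rbind, lapply(phi, function(p) {
    cbind(a * sin(p) * cos(theta), b * sin(p) * sin(theta),
          rep(cc * cos(p), n_theta))
  }))
  rbind(c(0, 0, -cc), rings, c(0, 0, z_base))
}

# triangle list (local ids) for one closed surface: apex fan, quad strips,
# basal cap fan.  Winding is made globally outward by the caller.
surface_triangles <- function(n_theta, n_phi) {
  ring <- function(k, j) 1L + (k - 1L) * n_theta + (j - 1L) %% n_theta + 1L
  apex <- 1L
  ctr <- 2L + n_phi * n_theta
  j <- seq_len(n_theta)
  tri <- rbind(
    cbind(apex, ring(1L, j + 1L), ring(1L, j)),
    if (n_phi > 1L) do.call(rbind, lapply(seq_len(n_phi - 1L), function(k) {
      rbind(cbind(ring(k, j), ring(k, j + 1L), ring(k + 1L, j + 1L)),
            cbind(ring(k, j), ring(k + 1L, j + 1L), ring(k + 1L, j)))
    })),
    cbind(ctr, ring(n_phi, j), ring(n_phi, j + 1L))
  )
  colnames(tri) <- c("v1", "v2", "v3")
  tri
}

#' Build the default LV surface template
#'
#' Constructs a truncated-prolate-spheroid two-surface LV template:
#' endocardial and epicardial surfaces, each closed by a flat basal cap, with
#' apex and mitral-ring landmarks.  Each surface is an apex point, `n_phi`
#' rings of `n_theta` points and a basal cap-center point; the default grid
#' (41 x 19 per surface) gives the standard 1562 points per frame.  The ES
#' frame is a contracted version of ED (radially and longitudinally scaled
#' cavity, thicker wall) giving physiologic volumes, ejection fraction and
#' wall thickening.
#'
#' @param p_per_surface requested points per surface (>= 50); the realised
#'   count is the closest ring grid, exact for the default 781.
#' @param wall_mm ED wall thickness (mm).
#' @param cavity_axes ED endocardial semi-axes (a, b, c) in mm, long axis c.
#' @param base_fraction basal truncation plane height as a fraction of c.
#' @param es_radial_scale,es_long_scale ES cavity scaling relative to ED.
#' @param es_wall_mm ES wall thickness (mm).
#' @return An object of class `lv_template` (also an `lv_shape`).
#' @examples
#' tpl <- lv_template(p_per_surface = 83)
#' tpl$topology$n_points
#' @export
lv_template <- function(p_per_surface = 781, wall_mm = 8,
                        cavity_axes = c(28.5, 28.5, 50),
                        base_fraction = 0.4,
                        es_radial_scale = 0.68, es_long_scale = 0.86,
                        es_wall_mm = 11) {
  if (p_per_surface < 50) stop("p_per_surface must be at least 50")
  if (wall_mm <= 0) stop("wall_mm must be positive")
  if (es_wall_mm <= 0) stop("es_wall_mm must be positive")
  if (any(cavity_axes <= 0)) stop("cavity_axes must all be positive")

  g <- choose_grid(p_per_surface)
  n_loc <- 2L + g$n_theta * g$n_phi
  z_base <- base_fraction * cavity_axes[3]

  endo_ed <- spheroid_surface(cavity_axes, z_base, g$n_theta, g$n_phi)
  epi_ed <- spheroid_surface(cavity_axes + wall_mm, z_base, g$n_theta, g$n_phi)
  es_axes <- cavity_axes * c(es_radial_scale, es_radial_scale, es_long_scale)
  endo_es <- spheroid_surface(es_axes, z_base, g$n_theta, g$n_phi)
  epi_es <- spheroid_surface(es_axes + es_wall_mm, z_base, g$n_theta, g$n_phi)

  tri_loc <- surface_triangles(g$n_theta, g$n_phi)
  n_tri <- nrow(tri_loc)
  is_cap <- c(rep(FALSE, n_tri - g$n_theta), rep(TRUE, g$n_theta))
  triangles <- tibble::tibble(
    surface = rep(c("endo", "epi"), each = n_tri),
    part = rep(ifelse(is_cap, "cap", "wall"), 2L),
    v1 = c(tri_loc[, 1], tri_loc[, 1] + n_loc),
    v2 = c(tri_loc[, 2], tri_loc[, 2] + n_loc),
    v3 = c(tri_loc[, 3], tri_loc[, 3] + n_loc)
  )

  topology <- list(
    triangles = triangles,
    n_points = 2L * n_loc,
    n_per_surface = n_loc,
    n_theta = g$n_theta,
    n_phi = g$n_phi,
    endo_ids = seq_len(n_loc),
    epi_ids = n_loc + seq_len(n_loc),
    # myocardial wall points: apex + rings (cap centers are mesh plumbing)
    wall_local_ids = seq_len(n_loc - 1L)
  )

  base_ring <- 1L + (g$n_phi - 1L) * g$n_theta + seq_len(g$n_theta)
  landmarks <- list(
    apex_endo = 1L,
    mitral_ring = base_ring,
    base_center_endo = n_loc,
    apex_epi = n_loc + 1L,
    base_center_epi = 2L * n_loc,
    anterior_ref = base_ring[1L]
  )

  ed <- rbind(endo_ed, epi_ed)
  es <- rbind(endo_es, epi_es)
  # orient each closed surface outward (positive divergence-theorem volume)
  for (s in c("endo", "epi")) {
    sel <- triangles$surface == s
    tr <- as.matrix(triangles[sel, c("v1", "v2", "v3")])
    if (signed_mesh_volume(ed, tr) < 0) {
      triangles[sel, c("v2", "v3")] <- triangles[sel, c("v3", "v2")]
    }
  }
  topology$triangles <- triangles

  out <- lv_shape(ed, es, topology, landmarks,
                  subject_id = "template", exam = "baseline",
                  protocol = "SSFP")
  out$params <- list(p_per_surface = p_per_surface, wall_mm = wall_mm,
                     cavity_axes = cavity_axes, base_fraction = base_fraction,
                     es_radial_scale = es_radial_scale,
                     es_long_scale = es_long_scale, es_wall_mm = es_wall_mm)
  class(out) <- c("lv_template", "lv_shape")
  out
}

#' Flatten an LV shape to a coordinate vector
#'
#' The unit object of all atlas algebra: the ED frame then the ES frame, each
#' point as (x, y, z), giving a vector of length `2 * P * 3`.
#'
#' @param shape an `lv_shape`.
#' @return Numeric vector of length `2 * P * 3`.
#' @export
shape_to_vector <- function(shape) {
  c(t(shape$points$ED), t(shape$points$ES))
}

#' Rebuild an LV shape from a coordinate vector
#'
#' Inverse of [shape_to_vector()]; topology and landmarks are taken from a
#' reference shape (usually the template), so the round trip is lossless.
#'
#' @param v numeric vector of length `2 * P * 3`.
#' @param reference an `lv_shape` providing topology and landmarks.
#' @inheritParams lv_shape
#' @return An `lv_shape`.
#' @export
vector_to_shape <- function(v, reference, subject_id = "subject",
                            exam = "baseline", protocol = "SSFP") {
  p <- reference$topology$n_points
  if (length(v) != 2L * p * 3L) {
    stop("vector length ", length(v), " does not match 2 * P * 3 = ",
         2L * p * 3L)
  }
  ed <- matrix(v[seq_len(3L * p)], ncol = 3L, byrow = TRUE)
  es <- matrix(v[3L * p + seq_len(3L * p)], ncol = 3L, byrow = TRUE)
  lv_shape(ed, es, reference$topology, reference$landmarks,
           subject_id = subject_id, exam = exam, protocol = protocol)
}
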