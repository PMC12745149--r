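# Parameterised displacement fields on the template, used by the synthetic
# cohort generator to plant baseline variation, aging drift, protocol bias
# and risk-factor effect modes.  A field is a length 2*P*3 vector in
# shape_to_vector() order, in mm (per unit of whatever drives it).

# per-wall-point transmural unit vectors (endo -> epi) for one frame;
# zero rows for the basal cap-center points
transmural_dirs <- function(points, topology) {
  n_loc <- topology$n_per_surface
  dirs <- matrix(0, n_loc, 3)
  wl <- topology$wall_local_ids
  e <- points[topology$endo_ids[wl], , drop = FALSE]
  p <- points[topology$epi_ids[wl], , drop = FALSE]
  d <- p - e
  dirs[wl, ] <- d / sqrt(rowSums(d^2))
  dirs
}

# angular/longitudinal coordinates of wall points on the template ED frame
wall_coords <- function(template) {
  topo <- template$topology
  fr <- long_axis_frame(template$points$ED, template$landmarks)
  wl <- topo$wall_local_ids
  mid <- (template$points$ED[topo$endo_ids[wl], , drop = FALSE] +
          template$points$ED[topo$epi_ids[wl], , drop = FALSE]) / 2
  rel <- sweep(mid, 2, fr$apex)
  h <- as.vector(rel %*% fr$u) / fr$length
  d <- sweep(mid, 2, fr$base)
  theta <- atan2(as.vector(d %*% fr$e2), as.vector(d %*% fr$e1)) %% (2 * pi)
  list(theta = theta, h = h)
}

# assemble a field from per-frame endo/epi wall displacements (matrices of
# n_wall x 3; cap centers stay fixed)
assemble_field <- function(template, endo_ed, epi_ed, endo_es, epi_es) {
  topo <- template$topology
  n_loc <- topo$n_per_surface
  wl <- topo$wall_local_ids
  build <- function(endo_w, epi_w) {
    m <- matrix(0, 2L * n_loc, 3)
    m[topo$endo_ids[wl], ] <- endo_w
    m[topo$epi_ids[wl], ] <- epi_w
    m
  }
  c(t(build(endo_ed, epi_ed)), t(build(endo_es, epi_es)))
}

mod_values <- function(template, modulate) {
  if (is.null(modulate)) return(rep(1, length(template$topology$wall_local_ids)))
  wc <- wall_coords(template)
  modulate(wc$theta, wc$h)
}

#' Zero displacement field
#' @param template an `lv_shape`.
#' @return Numeric vector of zeros, length `2 * P * 3`.
#' @export
field_zero <- function(template) {
  numeric(2L * template$topology$n_points * 3L)
}

#' Uniform scaling field
#'
#' Displacement of every point away from its frame centroid; at `frac = f`
#' each frame is inflated by a factor `1 + f` per unit field.
#'
#' @param template an `lv_shape`.
#' @param frac fractional size change per unit field.
#' @return A displacement field (length `2 * P * 3`).
#' @export
field_scale <- function(template, frac = 0.01) {
  ed <- template$points$ED; es <- template$points$ES
  c(t(sweep(ed, 2, colMeans(ed)) * frac), t(sweep(es, 2, colMeans(es)) * frac))
}

#' Long-axis stretch field
#'
#' Displacement along the long axis proportional to apex distance: per unit
#' field the apex-to-base length grows by the fraction `frac`.
#'
#' @inheritParams field_scale
#' @export
field_long_stretch <- function(template, frac = 0.01) {
  fr <- long_axis_frame(template$points$ED, template$landmarks)
  one <- function(pts) {
    t_along <- as.vector(sweep(pts, 2, fr$apex) %*% fr$u)
    outer(t_along * frac, fr$u)
  }
  c(t(one(template$points$ED)), t(one(template$points$ES)))
}

#' Endocardial transmural displacement field
#'
#' Moves endocardial wall points along the local transmural (endo-to-epi)
#' direction; positive `mm` enlarges the cavity.  An optional `modulate`
#' function of the circumferential angle `theta` (radians, 0 at the anterior
#' reference) and normalized long-axis height `h` (0 apex, 1 base) scales the
#' displacement regionally.
#'
#' @param template an `lv_shape`.
#' @param mm displacement magnitude (mm per unit field).
#' @param modulate optional `function(theta, h)` returning multipliers.
#' @param frames multipliers for the ED and ES frames.
#' @export
field_endo_radial <- function(template, mm = 1, modulate = NULL,
                              frames = c(ED = 1, ES = 1)) {
  topo <- template$topology
  wl <- topo$wall_local_ids
  m <- mod_values(template, modulate)
  dir_ed <- transmural_dirs(template$points$ED, topo)[wl, , drop = FALSE]
  dir_es <- transmural_dirs(template$points$ES, topo)[wl, , drop = FALSE]
  z <- matrix(0, length(wl), 3)
  assemble_field(template,
                 endo_ed = dir_ed * mm * m * frames[["ED"]], epi_ed = z,
                 endo_es = dir_es * mm * m * frames[["ES"]], epi_es = z)
}

#' Epicardial transmural displacement field
#'
#' Moves epicardial wall points along the local transmural direction;
#' positive `mm` displaces outward (mass increases).
#'
#' @inheritParams field_endo_radial
#' @export
field_epi_normal <- function(template, mm = 1, modulate = NULL,
                             frames = c(ED = 1, ES = 1)) {
  topo <- template$topology
  wl <- topo$wall_local_ids
  m <- mod_values(template, modulate)
  dir_ed <- transmural_dirs(template$points$ED, topo)[wl, , drop = FALSE]
  dir_es <- transmural_dirs(template$points$ES, topo)[wl, , drop = FALSE]
  z <- matrix(0, length(wl), 3)
  assemble_field(template,
                 endo_ed = z, epi_ed = dir_ed * mm * m * frames[["ED"]],
                 endo_es = z, epi_es = dir_es * mm * m * frames[["ES"]])
}

#' Wall-thickness change field
#'
#' Symmetric transmural displacement: endocardium inward and epicardium
#' outward by `mm / 2` each, so the corresponding-point wall thickness grows
#' by `mm` per unit field (concentric thickening).
#'
#' @inheritParams field_endo_radial
#' @export
field_wall_thickness <- function(template, mm = 1, modulate = NULL,
                                 frames = c(ED = 1, ES = 1)) {
  field_epi_normal(template, mm / 2, modulate, frames) -
    field_endo_radial(template, mm / 2, modulate, frames)
}

#' Volume-neutral regional shape field
#'
#' Endocardial transmural displacement modulated by `cos(2 * theta)`:
#' opposite sectors move in and out by equal cavity volume, so EDV, ESV, EF
#' and mass are unchanged to first order while the regional shape signal is
#' strong.  Used to demonstrate shape-score discrimination that mass/volume
#' predictors cannot see.
#'
#' @inheritParams field_endo_radial
#' @export
field_volume_neutral <- function(template, mm = 1) {
  field_endo_radial(template, mm, modulate = function(theta, h) cos(2 * theta))
}

#' Default GRE-to-SSFP protocol-bias field
#'
#' SSFP acquisitions yield larger cavity volumes and smaller mass than GRE:
#' the default bias moves the endocardium outward and the epicardium inward.
#'
#' @param template an `lv_shape`.
#' @param endo_mm outward endocardial displacement (mm).
#' @param epi_mm inward epicardial displacement (mm, positive = inward).
#' @export
default_protocol_bias <- function(template, endo_mm = 1.5, epi_mm = 1.0) {
  field_endo_radial(template, endo_mm) + field_epi_normal(template, -epi_mm)
}

#' Default cross-sectional baseline shape modes
#'
#' Inter-subject baseline variation: overall size, long-axis proportion and
#' wall thickness, with standard deviations chosen to give a realistic
#' spread of baseline EDV and mass (roughly 20 percent coefficient of
#' variation in volume).
#'
#' @param template an `lv_shape`.
#' @return A list of `list(field, sd)` entries.
#' @export
default_baseline_modes <- function(template) {
  list(
    size = list(field = field_scale(template, 1), sd = 0.06),
    elongation = list(field = field_long_stretch(template, 1), sd = 0.05),
    wall = list(field = field_wall_thickness(template, 1), sd = 0.8)
  )
}

#' Default within-cohort trajectory variation modes
#'
#' Subject-specific remodeling variation beyond the shared aging drift and
#' risk-factor effects (unexplained longitudinal change).
#'
#' @inheritParams default_baseline_modes
#' @export
default_trajectory_modes <- function(template) {
  list(
    size_change = list(field = field_scale(template, 1), sd = 0.02),
    wall_change = list(field = field_wall_thickness(template, 1), sd = 0.4)
  )
}

#' Default population aging-drift field (per decade)
#'
#' Concentric-remodeling drift: cavity shrinks while mass rises slightly, so
#' the mass-to-volume ratio increases over a decade, the dominant population
#' trend between the two exams.
#'
#' @inheritParams default_baseline_modes
#' @export
default_aging_drift <- function(template) {
  -field_endo_radial(template, 0.9) - field_epi_normal(template, 0.45) +
    field_endo_radial(template, 0.25, frames = c(ED = 0, ES = 1))
}

#' Default risk-factor effect fields
#'
#' Planted per-factor remodeling effects with directions matching the
#' qualitative clinical picture (obesity: concentric thickening with smaller
#' cavity; smoking: wall thinning and smaller cavity; hypertension and its
#' treatment: mass up / mass down; diabetes: smaller, less spherical cavity)
#' and magnitudes keeping derived-measure deltas within roughly 15 percent,
#' i.e. inside the small-deformation regime that justifies linear-shift
#' transport.
#'
#' @inheritParams default_baseline_modes
#' @return Named list of displacement fields, one per binary risk factor.
#' @export
default_effect_modes <- function(template) {
  list(
    obesity = field_wall_thickness(template, 0.9) -
      field_endo_radial(template, 0.3),
    high_cholesterol = -field_epi_normal(template, 0.2),
    hypertension = field_epi_normal(template, 0.5),
    smoking = -field_wall_thickness(template, 0.6) -
      field_endo_radial(template, 0.4),
    diabetes = -field_scale(template, 0.015) +
      field_long_stretch(template, 0.01),
    htn_medication = -field_epi_normal(template, 0.35),
    statins = field_endo_radial(template, 0.15)
  )
}
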