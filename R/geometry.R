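# Mesh geometry and derived clinical measures.

# signed divergence-theorem volume in the input units (mm^3 here)
signed_mesh_volume <- function(points, tri) {
  a <- points[tri[, 1], , drop = FALSE]
  b <- points[tri[, 2], , drop = FALSE]
  cc <- points[tri[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

# every undirected edge of a closed orientable surface is shared by exactly
# two triangles, traversed in opposite directions
check_watertight <- function(tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  bad <- names(cnt)[cnt != 2L]
  if (length(bad)) {
    stop("surface is not watertight: edge ", bad[1],
         " is used by ", cnt[bad[1]], " triangle(s)")
  }
  dir_cnt <- table(paste(e[, 1], e[, 2]))
  if (any(dir_cnt != 1L)) {
    b <- names(dir_cnt)[dir_cnt != 1L][1]
    stop("surface is not consistently oriented: directed edge ", b,
         " appears more than once")
  }
  invisible(TRUE)
}

#' Volume enclosed by a triangulated surface
#'
#' Divergence-theorem volume of a closed, consistently oriented triangle
#' mesh.  Coordinates are in mm; the result is returned in mL.
#'
#' @param points P x 3 matrix of vertex coordinates (mm).
#' @param triangles integer matrix/data frame with columns `v1, v2, v3`
#'   (1-based vertex indices) describing a watertight oriented surface.
#' @param strict if `TRUE` (default) an open, inconsistently oriented or
#'   fully degenerate surface is an error; if `FALSE` a degenerate surface
#'   returns 0 (openness is always an error).
#' @return Enclosed volume in mL (absolute value).
#' @examples
#' tpl <- lv_template(p_per_surface = 83)
#' endo <- tpl$topology$triangles[tpl$topology$triangles$surface == "endo", ]
#' mesh_volume(tpl$points$ED, endo)
#' @export
mesh_volume <- function(points, triangles, strict = TRUE) {
  tri <- as.matrix(as.data.frame(triangles)[, c("v1", "v2", "v3")])
  storage.mode(tri) <- "integer"
  check_watertight(tri)
  a <- points[tri[, 1], , drop = FALSE]
  b <- points[tri[, 2], , drop = FALSE]
  cc <- points[tri[, 3], , drop = FALSE]
  areas <- sqrt(rowSums((cbind(
    (b[, 2] - a[, 2]) * (cc[, 3] - a[, 3]) - (b[, 3] - a[, 3]) * (cc[, 2] - a[, 2]),
    (b[, 3] - a[, 3]) * (cc[, 1] - a[, 1]) - (b[, 1] - a[, 1]) * (cc[, 3] - a[, 3]),
    (b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1])
  ))^2)) / 2
  if (all(areas < 1e-12)) {
    if (strict) {
      stop("degenerate surface: all triangle areas are ~0 (first triangle: ",
           paste(tri[1, ], collapse = "-"), ")")
    }
    return(0)
  }
  abs(signed_mesh_volume(points, tri)) / 1000
}

# closed surface (wall + cap) triangles for one side
surface_tri <- function(topology, surface) {
  tt <- topology$triangles
  as.matrix(tt[tt$surface == surface, c("v1", "v2", "v3")])
}

# cavity / wall volumes (mL) for one frame
frame_volumes <- function(points, topology) {
  endo <- mesh_volume(points, surface_tri(topology, "endo"))
  epi <- mesh_volume(points, surface_tri(topology, "epi"))
  list(endo = endo, epi = epi)
}

# long-axis frame from landmarks: origin at endocardial apex, unit long axis
# u pointing apex -> mitral centroid, orthonormal in-plane axes (e1 toward
# the anterior reference landmark).  Rigid-motion equivariant by construction.
long_axis_frame <- function(points, landmarks) {
  apex <- points[landmarks$apex_endo, ]
  base <- colMeans(points[landmarks$mitral_ring, , drop = FALSE])
  u <- base - apex
  len <- sqrt(sum(u^2))
  if (len < 1e-9) stop("degenerate long axis: apex coincides with mitral centroid")
  u <- u / len
  aref <- points[landmarks$anterior_ref, ] - base
  e1 <- aref - sum(aref * u) * u
  n1 <- sqrt(sum(e1^2))
  if (n1 < 1e-9) stop("anterior reference landmark lies on the long axis")
  e1 <- e1 / n1
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(apex = apex, base = base, u = u, e1 = e1, e2 = e2, length = len)
}

#' Percent systolic wall thickening
#'
#' `100 * (wt_es - wt_ed) / wt_ed`, the regional thickening convention used
#' for the 17-segment maps.
#'
#' @param wt_ed,wt_es wall thickness at ED and ES (mm); `wt_ed` must be
#'   positive.
#' @return Thickening in percent.
#' @export
wall_thickening <- function(wt_ed, wt_es) {
  if (any(wt_ed <= 0)) stop("wall thickness at ED must be positive")
  100 * (wt_es - wt_ed) / wt_ed
}

#' Percent change between two values
#'
#' `100 * (after - before) / before`; used for longitudinal deltas of derived
#' measures (e.g. the mass-to-volume ratio worked example: 1.0 to 1.1 is a
#' 10 percent increase).
#'
#' @param before,after numeric; `before` must be nonzero.
#' @return Percent change.
#' @export
percent_change <- function(before, after) {
  if (any(before == 0)) stop("reference value must be nonzero")
  100 * (after - before) / before
}

#' AHA 17-segment assignment of myocardial points
#'
#' Assigns every myocardial wall point (endocardial and epicardial; basal
#' cap-center points are mesh plumbing, not myocardium) to one of the 17
#' American Heart Association segments, using the landmark-derived long-axis
#' frame of the ED endocardium: an apical-cap band (segment 17), then
#' apical/mid/basal thirds split into 4/6/6 circumferential sectors.  The
#' construction uses only landmark-relative geometry, so it is invariant
#' under rigid motion of the shape.
#'
#' @param shape an `lv_shape` with apex and mitral-ring landmarks.
#' @param apex_cap_fraction long-axis fraction below which points belong to
#'   the apical cap (segment 17).
#' @return A tibble with columns `point_id`, `surface` and `segment` (1-17),
#'   one row per myocardial point.
#' @export
aha17_segment_map <- function(shape, apex_cap_fraction = 0.15) {
  lm <- shape$landmarks
  if (is.null(lm$apex_endo) || is.null(lm$mitral_ring)) {
    stop("shape is missing apex/mitral-ring landmarks")
  }
  topo <- shape$topology
  seg <- aha17_segments_local(shape$points$ED, topo, lm, apex_cap_fraction)
  ids <- c(topo$endo_ids[topo$wall_local_ids], topo$epi_ids[topo$wall_local_ids])
  tibble::tibble(
    point_id = ids,
    surface = rep(c("endo", "epi"), each = length(topo$wall_local_ids)),
    segment = rep(seg, 2L)
  )
}

# segment (1..17) per wall-local point id, from midwall ED position
aha17_segments_local <- function(points, topology, landmarks,
                                 apex_cap_fraction = 0.15) {
  wl <- topology$wall_local_ids
  mid <- (points[topology$endo_ids[wl], , drop = FALSE] +
          points[topology$epi_ids[wl], , drop = FALSE]) / 2
  fr <- long_axis_frame(points, landmarks)
  rel <- sweep(mid, 2, fr$apex)
  h <- as.vector(rel %*% fr$u) / fr$length
  d <- sweep(mid, 2, fr$base)
  theta <- atan2(as.vector(d %*% fr$e2), as.vector(d %*% fr$e1)) %% (2 * pi)

  sector6 <- (floor(((theta + pi / 6) %% (2 * pi)) / (pi / 3)) %% 6) + 1L
  sector4 <- (floor(((theta + pi / 4) %% (2 * pi)) / (pi / 2)) %% 4) + 1L

  lo <- apex_cap_fraction
  thirds <- lo + (1 - lo) * c(1, 2) / 3
  seg <- integer(length(h))
  seg[h < lo] <- 17L
  api <- h >= lo & h < thirds[1]
  seg[api] <- 12L + sector4[api]
  mid3 <- h >= thirds[1] & h < thirds[2]
  seg[mid3] <- 6L + sector6[mid3]
  bas <- h >= thirds[2]
  seg[bas] <- sector6[bas]
  seg
}

# per-point wall thickness (corresponding endo/epi distance), wall-local order
point_wall_thickness <- function(points, topology) {
  wl <- topology$wall_local_ids
  e <- points[topology$endo_ids[wl], , drop = FALSE]
  p <- points[topology$epi_ids[wl], , drop = FALSE]
  sqrt(rowSums((p - e)^2))
}

# segments contributing to the conventional septal / inferolateral averages
septal_segments <- c(2L, 3L, 8L, 9L)
inferolateral_segments <- c(5L, 11L)

#' Derived clinical measures of an LV shape
#'
#' Computes cavity volumes, mass, ejection fraction, mass-to-volume ratio,
#' sphericity volume index, longitudinal shortening, wall thicknesses and
#' AHA 17-segment regional thickening from one exam's shape.
#'
#' Definitions: EDV/ESV are the endocardial surface volumes; mass is
#' `density * (epi - endo)` volume at ED; `EF = 100 (EDV - ESV)/EDV`;
#' `MVR = mass/EDV`; `L` is the apex-to-mitral-centroid length and
#' `LS = 100 (L_ED - L_ES)/L_ED`; SphVi (per frame) is cavity volume divided
#' by the volume of the sphere of diameter `L`; per-point wall thickness is
#' the corresponding endo-epi point distance; `RWT_ED` is twice the mean ED
#' inferolateral wall thickness over the mid-cavity internal diameter;
#' regional values average the per-point thickness over AHA segments, and
#' regional thickening applies [wall_thickening()] to the segment means.
#'
#' @param shape an `lv_shape`.
#' @param density myocardial density in g/mL (default 1.05, the standard CMR
#'   convention).
#' @return A one-row tibble with scalar measures and three 17-element
#'   list-columns (`regional_WT_ED`, `regional_WT_ES` in mm,
#'   `regional_thickening` in percent).
#' @export
derived_measures <- function(shape, density = 1.05) {
  topo <- shape$topology
  lm <- shape$landmarks
  ved <- frame_volumes(shape$points$ED, topo)
  ves <- frame_volumes(shape$points$ES, topo)
  edv <- ved$endo
  esv <- ves$endo
  if (edv <= 0) stop("zero or negative end-diastolic cavity volume")
  mass <- density * (ved$epi - ved$endo)

  fr_ed <- long_axis_frame(shape$points$ED, lm)
  fr_es <- long_axis_frame(shape$points$ES, lm)
  if (fr_ed$length <= 0 || fr_es$length <= 0) stop("zero long-axis length")
  ls <- 100 * (fr_ed$length - fr_es$length) / fr_ed$length
  # sphere of diameter L (mm): volume in mL = (pi/6) L^3 / 1000
  sph_ed <- edv / (pi / 6 * fr_ed$length^3 / 1000)
  sph_es <- esv / (pi / 6 * fr_es$length^3 / 1000)

  wt_ed <- point_wall_thickness(shape$points$ED, topo)
  wt_es <- point_wall_thickness(shape$points$ES, topo)
  seg <- aha17_segments_local(shape$points$ED, topo, lm)
  reg_ed <- vapply(1:17, function(s) mean(wt_ed[seg == s]), numeric(1))
  reg_es <- vapply(1:17, function(s) mean(wt_es[seg == s]), numeric(1))
  reg_thick <- wall_thickening(reg_ed, reg_es)

  septal <- mean(wt_ed[seg %in% septal_segments])
  infl <- mean(wt_ed[seg %in% inferolateral_segments])

  # mid-cavity internal diameter: twice the mean distance of mid-band
  # endocardial points from the long axis at ED
  wl <- topo$wall_local_ids
  endo_pts <- shape$points$ED[topo$endo_ids[wl], , drop = FALSE]
  rel <- sweep(endo_pts, 2, fr_ed$apex)
  h <- as.vector(rel %*% fr_ed$u) / fr_ed$length
  perp <- rel - outer(as.vector(rel %*% fr_ed$u), fr_ed$u)
  rad <- sqrt(rowSums(perp^2))
  midband <- h >= 0.4 & h <= 0.6
  if (!any(midband)) stop("no endocardial points in the mid-cavity band")
  idim <- 2 * mean(rad[midband])
  rwt <- 2 * infl / idim

  tibble::tibble(
    subject_id = shape$subject_id, exam = shape$exam,
    EDV = edv, ESV = esv, mass = mass,
    EF = 100 * (edv - esv) / edv, MVR = mass / edv,
    SphVi_ED = sph_ed, SphVi_ES = sph_es, LS = ls, RWT_ED = rwt,
    septal_WT = septal, inferolateral_WT = infl,
    regional_WT_ED = list(reg_ed), regional_WT_ES = list(reg_es),
    regional_thickening = list(reg_thick)
  )
}

#' Derived measures for every shape in a cohort
#'
#' @param cohort an `lv_cohort` (see [simulate_cohort()]).
#' @param density myocardial density in g/mL.
#' @return A tibble with one row per subject and exam.
#' @export
cohort_measures <- function(cohort, density = 1.05) {
  tpl <- cohort$template
  rows <- purrr::map(seq_len(nrow(cohort$subjects)), function(i) {
    dplyr::bind_rows(
      derived_measures(vector_to_shape(
        cohort$baseline[i, ], tpl,
        subject_id = cohort$subjects$subject_id[i], exam = "baseline",
        protocol = cohort$protocol[["baseline"]]), density),
      derived_measures(vector_to_shape(
        cohort$followup[i, ], tpl,
        subject_id = cohort$subjects$subject_id[i], exam = "followup",
        protocol = cohort$protocol[["followup"]]), density)
    )
  })
  dplyr::bind_rows(rows)
}
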