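# Plain-text interchange formats: per-point shape CSV, topology and landmark
# tables, covariates, atlas and bias-model directories.  point_id and vertex
# indices are 0-based on disk (template order), 1-based in memory.

#' Write shapes to the per-point CSV format
#'
#' Columns: `subject_id, exam, protocol, frame, point_id, x_mm, y_mm, z_mm`
#' with 0-based `point_id` in template order.
#'
#' @param shapes an `lv_shape`, a list of them, or an `lv_cohort`.
#' @param file output path.
#' @export
write_shapes <- function(shapes, file) {
  if (inherits(shapes, "lv_cohort")) {
    shapes <- unlist(lapply(seq_len(nrow(shapes$subjects)), function(i) {
      list(cohort_shape(shapes, i, "baseline"),
           cohort_shape(shapes, i, "followup"))
    }), recursive = FALSE)
  }
  if (inherits(shapes, "lv_shape")) shapes <- list(shapes)
  rows <- purrr::map_dfr(shapes, function(s) {
    p <- s$topology$n_points
    purrr::map_dfr(c("ED", "ES"), function(fr) {
      tibble::tibble(subject_id = s$subject_id, exam = s$exam,
                     protocol = s$protocol, frame = fr,
                     point_id = seq_len(p) - 1L,
                     x_mm = s$points[[fr]][, 1], y_mm = s$points[[fr]][, 2],
                     z_mm = s$points[[fr]][, 3])
    })
  })
  readr::write_csv(rows, file)
}

#' Write the shared triangulation
#'
#' Columns: `surface` (`endo` / `epi` / `cap`), `v0, v1, v2` (0-based).
#'
#' @param template an `lv_shape` carrying the topology.
#' @param file output path.
#' @export
write_topology <- function(template, file) {
  tt <- template$topology$triangles
  readr::write_csv(tibble::tibble(
    surface = ifelse(tt$part == "cap", "cap", tt$surface),
    v0 = tt$v1 - 1L, v1 = tt$v2 - 1L, v2 = tt$v3 - 1L
  ), file)
}

#' Write the landmark table
#'
#' Columns: `role`, `point_id` (0-based); the mitral ring spans several rows.
#'
#' @inheritParams write_topology
#' @export
write_landmarks <- function(template, file) {
  lm <- template$landmarks
  readr::write_csv(tibble::tibble(
    role = c("apex_endo", rep("mitral_ring", length(lm$mitral_ring)),
             "base_center_endo", "apex_epi", "base_center_epi",
             "anterior_ref"),
    point_id = c(lm$apex_endo, lm$mitral_ring, lm$base_center_endo,
                 lm$apex_epi, lm$base_center_epi, lm$anterior_ref) - 1L
  ), file)
}

# rebuild topology + landmarks from the interchange tables
parse_geometry <- function(topo_df, lm_df, n_points) {
  n_loc <- n_points %/% 2L
  v <- cbind(topo_df$v0, topo_df$v1, topo_df$v2) + 1L
  storage.mode(v) <- "integer"
  surf <- topo_df$surface
  cap <- surf == "cap"
  surf[cap] <- ifelse(apply(v[cap, , drop = FALSE] <= n_loc, 1, all),
                      "endo", "epi")
  lm_ids <- function(role) as.integer(lm_df$point_id[lm_df$role == role]) + 1L
  landmarks <- list(apex_endo = lm_ids("apex_endo"),
                    mitral_ring = lm_ids("mitral_ring"),
                    base_center_endo = lm_ids("base_center_endo"),
                    apex_epi = lm_ids("apex_epi"),
                    base_center_epi = lm_ids("base_center_epi"),
                    anterior_ref = lm_ids("anterior_ref"))
  centers_local <- c(landmarks$base_center_endo,
                     landmarks$base_center_epi - n_loc)
  topology <- list(
    triangles = tibble::tibble(surface = surf,
                               part = ifelse(cap, "cap", "wall"),
                               v1 = v[, 1], v2 = v[, 2], v3 = v[, 3]),
    n_points = n_points, n_per_surface = n_loc,
    endo_ids = seq_len(n_loc), epi_ids = n_loc + seq_len(n_loc),
    wall_local_ids = setdiff(seq_len(n_loc), centers_local)
  )
  list(topology = topology, landmarks = landmarks)
}

#' Read shapes from the per-point CSV format
#'
#' @param shape_file per-point shape CSV (see [write_shapes()]).
#' @param topology_file triangulation CSV (see [write_topology()]).
#' @param landmark_file landmark CSV (see [write_landmarks()]).
#' @return A list of `lv_shape` objects.
#' @export
read_shapes <- function(shape_file, topology_file, landmark_file) {
  pts <- readr::read_csv(shape_file, show_col_types = FALSE)
  topo_df <- readr::read_csv(topology_file, show_col_types = FALSE)
  lm_df <- readr::read_csv(landmark_file, show_col_types = FALSE)
  n_points <- max(pts$point_id) + 1L
  geo <- parse_geometry(topo_df, lm_df, n_points)
  groups <- split(pts, interaction(pts$subject_id, pts$exam, pts$protocol,
                                   drop = TRUE))
  shapes <- lapply(groups, function(g) {
    g <- g[order(g$frame, g$point_id), ]
    frames <- split(g, g$frame)
    mat <- function(fr) {
      m <- as.matrix(fr[, c("x_mm", "y_mm", "z_mm")])
      dimnames(m) <- NULL
      m
    }
    lv_shape(mat(frames$ED), mat(frames$ES),
             geo$topology, geo$landmarks,
             subject_id = g$subject_id[1], exam = g$exam[1],
             protocol = g$protocol[1])
  })
  unname(shapes)
}

#' Write / read the covariate table
#'
#' @param covariates covariate tibble (one row per subject and exam).
#' @param file CSV path.
#' @export
write_covariates <- function(covariates, file) {
  readr::write_csv(covariates, file)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(file) {
  readr::read_csv(file, show_col_types = FALSE)
}

#' Serialize a trajectory atlas to a directory
#'
#' Writes `mean_baseline.csv`, `mean_trajectory.csv`, `components.csv`
#' (M x 2*P*3), `variance.csv` and `metadata.json`.
#'
#' @param atlas a `trajectory_atlas`.
#' @param dir output directory (created if needed).
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tibble::tibble(value = atlas$mean_baseline),
                   file.path(dir, "mean_baseline.csv"))
  readr::write_csv(tibble::tibble(value = atlas$mean_trajectory),
                   file.path(dir, "mean_trajectory.csv"))
  utils::write.csv(as.data.frame(atlas$components),
                   file.path(dir, "components.csv"), row.names = FALSE)
  readr::write_csv(tibble::tibble(component = seq_along(atlas$variance),
                                  variance = atlas$variance,
                                  variance_ratio = atlas$variance_ratio,
                                  score_sd = atlas$score_sd),
                   file.path(dir, "variance.csv"))
  jsonlite::write_json(list(n_subjects = atlas$n_subjects,
                            n_components = nrow(atlas$components),
                            n_points = atlas$template$topology$n_points),
                       file.path(dir, "metadata.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a trajectory atlas from a directory
#'
#' @param dir directory written by [write_atlas()].
#' @param template the `lv_shape` template the atlas was built on.
#' @return A `trajectory_atlas`.
#' @export
read_atlas <- function(dir, template) {
  vr <- readr::read_csv(file.path(dir, "variance.csv"),
                        show_col_types = FALSE)
  comps <- as.matrix(utils::read.csv(file.path(dir, "components.csv")))
  dimnames(comps) <- NULL
  structure(list(
    mean_baseline = readr::read_csv(file.path(dir, "mean_baseline.csv"),
                                    show_col_types = FALSE)$value,
    mean_trajectory = readr::read_csv(file.path(dir, "mean_trajectory.csv"),
                                      show_col_types = FALSE)$value,
    components = comps, variance = vr$variance,
    variance_ratio = vr$variance_ratio, score_sd = vr$score_sd,
    n_subjects = jsonlite::read_json(file.path(dir, "metadata.json"))$n_subjects,
    template = template
  ), class = "trajectory_atlas")
}

#' Serialize a bias model to a directory
#'
#' Reference/mean shape CSVs, PCA basis matrix, PLSR coefficients and JSON
#' metadata.
#'
#' @param model a `bias_model`.
#' @param dir output directory.
#' @export
write_bias_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(model$gpa_reference),
                   file.path(dir, "gpa_reference.csv"), row.names = FALSE)
  readr::write_csv(tibble::tibble(value = model$gre_mean),
                   file.path(dir, "gre_mean.csv"))
  readr::write_csv(tibble::tibble(value = model$ssfp_mean),
                   file.path(dir, "ssfp_mean.csv"))
  utils::write.csv(as.data.frame(model$basis),
                   file.path(dir, "basis.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(model$plsr$coef),
                   file.path(dir, "plsr_coef.csv"), row.names = FALSE)
  readr::write_csv(tibble::tibble(value = model$plsr$intercept),
                   file.path(dir, "plsr_intercept.csv"))
  readr::write_csv(tibble::tibble(value = model$variance),
                   file.path(dir, "variance.csv"))
  jsonlite::write_json(list(k = model$k, n_plsr = model$n_plsr,
                            variance_keep = model$variance_keep,
                            n_training = model$n_training),
                       file.path(dir, "metadata.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a bias model from a directory
#'
#' @param dir directory written by [write_bias_model()].
#' @param template the `lv_shape` template.
#' @return A `bias_model`.
#' @export
read_bias_model <- function(dir, template) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  noname <- function(m) { dimnames(m) <- NULL; m }
  structure(list(
    gpa_reference = noname(as.matrix(utils::read.csv(
      file.path(dir, "gpa_reference.csv")))),
    gre_mean = readr::read_csv(file.path(dir, "gre_mean.csv"),
                               show_col_types = FALSE)$value,
    ssfp_mean = readr::read_csv(file.path(dir, "ssfp_mean.csv"),
                                show_col_types = FALSE)$value,
    basis = noname(as.matrix(utils::read.csv(file.path(dir, "basis.csv")))),
    variance = readr::read_csv(file.path(dir, "variance.csv"),
                               show_col_types = FALSE)$value,
    plsr = list(coef = noname(as.matrix(utils::read.csv(
                  file.path(dir, "plsr_coef.csv")))),
                intercept = readr::read_csv(
                  file.path(dir, "plsr_intercept.csv"),
                  show_col_types = FALSE)$value,
                ncomp = meta$n_plsr),
    n_plsr = meta$n_plsr, k = meta$k, variance_keep = meta$variance_keep,
    n_training = meta$n_training, template = template
  ), class = "bias_model")
}

#' Export a displacement field as ASCII VTK PolyData
#'
#' Writes the template ED surface with the ED block of a displacement field
#' attached as a point-data vector array, viewable in standard mesh viewers.
#'
#' @param field displacement field (length 2*P*3).
#' @param template an `lv_shape`.
#' @param file output `.vtk` path.
#' @export
write_field_vtk <- function(field, template, file) {
  p <- template$topology$n_points
  pts <- template$points$ED
  disp <- matrix(field[seq_len(3L * p)], ncol = 3L, byrow = TRUE)
  tt <- template$topology$triangles
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "LV displacement field", "ASCII", "DATASET POLYDATA",
               paste("POINTS", p, "float")), con)
  utils::write.table(pts, con, row.names = FALSE, col.names = FALSE)
  writeLines(paste("POLYGONS", nrow(tt), 4 * nrow(tt)), con)
  utils::write.table(cbind(3L, tt$v1 - 1L, tt$v2 - 1L, tt$v3 - 1L), con,
                     row.names = FALSE, col.names = FALSE)
  writeLines(c(paste("POINT_DATA", p), "VECTORS displacement float"), con)
  utils::write.table(disp, con, row.names = FALSE, col.names = FALSE)
  invisible(file)
}
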