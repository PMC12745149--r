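# Shared fixtures: templates are cached per resolution so the suite builds
# each mesh once.

.fixture_env <- new.env(parent = emptyenv())

fixture_template <- function(p_per_surface = 120) {
  key <- paste0("tpl_", p_per_surface)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- lv_template(p_per_surface = p_per_surface)
  }
  .fixture_env[[key]]
}

# near-closed spheroid mesh (tiny flat cap at the top) for analytic volume
# oracles: axes in mm, returns points + triangle table for one surface
spheroid_mesh <- function(axes, n_theta = 200, n_phi = 100,
                          cap_frac = 0.999) {
  pts <- spheroid_surface_test(axes, cap_frac * axes[3], n_theta, n_phi)
  tri <- surface_triangles_test(n_theta, n_phi)
  tri_df <- tibble::tibble(v1 = tri[, 1], v2 = tri[, 2], v3 = tri[, 3])
  if (lvtrajectory:::signed_mesh_volume(pts, tri) < 0) {
    tri_df <- tibble::tibble(v1 = tri[, 1], v2 = tri[, 3], v3 = tri[, 2])
  }
  list(points = pts, triangles = tri_df)
}

spheroid_surface_test <- function(axes, z_base, n_theta, n_phi) {
  lvtrajectory:::spheroid_surface(axes, z_base, n_theta, n_phi)
}

surface_triangles_test <- function(n_theta, n_phi) {
  lvtrajectory:::surface_triangles(n_theta, n_phi)
}

# Monte-Carlo volume oracle for the truncated ellipsoid (z < z_base), mL
mc_ellipsoid_volume <- function(axes, cap_frac = 0.999, n = 1e6,
                                seed = 42) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); code
  }
  withr_seed({
    x <- runif(n, -axes[1], axes[1])
    y <- runif(n, -axes[2], axes[2])
    z <- runif(n, -axes[3], axes[3])
    inside <- (x / axes[1])^2 + (y / axes[2])^2 + (z / axes[3])^2 < 1 &
      z < cap_frac * axes[3]
    p_hat <- mean(inside)
    box <- 8 * prod(axes)
    list(volume = p_hat * box / 1000,
         se = sqrt(p_hat * (1 - p_hat) / n) * box / 1000)
  })
}

# rigid transform helpers for invariance tests
rotate_shape <- function(shape, angle = 0.5, axis = c(1, 1, 1),
                         shift = c(5, -3, 2)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  out <- shape
  for (fr in c("ED", "ES")) {
    out$points[[fr]] <- sweep(shape$points[[fr]] %*% R, 2, shift, `+`)
  }
  out
}

withr_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}
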