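#' Morphology generator configuration
#'
#' Parameters of a synthetic dendritic point cloud. Stratification is
#' described in IPL units (the IPL spans `[0, 10]`; values outside are
#' INL/GCL processes), the tilt offset in micrometres in soma-centred
#' spherical coordinates with the polar angle measured from the y axis
#' (perpendicular to the retinal plane).
#'
#' @param n_points Number of dendritic points (>= 1).
#' @param y_mean Mean stratification depth, IPL units `[0, 10]`.
#' @param y_span Stratification width, IPL units.
#' @param tilt_r Distance of the dendritic centre of mass from the soma,
#'   micrometres.
#' @param tilt_theta Tilt strength in radians (`0` = no tilt, `pi/2` =
#'   CoM at the soma's own depth).
#' @param tilt_phi Tilt direction in radians, `[0, 2*pi)`;
#'   `atan2(z, x)` convention.
#' @param xz_spread Tangential scatter SD in micrometres.
#' @param seed Integer seed.
#' @param ipl_thickness_um Physical IPL thickness (default 20 um, so one
#'   IPL unit is 2 um).
#' @param region Region label, `"SZ"` or `"N"`.
#' @return A list of class `morph_gen_config`.
#' @export
morph_gen_config <- function(n_points = 200L, y_mean = 5, y_span = 2,
                             tilt_r = 10, tilt_theta = 0, tilt_phi = 0,
                             xz_spread = 10, seed = 1L,
                             ipl_thickness_um = 20, region = "N") {
  if (n_points < 1L) abort_invalid("`n_points` must be >= 1.")
  if (tilt_r <= 0) abort_invalid("`tilt_r` must be > 0.")
  structure(
    list(n_points = as.integer(n_points), y_mean = y_mean, y_span = y_span,
         tilt_r = tilt_r, tilt_theta = tilt_theta,
         tilt_phi = tilt_phi %% (2 * pi), xz_spread = xz_spread,
         seed = as.integer(seed), ipl_thickness_um = ipl_thickness_um,
         region = region),
    class = "morph_gen_config"
  )
}

#' Generate a synthetic dendritic point cloud
#'
#' Places the soma so that the dendritic centre of mass sits at the
#' planted spherical offset `(tilt_r, tilt_theta, tilt_phi)` from it
#' while the mean stratification depth equals `y_mean`. Scatter around
#' the CoM (uniform of width `y_span` in depth, Gaussian of SD
#' `xz_spread` tangentially) is mean-centred after sampling, so the
#' planted CoM holds exactly at any `n_points`; span and spread are
#' matched in distribution.
#'
#' @param cfg A [morph_gen_config()].
#' @return A tibble of class `morph_cloud` with columns `point_id`,
#'   `x_um`, `y_um`, `z_um`, `y_ipl` (depth rescaled so the IPL spans
#'   `[0, 10]`) and `is_soma`; attribute `region`.
#' @export
make_morph_cloud <- function(cfg) {
  stopifnot(inherits(cfg, "morph_gen_config"))
  u <- cfg$ipl_thickness_um / 10          # um per IPL unit
  offset <- cfg$tilt_r * c(
    sin(cfg$tilt_theta) * cos(cfg$tilt_phi),  # x
    cos(cfg$tilt_theta),                      # y
    sin(cfg$tilt_theta) * sin(cfg$tilt_phi)   # z
  )
  soma_y <- cfg$y_mean * u - offset[2]
  n <- cfg$n_points
  scatter <- withr::with_seed(cfg$seed, {
    cbind(
      x = rnorm(n, 0, cfg$xz_spread),
      y = runif(n, -cfg$y_span * u / 2, cfg$y_span * u / 2),
      z = rnorm(n, 0, cfg$xz_spread)
    )
  })
  scatter <- sweep(scatter, 2, colMeans(scatter))   # centre: CoM exact
  pts <- sweep(scatter, 2, c(offset[1], soma_y + offset[2], offset[3]), `+`)
  out <- tibble::tibble(
    point_id = 0:n,
    x_um = c(0, pts[, 1]),
    y_um = c(soma_y, pts[, 2]),
    z_um = c(0, pts[, 3]),
    is_soma = c(TRUE, rep(FALSE, n))
  )
  out$y_ipl <- out$y_um / u
  attr(out, "region") <- cfg$region
  class(out) <- c("morph_cloud", class(out))
  out
}
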