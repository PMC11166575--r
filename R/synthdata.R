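# Synthetic SPA metadata and tomogram point sets with known ground truth.
#
# Placement models operationalize the z-distribution shapes seen in real
# thin-film specimens: a mid-ice Gaussian layer, interface adsorption
# (steep slope at the interface plus a long tail of free particles), a
# bimodal two-interface mixture, a uniform slab, and an explicit double
# layer. All z values are distances from the slab mid-plane in Angstrom,
# truncated to [-thickness/2, +thickness/2].

#' Placement model constructors
#'
#' @param center_frac centre of the particle layer as a fraction of the
#'   slab (0 = lower interface, 1 = upper; default 0.5 = mid-ice).
#' @param sigma Gaussian layer width in Angstrom.
#' @param side which interface particles adsorb to: `"+"` (upper, positive
#'   z) or `"-"`.
#' @param decay_lambda exponential decay length of the adsorbed layer
#'   (Angstrom); the steep slope sits at the interface, the tail decays
#'   inward.
#' @param free_frac fraction of particles scattered uniformly through the
#'   slab rather than adsorbed (the long tail; default 0.2).
#' @param decay_lambda_a,decay_lambda_b decay lengths at the upper and
#'   lower interfaces of a bimodal model.
#' @param mix weight of the upper-interface component in (0, 1).
#' @param offset_frac half-separation of the two sheets of a double layer,
#'   as a fraction of the slab (default 0.25: sheets at -T/4 and +T/4).
#' @return a `placement_model` list with `kind` and parameters.
#' @name placement_models
NULL

.placement <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "placement_model")
}

#' @rdname placement_models
#' @export
model_mid_gauss <- function(center_frac = 0.5, sigma = 50) {
  stopifnot(center_frac > 0, center_frac < 1, sigma > 0)
  .placement("mid_gauss", center_frac = center_frac, sigma = sigma)
}

#' @rdname placement_models
#' @export
model_interface <- function(side = c("+", "-"), decay_lambda = 60,
                            free_frac = 0.2) {
  side <- match.arg(side)
  stopifnot(decay_lambda > 0, free_frac >= 0, free_frac <= 1)
  .placement("interface", side = side, decay_lambda = decay_lambda,
             free_frac = free_frac)
}

#' @rdname placement_models
#' @export
model_bimodal <- function(decay_lambda_a = 20, decay_lambda_b = 20, mix = 0.5) {
  stopifnot(decay_lambda_a > 0, decay_lambda_b > 0, mix > 0, mix < 1)
  .placement("bimodal", decay_lambda_a = decay_lambda_a,
             decay_lambda_b = decay_lambda_b, mix = mix)
}

#' @rdname placement_models
#' @export
model_uniform_slab <- function() .placement("uniform_slab")

#' @rdname placement_models
#' @export
model_double_layer <- function(sigma = 20, offset_frac = 0.25) {
  stopifnot(sigma > 0, offset_frac > 0, offset_frac < 0.5)
  .placement("double_layer", sigma = sigma, offset_frac = offset_frac)
}

# exponential decay from an interface inward, truncated to the slab
.rexp_trunc <- function(n, lambda, slab) {
  u <- stats::runif(n)
  -lambda * log(1 - u * (1 - exp(-slab / lambda)))
}

.rnorm_trunc <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Sample particle z-positions from a placement model
#'
#' Draws `n` signed distances from the slab mid-plane. Uses R's global
#' random number generator; seed via `set.seed()` or the manifest.
#'
#' @param model a `placement_model`.
#' @param slab_thickness slab thickness in Angstrom (> 0).
#' @param n number of particles (>= 1).
#' @return numeric vector of z values in [-slab/2, +slab/2] (Angstrom).
#' @export
sample_z <- function(model, slab_thickness, n) {
  stopifnot(inherits(model, "placement_model"), slab_thickness > 0, n >= 1L)
  half <- slab_thickness / 2
  scale_par <- switch(model$kind,
                      mid_gauss = model$sigma,
                      interface = model$decay_lambda,
                      bimodal = max(model$decay_lambda_a, model$decay_lambda_b),
                      double_layer = model$sigma,
                      0)
  if (scale_par >= slab_thickness) {
    warning("model length scale >= slab thickness; heavy truncation applied",
            call. = FALSE)
  }
  switch(model$kind,
    mid_gauss = .rnorm_trunc(n, slab_thickness * (model$center_frac - 0.5),
                             model$sigma, -half, half),
    uniform_slab = stats::runif(n, -half, half),
    interface = {
      free <- stats::runif(n) < model$free_frac
      z <- numeric(n)
      z[free] <- stats::runif(sum(free), -half, half)
      t_ads <- .rexp_trunc(sum(!free), model$decay_lambda, slab_thickness)
      z[!free] <- if (model$side == "+") half - t_ads else -half + t_ads
      z
    },
    bimodal = {
      upper <- stats::runif(n) < model$mix
      z <- numeric(n)
      z[upper] <- half - .rexp_trunc(sum(upper), model$decay_lambda_a,
                                     slab_thickness)
      z[!upper] <- -half + .rexp_trunc(sum(!upper), model$decay_lambda_b,
                                       slab_thickness)
      z
    },
    double_layer = {
      upper <- stats::runif(n) < 0.5
      off <- slab_thickness * model$offset_frac
      z <- numeric(n)
      z[upper] <- .rnorm_trunc(sum(upper), off, model$sigma, -half, half)
      z[!upper] <- .rnorm_trunc(sum(!upper), -off, model$sigma, -half, half)
      z
    },
    stop("unknown placement kind: ", model$kind, call. = FALSE)
  )
}

#' Build a truth manifest for a synthetic SPA dataset
#'
#' The manifest fully determines the generated dataset given its seed.
#' Defaults describe a realistic thin-film specimen: a 250 Angstrom slab
#' (mid-range of typical usable ice), plane tilts of order 0.01 (about
#' half a degree), 30 Angstrom defocus-measurement noise from CTF
#' refinement, and a 0.97 Angstrom pixel size on a 4096-pixel detector.
#'
#' @param seed integer RNG seed.
#' @param n_micrographs number of micrographs.
#' @param n_particles_per_micrograph particles per micrograph.
#' @param placement a `placement_model` (default mid-ice Gaussian).
#' @param slab_thickness slab thickness in Angstrom.
#' @param tilt_sd standard deviation of per-micrograph plane slopes
#'   (Angstrom z per Angstrom x).
#' @param defocus_noise_sd additive Gaussian noise on per-particle defocus
#'   (Angstrom).
#' @param astigmatism half-difference between defocus_u and defocus_v
#'   (Angstrom).
#' @param orientation `"uniform"` or a list
#'   `list(kind = "preferred", axis = c(x, y, z), concentration = kappa)`
#'   concentrating the projection direction about an axis (von
#'   Mises-Fisher).
#' @param pixel_size Angstrom per pixel.
#' @param detector_px detector side length in pixels.
#' @param z_convention defocus sign convention, see [defocus_to_z()].
#' @return a `truth_manifest` list.
#' @export
spa_manifest <- function(seed = 1L,
                         n_micrographs = 20L,
                         n_particles_per_micrograph = 500L,
                         placement = model_mid_gauss(),
                         slab_thickness = 250,
                         tilt_sd = 0.01,
                         defocus_noise_sd = 30,
                         astigmatism = 50,
                         orientation = "uniform",
                         pixel_size = 0.97,
                         detector_px = 4096L,
                         z_convention = "defocus_decreasing_up") {
  stopifnot(n_micrographs >= 1L, n_particles_per_micrograph >= 1L,
            inherits(placement, "placement_model"),
            slab_thickness > 0, tilt_sd >= 0, defocus_noise_sd >= 0,
            pixel_size > 0, detector_px > 0)
  if (is.list(orientation)) {
    stopifnot(identical(orientation$kind, "preferred"),
              length(orientation$axis) == 3L, orientation$concentration > 0)
  } else {
    stopifnot(identical(orientation, "uniform"))
  }
  structure(list(seed = as.integer(seed),
                 n_micrographs = as.integer(n_micrographs),
                 n_particles_per_micrograph = as.integer(n_particles_per_micrograph),
                 placement = placement,
                 slab_thickness = slab_thickness,
                 tilt_sd = tilt_sd,
                 defocus_noise_sd = defocus_noise_sd,
                 astigmatism = astigmatism,
                 orientation = orientation,
                 pixel_size = pixel_size,
                 detector_px = as.integer(detector_px),
                 z_convention = z_convention),
            class = "truth_manifest")
}

# von Mises-Fisher sample on S2 about unit axis mu (Wood's method, p = 3)
.rvmf <- function(n, mu, kappa) {
  mu <- mu / sqrt(sum(mu^2))
  u <- stats::runif(n)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  phi <- stats::runif(n, 0, 2 * pi)
  st <- sqrt(pmax(0, 1 - w^2))
  v <- cbind(st * cos(phi), st * sin(phi), w)
  # rotate z-axis onto mu
  z <- c(0, 0, 1)
  if (sum((mu - z)^2) < 1e-12) return(v)
  if (sum((mu + z)^2) < 1e-12) return(v %*% diag(c(1, -1, -1)))
  axis <- c(z[2L] * mu[3L] - z[3L] * mu[2L],
            z[3L] * mu[1L] - z[1L] * mu[3L],
            z[1L] * mu[2L] - z[2L] * mu[1L])
  ang <- acos(sum(z * mu))
  R <- .axis_rotation(axis, ang)
  t(R %*% t(v))
}

.sample_orientations <- function(n, orientation) {
  if (identical(orientation, "uniform")) {
    rot <- stats::runif(n, -180, 180)
    tilt <- acos(stats::runif(n, -1, 1)) / .deg2rad
  } else {
    v <- .rvmf(n, orientation$axis, orientation$concentration)
    tilt <- acos(pmin(1, pmax(-1, v[, 3L]))) / .deg2rad
    rot <- atan2(v[, 2L], v[, 1L]) / .deg2rad
  }
  data.frame(angle_rot = rot, angle_tilt = tilt,
             angle_psi = stats::runif(n, -180, 180))
}

#' Generate a synthetic single-particle dataset
#'
#' Per micrograph: uniform (x, y) positions, a random tilted ice plane,
#' true z from the placement model, and per-particle defocus consistent
#' with the manifest's z-convention plus Gaussian measurement noise.
#' Deterministic given the manifest seed.
#'
#' @param manifest a [spa_manifest()].
#' @return list with `table` (a [particle_table]) and `truth` (the
#'   manifest plus per-micrograph planes, base defocus and true z values).
#' @export
generate_spa_dataset <- function(manifest) {
  stopifnot(inherits(manifest, "truth_manifest"))
  set.seed(manifest$seed)
  s <- if (manifest$z_convention == "defocus_decreasing_up") -1 else 1
  n_mic <- manifest$n_micrographs
  npm <- manifest$n_particles_per_micrograph
  px <- manifest$pixel_size
  recs <- vector("list", n_mic)
  truth_mics <- vector("list", n_mic)
  for (m in seq_len(n_mic)) {
    id <- sprintf("mic_%03d.mrc", m)
    a <- stats::rnorm(1L, 0, manifest$tilt_sd)
    b <- stats::rnorm(1L, 0, manifest$tilt_sd)
    def0 <- stats::runif(1L, 10000, 25000)
    x_px <- stats::runif(npm, 0, manifest$detector_px)
    y_px <- stats::runif(npm, 0, manifest$detector_px)
    dz <- sample_z(manifest$placement, manifest$slab_thickness, npm)
    z_true <- a * x_px * px + b * y_px * px + dz
    defocus <- def0 + s * z_true +
      stats::rnorm(npm, 0, manifest$defocus_noise_sd)
    ang <- .sample_orientations(npm, manifest$orientation)
    recs[[m]] <- data.frame(micrograph_id = id,
                            coord_x = x_px, coord_y = y_px,
                            defocus_u = defocus + manifest$astigmatism,
                            defocus_v = defocus - manifest$astigmatism,
                            angle_rot = ang$angle_rot,
                            angle_tilt = ang$angle_tilt,
                            angle_psi = ang$angle_psi,
                            stringsAsFactors = FALSE)
    truth_mics[[m]] <- list(micrograph_id = id, a = a, b = b,
                            base_defocus = def0, z_true = z_true, dz = dz)
  }
  table <- particle_table(do.call(rbind, recs), pixel_size = px,
                          source_path = "<synthetic>")
  truth <- manifest
  truth$micrographs <- truth_mics
  list(table = table, truth = truth)
}

#' Generate a synthetic tomogram (particles + interface markers)
#'
#' Places particle centres on a plane parallel to two noisy interface
#' marker planes: the graphene-water interface (GWI) below and the
#' air-water interface (AWI) above, separated by `thickness`. The particle
#' plane sits `gap + particle_radius` above the GWI (centre height), so the
#' lower-edge gap equals `gap`. Coordinates are in voxels.
#'
#' @param seed integer RNG seed.
#' @param n_particles,n_markers set sizes.
#' @param thickness AWI-GWI separation (Angstrom).
#' @param gap lower-edge particle-to-GWI spacing (Angstrom, >= 0).
#' @param particle_radius particle radius (Angstrom).
#' @param voxel_size Angstrom per voxel.
#' @param marker_noise_voxels Gaussian z-noise of interface markers
#'   (voxels).
#' @param particle_jitter_sd Gaussian z-jitter of particle centres
#'   (Angstrom).
#' @param tilt_a,tilt_b plane slopes (z per x, z per y, voxel frame).
#' @param field_voxels lateral field size (voxels).
#' @param double_layer place half the particles on a second sheet one
#'   diameter higher (default FALSE).
#' @return list with `particles`, `awi_markers`, `gwi_markers`
#'   ([tomo_points]) and `truth` (generative parameters).
#' @export
generate_tomo_dataset <- function(seed = 1L, n_particles = 200L,
                                  n_markers = 60L, thickness = 250,
                                  gap = 25, particle_radius = 60,
                                  voxel_size = 5, marker_noise_voxels = 0,
                                  particle_jitter_sd = 0,
                                  tilt_a = 0.02, tilt_b = -0.01,
                                  field_voxels = 400L,
                                  double_layer = FALSE) {
  if (gap < 0) stop("gap must be >= 0", call. = FALSE)
  stopifnot(thickness > 0, particle_radius >= 0, voxel_size > 0)
  set.seed(as.integer(seed))
  gwi_c <- 40  # base GWI height, voxels
  # vertical offsets are slant-corrected so that orthogonal plane-to-plane
  # and particle-to-plane distances equal the requested Angstrom values
  slant <- sqrt(1 + tilt_a^2 + tilt_b^2)
  plane_z <- function(x, y, c0) tilt_a * x + tilt_b * y + c0
  mk <- function(n, c0, label) {
    x <- stats::runif(n, 0, field_voxels)
    y <- stats::runif(n, 0, field_voxels)
    z <- plane_z(x, y, c0) + stats::rnorm(n, 0, marker_noise_voxels)
    tomo_points(cbind(x, y, z), label = label, voxel_size = voxel_size)
  }
  gwi <- mk(n_markers, gwi_c, "gwi_marker")
  awi <- mk(n_markers, gwi_c + slant * thickness / voxel_size, "awi_marker")
  xp <- stats::runif(n_particles, 0, field_voxels)
  yp <- stats::runif(n_particles, 0, field_voxels)
  centre_h <- slant * (gap + particle_radius) / voxel_size
  zp <- plane_z(xp, yp, gwi_c) + centre_h +
    stats::rnorm(n_particles, 0, particle_jitter_sd) / voxel_size
  if (double_layer) {
    upper <- seq_len(n_particles) %% 2L == 0L
    zp[upper] <- zp[upper] + (2 * particle_radius + 40) / voxel_size
  }
  particles <- tomo_points(cbind(xp, yp, zp), label = "particle",
                           voxel_size = voxel_size)
  list(particles = particles, awi_markers = awi, gwi_markers = gwi,
       truth = list(seed = as.integer(seed), thickness = thickness,
                    gap = gap, particle_radius = particle_radius,
                    voxel_size = voxel_size,
                    marker_noise_voxels = marker_noise_voxels,
                    double_layer = double_layer))
}

#' Write a truth manifest as JSON
#'
#' Per-micrograph true z values are omitted; the dataset is reproducible
#' from the recorded parameters and seed alone.
#'
#' @param truth a `truth_manifest` (with or without attached micrographs).
#' @param path output path.
#' @export
write_manifest <- function(truth, path) {
  out <- unclass(truth)
  out$micrographs <- NULL
  out$placement <- unclass(out$placement)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
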