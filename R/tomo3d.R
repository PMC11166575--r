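# Tomogram-side analysis: particle plane, interface planes, spacings.

#' Analyze particle and interface planes in a tomogram
#'
#' Fits three least-squares planes — the particle plane, the air-water
#' interface (AWI) plane and the graphene-water interface (GWI) plane —
#' from point sets in a common voxel frame, and measures the gap between
#' the lower edge of the particles and each interface. The "edge" gap
#' subtracts a single spherical particle radius from the mean orthogonal
#' centre-to-plane distance. The monolayer flag tests whether the
#' central-80% extent of particle distances to their own plane is at most
#' `monolayer_factor` times the particle diameter.
#'
#' @param particles,awi_markers,gwi_markers [tomo_points] sets sharing one
#'   voxel frame and voxel size; each needs >= 3 non-collinear points.
#' @param particle_radius particle radius in Angstrom (>= 0).
#' @param monolayer_factor monolayer threshold as a multiple of the
#'   particle diameter (default 1.0).
#' @return object of class `tomo_report`: the three `plane_fit`s (Angstrom
#'   frame), spacings in Angstrom and slices, inter-interface thickness,
#'   monolayer flag and particle count.
#' @export
analyze_tomogram <- function(particles, awi_markers, gwi_markers,
                             particle_radius, monolayer_factor = 1.0) {
  sets <- list(particles = particles, awi_markers = awi_markers,
               gwi_markers = gwi_markers)
  for (nm in names(sets)) {
    if (!inherits(sets[[nm]], "tomo_points")) {
      stop(nm, " must be a tomo_points object", call. = FALSE)
    }
  }
  vs <- vapply(sets, attr, numeric(1L), "voxel_size")
  if (max(vs) - min(vs) > 1e-9) stop("voxel sizes differ between point sets", call. = FALSE)
  voxel_size <- vs[[1L]]
  stopifnot(is.numeric(particle_radius), particle_radius >= 0)

  to_cloud <- function(p, id) {
    z_cloud(p$x * voxel_size, p$y * voxel_size, p$z * voxel_size,
            micrograph_id = id)
  }
  fits <- lapply(names(sets), function(nm) {
    cl <- to_cloud(sets[[nm]], nm)
    tryCatch(fit_plane(cl, min_points = 3L), error = function(e)
      stop("degenerate point set '", nm, "': ", conditionMessage(e), call. = FALSE))
  })
  names(fits) <- c("particle_plane", "awi_plane", "gwi_plane")

  pc <- to_cloud(particles, "particles")
  # mean orthogonal centre-to-plane distances (absolute)
  plane_dist <- function(cloud, fit) {
    nz <- fit$unit_normal[3L]
    mean(abs((cloud$z - fit$a * cloud$x - fit$b * cloud$y - fit$c) * nz))
  }
  d_gwi <- plane_dist(pc, fits$gwi_plane)
  d_awi <- plane_dist(pc, fits$awi_plane)
  gap_gwi <- d_gwi - particle_radius
  gap_awi <- d_awi - particle_radius

  # ice thickness: orthogonal distance from the AWI plane centroid to GWI
  awi_cloud <- to_cloud(awi_markers, "awi")
  centroid <- c(mean(awi_cloud$x), mean(awi_cloud$y), mean(awi_cloud$z))
  g <- fits$gwi_plane
  thickness <- abs((centroid[3L] - g$a * centroid[1L] - g$b * centroid[2L] - g$c) *
                     g$unit_normal[3L])

  self_d <- distances_to_plane(pc, fits$particle_plane)
  extent <- ice_thickness(self_d, fraction = 0.8)
  structure(list(
    particle_plane = fits$particle_plane,
    awi_plane = fits$awi_plane,
    gwi_plane = fits$gwi_plane,
    particle_to_gwi_spacing = c(angstrom = gap_gwi,
                                slices = slice_spacing(gap_gwi, voxel_size)),
    particle_to_awi_spacing = c(angstrom = gap_awi,
                                slices = slice_spacing(gap_awi, voxel_size)),
    monolayer = extent <= monolayer_factor * 2 * particle_radius,
    particle_extent = extent,
    thickness = thickness,
    n_particles = nrow(particles),
    voxel_size = voxel_size,
    particle_radius = particle_radius
  ), class = "tomo_report")
}

#' @export
print.tomo_report <- function(x, ...) {
  cat(sprintf("tomo_report: %d particles, voxel %.3g A\n", x$n_particles, x$voxel_size))
  cat(sprintf("  particle lower edge to GWI: %.1f A (%.1f slices)\n",
              x$particle_to_gwi_spacing[["angstrom"]],
              x$particle_to_gwi_spacing[["slices"]]))
  cat(sprintf("  particle lower edge to AWI: %.1f A (%.1f slices)\n",
              x$particle_to_awi_spacing[["angstrom"]],
              x$particle_to_awi_spacing[["slices"]]))
  cat(sprintf("  AWI-GWI thickness: %.1f A; monolayer: %s\n",
              x$thickness, x$monolayer))
  invisible(x)
}

#' Convert a spacing in Angstrom to tomogram slices
#'
#' A negative spacing (planes interleaving the particles) passes through
#' with its sign as a diagnostic.
#'
#' @param spacing_angstrom spacing in Angstrom.
#' @param voxel_size voxel (slice) size in Angstrom (> 0).
#' @return spacing in slices, rounded to one decimal.
#' @export
slice_spacing <- function(spacing_angstrom, voxel_size) {
  if (!is.numeric(voxel_size) || voxel_size <= 0) {
    stop("voxel_size must be positive", call. = FALSE)
  }
  round(spacing_angstrom / voxel_size, 1L)
}
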