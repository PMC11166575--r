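# Point-group symmetry and (rot, tilt) orientation heatmaps.
#
# Euler convention: RELION ZYZ. The orientation matrix is
# A = Rz(psi) %*% Ry(tilt) %*% Rz(rot) with passive (coordinate-transform)
# rotation matrices; the projection direction lives in the third row of A,
# which is independent of psi.

.deg2rad <- pi / 180

.rz_passive <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3L, 3L, byrow = TRUE)
}
.ry_passive <- function(b) {
  cb <- cos(b); sb <- sin(b)
  matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3L, 3L, byrow = TRUE)
}

#' ZYZ Euler angles to rotation matrix
#' @param rot,tilt,psi angles in degrees (RELION AngleRot/AngleTilt/AnglePsi).
#' @return 3x3 orientation matrix.
#' @export
euler_to_matrix <- function(rot, tilt, psi = 0) {
  stopifnot(is.finite(rot), is.finite(tilt), is.finite(psi))
  .rz_passive(psi * .deg2rad) %*% .ry_passive(tilt * .deg2rad) %*%
    .rz_passive(rot * .deg2rad)
}

#' Rotation matrix to ZYZ Euler angles
#' @param A 3x3 orientation matrix.
#' @return named vector (rot, tilt, psi) in degrees, tilt in [0, 180].
#' @export
matrix_to_euler <- function(A) {
  ct <- min(1, max(-1, A[3L, 3L]))
  tilt <- acos(ct)
  if (abs(sin(tilt)) > 1e-10) {
    rot <- atan2(A[3L, 2L], A[3L, 1L])
    psi <- atan2(A[2L, 3L], -A[1L, 3L])
  } else {
    rot <- 0
    psi <- atan2(A[1L, 2L], A[1L, 1L]) * sign(ct)
  }
  c(rot = rot / .deg2rad, tilt = tilt / .deg2rad, psi = psi / .deg2rad)
}

# Rodrigues rotation about unit axis u by angle theta (radians).
.axis_rotation <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, -u[3L], u[2L], u[3L], 0, -u[1L], -u[2L], u[1L], 0),
              3L, 3L, byrow = TRUE)
  diag(3L) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

.mat_key <- function(M) paste(sprintf("%.6f", round(M, 6) + 0), collapse = ",")

# Close a generator set under composition (finite groups only).
.close_group <- function(generators, max_order = 120L) {
  elems <- list(diag(3L))
  keys <- .mat_key(diag(3L))
  queue <- generators
  while (length(queue)) {
    g <- queue[[1L]]; queue <- queue[-1L]
    k <- .mat_key(g)
    if (k %in% keys) next
    elems[[length(elems) + 1L]] <- g
    keys <- c(keys, k)
    if (length(elems) > max_order) stop("group closure exceeded max order", call. = FALSE)
    for (h in elems) {
      queue <- c(queue, list(g %*% h), list(h %*% g))
    }
  }
  elems
}

#' Build a rotational point group
#'
#' Constructs the explicit proper-rotation operators of a point group by
#' generator closure: cyclic Cn (n-fold about z), dihedral Dn (Cn plus an
#' in-plane 2-fold), tetrahedral T (12), octahedral O (24) and icosahedral
#' I (60). The asymmetric-unit extents used by heatmaps are analytic for
#' Cn/Dn and determined numerically (reduction of a fine orientation grid)
#' for T/O/I.
#'
#' @param name symmetry name: `"C1"`, `"C2"`, ..., `"D2"`, ..., `"T"`,
#'   `"O"`, `"I"` (case-insensitive).
#' @return object of class `point_group`: list with `name`, `order`,
#'   `rotations` (list of 3x3 matrices), `rot_range`, `tilt_range`
#'   (degrees).
#' @export
build_group <- function(name) {
  nm <- toupper(trimws(name))
  if (!is.null(.group_cache[[nm]])) return(.group_cache[[nm]])
  phi <- (1 + sqrt(5)) / 2
  if (grepl("^C[0-9]+$", nm)) {
    n <- as.integer(substring(nm, 2L))
    if (n < 1L) stop("unknown point group: ", name, call. = FALSE)
    gens <- if (n == 1L) list() else list(.axis_rotation(c(0, 0, 1), 2 * pi / n))
    rot_range <- c(-180, -180 + 360 / n)
    tilt_range <- c(0, 180)
  } else if (grepl("^D[0-9]+$", nm)) {
    n <- as.integer(substring(nm, 2L))
    if (n < 2L) stop("unknown point group: ", name, call. = FALSE)
    gens <- list(.axis_rotation(c(0, 0, 1), 2 * pi / n),
                 .axis_rotation(c(1, 0, 0), pi))
    rot_range <- c(-180, -180 + 360 / n)
    tilt_range <- c(0, 90)
  } else if (nm == "T") {
    gens <- list(.axis_rotation(c(0, 0, 1), pi),
                 .axis_rotation(c(1, 1, 1), 2 * pi / 3))
    rot_range <- tilt_range <- NULL
  } else if (nm == "O") {
    gens <- list(.axis_rotation(c(0, 0, 1), pi / 2),
                 .axis_rotation(c(1, 1, 1), 2 * pi / 3))
    rot_range <- tilt_range <- NULL
  } else if (nm == "I") {
    gens <- list(.axis_rotation(c(0, 0, 1), pi),
                 .axis_rotation(c(0, 1, phi), 2 * pi / 5))
    rot_range <- tilt_range <- NULL
  } else {
    stop("unknown point group: ", name, call. = FALSE)
  }
  rotations <- .close_group(gens)
  expected <- c(C = NA, D = NA, T = 12L, O = 24L, I = 60L)
  ord <- length(rotations)
  if (grepl("^C", nm)) stopifnot(ord == as.integer(substring(nm, 2L)))
  else if (grepl("^D", nm)) stopifnot(ord == 2L * as.integer(substring(nm, 2L)))
  else stopifnot(ord == expected[[nm]])
  grp <- structure(list(name = nm, order = ord, rotations = rotations,
                        rot_range = rot_range, tilt_range = tilt_range),
                   class = "point_group")
  if (is.null(rot_range)) {
    rt <- .numeric_extents(grp)
    grp$rot_range <- rt$rot_range
    grp$tilt_range <- rt$tilt_range
  }
  .group_cache[[nm]] <- grp
  grp
}

#' @export
print.point_group <- function(x, ...) {
  cat(sprintf("point_group %s: %d proper rotations, rot [%g, %g], tilt [%g, %g] deg\n",
              x$name, x$order, x$rot_range[1L], x$rot_range[2L],
              x$tilt_range[1L], x$tilt_range[2L]))
  invisible(x)
}

# Vectorised reduction core. V is an n x 3 matrix of projection-direction
# rows (third rows of orientation matrices); returns the reduced (rot,
# tilt) in degrees under the lexicographic-minimum rule: minimal tilt,
# ties (within 1e-9 deg) broken by minimal rot.
.reduce_rows <- function(V, rotations) {
  n <- nrow(V)
  ns <- length(rotations)
  tilt_c <- matrix(0, n, ns)
  rot_c <- matrix(0, n, ns)
  for (j in seq_len(ns)) {
    W <- V %*% rotations[[j]]
    tilt_c[, j] <- acos(pmin(1, pmax(-1, W[, 3L]))) / .deg2rad
    rot_c[, j] <- ifelse(abs(W[, 3L]) >= 1 - 1e-12, 0,
                         atan2(W[, 2L], W[, 1L]) / .deg2rad)
  }
  tmin <- do.call(pmin, as.data.frame(tilt_c))
  rot_masked <- rot_c
  rot_masked[tilt_c > tmin + 1e-9] <- Inf
  list(rot = do.call(pmin, as.data.frame(rot_masked)), tilt = tmin)
}

.numeric_extents <- function(group) {
  grid <- expand.grid(rot = seq(-179.5, 180, by = 1), tilt = seq(0.25, 179.75, by = 0.5))
  st <- sin(grid$tilt * .deg2rad); ct <- cos(grid$tilt * .deg2rad)
  V <- cbind(st * cos(grid$rot * .deg2rad), st * sin(grid$rot * .deg2rad), ct)
  red <- .reduce_rows(V, group$rotations)
  # pad by one grid step so boundary orientations fall inside the box
  list(rot_range = c(max(-180, min(red$rot) - 1), min(180, max(red$rot) + 1)),
       tilt_range = c(0, min(180, max(red$tilt) + 0.5)))
}

.group_cache <- new.env(parent = emptyenv())

#' Reduce orientations to the asymmetric unit of a point group
#'
#' Every symmetry-equivalent orientation maps to the same representative:
#' among all group-composed orientations, the one whose (tilt, rot) pair is
#' lexicographically minimal (minimal tilt; ties broken by minimal rot).
#' psi enters the orientation matrix but does not affect the projection
#' direction, so only (rot, tilt) are returned.
#'
#' @param angles numeric vector (rot, tilt, psi) in degrees, or an n x 3
#'   matrix / data.frame of such rows.
#' @param group a [build_group()] result.
#' @return data.frame with columns `rot`, `tilt` (degrees).
#' @export
reduce_to_asymmetric_unit <- function(angles, group) {
  stopifnot(inherits(group, "point_group"))
  if (is.null(dim(angles))) angles <- matrix(angles, nrow = 1L)
  angles <- as.matrix(angles)
  if (ncol(angles) < 2L || any(!is.finite(angles))) {
    stop("malformed Euler angles", call. = FALSE)
  }
  if (any(angles[, 2L] < 0 | angles[, 2L] > 180)) {
    stop("tilt must lie in [0, 180] degrees", call. = FALSE)
  }
  st <- sin(angles[, 2L] * .deg2rad); ct <- cos(angles[, 2L] * .deg2rad)
  V <- cbind(st * cos(angles[, 1L] * .deg2rad),
             st * sin(angles[, 1L] * .deg2rad), ct)
  red <- .reduce_rows(V, group$rotations)
  data.frame(rot = red$rot, tilt = red$tilt)
}

#' Orientation heatmap over the asymmetric unit
#'
#' Reduces every particle's Euler angles to the point group's asymmetric
#' unit and bins the (rot, tilt) pairs on a regular 2D grid spanning the
#' group's asymmetric-unit extents. Raw counts are binned by default,
#' matching the way refinement packages display angular distributions; set
#' `sin_tilt_weighted = TRUE` to de-weight by the spherical area element.
#'
#' @param table a [particle_table] with Euler angles.
#' @param group a [build_group()] result (or a symmetry name).
#' @param n_rot_bins,n_tilt_bins grid size (defaults 36 x 18).
#' @param sin_tilt_weighted divide counts by sin(tilt) bin area (default
#'   FALSE).
#' @return object of class `orientation_map`: list with `bins` (tilt rows x
#'   rot columns), `rot_breaks`, `tilt_breaks` (degrees), `n_particles`,
#'   `group`.
#' @export
orientation_heatmap <- function(table, group, n_rot_bins = 36L,
                                n_tilt_bins = 18L, sin_tilt_weighted = FALSE) {
  if (is.character(group)) group <- build_group(group)
  stopifnot(inherits(group, "point_group"))
  if (!has_angles(as.data.frame(table))) {
    stop("particle table has no Euler angles; re-read the STAR file with ",
         "_rlnAngleRot/_rlnAngleTilt/_rlnAnglePsi columns", call. = FALSE)
  }
  red <- reduce_to_asymmetric_unit(
    cbind(table$angle_rot, table$angle_tilt, table$angle_psi), group)
  rot_breaks <- seq(group$rot_range[1L], group$rot_range[2L],
                    length.out = n_rot_bins + 1L)
  tilt_breaks <- seq(group$tilt_range[1L], group$tilt_range[2L],
                     length.out = n_tilt_bins + 1L)
  # numerical spill just outside the stored extents is clamped in
  clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  ri <- clamp(findInterval(red$rot, rot_breaks, rightmost.closed = TRUE),
              1L, n_rot_bins)
  ti <- clamp(findInterval(red$tilt, tilt_breaks, rightmost.closed = TRUE),
              1L, n_tilt_bins)
  bins <- matrix(0, n_tilt_bins, n_rot_bins)
  for (k in seq_along(ri)) bins[ti[k], ri[k]] <- bins[ti[k], ri[k]] + 1
  if (sin_tilt_weighted) {
    mid <- (head(tilt_breaks, -1L) + tail(tilt_breaks, -1L)) / 2
    w <- pmax(sin(mid * .deg2rad), 1e-6)
    bins <- sweep(bins, 1L, w, "/")
  }
  structure(list(bins = bins, rot_breaks = rot_breaks,
                 tilt_breaks = tilt_breaks, n_particles = nrow(table),
                 group = group, weighted = sin_tilt_weighted),
            class = "orientation_map")
}

#' @export
print.orientation_map <- function(x, ...) {
  cat(sprintf("orientation_map (%s): %d particles in %d x %d bins, coverage %.2f\n",
              x$group$name, x$n_particles, nrow(x$bins), ncol(x$bins),
              coverage_fraction(x)))
  invisible(x)
}

#' Fraction of orientation bins populated
#' @param map an `orientation_map`.
#' @return fraction in [0, 1] of bins with at least one particle.
#' @export
coverage_fraction <- function(map) {
  stopifnot(inherits(map, "orientation_map"))
  mean(map$bins > 0)
}

#' Export a heatmap as a delimited matrix with axis metadata
#' @param map an `orientation_map`.
#' @param path output TSV path.
#' @export
write_orientation_map <- function(map, path) {
  stopifnot(inherits(map, "orientation_map"))
  hdr <- c(sprintf("# point group: %s", map$group$name),
           sprintf("# rot breaks (deg): %s", paste(signif(map$rot_breaks, 6), collapse = " ")),
           sprintf("# tilt breaks (deg): %s", paste(signif(map$tilt_breaks, 6), collapse = " ")))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(map$bins, path, append = TRUE, sep = "\t",
                                      row.names = FALSE, col.names = FALSE))
  invisible(path)
}
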