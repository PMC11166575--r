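# Defocus -> z conversion, per-micrograph plane fitting, signed distances.

#' Convert per-particle defocus to z-heights
#'
#' For each particle the defocus is the mean of the two astigmatic values
#' (astigmatism is an in-plane property, not a height). Within each
#' micrograph, z is the mean-centred defocus with a sign set by the
#' convention: under `defocus_decreasing_up` (default) a smaller underfocus
#' maps to a larger z, i.e. z = -(defocus - mean defocus). Coordinates are
#' converted from pixels to Angstrom via the table's pixel size.
#'
#' @param table a [particle_table].
#' @param convention `"defocus_decreasing_up"` or `"defocus_increasing_up"`.
#' @return a named list of `z_cloud` objects, one per micrograph, in first-
#'   appearance order. Each `z_cloud` is a data.frame with columns x, y, z
#'   (Angstrom) and attributes `micrograph_id` and `z_convention`.
#' @export
defocus_to_z <- function(table,
                         convention = c("defocus_decreasing_up",
                                        "defocus_increasing_up")) {
  convention <- match.arg(convention)
  stopifnot(inherits(table, "particle_table"))
  if (nrow(table) == 0L) stop("empty particle table", call. = FALSE)
  bad <- which(!is.finite(table$defocus_u) | !is.finite(table$defocus_v))
  if (length(bad)) stop("non-finite defocus at particle index ", bad[1L], call. = FALSE)
  s <- if (convention == "defocus_decreasing_up") -1 else 1
  px <- pixel_size(table)
  def <- (table$defocus_u + table$defocus_v) / 2
  ids <- unique(table$micrograph_id)
  out <- lapply(ids, function(id) {
    sel <- table$micrograph_id == id
    z_cloud(x = table$coord_x[sel] * px,
            y = table$coord_y[sel] * px,
            z = s * (def[sel] - mean(def[sel])),
            micrograph_id = id, z_convention = convention)
  })
  names(out) <- ids
  out
}

#' Construct a z point cloud
#' @param x,y,z coordinates in Angstrom.
#' @param micrograph_id micrograph identifier.
#' @param z_convention sign convention tag.
#' @export
z_cloud <- function(x, y, z, micrograph_id = "cloud",
                    z_convention = "defocus_decreasing_up") {
  stopifnot(length(x) == length(y), length(y) == length(z), length(z) >= 1L,
            all(is.finite(x)), all(is.finite(y)), all(is.finite(z)))
  structure(data.frame(x = x, y = y, z = z),
            micrograph_id = micrograph_id, z_convention = z_convention,
            class = c("z_cloud", "data.frame"))
}

#' Least-squares plane fit
#'
#' Fits z = a*x + b*y + c by minimising the sum of squared vertical
#' residuals. Vertical rather than total least squares is used because ice
#' planes are tilted by at most a few degrees, where the two coincide to
#' first order. The unit normal is normalise(-a, -b, 1), so its z-component
#' is positive.
#'
#' @param cloud a `z_cloud` (or data.frame with x, y, z in a common frame).
#' @param min_points minimum number of points required (default 3; callers
#'   enforcing the per-micrograph inclusion threshold pass their own).
#' @return object of class `plane_fit`: list with `a`, `b`, `c`
#'   (coefficients), `unit_normal`, `rms_residual` (Angstrom), `n_points`,
#'   `micrograph_id`.
#' @export
fit_plane <- function(cloud, min_points = 3L) {
  df <- as.data.frame(cloud)
  n <- nrow(df)
  if (n < min_points) {
    stop(sprintf("insufficient points for plane fit: %d < %d", n, min_points),
         call. = FALSE)
  }
  X <- cbind(df$x, df$y, 1)
  qrX <- qr(X)
  if (qrX$rank < 3L) stop("degenerate (collinear) point configuration", call. = FALSE)
  beta <- qr.coef(qrX, df$z)
  res <- df$z - X %*% beta
  nvec <- c(-beta[1L], -beta[2L], 1)
  nvec <- nvec / sqrt(sum(nvec^2))
  structure(list(a = unname(beta[1L]), b = unname(beta[2L]), c = unname(beta[3L]),
                 unit_normal = nvec,
                 rms_residual = sqrt(mean(res^2)),
                 n_points = n,
                 micrograph_id = attr(cloud, "micrograph_id")),
            class = "plane_fit")
}

#' @export
print.plane_fit <- function(x, ...) {
  cat(sprintf("plane_fit: z = %.6g*x + %.6g*y + %.6g  (n = %d, rms = %.4g A)\n",
              x$a, x$b, x$c, x$n_points, x$rms_residual))
  invisible(x)
}

#' Signed orthogonal distances from points to a fitted plane
#'
#' The true point-to-plane distance with sign: positive on the side the
#' unit normal points to (larger z). For a cloud and its own least-squares
#' fit the distances average to zero.
#'
#' @param cloud a `z_cloud`.
#' @param fit a `plane_fit` computed from a cloud in the same frame.
#' @return numeric vector of signed distances in Angstrom.
#' @export
distances_to_plane <- function(cloud, fit) {
  stopifnot(inherits(fit, "plane_fit"))
  cid <- attr(cloud, "micrograph_id")
  if (!is.null(cid) && !is.null(fit$micrograph_id) &&
      !identical(cid, fit$micrograph_id)) {
    stop(sprintf("frame mismatch: cloud '%s' vs fit '%s'", cid, fit$micrograph_id),
         call. = FALSE)
  }
  df <- as.data.frame(cloud)
  nz <- fit$unit_normal[3L]
  (df$z - fit$a * df$x - fit$b * df$y - fit$c) * nz
}
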