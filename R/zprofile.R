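# Per-micrograph z-height distribution statistics and dataset summaries.

#' Gaussian-kernel density summary of z-height distances
#'
#' Estimates the density on a regular grid spanning the data range plus
#' three bandwidths on each side. The mode is the grid argmax of the KDE;
#' mean and median come from the raw data, not the smoothed curve.
#'
#' @param distances numeric vector of signed distances (Angstrom).
#' @param bandwidth either `"silverman"` (default, Silverman's
#'   rule-of-thumb) or a positive number in Angstrom.
#' @param n_grid number of grid points (default 512).
#' @return list with `grid` (positions, Angstrom), `density` (1/Angstrom),
#'   `mode`, `mean`, `median`, `bandwidth`.
#' @export
kde_summary <- function(distances, bandwidth = "silverman", n_grid = 512L) {
  distances <- as.numeric(distances)
  stopifnot(length(distances) >= 2L, all(is.finite(distances)))
  if (stats::sd(distances) == 0) {
    stop("degenerate input: zero variance, KDE undefined", call. = FALSE)
  }
  bw <- if (identical(bandwidth, "silverman")) stats::bw.nrd0(distances)
        else {
          stopifnot(is.numeric(bandwidth), bandwidth > 0)
          bandwidth
        }
  d <- stats::density(distances, bw = bw, n = n_grid,
                      from = min(distances) - 3 * bw,
                      to = max(distances) + 3 * bw)
  list(grid = d$x, density = d$y,
       mode = d$x[which.max(d$y)],
       mean = mean(distances),
       median = stats::median(distances),
       bandwidth = bw)
}

#' Moment-coefficient skewness
#'
#' g1 = m3 / m2^(3/2) with central moments computed on the raw distances;
#' no small-sample bias correction is applied (per-micrograph n is in the
#' hundreds in practice).
#'
#' @param distances numeric vector, length >= 3, non-zero variance.
#' @return dimensionless skewness.
#' @export
skewness <- function(distances) {
  x <- as.numeric(distances)
  stopifnot(length(x) >= 3L, all(is.finite(x)))
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 == 0) stop("skewness undefined for zero-variance input", call. = FALSE)
  mean(xc^3) / m2^1.5
}

#' Classify a skewness value into a tier
#'
#' |s| < 0.5 is approximately symmetric, 0.5 <= |s| <= 1 moderately skewed
#' and |s| > 1 highly skewed, signed by the side of the long tail. The
#' boundary values 0.5 and 1 are assigned to the more-skewed tier, so the
#' symmetric band is the open interval (-0.5, 0.5).
#'
#' @param s finite skewness value (vectorised).
#' @return character vector in `symmetric`, `moderate_left`,
#'   `moderate_right`, `high_left`, `high_right`.
#' @export
classify_skewness <- function(s) {
  stopifnot(all(is.finite(s)))
  side <- ifelse(s < 0, "left", "right")
  ifelse(abs(s) >= 1, paste0("high_", side),
         ifelse(abs(s) >= 0.5, paste0("moderate_", side), "symmetric"))
}

# Peak prominence on a regular-grid density: for each local maximum, walk
# out to the nearest higher point on each side; the base on that side is
# the minimum in between (or the minimum to the boundary when nothing
# higher exists). Prominence = height - max(left base, right base).
.peak_prominences <- function(y) {
  n <- length(y)
  peaks <- which(diff(sign(diff(y))) < 0) + 1L
  if (!length(peaks)) return(list(peaks = integer(), prominence = numeric()))
  prom <- vapply(peaks, function(p) {
    h <- y[p]
    left <- if (p > 1L) {
      higher <- which(y[seq_len(p - 1L)] > h)
      lo <- if (length(higher)) max(higher) + 1L else 1L
      min(y[lo:p])
    } else h
    right <- if (p < n) {
      higher <- which(y[(p + 1L):n] > h) + p
      hi <- if (length(higher)) min(higher) - 1L else n
      min(y[p:hi])
    } else h
    h - max(left, right)
  }, numeric(1L))
  list(peaks = peaks, prominence = prom)
}

#' Detect single- versus double-layer particle arrangement
#'
#' Counts KDE local maxima whose prominence is at least `prominence_frac`
#' of the global density maximum. One prominent peak means a single layer
#' (`unimodal`), two mean a double layer (`bimodal`); anything else is
#' `indeterminate`. A heavy tail does not register as a second layer.
#'
#' @param distances numeric vector of signed distances.
#' @param prominence_frac prominence threshold as a fraction of the global
#'   maximum (default 0.2).
#' @param bandwidth passed to [kde_summary()].
#' @return one of `"unimodal"`, `"bimodal"`, `"indeterminate"`.
#' @export
detect_layering <- function(distances, prominence_frac = 0.2,
                            bandwidth = "silverman") {
  k <- tryCatch(kde_summary(distances, bandwidth = bandwidth),
                error = function(e) NULL)
  if (is.null(k)) return("indeterminate")
  pp <- .peak_prominences(k$density)
  n_prominent <- sum(pp$prominence >= prominence_frac * max(k$density))
  if (n_prominent == 1L) "unimodal"
  else if (n_prominent == 2L) "bimodal"
  else "indeterminate"
}

#' Ice thickness from the central extent of particle distances
#'
#' The thickness is the extent of the central `fraction` of particles in
#' the direction orthogonal to the fitted plane: the distance between the
#' (0.5 - fraction/2) and (0.5 + fraction/2) quantiles. With the default
#' fraction of 0.8 this is the 10th-to-90th-percentile extent.
#'
#' @param distances numeric vector of signed distances (Angstrom).
#' @param fraction central fraction in (0, 1] (default 0.8).
#' @return thickness in Angstrom.
#' @export
ice_thickness <- function(distances, fraction = 0.8) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  q <- stats::quantile(distances, c(0.5 - fraction / 2, 0.5 + fraction / 2),
                       names = FALSE)
  q[2L] - q[1L]
}

#' Full z-height profile of one micrograph
#'
#' Bundles the distance set with its KDE summary, skewness and tier,
#' layering call and central-80% thickness.
#'
#' @param distances signed orthogonal distances (Angstrom).
#' @param micrograph_id identifier.
#' @param min_particles minimum n for a valid profile (default 10).
#' @param bandwidth,prominence_frac,thickness_fraction tuning parameters,
#'   see [kde_summary()], [detect_layering()], [ice_thickness()].
#' @return object of class `z_profile`, or `NULL` (with a message) when
#'   n < `min_particles` (the micrograph is excluded from dataset
#'   summaries).
#' @export
z_profile <- function(distances, micrograph_id = "micrograph",
                      min_particles = 10L, bandwidth = "silverman",
                      prominence_frac = 0.2, thickness_fraction = 0.8) {
  n <- length(distances)
  if (n < min_particles) {
    message(sprintf("micrograph '%s' excluded: %d particles < min_particles = %d",
                    micrograph_id, n, min_particles))
    return(NULL)
  }
  k <- kde_summary(distances, bandwidth = bandwidth)
  s <- skewness(distances)
  structure(list(
    micrograph_id = micrograph_id,
    distances = as.numeric(distances),
    n = n,
    mean = k$mean, median = k$median, mode = k$mode,
    skewness = s,
    tier = classify_skewness(s),
    modality = detect_layering(distances, prominence_frac = prominence_frac,
                               bandwidth = bandwidth),
    thickness = ice_thickness(distances, fraction = thickness_fraction),
    kde_grid = list(positions = k$grid, density = k$density),
    bandwidth = k$bandwidth
  ), class = "z_profile")
}

#' @export
print.z_profile <- function(x, ...) {
  cat(sprintf("z_profile '%s': n = %d, skewness = %.3f (%s), %s, thickness = %.1f A\n",
              x$micrograph_id, x$n, x$skewness, x$tier, x$modality, x$thickness))
  invisible(x)
}

# Tukey boxplot of a sample: whiskers at the furthest datum within
# 1.5 * IQR of the quartiles; points beyond are outliers.
.boxplot_stats <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3L] - q[1L]
  lo_lim <- q[1L] - 1.5 * iqr
  hi_lim <- q[3L] + 1.5 * iqr
  inside <- x[x >= lo_lim & x <= hi_lim]
  list(median = q[2L], q1 = q[1L], q3 = q[3L],
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = sort(x[x < lo_lim | x > hi_lim]))
}

#' Dataset-level summary of z-height profiles
#'
#' Collects per-micrograph skewness into a Tukey boxplot, tier fractions,
#' and an ice-thickness mean with a normal-approximation 95% confidence
#' interval (mean +/- 1.96 * SE across micrographs). Which physical
#' interface (air-water or graphene-water) sits on the positive-z side is
#' dataset-level knowledge supplied by the caller, never inferred from the
#' sign convention.
#'
#' @param profiles list of `z_profile` objects (NULL entries, from excluded
#'   micrographs, are dropped).
#' @param interface_map `"AWI_positive"` or `"GWI_positive"`: which
#'   interface the positive z side corresponds to.
#' @return object of class `dataset_summary`.
#' @export
summarize_dataset <- function(profiles,
                              interface_map = c("AWI_positive", "GWI_positive")) {
  interface_map <- match.arg(interface_map)
  profiles <- Filter(Negate(is.null), profiles)
  if (!length(profiles)) stop("no valid micrograph profiles", call. = FALSE)
  sk <- vapply(profiles, `[[`, numeric(1L), "skewness")
  th <- vapply(profiles, `[[`, numeric(1L), "thickness")
  tiers <- vapply(profiles, `[[`, character(1L), "tier")
  tier_levels <- c("symmetric", "moderate_left", "moderate_right",
                   "high_left", "high_right")
  tf <- table(factor(tiers, levels = tier_levels)) / length(tiers)
  n_mic <- length(profiles)
  se <- if (n_mic > 1L) stats::sd(th) / sqrt(n_mic) else 0
  structure(list(
    per_micrograph = profiles,
    skewness_values = sk,
    boxplot = .boxplot_stats(sk),
    tier_fractions = as.list(tf),
    thickness_mean = mean(th),
    thickness_ci95 = c(mean(th) - 1.96 * se, mean(th) + 1.96 * se),
    interface_map = interface_map,
    n_micrographs = n_mic
  ), class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat(sprintf("dataset_summary: %d micrographs, positive z side = %s\n",
              x$n_micrographs, sub("_positive", "", x$interface_map)))
  cat(sprintf("  skewness median %.3f [Q1 %.3f, Q3 %.3f], %d outlier(s)\n",
              x$boxplot$median, x$boxplot$q1, x$boxplot$q3,
              length(x$boxplot$outliers)))
  cat(sprintf("  thickness %.1f A (95%% CI %.1f-%.1f A)\n",
              x$thickness_mean, x$thickness_ci95[1L], x$thickness_ci95[2L]))
  tf <- unlist(x$tier_fractions)
  cat("  tiers:", paste(sprintf("%s %.2f", names(tf), tf), collapse = ", "), "\n")
  invisible(x)
}

#' Per-micrograph summary table of a dataset
#' @param summary a `dataset_summary`.
#' @return data.frame with one row per micrograph.
#' @export
profile_table <- function(summary) {
  stopifnot(inherits(summary, "dataset_summary"))
  do.call(rbind, lapply(summary$per_micrograph, function(p) {
    data.frame(micrograph_id = p$micrograph_id, n = p$n,
               mean = p$mean, median = p$median, mode = p$mode,
               skewness = p$skewness, tier = p$tier, modality = p$modality,
               thickness = p$thickness, stringsAsFactors = FALSE)
  }))
}
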