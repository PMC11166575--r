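# Orchestration: simulate -> analyze -> report, plus recovery checks.

#' Analyze a single-particle table end to end
#'
#' Runs the full z-height pipeline: defocus to z conversion, per-micrograph
#' least-squares plane fit, signed orthogonal distances, per-micrograph
#' profiles and the dataset summary. Micrographs with fewer than
#' `min_particles` particles are excluded (and reported). When a symmetry
#' name is given and Euler angles are present, the symmetry-reduced
#' orientation heatmap is attached.
#'
#' @param table a [particle_table].
#' @param z_convention see [defocus_to_z()].
#' @param interface_map which interface lies on the positive z side
#'   (`"AWI_positive"` or `"GWI_positive"`); dataset-level configuration.
#' @param min_particles per-micrograph inclusion threshold (default 10).
#' @param bandwidth,prominence_frac,thickness_fraction see [z_profile()].
#' @param symmetry optional point-group name for the orientation heatmap.
#' @param n_rot_bins,n_tilt_bins heatmap grid.
#' @return object of class `spa_report`: list with `summary`
#'   (a `dataset_summary`), `profiles`, `plane_fits`, `excluded`
#'   (data.frame of skipped micrographs), `orientation` (heatmap or NULL)
#'   and the resolved configuration.
#' @export
analyze_spa <- function(table,
                        z_convention = "defocus_decreasing_up",
                        interface_map = "AWI_positive",
                        min_particles = 10L,
                        bandwidth = "silverman",
                        prominence_frac = 0.2,
                        thickness_fraction = 0.8,
                        symmetry = NULL,
                        n_rot_bins = 36L, n_tilt_bins = 18L) {
  clouds <- defocus_to_z(table, convention = z_convention)
  profiles <- list()
  fits <- list()
  excluded <- data.frame(micrograph_id = character(), n = integer(),
                         reason = character(), stringsAsFactors = FALSE)
  for (cl in clouds) {
    id <- attr(cl, "micrograph_id")
    n <- nrow(cl)
    if (n < max(min_particles, 3L)) {
      excluded <- rbind(excluded, data.frame(
        micrograph_id = id, n = n,
        reason = sprintf("fewer than min_particles = %d", min_particles)))
      next
    }
    fit <- tryCatch(fit_plane(cl, min_points = 3L), error = function(e) NULL)
    if (is.null(fit)) {
      excluded <- rbind(excluded, data.frame(micrograph_id = id, n = n,
                                             reason = "degenerate plane fit"))
      next
    }
    d <- distances_to_plane(cl, fit)
    prof <- suppressMessages(
      z_profile(d, micrograph_id = id, min_particles = min_particles,
                bandwidth = bandwidth, prominence_frac = prominence_frac,
                thickness_fraction = thickness_fraction))
    if (is.null(prof)) {
      excluded <- rbind(excluded, data.frame(micrograph_id = id, n = n,
                                             reason = "profile rejected"))
      next
    }
    profiles[[id]] <- prof
    fits[[id]] <- fit
  }
  if (!length(profiles)) {
    stop("no micrograph passed the min_particles threshold", call. = FALSE)
  }
  omap <- NULL
  if (!is.null(symmetry)) {
    if (!has_angles(as.data.frame(table))) {
      warning("Euler angles absent; orientation heatmap skipped", call. = FALSE)
    } else {
      omap <- orientation_heatmap(table, symmetry, n_rot_bins = n_rot_bins,
                                  n_tilt_bins = n_tilt_bins)
    }
  }
  structure(list(
    summary = summarize_dataset(profiles, interface_map = interface_map),
    profiles = profiles,
    plane_fits = fits,
    excluded = excluded,
    orientation = omap,
    config = list(z_convention = z_convention, interface_map = interface_map,
                  min_particles = min_particles, bandwidth = bandwidth,
                  prominence_frac = prominence_frac,
                  thickness_fraction = thickness_fraction,
                  symmetry = symmetry,
                  version = as.character(utils::packageVersion("cryolayer")))
  ), class = "spa_report")
}

#' @export
print.spa_report <- function(x, ...) {
  print(x$summary)
  if (nrow(x$excluded)) {
    cat(sprintf("  %d micrograph(s) excluded\n", nrow(x$excluded)))
  }
  if (!is.null(x$orientation)) print(x$orientation)
  invisible(x)
}

#' Write a SPA report to disk
#'
#' Emits `per_micrograph.tsv` (one row per micrograph), `summary.json`
#' (dataset statistics plus the resolved configuration) and, when present,
#' `orientation_map.tsv`.
#'
#' @param report an `spa_report`.
#' @param out_dir output directory (created if needed).
#' @return the output directory, invisibly.
#' @export
write_spa_report <- function(report, out_dir) {
  stopifnot(inherits(report, "spa_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(profile_table(report$summary),
                     file.path(out_dir, "per_micrograph.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  s <- report$summary
  js <- list(
    n_micrographs = s$n_micrographs,
    interface_map = s$interface_map,
    skewness_boxplot = s$boxplot,
    tier_fractions = s$tier_fractions,
    thickness_mean_angstrom = s$thickness_mean,
    thickness_ci95_angstrom = s$thickness_ci95,
    excluded = report$excluded,
    config = report$config
  )
  jsonlite::write_json(js, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(report$orientation)) {
    write_orientation_map(report$orientation,
                          file.path(out_dir, "orientation_map.tsv"))
  }
  invisible(out_dir)
}

#' Simulate a dataset to disk
#'
#' Generates a synthetic SPA dataset (STAR file plus JSON truth manifest)
#' and a synthetic tomogram (three point files) under `out_dir`.
#'
#' @param manifest a [spa_manifest()].
#' @param out_dir output directory.
#' @param tomo also write a tomogram point set generated with the same
#'   seed (default TRUE).
#' @return list of written paths.
#' @export
cmd_simulate <- function(manifest, out_dir, tomo = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- generate_spa_dataset(manifest)
  star_path <- file.path(out_dir, "particles.star")
  write_particle_star(ds$table, star_path)
  manifest_path <- file.path(out_dir, "manifest.json")
  write_manifest(ds$truth, manifest_path)
  paths <- list(star = star_path, manifest = manifest_path)
  if (tomo) {
    td <- generate_tomo_dataset(seed = manifest$seed)
    for (nm in c("particles", "awi_markers", "gwi_markers")) {
      p <- file.path(out_dir, paste0("tomo_", nm, ".txt"))
      write_tomo_points(td[[nm]], p)
      paths[[paste0("tomo_", nm)]] <- p
    }
    jsonlite::write_json(td$truth, file.path(out_dir, "tomo_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths$tomo_truth <- file.path(out_dir, "tomo_truth.json")
  }
  paths
}

#' Analyze a STAR file from disk
#'
#' File-level wrapper around [analyze_spa()] that also writes the report.
#'
#' @param star_path particle STAR path.
#' @param out_dir output directory for the report.
#' @param default_pixel_size used when the file carries no pixel size.
#' @param ... passed to [analyze_spa()].
#' @return the `spa_report`, invisibly.
#' @export
cmd_analyze_spa <- function(star_path, out_dir, default_pixel_size = NULL, ...) {
  table <- read_particle_star(star_path, default_pixel_size = default_pixel_size)
  report <- analyze_spa(table, ...)
  write_spa_report(report, out_dir)
  invisible(report)
}

#' Analyze tomogram point files from disk
#'
#' @param particle_path,awi_path,gwi_path delimited coordinate files.
#' @param voxel_size voxel size in Angstrom.
#' @param particle_radius particle radius in Angstrom.
#' @param out_dir optional directory; when given, `tomo_report.json` is
#'   written.
#' @param ... passed to [analyze_tomogram()].
#' @return the `tomo_report`, invisibly.
#' @export
cmd_analyze_tomo <- function(particle_path, awi_path, gwi_path, voxel_size,
                             particle_radius, out_dir = NULL, ...) {
  particles <- read_tomo_points(particle_path, "particle", voxel_size)
  awi <- read_tomo_points(awi_path, "awi_marker", voxel_size)
  gwi <- read_tomo_points(gwi_path, "gwi_marker", voxel_size)
  report <- analyze_tomogram(particles, awi, gwi,
                             particle_radius = particle_radius, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    js <- list(
      particle_to_gwi_angstrom = report$particle_to_gwi_spacing[["angstrom"]],
      particle_to_gwi_slices = report$particle_to_gwi_spacing[["slices"]],
      particle_to_awi_angstrom = report$particle_to_awi_spacing[["angstrom"]],
      particle_to_awi_slices = report$particle_to_awi_spacing[["slices"]],
      thickness_angstrom = report$thickness,
      monolayer = report$monolayer,
      n_particles = report$n_particles
    )
    jsonlite::write_json(js, file.path(out_dir, "tomo_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}

#' Compare pipeline estimates with generative truth
#'
#' Given the truth attached by [generate_spa_dataset()] and an
#' [analyze_spa()] report on the generated table, checks per-criterion
#' recovery: plane tilt, ice thickness, skewness-tier side, and modality.
#' The expected tier side for an interface model is opposite to the
#' adsorption side: particles piled at the +z interface leave a long tail
#' toward -z, so the distribution is left-skewed.
#'
#' @param truth the `truth` element of [generate_spa_dataset()].
#' @param report the matching `spa_report`.
#' @param tilt_tol absolute tolerance on recovered plane slopes.
#' @param thickness_rel_tol relative tolerance on mean thickness against
#'   the truth's placement model (only checked for mid_gauss, where the
#'   central-80% extent has the closed form 2 * 1.2816 * sigma_effective).
#' @return data.frame with one row per criterion: `criterion`, `value`,
#'   `expected`, `pass`.
#' @export
cmd_recover <- function(truth, report, tilt_tol = 5e-3,
                        thickness_rel_tol = 0.10) {
  stopifnot(inherits(report, "spa_report"))
  rows <- list()
  add <- function(criterion, value, expected, pass) {
    rows[[length(rows) + 1L]] <<- data.frame(
      criterion = criterion, value = value, expected = expected,
      pass = pass, stringsAsFactors = FALSE)
  }
  # plane tilt: mean absolute error of fitted slopes vs truth
  ids <- names(report$plane_fits)
  truth_by_id <- stats::setNames(truth$micrographs,
                                 vapply(truth$micrographs, `[[`, "", "micrograph_id"))
  err_a <- vapply(ids, function(id)
    abs(report$plane_fits[[id]]$a - truth_by_id[[id]]$a), numeric(1L))
  add("plane_tilt_mae", mean(err_a), tilt_tol, mean(err_a) <= tilt_tol)

  kind <- truth$placement$kind
  tiers <- vapply(report$summary$per_micrograph, `[[`, "", "tier")
  modal <- vapply(report$summary$per_micrograph, `[[`, "", "modality")
  if (kind == "mid_gauss") {
    frac_sym <- mean(tiers == "symmetric")
    add("tier_symmetric_fraction", frac_sym, 0.95, frac_sym >= 0.95)
    sigma_eff <- sqrt(truth$placement$sigma^2 + truth$defocus_noise_sd^2)
    exp_th <- 2 * stats::qnorm(0.9) * sigma_eff
    rel <- abs(report$summary$thickness_mean - exp_th) / exp_th
    add("thickness_rel_err", rel, thickness_rel_tol, rel <= thickness_rel_tol)
  } else if (kind == "interface") {
    want <- if (truth$placement$side == "+") "left" else "right"
    frac_side <- mean(grepl(want, tiers))
    add("tier_side_fraction", frac_side, 0.95, frac_side >= 0.95)
  } else if (kind %in% c("bimodal", "double_layer")) {
    frac_bi <- mean(modal == "bimodal")
    add("bimodal_fraction", frac_bi, 0.95, frac_bi >= 0.95)
  } else if (kind == "uniform_slab") {
    frac_sym <- mean(tiers == "symmetric")
    add("tier_symmetric_fraction", frac_sym, 0.95, frac_sym >= 0.95)
  }
  do.call(rbind, rows)
}
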