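# Fixtures built in code: small STAR files and reusable generators.

# RELION >= 3.1 dialect fixture: 3 particles, 2 micrographs.
write_star_fixture <- function(path = tempfile(fileext = ".star"),
                               drop_tag = NULL) {
  tags <- c("_rlnMicrographName", "_rlnCoordinateX", "_rlnCoordinateY",
            "_rlnDefocusU", "_rlnDefocusV",
            "_rlnAngleRot", "_rlnAngleTilt", "_rlnAnglePsi")
  rows <- c(
    "mic_a.mrc 100.0 200.0 10000.0 10050.0  30.0  45.0  10.0",
    "mic_a.mrc 300.0 400.0 10100.0 10150.0 -60.0  90.0  20.0",
    "mic_b.mrc 500.0 600.0 10200.0 10250.0 120.0 135.0 -30.0"
  )
  if (!is.null(drop_tag)) {
    j <- match(drop_tag, tags)
    tags <- tags[-j]
    rows <- vapply(rows, function(r) {
      cells <- strsplit(trimws(r), "\\s+")[[1L]]
      paste(cells[-j], collapse = " ")
    }, character(1L), USE.NAMES = FALSE)
  }
  lines <- c("data_optics", "", "loop_",
             "_rlnOpticsGroup #1", "_rlnImagePixelSize #2",
             "1 1.200000", "",
             "data_particles", "", "loop_",
             sprintf("%s #%d", tags, seq_along(tags)),
             rows)
  writeLines(lines, path)
  path
}

# Legacy single-block STAR (no optics block, no pixel size).
write_legacy_star_fixture <- function(path = tempfile(fileext = ".star")) {
  lines <- c("data_", "", "loop_",
             "_rlnMicrographName #1", "_rlnCoordinateX #2", "_rlnCoordinateY #3",
             "_rlnDefocusU #4", "_rlnDefocusV #5",
             "mic_a.mrc 10 20 12000 12100",
             "mic_a.mrc 30 40 12200 12300",
             "mic_a.mrc 50 60 12400 12500")
  writeLines(lines, path)
  path
}

# Independent normal-equations least-squares oracle for z = a x + b y + c:
# coefficients and their standard errors from the closed form.
ls_plane_oracle <- function(x, y, z) {
  X <- cbind(x, y, 1)
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% z
  res <- z - X %*% beta
  s2 <- sum(res^2) / (length(z) - 3L)
  list(beta = as.numeric(beta), se = sqrt(s2 * diag(XtX_inv)))
}

# One-micrograph synthetic run through the full z pipeline.
profile_one_micrograph <- function(seed, placement, n = 1500L, ...) {
  m <- spa_manifest(seed = seed, n_micrographs = 1L,
                    n_particles_per_micrograph = n, placement = placement, ...)
  ds <- generate_spa_dataset(m)
  cl <- defocus_to_z(ds$table)[[1L]]
  fit <- fit_plane(cl)
  z_profile(distances_to_plane(cl, fit))
}
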