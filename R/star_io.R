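# STAR (RELION dialect) particle metadata and tomogram point-set I/O.

#' Required particle loop tags
#'
#' Column tags that must be present in a particles loop for the z-height
#' pipeline. Euler angles are optional at read time (orientation analysis
#' refuses tables without them).
#' @keywords internal
.required_tags <- c(
  "_rlnMicrographName",
  "_rlnCoordinateX", "_rlnCoordinateY",
  "_rlnDefocusU", "_rlnDefocusV"
)

.angle_tags <- c("_rlnAngleRot", "_rlnAngleTilt", "_rlnAnglePsi")

#' Construct a particle table
#'
#' A `particle_table` is a plain `data.frame` with one row per particle and
#' columns `micrograph_id`, `coord_x`, `coord_y` (pixels, detector frame),
#' `defocus_u`, `defocus_v` (Angstrom, underfocus positive), and optionally
#' `angle_rot`, `angle_tilt`, `angle_psi` (degrees, ZYZ Euler convention)
#' and `optics_group`. The pixel size (Angstrom/pixel) and source path
#' travel as attributes.
#'
#' @param records data.frame with the columns above.
#' @param pixel_size pixel size in Angstrom per pixel (> 0).
#' @param source_path provenance string (optional).
#' @return object of class `particle_table`.
#' @export
particle_table <- function(records, pixel_size, source_path = NA_character_) {
  stopifnot(is.data.frame(records))
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0) {
    stop("pixel_size must be a single finite positive number", call. = FALSE)
  }
  needed <- c("micrograph_id", "coord_x", "coord_y", "defocus_u", "defocus_v")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop("particle records lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) > 0L) {
    if (any(!nzchar(records$micrograph_id) | is.na(records$micrograph_id))) {
      stop("every record needs a non-empty micrograph_id", call. = FALSE)
    }
    bad <- which(!is.finite(records$defocus_u) | !is.finite(records$defocus_v))
    if (length(bad)) {
      stop("non-finite defocus at particle index ", bad[1L], call. = FALSE)
    }
    if (has_angles(records)) {
      tl <- records$angle_tilt
      if (any(is.finite(tl) & (tl < 0 | tl > 180))) {
        stop("angle_tilt must lie in [0, 180] degrees", call. = FALSE)
      }
    }
  }
  structure(records,
            pixel_size = pixel_size,
            source_path = source_path,
            class = c("particle_table", "data.frame"))
}

has_angles <- function(df) all(c("angle_rot", "angle_tilt", "angle_psi") %in% names(df))

#' @export
print.particle_table <- function(x, ...) {
  cat(sprintf("particle_table: %d particles, %d micrograph(s), pixel size %.4g A/px\n",
              nrow(x), length(unique(x$micrograph_id)), attr(x, "pixel_size")))
  cat(if (has_angles(x)) "Euler angles: present\n" else "Euler angles: absent\n")
  invisible(x)
}

#' Pixel size of a particle table
#' @param table a `particle_table`.
#' @return pixel size in Angstrom/pixel.
#' @export
pixel_size <- function(table) attr(table, "pixel_size")

# ---- STAR parsing ----------------------------------------------------------

# Split a STAR file into named blocks; each block is a list with either
# key-value pairs or a loop (tags + a character matrix of cells).
.parse_star_blocks <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  idx <- which(keep)
  lines <- lines[keep]
  blocks <- list()
  cur_name <- NULL
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- lines[i]
    if (startsWith(ln, "data_")) {
      cur_name <- substring(ln, 6L)
      if (!nzchar(cur_name)) cur_name <- "unnamed"
      blocks[[cur_name]] <- list(pairs = list(), tags = character(), rows = list(),
                                 row_lines = integer())
      i <- i + 1L
    } else if (identical(ln, "loop_")) {
      if (is.null(cur_name)) stop("STAR format error: loop_ before any data_ block",
                                  call. = FALSE)
      i <- i + 1L
      tags <- character()
      while (i <= n && startsWith(lines[i], "_")) {
        tags <- c(tags, strsplit(lines[i], "\\s+")[[1L]][1L])
        i <- i + 1L
      }
      rows <- list()
      row_lines <- integer()
      while (i <= n && !startsWith(lines[i], "data_") &&
             !identical(lines[i], "loop_") && !startsWith(lines[i], "_")) {
        cells <- strsplit(lines[i], "\\s+")[[1L]]
        if (length(cells) != length(tags)) {
          stop(sprintf("STAR format error at line %d: %d fields, expected %d",
                       idx[i], length(cells), length(tags)), call. = FALSE)
        }
        rows[[length(rows) + 1L]] <- cells
        row_lines <- c(row_lines, idx[i])
        i <- i + 1L
      }
      blocks[[cur_name]]$tags <- tags
      blocks[[cur_name]]$rows <- rows
      blocks[[cur_name]]$row_lines <- row_lines
    } else if (startsWith(ln, "_")) {
      if (is.null(cur_name)) stop("STAR format error: tag before any data_ block",
                                  call. = FALSE)
      kv <- strsplit(ln, "\\s+")[[1L]]
      blocks[[cur_name]]$pairs[[kv[1L]]] <- if (length(kv) > 1L) kv[2L] else ""
      i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  blocks
}

.loop_column <- function(block, tag, numeric = TRUE) {
  j <- match(tag, block$tags)
  if (is.na(j)) return(NULL)
  vals <- vapply(block$rows, `[[`, character(1L), j)
  if (!numeric) return(vals)
  out <- suppressWarnings(as.numeric(vals))
  bad <- which(is.na(out) & !is.na(vals))
  if (length(bad)) {
    stop(sprintf("unparseable numeric cell for %s at row %d (file line %d)",
                 tag, bad[1L], block$row_lines[bad[1L]]), call. = FALSE)
  }
  out
}

#' Read a RELION particle STAR file
#'
#' Accepts both the RELION >= 3.1 dialect (a `data_optics` block plus a
#' `data_particles` block) and legacy single-block files. The pixel size is
#' taken from the optics block (`_rlnImagePixelSize`) when present;
#' otherwise `default_pixel_size` must be supplied. When both are present
#' and differ, the optics value wins with a warning.
#'
#' @param path path to the STAR file.
#' @param default_pixel_size pixel size (Angstrom/pixel) used when the file
#'   carries none.
#' @return a [particle_table].
#' @export
read_particle_star <- function(path, default_pixel_size = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  blocks <- .parse_star_blocks(readLines(path, warn = FALSE))
  part_name <- if ("particles" %in% names(blocks)) "particles" else {
    with_loop <- names(blocks)[vapply(blocks, function(b) length(b$tags) > 0L, logical(1L))]
    with_loop <- setdiff(with_loop, "optics")
    if (!length(with_loop)) stop("STAR format error: no particles loop found", call. = FALSE)
    with_loop[1L]
  }
  pb <- blocks[[part_name]]
  missing <- setdiff(.required_tags, pb$tags)
  if (length(missing)) {
    stop("STAR format error: missing required tag(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  file_px <- NA_real_
  if ("optics" %in% names(blocks)) {
    ob <- blocks[["optics"]]
    px <- .loop_column(ob, "_rlnImagePixelSize")
    if (is.null(px) && "_rlnImagePixelSize" %in% names(ob$pairs)) {
      px <- as.numeric(ob$pairs[["_rlnImagePixelSize"]])
    }
    if (!is.null(px) && length(px)) file_px <- px[1L]
  }
  if ("_rlnImagePixelSize" %in% pb$tags && is.na(file_px)) {
    file_px <- .loop_column(pb, "_rlnImagePixelSize")[1L]
  }
  if (is.finite(file_px)) {
    if (!is.null(default_pixel_size) &&
        abs(file_px - default_pixel_size) > 1e-6 * max(file_px, default_pixel_size)) {
      warning(sprintf("pixel size in optics block (%.6g) overrides supplied %.6g",
                      file_px, default_pixel_size), call. = FALSE)
    }
    px_size <- file_px
  } else if (!is.null(default_pixel_size)) {
    px_size <- default_pixel_size
  } else {
    stop("no pixel size in file and no default_pixel_size supplied", call. = FALSE)
  }

  rec <- data.frame(
    micrograph_id = .loop_column(pb, "_rlnMicrographName", numeric = FALSE),
    coord_x = .loop_column(pb, "_rlnCoordinateX"),
    coord_y = .loop_column(pb, "_rlnCoordinateY"),
    defocus_u = .loop_column(pb, "_rlnDefocusU"),
    defocus_v = .loop_column(pb, "_rlnDefocusV"),
    stringsAsFactors = FALSE
  )
  angle_map <- c(angle_rot = "_rlnAngleRot", angle_tilt = "_rlnAngleTilt",
                 angle_psi = "_rlnAnglePsi")
  if (all(angle_map %in% pb$tags)) {
    for (nm in names(angle_map)) rec[[nm]] <- .loop_column(pb, angle_map[[nm]])
  }
  og <- .loop_column(pb, "_rlnOpticsGroup")
  if (!is.null(og)) rec$optics_group <- as.integer(og)
  particle_table(rec, pixel_size = px_size, source_path = path)
}

#' Write a particle table to STAR
#'
#' Emits the RELION >= 3.1 dialect: a `data_optics` block carrying the
#' pixel size and a `data_particles` loop. Round-tripping through
#' [read_particle_star()] reproduces all numeric fields to better than
#' 1e-4 relative difference.
#'
#' @param table a non-empty [particle_table].
#' @param path output path.
#' @export
write_particle_star <- function(table, path) {
  stopifnot(inherits(table, "particle_table"))
  if (nrow(table) == 0L) stop("refusing to write an empty particle table", call. = FALSE)
  px <- pixel_size(table)
  num <- function(x) formatC(x, format = "f", digits = 6)
  lines <- c(
    "# written by cryolayer",
    "",
    "data_optics", "", "loop_",
    "_rlnOpticsGroup #1", "_rlnImagePixelSize #2",
    paste("1", num(px)),
    "",
    "data_particles", "", "loop_"
  )
  tags <- c("_rlnMicrographName", "_rlnCoordinateX", "_rlnCoordinateY",
            "_rlnDefocusU", "_rlnDefocusV")
  cols <- list(table$micrograph_id, num(table$coord_x), num(table$coord_y),
               num(table$defocus_u), num(table$defocus_v))
  if (has_angles(table)) {
    tags <- c(tags, .angle_tags)
    cols <- c(cols, list(num(table$angle_rot), num(table$angle_tilt),
                         num(table$angle_psi)))
  }
  if ("optics_group" %in% names(table)) {
    tags <- c(tags, "_rlnOpticsGroup")
    cols <- c(cols, list(as.character(table$optics_group)))
  }
  lines <- c(lines, sprintf("%s #%d", tags, seq_along(tags)),
             do.call(paste, cols), "")
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path, call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read tomogram point coordinates
#'
#' Reads a plain delimited text file with one 3D point per row (x, y, z in
#' voxels), whitespace- or comma-delimited. A single non-numeric leading
#' line is treated as a header and skipped.
#'
#' @param path file path.
#' @param label one of `"particle"`, `"awi_marker"`, `"gwi_marker"`.
#' @param voxel_size voxel size in Angstrom (> 0).
#' @return a `tomo_points` object: a data.frame with columns x, y, z and
#'   attributes `label` and `voxel_size`.
#' @export
read_tomo_points <- function(path, label = c("particle", "awi_marker", "gwi_marker"),
                             voxel_size) {
  label <- match.arg(label)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L ||
      !is.finite(voxel_size) || voxel_size <= 0) {
    stop("voxel_size must be a single positive number", call. = FALSE)
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  nz <- which(nzchar(lines))
  parse_row <- function(ln) {
    cells <- strsplit(gsub(",", " ", ln), "\\s+")[[1L]]
    suppressWarnings(as.numeric(cells))
  }
  start <- 1L
  if (length(nz)) {
    first <- parse_row(lines[nz[1L]])
    if (anyNA(first)) start <- 2L  # single header line allowed
  }
  data_lines <- nz[seq_along(nz) >= start]
  if (!length(data_lines)) stop("no points in file: ", path, call. = FALSE)
  rows <- lapply(data_lines, function(k) {
    vals <- parse_row(lines[k])
    if (length(vals) != 3L || anyNA(vals)) {
      stop(sprintf("line %d: expected 3 numeric fields", k), call. = FALSE)
    }
    vals
  })
  pts <- do.call(rbind, rows)
  tomo_points(pts, label = label, voxel_size = voxel_size)
}

#' Construct a tomogram point set
#' @param xyz numeric matrix (n x 3) or data.frame of voxel coordinates.
#' @param label point-set label.
#' @param voxel_size voxel size in Angstrom (> 0).
#' @export
tomo_points <- function(xyz, label = c("particle", "awi_marker", "gwi_marker"),
                        voxel_size) {
  label <- match.arg(label)
  stopifnot(voxel_size > 0)
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, nrow(xyz) >= 1L, all(is.finite(xyz)))
  df <- data.frame(x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L])
  structure(df, label = label, voxel_size = voxel_size,
            class = c("tomo_points", "data.frame"))
}

#' Write tomogram points to delimited text
#' @param points a `tomo_points` object.
#' @param path output path.
#' @export
write_tomo_points <- function(points, path) {
  stopifnot(inherits(points, "tomo_points"))
  utils::write.table(as.data.frame(points)[, c("x", "y", "z")], path,
                     row.names = FALSE, col.names = c("x", "y", "z"),
                     quote = FALSE, sep = "\t")
  invisible(path)
}
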