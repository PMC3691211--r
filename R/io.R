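# Readers and writers shared by all stages. Conventions, stated in every
# file this package writes: 0-based pixel indices, pixel-center origin,
# x = column, y = row; physical units are micrometers and minutes.

#' Read a grayscale TIFF as a cell image
#'
#' Accepts single- or two-channel grayscale TIFFs. The pixel size is taken
#' from the TIFF x-resolution tag when present (resolution unit inch or
#' centimeter) and can always be overridden with `pixel_size_um`; if
#' neither source is available, reading fails. Multi-page stacks are
#' reduced by per-pixel maximum projection when `max_project = TRUE`, and
#' rejected otherwise.
#'
#' @param path TIFF file path.
#' @param pixel_size_um optional pixel size override (micrometers).
#' @param max_project reduce a multi-page stack by max projection.
#' @return A [cell_image()].
#' @export
read_image <- function(path, pixel_size_um = NULL, max_project = FALSE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  pages <- suppressWarnings(tiff::readTIFF(path, info = TRUE, all = TRUE))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) > 1) {
    if (!max_project) {
      stop(sprintf("%s has %d pages; pass max_project = TRUE to project",
                   path, length(pages)))
    }
    pages <- list(Reduce(pmax, pages))
  }
  m <- pages[[1]]
  strip <- function(x) matrix(as.numeric(x), nrow(x), ncol(x))
  if (length(dim(m)) == 3) {
    if (dim(m)[3] > 2) {
      stop(sprintf("unsupported image shape %s: RGB or >2 channels",
                   paste(dim(m), collapse = "x")))
    }
    ch2 <- if (dim(m)[3] == 2) strip(m[, , 2]) else NULL
    m1 <- strip(m[, , 1])
  } else {
    m1 <- strip(m)
    ch2 <- NULL
  }
  if (is.null(pixel_size_um)) {
    info <- attributes(pages[[1]])
    xres <- info$x.resolution
    unit <- info$resolution.unit
    if (is.null(xres) || !is.numeric(xres) || xres <= 0) {
      stop("pixel size unknown: no resolution tag and no `pixel_size_um` override")
    }
    per_um <- switch(as.character(unit %||% "inch"),
                     inch = xres / 25400, cm = xres / 10000,
                     stop("pixel size unknown: unsupported resolution unit"))
    pixel_size_um <- 1 / per_um
  }
  cell_image(m1, pixel_size_um, channel2 = ch2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cell image as a 16-bit grayscale TIFF
#'
#' Intensities must lie in `[0, 1]` and are stored at the standard 16-bit
#' microscopy depth. Writing snaps intensities to the 16-bit grid
#' (multiples of 1/65535, a quantization of at most 7.7e-6), after which
#' write/read round trips are bit-identical; images that already sit on
#' the grid -- anything previously read from a 16-bit TIFF -- round-trip
#' bit-identically from the first write.
#'
#' @param image a [cell_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "cell_image"))
  what <- if (is.null(image$channel2)) {
    image$pixels
  } else {
    array(c(image$pixels, image$channel2), dim = c(dim(image$pixels), 2))
  }
  if (min(what) < 0 || max(what) > 1) {
    stop("image intensities must lie in [0, 1] for TIFF output; rescale first")
  }
  # snap to the 16-bit sample grid; grid values are exact fixed points of
  # the writer/reader pair, so round trips are bit-identical
  what <- round(what * 65535) / 65535
  tiff::writeTIFF(what, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read comet / tip tracks from CSV
#'
#' Expects columns `track_id`, `frame`, `x_px`, `y_px`. Rows are grouped
#' by `track_id` and sorted by frame; duplicate (track_id, frame) pairs
#' are an error reporting the offending row.
#'
#' @param path CSV path.
#' @param frame_interval_s,pixel_size_um acquisition metadata attached to
#'   every track.
#' @return A list of [track()] objects (empty for a header-only file).
#' @export
read_tracks <- function(path, frame_interval_s, pixel_size_um) {
  df <- utils::read.csv(path)
  need <- c("track_id", "frame", "x_px", "y_px")
  if (!all(need %in% names(df))) {
    stop(sprintf("track CSV must have columns %s", paste(need, collapse = ", ")))
  }
  if (nrow(df) == 0) return(list())
  dup <- duplicated(df[, c("track_id", "frame")])
  if (any(dup)) {
    stop(sprintf("duplicate (track_id, frame) at row %d of %s",
                 which(dup)[1] + 1L, path)) # +1 for the header line
  }
  ids <- unique(df$track_id)
  lapply(ids, function(id) {
    g <- df[df$track_id == id, ]
    track(id, g$frame, g$x_px, g$y_px, frame_interval_s, pixel_size_um)
  })
}

#' Write tracks to CSV
#'
#' @param tracks list of [track()] objects.
#' @param path output path.
#' @param labels optional character vector (one per track) written as an
#'   `origin` column.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path, labels = NULL) {
  rows <- lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    out <- cbind(track_id = tr$track_id, tr$samples)
    if (!is.null(labels)) out$origin <- labels[i]
    out
  })
  df <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(track_id = integer(0), frame = integer(0),
               x_px = numeric(0), y_px = numeric(0))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read cell geometry from an ROI CSV
#'
#' Format: columns `type`, `x_px`, `y_px`; exactly one `center` row and
#' at least three `vertex` rows in boundary order.
#'
#' @param path CSV path.
#' @return A [cell_geometry()].
#' @export
read_roi <- function(path) {
  df <- utils::read.csv(path)
  need <- c("type", "x_px", "y_px")
  if (!all(need %in% names(df))) {
    stop(sprintf("ROI CSV must have columns %s", paste(need, collapse = ", ")))
  }
  ctr <- df[df$type == "center", ]
  vert <- df[df$type == "vertex", ]
  if (nrow(ctr) != 1) stop("ROI CSV must contain exactly one center row")
  cell_geometry(c(ctr$x_px, ctr$y_px), as.matrix(vert[, c("x_px", "y_px")]))
}

#' Write cell geometry to an ROI CSV
#'
#' @param geometry a [cell_geometry()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roi <- function(geometry, path) {
  stopifnot(inherits(geometry, "cell_geometry"))
  df <- rbind(
    data.frame(type = "center", x_px = geometry$center_px[1],
               y_px = geometry$center_px[2]),
    data.frame(type = "vertex", x_px = geometry$boundary_px[, 1],
               y_px = geometry$boundary_px[, 2]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read immunogold EM annotations
#'
#' `polyline_path`: CSV with `filament_id`, `vertex_index`, `x_um`,
#' `y_um`. `particle_path`: CSV with `filament_id`, `x_um`, `y_um`
#' (optional; filaments absent from it carry zero particles).
#'
#' @param polyline_path,particle_path CSV paths.
#' @return A list of [em_filament()] objects.
#' @export
read_em_annotations <- function(polyline_path, particle_path = NULL) {
  pl <- utils::read.csv(polyline_path)
  stopifnot(all(c("filament_id", "vertex_index", "x_um", "y_um") %in% names(pl)))
  pts <- if (!is.null(particle_path)) utils::read.csv(particle_path) else NULL
  lapply(unique(pl$filament_id), function(id) {
    g <- pl[pl$filament_id == id, ]
    g <- g[order(g$vertex_index), ]
    pp <- matrix(numeric(0), 0, 2)
    if (!is.null(pts)) {
      q <- pts[pts$filament_id == id, ]
      if (nrow(q)) pp <- as.matrix(q[, c("x_um", "y_um")])
    }
    em_filament(id, as.matrix(g[, c("x_um", "y_um")]), pp)
  })
}

#' Write immunogold EM annotations
#'
#' @param filaments list of [em_filament()] objects.
#' @param polyline_path,particle_path output CSV paths.
#' @return `polyline_path`, invisibly.
#' @export
write_em_annotations <- function(filaments, polyline_path, particle_path) {
  pl <- do.call(rbind, lapply(filaments, function(f) {
    data.frame(filament_id = f$filament_id,
               vertex_index = seq_len(nrow(f$polyline_um)),
               x_um = f$polyline_um[, 1], y_um = f$polyline_um[, 2])
  }))
  pp <- do.call(rbind, lapply(filaments, function(f) {
    if (nrow(f$particle_positions) == 0) return(NULL)
    data.frame(filament_id = f$filament_id,
               x_um = f$particle_positions[, 1],
               y_um = f$particle_positions[, 2])
  }))
  if (is.null(pl)) {
    pl <- data.frame(filament_id = integer(0), vertex_index = integer(0),
                     x_um = numeric(0), y_um = numeric(0))
  }
  if (is.null(pp)) {
    pp <- data.frame(filament_id = integer(0), x_um = numeric(0),
                     y_um = numeric(0))
  }
  utils::write.csv(pl, polyline_path, row.names = FALSE)
  utils::write.csv(pp, particle_path, row.names = FALSE)
  invisible(polyline_path)
}

#' Reproducibility metadata block for an analysis run
#'
#' Every analysis driver writes this YAML block next to its outputs: the
#' package version, the seed, every parameter verbatim, and a hash of the
#' serialized parameter list, which together identify a deterministic run
#' bit-exactly.
#'
#' @param params named list of run parameters.
#' @param seed integer seed of the run.
#' @param path output path for the YAML block (`NULL` returns the string).
#' @return The YAML string, invisibly when written to `path`.
#' @export
run_metadata <- function(params, seed, path = NULL) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(params, tf)
  meta <- list(
    package = "mtquant",
    version = as.character(utils::packageVersion("mtquant")),
    seed = as.integer(seed),
    config_hash = unname(tools::md5sum(tf)),
    params = params)
  txt <- yaml::as.yaml(meta)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
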