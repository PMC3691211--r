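#' MDI measurement settings
#'
#' Controls the radial line-profile measurement behind the Microtubule
#' Distribution Index: lines are drawn from the cell center to the boundary
#' at a fixed angular interval; the inner fraction of each line (adjacent
#' to the center) and the outer fraction (adjacent to the boundary) are
#' aggregated and their ratio taken. The defaults (3 degrees, inner 10%,
#' outer 40%, mean aggregation) correspond to 120 lines per cell.
#'
#' @param angle_interval_deg angular spacing between consecutive lines,
#'   degrees. Lines are drawn at `k * angle_interval_deg` for
#'   `k = 0 .. floor(360 / angle_interval_deg) - 1`.
#' @param inner_fraction fraction of each line length, measured from the
#'   center, whose intensities form the inner summary `I_i`.
#' @param outer_fraction fraction of each line length, measured from the
#'   boundary, whose intensities form the outer summary `I_o`.
#' @param aggregate `"mean"` (default) or `"max"`: how intensities within
#'   the inner and outer windows are summarised.
#' @return An object of class `mdi_config`.
#' @export
mdi_config <- function(angle_interval_deg = 3, inner_fraction = 0.10,
                       outer_fraction = 0.40, aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  check_scalar(angle_interval_deg, "angle_interval_deg", positive = TRUE)
  check_scalar(inner_fraction, "inner_fraction", positive = TRUE)
  check_scalar(outer_fraction, "outer_fraction", positive = TRUE)
  if (inner_fraction >= 1 || outer_fraction >= 1) {
    stop("`inner_fraction` and `outer_fraction` must lie in (0, 1)")
  }
  if (inner_fraction + outer_fraction > 1) {
    stop("`inner_fraction` + `outer_fraction` must not exceed 1")
  }
  structure(
    list(angle_interval_deg = angle_interval_deg,
         inner_fraction = inner_fraction, outer_fraction = outer_fraction,
         aggregate = aggregate),
    class = "mdi_config"
  )
}

#' Radial measurement lines from cell center to boundary
#'
#' One straight segment per angle `k * angle_interval_deg`, measured
#' counterclockwise from the +x axis in image coordinates, from the center
#' point to the first intersection of that ray with the boundary polygon
#' (the first crossing keeps the profile inside the cell for concave
#' outlines).
#'
#' @param geometry a [cell_geometry()].
#' @param config an [mdi_config()].
#' @return A data.frame with one row per line: `angle_deg`, `x0`, `y0`
#'   (center), `x1`, `y1` (boundary hit) and `length_px`.
#' @export
radial_lines <- function(geometry, config = mdi_config()) {
  stopifnot(inherits(geometry, "cell_geometry"), inherits(config, "mdi_config"))
  n_lines <- floor(360 / config$angle_interval_deg)
  angles <- (seq_len(n_lines) - 1) * config$angle_interval_deg
  cx <- geometry$center_px[1]; cy <- geometry$center_px[2]
  hits <- lapply(angles, function(a) {
    th <- a * pi / 180
    hit <- ray_polygon_first_hit(c(cx, cy), c(cos(th), sin(th)),
                                 geometry$boundary_px)
    if (is.null(hit)) {
      stop(sprintf("geometry error: ray at %g degrees does not reach the boundary", a))
    }
    hit
  })
  hits <- do.call(rbind, hits)
  len <- sqrt((hits[, 1] - cx)^2 + (hits[, 2] - cy)^2)
  if (any(len <= 0)) stop("geometry error: zero-length radial line")
  data.frame(angle_deg = angles, x0 = cx, y0 = cy,
             x1 = hits[, 1], y1 = hits[, 2], length_px = len)
}

#' Outer/inner intensity ratio along one radial line
#'
#' Samples the image along the segment at approximately 1-pixel arc
#' spacing with bilinear interpolation, summarises the inner
#' `inner_fraction` of the length (adjacent to the center) as `I_i` and the
#' outer `outer_fraction` (adjacent to the boundary) as `I_o`, and returns
#' `R = I_o / I_i`. The middle stretch of the line contributes to neither
#' window. When `I_i` is zero the ratio is undefined and `NA` is returned;
#' [compute_mdi()] excludes such lines from the per-cell average.
#'
#' @param image a [cell_image()].
#' @param segment one row of the data.frame returned by [radial_lines()]
#'   (or any list with `x0`, `y0`, `x1`, `y1`).
#' @param config an [mdi_config()].
#' @return A single ratio, or `NA_real_` when the inner summary is zero.
#' @export
line_ratio <- function(image, segment, config = mdi_config()) {
  stopifnot(inherits(image, "cell_image"))
  dx <- segment$x1 - segment$x0
  dy <- segment$y1 - segment$y0
  len <- sqrt(dx^2 + dy^2)
  if (!is.finite(len) || len <= 0) stop("zero-length line segment")
  n <- max(2L, ceiling(len)) + 1L
  s <- seq(0, 1, length.out = n)
  vals <- bilinear_sample(image$pixels,
                          segment$x0 + s * dx, segment$y0 + s * dy)
  agg <- if (config$aggregate == "mean") mean else max
  inner <- agg(vals[s <= config$inner_fraction + 1e-12])
  outer <- agg(vals[s >= 1 - config$outer_fraction - 1e-12])
  if (inner == 0) return(NA_real_)
  outer / inner
}

#' Microtubule Distribution Index of one cell
#'
#' The MDI is the per-cell mean of the outer/inner intensity ratio `R`
#' over all radial lines ([line_ratio()]): low values indicate a
#' centrosome-concentrated (aster-like) MT network, higher values a
#' network spread towards the periphery. Lines with an undefined ratio
#' (zero inner intensity) are excluded from the average; it is an error
#' for all lines to be undefined.
#'
#' @inheritParams radial_lines
#' @param image a [cell_image()].
#' @return An object of class `mdi_result`: list with `mdi`, `per_line_R`
#'   (one entry per line, `NA` where undefined), `n_lines` and the line
#'   table.
#' @export
compute_mdi <- function(image, geometry, config = mdi_config()) {
  lines <- radial_lines(geometry, config)
  R <- vapply(seq_len(nrow(lines)), function(i) {
    line_ratio(image, lines[i, ], config)
  }, numeric(1))
  if (all(is.na(R))) stop("MDI undefined (empty inner intensities)")
  structure(
    list(mdi = mean(R, na.rm = TRUE), per_line_R = R,
         n_lines = nrow(lines), lines = lines),
    class = "mdi_result"
  )
}

#' @export
print.mdi_result <- function(x, ...) {
  cat(sprintf("<mdi_result> MDI = %.4f over %d lines (%d undefined)\n",
              x$mdi, x$n_lines, sum(is.na(x$per_line_R))))
  invisible(x)
}
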