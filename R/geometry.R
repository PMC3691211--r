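#' Cell geometry: center point and boundary polygon
#'
#' The manual annotation the MDI consumes: a central point placed inside
#' the region of highest tubulin concentration, and the cell border
#' outlined as a simple closed polygon. Coordinates are 0-based pixel
#' positions (x = column, y = row).
#'
#' @param center_px numeric length-2 vector `c(x, y)`.
#' @param boundary_px numeric matrix with >= 3 rows and columns `(x, y)`;
#'   the polygon is closed implicitly (last vertex connects to the first).
#' @return An object of class `cell_geometry`.
#' @export
cell_geometry <- function(center_px, boundary_px) {
  center_px <- as.numeric(center_px)
  if (length(center_px) != 2 || any(!is.finite(center_px))) {
    stop("`center_px` must be a finite (x, y) pair")
  }
  boundary_px <- as.matrix(boundary_px)
  if (ncol(boundary_px) != 2 || nrow(boundary_px) < 3) {
    stop("`boundary_px` must be an n x 2 matrix with n >= 3")
  }
  storage.mode(boundary_px) <- "double"
  g <- structure(list(center_px = center_px, boundary_px = boundary_px),
                 class = "cell_geometry")
  if (!point_in_polygon(center_px[1], center_px[2], boundary_px)) {
    stop("geometry error: center point lies outside the boundary polygon")
  }
  g
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("<cell_geometry> center (%.1f, %.1f), %d boundary vertices\n",
              x$center_px[1], x$center_px[2], nrow(x$boundary_px)))
  invisible(x)
}

#' Regular-polygon approximation of a circular cell outline
#'
#' Convenience for building synthetic geometries.
#'
#' @param center numeric `c(x, y)` center in pixels.
#' @param radius_px circle radius in pixels.
#' @param n_vertices number of polygon vertices.
#' @return A `cell_geometry`.
#' @export
circle_geometry <- function(center, radius_px, n_vertices = 64L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  cell_geometry(center,
                cbind(center[1] + radius_px * cos(th),
                      center[2] + radius_px * sin(th)))
}

#' Point-in-polygon test
#'
#' Even-odd ray-casting test, vectorised over points. Points exactly on
#' the boundary may fall either way; keep test points clearly inside or
#' outside.
#'
#' @param px,py point coordinates (vectors).
#' @param poly n x 2 vertex matrix of a simple polygon.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  j <- n
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Shoelace area of a polygon given as an n x 2 matrix (absolute value).
polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3) stop("degenerate polygon: fewer than 3 vertices")
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  a <- abs(sum(x * yn - xn * y)) / 2
  if (a <= 0) stop("degenerate polygon: zero area")
  a
}

# First intersection of the ray origin + t * dir (t > 0) with the polygon
# boundary. Returns the intersection point, or NULL when the ray never
# crosses an edge (origin outside the polygon, or degenerate direction).
ray_polygon_first_hit <- function(origin, dir, poly) {
  n <- nrow(poly)
  p1 <- poly
  p2 <- poly[c(2:n, 1), , drop = FALSE]
  ex <- p2[, 1] - p1[, 1]
  ey <- p2[, 2] - p1[, 2]
  # Solve origin + t*dir = p1 + u*e for each edge
  denom <- dir[1] * (-ey) - dir[2] * (-ex)
  wx <- p1[, 1] - origin[1]
  wy <- p1[, 2] - origin[2]
  t <- (wx * (-ey) - wy * (-ex)) / denom
  u <- (dir[1] * wy - dir[2] * wx) / denom
  ok <- is.finite(t) & is.finite(u) & t > 1e-9 & u >= -1e-9 & u <= 1 + 1e-9
  if (!any(ok)) return(NULL)
  tmin <- min(t[ok])
  c(origin[1] + tmin * dir[1], origin[2] + tmin * dir[2])
}
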