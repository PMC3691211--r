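# Synthetic immunogold EM annotations: filaments with known lengths and
# gold particles placed by a Poisson process whose intensity may depend on
# filament length.

#' Single EM filament annotation
#'
#' @param filament_id identifier.
#' @param polyline_um n x 2 matrix of vertices in micrometers.
#' @param particle_positions m x 2 matrix of gold-particle coordinates
#'   (micrometers); may have zero rows.
#' @return An object of class `em_filament` with fields `filament_id`,
#'   `polyline_um`, `length_um` and `particle_positions`.
#' @export
em_filament <- function(filament_id, polyline_um,
                        particle_positions = matrix(numeric(0), 0, 2)) {
  polyline_um <- as.matrix(polyline_um)
  stopifnot(ncol(polyline_um) == 2, nrow(polyline_um) >= 2)
  particle_positions <- as.matrix(particle_positions)
  if (length(particle_positions) == 0) {
    particle_positions <- matrix(numeric(0), 0, 2)
  }
  stopifnot(ncol(particle_positions) == 2)
  len <- path_length(polyline_um)
  if (len <= 0) stop("EM filament must have positive length")
  structure(
    list(filament_id = filament_id, polyline_um = polyline_um,
         length_um = len, particle_positions = particle_positions),
    class = "em_filament"
  )
}

draw_lengths <- function(n, length_dist) {
  d <- length_dist$dist
  switch(d,
    uniform = stats::runif(n, length_dist$min, length_dist$max),
    lognormal = stats::rlnorm(n, length_dist$meanlog, length_dist$sdlog),
    exponential = stats::rexp(n, 1 / length_dist$mean),
    stop(sprintf("unknown length distribution '%s'", d))
  )
}

#' Generate synthetic immunogold EM filaments
#'
#' Each filament is a straight polyline with length drawn from
#' `length_dist`; gold particles are placed along it by a homogeneous
#' Poisson process with intensity `density_fn(length)` particles per
#' micrometer, offset perpendicularly by up to `capture_um` (antibody
#' reach).
#'
#' @param n number of filaments.
#' @param length_dist a list describing the length distribution: one of
#'   `list(dist = "uniform", min=, max=)`,
#'   `list(dist = "lognormal", meanlog=, sdlog=)`,
#'   `list(dist = "exponential", mean=)`.
#' @param density_fn function mapping length (um) to expected particles
#'   per micrometer.
#' @param capture_um maximal perpendicular particle offset.
#' @param seed integer seed.
#' @return A list of [em_filament()] objects.
#' @export
make_em_filaments <- function(n,
                              length_dist = list(dist = "lognormal",
                                                 meanlog = log(2), sdlog = 0.5),
                              density_fn = function(L) 3,
                              capture_um = 0.025, seed = 1L) {
  stopifnot(n >= 0)
  if (n == 0) return(list())
  with_seed(seed, {
    lens <- draw_lengths(n, length_dist)
    lapply(seq_len(n), function(i) {
      L <- lens[i]
      th <- stats::runif(1, 0, 2 * pi)
      origin <- stats::runif(2, 0, 50)
      u <- c(cos(th), sin(th))
      v <- c(-sin(th), cos(th))
      poly <- rbind(origin, origin + L * u)
      k <- stats::rpois(1, max(density_fn(L), 0) * L)
      if (k > 0) {
        s <- stats::runif(k, 0, L)
        off <- stats::runif(k, -capture_um, capture_um)
        pts <- cbind(origin[1] + s * u[1] + off * v[1],
                     origin[2] + s * u[2] + off * v[2])
      } else {
        pts <- matrix(numeric(0), 0, 2)
      }
      em_filament(i, poly, pts)
    })
  })
}
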