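# Synthetic filament image generator.
#
# Renders sets of straight filaments as 1-pixel-wide anti-aliased lines of
# unit amplitude, convolves with a Gaussian point-spread function and adds
# background and noise. The diffraction-limited appearance of a single
# microtubule (width well below the PSF) is emulated by the unit-amplitude
# line + blur combination. Ground truth (every polyline, its physical
# length, its acetylation flag) is returned alongside the image so that
# downstream counting, length and de novo calls can be scored exactly.

# Distance-based anti-aliased rendering of one segment onto a canvas.
# Intensity profile across the line: 1 within 0.5 px of the centerline,
# falling linearly to 0 at 1.5 px. Overlapping filaments combine by max
# (fluorophore density on a single structure, not additive across the
# blur-free centerline).
render_segment <- function(canvas, x0, y0, x1, y1) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  xmin <- max(0L, floor(min(x0, x1)) - 2L); xmax <- min(nc - 1L, ceiling(max(x0, x1)) + 2L)
  ymin <- max(0L, floor(min(y0, y1)) - 2L); ymax <- min(nr - 1L, ceiling(max(y0, y1)) + 2L)
  if (xmin > xmax || ymin > ymax) return(canvas)
  xs <- xmin:xmax; ys <- ymin:ymax
  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  dx <- x1 - x0; dy <- y1 - y0
  l2 <- dx^2 + dy^2
  if (l2 == 0) {
    d <- sqrt((px - x0)^2 + (py - y0)^2)
  } else {
    t <- clamp(((px - x0) * dx + (py - y0) * dy) / l2, 0, 1)
    d <- sqrt((px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2)
  }
  val <- clamp(1.5 - d, 0, 1)
  idx <- cbind(py + 1L, px + 1L)
  canvas[idx] <- pmax(canvas[idx], val)
  canvas
}

render_segments <- function(dim_hw, segments) {
  canvas <- matrix(0, dim_hw[1], dim_hw[2])
  for (seg in segments) {
    for (i in seq_len(nrow(seg) - 1)) {
      canvas <- render_segment(canvas, seg[i, 1], seg[i, 2],
                               seg[i + 1, 1], seg[i + 1, 2])
    }
  }
  canvas
}

apply_noise <- function(m, noise_model, noise_param) {
  if (noise_model == "none" || noise_param <= 0) return(m)
  if (noise_model == "gaussian") {
    m <- m + matrix(stats::rnorm(length(m), sd = noise_param), nrow(m))
  } else if (noise_model == "poisson") {
    m <- matrix(stats::rpois(length(m), lambda = pmax(m, 0) * noise_param),
                nrow(m)) / noise_param
  }
  pmax(m, 0)
}

# Minimum distance between two segments, approximated by dense point
# sampling (adequate for the rejection-sampling overlap test).
segment_min_dist <- function(a, b) {
  pts <- function(s) {
    L <- max(1, ceiling(sqrt(sum((s[2, ] - s[1, ])^2))))
    t <- seq(0, 1, length.out = L + 1)
    cbind(s[1, 1] + t * (s[2, 1] - s[1, 1]), s[1, 2] + t * (s[2, 2] - s[1, 2]))
  }
  pa <- pts(a); pb <- pts(b)
  min(sqrt(outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2))
}

#' Generate a synthetic filament image with ground truth
#'
#' Draws `n_filaments` straight filaments either radiating from a
#' centrosome point (`layout = "aster"`) or scattered with uniform random
#' midpoints and orientations (`layout = "dispersed"`), renders them as
#' unit-amplitude anti-aliased lines, applies PSF blur, background and
#' noise per `spec`, and returns the image together with the exact ground
#' truth. A fraction of filaments can be flagged acetylated; those are
#' additionally rendered into a second channel, emulating an
#' acetyl-tubulin co-staining.
#'
#' @param spec an [image_spec()].
#' @param n_filaments number of filaments (>= 0).
#' @param length_range_um length-2 vector; lengths are drawn uniformly
#'   from this interval (micrometers).
#' @param layout `"dispersed"` or `"aster"`.
#' @param acetyl_fraction fraction of filaments flagged acetylated
#'   (rounded to a count; the first `round(n * f)` drawn filaments carry
#'   the flag).
#' @param centrosome_px aster origin `c(x, y)`; defaults to the image
#'   center for `layout = "aster"`.
#' @param min_separation_px when > 0, filaments are placed by rejection
#'   sampling so that every pair of centerlines is at least this far
#'   apart; after 10,000 failed attempts placement aborts with error
#'   "no placement area".
#' @param margin_px placement margin kept free around the image border.
#' @return A list with `image` (a [cell_image()], with `channel2` when any
#'   filament is acetylated) and `truth` (class `filament_ground_truth`:
#'   `segments` list of 2 x 2 polyline matrices in pixel coordinates,
#'   `lengths_um`, `is_acetylated`, `centrosome_px`).
#' @export
make_filament_image <- function(spec, n_filaments,
                                length_range_um = c(2, 6),
                                layout = c("dispersed", "aster"),
                                acetyl_fraction = 0,
                                centrosome_px = NULL,
                                min_separation_px = 0,
                                margin_px = 4) {
  stopifnot(inherits(spec, "image_spec"))
  layout <- match.arg(layout)
  if (n_filaments < 0) stop("`n_filaments` must be >= 0")
  stopifnot(length(length_range_um) == 2, all(length_range_um > 0),
            length_range_um[2] >= length_range_um[1])
  w <- spec$width_px; h <- spec$height_px
  if (layout == "aster" && is.null(centrosome_px)) {
    centrosome_px <- c((w - 1) / 2, (h - 1) / 2)
  }
  if (layout == "aster") {
    if (centrosome_px[1] < 0 || centrosome_px[1] > w - 1 ||
        centrosome_px[2] < 0 || centrosome_px[2] > h - 1) {
      stop("aster layout requires a centrosome point inside the image")
    }
  }

  out <- with_seed(spec$seed, {
    segments <- vector("list", n_filaments)
    if (n_filaments > 0) {
      len_px <- stats::runif(n_filaments, length_range_um[1], length_range_um[2]) /
        spec$pixel_size_um
      lo <- margin_px; hix <- w - 1 - margin_px; hiy <- h - 1 - margin_px
      if (hix <= lo || hiy <= lo) stop("no placement area")
      attempts <- 0L
      for (i in seq_len(n_filaments)) {
        repeat {
          attempts <- attempts + 1L
          if (attempts > 10000L) stop("no placement area")
          if (layout == "aster") {
            th <- stats::runif(1, 0, 2 * pi)
            r0 <- 2
            p0 <- centrosome_px + r0 * c(cos(th), sin(th))
            p1 <- centrosome_px + (r0 + len_px[i]) * c(cos(th), sin(th))
          } else {
            th <- stats::runif(1, 0, 2 * pi)
            mid <- c(stats::runif(1, lo, hix), stats::runif(1, lo, hiy))
            half <- len_px[i] / 2 * c(cos(th), sin(th))
            p0 <- mid - half
            p1 <- mid + half
          }
          inside <- all(c(p0, p1) >= lo - 1e-9) &&
            p0[1] <= hix && p1[1] <= hix && p0[2] <= hiy && p1[2] <= hiy
          if (!inside) next
          seg <- rbind(p0, p1)
          if (min_separation_px > 0 && i > 1) {
            dmin <- min(vapply(segments[seq_len(i - 1)], segment_min_dist,
                               numeric(1), b = seg))
            if (dmin < min_separation_px) next
          }
          segments[[i]] <- seg
          break
        }
      }
    }
    is_acetyl <- rep(FALSE, n_filaments)
    if (n_filaments > 0 && acetyl_fraction > 0) {
      is_acetyl[seq_len(round(acetyl_fraction * n_filaments))] <- TRUE
    }

    main <- render_segments(c(h, w), segments)
    main <- blur_image(main, spec$psf_sigma_px) + spec$background_level
    main <- apply_noise(main, spec$noise_model, spec$noise_param)
    ch2 <- NULL
    if (any(is_acetyl)) {
      ch2 <- render_segments(c(h, w), segments[is_acetyl])
      ch2 <- blur_image(ch2, spec$psf_sigma_px) + spec$background_level
      ch2 <- apply_noise(ch2, spec$noise_model, spec$noise_param)
    }
    list(main = main, ch2 = ch2, segments = segments, is_acetyl = is_acetyl)
  })

  lengths_um <- vapply(out$segments, function(s) {
    path_length(s) * spec$pixel_size_um
  }, numeric(1))
  truth <- structure(
    list(segments = out$segments, lengths_um = lengths_um,
         is_acetylated = out$is_acetyl,
         centrosome_px = if (layout == "aster") centrosome_px else NULL),
    class = "filament_ground_truth"
  )
  list(image = cell_image(out$main, spec$pixel_size_um, channel2 = out$ch2),
       truth = truth)
}
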