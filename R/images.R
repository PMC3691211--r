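#' Cell image container
#'
#' A 2D grayscale fluorescence image with physical pixel size and an
#' optional second channel (e.g. acetyl-tubulin co-staining). Pixels are
#' stored as a numeric matrix indexed `[row, col]` = `[y + 1, x + 1]` with
#' 0-based pixel-center coordinates: pixel `(x, y)` has its center at
#' `(x, y)` and column `x + 1`, row `y + 1` in the matrix.
#'
#' @param pixels numeric matrix of intensities (rows = y, columns = x).
#' @param pixel_size_um physical size of one pixel in micrometers.
#' @param channel2 optional second-channel matrix of identical dimensions.
#' @return An object of class `cell_image`.
#' @export
cell_image <- function(pixels, pixel_size_um, channel2 = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix")
  }
  check_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  if (!is.null(channel2)) {
    if (!is.matrix(channel2) || !all(dim(channel2) == dim(pixels))) {
      stop("`channel2` must be a matrix with the same dimensions as `pixels`")
    }
  }
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um, channel2 = channel2),
    class = "cell_image"
  )
}

#' @export
print.cell_image <- function(x, ...) {
  cat(sprintf(
    "<cell_image> %d x %d px, %.4g um/px, %s channel(s), range [%.4g, %.4g]\n",
    ncol(x$pixels), nrow(x$pixels), x$pixel_size_um,
    if (is.null(x$channel2)) "1" else "2",
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' @export
dim.cell_image <- function(x) dim(x$pixels)

#' Synthetic image rendering parameters
#'
#' Describes the raster onto which synthetic filaments are rendered:
#' dimensions, physical pixel size, point-spread-function blur, background
#' offset and a noise model. Defaults follow a typical confocal nucleation
#' field: 1024 x 1024 pixels at 0.1 um/pixel.
#'
#' @param width_px,height_px image dimensions in pixels (>= 32).
#' @param pixel_size_um pixel size in micrometers.
#' @param psf_sigma_px standard deviation of the Gaussian point-spread
#'   function, in pixels; 0 disables blurring.
#' @param background_level constant background intensity added before noise.
#' @param noise_model one of `"none"`, `"gaussian"` (additive, sd =
#'   `noise_param`) or `"poisson"` (`noise_param` = photons per intensity
#'   unit; shot noise scales as the square root of the signal).
#' @param noise_param noise magnitude, see `noise_model`.
#' @param seed integer seed for the noise (and any stochastic placement).
#' @return An object of class `image_spec`.
#' @export
image_spec <- function(width_px = 1024, height_px = 1024, pixel_size_um = 0.1,
                       psf_sigma_px = 1.5, background_level = 0,
                       noise_model = c("none", "gaussian", "poisson"),
                       noise_param = 0, seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (width_px < 32 || height_px < 32) {
    stop("image dimensions must be at least 32 x 32 pixels")
  }
  check_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  check_scalar(psf_sigma_px, "psf_sigma_px", nonneg = TRUE)
  check_scalar(background_level, "background_level", nonneg = TRUE)
  check_scalar(noise_param, "noise_param", nonneg = TRUE)
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         pixel_size_um = pixel_size_um, psf_sigma_px = psf_sigma_px,
         background_level = background_level, noise_model = noise_model,
         noise_param = noise_param, seed = as.integer(seed)),
    class = "image_spec"
  )
}

# Gaussian blur with replicate padding (avoids wrap-around of structures
# near the border that circular convolution would introduce). The FFT
# leaves noise-floor residues (~1e-16) across the whole frame; these are
# truncated to exact zero so that empty background stays empty -- ratio
# statistics rely on zero meaning zero.
blur_image <- function(m, sigma) {
  if (sigma <= 0) return(m)
  pad <- max(4L, ceiling(4 * sigma))
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rep(1L, pad), seq_len(nr), rep(nr, pad))
  ci <- c(rep(1L, pad), seq_len(nc), rep(nc, pad))
  padded <- m[ri, ci]
  out <- EBImage::gblur(padded, sigma = sigma)
  out <- out[pad + seq_len(nr), pad + seq_len(nc)]
  floor_val <- 1e-9 * max(abs(out))
  out[abs(out) < floor_val] <- 0
  out
}

# Bilinear interpolation of image values at continuous (x, y) positions,
# 0-based pixel-center convention. Out-of-bounds positions are clamped to
# the border pixel.
bilinear_sample <- function(pixels, x, y) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  x <- clamp(x, 0, nc - 1)
  y <- clamp(y, 0, nr - 1)
  x0 <- clamp(floor(x), 0, nc - 1); x1 <- pmin(x0 + 1, nc - 1)
  y0 <- clamp(floor(y), 0, nr - 1); y1 <- pmin(y0 + 1, nr - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- pixels[cbind(y0 + 1, x0 + 1)]
  i10 <- pixels[cbind(y0 + 1, x1 + 1)]
  i01 <- pixels[cbind(y1 + 1, x0 + 1)]
  i11 <- pixels[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i10) + fy * ((1 - fx) * i01 + fx * i11)
}
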