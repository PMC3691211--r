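# Filament segmentation and counting: Hessian ridge enhancement,
# topological thinning to 1-px skeletons, 8-connected object labelling
# with sqrt(2)-weighted path lengths, de novo calling against an
# acetyl-tubulin channel, and aster-area measurement.

#' Hessian ridge (tubularity) enhancement
#'
#' Smooths the image with a Gaussian of `scale_px` and computes, per
#' pixel, the eigenvalues of the intensity Hessian. Bright curvilinear
#' structures have a strongly negative eigenvalue across the ridge; the
#' response is the scale-normalised magnitude of the most negative
#' eigenvalue, clipped at zero. Flat regions respond with 0 and blob-like
#' regions (e.g. the dense centrosome core) respond weaker than lines of
#' equal peak intensity, which is what makes the filter useful as a
#' pre-processing step before skeletonization.
#'
#' @param image a [cell_image()].
#' @param scale_px Gaussian scale in pixels (>= 0.5); match it to the PSF
#'   width for single microtubules.
#' @return A [cell_image()] holding the non-negative ridge response.
#' @export
enhance_tubular <- function(image, scale_px = 1.5) {
  stopifnot(inherits(image, "cell_image"))
  if (scale_px < 0.5) stop("`scale_px` must be >= 0.5")
  m <- blur_image(image$pixels, scale_px)
  nr <- nrow(m); nc <- ncol(m)
  # replicate-padded central differences
  up    <- m[c(1, 1:(nr - 1)), ]
  down  <- m[c(2:nr, nr), ]
  left  <- m[, c(1, 1:(nc - 1))]
  right <- m[, c(2:nc, nc)]
  ul <- m[c(1, 1:(nr - 1)), c(1, 1:(nc - 1))]
  ur <- m[c(1, 1:(nr - 1)), c(2:nc, nc)]
  dl <- m[c(2:nr, nr), c(1, 1:(nc - 1))]
  dr <- m[c(2:nr, nr), c(2:nc, nc)]
  hyy <- up + down - 2 * m
  hxx <- left + right - 2 * m
  hxy <- (dr + ul - ur - dl) / 4
  tr2 <- (hxx + hyy) / 2
  disc <- sqrt(((hxx - hyy) / 2)^2 + hxy^2)
  lam_low <- tr2 - disc # more negative eigenvalue
  resp <- pmax(-lam_low, 0) * scale_px^2
  # the FFT smoothing step leaves ~1e-15 relative residue even on flat
  # images; curvature that small is numerically zero
  resp[resp < 1e-10 * max(abs(m))] <- 0
  cell_image(resp, image$pixel_size_um)
}

# Zhang-Suen thinning of a logical mask to a 1-px-wide 8-connected
# skeleton; vectorised over the whole image per sub-iteration.
thin_binary <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- as.integer(mask)
  nr <- nrow(m); nc <- ncol(m)
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p  <- m[ri, ci]
      p2 <- m[ri - 1, ci];     p3 <- m[ri - 1, ci + 1]
      p4 <- m[ri, ci + 1];     p5 <- m[ri + 1, ci + 1]
      p6 <- m[ri + 1, ci];     p7 <- m[ri + 1, ci - 1]
      p8 <- m[ri, ci - 1];     p9 <- m[ri - 1, ci - 1]
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) +
           (p4 == 0 & p5 == 1) + (p5 == 0 & p6 == 1) +
           (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (sub == 1) {
        cond <- p == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- p == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        changed <- TRUE
        inner <- m[ri, ci]
        inner[cond] <- 0L
        m[ri, ci] <- inner
      }
    }
    if (!changed) break
  }
  m[ri, ci] == 1L
}

# 8-connected component labelling of a logical mask via the pixel
# adjacency graph. Returns an integer matrix of labels (0 = background).
label_components8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0) return(lab)
  id <- matrix(0L, nrow(mask), ncol(mask))
  id[idx] <- seq_along(idx)
  nr <- nrow(mask); nc <- ncol(mask)
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  edges <- list()
  neigh <- function(dr, dc) {
    ok <- row + dr >= 1 & row + dr <= nr & col + dc >= 1 & col + dc <= nc
    j <- idx[ok] + dr + dc * nr
    keep <- id[j] > 0L
    cbind(id[idx[ok]][keep], id[j][keep])
  }
  edges <- rbind(neigh(0L, 1L), neigh(1L, 0L), neigh(1L, 1L), neigh(-1L, 1L))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- comp[seq_along(idx)]
  lab
}

# Path length of one skeleton component in pixels: orthogonal steps count
# 1, diagonal steps sqrt(2); a diagonal step is not counted when its two
# pixels already share an orthogonal neighbour inside the component
# (corner-cut rule). Isolated single pixels get length 1 (their footprint).
skeleton_length_px <- function(mask_idx, nr, nc, member) {
  pts <- mask_idx
  inset <- logical(nr * nc)
  inset[pts] <- TRUE
  row <- ((pts - 1L) %% nr) + 1L
  col <- ((pts - 1L) %/% nr) + 1L
  pair_count <- function(dr, dc) {
    ok <- row + dr >= 1 & row + dr <= nr & col + dc >= 1 & col + dc <= nc
    j <- pts[ok] + dr + dc * nr
    sum(inset[j])
  }
  n_ortho <- pair_count(0L, 1L) + pair_count(1L, 0L)
  diag_count <- function(dr, dc) {
    ok <- row + dr >= 1 & row + dr <= nr & col + dc >= 1 & col + dc <= nc
    i <- pts[ok]
    j <- i + dr + dc * nr
    present <- inset[j]
    # common orthogonal neighbours of (i, j): (i + dr rows) and (i + dc cols)
    c1 <- i + dr
    c2 <- i + dc * nr
    shortcut <- inset[c1] | inset[c2]
    sum(present & !shortcut)
  }
  n_diag <- diag_count(1L, 1L) + diag_count(-1L, 1L)
  len <- n_ortho + sqrt(2) * n_diag
  if (len == 0) len <- 1
  len
}

#' Skeletonize a ridge-enhanced image and count filament objects
#'
#' Binarizes the enhanced image, thins the foreground to 1-pixel-wide
#' skeletons, labels 8-connected components and measures each component's
#' path length (orthogonal steps 1 pixel, diagonal steps sqrt(2), times
#' the pixel size). Components longer than `size_max_um` are removed --
#' the explicit stand-in for the per-image threshold used to drop
#' overlapping microtubules erroneously merged into one object -- and
#' components shorter than `size_min_um` are discarded as specks.
#'
#' @param enhanced a [cell_image()], typically the output of
#'   [enhance_tubular()].
#' @param binarize_threshold intensity threshold; `NULL` (default) uses
#'   Otsu's method on the enhanced image.
#' @param size_min_um,size_max_um lower / upper path-length bounds (um)
#'   for keeping an object.
#' @return An object of class `filament_set`: `objects` (data.frame with
#'   `id`, `n_pixels`, `path_length_um`, `mean_intensity`, bounding box),
#'   `pixel_map` (label matrix), `pixel_size_um`, `threshold`,
#'   `size_min_um`, `size_max_um`.
#' @export
skeletonize_and_count <- function(enhanced, binarize_threshold = NULL,
                                  size_min_um = 0, size_max_um = Inf) {
  stopifnot(inherits(enhanced, "cell_image"))
  m <- enhanced$pixels
  if (is.null(binarize_threshold)) {
    rng <- range(m)
    binarize_threshold <- if (diff(rng) <= 0) {
      rng[2] + 1 # constant image: no foreground
    } else {
      EBImage::otsu((m - rng[1]) / diff(rng), range = c(0, 1)) *
        diff(rng) + rng[1]
    }
  }
  mask <- m > binarize_threshold
  objects <- data.frame(id = integer(0), n_pixels = integer(0),
                        path_length_um = numeric(0),
                        mean_intensity = numeric(0),
                        xmin = integer(0), xmax = integer(0),
                        ymin = integer(0), ymax = integer(0))
  lab <- matrix(0L, nrow(m), ncol(m))
  if (any(mask)) {
    skel <- thin_binary(mask)
    lab <- label_components8(skel)
    nlab <- max(lab)
    if (nlab > 0) {
      nr <- nrow(lab); nc <- ncol(lab)
      keep_rows <- vector("list", nlab)
      for (k in seq_len(nlab)) {
        pts <- which(lab == k)
        row <- ((pts - 1L) %% nr) + 1L
        col <- ((pts - 1L) %/% nr) + 1L
        len_um <- skeleton_length_px(pts, nr, nc, k) * enhanced$pixel_size_um
        keep_rows[[k]] <- data.frame(
          id = k, n_pixels = length(pts), path_length_um = len_um,
          mean_intensity = mean(m[pts]),
          xmin = min(col) - 1L, xmax = max(col) - 1L,
          ymin = min(row) - 1L, ymax = max(row) - 1L)
      }
      objects <- do.call(rbind, keep_rows)
      drop <- objects$path_length_um < size_min_um |
        objects$path_length_um > size_max_um
      if (any(drop)) {
        lab[lab %in% objects$id[drop]] <- 0L
        objects <- objects[!drop, , drop = FALSE]
        rownames(objects) <- NULL
      }
    }
  }
  structure(
    list(objects = objects, pixel_map = lab,
         pixel_size_um = enhanced$pixel_size_um,
         threshold = binarize_threshold,
         size_min_um = size_min_um, size_max_um = size_max_um),
    class = "filament_set"
  )
}

#' @export
print.filament_set <- function(x, ...) {
  cat(sprintf("<filament_set> %d objects, total length %.2f um (threshold %.4g)\n",
              nrow(x$objects), sum(x$objects$path_length_um), x$threshold))
  invisible(x)
}

#' De novo calling configuration
#'
#' @param acetyl_threshold acetyl-channel intensity above which a pixel
#'   counts as acetylated.
#' @param overlap_dilation_px dilation (in pixels) applied to each
#'   skeleton before probing the acetyl channel; absorbs small
#'   channel-registration offsets.
#' @return An object of class `de_novo_config`.
#' @export
de_novo_config <- function(acetyl_threshold, overlap_dilation_px = 1L) {
  check_scalar(acetyl_threshold, "acetyl_threshold", nonneg = TRUE)
  check_scalar(overlap_dilation_px, "overlap_dilation_px", nonneg = TRUE)
  structure(list(acetyl_threshold = acetyl_threshold,
                 overlap_dilation_px = as.integer(overlap_dilation_px)),
            class = "de_novo_config")
}

#' Call de novo (non-acetylated) microtubules
#'
#' An object counts as truly de novo only when no pixel of its (dilated)
#' skeleton shows acetyl-channel intensity above the threshold -- any sign
#' of acetylation disqualifies it, since acetylation marks pre-existing
#' polymer that survived depolymerization.
#'
#' @param filaments a [skeletonize_and_count()] result.
#' @param acetyl_channel a [cell_image()] of the acetyl-tubulin staining,
#'   registered to and sized like the filament image.
#' @param config a [de_novo_config()].
#' @return A list with `n_de_novo` and `de_novo` (named logical per
#'   object, in `filaments$objects$id` order).
#' @export
call_de_novo <- function(filaments, acetyl_channel, config) {
  stopifnot(inherits(filaments, "filament_set"),
            inherits(acetyl_channel, "cell_image"),
            inherits(config, "de_novo_config"))
  if (!all(dim(filaments$pixel_map) == dim(acetyl_channel$pixels))) {
    stop("dimension mismatch between filament map and acetyl channel")
  }
  ids <- filaments$objects$id
  if (length(ids) == 0) {
    return(list(n_de_novo = 0L, de_novo = logical(0)))
  }
  r <- config$overlap_dilation_px
  nr <- nrow(filaments$pixel_map); nc <- ncol(filaments$pixel_map)
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  de_novo <- vapply(ids, function(k) {
    pts <- which(filaments$pixel_map == k)
    row <- ((pts - 1L) %% nr) + 1L
    col <- ((pts - 1L) %/% nr) + 1L
    for (o in seq_len(nrow(offs))) {
      rr <- clamp(row + offs$dr[o], 1, nr)
      cc <- clamp(col + offs$dc[o], 1, nc)
      if (any(acetyl_channel$pixels[cbind(rr, cc)] > config$acetyl_threshold)) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  names(de_novo) <- ids
  list(n_de_novo = sum(de_novo), de_novo = de_novo)
}

#' Aster area
#'
#' `mode = "roi"` reproduces the manual measurement: the area of a
#' hand-drawn polygon around the aster, in square micrometers.
#' `mode = "seeded"` is an automation convenience beyond the manual
#' protocol: it thresholds a window around a seed point with Otsu's
#' method and returns the area of the 8-connected above-threshold region
#' containing the seed.
#'
#' @param image a [cell_image()].
#' @param roi polygon (n x 2 matrix, pixels) for `mode = "roi"`.
#' @param seed_px seed point `c(x, y)` for `mode = "seeded"`.
#' @param mode `"roi"` or `"seeded"`.
#' @param window_px half-size of the local Otsu window around the seed;
#'   `NULL` uses the whole image.
#' @return Area in square micrometers.
#' @export
aster_area <- function(image, roi = NULL, seed_px = NULL,
                       mode = c("roi", "seeded"), window_px = NULL) {
  stopifnot(inherits(image, "cell_image"))
  mode <- match.arg(mode)
  if (mode == "roi") {
    if (is.null(roi)) stop("`roi` polygon required for mode = \"roi\"")
    return(polygon_area(as.matrix(roi)) * image$pixel_size_um^2)
  }
  if (is.null(seed_px)) stop("`seed_px` required for mode = \"seeded\"")
  m <- image$pixels
  nr <- nrow(m); nc <- ncol(m)
  sx <- round(seed_px[1]) + 1L; sy <- round(seed_px[2]) + 1L
  if (sx < 1 || sx > nc || sy < 1 || sy > nr) stop("seed outside image")
  if (is.null(window_px)) {
    win <- m
    oy <- ox <- 0L
  } else {
    r0 <- max(1L, sy - window_px); r1 <- min(nr, sy + window_px)
    c0 <- max(1L, sx - window_px); c1 <- min(nc, sx + window_px)
    win <- m[r0:r1, c0:c1]
    oy <- r0 - 1L; ox <- c0 - 1L
  }
  rng <- range(win)
  if (diff(rng) <= 0) return(0) # flat window: nothing to segment
  thr <- EBImage::otsu((win - rng[1]) / diff(rng), range = c(0, 1)) *
    diff(rng) + rng[1]
  mask <- win > thr
  if (!mask[sy - oy, sx - ox]) return(0)
  lab <- label_components8(mask)
  sum(lab == lab[sy - oy, sx - ox]) * image$pixel_size_um^2
}
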