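# In vitro nucleation-field quantification and immunogold density
# analysis, including the Spearman rank correlation of particle density
# against microtubule length.

#' Quantify one nucleation-assay field
#'
#' Binarizes the field at a fixed minimum intensity, labels 8-connected
#' particles, discards components smaller than `min_area_px` and returns
#' the particle count and sizes.
#'
#' @param image a [cell_image()].
#' @param min_intensity fixed minimum intensity threshold (pixels strictly
#'   above it are foreground).
#' @param min_area_px minimal component area in pixels (default 4,
#'   suppressing single-pixel noise).
#' @param field_id identifier carried into the result.
#' @return An object of class `field_result`: `field_id`, `n_particles`,
#'   `particle_sizes_um2`.
#' @export
quantify_field <- function(image, min_intensity, min_area_px = 4L,
                           field_id = 1L) {
  stopifnot(inherits(image, "cell_image"))
  mask <- image$pixels > min_intensity
  sizes <- numeric(0)
  if (any(mask)) {
    lab <- label_components8(mask)
    npix <- tabulate(lab[lab > 0])
    npix <- npix[npix >= min_area_px]
    sizes <- npix * image$pixel_size_um^2
  }
  structure(list(field_id = field_id, n_particles = length(sizes),
                 particle_sizes_um2 = sizes),
            class = "field_result")
}

#' Aggregate nucleation fields into a per-condition summary
#'
#' Mean and SEM of the particle count per field and of the particle size
#' pooled over fields. A warning is raised when fewer than `min_fields`
#' fields are supplied (the assay convention is at least 25 random fields
#' per condition). With a single field the SEM is undefined and returned
#' as `NA`.
#'
#' @param results list of [quantify_field()] results.
#' @param min_fields minimal expected number of fields.
#' @return A list with `n_fields`, `mean_count`, `sem_count`,
#'   `mean_size_um2`, `sem_size_um2`.
#' @export
aggregate_fields <- function(results, min_fields = 25L) {
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, logical(1), "field_result")))
  if (length(results) < min_fields) {
    warning(sprintf("only %d fields aggregated (expected at least %d)",
                    length(results), min_fields))
  }
  counts <- vapply(results, `[[`, numeric(1), "n_particles")
  sizes <- unlist(lapply(results, `[[`, "particle_sizes_um2"))
  sem <- function(x) {
    if (length(x) < 2) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  }
  list(n_fields = length(results),
       mean_count = mean(counts), sem_count = sem(counts),
       mean_size_um2 = if (length(sizes)) mean(sizes) else NA_real_,
       sem_size_um2 = sem(sizes))
}

#' Gold-particle density of one EM filament
#'
#' @param filament an [em_filament()].
#' @return Particles per micrometer of filament length.
#' @export
particle_density <- function(filament) {
  stopifnot(inherits(filament, "em_filament"))
  if (filament$length_um <= 0) stop("zero-length filament")
  nrow(filament$particle_positions) / filament$length_um
}

#' Spearman rank correlation with permutation p-value
#'
#' Average ranks are assigned to ties; the correlation is the Pearson
#' correlation of the rank vectors. For `n <= exact_n_max` the two-sided
#' p-value is taken from the exact permutation distribution of the
#' statistic (all `n!` orderings); for larger `n` the t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2` degrees of freedom
#' is used.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param exact_n_max largest n for which the exact permutation
#'   distribution is enumerated.
#' @return A list with `rho`, `p_value`, `n` and `method`; `rho` is `NA`
#'   (flagged by `method = "undefined"`) when either input is constant.
#' @export
spearman_rank_test <- function(x, y, exact_n_max = 10L) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "undefined"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_n_max) {
    perms <- permutations_of(n)
    # Pearson on ranks is linear in sum(rx * ry[perm]); enumerate it
    sx <- sum(rx); sxx <- sum(rx^2)
    sy <- sum(ry); syy <- sum(ry^2)
    denom <- sqrt((sxx - sx^2 / n) * (syy - sy^2 / n))
    cross <- as.vector(matrix(ry[perms], nrow(perms)) %*% rx)
    rho_all <- (cross - sx * sy / n) / denom
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

# All permutations of 1..n as an (n!) x n integer matrix, built
# iteratively by insertion.
permutations_of <- function(n) {
  out <- matrix(1L, 1, 1)
  for (k in 2:n) {
    blocks <- vector("list", k)
    for (pos in 1:k) {
      left <- if (pos > 1) out[, 1:(pos - 1), drop = FALSE] else NULL
      right <- if (pos <= k - 1) out[, pos:(k - 1), drop = FALSE] else NULL
      blocks[[pos]] <- cbind(left, matrix(k, nrow(out), 1), right)
    }
    out <- do.call(rbind, blocks)
  }
  out
}

#' Correlation of gold-particle density with microtubule length
#'
#' Computes each filament's bound-particle density ([particle_density()])
#' and its Spearman rank correlation with filament length
#' ([spearman_rank_test()]). A negative correlation indicates denser
#' decoration of shorter (younger) microtubules.
#'
#' @param filaments list of [em_filament()] objects (>= 3).
#' @return A list with `rho`, `p_value`, `n`, `method` and the per-filament
#'   `table` (data.frame `filament_id`, `length_um`, `n_particles`,
#'   `density_per_um`).
#' @export
density_length_correlation <- function(filaments) {
  stopifnot(length(filaments) >= 3,
            all(vapply(filaments, inherits, logical(1), "em_filament")))
  tab <- data.frame(
    filament_id = vapply(filaments, function(f) as.integer(f$filament_id),
                         integer(1)),
    length_um = vapply(filaments, `[[`, numeric(1), "length_um"),
    n_particles = vapply(filaments, function(f) nrow(f$particle_positions),
                         integer(1)))
  tab$density_per_um <- tab$n_particles / tab$length_um
  res <- spearman_rank_test(tab$density_per_um, tab$length_um)
  c(res, list(table = tab))
}
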