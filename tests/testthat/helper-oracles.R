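# Independent oracles and fixture builders shared across tests. These
# deliberately avoid the package's own code paths wherever they serve as a
# reference: ranks and correlations are computed from first principles.

# Average-rank assignment written from the definition (sort-based), not via
# base rank(), so the Spearman oracle is independent of the implementation.
oracle_ranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(x < x[i])
    eq <- sum(x == x[i])
    r[i] <- less + (eq + 1) / 2
  }
  r
}

# Pearson-on-ranks from explicit sums.
oracle_spearman_rho <- function(x, y) {
  rx <- oracle_ranks(x); ry <- oracle_ranks(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# Exact two-sided permutation p-value by explicit enumeration (recursive,
# small n only).
oracle_spearman_p <- function(x, y) {
  rho_obs <- oracle_spearman_rho(x, y)
  n <- length(y)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  all_p <- perms(seq_len(n))
  rhos <- vapply(all_p, function(p) oracle_spearman_rho(x, y[p]), numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# Stationary distribution of the three-phase switching process (growth,
# shrinkage, two pause sub-states split by the transition they interrupt),
# solved numerically from the generator matrix.
oracle_stationary <- function(k_cat, k_res, p_pause, q_pause) {
  Q <- matrix(0, 4, 4) # states: G, S, P->G, P->S
  Q[1, 2] <- k_cat * (1 - p_pause); Q[1, 4] <- k_cat * p_pause
  Q[2, 1] <- k_res * (1 - p_pause); Q[2, 3] <- k_res * p_pause
  Q[3, 1] <- q_pause; Q[4, 2] <- q_pause
  diag(Q) <- -rowSums(Q)
  pi_s <- qr.solve(rbind(t(Q), rep(1, 4)), c(0, 0, 0, 0, 1))
  c(growth = pi_s[1], shrink = pi_s[2], pause = pi_s[3] + pi_s[4])
}

# Circular geometry centred on an image of side `side`.
centered_circle <- function(side, radius_px, n_vertices = 64L) {
  circle_geometry(c((side - 1) / 2, (side - 1) / 2), radius_px, n_vertices)
}

# Analytic radial image I(x, y) = f(distance to center), evaluated at pixel
# centers.
radial_image <- function(side, center, f, pixel_size_um = 0.1) {
  xs <- 0:(side - 1)
  d <- sqrt(outer((xs - center[2])^2, (xs - center[1])^2, "+"))
  cell_image(matrix(f(d), side, side), pixel_size_um)
}

# Deterministic synthetic nucleation field: n disjoint square spots of the
# given intensity on a dark background.
spot_field <- function(n, side = 200, spot_px = 3, intensity = 1,
                       pixel_size_um = 0.1) {
  m <- matrix(0, side, side)
  per_row <- floor((side - 10) / 12)
  stopifnot(n <= per_row^2)
  for (i in seq_len(n)) {
    r <- 6 + 12 * ((i - 1) %/% per_row)
    c <- 6 + 12 * ((i - 1) %% per_row)
    m[r:(r + spot_px - 1), c:(c + spot_px - 1)] <- intensity
  }
  cell_image(m, pixel_size_um)
}

# A track with prescribed signed x-steps (um) starting at the origin.
steps_track <- function(steps_um, frame_interval_s = 3, pixel_size_um = 0.1,
                        id = 1L) {
  x_um <- cumsum(c(0, steps_um))
  track(id, frame = seq_along(x_um) - 1L, x_px = x_um / pixel_size_um,
        y_px = rep(0, length(x_um)), frame_interval_s = frame_interval_s,
        pixel_size_um = pixel_size_um)
}
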