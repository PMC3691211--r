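test_that("generators are deterministic given the seed", {
  spec <- image_spec(96, 96, psf_sigma_px = 1, noise_model = "gaussian",
                     noise_param = 0.05, seed = 21)
  g1 <- make_filament_image(spec, 12, c(1, 3), acetyl_fraction = 0.5)
  g2 <- make_filament_image(spec, 12, c(1, 3), acetyl_fraction = 0.5)
  expect_identical(g1$image$pixels, g2$image$pixels)
  expect_identical(g1$image$channel2, g2$image$channel2)
  expect_identical(g1$truth$segments, g2$truth$segments)

  p <- dynamics_params(n_frames = 50, seed = 5)
  expect_identical(simulate_di_track(p)$samples, simulate_di_track(p)$samples)

  geo <- centered_circle(400, 190)
  s1 <- simulate_comets(3, 3, c(199.5, 199.5), geo, seed = 9)
  s2 <- simulate_comets(3, 3, c(199.5, 199.5), geo, seed = 9)
  expect_identical(lapply(s1$tracks, `[[`, "samples"),
                   lapply(s2$tracks, `[[`, "samples"))

  e1 <- make_em_filaments(20, seed = 13)
  e2 <- make_em_filaments(20, seed = 13)
  expect_identical(e1, e2)
})

test_that("zero filaments yield a blank background image and empty truth", {
  spec <- image_spec(64, 64, psf_sigma_px = 2, background_level = 0.2)
  g <- make_filament_image(spec, 0)
  expect_true(all(g$image$pixels == 0.2))
  expect_length(g$truth$segments, 0)
  expect_length(g$truth$lengths_um, 0)
})

test_that("ground-truth lengths match polyline path lengths and the image covers them", {
  spec <- image_spec(128, 128, psf_sigma_px = 0, seed = 31)
  g <- make_filament_image(spec, 15, c(1.5, 4))
  for (i in seq_along(g$truth$segments)) {
    seg <- g$truth$segments[[i]]
    plen <- sum(sqrt(rowSums(diff(seg)^2))) * spec$pixel_size_um
    expect_equal(g$truth$lengths_um[i], plen, tolerance = 1e-6)
    # noise-free, blur-free rendering is bright on the polyline itself
    t <- seq(0, 1, length.out = 50)
    xs <- round(seg[1, 1] + t * (seg[2, 1] - seg[1, 1]))
    ys <- round(seg[1, 2] + t * (seg[2, 2] - seg[1, 2]))
    expect_true(all(g$image$pixels[cbind(ys + 1, xs + 1)] > 0))
  }
})

test_that("impossible placement regions abort with a clear error", {
  spec <- image_spec(64, 64)
  expect_error(make_filament_image(spec, 5, c(1, 2), margin_px = 40),
               "no placement area")
  # dense non-overlap demand that cannot be satisfied
  expect_error(
    make_filament_image(image_spec(48, 48), 400, c(3, 3),
                        min_separation_px = 6),
    "no placement area")
})

test_that("acetylated filaments appear in the second channel only", {
  spec <- image_spec(128, 128, psf_sigma_px = 1, seed = 17)
  g <- make_filament_image(spec, 10, c(1, 3), acetyl_fraction = 0.4)
  expect_equal(sum(g$truth$is_acetylated), 4)
  expect_false(is.null(g$image$channel2))
  # channel 2 foreground is a subset of channel 1 foreground
  expect_true(all(g$image$pixels[g$image$channel2 > 1e-6] > 1e-6))
  expect_lt(sum(g$image$channel2 > 1e-6), sum(g$image$pixels > 1e-6))
})

test_that("degenerate rate settings produce the expected deterministic tracks", {
  # no catastrophes: strictly monotone growth
  p <- dynamics_params(k_catastrophe_per_min = 0, k_rescue_per_min = 0,
                       jitter_sd_um = 0, n_frames = 30, seed = 2)
  tr <- simulate_di_track(p)
  expect_true(all(diff(tr$samples$x_px) > 0))
  expect_true(all(attr(tr, "truth")$interval_states == "growth"))

  # static tip: jitter-only displacements stay below the 0.3 um threshold
  p0 <- dynamics_params(v_growth_um_min = 0, v_shrink_um_min = 0,
                        jitter_sd_um = 0.05, n_frames = 60, seed = 3)
  seg <- segment_phases(simulate_di_track(p0), direction_ref = "+x")
  expect_true(all(seg$labels == "pause"))
  s <- summarize_dynamics(list(seg))
  expect_equal(s$pct_pause, 100)
})

test_that("simulated event counts recover the catastrophe rate (generator oracle)", {
  # oracle: true transition count / true growth time from the event history
  n_cat <- 0; t_growth <- 0
  for (i in 1:200) {
    p <- dynamics_params(k_catastrophe_per_min = 2, k_rescue_per_min = 2,
                         n_frames = 201, seed = 700 + i)
    truth <- attr(simulate_di_track(p), "truth")
    n_cat <- n_cat + truth$n_catastrophes
    t_growth <- t_growth + truth$time_in_min[["growth"]]
  }
  k_hat <- n_cat / t_growth
  se <- sqrt(n_cat) / t_growth
  expect_lt(abs(k_hat - 2), 3 * se)
})

test_that("phase occupancy converges to the stationary distribution", {
  an <- oracle_stationary(2, 2, 0.3, 1)
  fr <- matrix(0, 120, 3)
  for (i in 1:120) {
    p <- dynamics_params(k_catastrophe_per_min = 2, k_rescue_per_min = 2,
                         p_pause = 0.3, n_frames = 401, seed = 9000 + i)
    tr <- simulate_di_track(p, start_state = if (i %% 2) "growth" else "shrink")
    ph <- attr(tr, "truth")$phases
    # discard a 5 min burn-in: tracks never start in pause
    ov <- pmax(pmin(ph$t1_min, 20) - pmax(ph$t0_min, 5), 0)
    tt <- tapply(ov, factor(ph$state, c("growth", "shrink", "pause")), sum)
    tt[is.na(tt)] <- 0
    fr[i, ] <- tt / sum(tt)
  }
  emp <- colMeans(fr)
  se <- apply(fr, 2, stats::sd) / sqrt(nrow(fr))
  expect_true(all(abs(emp - an) < 3 * se))
})

test_that("comet generator respects counts, zones and the boundary", {
  geo <- centered_circle(400, 190)
  ctr <- c(199.5, 199.5)
  expect_identical(simulate_comets(0, 0, ctr, geo)$tracks, list())

  s <- simulate_comets(6, 6, ctr, geo, exclusion_radius_um = 6, seed = 4)
  expect_length(s$tracks, 12)
  expect_equal(s$origin, rep(c("centrosomal", "non_centrosomal"), each = 6))
  for (i in seq_along(s$tracks)) {
    sm <- s$tracks[[i]]$samples
    expect_true(all(point_in_polygon(sm$x_px, sm$y_px, geo$boundary_px)))
    d0 <- sqrt(sum((c(sm$x_px[1], sm$y_px[1]) - ctr)^2)) * 0.1
    if (s$origin[i] == "centrosomal") expect_lt(d0, 0.7) else expect_gt(d0, 5.8)
  }
})

test_that("EM filament generator honours the density function", {
  # zero density: no particles anywhere
  e0 <- make_em_filaments(25, density_fn = function(L) 0, seed = 6)
  expect_true(all(vapply(e0, function(f) nrow(f$particle_positions), integer(1)) == 0))

  # constructed arithmetic case: 4 particles on 2 um
  f <- em_filament(1, rbind(c(0, 0), c(2, 0)),
                   cbind(c(0.2, 0.8, 1.1, 1.9), 0))
  expect_equal(f$length_um, 2)
  expect_equal(particle_density(f), 2)

  # inverse-length density: strongly negative rank correlation
  e <- make_em_filaments(200,
                         length_dist = list(dist = "uniform", min = 0.5, max = 6),
                         density_fn = function(L) 6 / L, seed = 7)
  res <- density_length_correlation(e)
  expect_lt(res$rho, -0.5)
  expect_lt(res$p_value, 0.01)
})
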