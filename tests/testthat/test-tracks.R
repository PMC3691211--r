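test_that("the static threshold separates pause from directed motion", {
  # 0.2 um per frame: below the 0.3 um threshold, all pause
  seg <- segment_phases(steps_track(rep(0.2, 10)), direction_ref = "+x")
  expect_true(all(seg$labels == "pause"))

  # 0.5 um per frame outward at 3 s/frame: all growth at 10 um/min
  seg2 <- segment_phases(steps_track(rep(0.5, 8)), direction_ref = "+x")
  expect_true(all(seg2$labels == "growth"))
  expect_true(all(abs(seg2$speeds_um_min - 10) < 1e-9))

  # the same motion towards the reference point is shrinkage
  tr <- steps_track(rep(0.5, 8))
  seg3 <- segment_phases(tr, direction_ref = c(1e6, 0))
  expect_true(all(seg3$labels == "shrink"))

  expect_error(segment_phases(steps_track(rep(0.5, 4))), "direction_ref")
})

test_that("a hand-counted label sequence yields the expected frequencies", {
  # steps: G, G, S, S, G at 3 s intervals
  tr <- steps_track(c(0.6, 0.6, -0.8, -0.8, 0.6))
  seg <- segment_phases(tr, direction_ref = "+x")
  expect_equal(seg$labels, c("growth", "growth", "shrink", "shrink", "growth"))
  s <- summarize_dynamics(list(seg))
  expect_equal(s$n_catastrophes, 1)
  expect_equal(s$n_rescues, 1)
  # 1 catastrophe over 9 s of growth = 6.67 per min; 1 rescue over 6 s
  expect_equal(s$catastrophe_freq_per_min, 1 / 0.15, tolerance = 1e-9)
  expect_equal(s$rescue_freq_per_min, 1 / 0.10, tolerance = 1e-9)
  expect_equal(s$pct_growth + s$pct_shrink + s$pct_pause, 100)
  expect_equal(s$mean_growth_speed_um_min, 12)
  expect_equal(s$mean_shrink_speed_um_min, 16)
})

test_that("phase percentages always sum to exactly 100", {
  for (seed in 1:5) {
    p <- dynamics_params(p_pause = 0.3, n_frames = 101, seed = seed)
    seg <- segment_phases(simulate_di_track(p), direction_ref = "+x")
    s <- summarize_dynamics(list(seg))
    expect_equal(s$pct_growth + s$pct_shrink + s$pct_pause, 100,
                 tolerance = 1e-12)
  }
})

test_that("an all-pause track flags frequencies rather than inventing them", {
  seg <- segment_phases(steps_track(rep(0.1, 10)), direction_ref = "+x")
  s <- summarize_dynamics(list(seg))
  expect_equal(s$pct_pause, 100)
  # with the pause-inclusive denominator, zero events over positive time
  expect_equal(s$catastrophe_freq_per_min, 0)
  # with the phase-only denominator there is no at-risk time at all
  s2 <- summarize_dynamics(list(seg), at_risk = "phase_only")
  expect_true(is.na(s2$catastrophe_freq_per_min))
  expect_true(is.na(s2$rescue_freq_per_min))
})

test_that("phase labels reproduce simulated truth when steps clear the threshold", {
  # v * dt = 0.75 / 1.0 um per frame, both >= 0.6 um; slow switching keeps
  # transition frames (the only ambiguous ones) rare
  tot <- 0; match <- 0
  for (i in 1:50) {
    p <- dynamics_params(k_catastrophe_per_min = 0.25, k_rescue_per_min = 0.25,
                         n_frames = 201, seed = 4000 + i)
    tr <- simulate_di_track(p)
    seg <- segment_phases(tr, direction_ref = "+x")
    truth <- attr(tr, "truth")$interval_states
    tot <- tot + length(truth)
    match <- match + sum(seg$labels == truth)
  }
  expect_gte(match / tot, 0.99)
})

test_that("transition counts satisfy the bookkeeping identity", {
  # catastrophes - rescues must match the start/end state difference up to
  # the number of pause interludes
  for (i in 1:20) {
    p <- dynamics_params(p_pause = 0.25, n_frames = 151, seed = 880 + i)
    seg <- segment_phases(simulate_di_track(p), direction_ref = "+x")
    lab <- seg$labels
    tc <- mtquant:::count_transitions(lab)
    n_pause_runs <- sum(rle(lab)$values == "pause")
    lhs <- tc[["cat"]] - tc[["res"]]
    rhs <- (lab[length(lab)] == "shrink") - (lab[1] == "shrink")
    expect_lte(abs(lhs - rhs), n_pause_runs + 1)
  }
})

test_that("gapped tracks are rejected and split correctly", {
  tr <- track(1, frame = c(0, 1, 2, 5, 6, 7), x_px = 1:6, y_px = rep(0, 6),
              frame_interval_s = 3, pixel_size_um = 0.1)
  expect_error(segment_phases(tr, direction_ref = "+x"), "gap")
  parts <- split_track_at_gaps(tr)
  expect_length(parts, 2)
  expect_equal(parts[[1]]$samples$frame, 0:2)
  expect_equal(parts[[2]]$samples$frame, 5:7)
})

test_that("comet origin classification enforces the frame and zone rules", {
  ctr <- c(100, 100)
  # three frames only: excluded no matter where it starts
  t3 <- track(1, 0:2, c(100, 105, 110), rep(100, 3), 3, 0.1)
  expect_equal(classify_comet_origin(t3, ctr)$origin, "excluded")

  # starts on the centrosome moving outward: centrosomal
  t_c <- track(2, 0:5, 100 + 0:5 * 7, rep(100, 6), 3, 0.1)
  expect_equal(classify_comet_origin(t_c, ctr)$origin, "centrosomal")

  # starts near the centrosome but moves towards it: ambiguous
  t_in <- track(3, 0:5, 110 - 0:5 * 7, rep(100, 6), 3, 0.1)
  expect_equal(classify_comet_origin(t_in, ctr)$origin, "excluded")

  # starts far away: non-centrosomal
  t_f <- track(4, 0:5, 200 + 0:5 * 7, rep(100, 6), 3, 0.1)
  expect_equal(classify_comet_origin(t_f, ctr)$origin, "non_centrosomal")

  # starts inside the ambiguity annulus (2..4 um = 20..40 px): excluded
  t_a <- track(5, 0:5, 130 + 0:5 * 7, rep(100, 6), 3, 0.1)
  expect_equal(classify_comet_origin(t_a, ctr)$origin, "excluded")
})

test_that("labelled comets are classified perfectly with 3x zone separation", {
  geo <- centered_circle(400, 190)
  ctr <- c(199.5, 199.5)
  s <- simulate_comets(10, 10, ctr, geo, exclusion_radius_um = 6, seed = 77)
  calls <- vapply(s$tracks, function(tr) {
    classify_comet_origin(tr, ctr, centrosomal_radius_um = 2)$origin
  }, character(1))
  expect_identical(calls, s$origin)
})

test_that("origin calls are invariant under rigid motions", {
  geo <- centered_circle(400, 190)
  ctr <- c(199.5, 199.5)
  s <- simulate_comets(4, 4, ctr, geo, exclusion_radius_um = 6, seed = 15)
  th <- 0.83; shift <- c(31, -12)
  rot <- function(x, y) {
    cbind(cos(th) * x - sin(th) * y + shift[1],
          sin(th) * x + cos(th) * y + shift[2])
  }
  ctr_r <- as.vector(rot(ctr[1], ctr[2]))
  for (tr in s$tracks) {
    a <- classify_comet_origin(tr, ctr)
    xy <- rot(tr$samples$x_px, tr$samples$y_px)
    tr_r <- track(tr$track_id, tr$samples$frame, xy[, 1], xy[, 2],
                  tr$frame_interval_s, tr$pixel_size_um)
    b <- classify_comet_origin(tr_r, ctr_r)
    expect_identical(a$origin, b$origin)
    expect_equal(a$start_distance_um, b$start_distance_um, tolerance = 1e-9)
  }
})

test_that("time zero is the first fluorescence burst", {
  # flat trace: no burst
  flat <- detect_time_zero(rep(50, 20))
  expect_false(flat$detected)
  expect_true(is.na(flat$frame))

  # step to 10x baseline at frame 7
  y <- c(rep(10, 7), rep(100, 13))
  expect_equal(detect_time_zero(y)$frame, 7)

  # noisy ramp from a known onset: detected within one frame, 100 seeds
  ok <- 0L
  for (s in 1:100) {
    set.seed(s)
    f0 <- sample(8:25, 1)
    fr <- 0:39
    y <- 100 + pmax(0, fr - f0 + 1) * 100 + stats::rnorm(40, 0, 2)
    d <- detect_time_zero(data.frame(frame = fr, intensity = y))
    ok <- ok + (d$detected && abs(d$frame - f0) <= 1)
  }
  expect_equal(ok, 100L)
})

test_that("estimated switching rates recover simulation truth (spot check)", {
  segs <- vector("list", 200)
  for (i in 1:200) {
    p <- dynamics_params(k_catastrophe_per_min = 2, k_rescue_per_min = 2,
                         n_frames = 201, seed = 52000 + i)
    segs[[i]] <- segment_phases(simulate_di_track(p), direction_ref = "+x")
  }
  s <- summarize_dynamics(segs, discretization_correction = TRUE)
  t_gp <- s$total_time_min * (s$pct_growth + s$pct_pause) / 100
  t_sp <- s$total_time_min * (s$pct_shrink + s$pct_pause) / 100
  expect_lt(abs(s$catastrophe_freq_per_min - 2), 3 * sqrt(s$n_catastrophes) / t_gp)
  expect_lt(abs(s$rescue_freq_per_min - 2), 3 * sqrt(s$n_rescues) / t_sp)
  # speeds are recovered too
  expect_equal(s$mean_growth_speed_um_min, 15, tolerance = 0.1)
  expect_equal(s$mean_shrink_speed_um_min, 20, tolerance = 0.1)
})
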