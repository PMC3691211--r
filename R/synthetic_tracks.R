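# Simulators for microtubule tip tracks.
#
# Dynamic instability is modelled as a three-state continuous-time process:
# growth (tip advances at v_growth), shrinkage (tip retreats at v_shrink)
# and pause (stationary). Catastrophes (growth -> shrinkage) occur at rate
# k_catastrophe, rescues (shrinkage -> growth) at rate k_rescue. At each
# transition event the tip enters a pause with probability p_pause and
# completes the interrupted transition after an exponential dwell; with
# p_pause = 0 the model reduces to the classical two-state switch. The
# simulator records the full continuous-time event history, so estimators
# operating on the discretely sampled, jittered positions can be scored
# against exact truth.

#' Dynamic-instability simulation parameters
#'
#' @param v_growth_um_min,v_shrink_um_min growth and shrinkage speeds
#'   (micrometers per minute).
#' @param k_catastrophe_per_min,k_rescue_per_min transition rates out of
#'   growth and shrinkage (events per minute).
#' @param p_pause probability that a transition event is interrupted by a
#'   pause before completing.
#' @param pause_exit_rate_per_min exponential rate of leaving a pause.
#' @param frame_interval_s sampling interval of the recorded track.
#' @param n_frames number of recorded frames (>= 4).
#' @param jitter_sd_um isotropic Gaussian localisation error added to each
#'   recorded position. The default (0.05 um) is well below the 0.3
#'   um/frame static threshold, so jitter alone never turns a moving frame
#'   into a pause call.
#' @param pixel_size_um pixel size used to express positions in pixels.
#' @param seed integer seed.
#' @return An object of class `dynamics_params`.
#' @export
dynamics_params <- function(v_growth_um_min = 15, v_shrink_um_min = 20,
                            k_catastrophe_per_min = 2, k_rescue_per_min = 2,
                            p_pause = 0, pause_exit_rate_per_min = 1,
                            frame_interval_s = 3, n_frames = 40L,
                            jitter_sd_um = 0.05, pixel_size_um = 0.1,
                            seed = 1L) {
  check_scalar(v_growth_um_min, "v_growth_um_min", nonneg = TRUE)
  check_scalar(v_shrink_um_min, "v_shrink_um_min", nonneg = TRUE)
  check_scalar(k_catastrophe_per_min, "k_catastrophe_per_min", nonneg = TRUE)
  check_scalar(k_rescue_per_min, "k_rescue_per_min", nonneg = TRUE)
  check_scalar(p_pause, "p_pause", nonneg = TRUE)
  if (p_pause > 1) stop("`p_pause` must lie in [0, 1]")
  check_scalar(pause_exit_rate_per_min, "pause_exit_rate_per_min", positive = TRUE)
  check_scalar(frame_interval_s, "frame_interval_s", positive = TRUE)
  if (n_frames < 4) stop("`n_frames` must be >= 4")
  check_scalar(jitter_sd_um, "jitter_sd_um", nonneg = TRUE)
  check_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  structure(
    list(v_growth_um_min = v_growth_um_min, v_shrink_um_min = v_shrink_um_min,
         k_catastrophe_per_min = k_catastrophe_per_min,
         k_rescue_per_min = k_rescue_per_min, p_pause = p_pause,
         pause_exit_rate_per_min = pause_exit_rate_per_min,
         frame_interval_s = frame_interval_s, n_frames = as.integer(n_frames),
         jitter_sd_um = jitter_sd_um, pixel_size_um = pixel_size_um,
         seed = as.integer(seed)),
    class = "dynamics_params"
  )
}

rexp_or_inf <- function(rate) if (rate > 0) stats::rexp(1, rate) else Inf

#' Simulate one dynamic-instability tip track
#'
#' Simulates the three-state process of [dynamics_params()] in continuous
#' time, samples the tip position (motion along +x) every frame, and adds
#' isotropic Gaussian localisation jitter. The returned [track()] carries a
#' `truth` attribute with the exact event history: `phases` (data.frame of
#' `t0_min`, `t1_min`, `state`), `interval_states` (the state occupying the
#' majority of each inter-frame interval), continuous-time
#' `n_catastrophes` / `n_rescues` (transitions into shrinkage from
#' growth-or-pause, and into growth from shrinkage-or-pause) and
#' `time_in_min` per phase.
#'
#' @param params a [dynamics_params()].
#' @param track_id identifier stored on the track.
#' @param start_state initial state, `"growth"` or `"shrink"`.
#' @param start_um starting `(x, y)` position in micrometers.
#' @return A [track()] with attribute `truth`.
#' @export
simulate_di_track <- function(params, track_id = 1L,
                              start_state = c("growth", "shrink"),
                              start_um = c(0, 0)) {
  stopifnot(inherits(params, "dynamics_params"))
  start_state <- match.arg(start_state)
  dt_min <- params$frame_interval_s / 60
  t_end <- (params$n_frames - 1) * dt_min

  sim <- with_seed(params$seed, {
    t <- 0; state <- start_state; heading <- NA_character_
    t0 <- numeric(0); t1 <- numeric(0); st <- character(0)
    n_cat <- 0L; n_res <- 0L
    while (t < t_end) {
      dwell <- switch(state,
        growth = rexp_or_inf(params$k_catastrophe_per_min),
        shrink = rexp_or_inf(params$k_rescue_per_min),
        pause  = rexp_or_inf(params$pause_exit_rate_per_min))
      tn <- min(t + dwell, t_end)
      t0 <- c(t0, t); t1 <- c(t1, tn); st <- c(st, state)
      if (tn >= t_end) break
      if (state == "growth") {
        if (params$p_pause > 0 && stats::runif(1) < params$p_pause) {
          state <- "pause"; heading <- "shrink"
        } else {
          state <- "shrink"; n_cat <- n_cat + 1L
        }
      } else if (state == "shrink") {
        if (params$p_pause > 0 && stats::runif(1) < params$p_pause) {
          state <- "pause"; heading <- "growth"
        } else {
          state <- "growth"; n_res <- n_res + 1L
        }
      } else { # pause completes the interrupted transition
        state <- heading
        if (state == "shrink") n_cat <- n_cat + 1L else n_res <- n_res + 1L
        heading <- NA_character_
      }
      t <- tn
    }
    phases <- data.frame(t0_min = t0, t1_min = t1, state = st)
    jit <- matrix(stats::rnorm(2L * params$n_frames, sd = params$jitter_sd_um),
                  ncol = 2)
    list(phases = phases, n_cat = n_cat, n_res = n_res, jitter = jit)
  })
  phases <- sim$phases

  vel <- c(growth = params$v_growth_um_min,
           shrink = -params$v_shrink_um_min, pause = 0)
  seg_v <- vel[phases$state]
  seg_dx <- seg_v * (phases$t1_min - phases$t0_min)
  x_at_t1 <- cumsum(seg_dx)
  x_at_t0 <- x_at_t1 - seg_dx

  frame_t <- (seq_len(params$n_frames) - 1) * dt_min
  seg_idx <- findInterval(frame_t, phases$t0_min, rightmost.closed = FALSE)
  seg_idx <- clamp(seg_idx, 1, nrow(phases))
  x_um <- start_um[1] + x_at_t0[seg_idx] +
    seg_v[seg_idx] * (frame_t - phases$t0_min[seg_idx])

  # majority state per inter-frame interval
  occupancy <- function(a, b) {
    ov <- pmin(phases$t1_min, b) - pmax(phases$t0_min, a)
    ov <- pmax(ov, 0)
    tapply(ov, phases$state, sum)
  }
  interval_states <- vapply(seq_len(params$n_frames - 1), function(i) {
    occ <- occupancy(frame_t[i], frame_t[i + 1])
    names(occ)[which.max(occ)]
  }, character(1))

  time_in <- tapply(phases$t1_min - phases$t0_min, phases$state, sum)
  time_in_min <- c(growth = 0, shrink = 0, pause = 0)
  time_in_min[names(time_in)] <- time_in

  x_px <- (x_um + sim$jitter[, 1]) / params$pixel_size_um
  y_px <- (start_um[2] + sim$jitter[, 2]) / params$pixel_size_um
  tr <- track(track_id, frame = seq_len(params$n_frames) - 1L,
              x_px = x_px, y_px = y_px,
              frame_interval_s = params$frame_interval_s,
              pixel_size_um = params$pixel_size_um)
  attr(tr, "truth") <- list(
    phases = phases, interval_states = interval_states,
    n_catastrophes = sim$n_cat, n_rescues = sim$n_res,
    time_in_min = time_in_min)
  tr
}

#' Simulate labelled EB1 comet tracks
#'
#' Generates plus-end comet tracks with known origin: centrosomal comets
#' start within `start_radius_um` of the centrosome and move radially
#' outward; non-centrosomal comets start at uniform positions inside the
#' cell at least `exclusion_radius_um` from the centrosome and move in a
#' uniform random direction. All tracks remain inside the boundary
#' polygon (directions without enough clearance are resampled).
#'
#' @param n_centrosomal,n_noncentrosomal numbers of tracks of each origin.
#' @param centrosome_px centrosome position `c(x, y)` in pixels.
#' @param geometry a [cell_geometry()] containing the centrosome.
#' @param speed_um_min comet speed.
#' @param frame_interval_s,n_frames sampling of each track.
#' @param pixel_size_um pixel size.
#' @param start_radius_um maximal start distance of centrosomal comets
#'   from the centrosome.
#' @param exclusion_radius_um minimal start distance of non-centrosomal
#'   comets from the centrosome.
#' @param jitter_sd_um localisation jitter.
#' @param seed integer seed.
#' @return A list with `tracks` (list of [track()]) and `origin`
#'   (character vector `"centrosomal"` / `"non_centrosomal"`).
#' @export
simulate_comets <- function(n_centrosomal, n_noncentrosomal, centrosome_px,
                            geometry, speed_um_min = 15,
                            frame_interval_s = 3, n_frames = 8L,
                            pixel_size_um = 0.1, start_radius_um = 0.5,
                            exclusion_radius_um = 6, jitter_sd_um = 0.02,
                            seed = 1L) {
  stopifnot(n_centrosomal >= 0, n_noncentrosomal >= 0,
            inherits(geometry, "cell_geometry"))
  if (!point_in_polygon(centrosome_px[1], centrosome_px[2],
                        geometry$boundary_px)) {
    stop("centrosome must lie inside the boundary polygon")
  }
  n_total <- n_centrosomal + n_noncentrosomal
  if (n_total == 0) return(list(tracks = list(), origin = character(0)))
  step_px <- speed_um_min * (frame_interval_s / 60) / pixel_size_um
  run_px <- (n_frames - 1) * step_px
  poly <- geometry$boundary_px
  bbox <- apply(poly, 2, range)

  tracks <- with_seed(seed, {
    out <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      centro <- i <= n_centrosomal
      attempts <- 0L
      repeat {
        attempts <- attempts + 1L
        if (attempts > 10000L) stop("no placement area for comet tracks")
        if (centro) {
          th <- stats::runif(1, 0, 2 * pi)
          r <- stats::runif(1, 0, start_radius_um / pixel_size_um)
          p0 <- centrosome_px + r * c(cos(th), sin(th))
          dir <- p0 - centrosome_px
          if (sqrt(sum(dir^2)) < 1e-9) dir <- c(cos(th), sin(th))
          dir <- dir / sqrt(sum(dir^2))
        } else {
          p0 <- c(stats::runif(1, bbox[1, 1], bbox[2, 1]),
                  stats::runif(1, bbox[1, 2], bbox[2, 2]))
          if (!point_in_polygon(p0[1], p0[2], poly)) next
          if (sqrt(sum((p0 - centrosome_px)^2)) <
              exclusion_radius_um / pixel_size_um) next
          th <- stats::runif(1, 0, 2 * pi)
          dir <- c(cos(th), sin(th))
        }
        hit <- ray_polygon_first_hit(p0, dir, poly)
        if (is.null(hit)) next
        if (sqrt(sum((hit - p0)^2)) < run_px + 2) next
        break
      }
      tpos <- outer(step_px * (seq_len(n_frames) - 1), dir) +
        matrix(p0, n_frames, 2, byrow = TRUE)
      tpos <- tpos + matrix(stats::rnorm(2L * n_frames,
                                         sd = jitter_sd_um / pixel_size_um),
                            ncol = 2)
      out[[i]] <- track(i, frame = seq_len(n_frames) - 1L,
                        x_px = tpos[, 1], y_px = tpos[, 2],
                        frame_interval_s = frame_interval_s,
                        pixel_size_um = pixel_size_um)
    }
    out
  })
  origin <- c(rep("centrosomal", n_centrosomal),
              rep("non_centrosomal", n_noncentrosomal))
  list(tracks = tracks, origin = origin)
}
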