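#' Microtubule tip / EB1 comet track
#'
#' An ordered sequence of (frame, x, y) samples with the acquisition frame
#' interval and pixel size. Frames must be strictly increasing with no
#' duplicates and at least two samples.
#'
#' @param track_id identifier.
#' @param frame integer frame indices.
#' @param x_px,y_px positions in pixels (0-based pixel centers).
#' @param frame_interval_s time between consecutive frames, seconds.
#' @param pixel_size_um pixel size, micrometers.
#' @return An object of class `track` with a `samples` data.frame.
#' @export
track <- function(track_id, frame, x_px, y_px, frame_interval_s,
                  pixel_size_um) {
  frame <- as.integer(frame)
  stopifnot(length(frame) == length(x_px), length(frame) == length(y_px))
  if (length(frame) < 2) stop("a track needs at least 2 samples")
  if (anyDuplicated(frame)) stop("duplicate frames in track")
  o <- order(frame)
  check_scalar(frame_interval_s, "frame_interval_s", positive = TRUE)
  check_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  structure(
    list(track_id = track_id,
         samples = data.frame(frame = frame[o], x_px = as.numeric(x_px)[o],
                              y_px = as.numeric(y_px)[o]),
         frame_interval_s = frame_interval_s, pixel_size_um = pixel_size_um),
    class = "track"
  )
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track %s> %d frames @ %gs, %.4g um/px\n",
              format(x$track_id), nrow(x$samples), x$frame_interval_s,
              x$pixel_size_um))
  invisible(x)
}

n_frames_of <- function(track) nrow(track$samples)

# Signed per-interval displacement (um). direction_ref is either a point
# c(x, y) in pixels -- growth is motion that increases the distance to the
# reference (a minus-end proxy) -- or one of "+x", "-x", "+y", "-y"
# selecting a signed image axis.
signed_displacements <- function(track, direction_ref) {
  s <- track$samples
  if (is.character(direction_ref)) {
    ax <- match.arg(direction_ref, c("+x", "-x", "+y", "-y"))
    v <- switch(ax, "+x" = s$x_px, "-x" = -s$x_px,
                "+y" = s$y_px, "-y" = -s$y_px)
    diff(v) * track$pixel_size_um
  } else {
    if (length(direction_ref) != 2 || any(!is.finite(direction_ref))) {
      stop("`direction_ref` must be a point c(x, y) or a signed axis like \"+x\"")
    }
    r <- sqrt((s$x_px - direction_ref[1])^2 + (s$y_px - direction_ref[2])^2)
    diff(r) * track$pixel_size_um
  }
}

#' Per-interval phase segmentation of a tip track
#'
#' Applies the static-threshold rule frame pair by frame pair: the
#' displacement between consecutive frames, signed by motion away from
#' `direction_ref`, classifies the interval as pause when its magnitude is
#' below `static_threshold_um` (the tip "moved less than 0.3 um per
#' frame"), as growth when at or above the threshold and directed away
#' from the reference, and as shrinkage when directed towards it.
#'
#' @param track a [track()]. Frames must be consecutive; a gap splits the
#'   rule's "per frame" meaning, so gapped tracks are rejected (split them
#'   with [split_track_at_gaps()] first).
#' @param static_threshold_um displacement below which an interval is
#'   static (default 0.3 um per frame).
#' @param direction_ref reference defining the growth direction: a point
#'   `c(x, y)` in pixels (minus-end proxy; growth increases distance to
#'   it) or a signed axis `"+x"`, `"-x"`, `"+y"`, `"-y"`.
#' @return An object of class `phase_segmentation`: `labels` (`"growth"`,
#'   `"shrink"`, `"pause"` per interval), `speeds_um_min` (unsigned
#'   per-interval speed), `signed_um` (signed per-interval displacement),
#'   `frame_interval_s`, `track_id`.
#' @export
segment_phases <- function(track, static_threshold_um = 0.3, direction_ref) {
  stopifnot(inherits(track, "track"))
  check_scalar(static_threshold_um, "static_threshold_um", positive = TRUE)
  if (missing(direction_ref)) {
    stop("`direction_ref` is required: the growth sign is undefined without it")
  }
  if (any(diff(track$samples$frame) != 1L)) {
    stop("track has frame gaps; split it with split_track_at_gaps() first")
  }
  d <- signed_displacements(track, direction_ref)
  labels <- ifelse(abs(d) < static_threshold_um, "pause",
                   ifelse(d > 0, "growth", "shrink"))
  structure(
    list(labels = labels, speeds_um_min = abs(d) / (track$frame_interval_s / 60),
         signed_um = d, frame_interval_s = track$frame_interval_s,
         static_threshold_um = static_threshold_um,
         track_id = track$track_id),
    class = "phase_segmentation"
  )
}

#' Split a gapped track into gap-free sub-tracks
#'
#' The static-threshold rule is a per-frame rule, so intervals spanning
#' skipped frames are not comparable; each maximal run of consecutive
#' frames becomes an independent track (runs shorter than 2 samples are
#' dropped).
#'
#' @param track a [track()].
#' @return A list of [track()] objects.
#' @export
split_track_at_gaps <- function(track) {
  s <- track$samples
  grp <- cumsum(c(1L, diff(s$frame) != 1L))
  out <- lapply(split(seq_len(nrow(s)), grp), function(i) {
    if (length(i) < 2) return(NULL)
    track(track$track_id, s$frame[i], s$x_px[i], s$y_px[i],
          track$frame_interval_s, track$pixel_size_um)
  })
  Filter(Negate(is.null), unname(out))
}

phase_time_min <- function(seg) {
  dt <- seg$frame_interval_s / 60
  tab <- c(growth = 0, shrink = 0, pause = 0)
  t <- table(seg$labels) * dt
  tab[names(t)] <- t
  tab
}

count_transitions <- function(labels) {
  if (length(labels) < 2) {
    return(c(cat = 0L, res = 0L))
  }
  a <- labels[-length(labels)]
  b <- labels[-1]
  c(cat = sum((a == "growth" | a == "pause") & b == "shrink"),
    res = sum((a == "shrink" | a == "pause") & b == "growth"))
}

# Discrete-sampling correction for rate estimates, derived from renewal
# arguments for the two-state switch observed at interval dt. An interval
# whose growth-time fraction f satisfies f > fG is labelled growth,
# f < fS shrinkage, and pause in between, where fS and fG are the
# fractions at which the interval's net displacement crosses -threshold
# and +threshold. A growth or shrinkage period of duration e, starting at
# a uniform offset inside a frame, fails to put any interval's occupancy
# fraction above a threshold s with probability
#   M(s, k) = P(e <= s) + E[(2s - e)+ / dt ; e > s],   e ~ Exp(k),
# which gives, per period:
#  * a catastrophe goes uncounted when its shrinkage period shows no
#    shrink-labelled interval or the preceding growth period is rendered
#    entirely shrink-labelled;
#  * a rescue goes uncounted when its growth period shows no
#    growth-labelled interval or the preceding shrinkage period is
#    rendered entirely growth-labelled;
#  * whole-interval labelling of each visible transition shifts at-risk
#    time by dt*(1/2 - fS) (growth+pause denominator) and dt*(fG - 1/2)
#    (shrinkage+pause denominator) per event, and invisible periods park
#    their whole duration in the opposite phase's denominator.
# The corrected rates solve a small fixed-point problem.
correct_rates <- function(n_cat, n_res, t_gp, t_sp, dt_min, v_g, v_s,
                          threshold_um) {
  if (!is.finite(v_g) || !is.finite(v_s) || v_g + v_s <= 0 ||
      t_gp <= 0 || t_sp <= 0) {
    return(c(cat = if (t_gp > 0) n_cat / t_gp else NA_real_,
             res = if (t_sp > 0) n_res / t_sp else NA_real_))
  }
  th <- threshold_um / dt_min # um/min units
  fS <- clamp((v_s - th) / (v_g + v_s), 0, 1)
  fG <- clamp((v_s + th) / (v_g + v_s), 0, 1)
  Mfun <- function(s, k) {
    if (s <= 0) return(0)
    if (k <= 0) return(0)
    (1 - exp(-k * s)) +
      ((1 / k) * exp(-2 * k * s) + s * exp(-k * s) - (1 / k) * exp(-k * s)) /
      dt_min
  }
  k_c <- n_cat / t_gp
  k_r <- n_res / t_sp
  for (it in 1:50) {
    MS_shr <- Mfun((1 - fS) * dt_min, k_r) # shrink period shows no S interval
    MS_gro <- Mfun(fS * dt_min, k_c)       # growth period rendered all-S
    MG_gro <- Mfun(fG * dt_min, k_c)       # growth period shows no G interval
    MG_shr <- Mfun((1 - fG) * dt_min, k_r) # shrink period rendered all-G
    nc <- n_cat / max((1 - MS_shr) * (1 - MS_gro), 0.25)
    nr <- n_res / max((1 - MG_gro) * (1 - MG_shr), 0.25)
    t_inv_shr <- nc * MG_shr * (1 - fG) * dt_min / 2 # shrink time hidden in G+P
    t_inv_gro <- nr * MS_gro * fS * dt_min / 2       # growth time hidden in S+P
    tc <- t_gp - dt_min * (0.5 - fS) * (n_cat + n_res) + t_inv_gro - t_inv_shr
    ts <- t_sp - dt_min * (fG - 0.5) * (n_cat + n_res) + t_inv_shr - t_inv_gro
    tc <- max(tc, t_gp / 2); ts <- max(ts, t_sp / 2)
    k_c_new <- nc / tc
    k_r_new <- nr / ts
    if (abs(k_c_new - k_c) + abs(k_r_new - k_r) < 1e-12) break
    k_c <- k_c_new; k_r <- k_r_new
  }
  c(cat = k_c, res = k_r)
}

#' Pool phase segmentations into dynamic-instability parameters
#'
#' Computes the Table-style life-history summary: percentage of time in
#' growth, shrinkage and pause; mean speed over growth and over shrinkage
#' intervals; catastrophe frequency = transitions from growth (or pause)
#' into shrinkage per minute of at-risk time, and rescue frequency =
#' transitions from shrinkage (or pause) into growth per minute of at-risk
#' time. With `at_risk = "with_pause"` (default) at-risk time is
#' growth + pause time for catastrophes and shrinkage + pause time for
#' rescues; `"phase_only"` uses the pure growth and shrinkage times.
#' Frequencies whose at-risk time is zero are returned as `NA` (flagged
#' undefined, not 0).
#'
#' @param segmentations a non-empty list of [segment_phases()] results.
#' @param at_risk denominator convention, see above.
#' @param discretization_correction when `TRUE`, apply a finite-sampling
#'   correction for excursions shorter than one frame interval and for
#'   whole-interval labelling of transition frames (see the methods
#'   vignette); intended for rate estimation from regularly sampled data.
#' @return An object of class `dynamics_summary` with fields `pct_growth`,
#'   `pct_shrink`, `pct_pause` (summing to 100), `mean_growth_speed_um_min`,
#'   `mean_shrink_speed_um_min`, `catastrophe_freq_per_min`,
#'   `rescue_freq_per_min`, `n_catastrophes`, `n_rescues`, `n_tracks`,
#'   `total_time_min`.
#' @export
summarize_dynamics <- function(segmentations,
                               at_risk = c("with_pause", "phase_only"),
                               discretization_correction = FALSE) {
  at_risk <- match.arg(at_risk)
  if (length(segmentations) == 0) stop("no segmentations supplied")
  stopifnot(all(vapply(segmentations, inherits, logical(1),
                       "phase_segmentation")))
  times <- Reduce(`+`, lapply(segmentations, phase_time_min))
  total <- sum(times)
  trans <- Reduce(`+`, lapply(segmentations, function(s) {
    count_transitions(s$labels)
  }))
  all_labels <- unlist(lapply(segmentations, `[[`, "labels"))
  all_speeds <- unlist(lapply(segmentations, `[[`, "speeds_um_min"))
  g_speeds <- all_speeds[all_labels == "growth"]
  s_speeds <- all_speeds[all_labels == "shrink"]

  t_gp <- times[["growth"]] + if (at_risk == "with_pause") times[["pause"]] else 0
  t_sp <- times[["shrink"]] + if (at_risk == "with_pause") times[["pause"]] else 0

  if (discretization_correction) {
    dt_min <- segmentations[[1]]$frame_interval_s / 60
    # medians are unbiased for the within-phase speed: pure-phase intervals
    # dominate and carry exactly v * dt
    k <- correct_rates(trans[["cat"]], trans[["res"]], t_gp, t_sp, dt_min,
                       stats::median(g_speeds), stats::median(s_speeds),
                       threshold_um = segmentations[[1]]$static_threshold_um)
    cat_freq <- if (t_gp > 0) k[["cat"]] else NA_real_
    res_freq <- if (t_sp > 0) k[["res"]] else NA_real_
  } else {
    cat_freq <- if (t_gp > 0) trans[["cat"]] / t_gp else NA_real_
    res_freq <- if (t_sp > 0) trans[["res"]] / t_sp else NA_real_
  }

  structure(
    list(pct_growth = 100 * times[["growth"]] / total,
         pct_shrink = 100 * times[["shrink"]] / total,
         pct_pause = 100 * times[["pause"]] / total,
         mean_growth_speed_um_min =
           if (length(g_speeds)) mean(g_speeds) else NA_real_,
         mean_shrink_speed_um_min =
           if (length(s_speeds)) mean(s_speeds) else NA_real_,
         catastrophe_freq_per_min = cat_freq,
         rescue_freq_per_min = res_freq,
         n_catastrophes = unname(trans[["cat"]]),
         n_rescues = unname(trans[["res"]]),
         n_tracks = length(segmentations), total_time_min = total),
    class = "dynamics_summary"
  )
}

#' @export
print.dynamics_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<dynamics_summary> %d tracks, %.1f min\n",
           "  growth %.1f%% @ %.2f um/min | shrink %.1f%% @ %.2f um/min | pause %.1f%%\n",
           "  catastrophe %.3f /min (n=%d) | rescue %.3f /min (n=%d)\n"),
    x$n_tracks, x$total_time_min, x$pct_growth, x$mean_growth_speed_um_min,
    x$pct_shrink, x$mean_shrink_speed_um_min, x$pct_pause,
    x$catastrophe_freq_per_min, x$n_catastrophes,
    x$rescue_freq_per_min, x$n_rescues))
  invisible(x)
}

#' Classify the origin of an EB1 comet track
#'
#' A comet qualifies only when followed for more than three frames
#' (`n_frames >= min_frames`, default 4); shorter tracks are excluded.
#' Qualifying comets are centrosomal when their first sample lies within
#' `centrosomal_radius_um` of the centrosome and the first step carries
#' the comet away from it (its distance to the centrosome does not
#' decrease -- a test that stays well-conditioned for comets born
#' essentially on the centrosome, where the angle between step and radius
#' is localisation noise); non-centrosomal when the first sample lies
#' beyond `centrosomal_radius_um * ambiguity_factor`. Starts inside the
#' intermediate annulus (or centrosome-proximal starts moving inward) are
#' ambiguous and excluded.
#'
#' @param track a [track()].
#' @param centrosome_px centrosome position `c(x, y)` in pixels.
#' @param centrosomal_radius_um radius of the centrosomal start zone.
#' @param min_frames minimal number of frames a comet must be followed.
#' @param ambiguity_factor multiple of `centrosomal_radius_um` beyond
#'   which a start is unambiguously non-centrosomal.
#' @return An object of class `origin_call`: `track_id`, `origin`
#'   (`"centrosomal"`, `"non_centrosomal"` or `"excluded"`),
#'   `start_distance_um`, `n_frames`.
#' @export
classify_comet_origin <- function(track, centrosome_px,
                                  centrosomal_radius_um = 2,
                                  min_frames = 4L, ambiguity_factor = 2) {
  stopifnot(inherits(track, "track"))
  check_scalar(centrosomal_radius_um, "centrosomal_radius_um", positive = TRUE)
  s <- track$samples
  d0 <- sqrt(sum((c(s$x_px[1], s$y_px[1]) - centrosome_px)^2)) *
    track$pixel_size_um
  res <- function(origin) {
    structure(list(track_id = track$track_id, origin = origin,
                   start_distance_um = d0, n_frames = nrow(s)),
              class = "origin_call")
  }
  if (nrow(s) < min_frames) return(res("excluded"))
  if (d0 <= centrosomal_radius_um) {
    d1 <- sqrt(sum((c(s$x_px[2], s$y_px[2]) - centrosome_px)^2)) *
      track$pixel_size_um
    if (d1 >= d0) return(res("centrosomal"))
    return(res("excluded"))
  }
  if (d0 >= centrosomal_radius_um * ambiguity_factor) {
    return(res("non_centrosomal"))
  }
  res("excluded")
}

#' @export
print.origin_call <- function(x, ...) {
  cat(sprintf("<origin_call %s> %s (start %.2f um, %d frames)\n",
              format(x$track_id), x$origin, x$start_distance_um, x$n_frames))
  invisible(x)
}

#' Detect the first fluorescence burst in an intensity trace
#'
#' Defines time zero of a washout movie as the first frame whose summed
#' fluorescence exceeds the baseline (median of the first
#' `baseline_frames` frames) by `n_sigma` times the baseline's robust
#' deviation (scaled MAD, floored at `rel_floor` of the baseline so that
#' an exactly flat baseline does not make the threshold degenerate).
#'
#' @param trace data.frame with columns `frame` and `intensity`, or a
#'   numeric vector (frames then taken as `0 .. n-1`). At least 5 frames.
#' @param baseline_frames number of leading frames defining the baseline.
#' @param n_sigma detection threshold in robust-deviation units.
#' @param rel_floor lower bound on the deviation, as a fraction of the
#'   baseline.
#' @return A list with `frame` (the detected frame index, or `NA`),
#'   `detected` (logical), `baseline` and `threshold`.
#' @export
detect_time_zero <- function(trace, baseline_frames = 5L, n_sigma = 5,
                             rel_floor = 0.1) {
  if (is.numeric(trace)) {
    trace <- data.frame(frame = seq_along(trace) - 1L, intensity = trace)
  }
  stopifnot(all(c("frame", "intensity") %in% names(trace)))
  if (nrow(trace) < 5) stop("intensity trace must have at least 5 frames")
  trace <- trace[order(trace$frame), ]
  k <- min(baseline_frames, nrow(trace) - 1L)
  base <- stats::median(trace$intensity[seq_len(k)])
  dev <- stats::mad(trace$intensity[seq_len(k)])
  dev <- max(dev, rel_floor * abs(base))
  thr <- base + n_sigma * dev
  hit <- which(trace$intensity > thr)
  if (length(hit) == 0) {
    return(list(frame = NA_integer_, detected = FALSE, baseline = base,
                threshold = thr))
  }
  list(frame = trace$frame[hit[1]], detected = TRUE, baseline = base,
       threshold = thr)
}
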