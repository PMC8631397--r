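# Composite saccade/fixation detection: a velocity-threshold pass with
# duration and peak-velocity validation, followed by dispersion-threshold
# grouping of the remaining spans into fixations.

#' Detection parameters for the composite event detector
#'
#' @param velocity_threshold_dps Angular speed above which a sample is a
#'   saccade candidate (deg/s).
#' @param dispersion_threshold_deg Maximum positional dispersion
#'   (x-range + y-range, degrees) of one fixation.
#' @param min_fixation_ms Minimum fixation duration.
#' @param min_saccade_ms Minimum saccade duration.
#' @param smoothing_window_samples Width (odd) of the centred moving-average
#'   position filter.
#' @param velocity_span_samples Half-span of the central difference used for
#'   the velocity estimate.
#' @param peak_velocity_factor A candidate saccade run must reach
#'   `peak_velocity_factor * velocity_threshold_dps` at some sample;
#'   suppresses noise-induced runs that graze the onset threshold.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(velocity_threshold_dps = 30,
                             dispersion_threshold_deg = 1.0,
                             min_fixation_ms = 50,
                             min_saccade_ms = 12,
                             smoothing_window_samples = 5,
                             velocity_span_samples = 2,
                             peak_velocity_factor = 2) {
  vals <- c(velocity_threshold_dps, dispersion_threshold_deg, min_fixation_ms,
            min_saccade_ms, smoothing_window_samples, velocity_span_samples,
            peak_velocity_factor)
  if (any(vals <= 0)) stop("all detection parameters must be strictly positive")
  structure(list(velocity_threshold_dps = velocity_threshold_dps,
                 dispersion_threshold_deg = dispersion_threshold_deg,
                 min_fixation_ms = min_fixation_ms,
                 min_saccade_ms = min_saccade_ms,
                 smoothing_window_samples = smoothing_window_samples,
                 velocity_span_samples = velocity_span_samples,
                 peak_velocity_factor = peak_velocity_factor),
            class = "detection_params")
}

# centred running mean with shrinking (partial) windows at the edges
.running_mean <- function(x, w) {
  n <- length(x)
  if (w <= 1 || n == 1) return(x)
  h <- w %/% 2
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1)
  hi <- pmin(i + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

.check_recording <- function(recording) {
  need <- c("t_ms", "x_deg", "y_deg")
  if (!all(need %in% names(recording))) {
    stop("recording must have columns t_ms, x_deg, y_deg")
  }
  if (is.null(recording$valid)) recording$valid <- TRUE
  if (nrow(recording) == 0) stop("empty recording")
  if (any(diff(recording$t_ms) <= 0)) stop("timestamps must be strictly increasing")
  recording
}

#' Per-sample angular speed from a gaze recording
#'
#' Positions are smoothed with a centred moving average, then speed at
#' sample i is the central difference of the smoothed positions over
#' `span` samples each side (one-sided at the recording boundaries),
#' divided by the elapsed time. Invalid samples yield `NA` speed.
#'
#' @param recording Data frame with `t_ms`, `x_deg`, `y_deg` and optionally
#'   `valid`.
#' @param smoothing_window Moving-average width in samples.
#' @param span Central-difference half-span in samples.
#' @return Numeric vector of speeds (deg/s), one per sample.
#' @export
compute_velocity <- function(recording, smoothing_window = 5, span = 2) {
  recording <- .check_recording(recording)
  ok <- recording$valid
  if (sum(ok) < 2) stop("need at least 2 valid samples to compute velocity")
  n <- nrow(recording)
  xs <- .running_mean(recording$x_deg, smoothing_window)
  ys <- .running_mean(recording$y_deg, smoothing_window)
  i <- seq_len(n)
  lo <- pmax(i - span, 1)
  hi <- pmin(i + span, n)
  dts <- (recording$t_ms[hi] - recording$t_ms[lo]) / 1000
  speed <- sqrt((xs[hi] - xs[lo])^2 + (ys[hi] - ys[lo])^2) / dts
  speed[!ok] <- NA_real_
  speed
}

# runs of TRUE in a logical vector -> start/end index pairs
.true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  cbind(start = starts[keep], end = ends[keep])
}

#' Detect saccades and fixations in a gaze recording
#'
#' Contiguous runs of samples whose smoothed-velocity estimate reaches the
#' velocity threshold, lasting at least `min_saccade_ms` and containing at
#' least one sample at `peak_velocity_factor` times the threshold, become
#' saccades. The remaining spans (split at invalid samples) are grouped into
#' fixations by the classic dispersion-threshold scheme: a window of at
#' least `min_fixation_ms` whose dispersion (x-range + y-range of smoothed
#' positions) stays within the threshold is grown maximally and emitted.
#' Spans qualifying as neither are left unlabelled. Events never overlap and
#' are returned in time order.
#'
#' @param recording Data frame with `t_ms`, `x_deg`, `y_deg`, optional
#'   `valid`.
#' @param params A [detection_params()] object.
#' @return Data frame of events: `kind` (`saccade`/`fixation`), `onset_ms`,
#'   `offset_ms`, `start_x_deg`, `start_y_deg`, `end_x_deg`, `end_y_deg`,
#'   `amplitude_deg`, `peak_velocity_dps`.
#' @export
detect_events <- function(recording, params = detection_params()) {
  recording <- .check_recording(recording)
  if (!any(recording$valid)) stop("all samples invalid")
  speed <- compute_velocity(recording, params$smoothing_window_samples,
                            params$velocity_span_samples)
  xs <- .running_mean(recording$x_deg, params$smoothing_window_samples)
  ys <- .running_mean(recording$y_deg, params$smoothing_window_samples)
  t <- recording$t_ms
  n <- nrow(recording)

  cand <- !is.na(speed) & speed >= params$velocity_threshold_dps
  sac <- .true_runs(cand)
  if (nrow(sac)) {
    dur <- t[sac[, "end"]] - t[sac[, "start"]]
    peaks <- vapply(seq_len(nrow(sac)), function(k) {
      max(speed[sac[k, "start"]:sac[k, "end"]])
    }, numeric(1))
    keep <- dur >= params$min_saccade_ms &
      peaks >= params$peak_velocity_factor * params$velocity_threshold_dps
    sac <- sac[keep, , drop = FALSE]
    peaks <- peaks[keep]
  } else {
    peaks <- numeric(0)
  }

  events <- list()
  if (nrow(sac)) {
    for (k in seq_len(nrow(sac))) {
      s <- sac[k, "start"]; e <- sac[k, "end"]
      events[[length(events) + 1]] <- data.frame(
        kind = "saccade", onset_ms = t[s], offset_ms = t[e],
        start_x_deg = xs[s], start_y_deg = ys[s],
        end_x_deg = xs[e], end_y_deg = ys[e],
        amplitude_deg = sqrt((xs[e] - xs[s])^2 + (ys[e] - ys[s])^2),
        peak_velocity_dps = peaks[k], stringsAsFactors = FALSE)
    }
  }

  # spans outside saccades, further split at invalid samples
  in_sacc <- rep(FALSE, n)
  if (nrow(sac)) {
    for (k in seq_len(nrow(sac))) in_sacc[sac[k, "start"]:sac[k, "end"]] <- TRUE
  }
  free <- .true_runs(!in_sacc & recording$valid)
  if (nrow(free)) {
    for (k in seq_len(nrow(free))) {
      idx <- free[k, "start"]:free[k, "end"]
      for (fx in .idt_fixations(t[idx], xs[idx], ys[idx],
                                params$dispersion_threshold_deg,
                                params$min_fixation_ms)) {
        s <- idx[fx[1]]; e <- idx[fx[2]]
        events[[length(events) + 1]] <- data.frame(
          kind = "fixation", onset_ms = t[s], offset_ms = t[e],
          start_x_deg = xs[s], start_y_deg = ys[s],
          end_x_deg = xs[e], end_y_deg = ys[e],
          amplitude_deg = sqrt((xs[e] - xs[s])^2 + (ys[e] - ys[s])^2),
          peak_velocity_dps = max(speed[s:e], 0, na.rm = TRUE),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(events)) {
    return(data.frame(kind = character(0), onset_ms = numeric(0),
                      offset_ms = numeric(0), start_x_deg = numeric(0),
                      start_y_deg = numeric(0), end_x_deg = numeric(0),
                      end_y_deg = numeric(0), amplitude_deg = numeric(0),
                      peak_velocity_dps = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, events)
  out <- out[order(out$onset_ms), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# classic I-DT inner loop on one span; returns list of c(start, end) local
# indices of fixations
.idt_fixations <- function(t, x, y, disp_thr, min_dur) {
  n <- length(t)
  fixes <- list()
  i <- 1
  while (i <= n) {
    # smallest window starting at i covering min_dur
    j <- i
    while (j < n && t[j] - t[i] < min_dur) j <- j + 1
    if (t[j] - t[i] < min_dur) break  # tail too short for any fixation
    disp <- function(a, b) {
      (max(x[a:b]) - min(x[a:b])) + (max(y[a:b]) - min(y[a:b]))
    }
    if (disp(i, j) <= disp_thr) {
      while (j < n && disp(i, j + 1) <= disp_thr) j <- j + 1
      fixes[[length(fixes) + 1]] <- c(i, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  fixes
}

#' Screen geometry for pixel/degree conversion
#'
#' Defaults describe a 22-inch full-HD monitor (16:9, 48.7 x 27.4 cm)
#' viewed from 60 cm.
#'
#' @param width_px,height_px Resolution in pixels.
#' @param width_cm,height_cm Physical panel size in cm.
#' @param distance_cm Eye-to-screen distance in cm.
#' @return A list of class `screen_geometry`.
#' @export
screen_geometry <- function(width_px = 1920, height_px = 1080,
                            width_cm = 48.7, height_cm = 27.4,
                            distance_cm = 60) {
  vals <- c(width_px, height_px, width_cm, height_cm, distance_cm)
  if (any(vals <= 0)) stop("screen geometry values must be strictly positive")
  structure(list(width_px = width_px, height_px = height_px,
                 width_cm = width_cm, height_cm = height_cm,
                 distance_cm = distance_cm),
            class = "screen_geometry")
}

#' Convert screen-centred pixel offsets to degrees of visual angle
#'
#' Uses the arctangent of the physical offset over the viewing distance,
#' per axis. [deg_to_px()] is the exact inverse.
#'
#' @param x_px,y_px Pixel offsets from screen centre (x rightward, y upward).
#' @param screen A [screen_geometry()].
#' @return A list with numeric vectors `x_deg` and `y_deg`.
#' @export
px_to_deg <- function(x_px, y_px = 0, screen = screen_geometry()) {
  stopifnot(inherits(screen, "screen_geometry"))
  cm_per_px_x <- screen$width_cm / screen$width_px
  cm_per_px_y <- screen$height_cm / screen$height_px
  list(x_deg = atan2(x_px * cm_per_px_x, screen$distance_cm) * 180 / pi,
       y_deg = atan2(y_px * cm_per_px_y, screen$distance_cm) * 180 / pi)
}

#' @rdname px_to_deg
#' @param x_deg,y_deg Offsets in degrees of visual angle.
#' @return For [deg_to_px()]: a list with `x_px` and `y_px`.
#' @export
deg_to_px <- function(x_deg, y_deg = 0, screen = screen_geometry()) {
  stopifnot(inherits(screen, "screen_geometry"))
  cm_per_px_x <- screen$width_cm / screen$width_px
  cm_per_px_y <- screen$height_cm / screen$height_px
  list(x_px = tan(x_deg * pi / 180) * screen$distance_cm / cm_per_px_x,
       y_px = tan(y_deg * pi / 180) * screen$distance_cm / cm_per_px_y)
}
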