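#' Construct an IMU recording object
#'
#' @param location One of `trunk`, `thigh_left`, `thigh_right`, `shank_left`,
#'   `shank_right`.
#' @param accel n x 3 acceleration matrix, g.
#' @param gyro n x 3 angular velocity matrix, deg/s.
#' @param fs Sampling frequency, Hz.
#' @param start_time Recording start, s.
#' @return A list of class `pab_recording`.
#' @export
imu_recording <- function(location, accel, gyro, fs = 100, start_time = 0) {
  location <- match.arg(location, imu_locations())
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  if (ncol(accel) != 3 || ncol(gyro) != 3 || nrow(accel) != nrow(gyro))
    stop_pab("`accel` and `gyro` must be n x 3 matrices of equal length")
  if (fs <= 0) stop_pab("`fs` must be positive")
  structure(list(location = location, fs = fs, start_time = start_time,
                 n_samples = nrow(accel), accel = accel, gyro = gyro),
            class = "pab_recording")
}

#' @rdname imu_recording
#' @export
imu_locations <- function() {
  c("trunk", "thigh_left", "thigh_right", "shank_left", "shank_right")
}

rec_time <- function(rec) rec$start_time + (seq_len(rec$n_samples) - 1) / rec$fs

#' @export
print.pab_recording <- function(x, ...) {
  cat(sprintf("<pab_recording> %s: %d samples @ %g Hz (%.1f s from t=%g)\n",
              x$location, x$n_samples, x$fs, x$n_samples / x$fs, x$start_time))
  invisible(x)
}

#' Render synthetic IMU signals for an activity timeline
#'
#' Produces the five 100 Hz sensor recordings implied by a ground-truth
#' timeline. Trunk and thigh accelerometers carry a gravity vector whose
#' orientation encodes posture (near-vertical segment axis when upright,
#' near-horizontal thigh when sitting, trunk and thigh horizontal when lying)
#' plus a body-motion oscillation whose mean rectified amplitude equals the
#' segment's `body_accel`, plus white sensor noise. During walking, the shank
#' gyroscope pitch channel carries one synthetic mid-swing peak per step at
#' the segment's cadence; the two shank channels are rendered as redundant
#' step trains (physiologically each shank swings every other step, but the
#' simplified renderer exposes every step on both sides and the detector
#' deduplicates near-simultaneous contralateral events).
#'
#' @param timeline A `pab_timeline`.
#' @param config A [generator_config()]; supplies the noise levels.
#' @param seed Integer seed; identical seed gives bit-identical signals.
#' @param fs Sampling frequency, Hz.
#' @return Named list of five `pab_recording` objects.
#' @export
render_imu <- function(timeline, config, seed, fs = 100) {
  validate_timeline(timeline)
  noise <- config$noise
  day <- attr(timeline, "day_length") %||% max(timeline$end)
  n <- round(day * fs)
  t <- (seq_len(n) - 1) / fs
  ns <- nrow(timeline)

  with_seed(seed, {
    # Per-segment orientations (degrees from vertical of the segment axis).
    sitting <- timeline$mode == "lying_sitting" & runif(ns) < 0.7
    lying <- timeline$mode == "lying_sitting" & !sitting
    upright <- timeline$mode != "lying_sitting"
    ang <- function(mu, sd) pmin(89, pmax(0, rnorm(ns, mu, sd)))
    trunk_a <- ifelse(upright, ang(5, 2), ifelse(sitting, ang(10, 4), ang(85, 3)))
    thighL_a <- ifelse(upright, ang(5, 3), ang(82, 4))
    thighR_a <- ifelse(upright, ang(5, 3), ang(82, 4))
    shank_a <- ifelse(upright, ang(5, 3), ifelse(sitting, ang(25, 8), ang(85, 3)))

    # Body-motion oscillation per segment (static modes encode intensity;
    # walking uses a fixed trunk/thigh jiggle - cadence carries intensity).
    freq <- runif(ns, 0.8, 1.5)
    phase <- runif(ns, 0, 2 * pi)
    amp <- ifelse(upright & timeline$mode == "walking", 0.25,
                  pi / 2 * ifelse(is.na(timeline$body_accel), 0, timeline$body_accel))

    seg <- findInterval(t, timeline$start)
    osc <- amp[seg] * sin(2 * pi * freq[seg] * t + phase[seg])

    grav <- function(angles) {
      a <- angles[seg] * pi / 180
      cbind(cos(a), 0, sin(a))
    }
    noisy <- function(m, sd) m + matrix(rnorm(length(m), 0, sd), nrow(m), 3)

    make_accel <- function(angles) {
      g <- grav(angles)
      g[, 3] <- g[, 3] + osc
      noisy(g, noise$accel_sd)
    }

    # Gyro: white noise; pitch-axis (y) content during walking only.
    wseg <- which(timeline$mode == "walking")
    pitch_pulses <- numeric(n)
    sway <- numeric(n)
    for (i in wseg) {
      i0 <- timeline$start[i]; k <- timeline$n_steps[i]
      interval <- (timeline$end[i] - i0) / k
      centers <- i0 + (seq_len(k) - 0.5) * interval
      w <- min(0.08, interval / 6)
      amp_s <- rnorm(k, 240, 15)
      half <- ceiling(4 * w * fs)
      for (j in seq_len(k)) {
        ci <- round(centers[j] * fs) + 1
        idx <- max(1, ci - half):min(n, ci + half)
        pitch_pulses[idx] <- pitch_pulses[idx] +
          amp_s[j] * exp(-0.5 * ((t[idx] - centers[j]) / w)^2)
      }
      idx <- which(seg == i)
      sway[idx] <- 60 * sin(2 * pi * (k / (timeline$end[i] - i0)) * t[idx])
    }
    make_gyro <- function(y) noisy(cbind(0, y, 0), noise$gyro_sd)

    list(
      trunk = imu_recording("trunk", make_accel(trunk_a), make_gyro(sway), fs),
      thigh_left = imu_recording("thigh_left", make_accel(thighL_a), make_gyro(sway), fs),
      thigh_right = imu_recording("thigh_right", make_accel(thighR_a), make_gyro(sway), fs),
      shank_left = imu_recording("shank_left", make_accel(shank_a), make_gyro(pitch_pulses), fs),
      shank_right = imu_recording("shank_right", make_accel(shank_a), make_gyro(pitch_pulses), fs)
    )
  })
}
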