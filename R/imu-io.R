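#' Write / read IMU recordings as delimited text
#'
#' One file per sensor location with a one-line header:
#' `time_s ax_g ay_g az_g gx_dps gy_dps gz_dps`, tab-separated, timestamps in
#' seconds from recording start.
#'
#' @param rec A `pab_recording`.
#' @param path Output file.
#' @export
write_recording <- function(rec, path) {
  df <- data.frame(time_s = rec_time(rec),
                   ax_g = rec$accel[, 1], ay_g = rec$accel[, 2], az_g = rec$accel[, 3],
                   gx_dps = rec$gyro[, 1], gy_dps = rec$gyro[, 2], gz_dps = rec$gyro[, 3])
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Sensor-to-location assignment
#'
#' Maps file identifiers to the five body locations; used to correct an
#' accidental exchange of two sensors at setup time. Optional per-sensor axis
#' sign flips (e.g., a sensor worn upside down) are applied on read.
#'
#' @param files Character vector of file paths.
#' @param locations Character vector of the same length with the body
#'   location of each file; must be a bijection onto the five locations.
#' @param flips Optional named list: per location, a length-3 vector of +-1
#'   applied to both accelerometer and gyroscope axes.
#' @return A data frame of class `pab_sensormap`.
#' @export
sensor_map <- function(files, locations, flips = NULL) {
  locs <- imu_locations()
  if (length(files) != length(locations))
    stop_pab("`files` and `locations` must have equal length")
  missing <- setdiff(locs, locations)
  if (length(missing))
    stop_pab("sensor map is missing location(s): %s", paste(missing, collapse = ", "))
  if (anyDuplicated(locations) || length(locations) != 5)
    stop_pab("sensor map must assign each of the five locations exactly once")
  out <- data.frame(file = files, location = locations, stringsAsFactors = FALSE)
  attr(out, "flips") <- flips
  class(out) <- c("pab_sensormap", "data.frame")
  out
}

#' Read a synchronized five-sensor recording set
#'
#' Reads the five per-location text files, assigns body locations according
#' to the sensor map, checks that all sensors share one sampling rate, and
#' trims all recordings to the common overlapping time window (the sensors
#' are assumed hardware-synchronized, so no resampling is performed).
#'
#' @param map A [sensor_map()].
#' @return Named list of five `pab_recording` objects of equal length.
#' @export
read_recording_set <- function(map) {
  if (!inherits(map, "pab_sensormap")) stop_pab("`map` must come from sensor_map()")
  flips <- attr(map, "flips")
  raw <- lapply(seq_len(nrow(map)), function(i) {
    f <- map$file[i]
    if (!file.exists(f)) stop_pab("recording file for %s not found: %s", map$location[i], f)
    d <- as.data.frame(data.table::fread(f, sep = "\t"))
    need <- c("time_s", "ax_g", "ay_g", "az_g", "gx_dps", "gy_dps", "gz_dps")
    if (!all(need %in% names(d)))
      stop_pab("file %s lacks required columns (%s)", f, paste(need, collapse = ", "))
    if (nrow(d) < 2) stop_pab("file %s has too few samples", f)
    d
  })
  fs <- vapply(raw, function(d) 1 / median(diff(d$time_s)), numeric(1))
  if (diff(range(fs)) > 0.01 * mean(fs))
    stop_pab("unequal sampling rates across files (%.2f-%.2f Hz): %s",
             min(fs), max(fs), map$file[which.max(abs(fs - mean(fs)))])
  t0 <- max(vapply(raw, function(d) d$time_s[1], numeric(1)))
  t1 <- min(vapply(raw, function(d) d$time_s[nrow(d)], numeric(1)))
  if (t1 <= t0)
    stop_pab("recordings have no overlapping time window (file %s)",
             map$file[which.min(vapply(raw, function(d) d$time_s[nrow(d)], numeric(1)))])
  out <- lapply(seq_len(nrow(map)), function(i) {
    d <- raw[[i]]
    keep <- d$time_s >= t0 - 1e-9 & d$time_s <= t1 + 1e-9
    d <- d[keep, , drop = FALSE]
    acc <- as.matrix(d[, c("ax_g", "ay_g", "az_g")])
    gyr <- as.matrix(d[, c("gx_dps", "gy_dps", "gz_dps")])
    fl <- flips[[map$location[i]]]
    if (!is.null(fl)) {
      acc <- sweep(acc, 2, fl, `*`)
      gyr <- sweep(gyr, 2, fl, `*`)
    }
    imu_recording(map$location[i], acc, gyr, fs = round(mean(fs)),
                  start_time = d$time_s[1])
  })
  names(out) <- map$location
  nlen <- vapply(out, function(r) r$n_samples, numeric(1))
  out <- lapply(out, function(r) {
    m <- min(nlen)
    if (r$n_samples > m) {
      r$accel <- r$accel[seq_len(m), , drop = FALSE]
      r$gyro <- r$gyro[seq_len(m), , drop = FALSE]
      r$n_samples <- m
    }
    r
  })
  out[imu_locations()]
}

#' Auto-calibrate sensor axes from the data
#'
#' Recovers the functional axes of an arbitrarily mounted sensor from
#' movement (gait) windows, where body posture is unambiguously upright: the
#' vertical (gravity) axis is the mean accelerometer direction over those
#' windows (cyclic gait accelerations average out, leaving gravity), with
#' sign chosen so gravity is positive when upright; the dominant movement
#' axis (the pitch axis for shank sensors) is the first principal component
#' of the gyroscope over the same windows, made orthogonal to the vertical.
#' Still periods cannot serve as the vertical reference because a seated
#' thigh is static but horizontal. The resulting rotation is orthonormal, so
#' per-sample signal magnitudes are preserved exactly.
#'
#' @param rec A `pab_recording` (>= 60 s including some movement).
#' @param params [detection_params()] supplying the still/movement window
#'   thresholds (movement = gyroscope RMS above `5 * still_gyro`).
#' @return The rotated recording, with the rotation matrix in attribute
#'   `rotation` (rows are the new axes expressed in sensor coordinates).
#' @export
autocalibrate_axes <- function(rec, params = detection_params()) {
  fs <- rec$fs
  n <- rec$n_samples
  if (n < 60 * fs) stop_pab("need at least 60 s of data to calibrate")
  nw <- floor(n / fs)
  idx <- seq_len(nw * fs)
  win <- rep(seq_len(nw), each = fs)

  gmag <- sqrt(rowSums(rec$gyro[idx, ]^2))
  gyro_rms <- sqrt(tapply(gmag^2, win, mean))
  acc_norm <- sqrt(rowSums(rec$accel[idx, ]^2))

  if (sd(acc_norm) < 1e-12 && sd(gmag) < 1e-12)
    stop_pab("recording has near-zero variance; cannot orient axes")

  moving <- which(gyro_rms > 5 * params$still_gyro)
  if (!length(moving)) stop_pab("no movement found; cannot orient axes")

  smp_of <- function(wins) which(win %in% wins)
  g <- colMeans(rec$accel[smp_of(moving), , drop = FALSE])
  if (sqrt(sum(g^2)) < 0.5) stop_pab("movement-window gravity vector is degenerate")
  x <- g / sqrt(sum(g^2))

  gm <- rec$gyro[smp_of(moving), , drop = FALSE]
  pc1 <- prcomp(gm, center = TRUE, scale. = FALSE)$rotation[, 1]
  y <- pc1 - sum(pc1 * x) * x
  if (sqrt(sum(y^2)) < 1e-6) stop_pab("movement axis indistinguishable from vertical")
  y <- y / sqrt(sum(y^2))
  proj <- gm %*% y
  if (mean((proj - mean(proj))^3) < 0) y <- -y  # swing peaks positive
  z <- c(x[2] * y[3] - x[3] * y[2], x[3] * y[1] - x[1] * y[3], x[1] * y[2] - x[2] * y[1])
  R <- rbind(x = x, y = y, z = z)

  rec$accel <- rec$accel %*% t(R)
  rec$gyro <- rec$gyro %*% t(R)
  colnames(rec$accel) <- colnames(rec$gyro) <- c("x", "y", "z")
  attr(rec, "rotation") <- R
  rec
}
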