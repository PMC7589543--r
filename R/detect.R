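#' Detect steps from shank pitch angular velocity
#'
#' Band-passes the calibrated pitch channel (sagittal-plane angular velocity)
#' and returns one event per mid-swing positive peak exceeding the threshold,
#' with a refractory period so that peaks closer than the spacing implied by
#' the fastest plausible cadence yield a single event.
#'
#' @param rec A calibrated shank `pab_recording`.
#' @param params [detection_params()].
#' @param side Label attached to the events (`left`/`right`).
#' @return A data frame of class `pab_steps` with `time` (s), `side`, and
#'   `peak_angular_velocity` (deg/s); empty when no step is found.
#' @export
detect_steps <- function(rec, params = detection_params(), side = "left") {
  x <- rec$gyro[, 2]
  fs <- rec$fs
  if (sd(x) > 1e-12) {
    bf <- signal::butter(2, params$band / (fs / 2), type = "pass")
    x <- signal::filtfilt(bf, x)
  }
  n <- length(x)
  if (n < 3) return(empty_steps())
  is_peak <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n] &
                     x[2:(n - 1)] > params$swing_threshold) + 1
  if (!length(is_peak)) return(empty_steps())
  tt <- rec_time(rec)[is_peak]
  pk <- x[is_peak]
  keep <- logical(length(tt))
  last <- -Inf
  for (i in seq_along(tt)) {   # greedy refractory pass
    if (tt[i] - last >= params$refractory) {
      keep[i] <- TRUE
      last <- tt[i]
    }
  }
  out <- data.frame(time = tt[keep], side = side,
                    peak_angular_velocity = pk[keep], stringsAsFactors = FALSE)
  class(out) <- c("pab_steps", "data.frame")
  out
}

empty_steps <- function() {
  out <- data.frame(time = numeric(), side = character(),
                    peak_angular_velocity = numeric(), stringsAsFactors = FALSE)
  class(out) <- c("pab_steps", "data.frame")
  out
}

#' Merge left and right step events into one train
#'
#' Combines the two sides by time and collapses events from opposite shanks
#' that fall within `merge_window` of each other into a single step (the two
#' shank channels can carry redundant views of the same step). Single-sided
#' dropout is tolerated: an event present on one side only still counts.
#'
#' @param left,right `pab_steps` data frames.
#' @param params [detection_params()].
#' @return A merged `pab_steps` data frame ordered by time.
#' @export
merge_steps <- function(left, right, params = detection_params()) {
  all <- rbind(as.data.frame(left), as.data.frame(right))
  if (!nrow(all)) return(empty_steps())
  all <- all[order(all$time), , drop = FALSE]
  cl <- cumsum(c(TRUE, diff(all$time) >= params$merge_window))
  out <- data.frame(
    time = as.numeric(tapply(all$time, cl, mean)),
    side = as.character(tapply(all$side, cl, function(s) if (length(unique(s)) > 1) "both" else s[1])),
    peak_angular_velocity = as.numeric(tapply(all$peak_angular_velocity, cl, max)),
    stringsAsFactors = FALSE)
  class(out) <- c("pab_steps", "data.frame")
  out
}

#' Assemble walking bouts from a step train
#'
#' Consecutive steps separated by no more than `max_step_gap` form candidate
#' episodes; candidates with fewer than 4 steps are discarded. Bout duration
#' is the first-to-last step span plus half a mean step period at each end,
#' and cadence is `n_steps / duration * 60`.
#'
#' @param steps A time-ordered `pab_steps` data frame (sides merged).
#' @param params [detection_params()].
#' @return A data frame of class `pab_bouts` with `start`, `end` (s),
#'   `n_steps`, `cadence` (steps/min).
#' @export
assemble_bouts <- function(steps, params = detection_params()) {
  empty <- data.frame(start = numeric(), end = numeric(),
                      n_steps = integer(), cadence = numeric())
  class(empty) <- c("pab_bouts", "data.frame")
  if (!nrow(steps)) return(empty)
  tt <- sort(steps$time)
  grp <- cumsum(c(TRUE, diff(tt) > params$max_step_gap))
  rows <- lapply(split(tt, grp), function(g) {
    n <- length(g)
    if (n < 4) return(NULL)   # minimum of 4 consecutive steps
    span <- g[n] - g[1]
    msp <- span / (n - 1)
    data.frame(start = g[1] - msp / 2, end = g[n] + msp / 2,
               n_steps = n, cadence = n / (span + msp) * 60)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # end-padding can in principle touch the next bout; clip at midpoints
  if (nrow(out) > 1) {
    for (i in seq_len(nrow(out) - 1)) {
      if (out$end[i] > out$start[i + 1]) {
        mid <- (out$end[i] + out$start[i + 1]) / 2
        out$end[i] <- mid
        out$start[i + 1] <- mid
      }
    }
  }
  out$start <- pmax(out$start, 0)
  class(out) <- c("pab_bouts", "data.frame")
  out
}

#' Detect lying/sitting vs standing postures from gravity orientation
#'
#' Labels each non-walking epoch `standing` when both the trunk and at least
#' one thigh gravity vector lie within the angle threshold of vertical, and
#' `lying_sitting` otherwise (sitting and lying are deliberately not
#' distinguished: a vertical trunk over a horizontal thigh is sitting
#' geometry and maps to the merged class). Adjacent epochs with the same
#' label are merged into segments.
#'
#' @param trunk Calibrated trunk `pab_recording`.
#' @param thighs List of the two calibrated thigh recordings.
#' @param walking_mask Logical vector, one element per epoch; `TRUE` epochs
#'   belong to walking bouts and are excluded.
#' @param params [detection_params()].
#' @return A data frame of class `pab_postures` with `mode`, `start`, `end`,
#'   and attribute `epoch_labels` (per-epoch character vector, `NA` at
#'   walking epochs).
#' @export
detect_postures <- function(trunk, thighs, walking_mask = NULL,
                            params = detection_params()) {
  ne <- floor(trunk$n_samples / (trunk$fs * params$epoch))
  ang <- function(rec) {
    m <- epoch_means(rec$accel, rec$fs * params$epoch, ne)
    acos(pmin(1, pmax(-1, m[, 1] / sqrt(rowSums(m^2))))) * 180 / pi
  }
  a_tr <- ang(trunk)
  a_th <- do.call(pmin, lapply(thighs, ang))
  standing <- a_tr < params$posture_angle & a_th < params$posture_angle
  lab <- ifelse(standing, "standing", "lying_sitting")
  if (!is.null(walking_mask)) {
    walking_mask <- walking_mask[seq_len(ne)]
    lab[walking_mask] <- NA
  }
  segs <- runs_to_segments(lab, params$epoch)
  segs <- segs[!is.na(segs$mode), , drop = FALSE]
  rownames(segs) <- NULL
  attr(segs, "epoch_labels") <- lab
  class(segs) <- c("pab_postures", "data.frame")
  segs
}

epoch_means <- function(mat, per, ne) {
  idx <- seq_len(ne * per)
  sapply(seq_len(ncol(mat)), function(j) colMeans(matrix(mat[idx, j], nrow = per)))
}

runs_to_segments <- function(lab, epoch) {
  r <- rle(ifelse(is.na(lab), "<walk>", lab))
  ends <- cumsum(r$lengths) * epoch
  starts <- ends - r$lengths * epoch
  data.frame(mode = ifelse(r$values == "<walk>", NA, r$values),
             start = starts, end = ends, stringsAsFactors = FALSE)
}

#' Mean body acceleration of a recording interval
#'
#' Gravity is removed by subtracting the per-axis mean over the interval
#' (exact for a static posture); the statistic is the mean Euclidean norm of
#' the residual, in g. For a pure sinusoidal body motion of amplitude `a`
#' this converges to `2 a / pi`.
#'
#' @param rec A calibrated `pab_recording` (normally the trunk).
#' @param start,end Interval in seconds from recording start.
#' @return Non-negative scalar, g.
#' @export
body_acceleration <- function(rec, start, end) {
  tt <- rec_time(rec)
  idx <- which(tt >= start & tt < end)
  if (!length(idx)) stop_pab("segment [%g, %g) lies outside the recording", start, end)
  a <- rec$accel[idx, , drop = FALSE]
  res <- sweep(a, 2, colMeans(a))
  mean(sqrt(rowSums(res^2)))
}

#' Build an activity timeline from detected bouts and postures
#'
#' Combines walking bouts and posture segments on the epoch grid: each epoch
#' is assigned to the walking bout covering the majority of it, otherwise to
#' its posture label. Epochs covered by neither (a gap) or claimed twice (an
#' overlap among bouts) are hard errors. Walking segments carry the bout's
#' step count and cadence; static segments carry the supplied mean body
#' acceleration.
#'
#' @param bouts A `pab_bouts` data frame.
#' @param postures A `pab_postures` data frame (with `epoch_labels`).
#' @param day_length Recording length, s.
#' @param epoch Epoch length, s.
#' @param body_accels Optional function `(start, end) -> g` used to fill
#'   static-segment intensity (e.g., a closure over [body_acceleration()]);
#'   `NA` intensities otherwise.
#' @param subject_id Attached to the result.
#' @return A `pab_timeline`.
#' @export
build_timeline <- function(bouts, postures, day_length, epoch = 1,
                           body_accels = NULL, subject_id = "S000") {
  ne <- round(day_length / epoch)
  owner <- rep(NA_integer_, ne)  # bout id per epoch
  if (nrow(bouts)) {
    for (i in seq_len(nrow(bouts))) {
      cov <- epoch_overlap(bouts$start[i], bouts$end[i], ne, epoch)
      claim <- cov$idx[cov$w > epoch / 2]
      if (any(!is.na(owner[claim]))) stop_pab("walking bouts overlap on the epoch grid")
      owner[claim] <- i
    }
  }
  lab <- attr(postures, "epoch_labels")
  if (is.null(lab)) {  # reconstruct from segments
    lab <- rep(NA_character_, ne)
    for (i in seq_len(nrow(postures))) {
      cov <- epoch_overlap(postures$start[i], postures$end[i], ne, epoch)
      lab[cov$idx[cov$w > epoch / 2]] <- postures$mode[i]
    }
  }
  lab <- lab[seq_len(ne)]
  final <- ifelse(!is.na(owner), "walking", lab)
  if (anyNA(final)) stop_pab("epoch grid has gaps: %d uncovered epochs", sum(is.na(final)))

  key <- ifelse(final == "walking", paste0("w", owner), final)
  r <- rle(key)
  ends <- cumsum(r$lengths) * epoch
  starts <- ends - r$lengths * epoch
  mode <- ifelse(grepl("^w", r$values), "walking", r$values)
  n_steps <- rep(NA_real_, length(mode))
  cadence <- rep(NA_real_, length(mode))
  body <- rep(NA_real_, length(mode))
  for (i in seq_along(mode)) {
    if (mode[i] == "walking") {
      b <- as.integer(sub("^w", "", r$values[i]))
      n_steps[i] <- bouts$n_steps[b]
      cadence[i] <- bouts$cadence[b]
    } else if (!is.null(body_accels)) {
      body[i] <- body_accels(starts[i], ends[i])
    }
  }
  out <- data.frame(mode = mode, start = starts, end = ends,
                    body_accel = body, n_steps = n_steps, cadence = cadence,
                    stringsAsFactors = FALSE)
  attr(out, "subject_id") <- subject_id
  attr(out, "day_length") <- ne * epoch
  class(out) <- c("pab_timeline", "data.frame")
  validate_timeline(out)
  out
}

# Overlap (in seconds) of the interval [s, e) with each epoch it touches.
epoch_overlap <- function(s, e, ne, epoch) {
  i1 <- max(1L, floor(s / epoch) + 1L)
  i2 <- min(ne, ceiling(e / epoch))
  if (i2 < i1) return(list(idx = integer(), w = numeric()))
  idx <- i1:i2
  lo <- pmax(s, (idx - 1) * epoch)
  hi <- pmin(e, idx * epoch)
  list(idx = idx, w = hi - lo)
}

#' Run the full detection chain on a five-sensor recording set
#'
#' Calibrates each sensor, detects steps on both shanks, merges sides,
#' assembles walking bouts, labels postures on the non-walking epochs, and
#' returns the assembled timeline. Deterministic for fixed input and
#' parameters.
#'
#' @param recs Named list of five `pab_recording` objects.
#' @param params [detection_params()].
#' @param calibrate Apply [autocalibrate_axes()] first (default `TRUE`).
#' @param subject_id Attached to the timeline.
#' @return A `pab_timeline`.
#' @export
detect_timeline <- function(recs, params = detection_params(),
                            calibrate = TRUE, subject_id = "S000") {
  need <- imu_locations()
  if (!all(need %in% names(recs)))
    stop_pab("missing recording(s): %s", paste(setdiff(need, names(recs)), collapse = ", "))
  if (calibrate) recs <- lapply(recs, autocalibrate_axes, params = params)
  fs <- recs$trunk$fs
  day <- recs$trunk$n_samples / fs
  ne <- floor(day / params$epoch)

  sl <- detect_steps(recs$shank_left, params, side = "left")
  sr <- detect_steps(recs$shank_right, params, side = "right")
  steps <- merge_steps(sl, sr, params)
  bouts <- assemble_bouts(steps, params)

  wmask <- rep(FALSE, ne)
  if (nrow(bouts)) {
    for (i in seq_len(nrow(bouts))) {
      cov <- epoch_overlap(bouts$start[i], bouts$end[i], ne, params$epoch)
      wmask[cov$idx[cov$w > params$epoch / 2]] <- TRUE
    }
  }
  postures <- detect_postures(recs$trunk,
                              list(recs$thigh_left, recs$thigh_right),
                              walking_mask = wmask, params = params)
  build_timeline(bouts, postures, day_length = ne * params$epoch,
                 epoch = params$epoch,
                 body_accels = function(s, e) body_acceleration(recs$trunk, s, e),
                 subject_id = subject_id)
}
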