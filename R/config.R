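#' Capacity-to-behavior link parameters for the synthetic cohort
#'
#' Controls how strongly a subject's gross motor capacity score (GMFM-66,
#' 0-100) shapes the generated daily activity. Long-bout achievement is
#' logistic in capacity: the probability of producing at least one walking
#' bout longer than 120 s (the doorway to PAS 5) is
#' `plogis(strength_long * (gmfm66 - loc_long) / scale)`, and analogously for
#' bouts longer than 360 s (PAS 6) with `loc_very_long`. Walking-bout rate and
#' cadence shift smoothly with capacity; short-bout frequency has a mild
#' negative age link so that age-partialled correlations are exercised.
#'
#' Setting every strength/slope to zero (see [null_link()]) makes the
#' generated behavior independent of capacity, which is the null condition
#' used for family-wise error checks.
#'
#' @param loc_long,loc_very_long Logistic locations on the GMFM-66 scale for
#'   achieving a >120 s and a >360 s walking bout (defaults 75 and 87).
#' @param scale Logistic scale in GMFM-66 points.
#' @param strength_long,strength_very_long Multipliers on the logistic slope;
#'   0 gives a capacity-independent constant probability of 0.5.
#' @param act_strength Log-linear effect of capacity (per 15 GMFM-66 points)
#'   on the walking-bout rate; 0 disables.
#' @param cad_slope Cadence shift in steps/min per 15 GMFM-66 points.
#' @param age_strength Log-linear negative effect of age on bout rate.
#' @return A list of class `pab_link`.
#' @export
capacity_link <- function(loc_long = 75, loc_very_long = 87, scale = 3,
                          strength_long = 1, strength_very_long = 1,
                          act_strength = 0.35, cad_slope = 10,
                          age_strength = 0.2) {
  if (scale <= 0) stop_pab("logistic `scale` must be positive")
  structure(list(loc_long = loc_long, loc_very_long = loc_very_long,
                 scale = scale, strength_long = strength_long,
                 strength_very_long = strength_very_long,
                 act_strength = act_strength, cad_slope = cad_slope,
                 age_strength = age_strength),
            class = "pab_link")
}

#' @rdname capacity_link
#' @export
null_link <- function() {
  capacity_link(strength_long = 0, strength_very_long = 0,
                act_strength = 0, cad_slope = 0, age_strength = 0)
}

#' Sensor noise levels for rendered IMU signals
#'
#' Defaults reflect typical consumer MEMS specifications: accelerometer white
#' noise of a few milli-g and gyroscope noise below 1 deg/s at a 100 Hz
#' sampling rate.
#'
#' @param accel_sd Accelerometer white-noise standard deviation per axis, g.
#' @param gyro_sd Gyroscope white-noise standard deviation per axis, deg/s.
#' @return A list of class `pab_noise`.
#' @export
imu_noise <- function(accel_sd = 0.002, gyro_sd = 0.5) {
  if (accel_sd < 0 || gyro_sd < 0) stop_pab("noise levels must be >= 0")
  structure(list(accel_sd = accel_sd, gyro_sd = gyro_sd), class = "pab_noise")
}

#' Synthetic cohort generator configuration
#'
#' @param n_subjects Number of subjects (>= 0).
#' @param day_length Monitored day length in seconds; the default 33,840 s
#'   corresponds to the 9.4 h school-day recordings the method targets.
#' @param gmfcs_weights Relative sizes of the GMFCS I/II/III strata; when they
#'   are integers summing to `n_subjects` the stratum counts are exact.
#' @param gmfm_centers,gmfm_spread Per-stratum centers and spreads of the
#'   truncated-normal GMFM-66 capacity distributions (I > II > III).
#' @param walk_rate Mean number of walking bouts per upright cycle (Poisson);
#'   0 disables walking entirely (including injected long bouts).
#' @param capacity_link A [capacity_link()] object.
#' @param noise An [imu_noise()] object used when rendering IMU signals.
#' @param seed Master seed; identical config + seed reproduce the cohort.
#' @return A list of class `pab_gencfg`.
#' @export
generator_config <- function(n_subjects = 25,
                             day_length = 33840,
                             gmfcs_weights = c(I = 13, II = 4, III = 8),
                             gmfm_centers = c(I = 88, II = 75, III = 57),
                             gmfm_spread = c(I = 6, II = 7, III = 8),
                             walk_rate = 1.2,
                             capacity_link = pabarcode::capacity_link(),
                             noise = imu_noise(),
                             seed = 1L) {
  if (length(n_subjects) != 1 || is.na(n_subjects) || n_subjects < 0)
    stop_pab("`n_subjects` must be a single non-negative count")
  if (length(day_length) != 1 || is.na(day_length) || day_length <= 0)
    stop_pab("`day_length` must be a single positive number of seconds")
  if (length(gmfcs_weights) != 3 || any(gmfcs_weights < 0) || sum(gmfcs_weights) <= 0)
    stop_pab("`gmfcs_weights` must be three non-negative weights with positive sum")
  if (walk_rate < 0) stop_pab("`walk_rate` must be >= 0")
  if (!inherits(capacity_link, "pab_link")) stop_pab("`capacity_link` must come from capacity_link()")
  if (!inherits(noise, "pab_noise")) stop_pab("`noise` must come from imu_noise()")
  structure(list(n_subjects = as.integer(n_subjects),
                 day_length = day_length,
                 gmfcs_weights = gmfcs_weights,
                 gmfm_centers = gmfm_centers,
                 gmfm_spread = gmfm_spread,
                 walk_rate = walk_rate,
                 capacity_link = capacity_link,
                 noise = noise,
                 seed = as.integer(seed)),
            class = "pab_gencfg")
}

#' Detection parameters for step, bout and posture detection
#'
#' The upstream publications of the walking and posture detectors do not list
#' their working parameters, so these are declared engineering defaults and
#' every one is configurable and echoed in run metadata.
#'
#' @param swing_threshold Mid-swing peak threshold on band-passed shank pitch
#'   angular velocity, deg/s.
#' @param refractory Minimum spacing between detected steps, s (derived from a
#'   maximum plausible cadence of about 240 steps/min).
#' @param max_step_gap Maximum inter-step gap inside one walking bout, s.
#' @param merge_window Window for collapsing near-simultaneous contralateral
#'   detections into a single step, s.
#' @param posture_angle Maximum angle from vertical (degrees) of the gravity
#'   vector for an epoch to count as upright.
#' @param still_gyro,still_accel Thresholds classifying 1 s windows as still
#'   for axis auto-calibration (deg/s RMS and g SD).
#' @param epoch Epoch length for posture labeling, s.
#' @param band Band-pass corner frequencies for step detection, Hz.
#' @return A list of class `pab_detparams`.
#' @export
detection_params <- function(swing_threshold = 50, refractory = 0.25,
                             max_step_gap = 2, merge_window = 0.12,
                             posture_angle = 40, still_gyro = 3,
                             still_accel = 0.02, epoch = 1,
                             band = c(0.5, 5)) {
  vals <- c(swing_threshold, refractory, max_step_gap, merge_window,
            posture_angle, still_gyro, still_accel, epoch, band)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_pab("all detection parameters must be positive and finite")
  if (band[1] >= band[2]) stop_pab("`band` must be increasing")
  structure(list(swing_threshold = swing_threshold, refractory = refractory,
                 max_step_gap = max_step_gap, merge_window = merge_window,
                 posture_angle = posture_angle, still_gyro = still_gyro,
                 still_accel = still_accel, epoch = epoch, band = band),
            class = "pab_detparams")
}

#' Barcode classification parameters
#'
#' Duration and cadence bins follow the published state table: walking bouts
#' are short / medium / long / very long with half-open edges at 60, 120 and
#' 360 s, and slow / moderate / fast / very fast with half-open edges at 70,
#' 100 and 130 steps/min. The static body-acceleration thresholds are not
#' published anywhere; the defaults are actigraphy-scale values and must be
#' read as declared conventions, not recovered constants.
#'
#' @param epoch Barcode epoch length, s.
#' @param duration_edges Walking-bout duration bin edges, s (half-open,
#'   upper-edge exclusive).
#' @param cadence_edges Cadence bin edges, steps/min (half-open).
#' @param lying_edge Body-acceleration split between low and moderate
#'   lying/sitting, g.
#' @param standing_edges Body-acceleration edges between the four standing
#'   intensity classes, g.
#' @return A list of class `pab_bcparams`.
#' @export
barcode_params <- function(epoch = 1,
                           duration_edges = c(60, 120, 360),
                           cadence_edges = c(70, 100, 130),
                           lying_edge = 0.04,
                           standing_edges = c(0.04, 0.10, 0.20)) {
  if (epoch <= 0) stop_pab("`epoch` must be positive")
  if (length(duration_edges) != 3 || is.unsorted(duration_edges, strictly = TRUE))
    stop_pab("`duration_edges` must be three strictly increasing values")
  if (length(cadence_edges) != 3 || is.unsorted(cadence_edges, strictly = TRUE))
    stop_pab("`cadence_edges` must be three strictly increasing values")
  if (length(standing_edges) != 3 || is.unsorted(standing_edges, strictly = TRUE))
    stop_pab("`standing_edges` must be three strictly increasing values")
  if (length(lying_edge) != 1 || lying_edge <= 0)
    stop_pab("`lying_edge` must be a single positive value")
  structure(list(epoch = epoch, duration_edges = duration_edges,
                 cadence_edges = cadence_edges, lying_edge = lying_edge,
                 standing_edges = standing_edges),
            class = "pab_bcparams")
}

#' Complexity metric parameters
#'
#' @param K Design alphabet size used to normalize Hn and LZC; fixed at the
#'   22 barcode states by default so values are comparable across subjects
#'   regardless of how many states a subject actually visits.
#' @param sampen_m Template length for sample entropy (exact symbol matching).
#' @return A list of class `pab_cxparams`.
#' @export
complexity_params <- function(K = 22, sampen_m = 2) {
  if (K < 2) stop_pab("`K` must be >= 2")
  if (sampen_m < 1) stop_pab("`sampen_m` must be >= 1")
  structure(list(K = as.integer(K), sampen_m = as.integer(sampen_m)),
            class = "pab_cxparams")
}
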