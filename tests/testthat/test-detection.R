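# Step, bout and posture detection, body acceleration, timeline assembly.

mk_rec <- function(gy, fs = 100, location = "shank_left") {
  n <- length(gy)
  imu_recording(location, matrix(c(rep(1, n), rep(0, 2 * n)), n, 3),
                cbind(0, gy, 0), fs = fs)
}

pulse_train <- function(times, fs = 100, len = NULL, amp = 240, w = 0.06) {
  len <- len %||% ceiling((max(times) + 1) * fs)
  t <- (seq_len(len) - 1) / fs
  g <- numeric(len)
  for (tc in times) g <- g + amp * exp(-0.5 * ((t - tc) / w)^2)
  g
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("step detection finds swing peaks, ignores flat signal, respects refractory", {
  expect_equal(nrow(detect_steps(mk_rec(numeric(2000)))), 0)

  times <- 1 + (0:9) * 0.5
  st <- detect_steps(mk_rec(pulse_train(times)))
  expect_equal(nrow(st), 10)
  expect_equal(st$time, times, tolerance = 0.03)

  # two peaks 0.15 s apart (inside the 0.25 s refractory) yield one event
  st2 <- detect_steps(mk_rec(pulse_train(c(2, 2.15), w = 0.03)))
  expect_equal(nrow(st2), 1)
})

test_that("contralateral duplicates merge into single steps; dropout tolerated", {
  times <- 1 + (0:7) * 0.6
  l <- data.frame(time = times, side = "left", peak_angular_velocity = 200)
  r <- data.frame(time = times + 0.02, side = "right", peak_angular_velocity = 190)
  m <- merge_steps(l, r)
  expect_equal(nrow(m), 8)
  expect_true(all(m$side == "both"))
  m2 <- merge_steps(l[0, ], r)   # left sensor dropout
  expect_equal(nrow(m2), 8)
})

test_that("bout assembly enforces the 4-step minimum and the stated cadence rule", {
  p <- detection_params()
  mk <- function(k, gap = 0.5) data.frame(time = 1 + (0:(k - 1)) * gap,
                                          side = "both",
                                          peak_angular_velocity = 200)
  expect_equal(nrow(assemble_bouts(mk(3), p)), 0)
  expect_equal(nrow(assemble_bouts(mk(1), p)), 0)
  b4 <- assemble_bouts(mk(4), p)
  expect_equal(nrow(b4), 1)
  expect_equal(b4$n_steps, 4)

  # 21 steps spanning 10 s: mean step period 0.5 s, cadence 21/10.5*60 = 120
  b <- assemble_bouts(mk(21, gap = 0.5), p)
  expect_equal(b$cadence, 120)
  expect_equal(b$end - b$start, 10.5)

  # a gap over max_step_gap splits episodes; a 3-step tail is discarded
  tt <- c((0:5) * 0.5, 10 + (0:2) * 0.5)
  b2 <- assemble_bouts(data.frame(time = tt, side = "both",
                                  peak_angular_velocity = 200), p)
  expect_equal(nrow(b2), 1)
  expect_equal(b2$n_steps, 6)
})

test_that("posture labeling follows trunk-and-thigh gravity geometry", {
  n <- 3000  # 30 s
  vert <- matrix(c(rep(1, n), rep(0, 2 * n)), n, 3)
  horiz <- matrix(c(rep(0, n), rep(0, n), rep(1, n)), n, 3)
  z <- matrix(0, n, 3)
  mk <- function(acc, loc) imu_recording(loc, acc, z, fs = 100)

  up <- detect_postures(mk(vert, "trunk"), list(mk(vert, "thigh_left"),
                                                mk(vert, "thigh_right")))
  expect_equal(nrow(up), 1)
  expect_equal(up$mode, "standing")
  expect_equal(c(up$start, up$end), c(0, 30))

  # vertical trunk over horizontal thighs = sitting geometry -> lying_sitting
  sit <- detect_postures(mk(vert, "trunk"), list(mk(horiz, "thigh_left"),
                                                 mk(horiz, "thigh_right")))
  expect_equal(sit$mode, "lying_sitting")
})

test_that("body acceleration is zero for pure gravity and 2a/pi for a sinusoid", {
  n <- 6000
  t <- (seq_len(n) - 1) / 100
  static <- imu_recording("trunk", matrix(c(rep(1, n), rep(0, 2 * n)), n, 3),
                          matrix(0, n, 3))
  expect_equal(body_acceleration(static, 0, 60), 0)

  for (a in c(0.05, 0.2)) {
    acc <- cbind(1, 0, a * sin(2 * pi * 1 * t))
    rec <- imu_recording("trunk", acc, matrix(0, n, 3))
    expect_equal(body_acceleration(rec, 0, 60), 2 * a / pi, tolerance = 1e-3)
  }
  # monotone: larger body motion never decreases the value
  vals <- vapply(c(0.02, 0.05, 0.1, 0.3), function(a) {
    rec <- imu_recording("trunk", cbind(1, 0, a * sin(2 * pi * t)), matrix(0, n, 3))
    body_acceleration(rec, 0, 60)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("timeline assembly tiles the grid and rejects gaps", {
  post <- data.frame(mode = c("standing", "lying_sitting"), start = c(0, 40),
                     end = c(40, 100))
  bouts <- data.frame(start = numeric(), end = numeric(), n_steps = integer(),
                      cadence = numeric())
  tl <- build_timeline(bouts, post, day_length = 100)
  expect_s3_class(tl, "pab_timeline")
  expect_true(all(tl$mode != "walking"))
  expect_equal(sum(tl$end - tl$start), 100)

  gap <- data.frame(mode = "standing", start = 0, end = 60)
  expect_error(build_timeline(bouts, gap, day_length = 100), "gap")
})

test_that("full detection recovers a ground-truth day and is deterministic", {
  cfg <- small_cfg(n = 1, day = 1200, seed = 31)
  co <- generate_cohort(cfg)
  tl <- generate_timeline(co[1, ], cfg, seed = 77)
  recs <- render_imu(tl, cfg, seed = 78)
  d1 <- detect_timeline(recs, subject_id = "S001")
  d2 <- detect_timeline(recs, subject_id = "S001")
  expect_identical(d1, d2)

  b_truth <- to_barcode(tl)
  b_det <- to_barcode(d1)
  expect_gte(mean(unclass(b_truth) == unclass(b_det)), 0.95)

  # mode-level agreement, coarser than the 22-state comparison
  pas_t <- map_pas(unclass(b_truth)); pas_d <- map_pas(unclass(b_det))
  expect_gte(mean(pas_t == pas_d), 0.95)
})

test_that("detection accuracy degrades gracefully with sensor noise", {
  agree_at <- function(acc_sd, gyro_sd) {
    cfg <- small_cfg(n = 1, day = 900, seed = 41,
                     noise = imu_noise(accel_sd = acc_sd, gyro_sd = gyro_sd))
    co <- generate_cohort(cfg)
    tl <- generate_timeline(co[1, ], cfg, seed = 91)
    recs <- render_imu(tl, cfg, seed = 92)
    mean(unclass(to_barcode(tl)) == unclass(to_barcode(detect_timeline(recs))))
  }
  lo <- agree_at(0.002, 0.5)
  hi <- agree_at(0.08, 25)
  expect_gte(lo, 0.95)
  expect_lte(hi, lo + 0.02)  # allow tiny non-monotone wiggle
})
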