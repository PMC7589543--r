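#' Generate a synthetic cohort of subject profiles
#'
#' Draws subjects stratified by GMFCS level with capacity scores (GMFM-66,
#' 0-100) from truncated normal distributions whose centers decrease from
#' level I to level III, matching the ordering seen in clinical cohorts.
#' Latent activity propensities (long-bout achievement probabilities, bout
#' rate multiplier, cadence mean) are a deterministic function of the drawn
#' capacity, age, and the configured [capacity_link()].
#'
#' @param config A [generator_config()].
#' @return A data frame of class `pab_cohort` with one row per subject:
#'   `subject_id`, `age` (years), `sex`, `gmfcs` (I/II/III), `gmfm66`, and
#'   the propensity columns `p_long`, `p_very_long`, `rate_mult`,
#'   `cadence_mean`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "pab_gencfg")) stop_pab("`config` must come from generator_config()")
  n <- config$n_subjects
  levels3 <- c("I", "II", "III")
  if (n == 0) {
    out <- data.frame(subject_id = character(), age = numeric(),
                      sex = character(), gmfcs = character(),
                      gmfm66 = numeric(), p_long = numeric(),
                      p_very_long = numeric(), rate_mult = numeric(),
                      cadence_mean = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("pab_cohort", "data.frame")
    return(out)
  }
  counts <- allocate_counts(n, config$gmfcs_weights)
  with_seed(derive_seed(config$seed, 0L), {
    gmfcs <- rep(levels3, counts)
    lo <- c(I = 55, II = 35, III = 20)[gmfcs]
    gmfm66 <- rnorm_trunc(n, config$gmfm_centers[gmfcs], config$gmfm_spread[gmfcs],
                          lower = lo, upper = 100)
    age <- runif(n, 7, 20)
    sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.6, 0.4))
    prop <- propensity(gmfm66, age, config)
    out <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                      age = age, sex = sex, gmfcs = gmfcs, gmfm66 = gmfm66,
                      prop, stringsAsFactors = FALSE)
    class(out) <- c("pab_cohort", "data.frame")
    out
  })
}

# Deterministic capacity -> latent behavior mapping.
propensity <- function(gmfm66, age, config) {
  link <- config$capacity_link
  z <- (gmfm66 - 75) / 15
  data.frame(
    p_long = plogis(link$strength_long * (gmfm66 - link$loc_long) / link$scale),
    p_very_long = plogis(link$strength_very_long * (gmfm66 - link$loc_very_long) / link$scale),
    rate_mult = exp(link$act_strength * z) *
      exp(-link$age_strength * (age - 13.5) / 6.5),
    cadence_mean = 100 + link$cad_slope * z)
}

#' Generate one subject's daily activity timeline
#'
#' Builds a semi-Markov day alternating lying/sitting, standing and walking
#' segments that tile `[0, day_length]` exactly. Sedentary and upright
#' durations are log-normal; baseline walking bouts are log-normal truncated
#' below 120 s, so walking bouts longer than 120 s (and 360 s) appear only
#' through explicit achievement draws whose probabilities are logistic in the
#' subject's capacity score. This gives the downstream ROC stage a clean,
#' recoverable ground truth. Cadence is normal (truncated positive) around
#' the subject's capacity-linked mean; static segments carry a body
#' acceleration intensity drawn from log-normal distributions.
#'
#' @param profile One row of a [generate_cohort()] data frame (or a list with
#'   the same fields).
#' @param config The [generator_config()] used for the cohort.
#' @param seed Integer seed for this subject's stream.
#' @return A data frame of class `pab_timeline` with columns `mode`
#'   (`lying_sitting`/`standing`/`walking`), `start`, `end` (s), `body_accel`
#'   (g, static modes), `n_steps` and `cadence` (walking), plus attributes
#'   `subject_id`, `day_length` and `achieved` (the ground-truth long-bout
#'   achievement flags).
#' @export
generate_timeline <- function(profile, config, seed) {
  if (!inherits(config, "pab_gencfg")) stop_pab("`config` must come from generator_config()")
  profile <- as.list(profile)
  day <- config$day_length
  with_seed(seed, {
    segs <- build_day_segments(profile, config, day)
    tl <- truncate_day(segs, day)
    attr(tl, "subject_id") <- profile$subject_id %||% "S000"
    attr(tl, "day_length") <- day
    attr(tl, "achieved") <- attr(segs, "achieved")
    class(tl) <- c("pab_timeline", "data.frame")
    validate_timeline(tl)
    tl
  })
}

# Draw the (over-long) raw segment chain for one day, achievement bouts
# already inserted; truncation to the day window happens afterwards.
build_day_segments <- function(profile, config, day) {
  rate <- config$walk_rate * (profile$rate_mult %||% 1)
  cadm <- profile$cadence_mean %||% 100
  n_cycles <- max(4L, ceiling(day / 500) + 8L)

  sed <- rlnorm(n_cycles, log(420), 0.9)
  up1 <- rlnorm(n_cycles, log(80), 0.8)
  kw <- if (rate > 0) rpois(n_cycles, rate) else integer(n_cycles)

  m <- sum(kw)
  wdur <- rlnorm_trunc(m, log(25), 0.7, lower = 6, upper = 119)
  wcad <- rnorm_trunc(m, cadm, 6, lower = 40, upper = 180)
  up2 <- rlnorm(m, log(40), 0.8)

  modes <- character(0); durs <- numeric(0); cads <- numeric(0)
  wi <- 0L
  for (ci in seq_len(n_cycles)) {
    modes <- c(modes, "lying_sitting", "standing")
    durs <- c(durs, sed[ci], up1[ci])
    cads <- c(cads, NA, NA)
    if (kw[ci] > 0) {
      for (j in seq_len(kw[ci])) {
        wi <- wi + 1L
        modes <- c(modes, "walking", "standing")
        durs <- c(durs, wdur[wi], up2[wi])
        cads <- c(cads, wcad[wi], NA)
      }
    }
    if (sum(durs) > day + 900) break
  }

  # Achievement draws: long (>120 s) and very long (>360 s) walking bouts.
  achieved <- c(long = FALSE, very_long = FALSE)
  if (rate > 0) {
    inj_dur <- numeric(0)
    if (runif(1) < (profile$p_long %||% 0.5)) {
      achieved["long"] <- TRUE
      inj_dur <- c(inj_dur, runif(1 + rpois(1, 0.6), 130, 350))
    }
    if (runif(1) < (profile$p_very_long %||% 0.5)) {
      achieved["very_long"] <- TRUE
      inj_dur <- c(inj_dur, runif(1, 380, 650))
    }
    for (d in inj_dur) {
      if (day < d + 60) next  # day too short to hold the bout
      starts <- cumsum(durs) - durs
      ok <- which(starts < day - d - 120)
      pos <- if (length(ok)) sample(length(ok), 1) else 1L
      cad <- rnorm_trunc(1, cadm, 6, lower = 40, upper = 180)
      modes <- append(modes, c("standing", "walking", "standing"), after = pos)
      durs <- append(durs, c(15, d, 15), after = pos)
      cads <- append(cads, c(NA, cad, NA), after = pos)
    }
  }

  out <- data.frame(mode = modes, dur = durs, cadence = cads,
                    stringsAsFactors = FALSE)
  attr(out, "achieved") <- achieved
  out
}

# Cut the raw chain at the day boundary, fill intensities and step counts,
# and guarantee every timeline invariant.
truncate_day <- function(segs, day) {
  ends <- cumsum(segs$dur)
  if (ends[length(ends)] < day) {  # extend coverage defensively
    segs <- rbind(segs, data.frame(mode = "lying_sitting",
                                   dur = day - ends[length(ends)] + 1,
                                   cadence = NA))
    ends <- cumsum(segs$dur)
  }
  keep <- which(ends - segs$dur < day)
  segs <- segs[keep, , drop = FALSE]
  ends <- ends[keep]
  starts <- ends - segs$dur
  ends[length(ends)] <- day
  dur <- ends - starts

  mode <- segs$mode
  cadence <- segs$cadence
  # A truncated tail walking segment may no longer hold 4 steps.
  last <- length(mode)
  if (mode[last] == "walking" && dur[last] * cadence[last] / 60 < 4) {
    mode[last] <- "standing"
    cadence[last] <- NA
  }

  n_steps <- rep(NA_real_, length(mode))
  w <- mode == "walking"
  if (any(w)) {
    n_steps[w] <- pmax(4, round(dur[w] * cadence[w] / 60))
    cadence[w] <- n_steps[w] / dur[w] * 60  # consistent steps/duration/cadence
  }
  body <- rep(NA_real_, length(mode))
  ls <- mode == "lying_sitting"
  st <- mode == "standing"
  if (any(ls)) body[ls] <- rlnorm_trunc(sum(ls), log(0.018), 0.45, upper = 0.15)
  if (any(st)) body[st] <- rlnorm_trunc(sum(st), log(0.03), 0.60, upper = 0.60)

  data.frame(mode = mode, start = starts, end = ends, body_accel = body,
             n_steps = n_steps, cadence = cadence, stringsAsFactors = FALSE)
}

#' Validate an activity timeline
#'
#' Checks the structural invariants: contiguous non-overlapping segments that
#' tile `[0, day_length]`, positive durations, walking segments with at least
#' 4 steps and positive cadence.
#'
#' @param tl A `pab_timeline` data frame.
#' @return `tl`, invisibly; errors describe the violated invariant.
#' @export
validate_timeline <- function(tl) {
  day <- attr(tl, "day_length")
  if (nrow(tl) == 0) stop_pab("timeline has no segments")
  if (abs(tl$start[1]) > 1e-9) stop_pab("timeline must start at 0")
  if (!is.null(day) && abs(tl$end[nrow(tl)] - day) > 1e-6)
    stop_pab("timeline must end at day_length")
  if (any(tl$end - tl$start <= 0)) stop_pab("every segment needs end > start")
  if (nrow(tl) > 1 && any(abs(tl$start[-1] - tl$end[-nrow(tl)]) > 1e-6))
    stop_pab("segments must be contiguous (no gaps or overlaps)")
  if (!all(tl$mode %in% c("lying_sitting", "standing", "walking")))
    stop_pab("unknown segment mode")
  w <- tl$mode == "walking"
  if (any(w)) {
    if (any(tl$n_steps[w] < 4)) stop_pab("walking segments need >= 4 steps")
    if (any(tl$cadence[w] <= 0)) stop_pab("walking cadence must be positive")
  }
  invisible(tl)
}

#' @export
print.pab_timeline <- function(x, ...) {
  if (!all(c("mode", "start", "end") %in% names(x))) return(NextMethod())
  day <- attr(x, "day_length")
  cat(sprintf("<pab_timeline> subject %s: %d segments over %.0f s\n",
              attr(x, "subject_id") %||% "?", nrow(x), day %||% max(x$end)))
  tot <- tapply(x$end - x$start, x$mode, sum)
  for (m in names(tot))
    cat(sprintf("  %-13s %8.0f s (%.1f%%)\n", m, tot[[m]],
                100 * tot[[m]] / sum(tot)))
  invisible(x)
}

#' Read and write cohort and timeline tables
#'
#' Plain tab-delimited text, one subject per row for cohorts and one segment
#' per row for timelines (`subject_id`, `mode`, `start_s`, `end_s`,
#' `body_accel_g`, `n_steps`, `cadence_spm`; fields empty where not
#' applicable). Detected and ground-truth timelines share this format and are
#' interchangeable downstream.
#'
#' @param cohort,timelines Objects to write.
#' @param path File path.
#' @name cohort_io
#' @export
write_cohort <- function(cohort, path) {
  data.table::fwrite(as.data.frame(cohort), path, sep = "\t", na = "")
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_cohort <- function(path) {
  out <- as.data.frame(data.table::fread(path, sep = "\t"))
  class(out) <- c("pab_cohort", "data.frame")
  out
}

#' @rdname cohort_io
#' @export
write_timelines <- function(timelines, path) {
  if (inherits(timelines, "pab_timeline")) timelines <- list(timelines)
  rows <- lapply(timelines, function(tl) {
    data.frame(subject_id = attr(tl, "subject_id") %||% "S000",
               mode = tl$mode, start_s = tl$start, end_s = tl$end,
               body_accel_g = tl$body_accel, n_steps = tl$n_steps,
               cadence_spm = tl$cadence, stringsAsFactors = FALSE)
  })
  data.table::fwrite(do.call(rbind, rows), path, sep = "\t", na = "")
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_timelines <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  split_rows <- split(df, df$subject_id)
  out <- lapply(split_rows, function(d) {
    tl <- data.frame(mode = d$mode, start = d$start_s, end = d$end_s,
                     body_accel = d$body_accel_g, n_steps = d$n_steps,
                     cadence = d$cadence_spm, stringsAsFactors = FALSE)
    tl <- tl[order(tl$start), , drop = FALSE]
    rownames(tl) <- NULL
    attr(tl, "subject_id") <- d$subject_id[1]
    attr(tl, "day_length") <- max(tl$end)
    class(tl) <- c("pab_timeline", "data.frame")
    tl
  })
  out[order(names(out))]
}
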