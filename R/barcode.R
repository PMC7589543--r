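#' Classify activity segments into the 22 barcode states
#'
#' One state per segment, combining activity type, bout duration and
#' intensity. Lying/sitting maps to states 1-2 by mean body acceleration;
#' standing to states 3-6 by body acceleration; walking/running to states
#' 7-22 by the duration bin (short / medium / long / very long, half-open
#' edges at 60, 120, 360 s) crossed with the cadence bin (slow / moderate /
#' fast / very fast, half-open edges at 70, 100, 130 steps/min). The bins are
#' contiguous and half-open, so the classifier is total and single-valued:
#' the very-long slow combination is state 19, long moderate is state 16,
#' low-intensity lying/sitting is state 1.
#'
#' @param mode Character vector: `lying_sitting`, `standing` or `walking`.
#' @param duration Segment duration(s), s.
#' @param intensity Mean body acceleration, g (static modes).
#' @param cadence Steps/min (walking).
#' @param params [barcode_params()].
#' @return Integer state(s) in 1..22.
#' @export
classify_segment <- function(mode, duration, intensity = NA, cadence = NA,
                             params = barcode_params()) {
  n <- max(length(mode), length(duration), length(intensity), length(cadence))
  mode <- rep_len(mode, n); duration <- rep_len(duration, n)
  intensity <- rep_len(intensity, n); cadence <- rep_len(cadence, n)
  if (!all(mode %in% c("lying_sitting", "standing", "walking")))
    stop_pab("unknown mode(s): %s",
             paste(setdiff(unique(mode), c("lying_sitting", "standing", "walking")), collapse = ", "))
  if (any(!is.finite(duration) | duration <= 0))
    stop_pab("`duration` must be positive")
  out <- integer(n)
  ls <- mode == "lying_sitting"
  st <- mode == "standing"
  wk <- mode == "walking"
  if (any(ls)) {
    if (anyNA(intensity[ls])) stop_pab("lying/sitting segments need an intensity")
    out[ls] <- ifelse(intensity[ls] < params$lying_edge, 1L, 2L)
  }
  if (any(st)) {
    if (anyNA(intensity[st])) stop_pab("standing segments need an intensity")
    out[st] <- 3L + findInterval(intensity[st], params$standing_edges)
  }
  if (any(wk)) {
    if (anyNA(cadence[wk])) stop_pab("walking segments need a cadence")
    db <- findInterval(duration[wk], params$duration_edges)
    cb <- findInterval(cadence[wk], params$cadence_edges)
    out[wk] <- 7L + 4L * db + cb
  }
  out
}

#' Symbolize a timeline into a barcode sequence
#'
#' Classifies every segment once (using its full duration) and writes the
#' resulting state into every epoch the segment covers; an epoch split
#' between segments goes to the segment covering the majority of it.
#'
#' @param timeline A `pab_timeline`.
#' @param params [barcode_params()].
#' @return An integer vector of class `pab_barcode` (codes in 1..22) with
#'   attributes `epoch`, `subject_id` and `total_time`.
#' @export
to_barcode <- function(timeline, params = barcode_params()) {
  validate_timeline(timeline)
  day <- attr(timeline, "day_length") %||% max(timeline$end)
  ne <- round(day / params$epoch)
  states <- classify_segment(timeline$mode, timeline$end - timeline$start,
                             timeline$body_accel, timeline$cadence, params)
  codes <- integer(ne)
  best <- numeric(ne)
  for (i in seq_len(nrow(timeline))) {
    cov <- epoch_overlap(timeline$start[i], timeline$end[i], ne, params$epoch)
    take <- cov$w > best[cov$idx]
    codes[cov$idx[take]] <- states[i]
    best[cov$idx[take]] <- cov$w[take]
  }
  structure(codes, epoch = params$epoch,
            subject_id = attr(timeline, "subject_id") %||% "S000",
            total_time = ne * params$epoch,
            class = "pab_barcode")
}

#' Map barcode states to the six physical activity states
#'
#' PAS collapse intensity but keep type and duration: states 1-2 (lying or
#' sitting) are PAS 1, 3-6 (standing) PAS 2, then each walking duration band
#' forms one PAS: 7-10 -> 3 (active short), 11-14 -> 4 (active medium),
#' 15-18 -> 5 (active long), 19-22 -> 6 (active very long).
#'
#' @param state Integer state(s) in 1..22.
#' @return Integer PAS in 1..6.
#' @export
map_pas <- function(state) {
  if (anyNA(state) || any(state < 1 | state > 22 | state != round(state)))
    stop_pab("states must be integers in 1..22")
  pas <- rep(3:6, each = 4)
  c(1L, 1L, 2L, 2L, 2L, 2L, pas)[state]
}

#' Summarize a barcode into state and PAS time fractions
#'
#' Fractions are epoch counts over total epochs, in percent of the monitored
#' time. `%activity` is the time in barcode states 3-22 (everything except
#' lying/sitting). Achiever flags per PAS are an exact zero test on the
#' accumulated epoch counts, not on rounded percentages.
#'
#' @param barcode A `pab_barcode`.
#' @return A list of class `pab_pasummary`: `state_fractions` (22),
#'   `pas_fractions` (6), `pas_3_6`, `pas_4_6`, `pct_activity`, `achiever`
#'   (6 logicals), `total_time`, `subject_id`.
#' @export
pa_summary <- function(barcode) {
  codes <- unclass(barcode)
  if (!length(codes)) stop_pab("empty barcode")
  counts <- tabulate(codes, nbins = 22)
  n <- length(codes)
  state_fractions <- 100 * counts / n
  pas_counts <- as.numeric(tapply(counts, map_pas(1:22), sum))
  pas_fractions <- 100 * pas_counts / n
  structure(list(
    subject_id = attr(barcode, "subject_id") %||% "S000",
    state_fractions = state_fractions,
    pas_fractions = pas_fractions,
    pas_3_6 = sum(pas_fractions[3:6]),
    pas_4_6 = sum(pas_fractions[4:6]),
    pct_activity = sum(state_fractions[3:22]),
    achiever = pas_counts > 0,
    total_time = n * (attr(barcode, "epoch") %||% 1)),
    class = "pab_pasummary")
}

#' @export
summary.pab_barcode <- function(object, ...) pa_summary(object)

#' @export
print.pab_pasummary <- function(x, ...) {
  cat(sprintf("<pab_pasummary> subject %s (%.0f s monitored)\n",
              x$subject_id, x$total_time))
  lbl <- c("1 lying/sitting", "2 standing", "3 active short", "4 active medium",
           "5 active long", "6 active very long")
  for (k in 1:6)
    cat(sprintf("  PAS %-18s %6.2f%%  %s\n", lbl[k], x$pas_fractions[k],
                if (x$achiever[k]) "achiever" else "non-achiever"))
  cat(sprintf("  PAS 3-6 %6.2f%%   PAS 4-6 %6.2f%%   %%activity %6.2f%%\n",
              x$pas_3_6, x$pas_4_6, x$pct_activity))
  invisible(x)
}

#' Fixed 22-color barcode palette
#'
#' Greys for lying/sitting, greens for standing intensities, and one hue per
#' walking duration band with lightness encoding cadence; all 22 colors are
#' distinct.
#'
#' @return Character vector of 22 colors named by state.
#' @export
barcode_palette <- function() {
  hues <- c(135, 250, 290, 45, 10)  # standing, then one hue per duration band
  shades <- function(h) grDevices::hcl(h, c = 65, l = c(78, 62, 46, 30))
  pal <- c("grey85", "grey60", as.vector(vapply(hues, shades, character(4))))
  names(pal) <- as.character(1:22)
  pal
}

#' Plot a barcode as a horizontal color stripe
#'
#' @param x A `pab_barcode`.
#' @param y Unused.
#' @param ... Passed to [graphics::image()].
#' @export
plot.pab_barcode <- function(x, y, ...) {
  codes <- unclass(x)
  image(z = matrix(codes, ncol = 1), zlim = c(0.5, 22.5),
        col = barcode_palette(), breaks = seq(0.5, 22.5, by = 1),
        axes = FALSE, xlab = "time", ylab = "",
        main = attr(x, "subject_id"), ...)
  ax <- pretty(c(0, length(codes) * (attr(x, "epoch") %||% 1) / 3600))
  axis(1, at = ax / (length(codes) * (attr(x, "epoch") %||% 1) / 3600),
       labels = paste0(ax, "h"))
  invisible(x)
}

#' Render a barcode stripe to an image file
#'
#' @param barcode A `pab_barcode`.
#' @param path Output PNG path.
#' @param width,height Image size in pixels.
#' @export
render_barcode_image <- function(barcode, path, width = max(400, length(barcode)),
                                 height = 120) {
  grDevices::png(path, width = width, height = height)
  op <- par(mar = c(2.5, 0.5, 1.5, 0.5))
  on.exit({ par(op); dev.off() }, add = TRUE)
  plot(barcode)
  invisible(path)
}

#' Read and write barcode sequences
#'
#' One line per subject: `subject_id`, epoch length, then the code series
#' space-separated.
#'
#' @param barcodes A `pab_barcode` or list of them.
#' @param path File path.
#' @name barcode_io
#' @export
write_barcodes <- function(barcodes, path) {
  if (inherits(barcodes, "pab_barcode")) barcodes <- list(barcodes)
  lines <- vapply(barcodes, function(b) {
    paste(attr(b, "subject_id") %||% "S000", attr(b, "epoch") %||% 1,
          paste(unclass(b), collapse = " "), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname barcode_io
#' @export
read_barcodes <- function(path) {
  lines <- readLines(path)
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    codes <- as.integer(strsplit(parts[3], " ", fixed = TRUE)[[1]])
    structure(codes, epoch = as.numeric(parts[2]), subject_id = parts[1],
              total_time = length(codes) * as.numeric(parts[2]),
              class = "pab_barcode")
  })
  names(out) <- vapply(out, attr, character(1), "subject_id")
  out
}
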