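# Pattern-complexity metrics of a barcode sequence: normalized information
# entropy, sample entropy on symbols, Lempel-Ziv complexity, and the
# composite scores CC and CDS.

as_codes <- function(x) {
  codes <- as.integer(unclass(x))
  if (!length(codes)) stop_pab("empty barcode")
  if (anyNA(codes) || any(codes < 1)) stop_pab("barcode codes must be positive integers")
  codes
}

#' Normalized information entropy of a barcode
#'
#' Shannon entropy of the empirical state distribution divided by `log(K)`
#' with the design alphabet `K = 22`, so a subject using few states scores
#' low regardless of sequence order, and equal time in all 22 states scores
#' exactly 1. Depends only on the state histogram (permutation invariant).
#'
#' @param barcode A `pab_barcode` or integer vector of codes.
#' @param params [complexity_params()].
#' @return Hn in `[0, 1]`.
#' @export
entropy_norm <- function(barcode, params = complexity_params()) {
  codes <- as_codes(barcode)
  p <- tabulate(codes, nbins = max(params$K, max(codes))) / length(codes)
  p <- p[p > 0]
  h <- -sum(p * log(p))
  min(1, h / log(params$K))
}

#' Normalized Lempel-Ziv complexity of a barcode
#'
#' Counts the phrases of the LZ76 exhaustive-history parse (the number of new
#' sub-patterns discovered as the sequence progresses) and normalizes by the
#' asymptotic phrase count of a maximally random sequence over the design
#' alphabet: `LZC = c(n) * log_K(n) / n`, clamped to `[0, 1]`. A constant
#' sequence parses into 2 phrases and scores near 0; i.i.d. uniform
#' sequences over the full alphabet approach 1.
#'
#' @inheritParams entropy_norm
#' @return LZC in `[0, 1]`.
#' @export
lz_complexity_norm <- function(barcode, params = complexity_params()) {
  codes <- as_codes(barcode)
  n <- length(codes)
  if (n < 2) stop_pab("need at least 2 symbols for LZC")
  c_n <- lz76_phrase_count(codes)
  min(1, c_n * (log(n) / log(params$K)) / n)
}

#' @rdname lz_complexity_norm
#' @details `lz76_phrases()` exposes the raw phrase count of the
#'   exhaustive-history parse.
#' @export
lz76_phrases <- function(barcode) lz76_phrase_count(as_codes(barcode))

#' Normalized sample entropy of a barcode
#'
#' Sample entropy with template length `m` and exact symbol matching (the
#' tolerance concept of continuous-valued SampEn collapses for categorical
#' data): `SampEn = -log(A/B)` where `B` counts matching pairs of
#' `m`-templates and `A` matching pairs of `(m+1)`-templates, self-matches
#' excluded, both over template positions `1..n-m`. The unbounded value is
#' mapped to `[0, 1]` by the finite-sample maximum `log(B)` (attained when
#' only a single template pair still matches at length `m+1`); when `A = 0`
#' the value is capped at that maximum, i.e. 1. Perfectly regular input
#' (constant or strictly periodic) scores 0.
#'
#' @inheritParams entropy_norm
#' @return SampEn in `[0, 1]`.
#' @export
sample_entropy_norm <- function(barcode, params = complexity_params()) {
  codes <- as_codes(barcode)
  n <- length(codes)
  m <- params$sampen_m
  if (n <= m + 1) stop_pab("need more than m + 1 = %d symbols for SampEn", m + 1)
  B <- template_pairs(codes, m, limit = n - m)
  A <- template_pairs(codes, m + 1, limit = n - m)
  if (B == 0) return(1)
  log_max <- log(B)
  raw <- if (A > 0) -log(A / B) else Inf
  if (raw <= 0) return(0)
  if (log_max <= 0) return(1)  # B = 1 and that pair broke at m+1
  min(1, raw / log_max)
}

# Number of unordered pairs of equal length-m templates among positions
# 1..limit (default n - m + 1), via integer gram hashing.
template_pairs <- function(codes, m, limit = length(codes) - m + 1) {
  if (limit < 2) return(0)
  K1 <- max(codes) + 1
  idx <- seq_len(limit)
  gram <- codes[idx]
  if (m > 1) {
    for (j in seq_len(m - 1)) gram <- gram * K1 + codes[idx + j]
  }
  cnt <- table(gram)
  sum(cnt * (cnt - 1) / 2)
}

#' Percentage of monitored time spent active
#'
#' Share of epochs in barcode states 3-22, i.e. everything except
#' lying/sitting (standing counts as activity).
#'
#' @inheritParams entropy_norm
#' @return Percent in `[0, 100]`.
#' @export
percent_activity <- function(barcode) {
  codes <- as_codes(barcode)
  100 * mean(codes >= 3)
}

#' Composite complexity and composite deterministic score
#'
#' `CC = Hn + SampEn + LZC` (range 0-3) and `CDS = CC * %activity` with
#' `%activity` on the 0-100 scale, so daily CDS values land in the same
#' magnitude range as published cohort tables (roughly 3-25).
#'
#' @param Hn,SampEn,LZC Normalized metrics in `[0, 1]`.
#' @param pct_activity Percent of time active, `[0, 100]`.
#' @return Named list with `CC` and `CDS`.
#' @export
composite_scores <- function(Hn, SampEn, LZC, pct_activity) {
  vals <- c(Hn = Hn, SampEn = SampEn, LZC = LZC)
  if (any(vals < -1e-12 | vals > 1 + 1e-12))
    stop_pab("Hn, SampEn and LZC must lie in [0, 1]")
  if (pct_activity < -1e-12 || pct_activity > 100 + 1e-9)
    stop_pab("`pct_activity` must lie in [0, 100]")
  CC <- Hn + SampEn + LZC
  list(CC = CC, CDS = CC * pct_activity)
}

#' All pattern-complexity metrics of one barcode
#'
#' @inheritParams entropy_norm
#' @return A list of class `pab_complexity`: `Hn`, `SampEn`, `LZC`, `CC`,
#'   `pct_activity`, `CDS`, `subject_id`.
#' @export
complexity_metrics <- function(barcode, params = complexity_params()) {
  Hn <- entropy_norm(barcode, params)
  SampEn <- sample_entropy_norm(barcode, params)
  LZC <- lz_complexity_norm(barcode, params)
  act <- percent_activity(barcode)
  cs <- composite_scores(Hn, SampEn, LZC, act)
  structure(list(subject_id = attr(barcode, "subject_id") %||% "S000",
                 Hn = Hn, SampEn = SampEn, LZC = LZC, CC = cs$CC,
                 pct_activity = act, CDS = cs$CDS),
            class = "pab_complexity")
}

#' @export
print.pab_complexity <- function(x, ...) {
  cat(sprintf("<pab_complexity> subject %s\n", x$subject_id))
  cat(sprintf("  Hn %.4f  SampEn %.4f  LZC %.4f  ->  CC %.4f\n",
              x$Hn, x$SampEn, x$LZC, x$CC))
  cat(sprintf("  %%activity %.2f  ->  CDS %.3f\n", x$pct_activity, x$CDS))
  invisible(x)
}
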