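# Independent oracles and small fixture builders shared across tests.
# The oracles are deliberately naive re-derivations from first principles and
# never call the implementation paths they are used to check.

# Brute-force LZ76 exhaustive-history parse: a phrase is the shortest
# extension of the remaining suffix that is not a substring of everything
# seen before it (self-overlap allowed); the final phrase may be reproducible.
lz76_oracle <- function(s) {
  ch <- paste(letters[s], collapse = "")
  n <- nchar(ch)
  c <- 0L; p <- 1L
  while (p <= n) {
    q <- p
    repeat {
      if (q > n) { q <- n; break }
      if (!grepl(substr(ch, p, q), substr(ch, 1, q - 1), fixed = TRUE)) break
      q <- q + 1L
    }
    c <- c + 1L
    p <- q + 1L
  }
  c
}

# Exhaustive-threshold ROC oracle. Positives are non-achievers, predicted
# positive when score < threshold; AUC by direct pair counting.
roc_oracle <- function(scores, achiever) {
  pos <- scores[!achiever]; neg <- scores[achiever]
  pairs <- outer(pos, neg, function(p, n) (p < n) + 0.5 * (p == n))
  auc <- mean(pairs)
  ss <- sort(unique(scores))
  cand <- if (length(ss) > 1) (ss[-length(ss)] + ss[-1]) / 2 else numeric(0)
  best <- list(youden = -Inf, cutoff = NA_real_, sens = NA_real_, spec = NA_real_)
  for (c0 in cand) {   # ascending, first max = lowest threshold on ties
    sens <- mean(pos < c0); spec <- mean(neg >= c0)
    j <- sens + spec - 1
    if (j > best$youden + 1e-12) best <- list(youden = j, cutoff = c0, sens = sens, spec = spec)
  }
  list(auc = auc, youden = best$youden, cutoff = best$cutoff,
       sensitivity = best$sens, specificity = best$spec)
}

# Hand-built timeline: modes/durations (+ cadence for walking), tiling [0, sum).
mk_timeline <- function(modes, durs, cadence = NULL, body = NULL,
                        subject_id = "T01") {
  ends <- cumsum(durs)
  n <- length(modes)
  cad <- rep(NA_real_, n); ba <- rep(NA_real_, n); steps <- rep(NA_real_, n)
  if (!is.null(cadence)) cad <- cadence
  if (!is.null(body)) ba <- body
  w <- modes == "walking"
  ba[!w & is.na(ba)] <- 0.02
  steps[w] <- pmax(4, round(durs[w] * cad[w] / 60))
  tl <- data.frame(mode = modes, start = ends - durs, end = ends,
                   body_accel = ba, n_steps = steps, cadence = cad,
                   stringsAsFactors = FALSE)
  attr(tl, "subject_id") <- subject_id
  attr(tl, "day_length") <- ends[n]
  class(tl) <- c("pab_timeline", "data.frame")
  tl
}

# Random barcode generator mixing constant, periodic and i.i.d. sequences.
random_barcodes <- function(n_seq, len_range = c(100, 3000), seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_seq), function(i) {
    n <- sample(len_range[1]:len_range[2], 1)
    kind <- sample(c("iid", "const", "periodic", "blocky"), 1,
                   prob = c(0.55, 0.1, 0.15, 0.2))
    switch(kind,
      iid = sample(1:22, n, replace = TRUE),
      const = rep(sample(1:22, 1), n),
      periodic = rep_len(sample(1:22, sample(2:6, 1)), n),
      blocky = {
        r <- sample(1:22, 60, replace = TRUE)
        rep_len(rep(r, times = sample(5:80, 60, replace = TRUE)), n)
      })
  })
}

small_cfg <- function(n = 4, day = 1200, seed = 7, ...) {
  generator_config(n_subjects = n, day_length = day, seed = seed, ...)
}
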