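# Cohort statistics: descriptives, normality screen, Spearman/Holm battery,
# partial correlations, achiever split, ROC with Youden cut-off.

mk_tab <- function(df) {
  class(df) <- c("pab_cohort_table", "data.frame")
  df
}

test_that("descriptive table computes type-7 median and IQR per group", {
  tab <- mk_tab(data.frame(gmfcs = rep("I", 5), pas1 = 1:5))
  d <- descriptive_table(tab, metrics = "pas1")
  expect_equal(d$I_median, 3)
  expect_equal(d$I_q1, 2)
  expect_equal(d$I_q3, 4)
  one <- descriptive_table(mk_tab(data.frame(gmfcs = "II", pas1 = 7)), metrics = "pas1")
  expect_equal(c(one$II_median, one$II_q1, one$II_q3), c(7, 7, 7))
  d2 <- descriptive_table(tab, metrics = c("pas1", "missing_metric"))
  expect_equal(d2$metric, "pas1")  # row set matches available metrics
})

test_that("normality screen accepts normal samples, rejects exponential, flags constants", {
  null_ok <- vapply(1:30, function(i) {
    set.seed(1000 + i)
    normality_screen(data.frame(x = rnorm(500)), "x")$p > 0.05
  }, logical(1))
  expect_gte(mean(null_ok), 0.9)
  alt_rej <- vapply(1:30, function(i) {
    set.seed(2000 + i)
    normality_screen(data.frame(x = rexp(500)), "x")$p < 0.05
  }, logical(1))
  expect_gte(mean(alt_rej), 0.9)
  flat <- normality_screen(data.frame(x = rep(3, 10)), "x")
  expect_true(flat$degenerate)
})

test_that("correlation bands follow the fixed cut-points", {
  expect_equal(interpret_band(0.619), "moderate to good")
  expect_equal(interpret_band(-0.446), "fair")
  expect_equal(interpret_band(0), "no to little")
  expect_equal(interpret_band(c(0.24, 0.25, 0.75, -1)),
               c("no to little", "fair", "very good to excellent",
                 "very good to excellent"))
  expect_error(interpret_band(1.2), "-1, 1")
})

test_that("the battery has 7 + 4 tests, Holm within family, N.A. exclusions", {
  set.seed(42)
  n <- 25
  tab <- mk_tab(data.frame(
    gmfm66 = runif(n, 40, 100), age = runif(n, 7, 20),
    pas1 = runif(n, 40, 90), pas2 = runif(n, 5, 30), pas3 = runif(n, 1, 10),
    pas4 = runif(n, 0, 3), pas5 = runif(n, 0, 2),
    pas_3_6 = runif(n, 2, 14), pas_4_6 = runif(n, 0, 5),
    Hn = runif(n, 0.1, 0.4), SampEn = runif(n, 0, 0.05),
    LZC = runif(n, 0.05, 0.12), CDS = runif(n, 2, 25)))
  res <- spearman_battery(tab)
  expect_equal(sum(res$family == "PAS"), 7)
  expect_equal(sum(res$family == "complexity"), 4)
  expect_true(all(res$p_adj >= res$p_raw - 1e-12, na.rm = TRUE))
  # Holm is applied separately: the smallest PAS p is multiplied by at most 7
  pas <- res[res$family == "PAS", ]
  expect_equal(min(pas$p_adj), min(1, min(pas$p_raw) * 7), tolerance = 1e-9)

  # a variable achieved by almost nobody is excluded as N.A.
  tab$pas5 <- c(0.4, rep(0, n - 1))
  res2 <- spearman_battery(tab)
  row <- res2[res2$variable == "pas5", ]
  expect_true(is.na(row$rho) && row$band == "N.A.")
  expect_match(row$note, "excluded")
  # and it does not consume a Holm slot (adjustment over 6, not 7)
  pas2 <- res2[res2$family == "PAS" & !is.na(res2$p_raw), ]
  expect_equal(min(pas2$p_adj), min(1, min(pas2$p_raw) * 6), tolerance = 1e-9)
})

test_that("perfect monotone association gives rho 1; tiny n uses the exact null", {
  tab <- mk_tab(data.frame(gmfm66 = 1:20, y = (1:20)^2))
  st <- pabarcode:::spearman_test(tab$gmfm66, tab$y)
  expect_equal(st$rho, 1)
  expect_lt(st$p, 1e-10)
  # n = 6: p from full permutation enumeration, never below 2/6!
  st2 <- pabarcode:::spearman_test(1:6, c(2, 1, 4, 3, 6, 5))
  perms <- pabarcode:::all_permutations(6)
  null_rho <- as.vector(cor(rank(1:6), matrix(rank(c(2, 1, 4, 3, 6, 5))[perms], nrow = 6)))
  expect_equal(st2$p, mean(abs(null_rho) >= abs(st2$rho) - 1e-12))
  expect_error(pabarcode:::spearman_test(1:3, 3:1), "n >= 4")
})

test_that("raw type-I error is near alpha and Holm controls the family", {
  set.seed(77)
  m <- 400
  raw_rej <- logical(m); fam_rej <- logical(m)
  for (i in 1:m) {
    x <- rnorm(25)
    ys <- matrix(rnorm(25 * 7), 25)
    ps <- apply(ys, 2, function(y) pabarcode:::spearman_test(x, y)$p)
    raw_rej[i] <- ps[1] < 0.05
    fam_rej[i] <- any(p.adjust(ps, "holm") < 0.05)
  }
  expect_gt(mean(raw_rej), 0.02)
  expect_lt(mean(raw_rej), 0.09)
  expect_lte(mean(fam_rej), 0.07)
})

test_that("partial correlation removes the control's contribution", {
  set.seed(8)
  n <- 500
  z <- rnorm(n)
  x <- rnorm(n); y <- rnorm(n) + 0.6 * x
  plain <- pabarcode:::spearman_test(x, y)$rho
  part <- partial_spearman(data.frame(x = x, y = y, z = z), "x", "y", "z")
  expect_lt(abs(part$rho - plain), 0.05)   # independent control changes little

  conf <- partial_spearman(data.frame(x = z + rnorm(n, sd = 1e-9), y = z, z = z),
                           "x", "y", "z")
  expect_lt(abs(conf$rho), 0.05)           # y = control exactly

  # purely control-mediated association attenuates toward zero
  x2 <- z + rnorm(n, sd = 0.7)
  y2 <- z + rnorm(n, sd = 0.7)
  plain2 <- pabarcode:::spearman_test(x2, y2)$rho
  part2 <- partial_spearman(data.frame(x = x2, y = y2, z = z), "x", "y", "z")
  expect_lt(abs(part2$rho), abs(plain2) / 2)
  expect_warning(
    partial_spearman(data.frame(x = rnorm(20), y = rnorm(20), z = rep(1, 20)),
                     "x", "y", "z"), "constant control")
})

test_that("achiever split is an exact zero test", {
  tab <- mk_tab(data.frame(pas5 = c(0, 0.2, 0, 5e-9, 3.5)))
  expect_equal(split_achievers(tab, 5), c(FALSE, TRUE, FALSE, TRUE, TRUE))
  # cohort-shaped case: 3 achievers among 25
  tab2 <- mk_tab(data.frame(pas6 = c(rep(0, 22), 0.3, 0.7, 1.2)))
  lab <- split_achievers(tab2, 6)
  expect_equal(sum(!lab), 22)  # 22 non-achievers = positives
  expect_equal(sum(lab), 3)
})

test_that("ROC separates perfectly separable classes with a mid-gap cut-off", {
  scores <- c(40, 45, 50, 55, 80, 85, 90, 95)
  ach <- scores > 70
  r <- roc_cutoff(scores, ach, n_perm = 2000, seed = 1)
  expect_equal(r$auc, 1)
  expect_equal(r$youden, 1)
  expect_equal(r$cutoff, (55 + 80) / 2)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_error(roc_cutoff(scores, rep(TRUE, 8)), "both classes")
})

test_that("Youden identity holds at every threshold, recomputed from confusion counts", {
  set.seed(12)
  scores <- sample(30:100, 25, replace = TRUE)
  ach <- runif(25) < plogis((scores - 70) / 8)
  if (length(unique(ach)) < 2) ach[1:3] <- c(TRUE, FALSE, TRUE)
  r <- roc_cutoff(scores, ach, n_perm = 500, seed = 3)
  thr <- r$all_thresholds
  pos <- scores[!ach]; neg <- scores[ach]
  for (i in seq_len(nrow(thr))) {
    c0 <- thr$threshold[i]
    tp <- sum(pos < c0); fn <- sum(pos >= c0)
    tn <- sum(neg >= c0); fp <- sum(neg < c0)
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    expect_equal(thr$sensitivity[i], sens)
    expect_equal(thr$specificity[i], spec)
    expect_equal(thr$youden[i], sens + spec - 1)
  }
})

test_that("ROC AUC, Youden and cut-off match the exhaustive oracle on small instances", {
  set.seed(21)
  for (i in 1:120) {
    n <- sample(6:12, 1)
    scores <- sample(1:15, n, replace = TRUE)   # ties on purpose
    ach <- runif(n) < 0.5
    if (all(ach) || all(!ach)) ach[1] <- !ach[1]
    r <- roc_cutoff(scores, ach, alpha = 2, n_perm = 50, seed = i)
    o <- roc_oracle(scores, ach)
    expect_equal(r$auc, o$auc)
    expect_equal(r$youden, o$youden)
    expect_equal(r$cutoff, o$cutoff)
    expect_equal(r$sensitivity, o$sensitivity)
    expect_equal(r$specificity, o$specificity)
  }
})

test_that("AUC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  scores <- rnorm(40, 70, 10)
  ach <- runif(40) < plogis((scores - 70) / 5)
  if (length(unique(ach)) < 2) ach[1:2] <- c(TRUE, FALSE)
  r <- roc_cutoff(scores, ach, alpha = 2, n_perm = 100, seed = 2)
  ref <- suppressMessages(pROC::auc(pROC::roc(response = !ach, predictor = scores,
                                              direction = ">")))
  # orientation: positives (non-achievers) have low scores
  expect_equal(r$auc, as.numeric(ref), tolerance = 1e-9)
})

test_that("null labels suppress the cut-off at about the nominal rate", {
  set.seed(55)
  suppressed <- vapply(1:100, function(i) {
    scores <- rnorm(25, 70, 12)
    ach <- sample(c(TRUE, FALSE), 25, replace = TRUE)
    if (all(ach) || all(!ach)) ach[1] <- !ach[1]
    is.na(roc_cutoff(scores, ach, n_perm = 400, seed = i)$cutoff)
  }, logical(1))
  expect_gte(mean(suppressed), 0.88)
})

test_that("run_analysis assembles every stage and stays reproducible", {
  cfg <- generator_config(n_subjects = 30, day_length = 6000, seed = 23)
  co <- generate_cohort(cfg)
  tls <- lapply(seq_len(nrow(co)), function(i)
    generate_timeline(co[i, ], cfg, seed = 600 + i))
  bcs <- lapply(tls, to_barcode)
  sms <- lapply(bcs, pa_summary); names(sms) <- co$subject_id
  cxs <- lapply(bcs, complexity_metrics); names(cxs) <- co$subject_id
  tab <- build_cohort_table(co, sms, cxs)
  a1 <- run_analysis(tab, n_perm = 500, seed = 77)
  a2 <- run_analysis(tab, n_perm = 500, seed = 77)
  expect_identical(a1$correlations, a2$correlations)
  expect_identical(lapply(a1$roc, `[[`, "auc_p"), lapply(a2$roc, `[[`, "auc_p"))
  expect_s3_class(a1$descriptives, "data.frame")
  expect_true(all(c("PAS", "complexity") %in% a1$correlations$family))
})
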