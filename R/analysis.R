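# Cohort-level capacity-vs-performance battery: descriptives, normality
# screening, Spearman/Holm correlation families, age-partialled rank
# correlations, achiever/non-achiever ROC with Youden-optimal cut-offs.

#' Join subject profiles, PAS summaries and complexity metrics
#'
#' @param cohort A `pab_cohort` data frame.
#' @param summaries Named list of `pab_pasummary` (names = subject ids).
#' @param metrics Named list of `pab_complexity`.
#' @return A data frame of class `pab_cohort_table`, one row per subject with
#'   columns `pas1..pas6`, `pas_3_6`, `pas_4_6`, `Hn`, `SampEn`, `LZC`, `CC`,
#'   `pct_activity`, `CDS` joined to the profile columns.
#' @export
build_cohort_table <- function(cohort, summaries, metrics = NULL) {
  ids <- cohort$subject_id
  if (anyDuplicated(ids)) stop_pab("subject ids must be unique")
  srows <- lapply(ids, function(id) {
    s <- summaries[[id]]
    if (is.null(s)) stop_pab("no PAS summary for subject %s", id)
    stats::setNames(as.list(c(s$pas_fractions, s$pas_3_6, s$pas_4_6)),
                    c(paste0("pas", 1:6), "pas_3_6", "pas_4_6"))
  })
  out <- cbind(as.data.frame(cohort),
               do.call(rbind, lapply(srows, as.data.frame)))
  if (!is.null(metrics)) {
    mrows <- lapply(ids, function(id) {
      m <- metrics[[id]]
      if (is.null(m)) stop_pab("no complexity metrics for subject %s", id)
      as.data.frame(m[c("Hn", "SampEn", "LZC", "CC", "pct_activity", "CDS")])
    })
    out <- cbind(out, do.call(rbind, mrows))
  }
  rownames(out) <- NULL
  class(out) <- c("pab_cohort_table", "data.frame")
  out
}

#' Grouped descriptive summary (median and IQR)
#'
#' Median, first and third quartile for every metric, per GMFCS level and
#' overall. Quartiles use linear interpolation (type-7), the convention
#' echoed in the run metadata.
#'
#' @param tab A `pab_cohort_table`.
#' @param metrics Character vector of columns to summarize, in output order.
#' @param by Grouping column (default `gmfcs`).
#' @return A data frame: one row per metric, columns
#'   `<level>_median`, `<level>_q1`, `<level>_q3` per group plus `all_*`.
#' @export
descriptive_table <- function(tab,
                              metrics = c("Hn", "SampEn", "LZC", "CDS",
                                          paste0("pas", 1:6), "pas_3_6", "pas_4_6"),
                              by = "gmfcs") {
  metrics <- intersect(metrics, names(tab))
  groups <- c(split(tab, tab[[by]]), list(all = tab))
  empty <- names(groups)[vapply(groups, nrow, integer(1)) == 0]
  if (length(empty)) warning("empty group(s): ", paste(empty, collapse = ", "))
  out <- data.frame(metric = metrics, stringsAsFactors = FALSE)
  for (g in names(groups)) {
    d <- groups[[g]]
    q <- vapply(metrics, function(m) {
      if (!nrow(d)) return(c(NA_real_, NA_real_, NA_real_))
      unname(quantile(d[[m]], c(0.5, 0.25, 0.75), type = 7, na.rm = TRUE))
    }, numeric(3))
    out[[paste0(g, "_median")]] <- q[1, ]
    out[[paste0(g, "_q1")]] <- q[2, ]
    out[[paste0(g, "_q3")]] <- q[3, ]
  }
  out
}

#' Normality screening (Kolmogorov-Smirnov)
#'
#' One-sample KS test of each variable against a normal distribution with
#' moments estimated from the sample. Advisory only: the analysis pipeline
#' stays nonparametric regardless of the outcome. Constant variables are
#' flagged degenerate rather than tested.
#'
#' @param tab A `pab_cohort_table` (or any data frame).
#' @param variables Columns to screen.
#' @return Data frame with `variable`, `statistic`, `p`, `degenerate`.
#' @export
normality_screen <- function(tab, variables) {
  rows <- lapply(variables, function(v) {
    x <- tab[[v]]
    x <- x[!is.na(x)]
    if (length(x) < 3) stop_pab("need n >= 3 for %s", v)
    if (sd(x) == 0)
      return(data.frame(variable = v, statistic = NA_real_, p = NA_real_,
                        degenerate = TRUE))
    kt <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
    data.frame(variable = v, statistic = unname(kt$statistic),
               p = kt$p.value, degenerate = FALSE)
  })
  do.call(rbind, rows)
}

#' Interpretation band for a correlation coefficient
#'
#' Fixed cut-points on `|rho|`: `[0, 0.25)` no to little, `[0.25, 0.50)`
#' fair, `[0.50, 0.75)` moderate to good, `[0.75, 1]` very good to
#' excellent.
#'
#' @param rho Correlation coefficient(s) in `[-1, 1]`.
#' @return Character vector of band labels.
#' @export
interpret_band <- function(rho) {
  if (any(abs(rho) > 1 + 1e-9, na.rm = TRUE)) stop_pab("rho must lie in [-1, 1]")
  bands <- c("no to little", "fair", "moderate to good", "very good to excellent")
  bands[pmin(4L, findInterval(abs(rho), c(0, 0.25, 0.50, 0.75)))]
}

# Spearman rho and two-sided p. t-approximation for n >= 10, exact
# permutation null below (small cohorts), average ranks for ties.
spearman_test <- function(x, y) {
  ok <- complete.cases(x, y)   # pairwise deletion
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop_pab("need n >= 4 for a rank correlation")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) stop_pab("constant variable in correlation")
  rho <- cor(rx, ry)
  if (n >= 10) {
    r2 <- min(abs(rho), 1 - 1e-12)
    tt <- r2 * sqrt((n - 2) / (1 - r2^2))
    p <- 2 * pt(-tt, n - 2)
  } else {
    perms <- all_permutations(n)
    null_rho <- as.vector(cor(rx, matrix(ry[perms], nrow = n)))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  }
  list(rho = rho, p = p, n = n)
}

# All permutations of 1..n as an n x n! matrix (cached; n <= 9 in practice).
perm_cache <- new.env(parent = emptyenv())
all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(perm_cache[[key]])) return(perm_cache[[key]])
  gen <- function(v) {
    if (length(v) == 1) return(matrix(v))
    do.call(cbind, lapply(seq_along(v), function(i)
      rbind(v[i], gen(v[-i]))))
  }
  m <- gen(seq_len(n))
  perm_cache[[key]] <- m
  m
}

#' Spearman correlation battery with family-wise Holm correction
#'
#' Correlates the capacity score with every target variable, applying the
#' Holm step-down adjustment separately within each family. The default
#' families mirror the two constructs of the analysis: seven PAS variables
#' (PAS 1-5 plus the grouping variables PAS 3-6 and PAS 4-6) and four
#' complexity variables (Hn, SampEn, LZC, CDS). A target with fewer than two
#' distinct nonzero values (e.g. a PAS almost nobody achieves) is excluded
#' from testing and reported as `N.A.`, and does not consume a Holm slot.
#'
#' @param tab A `pab_cohort_table`.
#' @param x Capacity column (default `gmfm66`).
#' @param families Named list of character vectors of target columns.
#' @param alpha Significance level used for the `significant` flag.
#' @return A data frame of class `pab_correlations` with `variable`,
#'   `family`, `n`, `rho`, `p_raw`, `p_adj`, `band`, `significant`, `note`.
#' @export
spearman_battery <- function(tab, x = "gmfm66",
                             families = list(
                               PAS = c(paste0("pas", 1:5), "pas_3_6", "pas_4_6"),
                               complexity = c("Hn", "SampEn", "LZC", "CDS")),
                             alpha = 0.05) {
  rows <- list()
  for (fam in names(families)) {
    vars <- families[[fam]]
    res <- lapply(vars, function(v) {
      y <- tab[[v]]
      if (is.null(y)) stop_pab("column %s not found", v)
      nz <- unique(y[!is.na(y) & y != 0])
      if (length(nz) < 2)
        return(data.frame(variable = v, family = fam, n = sum(!is.na(y)),
                          rho = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
                          band = "N.A.", significant = FALSE,
                          note = "excluded: fewer than 2 distinct nonzero values",
                          stringsAsFactors = FALSE))
      st <- spearman_test(tab[[x]], y)
      data.frame(variable = v, family = fam, n = st$n, rho = st$rho,
                 p_raw = st$p, p_adj = NA_real_,
                 band = interpret_band(st$rho), significant = FALSE,
                 note = "", stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    tested <- !is.na(res$p_raw)
    res$p_adj[tested] <- p.adjust(res$p_raw[tested], method = "holm")
    res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
    rows[[fam]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pab_correlations", "data.frame")
  out
}

#' @export
print.pab_correlations <- function(x, ...) {
  cat("<pab_correlations> Holm-adjusted within family\n")
  d <- as.data.frame(x)
  d$rho <- round(d$rho, 3); d$p_raw <- signif(d$p_raw, 3)
  d$p_adj <- signif(d$p_adj, 3)
  print(d[, c("family", "variable", "n", "rho", "p_raw", "p_adj", "band",
              "significant")], row.names = FALSE)
  invisible(x)
}

#' Age-partialled Spearman correlation
#'
#' Rank-transforms all three variables and computes the partial correlation
#' of `x` and `y` given the control from the rank-scale correlation matrix;
#' p-value from the t distribution with `n - 3` degrees of freedom. A
#' constant control falls back to the plain rank correlation with a warning.
#'
#' @param tab Data frame.
#' @param x,y,control Column names (control defaults to `age`).
#' @return Data frame row: `x`, `y`, `control`, `n`, `rho`, `p`.
#' @export
partial_spearman <- function(tab, x, y, control = "age") {
  ok <- complete.cases(tab[[x]], tab[[y]], tab[[control]])
  xv <- tab[[x]][ok]; yv <- tab[[y]][ok]; cv <- tab[[control]][ok]
  n <- length(xv)
  if (n < 5) stop_pab("need n >= 5 for a partial correlation")
  if (sd(cv) == 0) {
    warning("constant control variable; returning plain Spearman correlation")
    st <- spearman_test(xv, yv)
    return(data.frame(x = x, y = y, control = control, n = n,
                      rho = st$rho, p = st$p, stringsAsFactors = FALSE))
  }
  rx <- rank(xv); ry <- rank(yv); rc <- rank(cv)
  rxy <- cor(rx, ry); rxc <- cor(rx, rc); ryc <- cor(ry, rc)
  denom <- (1 - rxc^2) * (1 - ryc^2)
  # a variable rank-identical to the control has nothing left to correlate
  pr <- if (denom < 1e-12) 0 else (rxy - rxc * ryc) / sqrt(denom)
  pr <- max(-1, min(1, pr))
  r2 <- min(abs(pr), 1 - 1e-12)
  tt <- r2 * sqrt((n - 3) / (1 - r2^2))
  data.frame(x = x, y = y, control = control, n = n, rho = pr,
             p = 2 * pt(-tt, n - 3), stringsAsFactors = FALSE)
}

#' Split a cohort into achievers and non-achievers of one PAS
#'
#' A subject is an achiever of a PAS when they spent any nonzero time in it
#' (exact zero test on the accumulated fractions, never on rounded output).
#'
#' @param tab A `pab_cohort_table`.
#' @param pas_id PAS number (1-6).
#' @return Logical vector, `TRUE` = achiever.
#' @export
split_achievers <- function(tab, pas_id) {
  col <- paste0("pas", pas_id)
  if (is.null(tab[[col]])) stop_pab("column %s not found", col)
  tab[[col]] > 0
}

#' ROC analysis of capacity scores against achiever status
#'
#' Positives are the NON-achievers: the question is whether a low capacity
#' score predicts never reaching the PAS. The prediction rule is
#' "non-achiever if score < threshold"; candidate thresholds are the
#' midpoints between adjacent distinct observed scores, ties in the Youden
#' index broken toward the lower threshold. AUC is the rank (Mann-Whitney)
#' statistic; its difference from 0.5 is tested with a seeded label
#' permutation test. The cut-off (with its sensitivity and specificity) is
#' only reported when the AUC differs significantly from chance.
#'
#' @param scores Numeric capacity scores (e.g. GMFM-66).
#' @param achiever Logical labels, `TRUE` = achiever.
#' @param alpha Significance level gating cut-off reporting.
#' @param n_perm Number of label permutations.
#' @param seed Optional seed for the permutation draw.
#' @return A list of class `pab_roc`: `auc`, `auc_p`, `cutoff`,
#'   `sensitivity`, `specificity`, `youden`, `n_pos`, `n_neg`, `alpha`,
#'   plus `all_thresholds` (data frame over every candidate).
#' @export
roc_cutoff <- function(scores, achiever, alpha = 0.05, n_perm = 10000,
                       seed = NULL) {
  ok <- complete.cases(scores, achiever)
  scores <- scores[ok]; achiever <- as.logical(achiever[ok])
  pos <- !achiever   # positives = non-achievers
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0 || n2 == 0) stop_pab("both classes must be present for ROC")

  r <- rank(scores)
  auc_from_ranksum <- function(w) 1 - (w - n1 * (n1 + 1) / 2) / (n1 * n2)
  auc <- auc_from_ranksum(sum(r[pos]))

  perm_draw <- function() {
    vapply(seq_len(n_perm), function(i) sum(r[sample.int(length(r), n1)]),
           numeric(1))
  }
  w_perm <- if (is.null(seed)) perm_draw() else with_seed(seed, perm_draw())
  auc_perm <- auc_from_ranksum(w_perm)
  auc_p <- (1 + sum(abs(auc_perm - 0.5) >= abs(auc - 0.5) - 1e-12)) / (n_perm + 1)

  ss <- sort(unique(scores))
  cand <- if (length(ss) > 1) (ss[-length(ss)] + ss[-1]) / 2 else numeric(0)
  thr <- data.frame(threshold = cand,
                    sensitivity = vapply(cand, function(c0) mean(scores[pos] < c0), numeric(1)),
                    specificity = vapply(cand, function(c0) mean(scores[!pos] >= c0), numeric(1)))
  thr$youden <- thr$sensitivity + thr$specificity - 1

  if (nrow(thr)) {
    # lowest threshold among (tolerance-)tied maxima
    best <- which(thr$youden > max(thr$youden) - 1e-9)[1]
    cutoff <- thr$threshold[best]
    sens <- thr$sensitivity[best]; spec <- thr$specificity[best]
    youden <- thr$youden[best]
  } else {
    cutoff <- sens <- spec <- youden <- NA_real_
  }
  suppressed <- auc_p >= alpha
  structure(list(auc = auc, auc_p = auc_p,
                 cutoff = if (suppressed) NA_real_ else cutoff,
                 sensitivity = if (suppressed) NA_real_ else sens,
                 specificity = if (suppressed) NA_real_ else spec,
                 youden = if (suppressed) NA_real_ else youden,
                 n_pos = n1, n_neg = n2, alpha = alpha,
                 all_thresholds = thr),
            class = "pab_roc")
}

#' @export
print.pab_roc <- function(x, ...) {
  cat(sprintf("<pab_roc> AUC = %.3f (p = %.4g; %d non-achievers vs %d achievers)\n",
              x$auc, x$auc_p, x$n_pos, x$n_neg))
  if (is.na(x$cutoff)) {
    cat(sprintf("  AUC not significantly different from 0.5 at alpha = %g; cut-off suppressed\n",
                x$alpha))
  } else {
    cat(sprintf("  Youden-optimal cut-off %.2f (sens %.2f, spec %.2f, J = %.2f)\n",
                x$cutoff, x$sensitivity, x$specificity, x$youden))
  }
  invisible(x)
}

#' Run the full cohort statistical battery
#'
#' Descriptive table, normality screen, the two Spearman/Holm families,
#' age-partialled correlations for every variable whose rank correlation
#' with age is nominally significant, and achiever/non-achiever ROC analyses
#' for the requested PAS (skipping any with a single class).
#'
#' @param tab A `pab_cohort_table`.
#' @param alpha Significance level.
#' @param roc_pas PAS ids to submit to ROC analysis.
#' @param n_perm Permutations for the AUC test.
#' @param seed Seed for the permutation draws.
#' @return A list of class `pab_analysis`.
#' @export
run_analysis <- function(tab, alpha = 0.05, roc_pas = 4:6, n_perm = 10000,
                         seed = 1L) {
  has_cx <- all(c("Hn", "SampEn", "LZC", "CDS") %in% names(tab))
  fams <- list(PAS = c(paste0("pas", 1:5), "pas_3_6", "pas_4_6"))
  if (has_cx) fams$complexity <- c("Hn", "SampEn", "LZC", "CDS")
  vars <- unlist(fams, use.names = FALSE)

  desc <- descriptive_table(tab, metrics = c(if (has_cx) c("Hn", "SampEn", "LZC", "CDS"),
                                             paste0("pas", 1:6), "pas_3_6", "pas_4_6"))
  norm <- normality_screen(tab, intersect(vars, names(tab)))
  corr <- spearman_battery(tab, families = fams, alpha = alpha)

  age_linked <- Filter(function(v) {
    y <- tab[[v]]
    if (length(unique(y[!is.na(y) & y != 0])) < 2) return(FALSE)
    spearman_test(tab$age, y)$p < alpha
  }, vars)
  partial <- if (length(age_linked))
    do.call(rbind, lapply(age_linked, function(v)
      partial_spearman(tab, "gmfm66", v, control = "age")))

  roc <- list()
  for (k in roc_pas) {
    ach <- split_achievers(tab, k)
    if (length(unique(ach)) < 2) {
      roc[[as.character(k)]] <- NULL
      next
    }
    roc[[as.character(k)]] <- roc_cutoff(tab$gmfm66, ach, alpha = alpha,
                                         n_perm = n_perm,
                                         seed = derive_seed(seed, 9000L + k))
  }
  structure(list(descriptives = desc, normality = norm, correlations = corr,
                 partial = partial, roc = roc, alpha = alpha, n = nrow(tab)),
            class = "pab_analysis")
}

#' @export
print.pab_analysis <- function(x, ...) {
  cat(sprintf("<pab_analysis> n = %d subjects, alpha = %g\n\n", x$n, x$alpha))
  print(x$correlations)
  if (!is.null(x$partial)) {
    cat("\nAge-partialled correlations:\n")
    print(x$partial, row.names = FALSE)
  }
  for (k in names(x$roc)) {
    cat(sprintf("\nROC for PAS %s achievement:\n", k))
    print(x$roc[[k]])
  }
  invisible(x)
}
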