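# Pipeline orchestration: each stage reads and writes only the documented
# plain-text formats, so stages are individually invokable and composable,
# and a detected timeline can replace a ground-truth one anywhere.

#' Run the synthetic-cohort-to-analysis pipeline
#'
#' Chains simulate -> (render + detect | ground truth) -> barcode ->
#' complexity -> analyze, writing every intermediate product as delimited
#' text into `outdir` together with a run-metadata file echoing the resolved
#' configuration and seeds. Identical config + seed regenerate identical
#' outputs.
#'
#' @param config A [generator_config()].
#' @param outdir Output directory (created if missing).
#' @param detect `"ground_truth"` uses the simulated timelines directly;
#'   `"imu"` renders IMU signals and runs the full detection chain.
#' @param det_params,bc_params,cx_params Stage parameter objects.
#' @param alpha Significance level for the analysis stage.
#' @param complexity Compute pattern-complexity metrics (the slowest stage
#'   on long barcodes).
#' @param verbose Print stage log lines.
#' @return The `pab_analysis` object, invisibly; side effect: files in
#'   `outdir`.
#' @export
run_pipeline <- function(config, outdir, detect = c("ground_truth", "imu"),
                         det_params = detection_params(),
                         bc_params = barcode_params(),
                         cx_params = complexity_params(),
                         alpha = 0.05, complexity = TRUE, verbose = TRUE) {
  detect <- match.arg(detect)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(stage, msg) {
    if (verbose) message(sprintf("[%s] %s seed=%d %s",
                                 format(Sys.time(), "%H:%M:%S"), stage,
                                 config$seed, msg))
  }

  log_line("simulate", sprintf("n=%d day=%gs", config$n_subjects, config$day_length))
  cohort <- generate_cohort(config)
  write_cohort(cohort, file.path(outdir, "cohort.tsv"))
  timelines <- lapply(seq_len(nrow(cohort)), function(i)
    generate_timeline(cohort[i, ], config, seed = derive_seed(config$seed, i)))
  names(timelines) <- cohort$subject_id
  write_timelines(timelines, file.path(outdir, "timelines_truth.tsv"))

  if (detect == "imu") {
    log_line("detect", "rendering IMU signals and re-detecting")
    timelines <- lapply(cohort$subject_id, function(id) {
      recs <- render_imu(timelines[[id]], config,
                         seed = derive_seed(config$seed, 100000L + match(id, cohort$subject_id)))
      detect_timeline(recs, det_params, subject_id = id)
    })
    names(timelines) <- cohort$subject_id
    write_timelines(timelines, file.path(outdir, "timelines_detected.tsv"))
  }

  log_line("barcode", sprintf("epoch=%gs", bc_params$epoch))
  barcodes <- lapply(timelines, to_barcode, params = bc_params)
  write_barcodes(barcodes, file.path(outdir, "barcodes.txt"))
  summaries <- lapply(barcodes, pa_summary)
  write_summaries(summaries, file.path(outdir, "pa_summary.tsv"))

  metrics <- NULL
  if (complexity) {
    log_line("complexity", sprintf("K=%d m=%d", cx_params$K, cx_params$sampen_m))
    metrics <- lapply(barcodes, complexity_metrics, params = cx_params)
    write_complexity(metrics, file.path(outdir, "complexity.tsv"))
  }

  log_line("analyze", sprintf("alpha=%g", alpha))
  tab <- build_cohort_table(cohort, summaries, metrics)
  data.table::fwrite(as.data.frame(tab), file.path(outdir, "cohort_table.tsv"),
                     sep = "\t", na = "")
  ana <- run_analysis(tab, alpha = alpha, seed = config$seed)
  write_analysis(ana, outdir)

  meta <- list(package = "pabarcode",
               version = as.character(utils::packageVersion("pabarcode")),
               seed = config$seed,
               detect = detect,
               generator = unclass_config(config),
               detection = if (detect == "imu") unclass(det_params),
               barcode = unclass(bc_params),
               complexity = if (complexity) unclass(cx_params),
               alpha = alpha,
               quartile_type = 7)
  yaml::write_yaml(meta, file.path(outdir, "run_metadata.yml"))
  invisible(ana)
}

unclass_config <- function(config) {
  out <- unclass(config)
  out$capacity_link <- unclass(out$capacity_link)
  out$noise <- unclass(out$noise)
  lapply(out, function(x) if (is.numeric(x) && !is.null(names(x))) as.list(x) else x)
}

write_summaries <- function(summaries, path) {
  rows <- lapply(summaries, function(s) {
    cbind(data.frame(subject_id = s$subject_id),
          stats::setNames(as.data.frame(as.list(s$state_fractions)), paste0("state", 1:22)),
          stats::setNames(as.data.frame(as.list(s$pas_fractions)), paste0("pas", 1:6)),
          data.frame(pas_3_6 = s$pas_3_6, pas_4_6 = s$pas_4_6,
                     pct_activity = s$pct_activity),
          stats::setNames(as.data.frame(as.list(s$achiever)), paste0("achiever", 1:6)))
  })
  data.table::fwrite(do.call(rbind, rows), path, sep = "\t")
  invisible(path)
}

write_complexity <- function(metrics, path) {
  rows <- lapply(metrics, function(m)
    as.data.frame(m[c("subject_id", "Hn", "SampEn", "LZC", "CC",
                      "pct_activity", "CDS")]))
  data.table::fwrite(do.call(rbind, rows), path, sep = "\t")
  invisible(path)
}

write_analysis <- function(ana, outdir) {
  data.table::fwrite(ana$descriptives, file.path(outdir, "descriptives.tsv"),
                     sep = "\t", na = "")
  data.table::fwrite(as.data.frame(ana$correlations),
                     file.path(outdir, "correlations.tsv"), sep = "\t", na = "")
  data.table::fwrite(ana$normality, file.path(outdir, "normality.tsv"),
                     sep = "\t", na = "")
  if (!is.null(ana$partial))
    data.table::fwrite(ana$partial, file.path(outdir, "partial_correlations.tsv"),
                       sep = "\t", na = "")
  if (length(ana$roc)) {
    rows <- lapply(names(ana$roc), function(k) {
      r <- ana$roc[[k]]
      data.frame(pas_id = k, auc = r$auc, auc_p = r$auc_p, cutoff = r$cutoff,
                 sensitivity = r$sensitivity, specificity = r$specificity,
                 youden = r$youden, n_non_achievers = r$n_pos,
                 n_achievers = r$n_neg)
    })
    data.table::fwrite(do.call(rbind, rows), file.path(outdir, "roc.tsv"),
                       sep = "\t", na = "")
  }
  invisible(outdir)
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `inst/cli/pabarcode.R` script. Subcommands:
#' `simulate`, `detect`, `barcode`, `complexity`, `analyze`, `viz`,
#' `run-all`. Each stage reads and writes only the documented text formats,
#' so outputs of one invocation feed the next; `run-all` chains everything.
#' Flags: `--config <yaml>` (generator/analysis settings), `--in <dir>`,
#' `--out <dir>`, `--seed <int>`, `--detect ground_truth|imu`, `--quiet`.
#'
#' @param args Character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return Integer exit status (0 on success), invisibly.
#' @export
pab_cli <- function(args) {
  usage <- paste(
    "usage: pabarcode.R <subcommand> [--config cfg.yml] [--in dir] [--out dir]",
    "                  [--seed N] [--detect ground_truth|imu] [--quiet]",
    "subcommands: simulate | detect | barcode | complexity | analyze | viz | run-all",
    sep = "\n")
  status <- tryCatch({
    if (!length(args)) stop(usage, call. = FALSE)
    cmd <- args[1]
    opts <- parse_cli_flags(args[-1])
    if (!cmd %in% c("simulate", "detect", "barcode", "complexity", "analyze",
                    "viz", "run-all"))
      stop("unknown subcommand: ", cmd, "\n", usage, call. = FALSE)
    cfg <- load_run_config(opts)
    indir <- opts[["in"]] %||% opts$out %||% "."
    outdir <- opts$out %||% indir
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    verbose <- is.null(opts$quiet)

    switch(cmd,
      "run-all" = {
        run_pipeline(cfg$generator, outdir,
                     detect = opts$detect %||% "ground_truth",
                     alpha = cfg$alpha, verbose = verbose)
        barcodes <- read_barcodes(file.path(outdir, "barcodes.txt"))
        for (b in barcodes)
          render_barcode_image(b, file.path(outdir, paste0("barcode_", attr(b, "subject_id"), ".png")))
      },
      "simulate" = {
        cohort <- generate_cohort(cfg$generator)
        write_cohort(cohort, file.path(outdir, "cohort.tsv"))
        tls <- lapply(seq_len(nrow(cohort)), function(i)
          generate_timeline(cohort[i, ], cfg$generator,
                            seed = derive_seed(cfg$generator$seed, i)))
        names(tls) <- cohort$subject_id
        write_timelines(tls, file.path(outdir, "timelines_truth.tsv"))
        imudir <- file.path(outdir, "imu")
        dir.create(imudir, showWarnings = FALSE)
        for (i in seq_along(tls)) {
          recs <- render_imu(tls[[i]], cfg$generator,
                             seed = derive_seed(cfg$generator$seed, 100000L + i))
          for (loc in names(recs))
            write_recording(recs[[loc]],
                            file.path(imudir, sprintf("%s_%s.tsv", names(tls)[i], loc)))
        }
      },
      "detect" = {
        imudir <- file.path(indir, "imu")
        files <- list.files(imudir, pattern = "\\.tsv$")
        ids <- unique(sub("_(trunk|thigh_left|thigh_right|shank_left|shank_right)\\.tsv$", "", files))
        tls <- lapply(ids, function(id) {
          map <- sensor_map(file.path(imudir, sprintf("%s_%s.tsv", id, imu_locations())),
                            imu_locations())
          detect_timeline(read_recording_set(map), subject_id = id)
        })
        names(tls) <- ids
        write_timelines(tls, file.path(outdir, "timelines_detected.tsv"))
      },
      "barcode" = {
        tl_file <- cli_timeline_file(indir)
        tls <- read_timelines(tl_file)
        barcodes <- lapply(tls, to_barcode)
        write_barcodes(barcodes, file.path(outdir, "barcodes.txt"))
        write_summaries(lapply(barcodes, pa_summary), file.path(outdir, "pa_summary.tsv"))
      },
      "complexity" = {
        barcodes <- read_barcodes(file.path(indir, "barcodes.txt"))
        write_complexity(lapply(barcodes, complexity_metrics),
                         file.path(outdir, "complexity.tsv"))
      },
      "analyze" = {
        cohort <- read_cohort(file.path(indir, "cohort.tsv"))
        barcodes <- read_barcodes(file.path(indir, "barcodes.txt"))
        summaries <- lapply(barcodes, pa_summary)
        cx_file <- file.path(indir, "complexity.tsv")
        metrics <- NULL
        if (file.exists(cx_file)) {
          cx <- as.data.frame(data.table::fread(cx_file, sep = "\t"))
          metrics <- lapply(seq_len(nrow(cx)), function(i) as.list(cx[i, ]))
          names(metrics) <- cx$subject_id
        }
        tab <- build_cohort_table(cohort, summaries, metrics)
        ana <- run_analysis(tab, alpha = cfg$alpha, seed = cfg$generator$seed)
        write_analysis(ana, outdir)
      },
      "viz" = {
        barcodes <- read_barcodes(file.path(indir, "barcodes.txt"))
        for (b in barcodes)
          render_barcode_image(b, file.path(outdir, paste0("barcode_", attr(b, "subject_id"), ".png")))
      })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cli_timeline_file <- function(indir) {
  for (f in c("timelines_detected.tsv", "timelines_truth.tsv", "timelines.tsv")) {
    p <- file.path(indir, f)
    if (file.exists(p)) return(p)
  }
  stop_pab("no timeline file found in %s", indir)
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--quiet") {
      opts$quiet <- TRUE; i <- i + 1
    } else if (grepl("^--", a)) {
      if (i == length(args)) stop("flag ", a, " needs a value", call. = FALSE)
      opts[[sub("^--", "", a)]] <- args[i + 1]
      i <- i + 2
    } else stop("unexpected argument: ", a, call. = FALSE)
  }
  opts
}

# Resolve a YAML run config (all fields optional) against package defaults.
load_run_config <- function(opts) {
  raw <- if (!is.null(opts$config)) {
    if (!file.exists(opts$config)) stop("config file not found: ", opts$config, call. = FALSE)
    yaml::read_yaml(opts$config)
  } else list()
  gen_args <- raw$generator %||% list()
  if (!is.null(raw$capacity_link))
    gen_args$capacity_link <- do.call(capacity_link, raw$capacity_link)
  if (!is.null(raw$noise)) gen_args$noise <- do.call(imu_noise, raw$noise)
  if (!is.null(opts$seed)) gen_args$seed <- as.integer(opts$seed)
  list(generator = do.call(generator_config, gen_args),
       alpha = raw$alpha %||% 0.05)
}
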