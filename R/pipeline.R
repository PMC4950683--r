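#' Experiment configuration
#'
#' Assembles and validates the settings for a full synthetic experiment.
#' Unknown arguments are rejected.
#'
#' @param n_subjects number of synthetic subjects.
#' @param designs named list of task designs to run.
#' @param methods extraction methods to evaluate.
#' @param gsr `"on"`, `"off"`, or `"both"` global-signal-regression
#'   conditions.
#' @param seed master RNG seed.
#' @param truth a [synth_truth()] describing the generator.
#' @param band band-pass edges in Hz.
#' @param dice_threshold Dice binarisation threshold.
#' @param min_seconds minimum retained duration for concatenation methods.
#' @param shift_reference reference for [estimate_shift()] (`"boxcar"` per
#'   the shifted-boxcar procedure, or `"convolved"`).
#' @param max_shift_trs shift cap in TRs.
#' @param out_dir output directory for CSV/JSON artefacts, or `NULL` to keep
#'   results in memory only.
#' @return a validated list of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 8L,
                              designs = list(rft = design_rft(),
                                             edt = design_edt()),
                              methods = extraction_methods(),
                              gsr = c("on", "off", "both"),
                              seed = 1L,
                              truth = synth_truth(),
                              band = c(0.009, 0.08),
                              dice_threshold = 0.3,
                              min_seconds = 30,
                              shift_reference = "boxcar",
                              max_shift_trs = 7L,
                              out_dir = NULL) {
  gsr <- match.arg(gsr)
  methods <- toupper(methods)
  bad <- setdiff(methods, extraction_methods())
  if (length(bad))
    stop("unknown methods in config: ", paste(bad, collapse = ", "))
  if (!(band[1] > 0 && band[1] < band[2]))
    stop("config band must satisfy 0 < low < high")
  stopifnot(inherits(truth, "synth_truth"), n_subjects >= 2L)
  if (is.null(names(designs)) || any(names(designs) == ""))
    stop("'designs' must be a named list")
  structure(list(n_subjects = as.integer(n_subjects), designs = designs,
                 methods = methods, gsr = gsr, seed = as.integer(seed),
                 truth = truth, band = band,
                 dice_threshold = dice_threshold, min_seconds = min_seconds,
                 shift_reference = shift_reference,
                 max_shift_trs = as.integer(max_shift_trs),
                 out_dir = out_dir),
            class = "experiment_config")
}

config_checksum <- function(config) {
  s <- jsonlite::toJSON(list(n_subjects = config$n_subjects,
                             methods = config$methods, gsr = config$gsr,
                             seed = config$seed, band = config$band,
                             designs = names(config$designs)),
                        auto_unbox = TRUE)
  sum(utf8ToInt(as.character(s)) * seq_len(nchar(s))) %% 1e9
}

#' Run the full synthetic comparison experiment
#'
#' Generates the group, estimates each subject's hemodynamic delay from the
#' occipital ROI of each task run, applies every configured extraction
#' method, computes seed connectivity for the extracted data and for
#' duration-matched rest, evaluates ICC/Dice/R-squared per subject, method
#' and network, adds the test-retest condition (two independent rest runs),
#' and runs the group statistics. Designs whose baseline blocks retain less
#' than the configured minimum duration have the affected concatenation
#' method skipped with a logged reason.
#'
#' @param config an [experiment_config()].
#' @param quiet suppress progress messages.
#' @return list of class `experiment_result`: `records` (long similarity
#'   table), `stats` (per design x GSR [group_compare()] results), `skips`
#'   (skipped method/design combinations with reasons), `shifts` (per
#'   subject x design delay estimates), `manifest`, and `tables` (wide
#'   group-mean tables, methods x networks per metric and GSR condition).
#' @export
run_experiment <- function(config = experiment_config(), quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) if (!quiet) message(sprintf(...))
  stage_times <- c()
  tick <- function(stage) {
    stage_times[[stage]] <<- proc.time()[["elapsed"]] - t0
    t0 <<- proc.time()[["elapsed"]]
  }

  truth <- config$truth
  say("generating %d synthetic subjects (seed %d)", config$n_subjects,
      config$seed)
  grp <- generate_group(truth, config$n_subjects, config$designs,
                        seed = config$seed, retest = TRUE)
  tick("generate")

  seeds <- truth_seeds(truth)
  gsr_flags <- switch(config$gsr, on = TRUE, off = FALSE,
                      both = c(TRUE, FALSE))
  records <- NULL; skips <- NULL; shifts <- NULL

  for (subj in grp$subjects) {
    rest <- subj$runs$rest
    for (dn in names(config$designs)) {
      design <- config$designs[[dn]]
      task <- subj$runs[[dn]]
      roi_ts <- roi_mean_timecourse(task$run, truth$networks$occipital)
      task_labs <- setdiff(unique(design$events$label), design$baseline_label)
      box <- Reduce(`+`, lapply(task_labs, function(l) boxcar(design, l)))
      shift <- estimate_shift(roi_ts, box, design$tr, config$max_shift_trs,
                              reference = config$shift_reference,
                              hrf = truth$hrf)
      shifts <- rbind(shifts, data.frame(
        subject = subj$id, design = dn, shift_trs = shift$shift_trs,
        shift_seconds = shift$shift_seconds, true_delay_trs = subj$delay_trs,
        peak_correlation = shift$peak_correlation))
      for (method in config$methods) {
        ex <- tryCatch(
          apply_method(method, task$run, task$confounds, design,
                       hrf = truth$hrf, shift = shift,
                       min_seconds = config$min_seconds),
          error = function(e) e)
        if (inherits(ex, "error")) {
          if (!grepl("insufficient data", conditionMessage(ex))) stop(ex)
          say("subject %d, %s: skipping %s (%s)", subj$id, dn, method,
              conditionMessage(ex))
          skips <- rbind(skips, data.frame(
            subject = subj$id, design = dn, method = method,
            reason = conditionMessage(ex)))
          next
        }
        k <- n_volumes(ex$run)
        rest_matched <- new_extraction_result(
          match_duration(rest$run, k),
          rest$confounds[seq_len(k), , drop = FALSE], "REST")
        for (gsr in gsr_flags) {
          maps_m <- run_connectivity(ex, seeds, use_gsr = gsr,
                                     low = config$band[1],
                                     high = config$band[2])
          maps_r <- run_connectivity(rest_matched, seeds, use_gsr = gsr,
                                     low = config$band[1],
                                     high = config$band[2])
          rec <- similarity_records(maps_m, maps_r, subj$id, method,
                                    gsr = gsr,
                                    dice_threshold = config$dice_threshold)
          rec$design <- dn
          records <- rbind(records, rec)
        }
      }
    }
    # test-retest reference: two independently acquired rest runs
    retest <- subj$runs$retest
    for (gsr in gsr_flags) {
      maps_a <- run_connectivity(rest$run, seeds, use_gsr = gsr,
                                 low = config$band[1], high = config$band[2],
                                 confounds = rest$confounds)
      maps_b <- run_connectivity(retest$run, seeds, use_gsr = gsr,
                                 low = config$band[1], high = config$band[2],
                                 confounds = retest$confounds)
      rec <- similarity_records(maps_a, maps_b, subj$id, "TESTRETEST",
                                gsr = gsr,
                                dice_threshold = config$dice_threshold)
      rec$design <- "rest"
      records <- rbind(records, rec)
    }
    say("subject %d done", subj$id)
  }
  tick("similarity")

  stats <- list()
  for (dn in names(config$designs)) {
    for (gsr in gsr_flags) {
      sub <- records[(records$design == dn | records$method == "TESTRETEST") &
                       records$gsr == gsr, , drop = FALSE]
      stats[[paste0(dn, if (gsr) "_gsr" else "_nogsr")]] <- group_compare(sub)
    }
  }
  tick("stats")

  tables <- make_wide_tables(records)
  manifest <- list(package = "restex",
                   version = as.character(utils::packageVersion("restex")),
                   config_checksum = config_checksum(config),
                   seed = config$seed,
                   n_subjects = config$n_subjects,
                   stage_seconds = as.list(round(unlist(stage_times), 2)))
  out <- structure(list(records = records, stats = stats, skips = skips,
                        shifts = shifts, manifest = manifest,
                        tables = tables, config = config),
                   class = "experiment_result")
  if (!is.null(config$out_dir)) write_tables(out, config$out_dir)
  out
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Experiment: %d subjects, %d similarity records, %d skip(s)\n",
              x$config$n_subjects, nrow(x$records),
              if (is.null(x$skips)) 0L else nrow(x$skips)))
  for (nm in names(x$tables)) {
    cat("\n", nm, " (group means):\n", sep = "")
    print(round(x$tables[[nm]], 3))
  }
  invisible(x)
}

make_wide_tables <- function(records) {
  tables <- list()
  for (gsr in unique(records$gsr)) {
    for (dn in setdiff(unique(records$design), "rest")) {
      sub <- records[(records$design == dn | records$method == "TESTRETEST") &
                       records$gsr == gsr, , drop = FALSE]
      for (metric in c("icc", "dice", "r2")) {
        agg <- stats::aggregate(sub[[metric]],
                                by = list(method = sub$method,
                                          network = sub$network), FUN = mean)
        wide <- stats::reshape(agg, idvar = "method", timevar = "network",
                               direction = "wide")
        rownames(wide) <- wide$method
        wide$method <- NULL
        colnames(wide) <- sub("^x\\.", "", colnames(wide))
        ord <- c(setdiff(rownames(wide), "TESTRETEST"), "TESTRETEST")
        key <- sprintf("%s_%s_%s", dn, metric, if (gsr) "gsr" else "nogsr")
        tables[[key]] <- as.matrix(wide[ord, , drop = FALSE])
      }
    }
  }
  tables
}

#' Write experiment outputs as CSV/JSON files
#'
#' Writes the long similarity table, one wide group-mean table per design,
#' metric and GSR condition (rows = methods plus test-retest, columns =
#' networks), the skip log, the delay estimates, the group statistics and
#' the manifest.
#'
#' @param result an `experiment_result` (or a long records data.frame).
#' @param out_dir output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_tables <- function(result, out_dir) {
  records <- if (inherits(result, "experiment_result")) result$records
             else result
  if (is.null(records) || nrow(records) == 0L)
    stop("no similarity records to write")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(records, file.path(out_dir, "similarity_long.csv"),
                   row.names = FALSE)
  tables <- if (inherits(result, "experiment_result")) result$tables
            else make_wide_tables(records)
  for (nm in names(tables))
    utils::write.csv(data.frame(method = rownames(tables[[nm]]),
                                tables[[nm]], check.names = FALSE),
                     file.path(out_dir, paste0("table_", nm, ".csv")),
                     row.names = FALSE)
  if (inherits(result, "experiment_result")) {
    if (!is.null(result$skips))
      utils::write.csv(result$skips, file.path(out_dir, "skips.csv"),
                       row.names = FALSE)
    if (!is.null(result$shifts))
      utils::write.csv(result$shifts, file.path(out_dir, "shifts.csv"),
                       row.names = FALSE)
    stats_df <- do.call(rbind, lapply(names(result$stats), function(k) {
      a <- result$stats[[k]]$anova; a$condition <- k; a
    }))
    utils::write.csv(stats_df, file.path(out_dir, "anova.csv"),
                     row.names = FALSE)
    jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}
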