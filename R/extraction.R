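#' Baseline (crosshair) periods of a design
#'
#' Explicit baseline events when the design has them, otherwise the gaps
#' between task events within the run.
#'
#' @param design a [task_design()].
#' @return data.frame with columns `onset` and `end` (seconds).
#' @export
baseline_periods <- function(design) {
  ev <- design$events
  bl <- ev[ev$label == design$baseline_label, , drop = FALSE]
  if (nrow(bl) > 0L)
    return(data.frame(onset = bl$onset, end = bl$onset + bl$duration))
  task <- ev[order(ev$onset), , drop = FALSE]
  bounds <- c(0, as.vector(rbind(task$onset, task$onset + task$duration)),
              design_duration(design))
  gaps <- matrix(bounds, ncol = 2L, byrow = TRUE)
  gaps <- gaps[gaps[, 2L] - gaps[, 1L] > 1e-9, , drop = FALSE]
  if (nrow(gaps) == 0L)
    stop("design has no baseline periods (no baseline events and no gaps)")
  data.frame(onset = gaps[, 1L], end = gaps[, 2L])
}

new_segment_list <- function(intervals, tr, n_vol) {
  intervals <- intervals[intervals$start < intervals$end, , drop = FALSE]
  intervals <- intervals[order(intervals$start), , drop = FALSE]
  rownames(intervals) <- NULL
  stopifnot(all(intervals$start >= 0L), all(intervals$end <= n_vol))
  if (nrow(intervals) > 1L &&
      any(intervals$start[-1L] < intervals$end[-nrow(intervals)]))
    stop("segments overlap")
  structure(list(intervals = intervals, tr = tr, n_volumes = n_vol),
            class = "segment_list")
}

#' @export
print.segment_list <- function(x, ...) {
  cat(sprintf("Resting segments: %d interval(s), %d of %d volumes (%.1f s)\n",
              nrow(x$intervals), segment_volumes(x), x$n_volumes,
              segment_volumes(x) * x$tr))
  for (i in seq_len(nrow(x$intervals)))
    cat(sprintf("  [%d, %d)  %.1f-%.1f s\n", x$intervals$start[i],
                x$intervals$end[i], x$intervals$start[i] * x$tr,
                x$intervals$end[i] * x$tr))
  invisible(x)
}

#' Total number of volumes selected by a segment list
#' @param segments a `segment_list`.
#' @return integer volume count.
#' @export
segment_volumes <- function(segments) {
  as.integer(sum(segments$intervals$end - segments$intervals$start))
}

# seconds -> half-open volume interval: start rounded up, end rounded down
interval_to_volumes <- function(start_s, end_s, tr, n_vol) {
  c(start = min(max(0L, as.integer(ceiling(start_s / tr - 1e-9))), n_vol),
    end = min(as.integer(floor(end_s / tr + 1e-9)), n_vol))
}

#' Fixed conservative cutting of baseline blocks
#'
#' For each baseline block, the retained "resting" interval starts `post_gap`
#' seconds after the end of the preceding task block (letting the evoked
#' response return to baseline) and, in the default `pre_extension_mode
#' = "into_task"`, extends `pre_extension` seconds into the following task
#' block (the hemodynamic delay means those samples still reflect baseline).
#' Leading/trailing baselines without a task neighbour keep their natural
#' boundary. Intervals are converted to volumes (start rounded up, end
#' rounded down) and empty intervals dropped.
#'
#' @param design a [task_design()].
#' @param post_gap seconds removed after each task block (default 15).
#' @param pre_extension seconds kept into the following task block
#'   (default 5).
#' @param pre_extension_mode `"into_task"` (default) extends past the
#'   following task onset; `"none"` stops at the baseline end.
#' @return a `segment_list`.
#' @export
segments_fixed <- function(design, post_gap = 15, pre_extension = 5,
                           pre_extension_mode = c("into_task", "none")) {
  pre_extension_mode <- match.arg(pre_extension_mode)
  bl <- baseline_periods(design)
  task <- design$events[design$events$label != design$baseline_label, ,
                        drop = FALSE]
  dur <- design_duration(design)
  rows <- lapply(seq_len(nrow(bl)), function(i) {
    prev_end <- suppressWarnings(max(task$onset[task$onset + task$duration <=
                                                  bl$onset[i] + 1e-9] +
                                     task$duration[task$onset + task$duration <=
                                                     bl$onset[i] + 1e-9]))
    next_on <- suppressWarnings(min(task$onset[task$onset >= bl$end[i] - 1e-9]))
    start_s <- if (is.finite(prev_end)) prev_end + post_gap else bl$onset[i]
    end_s <- if (is.finite(next_on) && pre_extension_mode == "into_task")
      next_on + pre_extension else bl$end[i]
    interval_to_volumes(start_s, min(end_s, dur), design$tr, design$n_volumes)
  })
  iv <- as.data.frame(do.call(rbind, rows))
  new_segment_list(iv, design$tr, design$n_volumes)
}

#' Delay-adaptive cutting of baseline blocks
#'
#' Uses a subject's estimated hemodynamic delay instead of fixed margins:
#' the effective baseline starts at the crosshair onset plus the estimated
#' shift and lasts the full crosshair duration, truncated at the run end.
#'
#' @param design a [task_design()].
#' @param shift a [estimate_shift()] result (or a number of seconds).
#' @return a `segment_list`.
#' @export
segments_var <- function(design, shift) {
  shift_s <- if (inherits(shift, "shift_estimate")) shift$shift_seconds
             else as.numeric(shift)
  stopifnot(shift_s >= 0)
  bl <- baseline_periods(design)
  dur <- design_duration(design)
  rows <- lapply(seq_len(nrow(bl)), function(i) {
    interval_to_volumes(bl$onset[i] + shift_s,
                        min(bl$onset[i] + shift_s + (bl$end[i] - bl$onset[i]),
                            dur),
                        design$tr, design$n_volumes)
  })
  iv <- as.data.frame(do.call(rbind, rows))
  new_segment_list(iv, design$tr, design$n_volumes)
}

#' Cut and concatenate the selected resting segments
#'
#' Slices the run and every confound column at the same volume indices and
#' concatenates them in temporal order; values are preserved exactly. Errors
#' when the retained duration falls below `min_seconds`, mirroring the
#' exclusion of concatenation methods on designs whose baselines are too
#' short.
#'
#' @param run a [bold_run()].
#' @param confounds confound data.frame aligned with the run.
#' @param segments a `segment_list`.
#' @param min_seconds minimum retained duration (default 30 s).
#' @param method method tag recorded in the result.
#' @return an `extraction_result`: `run`, `confounds`, `method`,
#'   `retained_seconds`, `segments`.
#' @export
concatenate_run <- function(run, confounds, segments, min_seconds = 30,
                            method = "BLOCK") {
  stopifnot(inherits(run, "bold_run"), inherits(segments, "segment_list"))
  check_confounds(confounds, run)
  if (segments$n_volumes != n_volumes(run))
    stop("segment list was built for a different run length")
  if (nrow(segments$intervals) == 0L)
    stop(sprintf("insufficient data for method %s: no resting segments remain",
                 method))
  idx <- unlist(lapply(seq_len(nrow(segments$intervals)), function(i)
    seq(segments$intervals$start[i], segments$intervals$end[i] - 1L)))
  retained <- length(idx) * run$tr
  if (retained < min_seconds)
    stop(sprintf(paste0("insufficient data for method %s: %.1f s retained, ",
                        "minimum is %.1f s"), method, retained, min_seconds))
  new_extraction_result(slice_run(run, idx),
                        confounds[idx + 1L, , drop = FALSE],
                        method, segments)
}

new_extraction_result <- function(run, confounds, method, segments = NULL) {
  rownames(confounds) <- NULL
  structure(list(run = run, confounds = confounds, method = method,
                 retained_seconds = n_volumes(run) * run$tr,
                 segments = segments),
            class = "extraction_result")
}

#' @export
print.extraction_result <- function(x, ...) {
  cat(sprintf("Extraction result [%s]: %d volumes retained (%.1f s)\n",
              x$method, n_volumes(x$run), x$retained_seconds))
  invisible(x)
}

#' Least-squares residuals of multiple channels against shared regressors
#'
#' Fits each channel (column) by OLS on the regressors plus an intercept and
#' returns the residuals; residuals are orthogonal to every regressor.
#'
#' @param series_matrix time x channels numeric matrix.
#' @param regressors time x k numeric matrix (intercept added internally).
#' @return residual matrix, same shape as `series_matrix`.
#' @export
ols_residuals <- function(series_matrix, regressors) {
  series_matrix <- as.matrix(series_matrix)
  X <- cbind(`(intercept)` = 1, as.matrix(regressors))
  if (nrow(X) != nrow(series_matrix))
    stop("'series_matrix' and 'regressors' must have the same number of rows")
  if (nrow(X) <= ncol(X) + 1L)
    stop("too few time points for the number of regressors")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1L, ncol(X))]]
    stop("regressor matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  qr.resid(qx, series_matrix)
}

#' Extraction method names
#' @return character vector of the five supported methods.
#' @export
extraction_methods <- function() {
  c("ORIG", "BLOCK", "BLOCKVAR", "REG", "BLOCKREG")
}

#' Apply a task-to-rest extraction method
#'
#' * `ORIG` — the unmodified run.
#' * `BLOCK` — concatenation of baseline blocks cut with fixed conservative
#'   margins ([segments_fixed()]).
#' * `BLOCKVAR` — concatenation with subject-adaptive margins from the
#'   estimated hemodynamic delay ([segments_var()]).
#' * `REG` — per-voxel OLS residuals against the HRF-convolved task
#'   regressors (one per task condition, plus intercept).
#' * `BLOCKREG` — task regression first, then delay-adaptive concatenation
#'   of the residuals.
#'
#' Confounds are cut and concatenated identically to the data in all cases.
#'
#' @param method one of [extraction_methods()] (case-insensitive).
#' @param run a [bold_run()].
#' @param confounds confound data.frame aligned with the run.
#' @param design a [task_design()]; required for all methods except `ORIG`.
#' @param hrf HRF parameters for the task regressors.
#' @param shift a [estimate_shift()] result; required for `BLOCKVAR` and
#'   `BLOCKREG`.
#' @param post_gap,pre_extension,pre_extension_mode passed to
#'   [segments_fixed()].
#' @param min_seconds minimum retained duration for concatenation methods.
#' @param blockreg_intervals whether `BLOCKREG` reuses the delay-adaptive
#'   (`"var"`, default) or the fixed (`"fixed"`) cutting intervals.
#' @return an `extraction_result`.
#' @export
apply_method <- function(method, run, confounds, design = NULL,
                         hrf = hrf_params(), shift = NULL,
                         post_gap = 15, pre_extension = 5,
                         pre_extension_mode = "into_task",
                         min_seconds = 30,
                         blockreg_intervals = c("var", "fixed")) {
  method <- toupper(method)
  blockreg_intervals <- match.arg(blockreg_intervals)
  if (!method %in% extraction_methods())
    stop(sprintf("unknown extraction method '%s'; available: %s", method,
                 paste(extraction_methods(), collapse = ", ")))
  check_confounds(confounds, run)
  if (method != "ORIG" && is.null(design))
    stop(method, " requires a task design")
  if (method %in% c("BLOCKVAR", "BLOCKREG") && is.null(shift))
    stop(method, " requires a hemodynamic delay estimate ('shift')")
  if (!is.null(design) && design$n_volumes != n_volumes(run))
    stop("design and run disagree on the number of volumes")

  regress <- function(r) {
    Y <- t(run_matrix(r))                    # time x voxels
    res <- ols_residuals(Y, task_regressors(design, hrf))
    matrix_to_run(t(res), r)
  }

  switch(method,
    ORIG = new_extraction_result(run, confounds, "ORIG"),
    BLOCK = concatenate_run(run, confounds,
                            segments_fixed(design, post_gap, pre_extension,
                                           pre_extension_mode),
                            min_seconds, "BLOCK"),
    BLOCKVAR = concatenate_run(run, confounds, segments_var(design, shift),
                               min_seconds, "BLOCKVAR"),
    REG = new_extraction_result(regress(run), confounds, "REG"),
    BLOCKREG = {
      seg <- if (blockreg_intervals == "var") segments_var(design, shift)
             else segments_fixed(design, post_gap, pre_extension,
                                 pre_extension_mode)
      out <- concatenate_run(regress(run), confounds, seg, min_seconds,
                             "BLOCKREG")
      out
    })
}
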