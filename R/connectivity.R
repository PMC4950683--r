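#' Nuisance regression with a global-signal toggle
#'
#' Replaces each voxel's series by its OLS residual against the six motion
#' parameters, the white-matter and ventricular series, optionally the
#' global signal, and an intercept.
#'
#' @param run a [bold_run()].
#' @param confounds confound data.frame aligned with the run (see
#'   [read_confounds_tsv()] for the columns).
#' @param use_gsr include the global-signal column as a regressor.
#' @return a cleaned `bold_run`.
#' @export
nuisance_regress <- function(run, confounds, use_gsr = TRUE) {
  check_confounds(confounds, run)
  cols <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z",
            "white_matter", "csf", if (use_gsr) "global_signal")
  X <- as.matrix(confounds[, cols, drop = FALSE])
  res <- ols_residuals(t(run_matrix(run)), X)
  matrix_to_run(t(res), run)
}

# steady-state initial filter state for a unit step (transposed direct
# form II), so the forward pass starts without a start-up transient
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  comp <- rbind(-a[2:n] / a[1], cbind(diag(1, n - 2L), numeric(n - 2L)))
  solve(diag(1, n - 1L) - t(comp), b[2:n] - a[2:n] * b[1])
}

# one IIR pass over the columns of x with initial state zi scaled by the
# first sample of each column
iir_pass <- function(x, b, a, zi) {
  nb <- length(b)
  nz <- nb - 1L
  z <- zi %o% x[1L, ]
  y <- matrix(0, nrow(x), ncol(x))
  for (t in seq_len(nrow(x))) {
    xt <- x[t, ]
    yt <- b[1L] * xt + z[1L, ]
    if (nz > 1L)
      z[seq_len(nz - 1L), ] <- z[-1L, , drop = FALSE] +
        outer(b[2:nz], xt) - outer(a[2:nz], yt)
    z[nz, ] <- b[nb] * xt - a[nb] * yt
    y[t, ] <- yt
  }
  y
}

# zero-phase forward-backward filtering, vectorised over columns of x;
# odd-reflection padding plus steady-state initial conditions keep edge
# transients small even with poles near the unit circle (0.009 Hz edge)
filtfilt_matrix <- function(x, b, a) {
  n <- nrow(x)
  npad <- min(n - 1L, 3L * max(length(a), length(b)))
  zi <- lfilter_zi(b, a)
  top <- 2 * x[rep(1L, npad), , drop = FALSE] -
    x[npad + 2L - seq_len(npad), , drop = FALSE]
  bot <- 2 * x[rep(n, npad), , drop = FALSE] -
    x[n - seq_len(npad), , drop = FALSE]
  ext <- rbind(top, x, bot)
  y <- iir_pass(ext, b, a, zi)
  y <- iir_pass(y[rev(seq_len(nrow(y))), , drop = FALSE], b, a, zi)
  y <- y[rev(seq_len(nrow(y))), , drop = FALSE]
  y[npad + seq_len(n), , drop = FALSE]
}

#' Zero-phase band-pass filtering of a run
#'
#' Order-2 Butterworth band-pass applied forward and backward (zero phase)
#' to every voxel; the DC component is removed.
#'
#' @param run a [bold_run()].
#' @param low,high band edges in Hz; defaults 0.009 and 0.08.
#' @return the filtered `bold_run`.
#' @export
bandpass <- function(run, low = 0.009, high = 0.08) {
  n <- n_volumes(run)
  if (n < 12L)
    stop("run too short for band-pass filtering: need at least 12 volumes")
  nyq <- 1 / (2 * run$tr)
  if (!(0 < low && low < high && high < nyq))
    stop(sprintf("need 0 < low < high < Nyquist (%.3f Hz)", nyq))
  flt <- signal::butter(2, c(low, high) / nyq, type = "pass")
  x <- t(run_matrix(run))
  x <- sweep(x, 2L, colMeans(x))
  matrix_to_run(t(filtfilt_matrix(x, flt$b, flt$a)), run)
}

#' Mean time course of a cubic seed region
#'
#' @param run a [bold_run()].
#' @param center integer xyz voxel coordinate (1-based) of the cube centre.
#' @param edge voxels per side (odd; default 3, i.e. a 3x3x3 cube).
#' @return numeric vector, the per-volume mean over the cube.
#' @export
seed_timecourse <- function(run, center, edge = 3L) {
  stopifnot(length(center) == 3L, edge >= 1L, edge %% 2L == 1L)
  half <- (edge - 1L) %/% 2L
  d <- dim(run$data)[1:3]
  if (any(center - half < 1L) || any(center + half > d))
    stop(sprintf("seed cube at (%d, %d, %d) with edge %d exceeds the volume",
                 center[1], center[2], center[3], edge))
  cube <- run$data[center[1] + (-half:half), center[2] + (-half:half),
                   center[3] + (-half:half), , drop = FALSE]
  colMeans(matrix(cube, ncol = n_volumes(run)))
}

#' Voxelwise Fisher-z seed-correlation map
#'
#' Pearson correlation of every in-mask voxel with the seed time course,
#' clipped to `1 - 1e-7` in magnitude and Fisher z-transformed
#' (`atanh`), so perfectly correlated voxels stay finite.
#'
#' @param run a [bold_run()].
#' @param seed_ts seed time course (e.g. [seed_timecourse()]).
#' @param method,network optional tags stored in the map.
#' @param seed_center,seed_edge optional seed geometry stored in the map.
#' @return object of class `connectivity_map` with fields `z` (3D array,
#'   zero outside the mask), `mask`, `method`, `network`, `seed_center`,
#'   `seed_edge`.
#' @export
correlation_zmap <- function(run, seed_ts, method = NA_character_,
                             network = NA_character_, seed_center = NULL,
                             seed_edge = 3L) {
  seed_ts <- as.numeric(seed_ts)
  if (n_volumes(run) < 3L) stop("need at least 3 volumes for correlation")
  if (length(seed_ts) != n_volumes(run))
    stop("seed time course length does not match the run")
  if (stats::sd(seed_ts) == 0) stop("seed time course is constant")
  m <- run_matrix(run)
  sds <- apply(m, 1L, stats::sd)
  r <- numeric(nrow(m))
  ok <- sds > 0
  r[ok] <- as.vector(stats::cor(seed_ts, t(m[ok, , drop = FALSE])))
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- array(0, dim = dim(run$mask))
  z[run$mask] <- atanh(r)
  structure(list(z = z, mask = run$mask, method = method, network = network,
                 seed_center = seed_center, seed_edge = seed_edge),
            class = "connectivity_map")
}

#' @export
print.connectivity_map <- function(x, ...) {
  v <- x$z[x$mask]
  cat(sprintf("Connectivity z-map [%s/%s]: %d voxels, z in [%.2f, %.2f]\n",
              x$method, x$network, length(v), min(v), max(v)))
  invisible(x)
}

#' In-mask values of a connectivity map
#' @param map a `connectivity_map`.
#' @return numeric vector of z values over the mask.
#' @export
map_values <- function(map) map$z[map$mask]

#' Seed-based connectivity for one extraction result
#'
#' The fixed processing order is nuisance regression, then zero-phase
#' band-pass filtering, then per-seed cube extraction and Fisher-z
#' correlation mapping. For concatenated (BLOCK-family) inputs the filter is
#' applied to the concatenated series, after extraction.
#'
#' @param extraction an `extraction_result` (or a [bold_run()] with
#'   `confounds` supplied).
#' @param seeds named list of integer xyz seed centres, one per network.
#' @param use_gsr include global-signal regression.
#' @param low,high band-pass edges in Hz.
#' @param seed_edge seed cube side length in voxels.
#' @param confounds required when `extraction` is a bare `bold_run`.
#' @return named list of `connectivity_map`s, one per network.
#' @export
run_connectivity <- function(extraction, seeds, use_gsr = TRUE,
                             low = 0.009, high = 0.08, seed_edge = 3L,
                             confounds = NULL) {
  if (inherits(extraction, "bold_run")) {
    stopifnot(!is.null(confounds))
    extraction <- new_extraction_result(extraction, confounds, "ORIG")
  }
  stopifnot(inherits(extraction, "extraction_result"))
  if (is.null(names(seeds)) || any(names(seeds) == ""))
    stop("'seeds' must be a named list (one entry per network)")
  cleaned <- nuisance_regress(extraction$run, extraction$confounds, use_gsr)
  filtered <- bandpass(cleaned, low, high)
  lapply(stats::setNames(names(seeds), names(seeds)), function(nm) {
    ts <- seed_timecourse(filtered, seeds[[nm]], seed_edge)
    correlation_zmap(filtered, ts, method = extraction$method, network = nm,
                     seed_center = seeds[[nm]], seed_edge = seed_edge)
  })
}

#' Write a connectivity map as NIfTI plus a JSON sidecar
#' @param map a `connectivity_map`.
#' @param path output NIfTI path; the sidecar replaces the extension with
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_zmap_nifti <- function(map, path) {
  RNifti::writeNifti(RNifti::asNifti(map$z), path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(method = map$method, network = map$network,
                            seed_center = map$seed_center,
                            seed_edge = map$seed_edge),
                       side, auto_unbox = TRUE)
  invisible(path)
}
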