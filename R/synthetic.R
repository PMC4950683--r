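#' Band-limited Gaussian series
#'
#' White Gaussian noise restricted to a frequency band by a hard FFT mask and
#' rescaled to unit variance. This is the latent-signal model of the
#' synthetic generator: power is concentrated in the analysis band so that
#' network connectivity is identifiable downstream.
#'
#' @param n number of time points.
#' @param tr sampling interval in seconds.
#' @param band two-sided frequency band in Hz, default the resting-state
#'   analysis band.
#' @param m number of independent series to draw.
#' @return an `n` x `m` matrix, each column unit variance and zero mean.
#' @export
bandlimited_series <- function(n, tr, band = c(0.009, 0.08), m = 1L) {
  stopifnot(n >= 4L, tr > 0, band[1] < band[2])
  x <- matrix(stats::rnorm(n * m), n, m)
  freq <- (seq_len(n) - 1L) / (n * tr)
  freq <- pmin(freq, 1 / tr - freq)   # fold to [0, Nyquist]
  keep <- freq >= band[1] & freq <= band[2]
  if (!any(keep)) stop("band contains no Fourier frequencies at this length")
  X <- stats::mvfft(x)
  X[!keep, ] <- 0
  y <- Re(stats::mvfft(X, inverse = TRUE)) / n
  sweep(sweep(y, 2L, colMeans(y)), 2L, apply(y, 2L, stats::sd), "/")
}

default_network_masks <- function(grid = c(20L, 20L, 10L)) {
  cube <- function(x0, y0, z0) {
    m <- array(FALSE, dim = grid)
    m[x0 + 0:2, y0 + 0:2, z0 + 0:2] <- TRUE
    m
  }
  list(dmn = cube(3L, 3L, 3L),
       cuneus = cube(15L, 3L, 3L),
       thalamus = cube(3L, 15L, 3L),
       sensorimotor = cube(15L, 15L, 6L),
       auditory = cube(9L, 15L, 6L),
       occipital = cube(9L, 3L, 6L))
}

#' Ground-truth parameters for the synthetic BOLD generator
#'
#' Defines the study conditions the simulator emulates: a small voxel grid
#' with rectangular network masks sharing band-limited spontaneous signal,
#' task-evoked responses with per-subject hemodynamic delays, nuisance
#' components (global fluctuation, motion-coupled signal, tissue signals) and
#' white noise. The `occipital` mask doubles as the ROI for hemodynamic-delay
#' estimation, mirroring an occipital sphere placement on real data.
#'
#' @param grid spatial dimensions of the synthetic brain.
#' @param networks named list of 3D logical masks; must fit inside `grid`.
#' @param tr repetition time in seconds.
#' @param rest_seconds duration of a rest acquisition.
#' @param latent_amp amplitude of each network's shared latent signal.
#' @param task_amplitude named vector: evoked-response amplitude per network
#'   (signal units; negative values model task deactivation). Networks not
#'   named carry no evoked response.
#' @param global_amp amplitude of the global fluctuation shared by all voxels.
#' @param motion_amp amplitude of the motion-coupled artefact signal.
#' @param tissue_amp amplitude of the white-matter/ventricular signal leakage.
#' @param noise_sd standard deviation of additive white noise.
#' @param band frequency band of the latent signals (Hz).
#' @param delay_range_trs inclusive integer range (in TRs) from which
#'   per-subject hemodynamic delays are drawn uniformly.
#' @param hrf HRF parameters used for evoked responses.
#' @return a list of class `synth_truth`.
#' @export
synth_truth <- function(grid = c(20L, 20L, 10L),
                        networks = default_network_masks(grid),
                        tr = 1.4,
                        rest_seconds = 360,
                        latent_amp = 1,
                        task_amplitude = c(occipital = 1.2, sensorimotor = 0.8,
                                           dmn = -0.6),
                        global_amp = 0.3,
                        motion_amp = 0.2,
                        tissue_amp = 0.1,
                        noise_sd = 1,
                        band = c(0.009, 0.08),
                        delay_range_trs = c(2L, 5L),
                        hrf = hrf_params()) {
  stopifnot(length(grid) == 3L, all(grid >= 3L), noise_sd >= 0,
            all(vapply(networks, function(m) all(dim(m) == grid), logical(1L))))
  if (is.null(names(networks)) || any(names(networks) == ""))
    stop("'networks' must be a named list of masks")
  bad <- setdiff(names(task_amplitude), names(networks))
  if (length(bad))
    stop("task_amplitude names not among networks: ", paste(bad, collapse = ", "))
  stopifnot(delay_range_trs[1] >= 0L, delay_range_trs[2] <= 7L,
            delay_range_trs[1] <= delay_range_trs[2])
  structure(list(grid = as.integer(grid), networks = networks, tr = tr,
                 rest_seconds = rest_seconds, latent_amp = latent_amp,
                 task_amplitude = task_amplitude, global_amp = global_amp,
                 motion_amp = motion_amp, tissue_amp = tissue_amp,
                 noise_sd = noise_sd, band = band,
                 delay_range_trs = as.integer(delay_range_trs), hrf = hrf),
            class = "synth_truth")
}

#' Seed coordinates implied by the ground truth
#'
#' Centroid voxel (1-based indices) of each connectivity network mask, the
#' synthetic stand-in for seed coordinates in standard space.
#'
#' @param truth a [synth_truth()].
#' @param networks which networks to return; defaults to all but `occipital`.
#' @return named list of integer xyz coordinates.
#' @export
truth_seeds <- function(truth, networks = setdiff(names(truth$networks),
                                                  "occipital")) {
  lapply(stats::setNames(networks, networks), function(nm) {
    idx <- which(truth$networks[[nm]], arr.ind = TRUE)
    as.integer(round(colMeans(idx)))
  })
}

#' Simulate one subject's BOLD run and confounds
#'
#' Every network's voxels share a band-limited latent series; task runs add
#' an evoked response (summed condition boxcar, delayed by the subject's
#' hemodynamic delay, convolved with the canonical HRF, unit-peak normalised,
#' scaled by the network's amplitude); all voxels receive global, motion and
#' tissue nuisance components plus white noise. The returned confounds are
#' the generating motion (6), white-matter and ventricular series, and the
#' realised global mean of the data.
#'
#' @param truth a [synth_truth()].
#' @param run_kind `"rest"` or `"task"`.
#' @param design a [task_design()]; required for task runs and rejected for
#'   rest runs (zero `task_amplitude` in the truth to simulate a task
#'   acquisition without evoked signal).
#' @param delay_trs the subject's hemodynamic delay in integer TRs.
#' @param seed RNG seed; the run is a deterministic function of it.
#' @return list with elements `run` (a [bold_run()]), `confounds`
#'   (data.frame), `delay_trs`, and `run_kind`.
#' @export
generate_subject <- function(truth, run_kind = c("rest", "task"),
                             design = NULL, delay_trs = 0L, seed = 1L) {
  run_kind <- match.arg(run_kind)
  stopifnot(inherits(truth, "synth_truth"))
  if (run_kind == "rest" && !is.null(design))
    stop("rest runs take no task design; simulate a task run with zeroed ",
         "task_amplitude to obtain an activation-free task acquisition")
  if (run_kind == "task" && is.null(design))
    stop("task runs require a 'design'")
  if (run_kind == "task" && !any(design$events$label != design$baseline_label))
    stop("task design has no task events")
  stopifnot(delay_trs >= 0L, delay_trs == round(delay_trs))

  tr <- if (run_kind == "task") design$tr else truth$tr
  n_t <- if (run_kind == "task") design$n_volumes
         else as.integer(ceiling(truth$rest_seconds / truth$tr))
  n_vox <- prod(truth$grid)
  set.seed(as.integer(seed))

  # shared latents: one per network, plus global / wm / csf sources
  nets <- names(truth$networks)
  lat <- bandlimited_series(n_t, tr, truth$band, m = length(nets) + 3L)
  y <- matrix(0, nrow = n_vox, ncol = n_t)
  for (i in seq_along(nets)) {
    v <- as.vector(truth$networks[[nets[i]]])
    y[v, ] <- y[v, ] + truth$latent_amp * rep(lat[, i], each = sum(v))
  }
  glob <- lat[, length(nets) + 1L]
  wm <- lat[, length(nets) + 2L]
  csf <- lat[, length(nets) + 3L]

  motion <- apply(matrix(stats::rnorm(n_t * 6L, sd = 0.02), n_t, 6L), 2L, cumsum)
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  msig <- scale(rowSums(motion))[, 1L]

  w_glob <- stats::runif(n_vox, 0.5, 1.5)
  w_mot <- stats::runif(n_vox, 0, 1)
  w_tis <- stats::runif(n_vox, 0, 1)
  y <- y + truth$global_amp * outer(w_glob, glob) +
    truth$motion_amp * outer(w_mot, msig) +
    truth$tissue_amp * outer(w_tis, wm + csf) / 2

  if (run_kind == "task") {
    task_labs <- setdiff(unique(design$events$label), design$baseline_label)
    box <- Reduce(`+`, lapply(task_labs, function(l) boxcar(design, l)))
    resp <- evoked_response(box, delay_trs, truth$hrf, tr)
    for (nm in names(truth$task_amplitude)) {
      a <- truth$task_amplitude[[nm]]
      if (a == 0) next
      v <- as.vector(truth$networks[[nm]])
      y[v, ] <- y[v, ] + a * rep(resp, each = sum(v))
    }
  }

  if (truth$noise_sd > 0)
    y <- y + matrix(stats::rnorm(n_vox * n_t, sd = truth$noise_sd), n_vox, n_t)

  run <- bold_run(array(y, dim = c(truth$grid, n_t)), tr = tr)
  confounds <- data.frame(motion, white_matter = wm, csf = csf,
                          global_signal = colMeans(y))
  list(run = run, confounds = confounds, delay_trs = as.integer(delay_trs),
       run_kind = run_kind)
}

# boxcar delayed by whole TRs, convolved with the canonical HRF,
# unit-peak normalised so task_amplitude is in signal units
evoked_response <- function(box, delay_trs, hrf, tr) {
  n <- length(box)
  shifted <- shift_boxcar(box, delay_trs)
  resp <- convolve_regressor(shifted, canonical_hrf(hrf, tr))
  m <- max(abs(resp))
  if (m > 0) resp <- resp / m
  resp
}

#' Simulate a multi-subject study
#'
#' Draws a hemodynamic delay per subject (discrete uniform over
#' `truth$delay_range_trs`) and generates, for each subject, a rest run, a
#' second independent rest run (the test-retest stand-in for a repeat visit),
#' and one task run per supplied design, with confounds. All runs are
#' deterministic functions of `seed`.
#'
#' @param truth a [synth_truth()].
#' @param n_subjects number of subjects (>= 2).
#' @param designs named list of [task_design()] objects (e.g.
#'   `list(rft = design_rft(), edt = design_edt())`).
#' @param seed master RNG seed; per-subject, per-run streams are derived
#'   from it.
#' @param retest whether to generate the second rest run.
#' @return list with `subjects` (per-subject list of runs, confounds and true
#'   delay), `truth`, and a `manifest` data.frame (subject, run, kind,
#'   volumes, delay_trs).
#' @export
generate_group <- function(truth, n_subjects = 8L,
                           designs = list(rft = design_rft(),
                                          edt = design_edt()),
                           seed = 1L, retest = TRUE) {
  stopifnot(inherits(truth, "synth_truth"))
  if (n_subjects < 2L)
    stop("'n_subjects' must be at least 2: group statistics are undefined ",
         "for a single subject")
  seed <- as.integer(seed)
  set.seed(seed)
  delays <- sample(seq(truth$delay_range_trs[1], truth$delay_range_trs[2]),
                   n_subjects, replace = TRUE)
  run_names <- c("rest", if (retest) "retest", names(designs))
  subjects <- vector("list", n_subjects)
  manifest <- NULL
  for (s in seq_len(n_subjects)) {
    runs <- list()
    for (r in seq_along(run_names)) {
      rn <- run_names[r]
      rs <- derive_seed(seed, s, r)
      runs[[rn]] <- if (rn %in% c("rest", "retest"))
        generate_subject(truth, "rest", seed = rs)
      else
        generate_subject(truth, "task", design = designs[[rn]],
                         delay_trs = delays[s], seed = rs)
      manifest <- rbind(manifest, data.frame(
        subject = s, run = rn, kind = runs[[rn]]$run_kind,
        volumes = n_volumes(runs[[rn]]$run), delay_trs = runs[[rn]]$delay_trs))
    }
    subjects[[s]] <- list(id = s, delay_trs = delays[s], runs = runs)
  }
  list(subjects = subjects, truth = truth, designs = designs,
       manifest = manifest, seed = seed)
}

# deterministic per-subject, per-run stream; kept inside 32-bit range
derive_seed <- function(master, subject, run) {
  as.integer((as.double(master) * 2654435761 + subject * 97561 + run * 7919) %%
               2147483647)
}
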