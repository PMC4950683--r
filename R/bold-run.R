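#' In-memory 4D BOLD run
#'
#' Wraps a 4D array `(x, y, z, t)` together with its repetition time and a
#' 3D brain mask. All pipeline stages operate on this container; helpers
#' convert between the 4D layout and a voxels-in-mask x time matrix.
#'
#' @param data 4D numeric array `(x, y, z, t)`.
#' @param tr repetition time in seconds.
#' @param mask 3D logical array matching the spatial dimensions; defaults to
#'   all voxels in-mask.
#' @return an object of class `bold_run`.
#' @export
bold_run <- function(data, tr, mask = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 4L)
  if (dim(data)[4L] < 2L) stop("a BOLD run needs at least 2 volumes")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("'tr' must be a single positive number of seconds")
  if (is.null(mask)) mask <- array(TRUE, dim = dim(data)[1:3])
  stopifnot(is.logical(mask), all(dim(mask) == dim(data)[1:3]))
  if (!any(mask)) stop("brain mask is empty")
  if (!all(is.finite(data[rep(as.vector(mask), dim(data)[4L])])))
    stop("non-finite values inside the brain mask")
  structure(list(data = data, tr = tr, mask = mask), class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("BOLD run: %dx%dx%d voxels x %d volumes, TR = %gs (%.1f s), %d in mask\n",
              d[1], d[2], d[3], d[4], x$tr, d[4] * x$tr, sum(x$mask)))
  invisible(x)
}

#' Number of volumes in a run
#' @param run a [bold_run()].
#' @return integer volume count.
#' @export
n_volumes <- function(run) dim(run$data)[4L]

#' Extract the voxels-in-mask x time matrix of a run
#' @param run a [bold_run()].
#' @return numeric matrix, one row per in-mask voxel (mask order), one column
#'   per volume.
#' @export
run_matrix <- function(run) {
  t <- n_volumes(run)
  m <- matrix(run$data, ncol = t)[as.vector(run$mask), , drop = FALSE]
  m
}

#' Rebuild a run from a voxels-in-mask x time matrix
#'
#' Inverse of [run_matrix()]: out-of-mask voxels are set to zero.
#'
#' @param mat matrix with `sum(mask)` rows.
#' @param template a `bold_run` supplying tr, mask and spatial dimensions.
#' @return a `bold_run` with `ncol(mat)` volumes.
#' @export
matrix_to_run <- function(mat, template) {
  stopifnot(nrow(mat) == sum(template$mask))
  t <- ncol(mat)
  full <- matrix(0, nrow = prod(dim(template$mask)), ncol = t)
  full[as.vector(template$mask), ] <- mat
  bold_run(array(full, dim = c(dim(template$mask), t)),
           tr = template$tr, mask = template$mask)
}

#' Keep only the first volumes of a run
#' @param run a [bold_run()].
#' @param volumes 0-based volume indices to keep, in order.
#' @return a `bold_run` with `length(volumes)` volumes.
#' @keywords internal
slice_run <- function(run, volumes) {
  stopifnot(all(volumes >= 0L), all(volumes < n_volumes(run)))
  bold_run(run$data[, , , volumes + 1L, drop = FALSE], run$tr, run$mask)
}

#' Read a 4D NIfTI file as a `bold_run`
#' @param path NIfTI file path.
#' @param tr repetition time; taken from the header `pixdim` when `NULL`.
#' @param mask optional 3D logical mask.
#' @return a `bold_run`.
#' @export
read_bold_nifti <- function(path, tr = NULL, mask = NULL) {
  img <- RNifti::readNifti(path)
  if (is.null(tr)) tr <- RNifti::pixdim(img)[4L]
  bold_run(array(as.numeric(img), dim = dim(img)), tr = tr, mask = mask)
}

#' Write a `bold_run` as a 4D NIfTI file
#' @param run a [bold_run()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(run, path) {
  img <- RNifti::asNifti(run$data)
  RNifti::pixdim(img) <- c(1, 1, 1, run$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a confounds table
#'
#' Tab-separated, header row, columns `trans_x`, `trans_y`, `trans_z`,
#' `rot_x`, `rot_y`, `rot_z`, `white_matter`, `csf`, `global_signal`.
#'
#' @param path confounds TSV path.
#' @return a data.frame with the nine confound columns.
#' @export
read_confounds_tsv <- function(path) {
  cf <- utils::read.delim(path, sep = "\t")
  need <- confound_columns()
  if (!all(need %in% names(cf)))
    stop("confounds file must have columns: ", paste(need, collapse = ", "))
  cf[, need, drop = FALSE]
}

#' Write a confounds table
#' @param confounds confound data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_confounds_tsv <- function(confounds, path) {
  utils::write.table(confounds, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

confound_columns <- function() {
  c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z",
    "white_matter", "csf", "global_signal")
}

check_confounds <- function(confounds, run) {
  stopifnot(is.data.frame(confounds))
  miss <- setdiff(confound_columns(), names(confounds))
  if (length(miss))
    stop("confounds missing columns: ", paste(miss, collapse = ", "))
  if (nrow(confounds) != n_volumes(run))
    stop(sprintf("confounds have %d rows but the run has %d volumes",
                 nrow(confounds), n_volumes(run)))
  if (!all(vapply(confounds, function(c) all(is.finite(c)), logical(1L))))
    stop("confounds contain non-finite values")
  invisible(confounds)
}
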