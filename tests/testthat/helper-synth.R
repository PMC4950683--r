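# small synthetic settings for fast unit tests; the acceptance suite uses
# the package defaults

small_truth <- function(task_amplitude = c(occipital = 1.2), ...) {
  grid <- c(10L, 10L, 6L)
  cube <- function(x0, y0, z0) {
    m <- array(FALSE, dim = grid)
    m[x0 + 0:2, y0 + 0:2, z0 + 0:2] <- TRUE
    m
  }
  synth_truth(grid = grid,
              networks = list(net_a = cube(2L, 2L, 2L),
                              net_b = cube(7L, 7L, 2L),
                              occipital = cube(7L, 2L, 2L)),
              task_amplitude = task_amplitude,
              ...)
}

# constant-free random run for plumbing tests
random_run <- function(nx = 3L, ny = 3L, nz = 3L, nt = 40L, tr = 1.4,
                       seed = 1L) {
  set.seed(seed)
  bold_run(array(rnorm(nx * ny * nz * nt), dim = c(nx, ny, nz, nt)), tr)
}

random_confounds <- function(nt, seed = 1L) {
  set.seed(seed)
  cf <- as.data.frame(matrix(rnorm(nt * 9L), nt, 9L))
  names(cf) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z",
                 "white_matter", "csf", "global_signal")
  cf
}
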