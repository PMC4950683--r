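test_that("nuisance regression removes exactly the modelled confounds", {
  nt <- 80L
  cf <- random_confounds(nt, seed = 3)
  # make the global signal orthogonal to the other confounds
  others <- as.matrix(cf[, 1:8])
  cf$global_signal <- qr.resid(qr(cbind(1, others)), cf$global_signal)
  arr <- array(0, dim = c(2, 1, 1, nt))
  arr[1, 1, 1, ] <- cf$global_signal
  arr[2, 1, 1, ] <- rnorm(nt)
  run <- bold_run(arr, 1.4)
  with_gsr <- nuisance_regress(run, cf, use_gsr = TRUE)
  expect_lt(max(abs(run_matrix(with_gsr)[1, ])), 1e-8)
  no_gsr <- nuisance_regress(run, cf, use_gsr = FALSE)
  expect_gt(cor(run_matrix(no_gsr)[1, ], cf$global_signal), 0.999)
  cf_bad <- cf; cf_bad$white_matter <- 0 * cf_bad$white_matter
  expect_error(nuisance_regress(run, cf_bad), "rank deficient")
  expect_error(nuisance_regress(run, cf[1:10, ]), "rows")
})

test_that("band-pass keeps in-band power and rejects out-of-band power", {
  tr <- 1.4; n <- 256L
  mk <- function(f) {
    s <- sin(2 * pi * f * (0:(n - 1)) * tr)
    bold_run(array(rep(s, each = 8), dim = c(2, 2, 2, n)), tr)
  }
  ratio <- function(f) {
    y <- run_matrix(bandpass(mk(f)))[1, ]
    x <- run_matrix(mk(f))[1, ]
    sum(y^2) / sum(x^2)   # FFT-equivalent power oracle on a pure tone
  }
  expect_gt(ratio(0.04), 0.9)
  expect_lt(ratio(0.2), 0.1)
  const <- bandpass(bold_run(array(7, dim = c(2, 2, 2, 64)), tr))
  expect_lt(max(abs(run_matrix(const))), 1e-8)
  expect_error(bandpass(random_run(2, 2, 2, 8)), "at least 12")
  expect_error(bandpass(random_run(2, 2, 2, 64), low = 0.1, high = 0.5),
               "Nyquist")
})

test_that("zero-phase filtering preserves lag structure", {
  tr <- 1.4; n <- 200L
  s <- sin(2 * pi * 0.03 * (0:(n - 1)) * tr)
  run <- bold_run(array(rep(s, each = 4), dim = c(2, 2, 1, n)), tr)
  y <- run_matrix(bandpass(run))[1, ]
  # peak cross-correlation with the input at zero lag
  lags <- -5:5
  cc <- vapply(lags, function(l) {
    idx <- seq(max(1, 1 + l), min(n, n + l))
    cor(y[idx], s[idx - l])
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 0L)
})

test_that("seed cube mean equals the direct 27-voxel average and bounds are checked", {
  run <- random_run(5, 5, 5, 30)
  ts <- seed_timecourse(run, c(3, 3, 3))
  oracle <- colMeans(matrix(run$data[2:4, 2:4, 2:4, ], ncol = 30))
  expect_equal(ts, oracle)
  same <- bold_run(array(rep(sin(1:30), each = 27), dim = c(3, 3, 3, 30)), 1)
  expect_equal(seed_timecourse(same, c(2, 2, 2)), sin(1:30))
  expect_error(seed_timecourse(run, c(1, 3, 3)), "exceeds the volume")
})

test_that("Fisher-z maps clip perfect correlation and are antisymmetric", {
  run <- random_run(3, 3, 3, 40)
  seed_ts <- run$data[1, 1, 1, ]
  map <- correlation_zmap(run, seed_ts)
  expect_equal(map$z[1, 1, 1], atanh(1 - 1e-7))
  neg <- correlation_zmap(run, -seed_ts)
  expect_equal(neg$z[1, 1, 1], -atanh(1 - 1e-7))
  expect_equal(map_values(neg), -map_values(map))
  # orthogonal series -> z ~ 0
  x <- rep(c(1, -1), 20); y <- rep(c(1, 1, -1, -1), 10)
  arr <- array(rep(x, each = 8), dim = c(2, 2, 2, 40))
  expect_lt(abs(correlation_zmap(bold_run(arr, 1), y)$z[1, 1, 1]), 1e-10)
  expect_error(correlation_zmap(run, rep(1, 40)), "constant")
})

test_that("z maps are invariant under positive affine rescaling of the data", {
  run <- random_run(3, 3, 3, 40)
  seed_ts <- seed_timecourse(run, c(2, 2, 2))
  scaled <- bold_run(3 * run$data + 5, run$tr)
  expect_equal(map_values(correlation_zmap(scaled, seed_ts)),
               map_values(correlation_zmap(run, seed_ts)), tolerance = 1e-10)
})

test_that("run_connectivity fans out over seeds, deterministically, in a fixed order", {
  tr <- small_truth()
  s <- generate_subject(tr, "rest", seed = 19)
  seeds <- truth_seeds(tr)
  maps <- run_connectivity(s$run, seeds, confounds = s$confounds)
  expect_named(maps, names(seeds))
  maps2 <- run_connectivity(s$run, seeds, confounds = s$confounds)
  expect_identical(lapply(maps, `[[`, "z"), lapply(maps2, `[[`, "z"))
  # order is regression then filtering: permuting the stages changes output
  cleaned_first <- bandpass(nuisance_regress(s$run, s$confounds, TRUE))
  filtered_first <- nuisance_regress(bandpass(s$run), s$confounds, TRUE)
  expect_equal(run_matrix(cleaned_first),
               run_matrix(bandpass(nuisance_regress(s$run, s$confounds,
                                                    TRUE))))
  expect_gt(max(abs(run_matrix(cleaned_first) - run_matrix(filtered_first))),
            1e-6)
  ts <- seed_timecourse(cleaned_first, seeds$net_a)
  expect_equal(map_values(maps$net_a),
               map_values(correlation_zmap(cleaned_first, ts)))
})

test_that("seed maps recover the generator's network structure at rest", {
  tr <- small_truth()
  s <- generate_subject(tr, "rest", seed = 23)
  maps <- run_connectivity(s$run, truth_seeds(tr), confounds = s$confounds)
  z <- maps$net_a$z
  inside <- mean(z[tr$networks$net_a])
  outside <- mean(z[!tr$networks$net_a & s$run$mask])
  expect_gt(inside, outside + 0.3)
})

test_that("a z map survives the NIfTI + sidecar round trip", {
  run <- random_run(3, 3, 3, 40)
  map <- correlation_zmap(run, seed_timecourse(run, c(2, 2, 2)),
                          method = "ORIG", network = "net_a",
                          seed_center = c(2, 2, 2))
  f <- tempfile(fileext = ".nii.gz")
  write_zmap_nifti(map, f)
  back <- RNifti::readNifti(f)
  expect_equal(array(as.numeric(back), dim = dim(map$z)), map$z,
               tolerance = 1e-6)
  side <- jsonlite::read_json(sub("\\.nii\\.gz$", ".json", f),
                              simplifyVector = TRUE)
  expect_equal(side$method, "ORIG")
  expect_equal(side$seed_center, c(2, 2, 2))
})
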