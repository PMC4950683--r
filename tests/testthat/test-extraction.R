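test_that("fixed cutting on the RFT design retains less than 30 s", {
  seg <- segments_fixed(design_rft())
  retained <- segment_volumes(seg) * 1.4
  expect_lt(retained, 30)
  expect_gt(retained, 0)
})

test_that("fixed cutting keeps an unflanked baseline whole and drops short ones", {
  lone <- task_design(data.frame(label = "baseline", onset = 0,
                                 duration = 14),
                      tr = 1, n_volumes = 14L)
  seg <- segments_fixed(lone)
  expect_equal(seg$intervals, data.frame(start = 0L, end = 14L))
  # 12 s baseline between two task blocks, post_gap 15: nothing survives
  squeezed <- task_design(data.frame(label = c("go", "baseline", "go"),
                                     onset = c(0, 10, 22),
                                     duration = c(10, 12, 10)),
                          tr = 1)
  expect_equal(nrow(segments_fixed(squeezed, pre_extension = 0)$intervals),
               0L)
  no_base <- task_design(data.frame(label = "go", onset = 0, duration = 10),
                         tr = 1, n_volumes = 10L)
  expect_error(segments_fixed(no_base), "no baseline")
})

test_that("fixed cutting on the EDT design matches hand arithmetic", {
  seg <- segments_fixed(design_edt())
  # leading baseline [0, 25) s; seven interior [task_end+15, next_onset+5);
  # final [335, 340) s; volumes: start ceil, end floor at TR 1.4
  expect_equal(seg$intervals$start[1], 0L)
  expect_equal(seg$intervals$end[1], 17L)     # floor(25 / 1.4)
  expect_equal(seg$intervals$start[2], 40L)   # ceil(55 / 1.4)
  expect_equal(seg$intervals$end[2], 46L)     # floor(65 / 1.4)
  expect_equal(nrow(seg$intervals), 9L)
  # independent arithmetic: interior baseline at onset o keeps [o+15, o+25) s
  interior <- vapply(seq(40, 280, by = 40), function(o) {
    floor((o + 25) / 1.4 + 1e-9) - ceiling((o + 15) / 1.4 - 1e-9)
  }, numeric(1))
  hand <- floor(25 / 1.4) + sum(interior) +
    (floor(340 / 1.4) - ceiling(335 / 1.4))
  expect_equal(segment_volumes(seg), as.integer(hand))
})

test_that("delay-adaptive cutting applies the shift and truncates at run end", {
  d <- design_edt()
  expect_equal(segments_var(d, 0)$intervals$start[1], 0L)
  # 20 s baseline at onset 40 s, shift 4 TRs (5.6 s): [45.6, 65.6) s
  seg <- segments_var(d, 4 * 1.4)
  expect_equal(seg$intervals$start[2], as.integer(ceiling(45.6 / 1.4)))
  expect_equal(seg$intervals$end[2], as.integer(floor(65.6 / 1.4)))
  # final baseline pushed past the run end is truncated
  last <- nrow(seg$intervals)
  expect_equal(seg$intervals$end[last], d$n_volumes)
  expect_lt((seg$intervals$end[last] - seg$intervals$start[last]) * 1.4, 20)
})

test_that("zero shift reproduces the baseline blocks exactly", {
  d <- task_design(data.frame(label = c("baseline", "go", "baseline"),
                              onset = c(0, 20, 40), duration = c(20, 20, 20)),
                   tr = 2)
  seg <- segments_var(d, 0)
  expect_equal(seg$intervals, data.frame(start = c(0L, 20L), end = c(10L, 30L)))
})

test_that("concatenation gathers exactly the selected volumes, in order", {
  run <- random_run(2, 2, 2, 50, tr = 1)
  cf <- random_confounds(50)
  seg <- restex:::new_segment_list(data.frame(start = c(5L, 30L),
                                              end = c(15L, 45L)), 1, 50L)
  out <- concatenate_run(run, cf, seg, min_seconds = 0)
  idx <- c(6:15, 31:45)
  expect_equal(run_matrix(out$run), run_matrix(run)[, idx])
  expect_equal(out$confounds$global_signal, cf$global_signal[idx])
  expect_equal(out$retained_seconds, 25)
  # identity when segments cover the run
  all_seg <- restex:::new_segment_list(data.frame(start = 0L, end = 50L), 1, 50L)
  expect_equal(run_matrix(concatenate_run(run, cf, all_seg,
                                          min_seconds = 0)$run),
               run_matrix(run))
})

test_that("concatenation refuses insufficient retained duration", {
  run <- random_run(2, 2, 2, 50, tr = 1)
  cf <- random_confounds(50)
  seg <- restex:::new_segment_list(data.frame(start = 0L, end = 10L), 1, 50L)
  expect_error(concatenate_run(run, cf, seg, min_seconds = 30,
                               method = "BLOCK"),
               "insufficient data for method BLOCK.*10\\.0 s")
  empty <- restex:::new_segment_list(data.frame(start = integer(),
                                                end = integer()), 1, 50L)
  expect_error(concatenate_run(run, cf, empty), "insufficient data")
})

test_that("OLS residuals are orthogonal to the regressors", {
  set.seed(10)
  Y <- matrix(rnorm(60 * 5), 60, 5)
  X <- matrix(rnorm(60 * 3), 60, 3)
  res <- ols_residuals(Y, X)
  expect_lt(max(abs(crossprod(cbind(1, X), res))), 1e-8)
  # channel equal to a regressor is fit perfectly
  res2 <- ols_residuals(cbind(X[, 1]), X)
  expect_lt(max(abs(res2)), 1e-10)
  # intercept-only model mean-centres
  res3 <- ols_residuals(Y, matrix(numeric(0), 60, 0))
  expect_equal(res3, sweep(Y, 2, colMeans(Y)), ignore_attr = TRUE)
  expect_error(ols_residuals(Y, cbind(a = X[, 1], b = X[, 1])),
               "rank deficient.*b")
})

test_that("each method transforms the run as specified", {
  tr <- small_truth()
  d <- design_edt()
  s <- generate_subject(tr, "task", design = d, delay_trs = 3, seed = 6)
  shift <- estimate_shift(roi_mean_timecourse(s$run, tr$networks$occipital),
                          boxcar(d, "emotion") + boxcar(d, "object"), d$tr)

  orig <- apply_method("ORIG", s$run, s$confounds, d)
  expect_equal(orig$retained_seconds, d$n_volumes * d$tr)
  expect_equal(run_matrix(orig$run), run_matrix(s$run))

  reg <- apply_method("REG", s$run, s$confounds, d)
  expect_equal(n_volumes(reg$run), d$n_volumes)
  R <- task_regressors(d)
  cors <- abs(cor(t(run_matrix(reg$run)), R))
  expect_lt(max(cors), 0.01)

  block <- apply_method("BLOCK", s$run, s$confounds, d)
  expect_equal(n_volumes(block$run), segment_volumes(segments_fixed(d)))

  bv <- apply_method("BLOCKVAR", s$run, s$confounds, d, shift = shift)
  expect_equal(n_volumes(bv$run),
               segment_volumes(segments_var(d, shift)))

  # BLOCKREG equals regression followed by delay-adaptive concatenation
  br <- apply_method("BLOCKREG", s$run, s$confounds, d, shift = shift)
  manual <- concatenate_run(reg$run, reg$confounds, segments_var(d, shift),
                            min_seconds = 30, method = "BLOCKREG")
  expect_equal(run_matrix(br$run), run_matrix(manual$run))

  expect_error(apply_method("FOO", s$run, s$confounds, d), "unknown")
  expect_error(apply_method("BLOCKVAR", s$run, s$confounds, d), "shift")
  expect_error(apply_method("REG", s$run, s$confounds), "task design")
})

test_that("REG on a run equal to the task regressor leaves near-zero residuals", {
  d <- design_rft()
  reg <- task_regressors(d)[, 1]
  arr <- array(rep(reg, each = 8), dim = c(2, 2, 2, d$n_volumes))
  run <- bold_run(arr, d$tr)
  out <- apply_method("REG", run, random_confounds(d$n_volumes), d)
  expect_lt(max(abs(run_matrix(out$run))), 1e-8)
})

test_that("retained durations order as ORIG = REG >= BLOCKVAR >= BLOCK on EDT", {
  tr <- small_truth()
  d <- design_edt()
  s <- generate_subject(tr, "task", design = d, delay_trs = 4, seed = 13)
  shift <- estimate_shift(roi_mean_timecourse(s$run, tr$networks$occipital),
                          boxcar(d, "emotion") + boxcar(d, "object"), d$tr)
  dur <- function(m) apply_method(m, s$run, s$confounds, d,
                                  shift = shift)$retained_seconds
  expect_equal(dur("ORIG"), dur("REG"))
  expect_gte(dur("REG"), dur("BLOCKVAR"))
  expect_gte(dur("BLOCKVAR"), dur("BLOCK"))
})

test_that("BLOCK on the RFT design reproduces the insufficient-data exclusion", {
  tr <- small_truth()
  d <- design_rft()
  s <- generate_subject(tr, "task", design = d, delay_trs = 3, seed = 17)
  expect_error(apply_method("BLOCK", s$run, s$confounds, d),
               "insufficient data for method BLOCK")
})
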