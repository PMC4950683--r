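test_that("ICC(A,1) matches the hand-computed two-way ANOVA table", {
  a <- c(1, 2, 3, 4)
  expect_equal(icc_maps(a, a), 1)
  # b = a + 10: row means 6..9, column means 2.5 / 12.5, grand mean 7.5;
  # MSR = 10/3, MSC = 200, MSE = 0 -> (10/3) / (10/3 + 100) = 1/31
  expect_equal(icc_maps(a, a + 10), 1 / 31)
  expect_lt(icc_maps(a, a + 10), 1)
  expect_lt(icc_maps(a, a + 10), icc_maps(a, a + 10, type = "consistency"))
  expect_equal(icc_maps(a, a + 10, type = "consistency"), 1)
  expect_error(icc_maps(rep(1, 4), rep(2, 4)), "undefined")
  expect_error(icc_maps(1:2, 1:2), "more than 2 voxels")
})

test_that("independent noise maps give near-zero ICC and R-squared", {
  set.seed(77)
  a <- rnorm(10000); b <- rnorm(10000)
  expect_lt(abs(icc_maps(a, b)), 0.05)
  expect_lt(as.numeric(r2_maps(a, b)), 0.01)
})

test_that("ICC is sensitive to offsets while R-squared is affine-invariant", {
  set.seed(5)
  a <- rnorm(500)
  expect_lt(icc_maps(a, a + 2), icc_maps(a, a))
  expect_equal(as.numeric(r2_maps(a, 2 * a + 1)), 1)
  expect_equal(as.numeric(r2_maps(a, a + 2)), 1)
})

test_that("Dice follows its set definition, including the empty case", {
  expect_equal(dice_maps(c(1, 1, 0, 0), c(1, 1, 0, 0), threshold = 0.5), 1)
  expect_equal(dice_maps(c(1, 1, 0, 0), c(0, 0, 1, 1), threshold = 0.5), 0)
  # |A| = 4, |B| = 4, overlap 2 -> 2*2 / 8 = 0.5
  a <- c(1, 1, 1, 1, 0, 0, 0, 0)
  b <- c(1, 1, 0, 0, 1, 1, 0, 0)
  expect_equal(dice_maps(a, b, threshold = 0.5), 0.5)
  d <- dice_maps(c(0, 0), c(0, 0), threshold = 0.3)
  expect_equal(as.numeric(d), 0)
  expect_true(attr(d, "empty"))
  # invariant to a monotone transform preserving the crossing set
  set.seed(9); x <- rnorm(200); y <- rnorm(200)
  expect_equal(dice_maps(x, y), dice_maps(sign(x - 0.3) * abs(x - 0.3)^0.5,
                                          sign(y - 0.3) * abs(y - 0.3)^0.5,
                                          threshold = 0))
})

test_that("all three metrics are symmetric in their arguments", {
  set.seed(11)
  x <- rnorm(300); y <- x * 0.5 + rnorm(300)
  expect_equal(icc_maps(x, y), icc_maps(y, x))
  expect_equal(dice_maps(x, y), dice_maps(y, x))
  expect_equal(as.numeric(r2_maps(x, y)), as.numeric(r2_maps(y, x)))
})

test_that("match_duration keeps exactly the first volumes", {
  run <- random_run(2, 2, 2, 30)
  expect_equal(run_matrix(match_duration(run, 30)), run_matrix(run))
  short <- match_duration(run, 7)
  expect_equal(n_volumes(short), 7L)
  expect_equal(run_matrix(short), run_matrix(run)[, 1:7])
  expect_error(match_duration(run, 0), "at least 1")
  expect_error(match_duration(run, 31), "cannot match")
})

test_that("similarity_records computes all metrics over the same voxel set", {
  run <- random_run(4, 4, 4, 60, seed = 2)
  seed_ts <- seed_timecourse(run, c(2, 2, 2))
  m1 <- correlation_zmap(run, seed_ts, network = "n1")
  run2 <- bold_run(run$data + array(rnorm(length(run$data), sd = 0.5),
                                    dim = dim(run$data)), run$tr)
  m2 <- correlation_zmap(run2, seed_timecourse(run2, c(2, 2, 2)),
                         network = "n1")
  rec <- similarity_records(list(n1 = m1), list(n1 = m2), subject = 1,
                            method = "ORIG")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$n_voxels, 64L)
  expect_equal(rec$icc, icc_maps(m1, m2))
  expect_equal(rec$dice, as.numeric(dice_maps(m1, m2)))
  expect_equal(rec$r2, as.numeric(r2_maps(m1, m2)))
  expect_equal(rec$r^2, rec$r2)
})

test_that("group statistics match textbook Welch t and detect shifts", {
  # hand-built table: 4 subjects x (one method + test-retest), dice metric
  a <- c(0.50, 0.60, 0.55, 0.65)
  b <- c(0.40, 0.45, 0.50, 0.42)
  rec <- data.frame(subject = rep(1:4, 2),
                    method = rep(c("REG", "TESTRETEST"), each = 4),
                    network = "dmn", icc = 0.5, r = 0.5, r2 = 0.25,
                    dice = c(a, b))
  g <- group_compare(rec, metrics = "dice")
  t_hand <- (mean(a) - mean(b)) / sqrt(var(a) / 4 + var(b) / 4)
  expect_equal(g$ttests$t, t_hand)
  expect_equal(g$ttests$mean_method, mean(a))

  # identical records across conditions: no effect anywhere
  rec0 <- rec; rec0$dice <- rep(a, 2)
  g0 <- group_compare(rec0, metrics = "dice")
  expect_equal(g0$anova$F, 0)
  expect_lt(abs(g0$ttests$t), 1e-10)

  # large constant shift: strongly significant
  rec2 <- rec; rec2$dice[rec2$method == "REG"] <- a - 0.3
  g2 <- group_compare(rec2, metrics = "dice")
  expect_lt(g2$ttests$p, 0.01)

  expect_error(group_compare(rec[rec$subject == 1, ]), "at least 2")
  expect_error(group_compare(rec[rec$method == "REG", ]), "TESTRETEST")
})

test_that("correlation-type metrics are Fisher z-transformed before testing", {
  set.seed(21)
  icc_a <- runif(6, 0.3, 0.5); icc_b <- runif(6, 0.5, 0.7)
  rec <- data.frame(subject = rep(1:6, 2),
                    method = rep(c("REG", "TESTRETEST"), each = 6),
                    network = "dmn", icc = c(icc_a, icc_b),
                    r = 0.5, r2 = 0.25, dice = 0.4)
  g <- group_compare(rec, metrics = "icc")
  t_hand <- unname(t.test(atanh(icc_a), atanh(icc_b))$statistic)
  expect_equal(g$ttests$t, t_hand)
})
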