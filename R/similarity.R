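map_vector <- function(map) {
  if (inherits(map, "connectivity_map")) map_values(map) else as.numeric(map)
}

check_map_pair <- function(a, b) {
  if (inherits(a, "connectivity_map") && inherits(b, "connectivity_map") &&
      !identical(dim(a$mask), dim(b$mask)))
    stop("maps have different mask geometry")
  va <- map_vector(a); vb <- map_vector(b)
  if (length(va) != length(vb)) stop("maps cover different voxel counts")
  list(a = va, b = vb, n = length(va))
}

#' Intraclass correlation between two maps
#'
#' Two-way absolute-agreement single-measures ICC (McGraw & Wong A,1) over
#' voxels, treating voxels as targets and the two maps as raters; computed
#' from the two-way ANOVA mean squares with k = 2. The consistency form
#' (C,1) is available via `type`. Unlike R-squared, the absolute-agreement
#' ICC penalises mean and scale offsets between the maps.
#'
#' @param map_a,map_b `connectivity_map`s (or numeric vectors) over the same
#'   mask.
#' @param type `"agreement"` (A,1; default) or `"consistency"` (C,1).
#' @return the ICC, a single number in `[-1, 1]`.
#' @export
icc_maps <- function(map_a, map_b, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  p <- check_map_pair(map_a, map_b)
  if (p$n <= 2L) stop("need more than 2 voxels for the ICC")
  if (stats::sd(p$a) == 0 && stats::sd(p$b) == 0)
    stop("both maps are constant; the ICC is undefined")
  x <- cbind(p$a, p$b)
  n <- p$n; k <- 2
  row_m <- rowMeans(x); col_m <- colMeans(x); g <- mean(x)
  msr <- k * sum((row_m - g)^2) / (n - 1)
  msc <- n * sum((col_m - g)^2) / (k - 1)
  mse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + g)^2) / ((n - 1) * (k - 1))
  if (type == "agreement")
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  else
    (msr - mse) / (msr + (k - 1) * mse)
}

#' Dice overlap of suprathreshold map regions
#'
#' Binarises each map at `z >= threshold` and returns
#' `2|A intersect B| / (|A| + |B|)`. When both suprathreshold sets are empty
#' the value is 0 and the result carries attribute `empty = TRUE`.
#'
#' @param map_a,map_b maps over the same mask.
#' @param threshold binarisation threshold on z (default 0.3).
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_maps <- function(map_a, map_b, threshold = 0.3) {
  p <- check_map_pair(map_a, map_b)
  A <- p$a >= threshold; B <- p$b >= threshold
  tot <- sum(A) + sum(B)
  if (tot == 0L) return(structure(0, empty = TRUE))
  2 * sum(A & B) / tot
}

#' Squared correlation between two maps
#'
#' Squared Pearson correlation across masked voxels; invariant to affine
#' rescaling of either map. The signed correlation is attached as attribute
#' `r` (used for Fisher z-transformation in group statistics).
#'
#' @param map_a,map_b maps over the same mask.
#' @return R-squared in `[0, 1]` with attribute `r`.
#' @export
r2_maps <- function(map_a, map_b) {
  p <- check_map_pair(map_a, map_b)
  if (stats::sd(p$a) == 0 || stats::sd(p$b) == 0)
    stop("a constant map has no defined correlation")
  r <- stats::cor(p$a, p$b)
  structure(r^2, r = r)
}

#' Truncate a rest run to a target duration
#'
#' Keeps the first `target_volumes` volumes, so each extraction method is
#' compared against rest data of matched length.
#'
#' @param rest_run a [bold_run()].
#' @param target_volumes number of volumes to keep (>= 1).
#' @return a `bold_run` of `target_volumes` volumes.
#' @export
match_duration <- function(rest_run, target_volumes) {
  stopifnot(inherits(rest_run, "bold_run"))
  if (target_volumes < 1L) stop("'target_volumes' must be at least 1")
  if (target_volumes > n_volumes(rest_run))
    stop(sprintf("rest run has %d volumes, cannot match %d",
                 n_volumes(rest_run), target_volumes))
  slice_run(rest_run, seq_len(target_volumes) - 1L)
}

#' Similarity of two map sets across networks
#'
#' Computes ICC, Dice and R-squared for each network's pair of maps and
#' returns one long-format row per network.
#'
#' @param maps_method named list of `connectivity_map`s (the extraction
#'   method condition).
#' @param maps_ref named list of reference maps (duration-matched rest),
#'   same names.
#' @param subject,method,gsr identifiers recorded in the rows.
#' @param dice_threshold threshold for [dice_maps()].
#' @return data.frame with columns subject, method, network, gsr, icc, dice,
#'   dice_empty, r, r2, n_voxels.
#' @export
similarity_records <- function(maps_method, maps_ref, subject, method,
                               gsr = TRUE, dice_threshold = 0.3) {
  stopifnot(setequal(names(maps_method), names(maps_ref)))
  rows <- lapply(names(maps_method), function(nm) {
    a <- maps_method[[nm]]; b <- maps_ref[[nm]]
    d <- dice_maps(a, b, dice_threshold)
    r2 <- r2_maps(a, b)
    data.frame(subject = subject, method = method, network = nm, gsr = gsr,
               icc = icc_maps(a, b), dice = as.numeric(d),
               dice_empty = isTRUE(attr(d, "empty")),
               r = attr(r2, "r"), r2 = as.numeric(r2),
               n_voxels = length(map_vector(a)))
  })
  do.call(rbind, rows)
}

fisher_clip <- function(x) atanh(pmin(pmax(x, -1 + 1e-7), 1 - 1e-7))

#' Group statistics across extraction methods
#'
#' Per metric and network: correlation-type metrics are Fisher z-transformed
#' (ICC via `atanh`; R-squared via its signed correlation; Dice left raw), a
#' one-way repeated-measures ANOVA tests the method factor (subjects as the
#' repeated factor, the test-retest condition included as a level), and
#' Welch two-sample t-tests compare each method against the test-retest
#' condition. P-values are reported two-sided and uncorrected.
#'
#' @param records long-format data.frame from [similarity_records()],
#'   containing the extraction methods and a test-retest condition.
#' @param retest_label method label of the test-retest condition.
#' @param metrics metrics to analyse.
#' @return list of class `group_comparison` with data.frames `anova`
#'   (metric, network, F, df1, df2, p) and `ttests` (metric, network,
#'   method, mean_method, mean_retest, t, df, p).
#' @export
group_compare <- function(records, retest_label = "TESTRETEST",
                          metrics = c("icc", "r2", "dice")) {
  stopifnot(is.data.frame(records),
            all(c("subject", "method", "network") %in% names(records)))
  if (length(unique(records$subject)) < 2L)
    stop("group statistics need at least 2 subjects")
  if (!retest_label %in% records$method)
    stop("records contain no '", retest_label, "' condition")
  transform_metric <- function(df, metric) {
    switch(metric,
           icc = fisher_clip(df$icc),
           r2 = fisher_clip(df$r),
           dice = df$dice)
  }
  anova_rows <- NULL; t_rows <- NULL
  for (metric in metrics) {
    for (nw in unique(records$network)) {
      d <- records[records$network == nw, , drop = FALSE]
      d$y <- transform_metric(d, metric)
      d$method <- factor(d$method)
      d$subject <- factor(d$subject)
      fit <- stats::aov(y ~ method + Error(subject), data = d)
      tab <- summary(fit)[["Error: Within"]][[1L]]
      Fval <- tab["method", "F value"]
      # no method variation at all: the F ratio is numerical noise (or 0/0
      # exactly); report no effect
      if (tab["method", "Sum Sq"] < 1e-12 && tab["Residuals", "Sum Sq"] < 1e-12)
        Fval <- 0
      anova_rows <- rbind(anova_rows, data.frame(
        metric = metric, network = nw,
        F = Fval,
        df1 = tab["method", "Df"], df2 = tab["Residuals", "Df"],
        p = tab["method", "Pr(>F)"]))
      ref <- d$y[d$method == retest_label]
      for (m in setdiff(levels(d$method), retest_label)) {
        v <- d$y[d$method == m]
        tt <- stats::t.test(v, ref)
        t_rows <- rbind(t_rows, data.frame(
          metric = metric, network = nw, method = m,
          mean_method = mean(v), mean_retest = mean(ref),
          t = unname(tt$statistic), df = unname(tt$parameter),
          p = tt$p.value))
      }
    }
  }
  structure(list(anova = anova_rows, ttests = t_rows,
                 retest_label = retest_label),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Repeated-measures ANOVA (method factor):\n")
  print(x$anova, row.names = FALSE, digits = 3)
  cat(sprintf("\nWelch t-tests vs %s:\n", x$retest_label))
  print(x$ttests, row.names = FALSE, digits = 3)
  invisible(x)
}
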