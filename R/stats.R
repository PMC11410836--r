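ANGLE_PARAMS <- c("HVA", "IMA", "PH1a", "MT1a", "MT2a", "MT3a", "MT4a",
                  "MT5a")

#' Per-parameter median of several raters' angle sets
#'
#' The manual reference for each parameter is the scalar median across
#' raters (with an even rater count, the mean of the middle two).
#'
#' @param raters List of `angle_set` objects (>= 1).
#' @return An `angle_set` of medians (HVA/IMA are medians of the raters'
#'   HVA/IMA, not differences of median inclinations).
#' @export
rater_median <- function(raters) {
  stopifnot(length(raters) >= 1)
  vals <- lapply(ANGLE_PARAMS, function(p) {
    v <- vapply(raters, function(r) {
      x <- r[[p]]
      if (is.null(x) || is.na(x)) stop("missing parameter ", p,
                                       " in a rater", call. = FALSE)
      x
    }, numeric(1))
    stats::median(v)
  })
  names(vals) <- ANGLE_PARAMS
  out <- vals[c("PH1a", paste0("MT", 1:5, "a"))]
  out <- angle_set(unlist(out), side = raters[[1]]$side)
  # keep the median HVA/IMA themselves (medians do not commute with
  # differencing)
  out$HVA <- vals$HVA
  out$IMA <- vals$IMA
  out
}

#' MAE against a reference with a one-tailed non-inferiority t-test
#'
#' Computes per-case absolute errors `AE_i = |auto_i - ref_i|`, their mean
#' (MAE), the one-sided 95% upper confidence bound of the mean AE, and the
#' p-value of a one-sample, one-tailed t-test of the alternative
#' hypothesis that the mean AE is below `bound` (default 3 degrees, the
#' margin below which manual goniometry is conventionally considered
#' good).
#'
#' With zero variance in the AEs the t statistic is undefined; the p-value
#' is then 0 when `MAE < bound`, 1 when `MAE > bound`, and 0.5 at equality.
#'
#' @param auto,reference Paired numeric vectors of measurements (degrees).
#' @param bound Non-inferiority margin in degrees (default 3).
#' @return List with `MAE`, `CI95_upper`, `p_value`, `AE` (per-case
#'   absolute errors), `n`.
#' @export
mae_test <- function(auto, reference, bound = 3) {
  stopifnot(length(auto) == length(reference))
  n <- length(auto)
  if (n < 2) stop("need at least 2 paired cases", call. = FALSE)
  ae <- abs(auto - reference)
  mae <- mean(ae)
  s <- stats::sd(ae)
  se <- s / sqrt(n)
  if (s == 0) {
    p <- if (mae < bound) 0 else if (mae > bound) 1 else 0.5
    ci <- mae
  } else {
    tt <- stats::t.test(ae, mu = bound, alternative = "less")
    p <- tt$p.value
    ci <- mae + stats::qt(0.95, df = n - 1) * se
  }
  list(MAE = mae, CI95_upper = ci, p_value = p, AE = ae, n = n)
}

#' Count absolute errors in clinical bands
#'
#' Bands are `[0, 3)`, `[3, 5]`, `(5, Inf)` degrees: "less than 3",
#' "between 3 and 5", "exceeding 5" with closed 3-5 endpoints.
#'
#' @param ae Numeric vector of absolute errors (>= 0).
#' @return Integer vector `c(lt3, band3to5, gt5)` summing to `length(ae)`.
#' @export
error_bands <- function(ae) {
  if (any(ae < 0)) stop("absolute errors must be non-negative",
                        call. = FALSE)
  c(lt3 = sum(ae < 3), band3to5 = sum(ae >= 3 & ae <= 5),
    gt5 = sum(ae > 5))
}

#' Pairwise inter-rater absolute differences
#'
#' For exactly three raters, per case: `Diff_12 = |r1 - r2|`,
#' `Diff_23 = |r2 - r3|`, `Diff_31 = |r3 - r1|`, and their mean
#' `Diff_123`.
#'
#' @param r1,r2,r3 Numeric vectors of per-case measurements by raters 1-3
#'   (equal length).
#' @return Data frame with columns `Diff_12`, `Diff_23`, `Diff_31`,
#'   `Diff_123`, one row per case.
#' @export
interrater_diffs <- function(r1, r2, r3) {
  if (missing(r3) || missing(r2)) {
    stop("exactly 3 raters are required", call. = FALSE)
  }
  stopifnot(length(r1) == length(r2), length(r2) == length(r3))
  d12 <- abs(r1 - r2); d23 <- abs(r2 - r3); d31 <- abs(r3 - r1)
  data.frame(Diff_12 = d12, Diff_23 = d23, Diff_31 = d31,
             Diff_123 = (d12 + d23 + d31) / 3)
}

#' Compare automatic error with inter-rater difference
#'
#' Two-tailed paired t-test on the per-case differences
#' `AE_i - Diff_123_i`. Identical vectors (all differences zero) return
#' p = 1 by convention.
#'
#' @param ae Per-case absolute errors of the automatic measurement.
#' @param diff123 Per-case inter-rater differences ([interrater_diffs()]).
#' @return List with `p_value`, `mean_difference` (AE minus Diff_123),
#'   `n`.
#' @export
compare_mae_vs_diff123 <- function(ae, diff123) {
  if (length(ae) != length(diff123)) {
    stop("length mismatch between AE and Diff_123", call. = FALSE)
  }
  n <- length(ae)
  if (n < 2) stop("need at least 2 cases", call. = FALSE)
  d <- ae - diff123
  if (stats::sd(d) == 0) {
    p <- if (all(d == 0)) 1 else 0
  } else {
    p <- stats::t.test(ae, diff123, paired = TRUE)$p.value
  }
  list(p_value = p, mean_difference = mean(d), n = n)
}

#' Sample size for the one-sided MAE non-inferiority t-test
#'
#' Smallest integer `n` such that a one-sample, one-sided t-test at level
#' `alpha` of H0: mean >= `bound` reaches the requested power when the
#' true mean error is `assumed_mae` with standard deviation `sd`. Power is
#' evaluated exactly with the noncentral t distribution:
#' `power(n) = P(T_{n-1, ncp} < t_{alpha, n-1})` with noncentrality
#' `ncp = (assumed_mae - bound) / (sd / sqrt(n))`, iterated over n.
#'
#' With the defaults (MAE 1.5 degrees, SD 3.58 degrees, margin 3 degrees,
#' power 0.99, alpha 0.05) the required size is 92 radiographs.
#'
#' @param assumed_mae Anticipated true mean absolute error, degrees.
#' @param sd Anticipated SD of the error, degrees.
#' @param bound Non-inferiority margin, degrees.
#' @param power Target power (0 < power < 1).
#' @param alpha One-sided significance level.
#' @return Integer sample size (>= 2).
#' @export
required_sample_size <- function(assumed_mae = 1.5, sd = 3.58, bound = 3,
                                 power = 0.99, alpha = 0.05) {
  stopifnot(power > 0, power < 1, sd > 0, alpha > 0, alpha < 1)
  if (assumed_mae >= bound) {
    stop("assumed MAE must be below the bound (zero effect)",
         call. = FALSE)
  }
  for (n in 2:1e6) {
    ncp <- (assumed_mae - bound) / (sd / sqrt(n))
    pow <- stats::pt(stats::qt(alpha, df = n - 1), df = n - 1, ncp = ncp)
    if (pow >= power) return(n)
  }
  stop("sample size exceeds 1e6; check the inputs", call. = FALSE)
}

#' Full validation report for a set of measured cases
#'
#' Reproduces the layout of a clinical validation table: for each
#' parameter (HVA, IMA, PH1a, MT1a-MT5a) the MAE of the automatic
#' measurement against the median of three raters, the one-sided 95%
#' upper confidence bound, the p-value of the one-tailed t-test against
#' `bound`, the error-band counts, the inter-rater difference summaries
#' (mean and SD of Diff_12, Diff_23, Diff_31, Diff_123 across cases), and
#' the two-tailed paired t-test comparing AE with Diff_123.
#'
#' @param auto List of `angle_set`s (automatic measurements), one per
#'   case.
#' @param raters List of cases, each a list of exactly 3 `angle_set`s.
#' @param bound Non-inferiority margin in degrees (default 3).
#' @return A `validation_report`: data frame with one row per parameter.
#' @export
validation_report <- function(auto, raters, bound = 3) {
  n <- length(auto)
  stopifnot(n == length(raters), n >= 2,
            all(vapply(raters, length, integer(1)) == 3))
  rows <- lapply(ANGLE_PARAMS, function(p) {
    a <- vapply(auto, function(x) x[[p]], numeric(1))
    r1 <- vapply(raters, function(x) x[[1]][[p]], numeric(1))
    r2 <- vapply(raters, function(x) x[[2]][[p]], numeric(1))
    r3 <- vapply(raters, function(x) x[[3]][[p]], numeric(1))
    # cases with a failed (NA) measurement are dropped per parameter;
    # the row's n records how many cases entered its statistics
    keep <- stats::complete.cases(a, r1, r2, r3)
    if (sum(keep) < 2) {
      return(data.frame(parameter = p, n = 0L, MAE = NA_real_,
                        CI95_upper = NA_real_, p_vs_bound = NA_real_,
                        n_lt3 = 0L, n_3to5 = 0L, n_gt5 = 0L,
                        Diff_12_mean = NA_real_, Diff_23_mean = NA_real_,
                        Diff_31_mean = NA_real_, Diff_123_mean = NA_real_,
                        Diff_123_sd_cases = NA_real_,
                        Diff_123_sd_pairs = NA_real_,
                        p_MAE_vs_Diff123 = NA_real_))
    }
    a <- a[keep]; r1 <- r1[keep]; r2 <- r2[keep]; r3 <- r3[keep]
    n <- sum(keep)
    ref <- apply(cbind(r1, r2, r3), 1, stats::median)
    mt <- mae_test(a, ref, bound = bound)
    bands <- error_bands(mt$AE)
    dif <- interrater_diffs(r1, r2, r3)
    cmp <- compare_mae_vs_diff123(mt$AE, dif$Diff_123)
    data.frame(parameter = p, n = n, MAE = mt$MAE,
               CI95_upper = mt$CI95_upper, p_vs_bound = mt$p_value,
               n_lt3 = bands[["lt3"]], n_3to5 = bands[["band3to5"]],
               n_gt5 = bands[["gt5"]],
               Diff_12_mean = mean(dif$Diff_12),
               Diff_23_mean = mean(dif$Diff_23),
               Diff_31_mean = mean(dif$Diff_31),
               Diff_123_mean = mean(dif$Diff_123),
               Diff_123_sd_cases = stats::sd(dif$Diff_123),
               Diff_123_sd_pairs = stats::sd(c(mean(dif$Diff_12),
                                               mean(dif$Diff_23),
                                               mean(dif$Diff_31))),
               p_MAE_vs_Diff123 = cmp$p_value)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("validation_report", class(out))
  out
}
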