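make_angleset <- function(base) {
  incl <- setNames(rep(90, 6) + seq(0, 2.5, by = 0.5),
                   paste0(bone_labels(), "a"))
  incl["PH1a"] <- base
  angle_set(incl)
}

test_that("rater medians follow the even/odd conventions", {
  a <- make_angleset(10); b <- make_angleset(12); c <- make_angleset(30)
  expect_equal(rater_median(list(a, b, c))$PH1a, 12)
  expect_equal(rater_median(list(a, a, a))$PH1a, 10)
  expect_equal(rater_median(list(a, b))$PH1a, 11)  # mean of middle two
  bad <- a; bad$MT4a <- NA_real_
  expect_error(rater_median(list(a, bad)), "missing parameter")
})

test_that("mae_test matches hand-computed values and conventions", {
  expect_equal(mae_test(c(1, 2, 3, 4), c(1, 2, 3, 4))$MAE, 0)
  # constant AE = 1: zero variance, bound 3 -> p = 0
  r <- mae_test(c(2, 3, 4, 5), c(1, 2, 3, 4), bound = 3)
  expect_equal(r$MAE, 1)
  expect_equal(r$p_value, 0)
  # 4-case toy input, hand-computed: AE = (1, 2, 2, 3)
  auto <- c(11, 10, 14, 20); ref <- c(10, 12, 12, 17)
  m <- mae_test(auto, ref, bound = 3)
  expect_equal(m$AE, c(1, 2, 2, 3))
  expect_equal(m$MAE, 2)
  s <- sd(c(1, 2, 2, 3)); se <- s / 2
  expect_equal(m$CI95_upper, 2 + qt(0.95, 3) * se)
  expect_equal(m$p_value, pt((2 - 3) / se, df = 3))
  expect_error(mae_test(1, 1), "at least 2")
})

test_that("mae_test p-value is confirmed by a bootstrap t within MC error", {
  set.seed(2024)
  ae <- abs(rnorm(30, 2.6, 1))
  m <- mae_test(ae, rep(0, 30), bound = 3)
  n <- 30
  tobs <- (mean(ae) - 3) / (sd(ae) / sqrt(n))
  z <- ae - mean(ae) + 3  # impose H0: mean = bound
  tstar <- vapply(1:10000, function(i) {
    zs <- sample(z, n, replace = TRUE)
    (mean(zs) - 3) / (sd(zs) / sqrt(n))
  }, numeric(1))
  p_boot <- mean(tstar <= tobs)
  expect_lt(abs(m$p_value - p_boot), 0.05)
})

test_that("error bands use [0,3), [3,5], (5,inf)", {
  expect_equal(unname(error_bands(c(2.9, 3.0, 5.0, 5.1))), c(1, 2, 1))
  expect_equal(unname(error_bands(rep(0, 4))), c(4, 0, 0))
  expect_equal(unname(error_bands(numeric(0))), c(0, 0, 0))
  expect_equal(sum(error_bands(runif(17, 0, 8))), 17)
  expect_error(error_bands(-1), "non-negative")
})

test_that("inter-rater differences match direct arithmetic", {
  d <- interrater_diffs(10, 12, 14)
  expect_equal(d$Diff_12, 2)
  expect_equal(d$Diff_23, 2)
  expect_equal(d$Diff_31, 4)
  expect_equal(d$Diff_123, 8 / 3)
  # identical raters -> all zero; permutation leaves Diff_123 unchanged
  expect_true(all(interrater_diffs(5, 5, 5) == 0))
  x <- runif(10); y <- runif(10); z <- runif(10)
  expect_equal(interrater_diffs(x, y, z)$Diff_123,
               interrater_diffs(z, x, y)$Diff_123)
  expect_error(interrater_diffs(x, y), "3 raters")
})

test_that("paired comparison of MAE and Diff_123 behaves at its edges", {
  x <- c(1, 2, 3, 4)
  expect_equal(compare_mae_vs_diff123(x, x)$p_value, 1)
  # constant shift with zero variance of the difference
  expect_equal(compare_mae_vs_diff123(x, x + 1)$p_value, 0)
  expect_equal(compare_mae_vs_diff123(x, x + 1)$mean_difference, -1)
  # construction guarantees ordering: precise auto vs noisy raters
  set.seed(11)
  auto_err <- abs(rnorm(200, 0, 0.5))
  d123 <- interrater_diffs(rnorm(200, 0, 2), rnorm(200, 0, 2),
                           rnorm(200, 0, 2))$Diff_123
  cmp <- compare_mae_vs_diff123(auto_err, d123)
  expect_lt(cmp$p_value, 0.05)
  expect_lt(cmp$mean_difference, 0)
  expect_error(compare_mae_vs_diff123(1:3, 1:4), "length mismatch")
})

test_that("power analysis reproduces its closed-form oracle and limits", {
  # independent route: continuous solution from power.t.test, ceilinged
  for (sd in c(1.79, 2.5, 3.58)) {
    cont <- power.t.test(delta = 1.5, sd = sd, sig.level = 0.05,
                         power = 0.99, type = "one.sample",
                         alternative = "one.sided")$n
    expect_equal(required_sample_size(1.5, sd, 3, 0.99, 0.05),
                 ceiling(cont))
  }
  # halving the SD quarters the sample size (within integer rounding)
  n_full <- required_sample_size(1.5, 3.58, 3, 0.99, 0.05)
  n_half <- required_sample_size(1.5, 1.79, 3, 0.99, 0.05)
  expect_lte(abs(n_half - n_full / 4), 2)
  # monotone in power and sd, antitone in the margin
  grid_pow <- vapply(c(0.5, 0.8, 0.9, 0.99),
                     function(p) required_sample_size(1.5, 3.58, 3, p),
                     numeric(1))
  expect_true(all(diff(grid_pow) >= 0))
  grid_sd <- vapply(c(1, 2, 3, 4),
                    function(s) required_sample_size(1.5, s, 3, 0.9),
                    numeric(1))
  expect_true(all(diff(grid_sd) >= 0))
  grid_bound <- vapply(c(2, 2.5, 3, 4),
                       function(b) required_sample_size(1.5, 3.58, b, 0.9),
                       numeric(1))
  expect_true(all(diff(grid_bound) <= 0))
  # vanishing power wants the minimal sample
  expect_equal(required_sample_size(1.5, 3.58, 3, power = 1e-6), 2)
  expect_error(required_sample_size(3.5, 3.58, 3), "below the bound")
})

test_that("validation reports aggregate per-parameter statistics coherently", {
  set.seed(3)
  n <- 12
  auto <- list(); raters <- list()
  for (i in 1:n) {
    incl <- setNames(90 + rnorm(6, 0, 5), paste0(bone_labels(), "a"))
    truth <- angle_set(incl)
    auto[[i]] <- angle_set(incl + rnorm(6, 0, 0.3))
    raters[[i]] <- lapply(1:3, function(r) angle_set(incl + rnorm(6, 0, 1)))
  }
  rep <- validation_report(auto, raters)
  expect_s3_class(rep, "validation_report")
  expect_equal(nrow(rep), 8)
  expect_true(all(rep$MAE >= 0))
  expect_equal(rep$n_lt3 + rep$n_3to5 + rep$n_gt5, rep(n, 8))
  expect_true(all(rep$Diff_123_mean >= 0))
})
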