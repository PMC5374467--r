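test_that("RMSE and correlation match hand arithmetic", {
  m <- decoding_metrics(c(0, 0), c(3, 4), allow_degenerate = TRUE)
  expect_equal(m$rmse, sqrt(12.5), tolerance = 1e-12)
  expect_true(is.na(m$cc))
  m2 <- decoding_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m2$rmse, 0)
  expect_equal(m2$cc, 1)
  # affine prediction: perfect correlation, RMSE by direct formula
  a <- c(1, 2, 3); p <- 2 * a + 7
  m3 <- decoding_metrics(a, p)
  expect_equal(m3$cc, 1, tolerance = 1e-12)
  expect_equal(m3$rmse, sqrt(mean((a - p)^2)), tolerance = 1e-12)
  expect_error(decoding_metrics(c(1, 1), c(1, 2)), "zero variance")
  expect_true(is.na(decoding_metrics(c(1, 1), c(1, 2),
                                     allow_degenerate = TRUE)$cc))
})

test_that("normalized-time resampling preserves structure", {
  expect_equal(resample_trial(rep(2.5, 7)), rep(2.5, 200))
  ramp <- seq(0, 1, length.out = 50)
  expect_equal(resample_trial(ramp), seq(0, 1, length.out = 200),
               tolerance = 1e-12)
  # refinement consistency: coarse and fine samplings agree after resampling
  s37 <- sin(2 * pi * seq(0, 1, length.out = 37))
  s1000 <- sin(2 * pi * seq(0, 1, length.out = 1000))
  expect_lt(max(abs(resample_trial(s37) - resample_trial(s1000))), 0.01)
  expect_error(resample_trial(3), "2 samples")
})

test_that("resampling commutes with averaging for equal-length trials", {
  set.seed(2)
  trials <- matrix(rnorm(6 * 57), 6, 57)
  avg_then <- resample_trial(colMeans(trials))
  then_avg <- colMeans(t(apply(trials, 1, resample_trial)))
  expect_equal(avg_then, then_avg, tolerance = 1e-9)
})

test_that("one-way ANOVA at time points matches hand computation", {
  groups <- rep(c("a", "b", "c"), each = 3)
  vals <- matrix(c(1, 2, 3, 2, 3, 4, 3, 4, 5), 9, 1)
  r <- anova_timepoints(vals, groups, taus = 0)
  expect_equal(r$F, 3, tolerance = 1e-12)       # SSB = 6, SSW = 6
  expect_equal(c(r$df1, r$df2), c(2, 6))
  # identical groups: no between-group variance
  same <- matrix(rep(c(1, 2, 3), 3), 9, 1)
  r0 <- anova_timepoints(same, groups, taus = 0)
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)
  # two groups: F equals the squared two-sample t
  set.seed(5)
  v2 <- matrix(rnorm(10), 10, 1)
  g2 <- rep(c("a", "b"), each = 5)
  r2 <- anova_timepoints(v2, g2, taus = 0)
  tt <- t.test(v2[1:5], v2[6:10], var.equal = TRUE)
  expect_equal(r2$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_error(anova_timepoints(v2, c("a", rep("b", 9)), taus = 0),
               ">= 2 trials")
})

# a small synthetic feature set with a realizable target, shaped like a
# session: 4 features, 8 "trials" of 1 s separated by 1 s rest
toy_cv_problem <- function(seed = 6, noise = 0) {
  set.seed(seed)
  fs <- 100
  n <- 17 * fs
  f <- matrix(rnorm(4 * n), 4)
  events <- data.frame(trial_id = 1:8,
                       t_start_s = seq(1, by = 2, length.out = 8),
                       t_end_s = seq(2, by = 2, length.out = 8),
                       path = rep(c(1L, 2L), 4),
                       mass_g = rep(c(25, 500), each = 4))
  ft <- structure(list(values = f, key = data.frame(
    channel = 1:4, band = "gamma1", variant = "rectified"),
    fs = fs, band_edges = ecog_bands()["gamma1"], n_channels = 4,
    stats = NULL), class = "feature_tensor")
  y <- drop(c(2, -1, 0, 0.5) %*% f) + 3 + noise * rnorm(n)
  list(ft = ft, y = y, events = events,
       config = decoder_config(m = 2L, dt_s = 0.01, row_stride = 1L,
                               variants = "rectified"))
}

test_that("cross-validation recovers a realizable target almost perfectly", {
  tc <- toy_cv_problem()
  cv <- decode_loocv(tc$ft, tc$y, tc$events, tc$config)
  expect_gte(cv$pooled_cc, 0.999)
  expect_lte(cv$pooled_rmse, 1e-3 * sd(tc$y))
  # fold bookkeeping: every trial tested exactly once
  expect_setequal(cv$per_trial$trial_id, tc$events$trial_id)
  expect_equal(nrow(cv$per_trial), 8)
  # pooled RMSE is the concatenated-residual RMSE, not the fold mean
  res2 <- unlist(lapply(cv$predictions, function(p)
    (p$actual - p$predicted)^2))
  expect_equal(cv$pooled_rmse, sqrt(mean(res2)), tolerance = 1e-12)
  expect_equal(cv$mean_rmse, mean(cv$per_trial$rmse), tolerance = 1e-12)
})

test_that("held-out samples never enter training (NaN poisoning)", {
  tc <- toy_cv_problem(noise = 0.1)
  n_s <- ncol(tc$ft$values)
  for (k in c(1, 4, 8)) {
    poisoned <- tc$ft
    idx <- ecogdecode:::trial_sample_idx(tc$events, k, tc$ft$fs, n_s)
    poisoned$values[, idx] <- NaN
    fit <- ecogdecode:::fit_trials_slir(poisoned, tc$y, tc$events,
                                        setdiff(1:8, k), tc$config)
    expect_true(all(is.finite(fit$model$w)))
    expect_true(all(is.finite(fit$stats$mu)))
  }
})

test_that("a permuted target on the toy problem decodes at chance", {
  tc <- toy_cv_problem(noise = 0.1)
  set.seed(31)
  cv <- decode_loocv(tc$ft, sample(tc$y), tc$events, tc$config)
  expect_lt(cv$mean_abs_cc, 0.25)
})

test_that("degenerate folds are excluded from correlation means", {
  tc <- toy_cv_problem()
  cv <- decode_loocv(tc$ft, rep(5, length(tc$y)), tc$events, tc$config)
  expect_equal(cv$n_cc_excluded, 8)
  expect_equal(cv$mean_abs_cc, 0)
  expect_lt(cv$pooled_rmse, 1e-9)
})
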