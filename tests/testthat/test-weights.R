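# construct a model with hand-set weights over a given feature key
hand_model <- function(w, w0, m = 1L) {
  p <- length(w)
  structure(list(w0 = w0, w = w, alpha = rep(1, p), beta = 1,
                 active = w != 0,
                 column_key = data.frame(feature = rep(seq_len(p / m),
                                                       each = m),
                                         lag = rep(seq_len(m) - 1L, p / m)),
                 fit_log = list(iterations = 0L, converged = TRUE,
                                n_active = sum(w != 0)),
                 fingerprint = NULL), class = "slir_model")
}

simple_key <- function(p) data.frame(channel = seq_len(p), band = "gamma1",
                                     variant = "rectified")

test_that("weight maps normalize by the global maximum", {
  m <- hand_model(c(0, 0, 0.7, 0), 1)
  wm <- weight_map(m, simple_key(4))
  expect_equal(wm$entries$norm, c(0, 0, 1, 0))
  m2 <- hand_model(c(2, -4, 1), 0)
  wm2 <- weight_map(m2, simple_key(3))
  expect_equal(wm2$entries$norm, c(0.5, 1, 0.25))
  expect_equal(wm2$w_max_abs, 4)
  expect_warning(wm0 <- weight_map(hand_model(c(0, 0), 0), simple_key(2)),
                 "all-zero")
  expect_true(wm0$all_zero)
})

test_that("weight maps are invariant to target rescaling", {
  set.seed(16)
  X <- matrix(rnorm(300 * 8), 300, 8)
  y <- drop(X %*% c(2, 0, -1, 0, 0, 0.5, 0, 0)) + rnorm(300, 0, 0.05)
  w1 <- weight_map(fit_slir(X, y), simple_key(8))
  w2 <- weight_map(fit_slir(X, 50 * y), simple_key(8))
  expect_equal(w1$entries$norm, w2$entries$norm, tolerance = 1e-3)
})

test_that("band weight shares sum to one and reflect concentration", {
  key <- data.frame(channel = 1, band = names(ecog_bands()),
                    variant = "rectified")
  m_delta <- hand_model(c(3, rep(0, 8)), 0)
  br <- band_weight_ratio(m_delta, key)
  expect_equal(unname(br$by_band["delta"]), 1)
  expect_equal(sum(br$by_band), 1)
  m_flat <- hand_model(rep(c(1, -1), length.out = 9), 0)
  br2 <- band_weight_ratio(m_flat, key)
  expect_equal(unname(br2$by_band), rep(1 / 9, 9), tolerance = 1e-12)
  expect_error(band_weight_ratio(hand_model(rep(0, 9), 0), key), "all weights")
})

test_that("the region t-test matches a textbook oracle", {
  set.seed(18)
  g1 <- rnorm(100); g2 <- rnorm(100, mean = 1)
  w <- c(abs(g1), abs(g2))
  wm <- weight_map(hand_model(w * max(abs(w)), 0), simple_key(200))
  wm$entries$norm <- c(g1, g2)          # inject the raw populations
  regions <- rep(c("PM", "M1"), each = 100)
  r <- region_ttest(wm, regions)
  # independently coded equal-variance two-sample t-test
  sp2 <- ((99 * var(g1)) + (99 * var(g2))) / 198
  t_hand <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / 100 + 1 / 100))
  p_hand <- 2 * pt(-abs(t_hand), df = 198)
  expect_equal(r$statistic, t_hand, tolerance = 1e-9)
  expect_equal(r$p, p_hand, tolerance = 1e-9)
  expect_equal(r$df, 198)
  # identical populations: t = 0, p = 1
  wm$entries$norm <- rep(c(g1), 2)
  r0 <- region_ttest(wm, regions)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1, tolerance = 1e-12)
  expect_error(region_ttest(wm, rep("PM", 200)), "absent")
})

# a tiny two-channel contribution fixture with hand-computable percentages:
# feature values are constants per (trial, channel) so window means are exact
toy_contribution <- function() {
  fs <- 100
  n <- 13 * fs
  vals <- matrix(0, 2, n)
  events <- data.frame(trial_id = 1:6,
                       t_start_s = seq(1, by = 2, length.out = 6),
                       t_end_s = seq(2, by = 2, length.out = 6),
                       path = 1L,
                       mass_g = rep(c(25, 500), each = 3))
  lv <- list(`25` = c(1, 2), `500` = c(4, 3))   # per-channel level by mass
  for (k in 1:6) {
    idx <- ecogdecode:::trial_sample_idx(events, k, fs, n)
    lev <- lv[[as.character(events$mass_g[k])]]
    vals[1, idx] <- lev[1]; vals[2, idx] <- lev[2]
  }
  ft <- structure(list(values = vals,
                       key = data.frame(channel = 1:2, band = "gamma1",
                                        variant = "rectified"),
                       fs = fs, band_edges = ecog_bands()["gamma1"],
                       n_channels = 2, stats = NULL),
                  class = "feature_tensor")
  model <- hand_model(c(2, 5), w0 = 7)
  list(fit = list(model = model, ftz = ft, events = events,
                  config = decoder_config(m = 1L, dt_s = 0.01,
                                          row_stride = 1L,
                                          variants = "rectified")))
}

test_that("contribution percentages equal hand-computed window means", {
  tc <- toy_contribution()
  cm <- contribution_map(tc$fit, mass_pair = c(25, 500), path = 1)
  # channel 1: w = 2, level 1 -> 4: diff = 2 * 3 = 6
  # channel 2: w = 5, level 2 -> 3: diff = 5 * 1 = 5; total 11
  expect_equal(cm$per_channel$mean_diff, c(6, 5), tolerance = 1e-12)
  expect_equal(cm$per_channel$percent, 100 * c(6, 5) / 11, tolerance = 1e-9)
  expect_equal(sum(cm$per_channel$percent), 100, tolerance = 1e-6)
  # decomposition identity: channel curves sum to the full difference curve
  expect_equal(colSums(cm$channel_diff_curves), cm$full_diff_curve,
               tolerance = 1e-12)
})

test_that("a single-channel model concentrates 100% of the contribution", {
  tc <- toy_contribution()
  tc$fit$model <- hand_model(c(0, 5), w0 = 2)
  cm <- contribution_map(tc$fit, mass_pair = c(25, 500), path = 1)
  expect_equal(cm$per_channel$percent, c(0, 100), tolerance = 1e-9)
})

test_that("a vanishing between-mass difference is refused", {
  tc <- toy_contribution()
  # weights chosen so the mass difference cancels: 2*3 + (-6)*1 = 0
  tc$fit$model <- hand_model(c(2, -6), w0 = 0)
  expect_error(contribution_map(tc$fit, mass_pair = c(25, 500), path = 1),
               "below 1e-9")
})

test_that("transfer evaluation refuses mismatched configurations", {
  tc <- toy_contribution()
  ft <- tc$fit$ftz
  # make features non-degenerate so fits work
  set.seed(40)
  ft$values <- ft$values + matrix(rnorm(length(ft$values), 0, 0.1),
                                  nrow(ft$values))
  y <- drop(c(1, -1) %*% ft$values) + rnorm(ncol(ft$values), 0, 0.05)
  tm <- transfer_matrix(ft, list(y = y), tc$fit$events,
                        config = tc$fit$config, masses = c(25, 500))
  expect_equal(dim(tm$rmse), c(2, 2))
  expect_true(all(is.finite(tm$rmse)))
})
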