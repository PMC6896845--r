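test_that("purity index is the EpCAM share of total marker signal", {
  expect_equal(purity_index(500, 0), 1.0)
  expect_equal(purity_index(300, 300), 0.5)
  expect_equal(purity_index(700, 300), 0.7)
  expect_error(purity_index(0, 0), "undefined")
  expect_error(purity_index(-1, 5), ">= 0")
})

test_that("purity index is invariant to common channel gain", {
  set.seed(31)
  e <- runif(50, 10, 2000)
  v <- runif(50, 10, 2000)
  for (k in c(0.01, 1, 7.3, 1e4)) {
    expect_equal(purity_index(k * e, k * v), purity_index(e, v))
  }
})

test_that("calibration fit is OLS of fraction on index with honest R^2", {
  # collinear points: perfect fit
  m <- fit_calibration(c(0, 0.25, 0.5, 1), c(0.1, 0.3, 0.5, 0.9))
  expect_equal(m$r_squared, 1.0)
  expect_equal(m$n_points, 4L)
  expect_error(fit_calibration(c(0, 0.5, 1), c(0.4, 0.4, 0.4)), "variance")
  expect_error(fit_calibration(c(0, 1), c(0, 1)), ">= 3")
  expect_error(fit_calibration(c(0, 0.5, 2), c(0, 0.4, 0.9)), "\\[0, 1\\]")
})

test_that("synthetic titration panel calibrates tightly and recovers the analytic line", {
  sp <- mixture_panel_spec(seed = 17)  # fractions 0-0.9, triplicate, CV 5%
  tb <- make_mixture_panel(sp)
  idx <- purity_index(tb$epcam, tb$vimentin)
  m <- fit_calibration(tb$true_fraction, idx)
  expect_gte(m$r_squared, 0.9373)
  # default channel means sum to the same total in both populations, so the
  # noise-free index is exactly linear: f = (1050 * idx - 50) / 950. The fit
  # recovers that line exactly without noise and closely at 5% channel CV
  # (ratio noise leaves a small O(cv^2) bias, so the check is absolute).
  tb0 <- make_mixture_panel(mixture_panel_spec(noise_cv = 0, seed = 17))
  m0 <- fit_calibration(tb0$true_fraction,
                        purity_index(tb0$epcam, tb0$vimentin))
  expect_equal(m0$slope, 1050 / 950, tolerance = 1e-10)
  expect_equal(m0$intercept, -50 / 950, tolerance = 1e-8)
  expect_lt(abs(m$slope - 1050 / 950), 0.05)
  expect_lt(abs(m$intercept - (-50 / 950)), 0.02)
})

test_that("predicted purity is the clipped linear map", {
  m <- structure(list(intercept = 0, slope = 1, r_squared = 1,
                      n_points = 10L), class = "calibration_model")
  expect_equal(as.numeric(predict_purity(m, 0.42)), 0.42)
  over <- predict_purity(structure(list(intercept = 0.5, slope = 1,
                                        r_squared = 1, n_points = 10L),
                                   class = "calibration_model"), 0.8)
  expect_equal(as.numeric(over), 1.0)
  expect_true(attr(over, "clipped"))
  expect_error(predict_purity(list(), 0.5), "calibration_model")
})

test_that("held-out prediction error is small at 5% noise", {
  train <- make_mixture_panel(mixture_panel_spec(seed = 41))
  test <- make_mixture_panel(mixture_panel_spec(
    fractions = seq(0.05, 0.85, by = 0.1), seed = 42))
  m <- fit_calibration(train$true_fraction,
                       purity_index(train$epcam, train$vimentin))
  pred <- predict_purity(m, purity_index(test$epcam, test$vimentin))
  expect_lt(mean(abs(pred - test$true_fraction)), 0.05)
})

test_that("purity gate is strict at the 30% threshold", {
  g <- qc_purity_gate(c(0.55, 0.30, 0.01))
  expect_equal(g$status, c("valid", "warn", "warn"))
  expect_match(g$message[1], "interpretable")
  expect_match(g$message[2], "masked")
  expect_equal(qc_purity_gate(0.31, threshold = 0.5)$status, "warn")
  expect_error(qc_purity_gate(1.2), "\\[0, 1\\]")
})

test_that("marker-positive fraction counts strict threshold exceedances", {
  expect_equal(marker_positive_fraction(rep(0, 10), 10), 0)
  expect_equal(marker_positive_fraction(c(1, 1, 20, 20), 10), 0.5)
  expect_error(marker_positive_fraction(numeric(0), 10), "empty")
  # bimodal mixture with 30% positive population
  set.seed(53)
  n <- 400
  pos <- runif(n) < 0.3
  marker <- ifelse(pos, 900, 30) * pillarscreen:::lognormal_noise(n, 0.2)
  thr <- marker_positivity_threshold(
    rep(30, 50) * pillarscreen:::lognormal_noise(50, 0.2))
  expect_lt(abs(marker_positive_fraction(marker, thr) - 0.30), 0.05)
})

test_that("fit then predict on the training panel is self-consistent", {
  tb <- make_mixture_panel(mixture_panel_spec(seed = 8))
  idx <- purity_index(tb$epcam, tb$vimentin)
  m <- fit_calibration(tb$true_fraction, idx)
  pred <- m$intercept + m$slope * idx  # unclipped fitted values
  r2 <- 1 - sum((tb$true_fraction - pred)^2) /
    sum((tb$true_fraction - mean(tb$true_fraction))^2)
  expect_equal(r2, m$r_squared, tolerance = 1e-10)
})
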