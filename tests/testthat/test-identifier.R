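test_that("ARX fits of noise-free first-order step traces reach machine-level loss", {
  tr <- synth_trace("first_order", k_a = 1, tau_a = 100, step_time = 30,
                    duration = 700, Ts = 1)
  m <- fit_arx(tr, 1, 1)
  expect_lt(m$loss, 1e-7)
  expect_equal(m$n_alpha, 1L)
})

test_that("degenerate traces raise identifiability errors", {
  t <- seq(0, 100, 1)
  tr <- sampled_trace(t, rep(0, length(t)), rep(0, length(t)))
  expect_error(fit_arx(tr, 2, 1), "identifiability")
  expect_error(identify_tf(tr), "identif")
})

test_that("the innovation variance estimate recovers the injected noise", {
  tr <- synth_trace("first_order", k_a = 1, tau_a = 100, step_time = 100,
                    duration = 3000, Ts = 1)
  lambda0 <- 1e-4
  set.seed(42)
  trn <- sampled_trace(tr$t, tr$u, tr$y + rnorm(nrow(tr), 0, sqrt(lambda0)))
  m <- fit_arx(trn, 1, 1)
  expect_lt(abs(m$lambda_hat - lambda0) / lambda0, 0.2)
  ## lambda_hat also agrees with the pre-stimulus variance of y
  idf <- suppressWarnings(identify_tf(trn))
  pre_var <- var(trn$y[seq_len(step_onset(trn) - 1L)])
  expect_lt(idf$lambda_hat / pre_var, 2)
  expect_gt(idf$lambda_hat / pre_var, 0.5)
})

test_that("the prediction-error loss is non-increasing in the AR order", {
  tr <- synth_trace("parallel", -5, 3, 5, 100)
  set.seed(3)
  trn <- sampled_trace(tr$t, tr$u, tr$y + rnorm(nrow(tr), 0, 0.02))
  losses <- vapply(1:4, function(na) fit_arx(trn, na, 1)$loss, numeric(1))
  expect_true(all(diff(losses) <= 1e-12))
})

test_that("identification recovers the generating transfer function features", {
  ## parallel-subtraction generator: 2 poles, 1 zero
  tr <- synth_trace("parallel", -5, 3, 5, 100)
  idf <- identify_tf(tr)
  expect_lt(idf$loss, 1e-7)
  ft <- idf$features
  expect_equal(ft$tau_poles, c(5, 100), tolerance = 0.01)
  expect_equal(ft$tau_zeros, 242.5, tolerance = 0.01)
  expect_equal(ft$dc_gain, -2, tolerance = 0.01)

  ## feedback generator
  tr2 <- synth_trace("feedback", -5, 2, 5, 200, duration = 1500)
  idf2 <- identify_tf(tr2)
  expect_equal(idf2$features$tau_poles, c(5, 200 / 3), tolerance = 0.01)
  expect_equal(idf2$features$tau_zeros, 200, tolerance = 0.01)

  ## pure first order: exactly one pole, no zero after pruning
  tr3 <- synth_trace("first_order", k_a = -2, tau_a = 50, duration = 400)
  idf3 <- identify_tf(tr3)
  expect_length(idf3$features$tau_poles, 1)
  expect_length(idf3$features$tau_zeros, 0)
  expect_equal(idf3$features$tau_poles, 50, tolerance = 0.01)
})

test_that("identified features match the generator over a coarse grid", {
  cases <- list(
    list(config = "cascade", k_a = -1, k_b = 3, tau_a = 10, tau_b = 50),
    list(config = "feedback", k_a = 3, k_b = 1, tau_a = 2, tau_b = 200),
    list(config = "parallel_add", k_a = 1, k_b = 3, tau_a = 20, tau_b = 100),
    list(config = "parallel_sub", k_a = -5, k_b = 1, tau_a = 10, tau_b = 200))
  for (cs in cases) {
    tr <- synth_trace(cs$config, cs$k_a, cs$k_b, cs$tau_a, cs$tau_b,
                      Ts = min(0.25, cs$tau_a / 20))
    G0 <- attr(tr, "G")
    idf <- identify_tf(tr)
    f0 <- tf_features(G0); f1 <- idf$features
    expect_equal(f1$tau_poles, f0$tau_poles, tolerance = 0.01)
    expect_equal(f1$dc_gain, f0$dc_gain, tolerance = 0.01)
    expect_length(f1$tau_zeros, length(f0$tau_zeros))
    if (length(f0$tau_zeros))
      expect_equal(f1$tau_zeros, f0$tau_zeros, tolerance = 0.01)
  }
})

test_that("zero-order-hold conversion is exact for known discrete systems", {
  ## 1st order: G(s) = b/(s+w) sampled at Ts has pole exp(-w Ts)
  Ts <- 0.5; w <- 0.02; b <- 0.06
  lam <- exp(-w * Ts)
  num_z <- (b / w) * (1 - lam)
  G <- d2c_zoh(num_z, c(1, -lam), Ts)
  expect_equal(G$den, c(1, w), tolerance = 1e-12)
  expect_equal(G$num, b, tolerance = 1e-12)
  ## oscillatory discrete poles rejected
  expect_error(d2c_zoh(c(1, 0), c(1, -1.8, 0.9), 1), "unsupported-dynamics")
  ## unstable pole rejected
  expect_error(d2c_zoh(1, c(1, -1.5), 1), "instability")
})
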