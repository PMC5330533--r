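test_that("a first-order transfer function carries its gain and time constant", {
  ft <- tf_features(make_first_order(k = -1, tau = 5))
  expect_equal(ft$tau_poles, 5)
  expect_length(ft$tau_zeros, 0)
  expect_equal(ft$dc_gain, -1)

  ## arbitrary k, tau: omega = 1/tau, b = k/tau, dc gain = k
  p <- first_order_process(1, 100)
  expect_equal(p$omega, 0.01)
  expect_equal(p$b, 0.01)
  ft2 <- tf_features(make_first_order(7, 50))
  expect_equal(ft2$tau_poles, 50)
  expect_equal(ft2$dc_gain, 7)

  ## zero gain gives an identically zero numerator
  G0 <- make_first_order(0, 10)
  expect_equal(G0$num, 0)

  expect_error(first_order_process(1, -2), "invalid-parameter")
  expect_error(first_order_process(1, 0), "invalid-parameter")
})

test_that("canonical combinations have the closed-form poles, zeros and gains", {
  a <- first_order_process(-5, 5)

  ## parallel subtraction: zero at (b_a w_b + b_b w_a)/(b_a + b_b)
  ftp <- tf_features(combine_processes(a, first_order_process(3, 100), "parallel"))
  expect_equal(ftp$tau_poles, c(5, 100))
  expect_equal(ftp$tau_zeros, 1 / 0.004123711, tolerance = 1e-6)
  expect_equal(ftp$dc_gain, -2)

  ## feedback: poles at w_a and w_b + b_b, zero at w_b
  ftf <- tf_features(combine_processes(a, first_order_process(2, 200), "feedback"))
  expect_equal(ftf$tau_poles, c(5, 1 / 0.015), tolerance = 1e-9)
  expect_equal(ftf$tau_zeros, 200, tolerance = 1e-9)

  ## cascade: no zero, dc gain k_a * k_b
  ftc <- tf_features(combine_processes(first_order_process(-1, 5),
                                       first_order_process(1, 100), "cascade"))
  expect_equal(ftc$tau_poles, c(5, 100))
  expect_length(ftc$tau_zeros, 0)
  expect_equal(ftc$dc_gain, -1)

  ## positive feedback rejected
  expect_error(combine_processes(a, first_order_process(-1, 100), "feedback"),
               "instability")
})

test_that("combination identities hold over a parameter grid", {
  for (ta in grid_tau_a) for (tb in grid_tau_b)
    for (ka in grid_k) for (kb in grid_k) {
      pa <- first_order_process(ka, ta); pb <- first_order_process(kb, tb)
      wa <- 1 / ta; wb <- 1 / tb; ba <- ka / ta; bb <- kb / tb

      ftc <- tf_features(combine_processes(pa, pb, "cascade"))
      expect_length(ftc$tau_poles, 2)
      expect_length(ftc$tau_zeros, 0)
      expect_equal(ftc$dc_gain, ka * kb, tolerance = 1e-9)

      if (kb >= 0) {
        G <- combine_processes(pa, pb, "feedback")
        ftf <- tf_features(G)
        expect_length(ftf$tau_poles, 2)
        expect_equal(sort(1 / ftf$tau_poles), sort(c(wa, wb + bb)),
                     tolerance = 1e-9)
        if (kb > 0) expect_equal(ftf$tau_zeros, tb, tolerance = 1e-9)
        expect_equal(ftf$dc_gain, ba * wb / (wa * (wb + bb)), tolerance = 1e-9)
      }

      Gp <- combine_processes(pa, pb, "parallel")
      ftp <- tf_features(Gp)
      expect_equal(sort(1 / ftp$tau_poles), sort(c(wa, wb)), tolerance = 1e-9)
      expect_equal(ftp$dc_gain, ka + kb, tolerance = 1e-9)
      if (ba + bb != 0) {
        expect_equal(1 / ftp$tau_zeros, (ba * wb + bb * wa) / (ba + bb),
                     tolerance = 1e-9)
      } else {
        expect_length(ftp$tau_zeros, 0)  # degenerate zero-less numerator
      }
    }
})

test_that("unstable and oscillatory transfer functions are rejected", {
  expect_error(tf_features(rational_tf(1, c(1, -0.1))), "instability")
  ## complex poles: s^2 + 0.2 s + 1
  expect_error(tf_features(rational_tf(1, c(1, 0.2, 1))), "unsupported-dynamics")
})

test_that("near pole-zero cancellations collapse to a lower order", {
  G <- zpk_tf(zeros = -0.0100000001, poles = c(-0.01, -0.2), gain = 2)
  Gp <- prune_cancellations(G, tol = 1e-6)
  expect_length(tf_poles(Gp), 1)
  expect_length(tf_zeros(Gp), 0)
  expect_equal(tf_features(Gp)$tau_poles, 5)
  ## distant pair untouched
  G2 <- zpk_tf(-0.05, c(-0.01, -0.2), 2)
  expect_length(tf_poles(prune_cancellations(G2, tol = 1e-6)), 2)
})

test_that("the analytic step response matches direct exponential formulas", {
  t <- seq(0, 600, 0.5)
  y <- tf_step_response(make_first_order(3, 100), t, step_time = 30)
  ref <- ifelse(t >= 30, 3 * (1 - exp(-(t - 30) / 100)), 0)
  expect_equal(y, ref, tolerance = 1e-12)
  ## dc value reached: final-value theorem
  G <- combine_processes(first_order_process(-5, 5),
                         first_order_process(2, 200), "feedback")
  yf <- tf_step_response(G, seq(0, 3000, 1), 0)
  expect_equal(yf[length(yf)], dc_gain(G), tolerance = 1e-4)
})

test_that("transfer functions serialize to zeros/poles/gain JSON", {
  G <- combine_processes(first_order_process(-5, 5),
                         first_order_process(3, 100), "parallel")
  j <- jsonlite::fromJSON(tf_to_json(G))
  expect_equal(sort(j$poles), c(-0.2, -0.01), tolerance = 1e-9)
  expect_equal(j$gain, -0.97, tolerance = 1e-9)
})
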