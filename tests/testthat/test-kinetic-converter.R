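test_that("closed-form rates match hand-computed values per configuration", {
  ## feedback: sigma = (w_a, b_b, w_b), gamma = k_a
  fb <- kinetrace:::scheme_params("feedback", -5, 2, 5, 200)
  expect_equal(unname(fb$sigma), c(0.2, 0.01, 0.005), tolerance = 1e-12)
  expect_equal(fb$gamma, -5)

  ## parallel subtraction: sigma3 is the zero rate, sigma2 = w_b - sigma3
  ps <- kinetrace:::scheme_params("parallel_sub", -5, 3, 5, 100)
  expect_equal(unname(ps$sigma), c(0.2, 0.0058762887, 0.0041237113),
               tolerance = 1e-8)
  expect_equal(ps$gamma, -2 * 0.01 / 0.0041237113, tolerance = 1e-8)

  ## parallel addition: sigma1 the gain-weighted mean rate, absorbing obs
  pa <- kinetrace:::scheme_params("parallel_add", 1, 3, 5, 100)
  expect_equal(unname(pa$sigma), c(0.0575, 0.1425, 0.01), tolerance = 1e-12)
  expect_equal(pa$gamma, 4)

  ## cascade and first order
  cs <- kinetrace:::scheme_params("cascade", -1, 1, 5, 100)
  expect_equal(unname(cs$sigma), c(0.2, 0.01))
  expect_equal(cs$gamma, -1)
  fo <- kinetrace:::scheme_params("first_order", -2, NA, 50, NA)
  expect_equal(unname(fo$sigma), 0.02)
  expect_equal(fo$gamma, -2)
})

test_that("conversion emits a scheme whose transfer function reproduces G", {
  grid <- canonical_grid()
  ## round-trip identity for every canonical configuration on a thinned grid
  for (g in grid[seq(1, length(grid), by = 7)]) {
    G <- if (g$config == "first_order") make_first_order(g$k_a, g$tau_a)
    else combine_processes(first_order_process(g$k_a, g$tau_a),
                           first_order_process(g$k_b, g$tau_b),
                           switch(g$config, feedback = "feedback",
                                  cascade = "cascade", "parallel"))
    sch <- convert_to_scheme(G, g$config,
                             params = c(k_a = g$k_a, k_b = g$k_b,
                                        tau_a = g$tau_a, tau_b = g$tau_b))
    expect_lt(kinetrace:::tf_coeff_mismatch(G, scheme_to_tf(sch)), 1e-9)
    expect_true(all(sch$transitions$sigma > 0))
    expect_length(sch$states, length(tf_poles(G)) + 1L)
  }
})

test_that("infeasible parameter combinations raise infeasible-scheme errors", {
  ## subtraction with the zero at the origin (k_a + k_b = 0)
  expect_error(convert_to_scheme(NULL, "parallel_sub",
                                 params = c(k_a = -1, k_b = 1, tau_a = 5, tau_b = 100),
                                 check_tol = Inf),
               "infeasible-scheme")
  ## right-half-plane zero (sums of gains and of b's with opposite signs)
  expect_error(convert_to_scheme(NULL, "parallel_sub",
                                 params = c(k_a = -1, k_b = 3, tau_a = 5, tau_b = 100),
                                 check_tol = Inf),
               "infeasible-scheme")
  ## conversion-integrity check trips on a mismatched G
  Gwrong <- combine_processes(first_order_process(-5, 5),
                              first_order_process(2, 150), "feedback")
  expect_error(convert_to_scheme(Gwrong, "feedback",
                                 params = c(k_a = -5, k_b = 2, tau_a = 5, tau_b = 200)),
               "conversion-integrity")
})

test_that("the scheme transfer function matches the first-order closed form", {
  sch <- convert_to_scheme(make_first_order(3, 100), "first_order",
                           params = c(k_a = 3, k_b = NA, tau_a = 100, tau_b = NA))
  Gk <- scheme_to_tf(sch)
  ## gamma sigma1 / (s + sigma1)
  expect_equal(Gk$num, 3 * 0.01, tolerance = 1e-12)
  expect_equal(Gk$den, c(1, 0.01), tolerance = 1e-12)
})

test_that("malformed schemes are rejected", {
  sch <- convert_to_scheme(NULL, "feedback",
                           params = c(k_a = -5, k_b = 2, tau_a = 5, tau_b = 200),
                           check_tol = Inf)
  ## remove the forward transition into the observable: singular system
  broken <- sch
  broken$transitions <- sch$transitions[-1, ]
  expect_error(scheme_to_tf(broken), "singular-system")
  expect_error(kinetic_scheme(c("A", "B"), data.frame(from = "A", to = "B",
                                                      sigma = -1),
                              "B", "A", 1), "infeasible-scheme")
  expect_error(kinetic_scheme(c("A", "B"), data.frame(from = "A", to = "C",
                                                      sigma = 1),
                              "B", "A", 1), "malformed-scheme")
})

test_that("unbalanced three-state circular flows are flagged", {
  expect_warning(kinetic_scheme(c("A", "B", "C", "D"),
                                data.frame(from = c("B", "C", "D"),
                                           to = c("C", "D", "B"),
                                           sigma = c(1, 1, 1)),
                                "B", "A", 1),
                 "reversibility")
})

test_that("scheme simulation conserves mass and reproduces closed forms", {
  ## unit step into a first-order scheme: z_obs = 1 - exp(-sigma1 t)
  sch <- convert_to_scheme(make_first_order(-2, 50), "first_order",
                           params = c(k_a = -2, k_b = NA, tau_a = 50, tau_b = NA))
  tr <- simulate_scheme(sch, input = list(type = "step", time = 0),
                        t = seq(0, 400, 0.5))
  expect_equal(tr$y, -2 * (1 - exp(-tr$t / 50)), tolerance = 1e-12)

  ## feedback scheme: final value from the dc gain of Eq-style closed form
  schf <- convert_to_scheme(NULL, "feedback",
                            params = c(k_a = -5, k_b = 2, tau_a = 5, tau_b = 200),
                            check_tol = Inf)
  trf <- simulate_scheme(schf, input = list(type = "step", time = 30),
                         t = seq(0, 2000, 0.25))
  expect_equal(trf$y[length(trf$y)], -5 * 0.005 / (0.2 * 0.015) * 0.2,
               tolerance = 1e-3)  # b_a w_b / (w_a (w_b + b_b))
  ## occupancies sum to the input everywhere, and stay within [0, 1]
  expect_lt(max(abs(rowSums(trf$z) - trf$u)), 1e-9)
  expect_gte(min(trf$z), -1e-9)
  expect_lte(max(trf$z), 1 + 1e-9)

  ## parallel subtraction: all-state conservation under a unit step
  schs <- convert_to_scheme(NULL, "parallel_sub",
                            params = c(k_a = -5, k_b = 3, tau_a = 5, tau_b = 100),
                            check_tol = Inf)
  trs <- simulate_scheme(schs, input = list(type = "step", time = 30),
                         t = seq(0, 700, 0.25))
  expect_lt(max(abs(rowSums(trs$z) - trs$u)), 1e-9)
})

test_that("user labels relabel states without changing dynamics", {
  sch <- convert_to_scheme(NULL, "feedback",
                           params = c(k_a = -5, k_b = 2, tau_a = 5, tau_b = 200),
                           check_tol = Inf, labels = c("C", "O", "I"))
  expect_equal(sch$states, c("C", "O", "I"))
  expect_equal(sch$observable, "O")
  j <- jsonlite::fromJSON(scheme_to_json(sch))
  expect_equal(j$observable, "O")
  expect_equal(nrow(j$transitions), 3)
})
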