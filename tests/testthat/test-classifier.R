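test_that("bounds are validated", {
  expect_error(scheme_bounds(tau_a = c(9, 1)), "interval")
  expect_error(scheme_bounds(tau_a = c(-1, 9)), "positive")
  expect_error(scheme_bounds(k_b_feedback = c(-1, 20)), "stability")
})

test_that("the matching problems recover generating parameters at near-zero cost", {
  b <- caption_bounds()
  G <- combine_processes(first_order_process(-5, 5),
                         first_order_process(3, 100), "parallel")
  pp <- solve_config_problem(G, "parallel", b)
  expect_lt(pp$f_val, 1e-12)
  expect_equal(unname(pp$par), c(-5, 3, 5, 100), tolerance = 1e-6)

  Gf <- combine_processes(first_order_process(-5, 5),
                          first_order_process(2, 200), "feedback")
  ff <- solve_config_problem(Gf, "feedback", b)
  expect_lt(ff$f_val, 1e-12)
  expect_equal(unname(ff$par), c(-5, 2, 5, 200), tolerance = 1e-6)
})

test_that("a 2-pole 1-zero G admits both closed-form readings (equivalence)", {
  ## the diagnostic exposes why bounds carry the discriminating information
  G <- combine_processes(first_order_process(-5, 5),
                         first_order_process(3, 100), "parallel")
  rd <- configuration_readings(G)
  expect_equal(unname(rd$parallel), c(-5, 3, 5, 100), tolerance = 1e-9)
  ## the feedback reading reproduces the same G exactly
  expect_false(is.null(rd$feedback))
  pf <- rd$feedback
  Gf <- combine_processes(first_order_process(pf[["k_a"]], pf[["tau_a"]]),
                          first_order_process(pf[["k_b"]], pf[["tau_b"]]),
                          "feedback")
  expect_equal(Gf$num, G$num, tolerance = 1e-9)
  expect_equal(Gf$den, G$den, tolerance = 1e-9)
  ## zero faster than the slow pole: no feedback reading exists
  G2 <- combine_processes(first_order_process(1, 5),
                          first_order_process(-5, 100), "parallel")
  expect_null(configuration_readings(G2)$feedback)
})

test_that("the decision flow routes orders and zero-less systems correctly", {
  b <- caption_bounds()
  ## three poles: higher order
  G3 <- zpk_tf(numeric(0), c(-0.5, -0.05, -0.005), 1e-4)
  expect_equal(classify_tf(G3, b)$configuration, "higher_order")
  ## one pole, no zero: first order
  c1 <- classify_tf(make_first_order(-2, 5), b)
  expect_equal(c1$configuration, "first_order")
  expect_equal(unname(c1$recovered["k_a"]), -2)
  ## two poles, no zero: cascade
  Gc <- combine_processes(first_order_process(-1, 5),
                          first_order_process(1, 100), "cascade")
  cc <- classify_tf(Gc, b)
  expect_equal(cc$configuration, "cascade")
  ## two poles and a numerically negligible zero also route to cascade
  Gc2 <- rational_tf(c(1e-12 * Gc$num[1], Gc$num), Gc$den)
  expect_equal(classify_tf(Gc2, b)$configuration, "cascade")
})

test_that("the two similar generators are assigned their distinct configurations", {
  b <- caption_bounds()
  Gp <- combine_processes(first_order_process(-5, 5),
                          first_order_process(3, 100), "parallel")
  Gf <- combine_processes(first_order_process(-5, 5),
                          first_order_process(2, 200), "feedback")
  clp <- classify_tf(Gp, b)
  clf <- classify_tf(Gf, b)
  expect_equal(clp$configuration, "parallel_sub")
  expect_equal(clf$configuration, "feedback")
  expect_equal(unname(clp$recovered), c(-5, 3, 5, 100), tolerance = 1e-6)
  expect_equal(unname(clf$recovered), c(-5, 2, 5, 200), tolerance = 1e-6)
})

test_that("classification over the grid recovers the generator under adequate priors", {
  grid <- Filter(function(g)
    g$config %in% c("parallel_sub", "parallel_add", "feedback"),
    canonical_grid())
  ## thin the sweep for runtime; the acceptance suite runs the full grid
  grid <- grid[seq(1, length(grid), by = 4)]
  for (g in grid) {
    G <- combine_processes(first_order_process(g$k_a, g$tau_a),
                           first_order_process(g$k_b, g$tau_b),
                           if (g$config == "feedback") "feedback" else "parallel")
    cl <- classify_tf(G, prior_bounds(g))
    expect_equal(cl$configuration, g$config,
                 label = sprintf("config for (%s, k_a=%g, k_b=%g, tau_a=%g, tau_b=%g)",
                                 g$config, g$k_a, g$k_b, g$tau_a, g$tau_b))
    expect_lt(min(cl$f_valp, cl$f_valf), 1e-6)
  }
})

test_that("the label is invariant to the multi-start seed", {
  G <- combine_processes(first_order_process(-5, 5),
                         first_order_process(3, 100), "parallel")
  labs <- vapply(1:10, function(s)
    classify_tf(G, caption_bounds(), seed = s)$configuration, "")
  expect_true(all(labs == "parallel_sub"))
})

test_that("genuinely symmetric ties are flagged ambiguous", {
  ## with near-zero k_b both configurations degenerate towards the same
  ## single-process system; margins coincide and no label is committed
  G <- combine_processes(first_order_process(-5, 5),
                         first_order_process(1e-4, 100), "feedback")
  cl <- classify_tf(G, scheme_bounds(tau_a = c(1, 9), tau_b = c(50, 250)))
  expect_true(cl$configuration %in% c("ambiguous", "cascade"))
})
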