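## Shared parameter grids for round-trip and property tests.
## Process a is fast (tau_a in ms), process b slow; gains span negative and
## positive strengths. Feedback requires k_b > 0 (negative k_b is unstable
## positive feedback); parallel excludes k_a + k_b = 0, where the subtraction
## scheme's zero sits exactly at the origin and no feasible scheme exists.

grid_tau_a <- c(2, 5, 10, 20)
grid_tau_b <- c(50, 100, 200)
grid_k <- c(-5, -1, 1, 3)

canonical_grid <- function() {
  out <- list()
  add <- function(config, k_a, k_b, tau_a, tau_b) {
    out[[length(out) + 1L]] <<- list(config = config, k_a = k_a, k_b = k_b,
                                     tau_a = tau_a, tau_b = tau_b)
  }
  for (ta in grid_tau_a) for (ka in grid_k) {
    add("first_order", ka, NA, ta, NA)
    for (tb in grid_tau_b) for (kb in grid_k) {
      add("cascade", ka, kb, ta, tb)
      if (kb > 0) add("feedback", ka, kb, ta, tb)
      ## the subtraction scheme exists only when the transfer-function zero
      ## is real, negative and slower than the slow pole (0 < sigma3 < w_b);
      ## k_a + k_b = 0 puts it at the origin, opposite-sign gain/b sums in
      ## the right half plane, and zeros between the poles would need
      ## sigma2 <= 0 - all true degeneracies of the canonical scheme set
      if (ka * kb > 0) {
        add("parallel_add", ka, kb, ta, tb)
      } else {
        babb <- ka / ta + kb / tb
        if (ka + kb != 0 && babb != 0) {
          s3_ratio <- (1 / ta) * (ka + kb) / babb  # sigma3 / w_b
          if (s3_ratio > 0 && s3_ratio < 1) add("parallel_sub", ka, kb, ta, tb)
        }
      }
    }
  }
  out
}

## wide bounds that contain the whole grid, for round-trip classification
grid_bounds <- function() {
  scheme_bounds(tau_a = c(1, 30), tau_b = c(40, 300),
                k_a = c(-20, 20), k_b = c(-20, 20),
                k_b_feedback = c(0, 20))
}

## per-run prior bounds bracketing the generating parameters, in the regime
## where the analytic configuration overlap is empty: the feedback
## alternative of any parallel-subtraction grid point needs tau_b >= 1.15x
## the true value, the parallel alternative of any feedback point needs
## tau_b <= 0.5x, and the second exact pole-pairing of the feedback problem
## needs tau_a outside +-20%. This is the "constraints sufficient to
## distinguish the processes" regime the classifier requires.
prior_bounds <- function(g) {
  scheme_bounds(tau_a = c(0.8 * g$tau_a, 1.2 * g$tau_a),
                tau_b = if (is.finite(g$tau_b)) c(0.7 * g$tau_b, 1.1 * g$tau_b)
                        else c(50, 250),
                k_a = c(-20, 20), k_b = c(-20, 20),
                k_b_feedback = c(0, 20))
}

## bounds quoted for the two-trace discrimination example
caption_bounds <- function() {
  scheme_bounds(tau_a = c(1, 9), tau_b = c(50, 250),
                k_a = c(-20, 20), k_b = c(-20, 20),
                k_b_feedback = c(0, 20))
}
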