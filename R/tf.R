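## Transfer-function algebra for first-order processes and their canonical
## second-order combinations. Time unit is milliseconds throughout; rates and
## the Laplace variable s are in 1/ms.

#' Elementary first-order process
#'
#' A single molecular process (activation, inactivation, ...) modelled as a
#' first-order linear system \eqn{G_i(s) = b_i / (s + \omega_i)} with
#' \eqn{\omega_i = 1/\tau_i} and \eqn{b_i = k_i/\tau_i}. The process is fully
#' characterized by its gain \code{k} (steady-state output per unit input) and
#' time constant \code{tau} (ms).
#'
#' @param k Dimensionless (or output-per-input) gain.
#' @param tau Time constant in ms; must be strictly positive.
#' @return An object of class \code{"first_order_process"} with fields
#'   \code{k}, \code{tau}, \code{omega} (\code{1/tau}) and \code{b}
#'   (\code{k/tau}).
#' @examples
#' p <- first_order_process(k = -1, tau = 5)
#' p$omega  # 0.2 /ms
#' @export
first_order_process <- function(k, tau) {
  stopifnot(is.numeric(k), length(k) == 1L, is.numeric(tau), length(tau) == 1L)
  if (!is.finite(tau) || tau <= 0)
    stop("invalid-parameter: time constant 'tau' must be finite and > 0 (ms)")
  if (!is.finite(k))
    stop("invalid-parameter: gain 'k' must be finite")
  structure(list(k = k, tau = tau, omega = 1 / tau, b = k / tau),
            class = "first_order_process")
}

#' @export
print.first_order_process <- function(x, ...) {
  cat(sprintf("First-order process: k = %g, tau = %g ms (omega = %g /ms, b = %g /ms)\n",
              x$k, x$tau, x$omega, x$b))
  invisible(x)
}

## ---- polynomial helpers (descending-power coefficient vectors) ----

poly_mul <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(numeric(0))
  rev(convolve(rev(a), b, type = "open"))
}

poly_from_roots <- function(r) {
  p <- 1
  for (ri in r) p <- poly_mul(p, c(1, -ri))
  ## roots come in conjugate pairs for real systems; drop residual imaginaries
  if (is.complex(p)) p <- Re(p)
  p
}

poly_eval <- function(coef, s) {
  out <- 0 * s
  for (c_i in coef) out <- out * s + c_i
  out
}

poly_trim <- function(coef, tol = 0) {
  nz <- which(abs(coef) > tol)
  if (length(nz) == 0L) return(0)
  coef[nz[1L]:length(coef)]
}

poly_roots <- function(coef) {
  coef <- poly_trim(coef)
  if (length(coef) <= 1L) return(complex(0))
  polyroot(rev(coef))
}

#' Rational (Laplace-domain) transfer function
#'
#' Container for a single-input single-output continuous transfer function
#' \eqn{G(s) = num(s)/den(s)}, stored as descending-power polynomial
#' coefficients with a monic denominator. The systems handled by this package
#' have real coefficients and, when stable, real strictly negative poles
#' (non-oscillatory relaxation dynamics).
#'
#' @param num Numerator coefficients, descending powers of s.
#' @param den Denominator coefficients, descending powers of s; degree must be
#'   at least the numerator degree (proper system).
#' @return An object of class \code{"rational_tf"}.
#' @seealso [make_first_order()], [combine_processes()], [tf_features()]
#' @export
rational_tf <- function(num, den) {
  num <- poly_trim(as.numeric(num))
  den <- poly_trim(as.numeric(den))
  if (length(den) == 0L || all(den == 0))
    stop("invalid transfer function: zero denominator")
  if (length(num) > length(den))
    stop("invalid transfer function: improper (numerator degree exceeds denominator)")
  num <- num / den[1L]
  den <- den / den[1L]
  structure(list(num = num, den = den), class = "rational_tf")
}

#' Build a transfer function from zeros, poles and gain
#'
#' @param zeros,poles Real (or conjugate-complete complex) roots of numerator
#'   and denominator.
#' @param gain Leading-coefficient ratio (the high-frequency gain factor).
#' @return A [rational_tf()] object.
#' @export
zpk_tf <- function(zeros, poles, gain = 1) {
  rational_tf(gain * poly_from_roots(zeros), poly_from_roots(poles))
}

#' @export
print.rational_tf <- function(x, ...) {
  fmt <- function(coef) paste(signif(coef, 6), collapse = ", ")
  cat("Rational transfer function G(s) (coefficients, descending powers):\n")
  cat("  num:", fmt(x$num), "\n")
  cat("  den:", fmt(x$den), "\n")
  ft <- try(tf_features(x), silent = TRUE)
  if (!inherits(ft, "try-error")) {
    cat(sprintf("  poles: tau = {%s} ms;  zeros: tau = {%s} ms;  dc gain = %g\n",
                paste(signif(ft$tau_poles, 6), collapse = ", "),
                if (length(ft$tau_zeros)) paste(signif(ft$tau_zeros, 6), collapse = ", ") else "",
                ft$dc_gain))
  }
  invisible(x)
}

tf_poles <- function(G) poly_roots(G$den)
tf_zeros <- function(G) poly_roots(G$num)

#' Evaluate a transfer function at complex frequencies
#'
#' @param G A [rational_tf()].
#' @param s Complex (or real) values of the Laplace variable, 1/ms.
#' @return Complex values \eqn{G(s)}.
#' @export
tf_eval <- function(G, s) poly_eval(G$num, s) / poly_eval(G$den, s)

#' Steady-state (dc) gain \eqn{G(0)}
#' @param G A [rational_tf()].
#' @return The value of the transfer function at \eqn{s = 0}.
#' @export
dc_gain <- function(G) {
  G$num[length(G$num)] / G$den[length(G$den)]
}

#' Single first-order transfer function
#'
#' Returns \eqn{G(s) = b/(s + \omega)} with \eqn{\omega = 1/\tau},
#' \eqn{b = k/\tau}; the dc gain equals \code{k}.
#'
#' @inheritParams first_order_process
#' @return A [rational_tf()] with one pole at \eqn{-1/\tau} and no zeros.
#' @examples
#' G <- make_first_order(k = -1, tau = 5)
#' tf_features(G)$dc_gain  # -1
#' @export
make_first_order <- function(k, tau) {
  p <- first_order_process(k, tau)
  rational_tf(p$b, c(1, p$omega))
}

#' Combine two first-order processes in a canonical configuration
#'
#' The three truly distinct ways to combine two first-order processes are
#' cascade (output of a feeds b), feedback (b feeds the output of a back,
#' subtractively, into its input) and parallel (outputs added; subtraction is
#' encoded by gains of opposite sign). The resulting second-order transfer
#' functions are
#' \deqn{G_{casc} = \frac{b_a b_b}{(s+\omega_a)(s+\omega_b)}, \quad
#'       G_{fb} = \frac{b_a (s+\omega_b)}{(s+\omega_a)(s+\omega_b+b_b)}, \quad
#'       G_{par} = \frac{(b_a+b_b) s + b_a\omega_b + b_b\omega_a}{(s+\omega_a)(s+\omega_b)}.}
#'
#' @param a,b [first_order_process()] objects (process a is the faster one by
#'   convention, but this is not enforced here).
#' @param config One of \code{"cascade"}, \code{"feedback"}, \code{"parallel"}.
#' @return A [rational_tf()].
#' @details Feedback with \code{b$k < 0} is positive feedback and yields an
#'   unstable system; it is rejected. A parallel combination with
#'   \eqn{b_a + b_b = 0} has no zero (degenerate, constant numerator).
#' @examples
#' a <- first_order_process(-5, 5); b <- first_order_process(3, 100)
#' G <- combine_processes(a, b, "parallel")
#' tf_features(G)
#' @export
combine_processes <- function(a, b, config = c("cascade", "feedback", "parallel")) {
  stopifnot(inherits(a, "first_order_process"), inherits(b, "first_order_process"))
  config <- match.arg(config)
  switch(config,
    cascade = rational_tf(a$b * b$b,
                          poly_mul(c(1, a$omega), c(1, b$omega))),
    feedback = {
      if (b$k < 0)
        stop("instability: feedback with negative k_b is positive feedback (unstable)")
      rational_tf(a$b * c(1, b$omega),
                  poly_mul(c(1, a$omega), c(1, b$omega + b$b)))
    },
    parallel = {
      num <- c(a$b + b$b, a$b * b$omega + b$b * a$omega)
      ## degenerate zero: b_a + b_b = 0 leaves a constant numerator
      if (abs(num[1L]) <= 1e-12 * max(abs(a$b), abs(b$b)))
        num <- num[2L]
      rational_tf(num, poly_mul(c(1, a$omega), c(1, b$omega)))
    })
}

## classify roots as real within tolerance
real_roots <- function(r, tol = 1e-7) {
  if (length(r) == 0L) return(numeric(0))
  scale <- pmax(Mod(r), .Machine$double.eps)
  if (any(abs(Im(r)) / scale > tol)) return(NULL)
  Re(r)
}

#' Pole/zero features of a transfer function
#'
#' Converts poles and zeros to time constants \eqn{\tau = -1/root} (ms) and
#' reports the steady-state gain \eqn{G(0)}. Complex or non-negative poles are
#' rejected: oscillatory or unstable dynamics are outside the model class.
#'
#' @param G A [rational_tf()].
#' @return A list of class \code{"tf_features"} with \code{tau_poles} (ms,
#'   ascending), \code{tau_zeros} (ms) and \code{dc_gain}.
#' @export
tf_features <- function(G) {
  p <- real_roots(tf_poles(G))
  if (is.null(p))
    stop("unsupported-dynamics: complex poles (oscillatory system) are out of scope")
  if (any(p >= 0))
    stop("instability: non-negative pole(s) found; system is not a stable relaxation")
  z <- real_roots(tf_zeros(G))
  if (is.null(z))
    stop("unsupported-dynamics: complex zeros are out of scope")
  structure(list(tau_poles = sort(-1 / p),
                 tau_zeros = if (length(z)) -1 / z else numeric(0),
                 dc_gain = dc_gain(G)),
            class = "tf_features")
}

#' @export
print.tf_features <- function(x, ...) {
  cat(sprintf("tau_poles = {%s} ms, tau_zeros = {%s} ms, dc gain = %g\n",
              paste(signif(x$tau_poles, 6), collapse = ", "),
              paste(signif(x$tau_zeros, 6), collapse = ", "),
              x$dc_gain))
  invisible(x)
}

#' Cancel near-coincident pole-zero pairs
#'
#' Pairs each zero with its closest pole and removes both when their relative
#' distance is below \code{tol}; the leading gain is preserved. Used to prune
#' over-parameterized identifications back to the true model order.
#'
#' @param G A [rational_tf()].
#' @param tol Relative distance \eqn{|z - p| / |p|} below which a pair is
#'   considered cancelled.
#' @param warn Emit a warning when a cancellation occurs.
#' @return A [rational_tf()] of possibly lower order.
#' @export
prune_cancellations <- function(G, tol = 1e-6, warn = FALSE) {
  p <- tf_poles(G)
  z <- tf_zeros(G)
  if (length(z) == 0L || length(p) == 0L) return(G)
  gain <- G$num[1L]
  keep_z <- rep(TRUE, length(z))
  keep_p <- rep(TRUE, length(p))
  for (i in seq_along(z)) {
    d <- Mod(z[i] - p) / pmax(Mod(p), .Machine$double.eps)
    d[!keep_p] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] < tol) {
      keep_z[i] <- FALSE
      keep_p[j] <- FALSE
    }
  }
  if (all(keep_z)) return(G)
  if (warn) warning("near pole-zero cancellation: collapsing to a lower-order transfer function")
  rational_tf(gain * poly_from_roots(z[keep_z]), poly_from_roots(p[keep_p]))
}

#' Analytic step response of a rational transfer function
#'
#' Closed-form response to a unit step applied at \code{step_time}, computed
#' by partial-fraction expansion over the (distinct, real, negative) poles.
#' Serves as an integration-free reference backend for the kinetic-scheme
#' simulator.
#'
#' @param G A [rational_tf()] with distinct stable real poles.
#' @param t Time grid, ms.
#' @param step_time Step onset, ms.
#' @param amplitude Step height.
#' @return Numeric vector of the response on \code{t}.
#' @export
tf_step_response <- function(G, t, step_time = 0, amplitude = 1) {
  p <- real_roots(tf_poles(G))
  if (is.null(p) || any(p >= 0))
    stop("tf_step_response requires stable real poles")
  if (length(p) >= 2L && min(dist(p)) < 1e-9 * max(abs(p)))
    stop("tf_step_response requires distinct poles")
  ## G(s) = sum r_i / (s - p_i); step response y(t) = sum r_i/p_i (e^{p_i t} - 1)
  r <- vapply(seq_along(p), function(i) {
    poly_eval(G$num, p[i]) / poly_eval(poly_from_roots(p[-i]), p[i])
  }, numeric(1))
  dt <- t - step_time
  y <- numeric(length(t))
  on <- dt >= 0
  for (i in seq_along(p))
    y[on] <- y[on] + (r[i] / p[i]) * (exp(p[i] * dt[on]) - 1)
  amplitude * y
}

#' Serialize a transfer function to JSON
#'
#' @param G A [rational_tf()].
#' @return A JSON string with fields \code{zeros}, \code{poles}, \code{gain}.
#' @export
tf_to_json <- function(G) {
  p <- real_roots(tf_poles(G)); z <- real_roots(tf_zeros(G))
  jsonlite::toJSON(list(zeros = as.numeric(z), poles = as.numeric(p),
                        gain = G$num[1L]),
                   auto_unbox = FALSE, digits = NA)
}
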