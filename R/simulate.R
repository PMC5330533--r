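## Synthetic trace simulator: step responses of the five canonical kinetic
## schemes plus calibrated noise, used as fixture generator and Monte-Carlo
## engine.

#' Generate a synthetic step-response trace from a canonical scheme
#'
#' Builds the kinetic scheme for the requested configuration from the
#' first-order process parameters (via the analytic converter closed forms)
#' and simulates its response to an ideal unit step, returning the (t, u, y)
#' trace. A direct transfer-function step response ([tf_step_response()]) is an
#' independent backend that must agree with this simulation.
#'
#' @param config One of \code{"first_order"}, \code{"cascade"},
#'   \code{"feedback"}, \code{"parallel"} (split into addition/subtraction by
#'   the gain signs), \code{"parallel_add"}, \code{"parallel_sub"}.
#' @param k_a,tau_a Gain and time constant (ms) of the fast process a.
#' @param k_b,tau_b Gain and time constant (ms) of the slow process b
#'   (ignored for \code{first_order}).
#' @param step_time Step onset, ms.
#' @param duration Total duration, ms; defaults to \code{step_time + 6 *
#'   tau_b} (or \code{6 * tau_a} for first order) so the response settles.
#' @param Ts Sampling interval, ms. The default 0.25 ms gives at least 12
#'   samples per time constant for the fastest fixtures (tau_a = 5 ms used
#'   throughout), with a comfortable margin.
#' @param amplitude Step height.
#' @return A [sampled_trace()]; the generating scheme and transfer function
#'   are attached as attributes \code{"scheme"} and \code{"G"}.
#' @examples
#' tr <- synth_trace("parallel", -5, 3, 5, 100)
#' attr(tr, "scheme")
#' @export
synth_trace <- function(config, k_a, k_b = NA, tau_a, tau_b = NA,
                        step_time = 30, duration = NULL, Ts = 0.25,
                        amplitude = 1) {
  if (identical(config, "parallel")) {
    config <- if (k_a * k_b < 0) "parallel_sub" else "parallel_add"
  }
  if (config == "first_order") {
    k_b <- NA; tau_b <- NA
    if (is.null(duration)) duration <- step_time + 6 * tau_a
    G <- make_first_order(k_a, tau_a)
  } else {
    stopifnot(is.finite(k_b), is.finite(tau_b))
    if (is.null(duration)) duration <- step_time + 6 * tau_b
    G <- combine_processes(first_order_process(k_a, tau_a),
                           first_order_process(k_b, tau_b),
                           if (config == "cascade") "cascade"
                           else if (config == "feedback") "feedback"
                           else "parallel")
  }
  scheme <- convert_to_scheme(G, config,
                              params = c(k_a = k_a, k_b = k_b,
                                         tau_a = tau_a, tau_b = tau_b),
                              check_tol = 1e-6)
  t <- seq(0, duration, by = Ts)
  traj <- simulate_scheme(scheme,
                          input = list(type = "step", time = step_time,
                                       amplitude = amplitude),
                          t = t)
  out <- sampled_trace(traj$t, traj$u, traj$y, Ts = Ts)
  attr(out, "scheme") <- scheme
  attr(out, "G") <- G
  out
}

## solve the white-noise variance lambda that yields a target SNR (dB):
## SNR = P_Y / (2 lambda BW_cs) with BW_cs the 3 dB bandwidth in cycles/sample
lambda_for_snr <- function(trace, G, snr_db_target) {
  on <- step_onset(trace)
  win <- if (is.na(on)) seq_along(trace$y) else on:nrow(trace)
  P_Y <- mean(trace$y[win]^2)
  bw <- tf_bandwidth_3db(G) * trace_Ts(trace)  # cycles/sample
  P_Y / (2 * bw * 10^(snr_db_target / 10))
}

#' Add calibrated noise to a trace
#'
#' White Gaussian noise of variance \code{lambda} is added sample-wise to the
#' output channel; Brownian noise is the cumulative sum of white increments.
#' When a target SNR (dB) is given instead of \code{lambda}, the variance is
#' solved from the signal power and the 3 dB bandwidth of the generating
#' transfer function (noise power = 2 lambda BW). Brownian noise has no flat
#' spectrum, so its target-SNR mode uses the same signal power but an
#' empirical in-band estimate of the realized noise power, rescaling the path
#' accordingly.
#'
#' @param trace A [sampled_trace()].
#' @param kind \code{"white_gaussian"} or \code{"brownian"}.
#' @param lambda Noise variance (white: per-sample variance; brownian:
#'   increment variance). Exactly one of \code{lambda}, \code{snr_db} must be
#'   given.
#' @param snr_db Target signal-to-noise ratio in dB (requires \code{G}).
#' @param G The generating [rational_tf()] (for the bandwidth in target-SNR
#'   mode); taken from the trace attribute when present.
#' @param seed Integer seed for reproducible noise.
#' @return A [sampled_trace()] with noisy \code{y}; attributes of the input
#'   trace are preserved and the injected \code{lambda} recorded.
#' @export
add_noise <- function(trace, kind = c("white_gaussian", "brownian"),
                      lambda = NULL, snr_db = NULL, G = NULL, seed = NULL) {
  kind <- match.arg(kind)
  if (is.null(lambda) == is.null(snr_db))
    stop("invalid-noise: give exactly one of 'lambda' or 'snr_db'")
  if (is.null(G)) G <- attr(trace, "G")
  n <- nrow(trace)
  if (!is.null(snr_db)) {
    if (is.null(G)) stop("target-SNR mode needs the generating transfer function G")
    lambda <- lambda_for_snr(trace, G, snr_db)
  }
  if (!is.finite(lambda) || lambda < 0) stop("invalid-noise: lambda must be >= 0")
  if (lambda == 0) return(trace)
  noise <- with_seed(seed, {
    if (kind == "white_gaussian") {
      stats::rnorm(n, 0, sqrt(lambda))
    } else {
      path <- cumsum(stats::rnorm(n, 0, sqrt(lambda)))
      if (!is.null(snr_db)) {
        ## rescale so the realized in-band noise power hits the target
        on <- step_onset(trace)
        win <- if (is.na(on)) seq_along(trace$y) else on:n
        P_Y <- mean(trace$y[win]^2)
        bw_cs <- tf_bandwidth_3db(G) * trace_Ts(trace)
        p_in <- inband_power(path, bw_cs)
        target_p <- P_Y / 10^(snr_db / 10)
        path <- path * sqrt(target_p / p_in)
      }
      path
    }
  })
  out <- sampled_trace(trace$t, trace$u, trace$y + noise, Ts = trace_Ts(trace))
  attr(out, "scheme") <- attr(trace, "scheme")
  attr(out, "G") <- G
  attr(out, "lambda") <- if (kind == "white_gaussian") lambda else NA_real_
  attr(out, "noise_kind") <- kind
  out
}

## empirical power of x within |f| <= bw (cycles/sample) via the periodogram
inband_power <- function(x, bw) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  f <- (seq_len(n) - 1) / n
  f <- pmin(f, 1 - f)
  sum(Mod(X[f <= bw])^2) / n^2
}

#' Zero-phase low-pass pre-filter
#'
#' Applies a forward-backward (zero-phase) Butterworth low-pass to the trace.
#' Both channels are filtered identically, which leaves the input-output
#' transfer function unchanged while removing out-of-band noise, so the
#' filtered trace can be fed directly to identification; filtering the output
#' alone would bias the identified dynamics by the filter response.
#'
#' @param trace A [sampled_trace()].
#' @param cutoff Cut-off frequency in cycles/ms; must be below the Nyquist
#'   frequency \code{1/(2 Ts)}.
#' @param order Butterworth order.
#' @param channels Which channels to filter (default both).
#' @return A filtered [sampled_trace()].
#' @export
prefilter <- function(trace, cutoff, order = 4L, channels = c("y", "u")) {
  nyq <- 1 / (2 * trace_Ts(trace))
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= nyq)
    stop(sprintf("invalid-filter: cutoff must lie in (0, Nyquist = %g cycles/ms)", nyq))
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  npad <- ceiling(6 / (cutoff * trace_Ts(trace)))
  yf <- if ("y" %in% channels) filtfilt_padded(bf, trace$y, npad) else trace$y
  uf <- if ("u" %in% channels) filtfilt_padded(bf, trace$u, npad) else trace$u
  out <- sampled_trace(trace$t, uf, yf, Ts = trace_Ts(trace))
  attr(out, "scheme") <- attr(trace, "scheme")
  attr(out, "G") <- attr(trace, "G")
  out
}
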