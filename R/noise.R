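## Signal-to-noise computation and Monte-Carlo noise-robustness sweeps.

#' 3 dB bandwidth of a transfer function
#'
#' Frequency (cycles/ms) at which the gain \eqn{|G(i 2\pi f)|} has dropped
#' 3 dB (factor 1/sqrt(2)) below its maximum. The maximum is searched over
#' frequency because band-pass-like responses (e.g. parallel subtraction with
#' a fast transient) peak away from dc. The largest crossing is returned
#' (upper band edge), refined by bisection.
#'
#' @param G A [rational_tf()].
#' @param f_max Upper end of the search grid, cycles/ms; defaults to 100 times
#'   the fastest pole rate.
#' @return Bandwidth in cycles/ms.
#' @export
tf_bandwidth_3db <- function(G, f_max = NULL) {
  p <- real_roots(tf_poles(G))
  if (is.null(p) || any(p >= 0)) stop("bandwidth requires stable real poles")
  if (is.null(f_max)) f_max <- 100 * max(abs(p)) / (2 * pi)
  f <- exp(seq(log(1e-6 * f_max), log(f_max), length.out = 2000L))
  g <- Mod(tf_eval(G, 2i * pi * f))
  gmax <- max(g, Mod(tf_eval(G, 0 + 0i)))
  thr <- gmax / sqrt(2)
  above <- g >= thr
  if (!any(above)) return(f[1L])
  i <- max(which(above))
  if (i == length(f)) return(f[i])
  ## refine the downward crossing between f[i] and f[i+1]
  lo <- f[i]; hi <- f[i + 1L]
  for (it in 1:60) {
    mid <- sqrt(lo * hi)
    if (Mod(tf_eval(G, 2i * pi * mid)) >= thr) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Signal-to-noise ratio of a trace in dB
#'
#' Signal power is the mean square of the response over the post-stimulus
#' window, with the per-sample noise variance subtracted so that heavy noise
#' does not inflate the apparent signal; noise power is the white-noise
#' variance restricted to the signal's 3 dB bandwidth, \eqn{P_N = 2 \lambda BW}
#' with BW in cycles/sample (an ideal low-pass band is assumed). Returns
#' \eqn{10 \log_{10}(P_Y / P_N)}.
#'
#' @param trace A [sampled_trace()] (baseline-subtracted response).
#' @param lambda_hat Noise variance estimate (e.g. from [identify_tf()], or a
#'   known injected value).
#' @param G The identified or generating [rational_tf()], for the bandwidth.
#' @return SNR in dB; \code{Inf} for \code{lambda_hat = 0}.
#' @export
snr_db <- function(trace, lambda_hat, G = NULL) {
  if (is.null(G)) G <- attr(trace, "G")
  if (is.null(G)) stop("snr_db needs a transfer function for the bandwidth")
  on <- step_onset(trace)
  win <- if (is.na(on)) seq_along(trace$y) else on:nrow(trace)
  y <- trace$y[win]
  if (length(win) && !is.na(on) && on > 1L) y <- y - mean(trace$y[seq_len(on - 1L)])
  if (lambda_hat < 0) stop("invalid lambda")
  P_Y <- mean(y^2) - lambda_hat
  if (P_Y <= 0) stop("undefined-SNR: no signal power above the noise floor")
  if (lambda_hat == 0) return(Inf)
  bw_cs <- tf_bandwidth_3db(G) * trace_Ts(trace)
  10 * log10(P_Y / (2 * lambda_hat * bw_cs))
}

#' Monte-Carlo noise-robustness sweep
#'
#' For each SNR level, generates \code{n_sim} noisy replicates of the
#' canonical trace, runs identification and classification on each, and
#' records the misclassification probability P_e (any label other than the
#' generating configuration, including wrong order and ambiguous outcomes,
#' counts as an error) and the relative errors of the recovered transition
#' rates \eqn{|\hat\sigma_k - \sigma_k| / \sigma_k} over the correctly
#' classified runs.
#'
#' @param config \code{"parallel_sub"}, \code{"parallel_add"},
#'   \code{"feedback"} or \code{"cascade"}.
#' @param k_a,k_b,tau_a,tau_b Generating process parameters.
#' @param snr_levels SNR levels in dB; use \code{Inf} for a noise-free point.
#' @param n_sim Replicates per level (default 100).
#' @param bounds A [scheme_bounds()] for the classifier.
#' @param seed Root seed; replicate seeds are derived deterministically.
#' @param noise_kind Passed to [add_noise()].
#' @param step_time,duration,Ts Trace geometry, passed to [synth_trace()].
#' @return An object of class \code{"noise_sweep"}: a data frame with one row
#'   per level (snr_db, p_e, mean/sd relative error per sigma, n_correct) plus
#'   the per-run details.
#' @export
noise_sweep <- function(config, k_a = -5, k_b = 3, tau_a = 5, tau_b = 100,
                        snr_levels = c(40, 35, 30, 25, 22, 18),
                        n_sim = 100L, bounds = scheme_bounds(), seed = 1L,
                        noise_kind = "white_gaussian", step_time = 30,
                        duration = NULL, Ts = 0.25) {
  if (n_sim < 10L) warning("n_sim < 10: probability-of-error estimates will be unstable")
  base <- synth_trace(config, k_a, k_b, tau_a, tau_b, step_time = step_time,
                      duration = duration, Ts = Ts)
  G0 <- attr(base, "G")
  sig0 <- scheme_rates(attr(base, "scheme"))
  sig0 <- sig0[setdiff(names(sig0), "gamma")]
  runs <- vector("list", length(snr_levels))
  for (li in seq_along(snr_levels)) {
    lev <- snr_levels[li]
    lab <- character(n_sim)
    rel <- matrix(NA_real_, n_sim, length(sig0),
                  dimnames = list(NULL, names(sig0)))
    for (r in seq_len(n_sim)) {
      rs <- (seed * 10007L + li * 101L + r) %% .Machine$integer.max
      tr <- if (is.finite(lev))
        add_noise(base, noise_kind, snr_db = lev, G = G0, seed = rs)
      else base
      lab[r] <- tryCatch({
        idf <- suppressWarnings(identify_tf(tr))
        cl <- classify_tf(idf$G, bounds)
        if (cl$configuration == config) {
          sch <- tryCatch(convert_to_scheme(idf$G, cl, check_tol = Inf),
                          error = function(e) NULL)
          if (!is.null(sch)) {
            sig <- scheme_rates(sch)[names(sig0)]
            rel[r, ] <- abs(sig - sig0) / abs(sig0)
          }
        }
        cl$configuration
      }, error = function(e) "error")
    }
    runs[[li]] <- list(snr_db = lev, labels = lab, rel_err = rel)
  }
  tab <- do.call(rbind, lapply(runs, function(z) {
    ok <- z$labels == config
    data.frame(snr_db = z$snr_db,
               p_e = mean(!ok),
               n_sim = length(z$labels),
               n_correct = sum(ok),
               rel_err_mean = mean(z$rel_err[ok, , drop = FALSE], na.rm = TRUE),
               rel_err_sd = stats::sd(z$rel_err[ok, , drop = FALSE], na.rm = TRUE))
  }))
  structure(list(config = config,
                 params = c(k_a = k_a, k_b = k_b, tau_a = tau_a, tau_b = tau_b),
                 table = tab, runs = runs, sigma_true = sig0,
                 n_sim = n_sim, seed = seed),
            class = "noise_sweep")
}

#' @export
print.noise_sweep <- function(x, ...) {
  cat(sprintf("Noise sweep: %s generator (k_a=%g, k_b=%g, tau_a=%g, tau_b=%g), %d runs/level\n",
              x$config, x$params["k_a"], x$params["k_b"],
              x$params["tau_a"], x$params["tau_b"], x$n_sim))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.noise_sweep <- function(x, ...) {
  tab <- x$table[is.finite(x$table$snr_db), ]
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(tab$snr_db, tab$p_e, type = "b", xlab = "SNR (dB)",
                 ylab = expression(P[e]), ylim = c(0, 1), ...)
  graphics::plot(tab$snr_db, tab$rel_err_mean, type = "b", xlab = "SNR (dB)",
                 ylab = "mean relative error of sigma", ...)
  invisible(x)
}

#' Serialize a sweep result to JSON
#' @param x A \code{"noise_sweep"}.
#' @return JSON string of the per-level summary table and run metadata.
#' @export
sweep_to_json <- function(x) {
  jsonlite::toJSON(list(config = x$config, params = as.list(x$params),
                        n_sim = x$n_sim, seed = x$seed, table = x$table),
                   dataframe = "rows", auto_unbox = TRUE, digits = NA)
}
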