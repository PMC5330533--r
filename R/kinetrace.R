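## The end-to-end model fit: identify -> classify -> convert -> verify,
## wrapped as a classed model object with the usual methods.

#' Fit a molecular kinetic scheme to a stimulus-response trace
#'
#' \code{kinetrace()} runs the full pipeline on a uniformly sampled
#' input/output trace pair: (1) ARX prediction-error identification of the
#' continuous transfer function G(s); (2) classification of the configuration
#' of the underlying first-order processes (first order, cascade, feedback,
#' parallel addition/subtraction, or higher order) by constrained least
#' squares; (3) analytic conversion of G(s) plus configuration into a
#' Markov-chain kinetic scheme with transition rates sigma_k (1/ms) and
#' observable scaling gamma; (4) a verification pass that simulates the scheme
#' against the observed trace and reports the relative RMS misfit.
#'
#' @param x A [sampled_trace()], a data frame with time/input/output columns,
#'   or a formula \code{y ~ u} naming the output and input columns of
#'   \code{data}.
#' @param ... Passed on to methods.
#' @return An object of class \code{"kinetrace"}; see
#'   [print.kinetrace()], [summary.kinetrace()], [coef.kinetrace()],
#'   [predict.kinetrace()], [plot.kinetrace()], [simulate.kinetrace()].
#' @examples
#' tr <- synth_trace("feedback", k_a = -5, k_b = 2, tau_a = 5, tau_b = 200)
#' fit <- kinetrace(tr)
#' fit
#' coef(fit)
#' @export
kinetrace <- function(x, ...) UseMethod("kinetrace")

#' @rdname kinetrace
#' @param bounds A [scheme_bounds()] constraining the classifier.
#' @param order_grid,baseline,prune_tol Passed to [identify_tf()].
#' @param tie_tol,n_starts,seed Passed to [classify_tf()].
#' @param labels Optional biological state labels attached to the scheme.
#' @export
kinetrace.sampled_trace <- function(x, bounds = scheme_bounds(),
                                    order_grid = NULL, baseline = "auto",
                                    prune_tol = 0.01, tie_tol = 0.05,
                                    n_starts = 16L, seed = 1L,
                                    labels = NULL, ...) {
  cl <- match.call()
  idf <- identify_tf(x, order_grid = order_grid, baseline = baseline,
                     prune_tol = prune_tol)
  cls <- classify_tf(idf$G, bounds, tie_tol = tie_tol,
                     n_starts = n_starts, seed = seed)
  scheme <- NULL
  traj <- NULL
  misfit <- NA_real_
  if (cls$configuration %in% c("first_order", "cascade", "feedback",
                               "parallel_add", "parallel_sub")) {
    scheme <- convert_to_scheme(idf$G, cls, check_tol = 1e-4, labels = labels)
    ## verification overlay: scheme response to the observed input
    u <- x$u
    win <- idf$baseline_window
    if (length(win)) u <- u - mean(u[win])
    traj <- simulate_scheme(scheme, input = u, t = x$t)
    yobs <- x$y
    if (length(win)) yobs <- yobs - mean(yobs[win])
    misfit <- sqrt(mean((traj$y - yobs)^2)) /
      max(sqrt(mean(yobs^2)), .Machine$double.xmin)
  }
  structure(list(trace = x, identification = idf, classification = cls,
                 scheme = scheme, trajectory = traj, misfit = misfit,
                 bounds = bounds, seed = seed, call = cl),
            class = "kinetrace")
}

#' @rdname kinetrace
#' @param time,input,output Column names (or positions) in the data frame.
#' @export
kinetrace.data.frame <- function(x, time = 1L, input = 2L, output = 3L, ...) {
  get1 <- function(col) if (is.character(col)) x[[col]] else x[[col]]
  tr <- sampled_trace(get1(time), get1(input), get1(output))
  kinetrace(tr, ...)
}

#' @rdname kinetrace
#' @param data Data frame holding the trace columns for the formula method.
#' @export
kinetrace.formula <- function(x, data, time = "t", ...) {
  yv <- all.vars(x[[2L]]); uv <- all.vars(x[[3L]])
  stopifnot(length(yv) == 1L, length(uv) == 1L)
  tr <- sampled_trace(data[[time]], data[[uv]], data[[yv]])
  kinetrace(tr, ...)
}

#' @export
print.kinetrace <- function(x, ...) {
  cat("Kinetic-scheme fit\n")
  ft <- x$identification$features
  cat(sprintf("  G(s): %d pole(s) tau = {%s} ms, %d zero(s)%s, dc gain %.4g\n",
              length(ft$tau_poles),
              paste(signif(ft$tau_poles, 5), collapse = ", "),
              length(ft$tau_zeros),
              if (length(ft$tau_zeros))
                sprintf(" tau = {%s} ms", paste(signif(ft$tau_zeros, 5), collapse = ", "))
              else "",
              ft$dc_gain))
  cat(sprintf("  configuration: %s\n", x$classification$configuration))
  if (!is.null(x$scheme)) {
    r <- scheme_rates(x$scheme)
    cat("  rates: ", paste(sprintf("%s = %.4g", names(r), r), collapse = ", "),
        " (1/ms; gamma in output units)\n", sep = "")
    cat(sprintf("  reconstruction misfit (rel. RMS): %.3g\n", x$misfit))
  }
  invisible(x)
}

#' @export
summary.kinetrace <- function(object, ...) {
  idf <- object$identification
  out <- list(fit = object,
              order = idf$order, loss = idf$loss,
              lambda_hat = idf$lambda_hat,
              snr_db = tryCatch(snr_db(object$trace, idf$lambda_hat, idf$G),
                                error = function(e) NA_real_),
              configuration = object$classification$configuration,
              f_valp = object$classification$f_valp,
              f_valf = object$classification$f_valf,
              recovered = object$classification$recovered,
              rates = if (!is.null(object$scheme)) scheme_rates(object$scheme),
              misfit = object$misfit)
  class(out) <- "summary.kinetrace"
  out
}

#' @export
print.summary.kinetrace <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  ARX order (n_a, n_b) = (%d, %d); loss = %.3g; lambda_hat = %.3g; trace SNR ~ %.1f dB\n",
              x$order[1L], x$order[2L], x$loss, x$lambda_hat, x$snr_db))
  if (is.finite(x$f_valp) || is.finite(x$f_valf))
    cat(sprintf("  classifier costs: f_valp = %.3g, f_valf = %.3g\n",
                x$f_valp, x$f_valf))
  if (!is.null(x$recovered)) {
    r <- x$recovered
    cat(sprintf("  recovered processes: k_a = %.4g, tau_a = %.4g ms; k_b = %.4g, tau_b = %.4g ms\n",
                r["k_a"], r["tau_a"], r["k_b"], r["tau_b"]))
  }
  invisible(x)
}

#' Kinetic parameters of the fitted scheme
#' @param object A \code{"kinetrace"} fit.
#' @param ... Unused.
#' @return Named vector of transition rates sigma_k (1/ms) and gamma.
#' @export
coef.kinetrace <- function(object, ...) {
  if (is.null(object$scheme))
    stop("no scheme: classification was ", object$classification$configuration)
  scheme_rates(object$scheme)
}

#' @export
fitted.kinetrace <- function(object, ...) {
  if (is.null(object$trajectory)) return(NULL)
  object$trajectory$y
}

#' @export
residuals.kinetrace <- function(object, ...) {
  if (is.null(object$trajectory)) return(NULL)
  win <- object$identification$baseline_window
  yobs <- object$trace$y
  if (length(win)) yobs <- yobs - mean(yobs[win])
  yobs - object$trajectory$y
}

#' Predict the response of the fitted scheme to a new input
#'
#' @param object A \code{"kinetrace"} fit with a committed scheme.
#' @param input A step specification \code{list(type = "step", time, amplitude)} or a
#'   sampled input vector on \code{t}.
#' @param t Time grid, ms; defaults to the grid of the fitted trace.
#' @param ... Unused.
#' @return A \code{"scheme_trajectory"}.
#' @export
predict.kinetrace <- function(object, input = NULL, t = NULL, ...) {
  if (is.null(object$scheme)) stop("no scheme committed; cannot predict")
  if (is.null(t)) t <- object$trace$t
  if (is.null(input)) input <- object$trace$u
  simulate_scheme(object$scheme, input = input, t = t)
}

#' Simulate noisy replicates from a fitted scheme
#'
#' @param object A \code{"kinetrace"} fit with a committed scheme.
#' @param nsim Number of replicate traces.
#' @param seed Root seed.
#' @param snr_db Target SNR of the replicates (dB); \code{NULL} for noise-free.
#' @param ... Unused.
#' @return A list of [sampled_trace()] objects.
#' @export
simulate.kinetrace <- function(object, nsim = 1, seed = NULL, snr_db = NULL,
                               ...) {
  if (is.null(object$scheme)) stop("no scheme committed; cannot simulate")
  base <- predict(object)
  tr <- sampled_trace(base$t, base$u, base$y)
  attr(tr, "G") <- object$identification$G
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    out[[i]] <- if (is.null(snr_db)) tr
    else add_noise(tr, "white_gaussian", snr_db = snr_db,
                   G = object$identification$G,
                   seed = if (is.null(seed)) NULL else seed + i - 1L)
  }
  if (nsim == 1L) out[[1L]] else out
}

#' @export
plot.kinetrace <- function(x, which = c("fit", "occupancy"), ...) {
  which <- match.arg(which)
  if (which == "fit") {
    win <- x$identification$baseline_window
    yobs <- x$trace$y
    if (length(win)) yobs <- yobs - mean(yobs[win])
    graphics::plot(x$trace$t, yobs, type = "l", col = "grey50",
                   xlab = "time (ms)", ylab = "response", ...)
    if (!is.null(x$trajectory))
      graphics::lines(x$trajectory$t, x$trajectory$y, col = "red", lwd = 2)
    graphics::legend("bottomright", c("observed", "scheme reconstruction"),
                     col = c("grey50", "red"), lwd = c(1, 2), bty = "n")
  } else {
    if (is.null(x$trajectory)) stop("no scheme trajectory available")
    plot(x$trajectory, which = "occupancy", ...)
  }
  invisible(x)
}

#' Full pipeline report as a serializable list
#'
#' Collects identification, classification, scheme and verification results in
#' a self-contained structure suitable for JSON export; re-running the
#' pipeline with the embedded settings reproduces it.
#'
#' @param fit A \code{"kinetrace"} object.
#' @return A list; serialize with \code{jsonlite::toJSON}.
#' @export
kinetrace_report <- function(fit) {
  idf <- fit$identification
  list(identification = list(
         order = as.list(idf$order),
         loss = idf$loss, lambda_hat = idf$lambda_hat,
         tau_poles = idf$features$tau_poles,
         tau_zeros = idf$features$tau_zeros,
         dc_gain = idf$features$dc_gain),
       classification = list(
         configuration = fit$classification$configuration,
         f_valp = fit$classification$f_valp,
         f_valf = fit$classification$f_valf,
         ambiguous = fit$classification$ambiguous,
         recovered = as.list(fit$classification$recovered)),
       scheme = if (!is.null(fit$scheme))
         list(states = fit$scheme$states,
              transitions = fit$scheme$transitions,
              observable = fit$scheme$observable,
              gamma = fit$scheme$gamma,
              rates = as.list(scheme_rates(fit$scheme))),
       misfit = fit$misfit,
       provenance = list(seed = fit$seed,
                         bounds = unclass(fit$bounds),
                         package_version = as.character(utils::packageVersion("kinetrace"))))
}
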