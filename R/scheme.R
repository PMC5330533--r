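## Markov-chain kinetic schemes: construction from a classified transfer
## function, back-conversion to a transfer function, and simulation.
##
## A scheme has n+1 states for an order-n transfer function. One state is
## input-linked: its occupancy is not integrated but set by mass conservation,
## sum_i z_i(t) = u(t), so the stimulus enters as the unique driver of the
## total population. One state is observable: y(t) = gamma * z_obs(t).

#' Construct a kinetic scheme object
#'
#' @param states Character vector of state labels (generic \code{S1..Sn} by
#'   default; biological names are user metadata, not inferred).
#' @param transitions Data frame with columns \code{from}, \code{to} (state
#'   labels) and \code{sigma} (rate, 1/ms, strictly positive).
#' @param observable Label of the single observable state.
#' @param input_state Label of the input-linked state (initial occupancy 1 for
#'   a unit step).
#' @param gamma Observable scaling (output units per unit fractional
#'   occupancy); may be negative.
#' @param configuration Provenance label (which canonical configuration the
#'   scheme was derived from).
#' @return An object of class \code{"kinetic_scheme"}.
#' @export
kinetic_scheme <- function(states, transitions, observable, input_state,
                           gamma, configuration = NA_character_) {
  stopifnot(is.character(states), length(states) >= 2L,
            all(c("from", "to", "sigma") %in% names(transitions)))
  if (!observable %in% states) stop("malformed-scheme: unknown observable state")
  if (!input_state %in% states) stop("malformed-scheme: unknown input state")
  if (anyDuplicated(states)) stop("malformed-scheme: duplicated state labels")
  if (!all(transitions$from %in% states) || !all(transitions$to %in% states))
    stop("malformed-scheme: transition endpoints must be states")
  if (any(!is.finite(transitions$sigma) | transitions$sigma <= 0))
    stop("infeasible-scheme: all transition rates sigma must be > 0 (a non-positive rate signals mis-classification)")
  sch <- structure(list(states = states,
                        transitions = as.data.frame(transitions),
                        observable = observable, input_state = input_state,
                        gamma = gamma, configuration = configuration),
                   class = "kinetic_scheme")
  check_reversibility(sch)
  sch
}

## microscopic reversibility: no directed simple cycle of length >= 3 may lack
## its reverse path. Canonical second-order schemes only ever contain 2-cycles,
## so detection (not repair) suffices here.
check_reversibility <- function(scheme) {
  st <- scheme$states
  n <- length(st)
  adj <- matrix(FALSE, n, n, dimnames = list(st, st))
  for (i in seq_len(nrow(scheme$transitions)))
    adj[scheme$transitions$from[i], scheme$transitions$to[i]] <- TRUE
  ## DFS for simple directed cycles of length >= 3
  found <- FALSE
  path <- character(0)
  visit <- function(v, start, depth) {
    if (found) return()
    path[depth] <<- v
    for (w in st[adj[v, ]]) {
      if (w == start && depth >= 3L) {
        ## cycle found: offset only if the full reverse cycle exists
        cyc <- c(path[seq_len(depth)], start)
        rev_ok <- all(vapply(seq_len(depth), function(i)
          adj[cyc[i + 1L], cyc[i]], logical(1)))
        if (!rev_ok) found <<- TRUE
      } else if (!w %in% path[seq_len(depth)] && depth < n) {
        visit(w, start, depth + 1L)
      }
    }
  }
  for (s in st) { path <- character(0); visit(s, s, 1L) }
  if (found)
    warning("microscopic reversibility: the scheme contains an unbalanced circular flow over 3+ states")
  invisible(!found)
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf("Kinetic scheme (%s): %d states\n",
              x$configuration, length(x$states)))
  for (i in seq_len(nrow(x$transitions)))
    cat(sprintf("  %s -> %s   sigma = %.6g /ms\n",
                x$transitions$from[i], x$transitions$to[i],
                x$transitions$sigma[i]))
  cat(sprintf("  observable: %s (gamma = %.6g); input-linked: %s\n",
              x$observable, x$gamma, x$input_state))
  invisible(x)
}

## state-space (A, B, C) of the scheme with the input state eliminated:
## x = occupancies of all non-input states, z_input = u - sum(x)
scheme_state_space <- function(scheme) {
  st <- scheme$states
  xs <- setdiff(st, scheme$input_state)
  n <- length(xs)
  A <- matrix(0, n, n, dimnames = list(xs, xs))
  B <- stats::setNames(numeric(n), xs)
  for (i in seq_len(nrow(scheme$transitions))) {
    f <- scheme$transitions$from[i]; t <- scheme$transitions$to[i]
    s <- scheme$transitions$sigma[i]
    if (f == scheme$input_state) {
      B[t] <- B[t] + s
      A[t, ] <- A[t, ] - s
    } else {
      A[f, f] <- A[f, f] - s
      if (t != scheme$input_state) A[t, f] <- A[t, f] + s
    }
  }
  if (scheme$observable == scheme$input_state)
    stop("malformed-scheme: the input-linked state cannot be the observable")
  C <- as.numeric(xs == scheme$observable)
  list(A = A, B = unname(B), C = C, xs = xs)
}

#' Transfer function of a kinetic scheme
#'
#' Solves the Laplace-transformed linear system (transition ODEs, observable
#' equation, mass conservation) for \eqn{G_{kin}(s) = Y(s)/U(s)} in closed
#' polynomial form, via the Faddeev-LeVerrier recursion on the eliminated
#' state-space realization.
#'
#' @param scheme A [kinetic_scheme()].
#' @return A [rational_tf()].
#' @export
scheme_to_tf <- function(scheme) {
  ss <- scheme_state_space(scheme)
  A <- ss$A; B <- ss$B; C <- ss$C
  n <- nrow(A)
  if (n == 0L) stop("malformed-scheme: no dynamic states")
  ## Faddeev-LeVerrier: den = s^n + c1 s^{n-1} + ... + cn,
  ## adj(sI - A) = sum_k s^{n-1-k} M_{k+1}
  M <- diag(n)
  cs <- numeric(n)
  num <- numeric(n)
  den <- c(1, numeric(n))
  for (k in seq_len(n)) {
    num[k] <- sum(C * (M %*% B))
    AM <- A %*% M
    cs[k] <- -sum(diag(AM)) / k
    den[k + 1L] <- cs[k]
    M <- AM + cs[k] * diag(n)
  }
  ## singularity of the Laplace system shows up as an identically zero output
  ## or a non-reachable/observable realization with zero numerator
  if (all(abs(num) == 0))
    stop("singular-system: the observable state is not driven by the input")
  rational_tf(scheme$gamma * num, den)
}

## closed-form rates and observable scaling per configuration, from the
## recovered first-order parameters (k_a, k_b, tau_a, tau_b)
scheme_params <- function(configuration, k_a, k_b, tau_a, tau_b) {
  wa <- 1 / tau_a
  switch(configuration,
    first_order = list(sigma = c(sigma1 = wa), gamma = k_a),
    cascade = {
      wb <- 1 / tau_b
      list(sigma = c(sigma1 = wa, sigma2 = wb), gamma = k_a * k_b)
    },
    feedback = {
      wb <- 1 / tau_b
      list(sigma = c(sigma1 = wa, sigma2 = k_b / tau_b, sigma3 = wb),
           gamma = k_a)
    },
    parallel_add = {
      ## two routes into an absorbing observable state: a direct transition at
      ## the gain-weighted mean rate sigma1 = (b_a+b_b)/(k_a+k_b) and an
      ## indirect route through the intermediate at omega_a - sigma1, omega_b
      wb <- 1 / tau_b
      ba <- k_a / tau_a; bb <- k_b / tau_b
      s1 <- (ba + bb) / (k_a + k_b)
      list(sigma = c(sigma1 = s1, sigma2 = wa - s1, sigma3 = wb),
           gamma = k_a + k_b)
    },
    parallel_sub = {
      ## chain with a reversible second step; sigma3 is the zero rate of the
      ## parallel transfer function. A zero at or right of the origin
      ## (k_a + k_b and b_a + b_b of opposite sign) yields sigma3 <= 0:
      ## no mass-conserving scheme of this class exists then.
      wb <- 1 / tau_b
      ba <- k_a / tau_a; bb <- k_b / tau_b
      s3 <- (ba * wb + bb * wa) / (ba + bb)
      list(sigma = c(sigma1 = wa, sigma2 = wb - s3, sigma3 = s3),
           gamma = (k_a + k_b) * wb / s3)
    },
    stop("unknown configuration: ", configuration))
}

## scheme wiring per configuration (placeholders for parallel filled from the
## block-diagram derivation; see scheme_topology below)
scheme_topology <- function(configuration, sigma) {
  tr <- function(...) {
    m <- matrix(c(...), ncol = 3L, byrow = TRUE)
    data.frame(from = m[, 1L], to = m[, 2L],
               sigma = as.numeric(sigma[m[, 3L]]),
               stringsAsFactors = FALSE)
  }
  switch(configuration,
    first_order = list(states = c("S1", "S2"), input = "S1", obs = "S2",
                       transitions = tr("S1", "S2", "sigma1")),
    cascade = list(states = c("S1", "S2", "S3"), input = "S1", obs = "S3",
                   transitions = tr("S1", "S2", "sigma1",
                                    "S2", "S3", "sigma2")),
    feedback = list(states = c("S1", "S2", "S3"), input = "S1", obs = "S2",
                    transitions = tr("S1", "S2", "sigma1",
                                     "S2", "S3", "sigma2",
                                     "S3", "S2", "sigma3")),
    parallel_add = list(states = c("S1", "S2", "S3"), input = "S1",
                        obs = "S3",
                        transitions = tr("S1", "S3", "sigma1",
                                         "S1", "S2", "sigma2",
                                         "S2", "S3", "sigma3")),
    parallel_sub = list(states = c("S1", "S2", "S3"), input = "S1",
                        obs = "S2",
                        transitions = tr("S1", "S2", "sigma1",
                                         "S2", "S3", "sigma2",
                                         "S3", "S2", "sigma3")),
    stop("unknown configuration: ", configuration))
}

#' Convert a classified transfer function into a kinetic scheme
#'
#' Emits the Markov-chain scheme for the classified configuration, with
#' transition rates and observable scaling from the analytic closed forms, and
#' verifies internal consistency by reconstructing the transfer function from
#' the scheme and comparing coefficients against \code{G}.
#'
#' @param G The identified [rational_tf()].
#' @param result A \code{"scheme_classification"} (from [classify_tf()]), or a
#'   configuration string together with \code{params}.
#' @param params Named vector (k_a, k_b, tau_a, tau_b) overriding the recovered
#'   parameters in \code{result}.
#' @param check_tol Maximum relative coefficient mismatch between \code{G} and
#'   the scheme's own transfer function before a conversion-integrity error is
#'   raised; set to \code{Inf} to skip.
#' @param labels Optional user-supplied biological state labels (character
#'   vector, same length as the scheme's states).
#' @return A [kinetic_scheme()].
#' @examples
#' G <- combine_processes(first_order_process(-5, 5),
#'                        first_order_process(2, 200), "feedback")
#' cl <- classify_tf(G)
#' convert_to_scheme(G, cl)
#' @export
convert_to_scheme <- function(G, result, params = NULL, check_tol = 1e-6,
                              labels = NULL) {
  configuration <- if (is.character(result)) result else result$configuration
  if (!configuration %in% c("first_order", "cascade", "feedback",
                            "parallel_add", "parallel_sub"))
    stop("conversion requires a committed canonical configuration, got: ",
         configuration)
  if (is.null(params)) {
    if (is.character(result))
      stop("params must be supplied when result is a configuration string")
    params <- result$recovered
  }
  pr <- scheme_params(configuration, params[["k_a"]], params[["k_b"]],
                      params[["tau_a"]], params[["tau_b"]])
  if (any(!is.finite(pr$sigma)) || any(pr$sigma <= 0))
    stop("infeasible-scheme: closed forms yield a non-positive rate (sigma = ",
         paste(signif(pr$sigma, 4), collapse = ", "),
         "); the configuration is inconsistent with the parameters")
  topo <- scheme_topology(configuration, pr$sigma)
  states <- topo$states
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(states))
    map <- stats::setNames(labels, states)
    topo$transitions$from <- unname(map[topo$transitions$from])
    topo$transitions$to <- unname(map[topo$transitions$to])
    topo$input <- unname(map[topo$input]); topo$obs <- unname(map[topo$obs])
    states <- labels
  }
  sch <- kinetic_scheme(states, topo$transitions, topo$obs, topo$input,
                        pr$gamma, configuration)
  attr(sch, "sigma") <- pr$sigma
  if (is.finite(check_tol) && !is.null(G)) {
    Gk <- scheme_to_tf(sch)
    mis <- tf_coeff_mismatch(G, Gk)
    if (mis > check_tol)
      stop(sprintf("conversion-integrity: scheme transfer function deviates from G (relative mismatch %.3g)", mis))
  }
  sch
}

## relative mismatch between two transfer functions, evaluated over the
## dynamic band (scale-free; insensitive to numerically negligible
## coefficients that a raw coefficient comparison would flag)
tf_coeff_mismatch <- function(G1, G2) {
  if (length(G1$den) != length(G2$den)) return(Inf)
  p <- c(Mod(tf_poles(G1)), Mod(tf_poles(G2)))
  p <- p[p > 0]
  if (!length(p)) return(Inf)
  s <- c(0, exp(seq(log(0.1 * min(p)), log(2 * max(p)), length.out = 30L)))
  g1 <- tf_eval(G1, s + 0i); g2 <- tf_eval(G2, s + 0i)
  max(Mod(g1 - g2) / pmax(Mod(g1), Mod(g2), 1e-300))
}

#' Transition rates and observable scaling of a scheme
#' @param scheme A [kinetic_scheme()].
#' @return Named vector: sigma_k rates (1/ms) and gamma.
#' @export
scheme_rates <- function(scheme) {
  s <- attr(scheme, "sigma")
  if (is.null(s)) {
    s <- scheme$transitions$sigma
    names(s) <- paste0("sigma", seq_along(s))
    s <- s[!duplicated(scheme$transitions$sigma)]
  }
  c(s, gamma = scheme$gamma)
}

#' Simulate the occupancy dynamics of a kinetic scheme
#'
#' Integrates the linear transition ODEs exactly on the output grid by
#' matrix-exponential stepping (the input is held constant over each sampling
#' interval, which is exact for step stimuli and the standard zero-order-hold
#' treatment of sampled inputs). The input-linked state is reconstructed from
#' mass conservation, \eqn{z_{in}(t) = u(t) - \sum_{other} z_i(t)}.
#'
#' @param scheme A [kinetic_scheme()].
#' @param input Either a list \code{list(type = "step", time, amplitude)} or a
#'   numeric vector of input samples on \code{t}.
#' @param t Output time grid, ms (uniform).
#' @param z0 Initial occupancies of the non-input states (defaults to zero:
#'   all occupancy change starts in the input-linked state).
#' @return An object of class \code{"scheme_trajectory"}: \code{t}, occupancy
#'   matrix \code{z} (one column per state), reconstructed output \code{y}
#'   (gamma times the observable occupancy) and \code{u}.
#' @export
simulate_scheme <- function(scheme, input = list(type = "step", time = 30,
                                                 amplitude = 1),
                            t = seq(0, 630, by = 0.25), z0 = NULL) {
  Ts <- diff(t)
  if (length(unique(round(Ts / Ts[1L], 9))) != 1L)
    stop("simulate_scheme requires a uniform time grid")
  Ts <- Ts[1L]
  n <- length(t)
  if (is.list(input)) {
    u <- ifelse(t >= input$time, input$amplitude %||% 1, 0)
  } else {
    u <- as.numeric(input)
    if (length(u) != n) stop("sampled input must match the time grid")
  }
  ss <- scheme_state_space(scheme)
  m <- nrow(ss$A)
  ## augmented exact discretization: expm([[A, B], [0, 0]] Ts)
  Aug <- rbind(cbind(ss$A, ss$B), 0)
  E <- mat_expm(Aug * Ts)
  Ad <- E[seq_len(m), seq_len(m), drop = FALSE]
  Bd <- E[seq_len(m), m + 1L]
  x <- matrix(0, n, m)
  x[1L, ] <- if (is.null(z0)) 0 else z0
  for (k in seq_len(n - 1L))
    x[k + 1L, ] <- Ad %*% x[k, ] + Bd * u[k]
  zin <- u - rowSums(x)
  z <- cbind(zin, x)
  colnames(z) <- c(scheme$input_state, ss$xs)
  z <- z[, scheme$states, drop = FALSE]
  if (min(z) < -1e-6 * max(1, max(abs(z))))
    stop("integration-failure: negative occupancy beyond tolerance")
  y <- scheme$gamma * z[, scheme$observable]
  structure(list(t = t, z = z, y = y, u = u, scheme = scheme),
            class = "scheme_trajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## scaled-and-squared Pade matrix exponential (small dense matrices)
mat_expm <- function(X) {
  n <- nrow(X)
  nrm <- max(rowSums(abs(X)))
  j <- max(0L, ceiling(log2(max(nrm, .Machine$double.xmin) / 5.4)))
  Xs <- X / 2^j
  ## Pade(6,6): P = sum c_k X^k, Q = sum (-1)^k c_k X^k
  c6 <- c(1, 1/2, 5/44, 1/66, 1/792, 1/15840, 1/924)
  P <- diag(n); Q <- diag(n); Xp <- diag(n)
  for (k in 1:6) {
    Xp <- Xp %*% Xs
    P <- P + c6[k + 1L] * Xp
    Q <- Q + (-1)^k * c6[k + 1L] * Xp
  }
  R <- solve(Q, P)
  for (i in seq_len(j)) R <- R %*% R
  R
}

#' @export
print.scheme_trajectory <- function(x, ...) {
  cat(sprintf("Scheme trajectory: %d samples, states: %s\n",
              length(x$t), paste(colnames(x$z), collapse = ", ")))
  cat(sprintf("  y range [%g, %g]; conservation max |sum z - u| = %.3g\n",
              min(x$y), max(x$y), max(abs(rowSums(x$z) - x$u))))
  invisible(x)
}

#' @export
plot.scheme_trajectory <- function(x, which = c("occupancy", "output"), ...) {
  which <- match.arg(which)
  if (which == "occupancy") {
    graphics::matplot(x$t, x$z, type = "l", lty = 1, xlab = "time (ms)",
                      ylab = "fractional occupancy", ...)
    graphics::legend("topright", legend = colnames(x$z), lty = 1,
                     col = seq_len(ncol(x$z)), bty = "n")
  } else {
    graphics::plot(x$t, x$y, type = "l", xlab = "time (ms)", ylab = "y", ...)
  }
  invisible(x)
}

#' Serialize a kinetic scheme to JSON
#' @param scheme A [kinetic_scheme()].
#' @return JSON string: states, transitions with rates (1/ms), observable
#'   flag, input state and gamma.
#' @export
scheme_to_json <- function(scheme) {
  jsonlite::toJSON(list(states = scheme$states,
                        transitions = scheme$transitions,
                        observable = scheme$observable,
                        input_state = scheme$input_state,
                        gamma = scheme$gamma,
                        configuration = scheme$configuration),
                   dataframe = "rows", auto_unbox = TRUE, digits = NA)
}
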