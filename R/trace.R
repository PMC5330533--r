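## Sampled stimulus-response traces and delimited-text I/O.

#' Uniformly sampled stimulus-response trace
#'
#' @param t Time grid in ms, strictly increasing with constant spacing.
#' @param u Input (stimulus) samples.
#' @param y Output (response) samples.
#' @param Ts Sampling interval, ms; inferred from \code{t} when missing.
#' @param uniform_tol Maximum tolerated relative deviation of the time grid
#'   from uniform spacing (default 0.1\%).
#' @return A data frame of class \code{"sampled_trace"} with columns
#'   \code{t}, \code{u}, \code{y} and attribute \code{Ts}.
#' @export
sampled_trace <- function(t, u, y, Ts = NULL, uniform_tol = 1e-3) {
  t <- as.numeric(t); u <- as.numeric(u); y <- as.numeric(y)
  n <- length(t)
  if (n < 10L || length(u) != n || length(y) != n)
    stop("format error: t, u, y must have equal length >= 10")
  bad <- which(!is.finite(t) | !is.finite(u) | !is.finite(y))
  if (length(bad))
    stop(sprintf("format error: non-finite value in row %d", bad[1L]))
  dt <- diff(t)
  if (any(dt <= 0))
    stop(sprintf("format error: time not strictly increasing at row %d",
                 which(dt <= 0)[1L] + 1L))
  Ts0 <- stats::median(dt)
  dev <- abs(dt - Ts0) / Ts0
  if (max(dev) > uniform_tol)
    stop(sprintf("non-uniform-sampling: max relative spacing deviation %.3g at row %d exceeds %.3g",
                 max(dev), which.max(dev) + 1L, uniform_tol))
  if (is.null(Ts)) Ts <- Ts0
  structure(data.frame(t = t, u = u, y = y),
            Ts = Ts, class = c("sampled_trace", "data.frame"))
}

#' Sampling interval of a trace
#' @param trace A [sampled_trace()].
#' @return The sampling interval Ts in ms.
#' @export
trace_Ts <- function(trace) attr(trace, "Ts")

#' @export
print.sampled_trace <- function(x, ...) {
  cat(sprintf("Sampled trace: %d samples, Ts = %g ms, duration %g ms\n",
              nrow(x), trace_Ts(x), x$t[nrow(x)] - x$t[1L]))
  cat(sprintf("  u in [%g, %g], y in [%g, %g]\n",
              min(x$u), max(x$u), min(x$y), max(x$y)))
  invisible(x)
}

#' Detect the step onset in the input channel
#'
#' Returns the index of the first sample at which the input departs from its
#' initial value by more than \code{frac} of the total input excursion, or
#' \code{NA} if the input never moves.
#'
#' @param trace A [sampled_trace()].
#' @param frac Departure threshold as a fraction of the input range.
#' @return Integer index of onset, or \code{NA_integer_}.
#' @export
step_onset <- function(trace, frac = 0.5) {
  u <- trace$u
  rng <- max(u) - min(u)
  if (rng == 0) return(NA_integer_)
  idx <- which(abs(u - u[1L]) > frac * rng)
  if (length(idx) == 0L) NA_integer_ else idx[1L]
}

#' Read a stimulus-response trace from delimited text
#'
#' Expects columns time, input (stimulus) and output (response), identified by
#' name or position. The time grid must be uniform.
#'
#' @param path File path (CSV by default).
#' @param sep Field separator.
#' @param time_col,input_col,output_col Column names or positions. Which
#'   channel is the stimulus depends on the experiment (voltage-clamp traces
#'   use voltage as input and current as output) and must be stated
#'   explicitly when the file layout differs from \code{t, u, y}.
#' @param header Whether the file has a header row.
#' @param ... Passed to [utils::read.table()].
#' @return A [sampled_trace()].
#' @export
read_trace <- function(path, sep = ",", time_col = 1L, input_col = 2L,
                       output_col = 3L, header = TRUE, ...) {
  df <- utils::read.table(path, sep = sep, header = header, ...)
  pick <- function(col, what) {
    if (is.character(col)) {
      if (!col %in% names(df))
        stop(sprintf("format error: missing %s column '%s' in %s", what, col, path))
      df[[col]]
    } else {
      if (col > ncol(df))
        stop(sprintf("format error: %s column %d not present (file has %d columns)",
                     what, col, ncol(df)))
      df[[col]]
    }
  }
  sampled_trace(pick(time_col, "time"), pick(input_col, "input"),
                pick(output_col, "output"))
}

#' Write a trace to delimited text
#'
#' @param trace A [sampled_trace()].
#' @param path Output file path.
#' @param sep Field separator.
#' @export
write_trace <- function(trace, path, sep = ",") {
  utils::write.table(as.data.frame(trace)[c("t", "u", "y")], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
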