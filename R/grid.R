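#' Uniform acquisition time grid
#'
#' A uniform time axis for dynamic perfusion curves.  The default mirrors a
#' standard bolus-tracking acquisition: 90 s scanned at 1 s temporal
#' resolution, time zero at the first retained volume.
#'
#' @param duration total scan duration in seconds.
#' @param dt sampling interval in seconds.
#' @param start time of the first sample in seconds.
#' @return A `time_grid` object with fields `start`, `dt`, `n` (number of
#'   samples) and `time` (the sample times, strictly increasing and uniform).
#' @examples
#' g <- time_grid()
#' g$n          # 90
#' range(g$time)
#' @export
time_grid <- function(duration = 90, dt = 1, start = 0) {
  stopifnot(is.numeric(duration), duration > 0, is.numeric(dt), dt > 0)
  n <- as.integer(round(duration / dt))
  if (abs(n * dt - duration) > 1e-8)
    stop("duration must be an integer multiple of dt")
  structure(
    list(start = start, dt = dt, n = n,
         time = start + (seq_len(n) - 1) * dt),
    class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> %d samples, dt = %g s, t = [%g, %g] s\n",
              x$n, x$dt, x$time[1], x$time[x$n]))
  invisible(x)
}

same_grid <- function(a, b) {
  a$n == b$n && isTRUE(all.equal(a$dt, b$dt)) && isTRUE(all.equal(a$start, b$start))
}

#' Trapezoidal area under a sampled curve
#'
#' @param y curve values on a uniform grid.
#' @param dt sampling interval in seconds.
#' @return The trapezoidal-rule integral.
#' @export
trapz_auc <- function(y, dt = 1) {
  n <- length(y)
  if (n < 2) stop("need at least 2 samples")
  (sum(y) - (y[1] + y[n]) / 2) * dt
}

#' Causal discrete convolution on a uniform grid
#'
#' Rectangle-rule causal convolution `(x * y)[n] = dt * sum_m x[m] y[n-m]`,
#' truncated to the length of `x`.  Used for the recirculation kernel and the
#' tissue residue-function convolution.
#'
#' @param x,y curves sampled on the same uniform grid.
#' @param dt sampling interval in seconds.
#' @return A vector of `length(x)` values.
#' @export
conv_causal <- function(x, y, dt = 1) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  # exact direct evaluation (no FFT roundoff): preserves causal zeros
  idx <- outer(seq_len(n), seq_len(n), function(i, j) i - j + 1)
  keep <- idx >= 1
  kmat <- matrix(0, n, n)
  kmat[keep] <- y[idx[keep]]
  as.numeric(kmat %*% x) * dt
}
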