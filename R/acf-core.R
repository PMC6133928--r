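# Shared autocorrelation machinery.
#
# Both the vector-reorientation ACF and the intermittent bond ACF reduce to
# S(lag) = sum over columns and time origins of x(t0) * x(t0 + lag), with
# every frame used as an origin. The transform route computes all lags at
# once from the zero-padded power spectrum (one inverse FFT of the summed
# spectrum, columns processed in chunks to bound memory); the direct route
# is the literal double loop and serves as the independent oracle.

# get_cols(j) must return the n_steps x k matrix of columns j; n_cols is
# the total column count.
acf_sums_fft <- function(get_cols, n_steps, n_cols, max_lag_steps, chunk = 16L) {
  L <- stats::nextn(2L * n_steps, 2L)
  pow <- numeric(L)
  j <- 1L
  while (j <= n_cols) {
    cols <- get_cols(j:min(j + chunk - 1L, n_cols))
    padded <- matrix(0, L, ncol(cols))
    padded[seq_len(n_steps), ] <- cols
    f <- stats::mvfft(padded)
    pow <- pow + rowSums(Re(f)^2 + Im(f)^2)
    j <- j + chunk
  }
  s <- Re(stats::fft(pow, inverse = TRUE)) / L
  s[seq_len(max_lag_steps + 1L)]
}

acf_sums_direct <- function(get_cols, n_steps, n_cols, max_lag_steps, chunk = 64L) {
  s <- numeric(max_lag_steps + 1L)
  j <- 1L
  while (j <= n_cols) {
    cols <- get_cols(j:min(j + chunk - 1L, n_cols))
    for (lag in 0:max_lag_steps) {
      i <- seq_len(n_steps - lag)
      s[lag + 1L] <- s[lag + 1L] +
        sum(cols[i, , drop = FALSE] * cols[lag + i, , drop = FALSE])
    }
    j <- j + chunk
  }
  s
}

#' Autocorrelation-function result
#'
#' Container for a normalized autocorrelation curve: `lags` (ps, starting
#' at 0, uniformly spaced), `values` (dimensionless, `values[1] = 1`), the
#' per-lag number of averaged origin/molecule products `n_origins`, and
#' optionally a naive per-lag `stderr` (computed as if origins were
#' independent; successive origins are correlated, so treat it as a lower
#' bound useful for relative comparisons).
#'
#' @param lags ps.
#' @param values dimensionless correlation values.
#' @param n_origins per-lag averaging counts.
#' @param stderr optional per-lag standard errors.
#' @return object of class `acf_result`.
#' @export
acf_result <- function(lags, values, n_origins, stderr = NULL) {
  if (length(lags) != length(values)) stop("lags/values length mismatch", call. = FALSE)
  if (lags[1] != 0) stop("lags must start at 0", call. = FALSE)
  if (length(lags) > 2L && any(abs(diff(diff(lags))) > 1e-9 * lags[2]))
    stop("lags must be uniformly spaced", call. = FALSE)
  structure(list(lags = lags, values = values, n_origins = n_origins,
                 stderr = stderr),
            class = "acf_result")
}

#' @export
print.acf_result <- function(x, ...) {
  cat(sprintf("acf_result: %d lags, dt = %s ps, C(max) = %.4g\n",
              length(x$lags), format(x$lags[2] %||% NA), x$values[length(x$values)]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' @export
plot.acf_result <- function(x, log = "y", ...) {
  v <- x$values
  if (grepl("y", log)) v[v <= 0] <- NA
  graphics::plot(x$lags, v, type = "l", log = log,
                 xlab = "lag (ps)", ylab = "C(t)", ...)
  invisible(x)
}
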