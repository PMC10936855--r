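# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cnap <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cnapsim_error")))
}

check_scalar_pos <- function(x, name, class = "cnapsim_parameter_error") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_cnap(sprintf("`%s` must be a single positive finite number", name), class)
  invisible(x)
}

#' @keywords internal
#' @noRd
fft_conv <- function(x, y) {
  # full linear convolution of two real vectors via zero-padded FFTs
  nx <- length(x); ny <- length(y)
  n  <- nx + ny - 1L
  nfft <- stats::nextn(n, c(2L, 3L, 5L))
  X <- stats::fft(c(x, numeric(nfft - nx)))
  Y <- stats::fft(c(y, numeric(nfft - ny)))
  out <- Re(stats::fft(X * Y, inverse = TRUE)) / nfft
  out[seq_len(n)]
}

# Normalised sinc: sin(pi x)/(pi x), sinc(0) = 1.
sinc <- function(x) {
  out <- rep(1, length(x))
  nz <- x != 0
  out[nz] <- sin(pi * x[nz]) / (pi * x[nz])
  out
}

# Band-limited (Whittaker-Shannon) evaluation of a uniformly sampled signal
# at arbitrary times: y(t) = sum_k s_k sinc((t - t_k)/T). The signal is
# treated as zero outside its samples. Uses
# sin(pi (x - k)) = (-1)^k sin(pi x) to avoid per-element trigonometry;
# chunked to bound the size of the difference matrix.
bandlimited_eval <- function(samples, period, t0, times, chunk = 2048L) {
  n <- length(samples)
  k <- seq_len(n) - 1
  x <- (times - t0) / period
  ak <- samples * rep_len(c(1, -1), n)
  sx <- sin(pi * x) / pi
  out <- numeric(length(times))
  r <- round(x)
  on_grid <- abs(x - r) < 1e-9 & r >= 0 & r <= n - 1   # x on a sample: sinc = 1
  for (start in seq(1L, length(times), by = chunk)) {
    j <- start:min(start + chunk - 1L, length(times))
    D <- outer(x[j], k, "-")
    y <- as.numeric((1 / D) %*% ak) * sx[j]
    hit <- on_grid[j]
    if (any(hit)) y[hit] <- samples[r[j][hit] + 1L]
    out[j] <- y
  }
  out
}

# Fourier resampling of a real signal to a new sampling period, preserving the
# time of the first sample. Output length covers the same duration.
resample_bandlimited <- function(x, period_in, period_out) {
  if (isTRUE(all.equal(period_in, period_out, tolerance = 1e-12))) return(x)
  n_in <- length(x)
  n_out <- max(1L, as.integer(round((n_in - 1L) * period_in / period_out)) + 1L)
  t_out <- (seq_len(n_out) - 1) * period_out
  bandlimited_eval(x, period_in, 0, t_out)
}

# Delay a sampled signal by a (possibly fractional) number of samples using an
# FFT phase ramp on a zero-padded copy; positive shift delays the signal.
fractional_delay <- function(x, shift_samples) {
  if (shift_samples == 0) return(x)
  n <- length(x)
  n2 <- stats::nextn(n + as.integer(ceiling(abs(shift_samples))) + 64L, c(2L, 3L, 5L))
  xp <- c(x, numeric(n2 - n))
  k <- 0:(n2 - 1L)
  freq <- ifelse(k <= n2 / 2, k, k - n2) / n2
  ramp <- exp(-2i * pi * freq * shift_samples)
  if (n2 %% 2L == 0L) ramp[n2 / 2 + 1L] <- Re(ramp[n2 / 2 + 1L])
  out <- Re(stats::fft(stats::fft(xp) * ramp, inverse = TRUE)) / n2
  out[seq_len(n)]
}
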