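# Single fiber action potentials. The brute-force path weights the full
# per-compartment current matrix by the recording sensitivity; the efficient
# path convolves one action potential template with a zero-inserted shift
# filter that encodes all per-compartment time shifts and weights at once.

#' Construct an SFAP/CNAP signal
#'
#' @param samples Signal samples in V.
#' @param sampling_period Sampling period in ms.
#' @param t0 Time of the first sample in ms.
#' @return An object of class `sfap_signal`.
#' @export
sfap_signal <- function(samples, sampling_period, t0 = 0) {
  check_scalar_pos(sampling_period, "sampling_period")
  if (!all(is.finite(samples)))
    stop_cnap("signal samples must be finite", "cnapsim_parameter_error")
  structure(list(samples = as.numeric(samples),
                 sampling_period = sampling_period, t0 = t0),
            class = "sfap_signal")
}

#' @export
print.sfap_signal <- function(x, ...) {
  cat(sprintf("<sfap_signal> %d samples @ %.4g ms from t = %.4g ms, pk-pk %.4g V\n",
              length(x$samples), x$sampling_period, x$t0,
              diff(range(x$samples))))
  invisible(x)
}

#' @export
plot.sfap_signal <- function(x, ...) {
  t <- x$t0 + (seq_along(x$samples) - 1L) * x$sampling_period
  graphics::plot(t, x$samples * 1e3, type = "l", xlab = "time (ms)",
                 ylab = "amplitude (mV)", ...)
  invisible(x)
}

#' Brute-force SFAP by weighted summation
#'
#' `f(n) = sum_m i(n, m) w(m)`: every compartment's transmembrane current
#' weighted by the recording sensitivity at that compartment and summed. For
#' myelinated fibers `i` is an `N x M x 11` array and `w` an `M x 11` matrix;
#' the sum additionally runs over the 11 compartment types. This is the
#' reference (oracle) implementation that the filter methods are validated
#' against.
#'
#' @param i Current matrix `N x M` (mA), or `N x M x 11` array, or the list
#'   returned by [reconstruct_current_matrix()].
#' @param w A [sensitivity_fn()] or a plain weight vector/matrix matching the
#'   compartment dimension(s) of `i`.
#' @param sampling_period,t0 Time base of `i` (taken from the reconstruction
#'   when `i` is one).
#' @return An [sfap_signal()] in V.
#' @export
sfap_brute_force <- function(i, w, sampling_period = NULL, t0 = 0) {
  if (is.list(i) && !is.null(i$values)) {
    sampling_period <- sampling_period %||% i$sampling_period
    t0 <- i$t0
    i <- i$values
  }
  wt <- if (inherits(w, "sensitivity_fn")) w$weights else as.matrix(w)
  if (length(dim(i)) == 3L) {
    if (dim(i)[2L] != nrow(wt) || dim(i)[3L] != ncol(wt))
      stop_cnap("current array and sensitivity shapes disagree",
                "cnapsim_contract_error")
    f <- numeric(dim(i)[1L])
    for (p in seq_len(dim(i)[3L])) f <- f + i[, , p] %*% wt[, p]
  } else {
    i <- as.matrix(i)
    if (ncol(i) != nrow(wt) || ncol(wt) != 1L)
      stop_cnap("current matrix and sensitivity shapes disagree",
                "cnapsim_contract_error")
    f <- i %*% wt
  }
  sfap_signal(as.numeric(f), sampling_period, t0)
}

# Integer shift count L/(T V): L in um, T in ms, V in m/s.
# L/V in ms is L * 1e-3 / V (mm divided by m/s gives ms).
shift_count <- function(L, T, V) L * 1e-3 / (T * V)

check_integer_shift <- function(L, T, V) {
  s <- shift_count(L, T, V)
  if (abs(s - round(s)) > 1e-9 * max(1, abs(s)))
    stop_cnap(sprintf("L/(T*V) = %.12g is not an integer; choose T with choose_sampling_period()", s),
              "cnapsim_contract_error")
  as.integer(round(s))
}

#' Choose a sampling period with an integer compartment shift
#'
#' The filter construction requires the per-compartment time shift
#' `L/(T*V)` to be an integer number of samples. The smallest admissible
#' shift count is used subject to `T <= T_max` and to the sampling rate
#' `1/T` being at least twice the template bandwidth (to avoid aliasing):
#' `n_shift = ceil((L/V)/T_max)`, increased until the rate condition holds,
#' and `T = (L/V)/n_shift`.
#'
#' @param L Compartment spacing in micrometers.
#' @param V Conduction velocity in m/s.
#' @param T_max Largest acceptable sampling period in ms.
#' @param template_bandwidth_khz Template bandwidth in kHz (see
#'   [estimate_template_bandwidth()]); 0 disables the rate condition.
#' @return List with `T_ms` (the chosen period) and `n_shift` (the exact
#'   integer `L/(T*V)`).
#' @export
choose_sampling_period <- function(L, V, T_max = 0.05,
                                   template_bandwidth_khz = 0) {
  check_scalar_pos(L, "L"); check_scalar_pos(V, "V")
  check_scalar_pos(T_max, "T_max")
  t_span <- L * 1e-3 / V                       # travel time per compartment, ms
  n <- max(1L, as.integer(ceiling(t_span / T_max - 1e-12)))
  if (template_bandwidth_khz > 0)
    n <- max(n, as.integer(ceiling(2 * template_bandwidth_khz * t_span - 1e-12)))
  list(T_ms = t_span / n, n_shift = n)
}

#' Estimate the bandwidth of a template
#'
#' Frequency (kHz) below which a given fraction of the template's spectral
#' energy lies, computed from the FFT of the nodal column. Used as the
#' "template bandwidth" in [choose_sampling_period()]; the 99.99 % energy
#' criterion is a robust stand-in for the highest frequency present in a
#' smooth, settled waveform.
#'
#' @param template An [ap_template()].
#' @param energy_fraction Fraction of total spectral energy (default 0.9999).
#' @return Bandwidth in kHz.
#' @export
estimate_template_bandwidth <- function(template, energy_fraction = 0.9999) {
  x <- template$currents[, 1L]
  n <- length(x)
  spec <- Mod(stats::fft(x))[seq_len(floor(n / 2) + 1L)]^2
  cum <- cumsum(spec) / sum(spec)
  k <- which(cum >= energy_fraction)[1L]
  (k - 1L) / (n * template$sampling_period)   # cycles per ms = kHz
}

#' Build a zero-inserted shift filter
#'
#' The filter has the same non-zero values as the sensitivity function `w`
#' but with `L/(T*V)` zeros inserted between them, so that convolving the
#' action potential template with the filter performs all the per-compartment
#' time shifts and weightings in one operation. Coefficient slot
#' `(m-1)*n_shift + 1` carries `w(m)`; total length `(M-1)*n_shift + 1`.
#'
#' @param w A [sensitivity_fn()] with one weight column, or a numeric vector.
#' @param L Compartment spacing in micrometers.
#' @param T Sampling period in ms; `L/(T*V)` must be an integer.
#' @param V Conduction velocity in m/s.
#' @param K Index of the reference compartment (1..M); recorded so output
#'   timing is referenced to compartment `K`.
#' @return An object of class `shift_filter`.
#' @export
build_shift_filter <- function(w, L, T, V, K = 1L) {
  wt <- if (inherits(w, "sensitivity_fn")) w$weights[, 1L] else as.numeric(w)
  M <- length(wt)
  if (K < 1L || K > M)
    stop_cnap("K must index a compartment", "cnapsim_contract_error")
  n_shift <- check_integer_shift(L, T, V)
  coef <- numeric((M - 1L) * n_shift + 1L)
  coef[(seq_len(M) - 1L) * n_shift + 1L] <- wt
  if (n_shift == 0L) coef <- sum(wt)   # simultaneous arrival: weights collapse
  structure(list(coefficients = coef, sampling_period = T,
                 n_shift = n_shift, K = as.integer(K), M = M),
            class = "shift_filter")
}

#' @export
print.shift_filter <- function(x, ...) {
  cat(sprintf("<shift_filter> M = %d, n_shift = %d, K = %d, T = %.4g ms, length %d\n",
              x$M, x$n_shift, x$K, x$sampling_period, length(x$coefficients)))
  invisible(x)
}

# Time of the first output sample of a filtered SFAP referenced to the
# template clock: compartment 1 leads compartment K by n_shift*(K-1) samples.
filter_t0 <- function(template_t0, filt) {
  template_t0 - filt$n_shift * (filt$K - 1L) * filt$sampling_period
}

#' Reconstruct the full current matrix from a template
#'
#' Builds the `N_out x M` matrix whose column `m` is the template delayed by
#' `n_shift * (m - K)` samples (zero padded), i.e. the time-shifted-template
#' model of the traveling action potential. Column `K` equals the template.
#' Used by the brute-force oracle to validate the filter methods.
#'
#' @param template An [ap_template()]; must already be sampled at period `T`.
#' @param L Compartment spacing in micrometers.
#' @param M Number of compartments.
#' @param K Reference compartment index.
#' @param T Sampling period in ms; `L/(T*V)` must be an integer.
#' @param type Template column to reconstruct (default 1, the node).
#' @return List with `values` (`N_out x M`), `sampling_period`, `t0`
#'   (time of the first row on the template clock) and `positions` (not set
#'   here; compartment geometry lives with the caller).
#' @export
reconstruct_current_matrix <- function(template, L, M, K = 1L, T = NULL,
                                       type = 1L) {
  stopifnot(inherits(template, "ap_template"))
  T <- T %||% template$sampling_period
  if (!isTRUE(all.equal(T, template$sampling_period, tolerance = 1e-9)))
    stop_cnap("template must be resampled to period T first",
              "cnapsim_contract_error")
  if (K < 1L || K > M)
    stop_cnap("K must index a compartment", "cnapsim_contract_error")
  n_shift <- check_integer_shift(L, T, template$cv)
  g <- template$currents[, type]
  N <- length(g)
  n_out <- N + n_shift * (M - 1L)
  values <- matrix(0, n_out, M)
  for (m in seq_len(M))
    values[(m - 1L) * n_shift + seq_len(N), m] <- g
  list(values = values, sampling_period = T,
       t0 = template$t0 - n_shift * (K - 1L) * T)
}

#' SFAP by time-domain convolution with the shift filter
#'
#' Full (non-truncated) linear convolution of the template's nodal column
#' with the zero-inserted filter coefficients; equivalent to the brute-force
#' weighted sum over the reconstructed current matrix.
#'
#' @param template An [ap_template()] sampled at the filter's period.
#' @param filt A [shift_filter()].
#' @param type Template column to use (default 1).
#' @return An [sfap_signal()] in V.
#' @export
sfap_time_domain <- function(template, filt, type = 1L) {
  stopifnot(inherits(template, "ap_template"), inherits(filt, "shift_filter"))
  if (!isTRUE(all.equal(template$sampling_period, filt$sampling_period,
                        tolerance = 1e-9)))
    stop_cnap("template and filter sampling periods differ; use sfap_freq_domain()",
              "cnapsim_contract_error")
  g <- template$currents[, type]
  f <- stats::convolve(g, rev(filt$coefficients), type = "open")
  sfap_signal(f, filt$sampling_period, filter_t0(template$t0, filt))
}

#' SFAP by frequency-domain multiplication with the shift filter
#'
#' Both signals are zero padded (in their own sampling rates) to a common
#' duration at least the sum of their durations, so the product of their
#' discrete Fourier transforms - taken at matched frequency resolution -
#' implements linear, not circular, convolution. When the sampling periods
#' differ, the product is formed over the band up to the lower of the two
#' Nyquist limits and zero elsewhere, and the result is returned at the finer
#' of the two rates; the filter period must then be an integer multiple of
#' the template period.
#'
#' @param template An [ap_template()].
#' @param filt A [shift_filter()].
#' @param type Template column to use (default 1).
#' @return An [sfap_signal()] in V at the finer sampling period.
#' @export
sfap_freq_domain <- function(template, filt, type = 1L) {
  stopifnot(inherits(template, "ap_template"), inherits(filt, "shift_filter"))
  g <- template$currents[, type]
  s <- filt$coefficients
  Tt <- template$sampling_period
  Tf <- filt$sampling_period
  if (isTRUE(all.equal(Tt, Tf, tolerance = 1e-9))) {
    f <- fft_conv(g, s)
    return(sfap_signal(f, Tf, filter_t0(template$t0, filt)))
  }
  r <- Tf / Tt
  if (abs(r - round(r)) > 1e-9 || r < 1)
    stop_cnap("filter period must be an integer multiple of the template period",
              "cnapsim_contract_error")
  r <- as.integer(round(r))
  n_lin <- length(g) + (length(s) - 1L) * r          # linear-convolution span
  nc <- as.integer(ceiling((n_lin + 8L) / r))        # coarse padded length
  n_out <- nc * r                                    # fine padded length
  Ft <- stats::fft(c(g, numeric(n_out - length(g))))
  Ff <- stats::fft(c(s, numeric(nc - length(s))))
  # shared frequency resolution 1/(n_out*Tt); keep the band up to the coarse
  # Nyquist, zero above it (band-limited product)
  G <- complex(n_out)
  half <- floor(nc / 2)
  jj <- 0:half
  G[jj + 1L] <- Ft[jj + 1L] * Ff[jj + 1L]
  mirror <- jj[jj > 0 & jj < nc / 2 + 1e-9]
  G[n_out - mirror + 1L] <- Conj(G[mirror + 1L])
  f <- Re(stats::fft(G, inverse = TRUE)) / n_out
  sfap_signal(f[seq_len(n_lin)], Tt, filter_t0(template$t0, filt))
}

#' SFAP of a myelinated fiber with 11 compartment types
#'
#' Sums per-type filtered reconstructions: for each compartment type `p` the
#' template column `p` is convolved with a zero-inserted filter built from
#' sensitivity column `p`, and the 11 partial SFAPs are added. Compartment
#' types sit at different positions within an internode; the zero-inserted
#' filter only encodes the internode-to-internode shift, so each type's
#' sub-internode propagation delay (`offset / V`) is applied to its template
#' as a fractional-sample delay before filtering.
#'
#' @param template An 11-column [ap_template()] sampled at period `T`.
#' @param w A [sensitivity_fn()] with 11 columns (`M x 11`).
#' @param L Internodal length in micrometers.
#' @param T Sampling period in ms; `L/(T*V)` must be an integer.
#' @param V Conduction velocity in m/s.
#' @param K Reference node index.
#' @param type_offsets_mm Length-11 longitudinal offsets of the compartment
#'   type centers within an internode, mm (see the ultrastructure geometry);
#'   `NULL` treats all types as co-located with their node.
#' @return An [sfap_signal()] in V.
#' @export
sfap_multitype <- function(template, w, L, T, V, K = 1L,
                           type_offsets_mm = NULL) {
  stopifnot(inherits(template, "ap_template"), inherits(w, "sensitivity_fn"))
  if (ncol(template$currents) != 11L || ncol(w$weights) != 11L)
    stop_cnap("multitype path needs 11 template and sensitivity columns",
              "cnapsim_contract_error")
  if (!is.null(type_offsets_mm) && length(type_offsets_mm) != 11L)
    stop_cnap("type_offsets_mm must have length 11", "cnapsim_contract_error")
  out <- NULL
  for (p in 1:11) {
    if (all(w$weights[, p] == 0)) next
    tpl_p <- template
    if (!is.null(type_offsets_mm) && type_offsets_mm[p] != 0) {
      delay_samples <- (type_offsets_mm[p] / V) / T
      tpl_p$currents[, p] <- fractional_delay(template$currents[, p],
                                              delay_samples)
    }
    filt_p <- build_shift_filter(w$weights[, p], L, T, V, K)
    f_p <- sfap_freq_domain(tpl_p, filt_p, type = p)
    out <- if (is.null(out)) f_p else add_signals(out, f_p)
  }
  out %||% sfap_signal(numeric(2L), T, filter_t0(template$t0,
    build_shift_filter(w$weights[, 1L], L, T, V, K)))
}

# Sum two signals sharing a sampling period; the result covers the union of
# their supports.
add_signals <- function(a, b) {
  stopifnot(isTRUE(all.equal(a$sampling_period, b$sampling_period,
                             tolerance = 1e-9)))
  T <- a$sampling_period
  t0 <- min(a$t0, b$t0)
  oa <- as.integer(round((a$t0 - t0) / T))
  ob <- as.integer(round((b$t0 - t0) / T))
  n <- max(oa + length(a$samples), ob + length(b$samples))
  out <- numeric(n)
  out[oa + seq_along(a$samples)] <- out[oa + seq_along(a$samples)] + a$samples
  out[ob + seq_along(b$samples)] <- out[ob + seq_along(b$samples)] + b$samples
  sfap_signal(out, T, t0)
}
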