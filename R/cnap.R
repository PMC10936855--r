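# Compound nerve action potentials: superposition of per-group SFAPs on a
# common output time base, plus the summary metrics used to characterise
# them.

#' Simulation settings for [simulate_cnap()]
#'
#' @param conduction_distance_mm Distance (mm) from the stimulation site to
#'   the center of the recording contact; the stimulation site is z = 0.
#' @param fiber_length_mm Length of every fiber (mm); fibers run along z and
#'   are centered longitudinally on the recording contact.
#' @param representation `"monopolar"` (default) or `"dipolar"`. The
#'   monopolar path is exact for the shifted-template current model; the
#'   dipolar path represents each compartment as a current dipole weighted by
#'   the spatial difference of the sensitivity, which is the more robust
#'   choice when templates carry residual charge imbalance (e.g. imported
#'   simulation outputs with imprecise conduction velocities) but treats the
#'   wave as fully developed, so it does not represent the initiation
#'   transient at the fiber end.
#' @param out_period_ms Output grid period in ms (default 0.01 ms, i.e. a
#'   100 kHz digitization rate).
#' @param duration_ms Output duration in ms; `NULL` chooses the smallest
#'   window containing every fiber's SFAP.
#' @param T_max_ms Largest per-fiber sampling period for the shift filters.
#' @param merge_tolerance_um Diameter tolerance for grouping fibers that
#'   share a template (default 0.001 um).
#' @param interpolation Template lookup: `"linear"` or `"nearest"`.
#' @param ref_fraction Position of the reference compartment along the fiber
#'   (default 0.75: templates are referenced 75 % along the fiber length).
#' @param use_type_offsets Apply sub-internode compartment-type delays for
#'   myelinated fibers (default `TRUE`).
#' @return A list of class `cnap_settings`.
#' @export
cnap_settings <- function(conduction_distance_mm = 21,
                          fiber_length_mm = 30,
                          representation = c("monopolar", "dipolar"),
                          out_period_ms = 0.01,
                          duration_ms = NULL,
                          T_max_ms = 0.05,
                          merge_tolerance_um = 0.001,
                          interpolation = c("linear", "nearest"),
                          ref_fraction = 0.75,
                          use_type_offsets = TRUE) {
  structure(list(conduction_distance_mm = conduction_distance_mm,
                 fiber_length_mm = fiber_length_mm,
                 representation = match.arg(representation),
                 out_period_ms = out_period_ms, duration_ms = duration_ms,
                 T_max_ms = T_max_ms,
                 merge_tolerance_um = merge_tolerance_um,
                 interpolation = match.arg(interpolation),
                 ref_fraction = ref_fraction,
                 use_type_offsets = use_type_offsets),
            class = "cnap_settings")
}

# Per-group SFAP on its own time base, with the absolute arrival time of the
# reference compartment folded into t0.
group_sfap <- function(group, fibers, bank, profile, settings) {
  tpl <- interpolate_template(bank, group$diameter,
                              method = settings$interpolation)
  rows <- fibers[group$indices, , drop = FALSE]
  V <- rows$cv_m_per_s[1L]
  L <- rows$spacing_um[1L]
  bw <- estimate_template_bandwidth(tpl)
  ts <- choose_sampling_period(L, V, T_max = settings$T_max_ms,
                               template_bandwidth_khz = bw)
  if (!isTRUE(all.equal(ts$T_ms, tpl$sampling_period, tolerance = 1e-9))) {
    tpl$currents <- apply(tpl$currents, 2L, resample_bandlimited,
                          period_in = tpl$sampling_period,
                          period_out = ts$T_ms)
    tpl$currents <- matrix(tpl$currents, ncol = ncol(bank$templates[[1L]]$currents))
    tpl$sampling_period <- ts$T_ms
  }
  M <- max(2L, as.integer(floor(settings$fiber_length_mm / (L * 1e-3))) + 1L)
  K <- max(1L, min(M, as.integer(round(settings$ref_fraction * M))))
  # compartment anchors, centered on the recording contact, per group member
  rel_z <- (seq_len(M) - (M + 1) / 2) * L * 1e-3
  myel <- tpl$kind == "myelinated"
  offsets <- NULL
  if (myel && settings$use_type_offsets) {
    geom <- ultrastructure_geometry(group$diameter,
                                    attr(fibers, "ultra") %||% ultrastructure_model())
    offsets <- compartment_type_offsets(geom)
  }
  ws <- lapply(seq_len(nrow(rows)), function(j) {
    z <- settings$conduction_distance_mm + rel_z + rows$z_offset_mm[j]
    if (inherits(profile, "sensitivity_fn")) {
      if (myel) {
        cols <- vapply(1:11, function(p)
          sample_along_trajectory(profile, z + (offsets[p] %||% 0))$weights[, 1L],
          numeric(M))
        sensitivity_fn(cols, z, representation = "monopolar",
                       source = profile$source)
      } else sample_along_trajectory(profile, z)
    } else {
      # profile is a function(trajectory) -> sensitivity_fn (analytic media)
      traj <- straight_trajectory(z, x = rows$x_mm[j], y = rows$y_mm[j])
      w1 <- profile(traj)
      if (myel) {
        cols <- vapply(1:11, function(p)
          profile(straight_trajectory(z + (offsets[p] %||% 0),
                                      x = rows$x_mm[j],
                                      y = rows$y_mm[j]))$weights[, 1L],
          numeric(M))
        sensitivity_fn(cols, z, representation = "monopolar",
                       source = "analytic")
      } else w1
    }
  })
  w <- merge_sensitivities(ws)
  if (settings$representation == "dipolar") {
    w <- differentiate_for_dipole(w)
    tpl <- dipolar_template_from_monopolar(tpl, ts$n_shift)
  }
  sf <- if (myel)
    sfap_multitype(tpl, w, L, ts$T_ms, V, K, type_offsets_mm = offsets)
  else
    sfap_freq_domain(tpl, build_shift_filter(w, L, ts$T_ms, V, K))
  # arrival of the reference feature at compartment K: propagation from the
  # stimulation site at z = 0, plus the template's own reference time
  z_K <- settings$conduction_distance_mm + rel_z[K]
  sf$t0 <- sf$t0 + tpl$ref_time + z_K / V
  sf
}

#' Simulate a compound nerve action potential
#'
#' Runs the full filtered-interpolation pipeline: fibers are grouped by
#' nearly identical diameter, one template is interpolated per group, the
#' group members' recording sensitivities are summed, a zero-inserted shift
#' filter computes the group SFAP, and all group SFAPs are superposed on a
#' common output grid by band-limited placement with each fiber's absolute
#' timing (conduction delay from the stimulation site at z = 0, plus
#' longitudinal jitter).
#'
#' @param fibers A [fiber_population()] (possibly empty).
#' @param bank A [template_bank()] covering the population's diameters.
#' @param sensitivity Either a tabulated [sensitivity_fn()] profile (weights
#'   versus absolute z in mm) or a function mapping a
#'   [straight_trajectory()] to a [sensitivity_fn()] (e.g. a closure over
#'   [analytic_point_source_sensitivity()]).
#' @param settings A [cnap_settings()] object.
#' @return An object of class `cnap_result` with the uniform time grid
#'   (`time_ms`, t = 0 at stimulus onset), the summed signal in mV
#'   (`signal_mV`), the contributing fiber count and the settings used.
#' @export
simulate_cnap <- function(fibers, bank, sensitivity,
                          settings = cnap_settings()) {
  stopifnot(inherits(fibers, "fiber_population"),
            inherits(settings, "cnap_settings"))
  if (!inherits(bank, "template_bank"))
    stop_cnap("bank must be a template_bank", "cnapsim_contract_error")
  groups <- merge_by_diameter(fibers, settings$merge_tolerance_um)
  sfaps <- lapply(groups, group_sfap, fibers = fibers, bank = bank,
                  profile = sensitivity, settings = settings)
  Tg <- settings$out_period_ms
  dur <- settings$duration_ms
  if (is.null(dur)) {
    dur <- if (length(sfaps))
      max(vapply(sfaps, function(s)
        s$t0 + (length(s$samples) - 1L) * s$sampling_period, numeric(1))) + 1
    else 10
  }
  time_ms <- seq(0, dur, by = Tg)
  signal_V <- numeric(length(time_ms))
  for (s in sfaps)
    signal_V <- signal_V + bandlimited_eval(s$samples, s$sampling_period,
                                            s$t0, time_ms)
  structure(list(time_ms = time_ms, signal_mV = signal_V * 1e3,
                 n_fibers = nrow(fibers), n_groups = length(groups),
                 conduction_distance_mm = settings$conduction_distance_mm,
                 settings = settings),
            class = "cnap_result")
}

#' @export
print.cnap_result <- function(x, ...) {
  cat(sprintf("<cnap_result> %d fibers in %d group(s), distance %.4g mm\n",
              x$n_fibers, x$n_groups, x$conduction_distance_mm))
  cat(sprintf("  %d samples @ %.4g ms, V_pk-pk = %.4g mV\n",
              length(x$time_ms), x$settings$out_period_ms, peak_to_peak(x)))
  invisible(x)
}

#' @export
summary.cnap_result <- function(object, ...) {
  res <- list(n_fibers = object$n_fibers, n_groups = object$n_groups,
              conduction_distance_mm = object$conduction_distance_mm,
              v_pk_pk_mV = peak_to_peak(object),
              negative_peak_latency_ms = tryCatch(
                negative_peak_latency(object), error = function(e) NA_real_))
  class(res) <- "summary.cnap_result"
  res
}

#' @export
print.summary.cnap_result <- function(x, ...) {
  cat(sprintf("CNAP: %d fibers (%d groups) at %.4g mm\n", x$n_fibers,
              x$n_groups, x$conduction_distance_mm))
  cat(sprintf("  peak-to-peak amplitude: %.6g mV\n", x$v_pk_pk_mV))
  cat(sprintf("  negative-peak latency:  %.6g ms\n",
              x$negative_peak_latency_ms))
  invisible(x)
}

#' @export
plot.cnap_result <- function(x, ...) {
  graphics::plot(x$time_ms, x$signal_mV, type = "l", xlab = "time (ms)",
                 ylab = "amplitude (mV)", ...)
  invisible(x)
}

signal_and_time <- function(x) {
  if (inherits(x, "cnap_result")) list(t = x$time_ms, y = x$signal_mV)
  else if (inherits(x, "sfap_signal"))
    list(t = x$t0 + (seq_along(x$samples) - 1L) * x$sampling_period,
         y = x$samples)
  else list(t = seq_along(x), y = as.numeric(x))
}

apply_window <- function(st, window) {
  if (is.null(window)) return(st)
  keep <- st$t >= window[1L] & st$t <= window[2L]
  if (!any(keep))
    stop_cnap("analysis window contains no samples", "cnapsim_contract_error")
  list(t = st$t[keep], y = st$y[keep])
}

#' Peak-to-peak amplitude
#'
#' Maximum minus minimum of the signal, optionally restricted to an analysis
#' window (e.g. excluding the stimulus artifact region).
#'
#' @param x A [cnap_result] (mV), [sfap_signal()] (V) or numeric vector.
#' @param window Optional `c(t_min, t_max)` in ms.
#' @return Peak-to-peak amplitude in the signal's units.
#' @export
peak_to_peak <- function(x, window = NULL) {
  st <- apply_window(signal_and_time(x), window)
  max(st$y) - min(st$y)
}

#' Latency of the negative peak
#'
#' Time of the global minimum of the signal within the window; ties resolve
#' to the earliest sample. A signal with no negative excursion has no defined
#' negative-peak latency and raises an error.
#'
#' @param x A [cnap_result], [sfap_signal()] or numeric vector.
#' @param window Optional `c(t_min, t_max)` in ms.
#' @return Latency in ms (sample index for bare vectors).
#' @export
negative_peak_latency <- function(x, window = NULL) {
  st <- apply_window(signal_and_time(x), window)
  if (min(st$y) >= 0)
    stop_cnap("signal has no negative excursion: latency undefined",
              "cnapsim_metric_error")
  st$t[which.min(st$y)]          # which.min: earliest of tied minima
}

#' Maximum percent discrepancy between two CNAPs
#'
#' `100 * max(abs(x - reference)) / peak_to_peak(reference)`: the largest
#' pointwise difference, as a percentage of the reference peak-to-peak
#' amplitude. Signals must share a time grid.
#'
#' @param x,reference [cnap_result] objects or numeric vectors on a common
#'   grid.
#' @return Discrepancy in percent.
#' @export
max_percent_discrepancy <- function(x, reference) {
  sx <- signal_and_time(x); sr <- signal_and_time(reference)
  if (length(sx$y) != length(sr$y) ||
      !isTRUE(all.equal(sx$t, sr$t, tolerance = 1e-9)))
    stop_cnap("signals must share a common time grid", "cnapsim_contract_error")
  p <- max(sr$y) - min(sr$y)
  if (p == 0)
    stop_cnap("reference has zero peak-to-peak amplitude",
              "cnapsim_contract_error")
  100 * max(abs(sx$y - sr$y)) / p
}

#' Fit a power law relating CNAP amplitude to conduction distance
#'
#' Least-squares fit of `log(amplitude)` against `log(distance)`, i.e.
#' `amplitude = a * distance^b`. Temporal dispersion makes CNAP amplitude
#' fall approximately as a power of the conduction distance.
#'
#' @param distances Conduction distances in mm (positive, at least two
#'   distinct values).
#' @param amplitudes Peak-to-peak amplitudes in mV (positive).
#' @return An object of class `power_fit` with coefficients `a` (mV) and `b`
#'   (dimensionless), supporting `coef`, `predict` and `print`.
#' @export
fit_amplitude_distance_power <- function(distances, amplitudes) {
  if (length(distances) != length(amplitudes) || length(distances) < 2L)
    stop_cnap("need matching distance/amplitude vectors of length >= 2",
              "cnapsim_domain_error")
  if (any(distances <= 0) || any(amplitudes <= 0))
    stop_cnap("distances and amplitudes must be positive",
              "cnapsim_domain_error")
  if (length(unique(distances)) < 2L)
    stop_cnap("need at least two distinct distances", "cnapsim_domain_error")
  fit <- stats::lm(log(amplitudes) ~ log(distances))
  structure(list(a = exp(unname(stats::coef(fit)[1L])),
                 b = unname(stats::coef(fit)[2L]),
                 domain_mm = range(distances), lm = fit),
            class = "power_fit")
}

#' @export
coef.power_fit <- function(object, ...) c(a = object$a, b = object$b)

#' @export
predict.power_fit <- function(object, newdata, ...) {
  d <- if (is.list(newdata)) newdata$distances else newdata
  object$a * d^object$b
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf("amplitude = %.4g * distance^%.4g (fit over %.4g-%.4g mm)\n",
              x$a, x$b, x$domain_mm[1L], x$domain_mm[2L]))
  invisible(x)
}
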