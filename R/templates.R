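# Action potential templates: per-compartment-type transmembrane current time
# series for one fiber diameter, reused with time shifts for every compartment
# of that type along the fiber.

#' Compartment types of the myelinated fiber model, in longitudinal order
#'
#' The eleven compartment types of one spatial period (internode) of a
#' myelinated fiber: the active node of Ranvier, myelin attachment segments
#' (MYSA), paranode main segments (FLUT) and six internode segments (STIN).
#'
#' @format Character vector of length 11.
#' @export
COMPARTMENT_TYPES <- c("NODE", "MYSA1", "FLUT1",
                       paste0("STIN", 1:6),
                       "FLUT2", "MYSA2")

# Fixed per-type attenuation applied to the nodal waveform when building
# synthetic myelinated templates. A testing fixture, not a biophysical claim:
# internodal compartments carry weaker membrane currents than the node.
MYELINATED_TYPE_ATTENUATION <- c(1.00, 0.45, 0.30,
                                 0.18, 0.15, 0.13, 0.13, 0.15, 0.18,
                                 0.30, 0.45)

#' Construct an action potential template
#'
#' An `ap_template` holds the transmembrane current time series (mA) of one
#' reference compartment per compartment type, for a single fiber diameter,
#' together with its sampling period, conduction velocity and alignment
#' metadata. Column 1 is always the node of Ranvier (or the sole compartment
#' type of an unmyelinated fiber).
#'
#' @param currents Numeric matrix, `n_time x n_types` (1 column unmyelinated,
#'   11 myelinated), transmembrane currents in mA.
#' @param sampling_period Sampling period in ms.
#' @param cv Conduction velocity in m/s.
#' @param diameter Fiber diameter in micrometers.
#' @param kind `"myelinated"` or `"unmyelinated"`.
#' @param representation `"monopolar"` (point current sources) or `"dipolar"`
#'   (point current dipoles).
#' @param t0 Time of the first sample in ms, relative to the aligned zero
#'   (the nodal current maximum after [align_template()]).
#' @param ref_time Time (ms) at which the nodal maximum occurred on the
#'   original simulation clock; recorded by [align_template()].
#' @param ref_position Longitudinal position (mm) of the reference compartment
#'   along the fiber.
#' @return An object of class `ap_template`.
#' @export
ap_template <- function(currents, sampling_period, cv, diameter,
                        kind = c("unmyelinated", "myelinated"),
                        representation = c("monopolar", "dipolar"),
                        t0 = 0, ref_time = 0, ref_position = 0) {
  kind <- match.arg(kind)
  representation <- match.arg(representation)
  currents <- as.matrix(currents)
  if (nrow(currents) < 2L)
    stop_cnap("template needs at least 2 time points", "cnapsim_parameter_error")
  if (!all(is.finite(currents)))
    stop_cnap("template currents must be finite", "cnapsim_parameter_error")
  check_scalar_pos(sampling_period, "sampling_period")
  check_scalar_pos(cv, "cv")
  check_scalar_pos(diameter, "diameter")
  expected_cols <- if (kind == "myelinated") 11L else 1L
  if (ncol(currents) != expected_cols)
    stop_cnap(sprintf("%s template must have %d column(s), got %d",
                      kind, expected_cols, ncol(currents)),
              "cnapsim_parameter_error")
  structure(list(currents = currents,
                 sampling_period = sampling_period,
                 cv = cv, diameter = diameter, kind = kind,
                 representation = representation,
                 t0 = t0, ref_time = ref_time, ref_position = ref_position),
            class = "ap_template")
}

#' @export
print.ap_template <- function(x, ...) {
  cat(sprintf("<ap_template> %s, %s, D = %.4g um\n", x$kind, x$representation,
              x$diameter))
  cat(sprintf("  %d samples x %d type(s) @ %.4g ms, CV = %.4g m/s\n",
              nrow(x$currents), ncol(x$currents), x$sampling_period, x$cv))
  cat(sprintf("  window [%.4g, %.4g] ms, ref_time %.4g ms, ref_position %.4g mm\n",
              x$t0, x$t0 + (nrow(x$currents) - 1L) * x$sampling_period,
              x$ref_time, x$ref_position))
  invisible(x)
}

template_times <- function(template) {
  template$t0 + (seq_len(nrow(template$currents)) - 1L) * template$sampling_period
}

#' Parameters of the synthetic action potential template generator
#'
#' The generator derives a transmembrane current waveform analytically from an
#' intracellular action potential time course
#' `Vm(t) = vm_amplitude * t^3 * exp(-vm_rate * t) + vm_rest` (mV, t in ms):
#' the current of the reference compartment is the second temporal derivative
#' of `Vm`, scaled by a diameter rule. A traveling-wave cable surrogate: the
#' second time derivative guarantees a triphasic shape and a zero temporal
#' integral (charge balance of a complete propagating action potential).
#'
#' @param vm_amplitude Amplitude coefficient of the `Vm` waveform in mV.
#' @param vm_rate Decay rate of the waveform in 1/ms.
#' @param vm_rest Resting potential in mV.
#' @param scale_coeff Current scale in mA*ms^2/mV per um^2 of the diameter
#'   rule (the nodal current is `scale_coeff * diameter^2 * d2Vm/dt2` by
#'   default).
#' @param scale_exponent Exponent of the diameter rule; the default 2 makes
#'   template amplitude grow quadratically with fiber diameter.
#' @param duration Template duration in ms; must be long enough for `Vm` to
#'   settle back to rest (within 0.1 % of its excursion).
#' @return A list of class `synthetic_template_params`.
#' @export
synthetic_template_params <- function(vm_amplitude = 36864, vm_rate = 8,
                                      vm_rest = -70, scale_coeff = 1e-9,
                                      scale_exponent = 2, duration = 4) {
  check_scalar_pos(vm_rate, "vm_rate")
  check_scalar_pos(duration, "duration")
  structure(list(vm_amplitude = vm_amplitude, vm_rate = vm_rate,
                 vm_rest = vm_rest, scale_coeff = scale_coeff,
                 scale_exponent = scale_exponent, duration = duration),
            class = "synthetic_template_params")
}

# Vm(t) and its second temporal derivative, evaluated analytically.
# f(t) = t^3 exp(-r t):  f'' = (6 t - 6 r t^2 + r^2 t^3) exp(-r t)
synthetic_vm <- function(t, params) {
  params$vm_amplitude * t^3 * exp(-params$vm_rate * t) + params$vm_rest
}

synthetic_d2vm <- function(t, params) {
  r <- params$vm_rate
  params$vm_amplitude * (6 * t - 6 * r * t^2 + r^2 * t^3) * exp(-r * t)
}

#' Generate a synthetic action potential template
#'
#' Builds a monopolar, aligned template from the analytic waveform described
#' in [synthetic_template_params()]. Myelinated templates carry 11 compartment
#'-type columns: the nodal waveform scaled by a fixed per-type attenuation
#' vector (a documented testing constant).
#'
#' @param diameter Fiber diameter in micrometers.
#' @param kind Fiber kind.
#' @param cv Conduction velocity in m/s.
#' @param params A [synthetic_template_params()] object.
#' @param sampling_period Template sampling period in ms.
#' @return An aligned monopolar [ap_template()].
#' @export
generate_synthetic_template <- function(diameter,
                                        kind = c("unmyelinated", "myelinated"),
                                        cv,
                                        params = synthetic_template_params(),
                                        sampling_period = 0.0025) {
  kind <- match.arg(kind)
  check_scalar_pos(diameter, "diameter")
  check_scalar_pos(cv, "cv")
  check_scalar_pos(sampling_period, "sampling_period")
  r <- params$vm_rate
  # settle check: waveform excursion at `duration` relative to its peak
  peak_excursion <- abs(params$vm_amplitude) * (3 / r)^3 * exp(-3)
  tail_excursion <- abs(params$vm_amplitude) * params$duration^3 *
    exp(-r * params$duration)
  if (params$vm_amplitude != 0 && tail_excursion > 1e-3 * peak_excursion)
    stop_cnap("duration too short: Vm does not settle to within 0.1% of rest",
              "cnapsim_validity_error")
  t <- seq(0, params$duration, by = sampling_period)
  node <- params$scale_coeff * diameter^params$scale_exponent *
    synthetic_d2vm(t, params)
  # the analytic second derivative integrates to zero exactly; remove the
  # tiny residual DC component of its Riemann sum so the sampled template is
  # charge balanced to machine precision as well
  node <- node - mean(node)
  currents <- if (kind == "myelinated")
    outer(node, MYELINATED_TYPE_ATTENUATION) else matrix(node, ncol = 1L)
  tpl <- ap_template(currents, sampling_period, cv, diameter, kind,
                     representation = "monopolar", t0 = 0)
  if (params$vm_amplitude == 0) return(tpl)
  align_template(tpl)
}

#' Align a template so the nodal current maximum sits at t = 0
#'
#' Shifts the template time axis so that the sample at which the node-of-
#' Ranvier column (the sole column for unmyelinated fibers) attains its
#' maximum has time 0 ms. If the maximum is attained at several samples, the
#' earliest is used. `ref_time` records the pre-shift clock time of that
#' maximum. Idempotent.
#'
#' @param template An [ap_template()].
#' @return The aligned template.
#' @export
align_template <- function(template) {
  stopifnot(inherits(template, "ap_template"))
  node <- template$currents[, 1L]
  if (diff(range(node)) == 0)
    stop_cnap("cannot align: anchor column is constant (no unique maximum)",
              "cnapsim_alignment_error")
  imax <- which.max(node)            # which.max returns the earliest maximum
  t_max <- template$t0 + (imax - 1L) * template$sampling_period
  template$ref_time <- template$ref_time + t_max
  template$t0 <- template$t0 - t_max
  template
}

#' Convert a monopolar current matrix to the dipolar representation
#'
#' The dipolar matrix is the negative cumulative sum of the monopolar matrix
#' along the spatial (column) dimension: `D(n, m) = -sum_{j<=m} I(n, j)`.
#' Columns must be ordered by longitudinal position. The two representations
#' carry the same spatiotemporal information; see [dipolar_to_monopolar()].
#'
#' @param currents Numeric matrix, time by compartments.
#' @return Matrix of the same shape.
#' @export
monopolar_to_dipolar <- function(currents) {
  currents <- as.matrix(currents)
  if (!all(is.finite(currents)))
    stop_cnap("current matrix must be finite", "cnapsim_parameter_error")
  if (ncol(currents) == 1L) return(-currents)
  -t(apply(currents, 1L, cumsum))
}

#' Convert a dipolar current matrix back to the monopolar representation
#'
#' Exact inverse of [monopolar_to_dipolar()]: the monopolar matrix is the
#' negative first spatial difference of the dipolar matrix, with the first
#' compartment equal to the negative of the first dipolar column.
#'
#' @param currents Numeric matrix, time by compartments.
#' @return Matrix of the same shape.
#' @export
dipolar_to_monopolar <- function(currents) {
  currents <- as.matrix(currents)
  if (!all(is.finite(currents)))
    stop_cnap("current matrix must be finite", "cnapsim_parameter_error")
  if (ncol(currents) == 1L) return(-currents)
  -cbind(currents[, 1L], t(apply(currents, 1L, function(r) diff(r))))
}

# Dipolar template matched to a given inter-compartment sample shift. For a
# traveling wave i(n, m) = g(n - s (m - K)), the negative cumulative spatial
# sum over all upstream compartments is itself a shifted template
# h(n) = -sum_{u >= 0} g(n + s u) once the wave is fully inside the fiber;
# the sum is finite because g has finite support.
dipolar_template_from_monopolar <- function(template, n_shift) {
  stopifnot(inherits(template, "ap_template"))
  if (template$representation != "monopolar")
    stop_cnap("template is already dipolar", "cnapsim_representation_error")
  n <- nrow(template$currents)
  s <- max(1L, as.integer(n_shift))
  out <- template$currents
  for (p in seq_len(ncol(out))) {
    g <- template$currents[, p]
    h <- -g
    u <- 1L
    while (u * s < n) {
      h[seq_len(n - u * s)] <- h[seq_len(n - u * s)] - g[(u * s + 1L):n]
      u <- u + 1L
    }
    out[, p] <- h
  }
  template$currents <- out
  template$representation <- "dipolar"
  template
}

#' Build a geometric fiber-diameter grid
#'
#' Log-equispaced diameters between `d_min` and `d_max` with a per-step ratio
#' of approximately `1 + increment_pct/100`. The number of steps is the
#' nearest integer to `ln(d_max/d_min)/ln(1 + increment_pct/100)`, so the
#' printed percentage is treated as a rounded description of the exact
#' per-step ratio and the endpoints are reproduced exactly.
#'
#' @param d_min,d_max Diameter range in micrometers.
#' @param increment_pct Per-step increment in percent.
#' @return Numeric vector of diameters, strictly increasing, endpoints exact.
#' @export
#' @examples
#' length(build_diameter_grid(0.105, 1.896, 3.06))  # 97
#' length(build_diameter_grid(1.013, 9.809, 1.19))  # 193
build_diameter_grid <- function(d_min, d_max, increment_pct) {
  check_scalar_pos(d_min, "d_min")
  check_scalar_pos(increment_pct, "increment_pct")
  if (!is.numeric(d_max) || d_max < d_min)
    stop_cnap("d_max must be >= d_min", "cnapsim_parameter_error")
  if (d_max == d_min) return(d_min)
  n_steps <- max(1L, as.integer(round(log(d_max / d_min) /
                                        log1p(increment_pct / 100))))
  out <- d_min * exp(seq(0, log(d_max / d_min), length.out = n_steps + 1L))
  out[1L] <- d_min
  out[n_steps + 1L] <- d_max
  out
}

#' Construct a template bank
#'
#' A bank is an ordered collection of aligned templates of one fiber kind and
#' one representation over a strictly increasing diameter grid, supporting
#' linear interpolation at arbitrary in-range diameters.
#'
#' @param templates List of [ap_template()] objects sorted by diameter.
#' @return An object of class `template_bank`.
#' @export
template_bank <- function(templates) {
  if (length(templates) == 0L)
    stop_cnap("empty template bank", "cnapsim_parameter_error")
  stopifnot(all(vapply(templates, inherits, logical(1), "ap_template")))
  d <- vapply(templates, function(x) x$diameter, numeric(1))
  if (is.unsorted(d, strictly = TRUE))
    stop_cnap("bank diameters must be strictly increasing",
              "cnapsim_parameter_error")
  kinds <- unique(vapply(templates, function(x) x$kind, character(1)))
  reps <- unique(vapply(templates, function(x) x$representation, character(1)))
  ncols <- unique(vapply(templates, function(x) ncol(x$currents), integer(1)))
  if (length(kinds) != 1L || length(reps) != 1L || length(ncols) != 1L)
    stop_cnap("bank templates must share kind, representation and column count",
              "cnapsim_parameter_error")
  structure(list(kind = kinds, representation = reps, diameters = d,
                 templates = templates),
            class = "template_bank")
}

#' @export
print.template_bank <- function(x, ...) {
  cat(sprintf("<template_bank> %s, %s: %d templates, D in [%.4g, %.4g] um\n",
              x$kind, x$representation, length(x$templates),
              min(x$diameters), max(x$diameters)))
  invisible(x)
}

#' Generate a synthetic template bank over a geometric diameter grid
#'
#' @param kind Fiber kind; sets the default grid to the built-in geometric
#'   grids (0.105-1.896 um in 3.06 % steps for unmyelinated fibers,
#'   1.013-9.809 um in 1.19 % steps for myelinated fibers).
#' @param diameters Optional explicit diameter grid.
#' @param cv_model A [cv_model()] used to assign conduction velocities.
#' @param params,sampling_period Passed to [generate_synthetic_template()].
#' @return A [template_bank()].
#' @export
synthetic_template_bank <- function(kind = c("unmyelinated", "myelinated"),
                                    diameters = NULL,
                                    cv_model = NULL,
                                    params = synthetic_template_params(),
                                    sampling_period = 0.0025) {
  kind <- match.arg(kind)
  if (is.null(diameters))
    diameters <- if (kind == "unmyelinated")
      build_diameter_grid(0.105, 1.896, 3.06)
    else build_diameter_grid(1.013, 9.809, 1.19)
  if (is.null(cv_model))
    cv_model <- if (kind == "unmyelinated") cv_model_unmyelinated()
                else cv_model_myelinated()
  templates <- lapply(diameters, function(d)
    generate_synthetic_template(d, kind, cv_of_diameter(cv_model, d),
                                params, sampling_period))
  template_bank(templates)
}

#' Interpolate an action potential template at an arbitrary diameter
#'
#' Linear interpolation between the two bank templates bracketing `d_i`:
#' `s_i(t) = (d2 - d_i)/(d2 - d1) s_1(t) + (d_i - d1)/(d2 - d1) s_2(t)`,
#' applied elementwise after resampling both templates to a common time grid
#' (band-limited, at the finer of the two native sampling periods, over the
#' intersection of their windows). The conduction velocity is interpolated
#' linearly between the bracketing values with the same weights. Queries at a
#' grid diameter return the stored template unchanged; queries outside the
#' grid raise an extrapolation error.
#'
#' @param bank A [template_bank()].
#' @param d_i Target diameter in micrometers.
#' @param method `"linear"` (the weighted average above) or `"nearest"`
#'   (return the grid template closest to `d_i`, with `cv` and `diameter`
#'   likewise taken from that neighbor); nearest-neighbor lookup emulates
#'   bin-center reconstruction and is provided for accuracy comparisons.
#' @return An [ap_template()] at diameter `d_i`.
#' @export
interpolate_template <- function(bank, d_i, method = c("linear", "nearest")) {
  stopifnot(inherits(bank, "template_bank"))
  method <- match.arg(method)
  d <- bank$diameters
  if (!is.finite(d_i) || d_i < d[1L] || d_i > d[length(d)])
    stop_cnap(sprintf("diameter %.6g um outside bank range [%.6g, %.6g]: refusing to extrapolate",
                      d_i, d[1L], d[length(d)]),
              "cnapsim_extrapolation_error")
  hit <- which(d == d_i)
  if (length(hit)) return(bank$templates[[hit[1L]]])
  if (method == "nearest")
    return(bank$templates[[which.min(abs(d - d_i))]])
  i2 <- findInterval(d_i, d) + 1L
  i1 <- i2 - 1L
  s1 <- bank$templates[[i1]]; s2 <- bank$templates[[i2]]
  w1 <- (d[i2] - d_i) / (d[i2] - d[i1])
  w2 <- (d_i - d[i1]) / (d[i2] - d[i1])
  period <- min(s1$sampling_period, s2$sampling_period)
  t_lo <- max(s1$t0, s2$t0)
  t_hi <- min(s1$t0 + (nrow(s1$currents) - 1L) * s1$sampling_period,
              s2$t0 + (nrow(s2$currents) - 1L) * s2$sampling_period)
  times <- seq(t_lo, t_hi, by = period)
  same_grid <- function(s) isTRUE(all.equal(s$sampling_period, period,
                                            tolerance = 1e-12)) &&
    isTRUE(all.equal(s$t0, t_lo, tolerance = 1e-12)) &&
    nrow(s$currents) == length(times)
  col_at <- function(s, p) {
    if (same_grid(s)) s$currents[, p]
    else bandlimited_eval(s$currents[, p], s$sampling_period, s$t0, times)
  }
  currents <- vapply(seq_len(ncol(s1$currents)), function(p)
    w1 * col_at(s1, p) + w2 * col_at(s2, p),
    numeric(length(times)))
  ap_template(as.matrix(currents), period,
              cv = w1 * s1$cv + w2 * s2$cv,
              diameter = d_i, kind = s1$kind,
              representation = s1$representation,
              t0 = t_lo,
              ref_time = w1 * s1$ref_time + w2 * s2$ref_time,
              ref_position = w1 * s1$ref_position + w2 * s2$ref_position)
}

#' Reduce a bank to k templates (for interpolation-accuracy studies)
#'
#' Selects `k` diameters spanning the bank (always keeping both endpoints,
#' log-equispaced in between, snapped to the nearest grid members).
#'
#' @param bank A [template_bank()].
#' @param k Number of templates to keep, `2 <= k <= length(bank$diameters)`.
#' @return A [template_bank()] with `k` templates.
#' @export
subsample_bank <- function(bank, k) {
  stopifnot(inherits(bank, "template_bank"))
  n <- length(bank$diameters)
  if (k < 2L || k > n)
    stop_cnap("k must be between 2 and the bank size", "cnapsim_parameter_error")
  target <- exp(seq(log(bank$diameters[1L]), log(bank$diameters[n]),
                    length.out = k))
  idx <- unique(vapply(target, function(d)
    which.min(abs(log(bank$diameters) - log(d))), integer(1)))
  template_bank(bank$templates[idx])
}
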