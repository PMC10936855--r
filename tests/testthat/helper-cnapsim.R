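# Shared fixtures and helpers, all built in code at test time.

relerr <- function(x, ref) max(abs(x - ref)) / max(abs(ref))

# Small template at an exact sampling period (so L/(T*V) is integer by
# construction given L and V).
tiny_template <- function(diameter = 1, kind = "unmyelinated", cv = 0.7,
                          sampling_period = 0.0025) {
  generate_synthetic_template(diameter, kind, cv,
                              sampling_period = sampling_period)
}

# Resample a template to a new period (columns independently).
resample_template <- function(tpl, T_new) {
  cols <- ncol(tpl$currents)
  cur <- vapply(seq_len(cols), function(p)
    cnapsim:::resample_bandlimited(tpl$currents[, p], tpl$sampling_period,
                                   T_new),
    numeric(length(cnapsim:::resample_bandlimited(tpl$currents[, 1L],
                                                  tpl$sampling_period,
                                                  T_new))))
  tpl$currents <- matrix(cur, ncol = cols)
  tpl$sampling_period <- T_new
  tpl
}

# Independent double-loop accumulation oracle for the weighted sum.
loop_sfap <- function(values, w) {
  out <- numeric(nrow(values))
  for (n in seq_len(nrow(values)))
    for (m in seq_len(ncol(values)))
      out[n] <- out[n] + values[n, m] * w[m]
  out
}

# Band-limited template for cross-rate tests: Ricker (second derivative of a
# Gaussian) whose spectrum is negligible above ~1/(2*sigma_ms*pi) scaled;
# sigma chosen so content above the coarse Nyquist is < 1e-10.
ricker_template <- function(sampling_period = 0.01, sigma_ms = 0.12,
                            duration = 4, cv = 1) {
  t <- seq(0, duration, by = sampling_period) - duration / 2
  g <- (1 - (t / sigma_ms)^2) * exp(-t^2 / (2 * sigma_ms^2))
  ap_template(matrix(g * 1e-6, ncol = 1L), sampling_period, cv = cv,
              diameter = 1, kind = "unmyelinated", t0 = -duration / 2)
}

# Small unmyelinated study population: right-skewed caliber histogram over
# the small-fiber range, 40 fibers.
study_distribution <- function() {
  fiber_diameter_distribution(seq(0.3, 1.5, length.out = 13L),
                              c(2, 5, 9, 14, 18, 20, 18, 14, 9, 5, 3, 2),
                              "unmyelinated")
}

study_population <- function(n = 40, seed = 11) {
  fiber_population(inverse_transform_sample(study_distribution(), n,
                                            seed = seed),
                   "unmyelinated")
}

study_bank <- function(increment_pct = 5) {
  synthetic_template_bank("unmyelinated",
                          diameters = build_diameter_grid(0.3, 1.5,
                                                          increment_pct))
}

# Analytic point electrode 1 mm off-axis at longitudinal position z_mm.
study_sensitivity <- function(z_mm) {
  force(z_mm)
  function(traj) analytic_point_source_sensitivity(
    straight_trajectory(traj$z, x = traj$x, y = traj$y - 1),
    c(0, 0, z_mm), 0.16)
}

study_settings <- function(distance_mm = 10, duration_ms = 40, ...) {
  cnap_settings(conduction_distance_mm = distance_mm, fiber_length_mm = 6,
                duration_ms = duration_ms, ...)
}
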