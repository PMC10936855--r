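# JSON run configuration and the three workflow commands: fixture
# generation, a single simulation, and parameter sweeps. These tie the
# modules into reproducible end-to-end runs; the command-line script in
# inst/cli/cnapsim.R is a thin wrapper over these functions.

#' Default run configuration
#'
#' Returns the default configuration as a named list; [load_config()] merges
#' a JSON file over these defaults and validates the result. All sources of
#' randomness are controlled by the explicit `seed` field.
#'
#' @return A list of class `cnap_config`.
#' @export
default_config <- function() {
  structure(list(
    kind = "unmyelinated",
    seed = 1L,
    template_bank = NULL,          # path to a bank directory (NULL: synthetic)
    sensitivity_profile = NULL,    # path to a profile CSV (NULL: analytic)
    fiber_table = NULL,            # path to a fiber list / histogram CSV
    sampling_scheme = "inverse_transform",  # or bin_center | explicit
    n_fibers = 200L,
    diameter_scale = 1,
    conduction_distance_mm = 21,
    fiber_length_mm = 30,
    out_period_ms = 0.01,
    duration_ms = NULL,
    representation = "monopolar",
    merge_tolerance_um = 0.001,
    interpolation = "linear",
    T_max_ms = 0.05,
    metric_window_ms = NULL,
    sigma_S_per_m = 0.16,
    electrode_y_mm = 1
  ), class = "cnap_config")
}

validate_config <- function(config) {
  ok_scheme <- config$sampling_scheme %in%
    c("inverse_transform", "bin_center", "explicit")
  if (!ok_scheme)
    stop_cnap(sprintf("config$sampling_scheme: unknown scheme '%s'",
                      config$sampling_scheme), "cnapsim_config_error")
  if (!config$kind %in% c("unmyelinated", "myelinated"))
    stop_cnap(sprintf("config$kind: unknown kind '%s'", config$kind),
              "cnapsim_config_error")
  if (!config$representation %in% c("dipolar", "monopolar"))
    stop_cnap(sprintf("config$representation: '%s'", config$representation),
              "cnapsim_config_error")
  for (field in c("diameter_scale", "conduction_distance_mm", "out_period_ms"))
    if (!is.numeric(config[[field]]) || config[[field]] <= 0)
      stop_cnap(sprintf("config$%s must be positive", field),
                "cnapsim_config_error")
  if (is.null(config$seed))
    stop_cnap("config$seed must be explicit", "cnapsim_config_error")
  config
}

#' Load and validate a JSON run configuration
#'
#' @param path Path to a JSON file, or a named list of overrides.
#' @return A validated `cnap_config` list.
#' @export
load_config <- function(path = NULL) {
  config <- default_config()
  if (!is.null(path)) {
    user <- if (is.list(path)) path
            else jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(user), names(config))
    if (length(unknown))
      stop_cnap(sprintf("config: unknown field(s) %s",
                        paste(unknown, collapse = ", ")),
                "cnapsim_config_error")
    config[names(user)] <- user
  }
  validate_config(config)
}

#' Hash of a configuration
#'
#' MD5 digest of the canonical JSON serialization; embedded in every output
#' so results can be traced back to the exact configuration that produced
#' them.
#'
#' @param config A `cnap_config` list.
#' @return A 32-character hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config[order(names(config))], tmp, auto_unbox = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

config_sensitivity <- function(config) {
  if (!is.null(config$sensitivity_profile))
    load_sensitivity_profile(config$sensitivity_profile)
  else {
    electrode <- c(0, 0, config$conduction_distance_mm)
    sigma <- config$sigma_S_per_m
    y_off <- config$electrode_y_mm
    function(traj) analytic_point_source_sensitivity(
      structure(data.frame(x = traj$x, y = traj$y - y_off, z = traj$z),
                class = c("fiber_trajectory", "data.frame")),
      electrode, sigma, sigma)
  }
}

config_bank <- function(config) {
  if (!is.null(config$template_bank)) read_template_bank(config$template_bank)
  else synthetic_template_bank(config$kind)
}

# Built-in synthetic diameter histogram used when no fiber table is given:
# a right-skewed distribution over the template grid range, the shape
# typical of vagal fiber calibers.
config_distribution <- function(config) {
  if (!is.null(config$fiber_table)) {
    tab <- read_fiber_table(config$fiber_table, config$kind)
    if (inherits(tab, "fiber_diameter_distribution")) return(tab)
    return(tab)  # explicit fiber list data frame
  }
  rng <- if (config$kind == "unmyelinated") c(0.105, 1.896) else c(1.013, 9.809)
  edges <- seq(rng[1L], rng[2L], length.out = 19L)
  mids <- (edges[-1L] + edges[-length(edges)]) / 2
  shape <- stats::dlnorm(mids, meanlog = log(rng[1L] + 0.3 * diff(rng)),
                         sdlog = 0.4)
  counts <- pmax(1L, round(1000 * shape / max(shape)))
  fiber_diameter_distribution(edges, counts, config$kind)
}

config_population <- function(config) {
  src <- config_distribution(config)
  diameters <- if (inherits(src, "fiber_diameter_distribution")) {
    switch(config$sampling_scheme,
           inverse_transform = inverse_transform_sample(src, config$n_fibers,
                                                        seed = config$seed),
           bin_center = bin_center_expand(src),
           explicit = stop_cnap("explicit scheme needs a fiber list, not a histogram",
                                "cnapsim_config_error"))
  } else src$diameter_um
  pop <- fiber_population(diameters, kind = config$kind)
  if (config$diameter_scale != 1)
    pop <- scale_diameters(pop, config$diameter_scale)
  pop
}

config_settings <- function(config) {
  cnap_settings(conduction_distance_mm = config$conduction_distance_mm,
                fiber_length_mm = config$fiber_length_mm,
                representation = config$representation,
                out_period_ms = config$out_period_ms,
                duration_ms = config$duration_ms,
                T_max_ms = config$T_max_ms,
                merge_tolerance_um = config$merge_tolerance_um,
                interpolation = config$interpolation)
}

#' Generate a self-contained fixture set
#'
#' Writes a synthetic template bank over the configured geometric diameter
#' grid, an analytic sensitivity profile export, and a synthetic fiber
#' diameter histogram, all reproducible from the configuration seed.
#'
#' @param config A `cnap_config` list (see [load_config()]).
#' @param out_dir Output directory.
#' @return Named list of the paths written, invisibly.
#' @export
cnap_make_fixtures <- function(config = load_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bank <- synthetic_template_bank(config$kind)
  bank_dir <- file.path(out_dir, "template_bank")
  write_template_bank(bank, bank_dir)
  span <- config$fiber_length_mm * 1.5
  z <- seq(config$conduction_distance_mm - span,
           config$conduction_distance_mm + span, by = 0.05)
  profile <- analytic_point_source_sensitivity(
    straight_trajectory(z, y = -config$electrode_y_mm),
    c(0, 0, config$conduction_distance_mm),
    config$sigma_S_per_m, config$sigma_S_per_m)
  profile_path <- file.path(out_dir, "sensitivity_profile.csv")
  write_sensitivity_profile(profile, profile_path)
  hist_path <- file.path(out_dir, "fiber_histogram.csv")
  write_fiber_histogram(config_distribution(config), hist_path)
  invisible(list(template_bank = bank_dir,
                 sensitivity_profile = profile_path,
                 fiber_histogram = hist_path))
}

#' Run a configured CNAP simulation
#'
#' Executes the pipeline (sample diameters, group by diameter, interpolate
#' templates, filter, superpose) and, if `out_dir` is given, writes the
#' signal CSV and a JSON metrics report carrying the seeds, scale factor and
#' configuration hash.
#'
#' @param config A `cnap_config` list.
#' @param out_dir Optional output directory.
#' @return A list with the [cnap_result][simulate_cnap()] and the metrics
#'   report.
#' @export
cnap_run_simulation <- function(config = load_config(), out_dir = NULL) {
  config <- validate_config(config)
  pop <- config_population(config)
  result <- simulate_cnap(pop, config_bank(config),
                          config_sensitivity(config),
                          config_settings(config))
  window <- config$metric_window_ms
  metrics <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    diameter_scale = config$diameter_scale,
    n_fibers = result$n_fibers,
    n_groups = result$n_groups,
    zero_fibers = result$n_fibers == 0L,
    v_pk_pk_mV = if (result$n_fibers) peak_to_peak(result, window) else 0,
    negative_peak_latency_ms = if (result$n_fibers)
      tryCatch(negative_peak_latency(result, window),
               error = function(e) NA_real_)
    else NA_real_)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cnap_csv(result, file.path(out_dir, "cnap_signal.csv"))
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  }
  list(result = result, metrics = metrics)
}

#' Sweep one parameter of a configured simulation
#'
#' Re-runs the simulation once per value of the swept parameter and tabulates
#' peak-to-peak amplitude and negative-peak latency; where a reference run
#' exists (the full bank for `template_count`, zero bin width is not
#' applicable, the first value otherwise not special) the maximum percent
#' discrepancy against it is included. Distance sweeps also attach the
#' amplitude-distance power fit as the `power_fit` attribute.
#'
#' @param config A `cnap_config` list.
#' @param parameter One of `"conduction_distance"`, `"diameter_scale"`,
#'   `"template_count"`, `"bin_width"`, `"cv_slope_scale"`.
#' @param values Numeric vector of parameter values.
#' @return A data frame with one row per value.
#' @export
cnap_sweep <- function(config = load_config(), parameter, values) {
  allowed <- c("conduction_distance", "diameter_scale", "template_count",
               "bin_width", "cv_slope_scale")
  if (!parameter %in% allowed)
    stop_cnap(sprintf("unknown sweep parameter '%s'", parameter),
              "cnapsim_config_error")
  config <- validate_config(config)
  pop <- config_population(config)
  bank <- config_bank(config)
  sens <- config_sensitivity(config)
  settings <- config_settings(config)
  window <- config$metric_window_ms
  reference <- NULL
  if (parameter == "template_count") {
    # the full bank is the reference; fix the output grid so sweep runs and
    # the reference share a common time base for the discrepancy statistic
    reference <- simulate_cnap(pop, bank, sens, settings)
    settings$duration_ms <- max(reference$time_ms)
  }

  run_one <- function(value) {
    pop_i <- pop; bank_i <- bank; settings_i <- settings
    switch(parameter,
      conduction_distance = {
        settings_i$conduction_distance_mm <- value
      },
      diameter_scale = {
        pop_i <- scale_diameters(pop, value)
      },
      template_count = {
        bank_i <- subsample_bank(bank, as.integer(value))
      },
      bin_width = {
        src <- config_distribution(config)
        if (!inherits(src, "fiber_diameter_distribution")) {
          d <- src$diameter_um
          e <- seq(min(d) - 1e-9, max(d) + 1e-9, length.out = 25L)
          src <- fiber_diameter_distribution(
            e, tabulate(findInterval(d, e, all.inside = TRUE), 24L),
            config$kind)
        }
        top <- src$bin_edges[length(src$bin_edges)]
        edges <- seq(src$bin_edges[1L], top, by = value)
        if (edges[length(edges)] < top) edges <- c(edges, top)
        counts <- vapply(seq_len(length(edges) - 1L), function(i)
          round((distribution_cdf(src, edges[i + 1L]) -
                   distribution_cdf(src, edges[i])) * sum(src$counts)),
          numeric(1))
        rebinned <- fiber_diameter_distribution(edges, counts, config$kind)
        diam <- if (config$sampling_scheme == "bin_center")
          bin_center_expand(rebinned)
        else inverse_transform_sample(rebinned, config$n_fibers,
                                      seed = config$seed)
        pop_i <- fiber_population(diam, kind = config$kind)
      },
      cv_slope_scale = {
        base <- attr(pop, "cv_model")
        model <- cv_model(base$form, base$slope * value, base$intercept)
        pop_i <- fiber_population(pop$diameter_um, kind = config$kind,
                                  cv_model = model,
                                  x_mm = pop$x_mm, y_mm = pop$y_mm,
                                  z_offset_mm = pop$z_offset_mm)
      })
    simulate_cnap(pop_i, bank_i, sens, settings_i)
  }

  results <- lapply(values, run_one)
  rows <- data.frame(
    parameter = parameter, value = values,
    v_pk_pk_mV = vapply(results, peak_to_peak, numeric(1), window = window),
    negative_peak_latency_ms = vapply(results, function(r)
      tryCatch(negative_peak_latency(r, window), error = function(e) NA_real_),
      numeric(1)),
    max_percent_discrepancy = vapply(results, function(r) {
      if (is.null(reference)) return(NA_real_)
      max_percent_discrepancy(r, reference)
    }, numeric(1)))
  if (parameter == "conduction_distance" && length(values) >= 2L)
    attr(rows, "power_fit") <-
      fit_amplitude_distance_power(values, rows$v_pk_pk_mV)
  rows
}
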