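# Recording sensitivity functions (lead fields): the weight, in V/mA, that a
# unit transmembrane current at each fiber position contributes to the
# recorded potential. By reciprocity this equals the potential on the fiber
# produced by a unit current applied at the recording contact.

#' Construct a recording sensitivity function
#'
#' @param weights Numeric matrix `n_positions x n_types` (1 column for
#'   unmyelinated fibers, 11 for myelinated), in V/mA.
#' @param positions Strictly increasing longitudinal coordinates (mm) of the
#'   compartment anchors (node positions for myelinated fibers).
#' @param representation `"monopolar"` or `"dipolar"`.
#' @param source Provenance tag, `"analytic"` or `"file"`.
#' @return An object of class `sensitivity_fn`.
#' @export
sensitivity_fn <- function(weights, positions,
                           representation = c("monopolar", "dipolar"),
                           source = "analytic") {
  representation <- match.arg(representation)
  weights <- as.matrix(weights)
  positions <- as.numeric(positions)
  if (nrow(weights) != length(positions))
    stop_cnap("weights rows must match positions length", "cnapsim_parameter_error")
  if (length(positions) > 1L && is.unsorted(positions, strictly = TRUE))
    stop_cnap("positions must be strictly increasing", "cnapsim_parameter_error")
  if (!all(is.finite(weights)))
    stop_cnap("weights must be finite", "cnapsim_parameter_error")
  structure(list(weights = weights, positions = positions,
                 representation = representation, source = source),
            class = "sensitivity_fn")
}

#' @export
print.sensitivity_fn <- function(x, ...) {
  cat(sprintf("<sensitivity_fn> %s (%s): %d position(s) x %d type column(s), span %.4g mm\n",
              x$representation, x$source, nrow(x$weights), ncol(x$weights),
              diff(range(x$positions))))
  invisible(x)
}

#' Straight fiber trajectory along the z axis
#'
#' @param z Longitudinal sample coordinates in mm (strictly increasing).
#' @param x,y Constant transverse offsets in mm.
#' @return A data frame with columns `x`, `y`, `z` (mm), class
#'   `fiber_trajectory`.
#' @export
straight_trajectory <- function(z, x = 0, y = 0) {
  z <- as.numeric(z)
  if (length(z) > 1L && is.unsorted(z, strictly = TRUE))
    stop_cnap("z must be strictly increasing", "cnapsim_parameter_error")
  structure(data.frame(x = rep_len(x, length(z)), y = rep_len(y, length(z)),
                       z = z),
            class = c("fiber_trajectory", "data.frame"))
}

#' Analytic point-source recording sensitivity
#'
#' Closed-form lead field of a point recording contact in an unbounded,
#' longitudinally anisotropic medium. For a unit current applied at the
#' contact, the potential at a fiber point offset by `(dx, dy, dz)` is
#' `1/(4*pi) / sqrt(sr*sz*(dx^2 + dy^2) + sr^2*dz^2)` (V/A with distances in
#' metres, `sr` = radial and `sz` = longitudinal conductivity in S/m),
#' reducing to `1/(4*pi*s*r)` in the isotropic case. Weights are returned in
#' V/mA.
#'
#' @param trajectory A [straight_trajectory()] (or data frame with x, y, z in
#'   mm) giving the fiber sample points.
#' @param electrode_position Numeric length-3, electrode (x, y, z) in mm.
#' @param sigma_radial,sigma_longitudinal Conductivities in S/m.
#' @return A monopolar [sensitivity_fn()] with one weight column.
#' @export
analytic_point_source_sensitivity <- function(trajectory, electrode_position,
                                              sigma_radial = 0.16,
                                              sigma_longitudinal = sigma_radial) {
  check_scalar_pos(sigma_radial, "sigma_radial")
  check_scalar_pos(sigma_longitudinal, "sigma_longitudinal")
  stopifnot(length(electrode_position) == 3L)
  dx <- (trajectory$x - electrode_position[1L]) * 1e-3
  dy <- (trajectory$y - electrode_position[2L]) * 1e-3
  dz <- (trajectory$z - electrode_position[3L]) * 1e-3
  denom2 <- sigma_radial * sigma_longitudinal * (dx^2 + dy^2) +
    sigma_radial^2 * dz^2
  if (any(denom2 <= 0))
    stop_cnap("electrode coincides with a fiber sample point",
              "cnapsim_singularity_error")
  w_V_per_A <- 1 / (4 * pi * sqrt(denom2))
  sensitivity_fn(matrix(w_V_per_A * 1e-3, ncol = 1L), trajectory$z,
                 representation = "monopolar", source = "analytic")
}

#' Load a tabulated recording sensitivity profile
#'
#' Reads a delimited-text profile with a header row: column `z_mm` plus
#' either a single `w_V_per_mA` column or eleven `w_<TYPE>_V_per_mA` columns
#' (one per myelinated compartment type, see [COMPARTMENT_TYPES]).
#'
#' @param path Path to a CSV file, or a data frame in the same layout.
#' @return A monopolar [sensitivity_fn()] with `source = "file"`.
#' @export
load_sensitivity_profile <- function(path) {
  tab <- if (is.data.frame(path)) path
         else utils::read.csv(path, check.names = FALSE)
  if (!"z_mm" %in% names(tab))
    stop_cnap("profile must have a z_mm column", "cnapsim_format_error")
  z <- tab$z_mm
  if (is.unsorted(z, strictly = TRUE))
    stop_cnap("profile z_mm must be strictly increasing", "cnapsim_format_error")
  typed <- paste0("w_", COMPARTMENT_TYPES, "_V_per_mA")
  if (all(typed %in% names(tab))) {
    w <- as.matrix(tab[typed])
    colnames(w) <- COMPARTMENT_TYPES
  } else if ("w_V_per_mA" %in% names(tab)) {
    w <- matrix(tab$w_V_per_mA, ncol = 1L)
  } else {
    stop_cnap("profile must have w_V_per_mA or all eleven w_<TYPE>_V_per_mA columns",
              "cnapsim_format_error")
  }
  sensitivity_fn(w, z, representation = "monopolar", source = "file")
}

#' Write a sensitivity profile as delimited text
#'
#' Inverse of [load_sensitivity_profile()]; numbers are written with 17
#' significant digits so a round trip reproduces the weights exactly.
#'
#' @param w A [sensitivity_fn()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_profile <- function(w, path) {
  stopifnot(inherits(w, "sensitivity_fn"))
  cols <- if (ncol(w$weights) == 11L)
    paste0("w_", COMPARTMENT_TYPES, "_V_per_mA") else "w_V_per_mA"
  tab <- data.frame(z_mm = sprintf("%.17g", w$positions),
                    apply(w$weights, 2L, function(col) sprintf("%.17g", col)),
                    check.names = FALSE)
  names(tab) <- c("z_mm", cols)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sample a sensitivity profile along a fiber trajectory
#'
#' Piecewise-linear interpolation of every weight column at the requested
#' longitudinal positions. Positions outside the tabulated range raise an
#' extrapolation error; the lead field is only known where it was exported.
#'
#' @param profile A [sensitivity_fn()].
#' @param positions Longitudinal coordinates (mm) of the compartment anchors,
#'   or a [straight_trajectory()] whose `z` column is used.
#' @return A [sensitivity_fn()] sampled at `positions`.
#' @export
sample_along_trajectory <- function(profile, positions) {
  stopifnot(inherits(profile, "sensitivity_fn"))
  if (inherits(positions, "fiber_trajectory")) positions <- positions$z
  positions <- as.numeric(positions)
  rng <- range(profile$positions)
  if (any(positions < rng[1L] - 1e-12) || any(positions > rng[2L] + 1e-12))
    stop_cnap(sprintf("positions outside the profile range [%.6g, %.6g] mm: refusing to extrapolate",
                      rng[1L], rng[2L]),
              "cnapsim_extrapolation_error")
  w <- apply(profile$weights, 2L, function(col)
    stats::approx(profile$positions, col, xout = positions, rule = 1)$y)
  w <- matrix(w, nrow = length(positions))
  colnames(w) <- colnames(profile$weights)
  sensitivity_fn(w, positions, representation = profile$representation,
                 source = profile$source)
}

#' Differentiate a sensitivity function for the dipolar representation
#'
#' The dipolar representation weights each compartment's current dipole by
#' the first spatial difference of the monopolar sensitivity along the
#' compartment order: `w'(m) = w(m+1) - w(m)` with `w(M+1) := 0`, so the
#' final element is `w'(M) = -w(M)`. The zero boundary makes the monopolar
#' and dipolar weighted sums agree exactly for every finite current matrix
#' (Abel summation), not just in the infinite-fiber limit.
#'
#' @param w A monopolar [sensitivity_fn()].
#' @return A dipolar [sensitivity_fn()] with the same shape.
#' @export
differentiate_for_dipole <- function(w) {
  stopifnot(inherits(w, "sensitivity_fn"))
  if (w$representation != "monopolar")
    stop_cnap("sensitivity is already dipolar", "cnapsim_representation_error")
  dw <- apply(w$weights, 2L, function(col) c(diff(col), -col[length(col)]))
  dw <- matrix(dw, nrow = nrow(w$weights))
  colnames(dw) <- colnames(w$weights)
  sensitivity_fn(dw, w$positions, representation = "dipolar", source = w$source)
}

#' Sum recording sensitivity functions
#'
#' Fibers with (nearly) the same diameter share one action potential
#' template, so their sensitivity functions can be summed into a joint
#' sensitivity before computing a single SFAP for the whole group.
#'
#' @param ws List of [sensitivity_fn()] objects with identical positions,
#'   representation and column count.
#' @return The elementwise sum as a [sensitivity_fn()].
#' @export
merge_sensitivities <- function(ws) {
  if (inherits(ws, "sensitivity_fn")) ws <- list(ws)
  stopifnot(length(ws) >= 1L,
            all(vapply(ws, inherits, logical(1), "sensitivity_fn")))
  ref <- ws[[1L]]
  for (w in ws[-1L]) {
    if (!identical(dim(w$weights), dim(ref$weights)) ||
        !isTRUE(all.equal(w$positions, ref$positions, tolerance = 1e-12)) ||
        w$representation != ref$representation)
      stop_cnap("sensitivity functions must share positions, shape and representation",
                "cnapsim_merge_error")
  }
  total <- Reduce(`+`, lapply(ws, `[[`, "weights"))
  sensitivity_fn(total, ref$positions, representation = ref$representation,
                 source = ref$source)
}
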