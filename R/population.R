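# Fiber populations: diameter distributions and sampling schemes, conduction
# velocity models, myelinated ultrastructure geometry, and grouping of fibers
# with nearly identical diameters.

# Run an expression with a private, restorable RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Construct a binned fiber diameter distribution
#'
#' @param bin_edges Strictly increasing bin edges in micrometers.
#' @param counts Non-negative fiber counts per bin
#'   (`length(counts) == length(bin_edges) - 1`).
#' @param kind Fiber kind.
#' @return An object of class `fiber_diameter_distribution`.
#' @export
fiber_diameter_distribution <- function(bin_edges, counts,
                                        kind = c("unmyelinated", "myelinated")) {
  kind <- match.arg(kind)
  bin_edges <- as.numeric(bin_edges)
  counts <- as.numeric(counts)
  if (length(counts) != length(bin_edges) - 1L)
    stop_cnap("need one count per bin", "cnapsim_parameter_error")
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop_cnap("bin_edges must be strictly increasing", "cnapsim_parameter_error")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_cnap("counts must be non-negative integers", "cnapsim_parameter_error")
  structure(list(bin_edges = bin_edges, counts = counts, kind = kind),
            class = "fiber_diameter_distribution")
}

# Empirical CDF of the binned distribution, piecewise linear within bins
# (uniform density per bin).
distribution_cdf <- function(dist, x) {
  total <- sum(dist$counts)
  cum <- c(0, cumsum(dist$counts)) / total
  stats::approx(dist$bin_edges, cum, xout = x, rule = 2, ties = "ordered")$y
}

#' Sample fiber diameters by inverse transform sampling
#'
#' Uniform variates are mapped through the piecewise-linear empirical CDF of
#' the binned distribution (uniform density within each bin), so raw
#' measurement lists are recovered as the bin width shrinks to zero.
#'
#' @param dist A [fiber_diameter_distribution()] with positive total count.
#' @param n Number of diameters to draw.
#' @param seed Integer seed; sampling is reproducible for a fixed seed.
#' @return Numeric vector of `n` diameters in micrometers.
#' @export
inverse_transform_sample <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "fiber_diameter_distribution"))
  if (n < 0) stop_cnap("n must be >= 0", "cnapsim_parameter_error")
  if (n == 0) return(numeric(0))
  total <- sum(dist$counts)
  if (total <= 0)
    stop_cnap("cannot sample from an empty distribution", "cnapsim_sampling_error")
  cum <- c(0, cumsum(dist$counts)) / total
  u <- with_seed(seed, stats::runif(n))
  # invert the piecewise-linear CDF; zero-count bins have zero probability of
  # receiving a draw, so flat CDF segments never see an interior u
  idx <- findInterval(u, cum, rightmost.closed = TRUE, all.inside = TRUE)
  # skip forward over flat (zero-count) segments
  while (any(bad <- (cum[idx + 1L] == cum[idx]) & dist$counts[idx] == 0))
    idx[bad] <- idx[bad] + 1L
  left <- dist$bin_edges[idx]
  width <- diff(dist$bin_edges)[idx]
  frac <- (u - cum[idx]) / (cum[idx + 1L] - cum[idx])
  left + frac * width
}

#' Expand a binned distribution to bin-center diameters
#'
#' Deterministic alternative to [inverse_transform_sample()]: every fiber in
#' a bin is assigned the bin's center diameter. Coarse bins therefore pile
#' identical fibers onto single diameters, which reduces destructive
#' interference between their SFAPs and biases the CNAP.
#'
#' @param dist A [fiber_diameter_distribution()].
#' @return Numeric vector of diameters, one per counted fiber.
#' @export
bin_center_expand <- function(dist) {
  stopifnot(inherits(dist, "fiber_diameter_distribution"))
  centers <- (dist$bin_edges[-1L] + dist$bin_edges[-length(dist$bin_edges)]) / 2
  rep(centers, times = dist$counts)
}

#' Conduction velocity versus fiber diameter model
#'
#' Myelinated fiber CV is linear in diameter, `CV = slope * D + intercept`;
#' unmyelinated fiber CV is linear in the square root of diameter,
#' `CV = slope * sqrt(D) + intercept`. Defaults are the relations that emerge
#' from biophysical fiber models of the rat cervical vagus nerve:
#' `4.01 * D - 2.5` (myelinated) and `0.70 * sqrt(D) - 1.9e-3`
#' (unmyelinated).
#'
#' @param form `"linear_in_D"` or `"linear_in_sqrtD"`.
#' @param slope Slope in m/s per um (or per sqrt um).
#' @param intercept Intercept in m/s.
#' @return An object of class `cv_model`.
#' @export
cv_model <- function(form = c("linear_in_D", "linear_in_sqrtD"),
                     slope, intercept) {
  form <- match.arg(form)
  structure(list(form = form, slope = slope, intercept = intercept),
            class = "cv_model")
}

#' @rdname cv_model
#' @export
cv_model_myelinated <- function() cv_model("linear_in_D", 4.01, -2.5)

#' @rdname cv_model
#' @export
cv_model_unmyelinated <- function() cv_model("linear_in_sqrtD", 0.70, -1.9e-3)

#' Evaluate a CV model at one or more diameters
#'
#' @param model A [cv_model()].
#' @param d Diameters in micrometers.
#' @return Conduction velocities in m/s. Diameters at which the model
#'   predicts a non-positive CV raise a domain error: such a fiber cannot
#'   propagate an action potential.
#' @export
cv_of_diameter <- function(model, d) {
  stopifnot(inherits(model, "cv_model"))
  cv <- switch(model$form,
               linear_in_D = model$slope * d + model$intercept,
               linear_in_sqrtD = model$slope * sqrt(d) + model$intercept)
  if (any(cv <= 0))
    stop_cnap(sprintf("CV model predicts non-positive velocity at D = %.4g um",
                      d[which(cv <= 0)[1L]]),
              "cnapsim_domain_error")
  cv
}

#' Myelinated fiber ultrastructure model
#'
#' Holder for the empirical fits mapping fiber diameter `D` (um) to the
#' geometry of one internode, with optional multiplicative/additive normal
#' variability factors, and the validity threshold below which the fitted
#' geometry degenerates.
#'
#' @param validity_threshold Minimum fiber diameter in micrometers (default
#'   1.01; smaller fibers produce an invalid modeled ultrastructure).
#' @param stochastic If `TRUE`, [ultrastructure_geometry()] draws the normal
#'   variability factors; if `FALSE` every factor is fixed at its mean.
#' @return An object of class `ultrastructure_model`.
#' @export
ultrastructure_model <- function(validity_threshold = 1.01, stochastic = FALSE) {
  structure(list(validity_threshold = validity_threshold,
                 stochastic = stochastic),
            class = "ultrastructure_model")
}

#' Ultrastructure geometry of a myelinated fiber
#'
#' Evaluates the empirical internode geometry fits at fiber diameter `D`
#' (um): nodal length 1 um; MYSA length 3 um; FLUT (paranode) length
#' `(-0.171 (D-9.45)^2 + 3.30 (D-9.45) + 44.85) x N(1, 0.06)` um; internodal
#' (node center-to-center) length
#' `(-2.071 (D-9.04)^2 + 87.95 (D-9.04) + 900.88) x N(1, 0.13)` um;
#' internodal axon diameter `(0.0201 (D-2.39) + 0.55 + N(0, 0.102)) D`;
#' nodal axon diameter `(-0.0111 (da-7.15) + 0.4 + N(0, 0.072)) da`; number
#' of myelin lamellae `exp(0.51 (da-1.75) + 3.2 + N(0, 0.3))`. The six STIN
#' segments share the remaining internode equally. In deterministic mode the
#' normal factors are fixed at their means; in stochastic mode they are drawn
#' once per fiber.
#'
#' @param D Fiber diameter in micrometers; must be at least the model's
#'   validity threshold (default 1.01 um).
#' @param model An [ultrastructure_model()].
#' @param seed Integer seed for the stochastic factors.
#' @return A list with elements `node_length_um`, `mysa_length_um`,
#'   `flut_length_um`, `stin_length_um`, `internodal_length_um`,
#'   `internodal_axon_diameter_um`, `nodal_axon_diameter_um`, `n_lamellae`.
#' @export
ultrastructure_geometry <- function(D, model = ultrastructure_model(),
                                    seed = NULL) {
  stopifnot(inherits(model, "ultrastructure_model"))
  if (!is.finite(D) || D < model$validity_threshold)
    stop_cnap(sprintf("D = %.4g um below the %.3g um threshold: invalid modeled ultrastructure",
                      D, model$validity_threshold),
              "cnapsim_validity_error")
  f <- if (model$stochastic)
    with_seed(seed, list(flut = stats::rnorm(1, 1, 0.06),
                         inl  = stats::rnorm(1, 1, 0.13),
                         da   = stats::rnorm(1, 0, 0.102),
                         dn   = stats::rnorm(1, 0, 0.072),
                         nl   = stats::rnorm(1, 0, 0.3)))
  else list(flut = 1, inl = 1, da = 0, dn = 0, nl = 0)
  node <- 1
  mysa <- 3
  flut <- (-0.171 * (D - 9.45)^2 + 3.30 * (D - 9.45) + 44.85) * f$flut
  inl  <- (-2.071 * (D - 9.04)^2 + 87.95 * (D - 9.04) + 900.88) * f$inl
  da   <- (0.0201 * (D - 2.39) + 0.55 + f$da) * D
  dn   <- (-0.0111 * (da - 7.15) + 0.4 + f$dn) * da
  nl   <- exp(0.51 * (da - 1.75) + 3.2 + f$nl)
  stin <- (inl - node - 2 * mysa - 2 * flut) / 6
  vals <- c(flut = flut, inl = inl, da = da, dn = dn, stin = stin)
  if (any(!is.finite(vals)) || any(vals <= 0) || nl < 1)
    stop_cnap(sprintf("D = %.4g um yields a non-physical geometry: invalid modeled ultrastructure", D),
              "cnapsim_validity_error")
  list(node_length_um = node, mysa_length_um = mysa, flut_length_um = flut,
       stin_length_um = stin, internodal_length_um = inl,
       internodal_axon_diameter_um = da, nodal_axon_diameter_um = dn,
       n_lamellae = nl)
}

# Longitudinal offsets (mm) of the 11 compartment-type centers within one
# internode, measured from the node center.
compartment_type_offsets <- function(geom) {
  um <- c(NODE = 0,
          MYSA1 = geom$node_length_um / 2 + geom$mysa_length_um / 2,
          FLUT1 = geom$node_length_um / 2 + geom$mysa_length_um +
            geom$flut_length_um / 2)
  base <- geom$node_length_um / 2 + geom$mysa_length_um + geom$flut_length_um
  stin <- base + (seq_len(6) - 0.5) * geom$stin_length_um
  names(stin) <- paste0("STIN", 1:6)
  flut2 <- base + 6 * geom$stin_length_um + geom$flut_length_um / 2
  mysa2 <- base + 6 * geom$stin_length_um + geom$flut_length_um +
    geom$mysa_length_um / 2
  c(um, stin, FLUT2 = unname(flut2), MYSA2 = unname(mysa2)) * 1e-3
}

#' Construct a fiber population
#'
#' A population is a data frame of fibers (diameter, kind, cross-section
#' position, longitudinal jitter) with conduction velocity and compartment
#' spacing derived from the attached models. Myelinated fibers must pass the
#' ultrastructure validity check; their compartment spacing is the fitted
#' internodal length. Unmyelinated fibers use a uniform compartment spacing.
#'
#' @param diameters Fiber diameters in micrometers.
#' @param kind Fiber kind, shared by the population.
#' @param cv_model A [cv_model()] (defaults by kind).
#' @param ultra An [ultrastructure_model()] (myelinated only).
#' @param x_mm,y_mm Cross-section positions (recycled).
#' @param z_offset_mm Longitudinal jitter per fiber (recycled). See
#'   [jitter_z_offsets()].
#' @param unmyelinated_spacing_um Compartment spacing for unmyelinated
#'   fibers, micrometers. The default 25 um resolves the spatial extent of
#'   the slowest fibers' action potentials severalfold, which the dipolar
#'   (cumulative) representation requires.
#' @param seed Seed for stochastic ultrastructure factors (drawn once per
#'   fiber when `ultra$stochastic` is `TRUE`).
#' @return A data frame of class `fiber_population` with columns
#'   `diameter_um`, `kind`, `x_mm`, `y_mm`, `z_offset_mm`, `cv_m_per_s`,
#'   `spacing_um`; the models are kept as attributes so diameters can be
#'   rescaled consistently.
#' @export
fiber_population <- function(diameters,
                             kind = c("unmyelinated", "myelinated"),
                             cv_model = NULL, ultra = ultrastructure_model(),
                             x_mm = 0, y_mm = 0, z_offset_mm = 0,
                             unmyelinated_spacing_um = 25, seed = NULL) {
  kind <- match.arg(kind)
  if (is.null(cv_model))
    cv_model <- if (kind == "unmyelinated") cv_model_unmyelinated()
                else cv_model_myelinated()
  n <- length(diameters)
  if (n > 0 && any(diameters <= 0))
    stop_cnap("diameters must be positive", "cnapsim_parameter_error")
  spacing <- if (kind == "myelinated" && n > 0) {
    seeds <- if (!is.null(seed)) seed + seq_len(n) else rep(list(NULL), n)
    vapply(seq_len(n), function(i)
      ultrastructure_geometry(diameters[i], ultra, seed = seeds[[i]])$internodal_length_um,
      numeric(1))
  } else rep(unmyelinated_spacing_um, n)
  pop <- data.frame(diameter_um = as.numeric(diameters),
                    kind = rep_len(kind, n),
                    x_mm = rep_len(x_mm, n), y_mm = rep_len(y_mm, n),
                    z_offset_mm = rep_len(z_offset_mm, n),
                    cv_m_per_s = if (n) cv_of_diameter(cv_model, diameters) else numeric(0),
                    spacing_um = spacing)
  structure(pop, class = c("fiber_population", "data.frame"),
            cv_model = cv_model, ultra = ultra,
            unmyelinated_spacing_um = unmyelinated_spacing_um)
}

#' Scale all fiber diameters by a common factor
#'
#' Emulates correction for histological shrinkage: every diameter is
#' multiplied by `factor` and the conduction velocity and compartment spacing
#' are re-derived from the scaled diameters using the population's models.
#'
#' @param fibers A [fiber_population()].
#' @param factor Positive scale factor (1 is the identity).
#' @param seed Seed for stochastic ultrastructure factors, if enabled.
#' @return A rescaled [fiber_population()].
#' @export
scale_diameters <- function(fibers, factor, seed = NULL) {
  stopifnot(inherits(fibers, "fiber_population"))
  check_scalar_pos(factor, "factor")
  fiber_population(fibers$diameter_um * factor,
                   kind = unique(fibers$kind),
                   cv_model = attr(fibers, "cv_model"),
                   ultra = attr(fibers, "ultra"),
                   x_mm = fibers$x_mm, y_mm = fibers$y_mm,
                   z_offset_mm = fibers$z_offset_mm,
                   unmyelinated_spacing_um = attr(fibers, "unmyelinated_spacing_um"),
                   seed = seed)
}

#' Draw longitudinal jitter offsets for a population
#'
#' Each fiber is displaced longitudinally by a uniform draw in plus or minus
#' half its own compartment spacing, emulating the random placement of nodes
#' relative to the recording contact.
#'
#' @param fibers A [fiber_population()].
#' @param seed Integer seed.
#' @return The population with its `z_offset_mm` column replaced.
#' @export
jitter_z_offsets <- function(fibers, seed = NULL) {
  stopifnot(inherits(fibers, "fiber_population"))
  half <- fibers$spacing_um * 1e-3 / 2
  fibers$z_offset_mm <- with_seed(seed,
    stats::runif(nrow(fibers), -half, half))
  fibers
}

#' Group fibers with nearly identical diameters
#'
#' Greedy grouping over ascending diameters: a fiber joins the current group
#' while its diameter is within `tolerance` of the group's first (anchor)
#' member. Fibers in one group share the anchor's interpolated template, so
#' their sensitivity functions can be summed and a single SFAP computed per
#' group. With `tolerance = 0`, each distinct diameter forms its own group
#' and the CNAP is unchanged.
#'
#' @param fibers A [fiber_population()] of a single kind.
#' @param tolerance Diameter tolerance in micrometers (default 0.001).
#' @return A list of groups, each with `diameter` (the anchor diameter) and
#'   `indices` (row indices into `fibers`, ascending by diameter).
#' @export
merge_by_diameter <- function(fibers, tolerance = 0.001) {
  stopifnot(inherits(fibers, "fiber_population"))
  if (tolerance < 0)
    stop_cnap("tolerance must be >= 0", "cnapsim_parameter_error")
  if (length(unique(fibers$kind)) > 1L)
    stop_cnap("cannot group fibers of mixed kinds", "cnapsim_grouping_error")
  if (nrow(fibers) == 0L) return(list())
  ord <- order(fibers$diameter_um)
  d <- fibers$diameter_um[ord]
  groups <- list()
  anchor <- 1L
  start <- 1L
  for (i in seq_along(d)) {
    if (d[i] - d[anchor] > tolerance) {
      groups[[length(groups) + 1L]] <-
        list(diameter = d[anchor], indices = ord[start:(i - 1L)])
      anchor <- i; start <- i
    }
  }
  groups[[length(groups) + 1L]] <-
    list(diameter = d[anchor], indices = ord[start:length(d)])
  groups
}

#' Read a fiber list or diameter histogram from delimited text
#'
#' Fiber lists have columns `diameter_um`, `kind` and optional `x_mm`,
#' `y_mm`, `z_offset_mm`; histograms have columns `bin_left_um`,
#' `bin_right_um`, `count`.
#'
#' @param path CSV path.
#' @param kind Fiber kind for histograms (fiber lists carry their own).
#' @return A data frame (fiber list) or a [fiber_diameter_distribution()].
#' @export
read_fiber_table <- function(path, kind = "unmyelinated") {
  tab <- utils::read.csv(path)
  if (all(c("bin_left_um", "bin_right_um", "count") %in% names(tab))) {
    edges <- c(tab$bin_left_um, tab$bin_right_um[nrow(tab)])
    if (!isTRUE(all.equal(tab$bin_left_um[-1L],
                          tab$bin_right_um[-nrow(tab)], tolerance = 1e-9)))
      stop_cnap("histogram bins must be contiguous", "cnapsim_format_error")
    return(fiber_diameter_distribution(edges, tab$count, kind))
  }
  if (!"diameter_um" %in% names(tab))
    stop_cnap("fiber table needs diameter_um or histogram columns",
              "cnapsim_format_error")
  tab
}

#' Write a diameter histogram as delimited text
#'
#' @param dist A [fiber_diameter_distribution()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fiber_histogram <- function(dist, path) {
  stopifnot(inherits(dist, "fiber_diameter_distribution"))
  n <- length(dist$counts)
  tab <- data.frame(bin_left_um = sprintf("%.17g", dist$bin_edges[seq_len(n)]),
                    bin_right_um = sprintf("%.17g", dist$bin_edges[-1L]),
                    count = dist$counts)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
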