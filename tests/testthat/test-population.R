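# Fiber populations: sampling schemes, CV models, ultrastructure geometry,
# diameter scaling and grouping.

test_that("inverse transform samples stay inside the support and reproduce", {
  single <- fiber_diameter_distribution(c(1, 2), 5L, "unmyelinated")
  d <- inverse_transform_sample(single, 500, seed = 1)
  expect_true(all(d >= 1 & d <= 2))
  expect_identical(inverse_transform_sample(single, 0, seed = 1), numeric(0))
  # bit-reproducible under a fixed seed
  dist <- study_distribution()
  expect_identical(inverse_transform_sample(dist, 1000, seed = 3),
                   inverse_transform_sample(dist, 1000, seed = 3))
  empty <- fiber_diameter_distribution(c(1, 2), 0L, "unmyelinated")
  expect_error(inverse_transform_sample(empty, 5, seed = 1),
               class = "cnapsim_sampling_error")
})

test_that("sample means converge to the distribution mean", {
  dist <- study_distribution()
  centers <- (dist$bin_edges[-1L] + dist$bin_edges[-13L]) / 2
  mu <- sum(centers * dist$counts) / sum(dist$counts)
  m1 <- mean(inverse_transform_sample(dist, 400, seed = 5))
  m2 <- mean(inverse_transform_sample(dist, 40000, seed = 5))
  expect_lt(abs(m2 - mu), abs(m1 - mu) + 0.02)
  expect_lt(abs(m2 - mu), 0.01)
})

test_that("bin-center expansion repeats centers by counts", {
  dist <- fiber_diameter_distribution(c(1, 2, 3), c(2L, 1L), "unmyelinated")
  expect_identical(bin_center_expand(dist), c(1.5, 1.5, 2.5))
  with_zero <- fiber_diameter_distribution(c(1, 2, 3, 4), c(2L, 0L, 1L),
                                           "unmyelinated")
  expect_identical(bin_center_expand(with_zero), c(1.5, 1.5, 3.5))
  # per-measurement bins recover the raw list
  raw <- c(0.8, 1.1, 1.4)
  eps <- 1e-9
  edges <- sort(c(raw - eps, raw + eps))
  narrow <- fiber_diameter_distribution(edges, c(1L, 0L, 1L, 0L, 1L),
                                        "unmyelinated")
  expect_equal(bin_center_expand(narrow), raw, tolerance = 1e-8)
})

test_that("CV models evaluate the published relations", {
  expect_equal(cv_of_diameter(cv_model_myelinated(), 2), 4.01 * 2 - 2.5)
  expect_equal(cv_of_diameter(cv_model_myelinated(), 2), 5.52)
  expect_equal(cv_of_diameter(cv_model_unmyelinated(), 1), 0.70 - 1.9e-3)
  expect_equal(cv_of_diameter(cv_model_unmyelinated(), 1), 0.6981)
  # root of the linear form: non-positive CV is a domain error
  expect_error(cv_of_diameter(cv_model_myelinated(), 2.5 / 4.01),
               class = "cnapsim_domain_error")
})

test_that("deterministic ultrastructure hits the fitted anchor values", {
  expect_equal(ultrastructure_geometry(9.45)$flut_length_um, 44.85)
  expect_equal(ultrastructure_geometry(9.04)$internodal_length_um, 900.88)
  g <- ultrastructure_geometry(2.39)
  expect_equal(g$internodal_axon_diameter_um, 0.55 * 2.39)
  # diameter at which the internodal axon diameter is 1.75 um gives
  # exp(3.2) lamellae
  f <- function(D) ultrastructure_geometry(D)$internodal_axon_diameter_um - 1.75
  D_star <- uniroot(f, c(2, 5), tol = 1e-12)$root
  expect_equal(ultrastructure_geometry(D_star)$n_lamellae, exp(3.2),
               tolerance = 1e-9)
  # STIN segments tile the internode exactly
  expect_equal(g$node_length_um + 2 * g$mysa_length_um +
                 2 * g$flut_length_um + 6 * g$stin_length_um,
               g$internodal_length_um, tolerance = 1e-12)
})

test_that("sub-threshold diameters are an invalid ultrastructure", {
  expect_error(ultrastructure_geometry(0.9), class = "cnapsim_validity_error")
  expect_error(ultrastructure_geometry(1.0), class = "cnapsim_validity_error")
  expect_silent(ultrastructure_geometry(1.013))
})

test_that("deterministic geometry is continuous in diameter", {
  D <- seq(1.05, 9.8, by = 0.005)
  inl <- vapply(D, function(d)
    ultrastructure_geometry(d)$internodal_length_um, numeric(1))
  flut <- vapply(D, function(d)
    ultrastructure_geometry(d)$flut_length_um, numeric(1))
  expect_lt(max(abs(diff(inl))), 1)     # no jumps at 0.005 um resolution
  expect_lt(max(abs(diff(flut))), 0.05)
})

test_that("stochastic ultrastructure is seeded and deterministic mode is not random", {
  m <- ultrastructure_model(stochastic = TRUE)
  a <- ultrastructure_geometry(5, m, seed = 42)
  b <- ultrastructure_geometry(5, m, seed = 42)
  c <- ultrastructure_geometry(5, m, seed = 43)
  expect_identical(a, b)
  expect_false(identical(a$internodal_length_um, c$internodal_length_um))
  expect_identical(ultrastructure_geometry(5), ultrastructure_geometry(5))
})

test_that("diameter scaling rescales CV through the model", {
  pop <- fiber_population(c(2, 3, 4.5), "myelinated")
  scaled <- scale_diameters(pop, 1.1)
  expect_equal(scaled$diameter_um, pop$diameter_um * 1.1)
  expect_equal(scaled$cv_m_per_s, 4.01 * 1.1 * pop$diameter_um - 2.5,
               tolerance = 1e-12)
  expect_equal(scale_diameters(pop, 1)$diameter_um, pop$diameter_um)
  expect_error(scale_diameters(pop, 0), class = "cnapsim_parameter_error")
})

test_that("longitudinal jitter stays within half a compartment spacing", {
  pop <- fiber_population(c(2, 3, 4.5, 6), "myelinated")
  jit <- jitter_z_offsets(pop, seed = 2)
  expect_true(all(abs(jit$z_offset_mm) <= jit$spacing_um * 1e-3 / 2))
  expect_identical(jitter_z_offsets(pop, seed = 2)$z_offset_mm,
                   jit$z_offset_mm)
})

test_that("diameter grouping is greedy with an anchored tolerance", {
  pop1 <- fiber_population(c(1.0000, 1.0005), "unmyelinated")
  expect_length(merge_by_diameter(pop1, 0.001), 1L)
  pop2 <- fiber_population(c(1.000, 1.002), "unmyelinated")
  expect_length(merge_by_diameter(pop2, 0.001), 2L)
  # tolerance 0: one group per distinct diameter
  pop3 <- fiber_population(c(1, 1, 1.5, 2, 2), "unmyelinated")
  g <- merge_by_diameter(pop3, 0)
  expect_length(g, 3L)
  expect_identical(vapply(g, function(x) length(x$indices), integer(1)),
                   c(2L, 1L, 2L))
  # representative is the first (anchor) member
  expect_identical(vapply(g, `[[`, numeric(1), "diameter"), c(1, 1.5, 2))
})

test_that("grouping preserves total sensitivity mass", {
  pop <- study_population(n = 15, seed = 21)
  z <- seq(-3, 3, by = 0.5)
  ws <- lapply(seq_len(nrow(pop)), function(i)
    analytic_point_source_sensitivity(straight_trajectory(z, y = 1 + 0.01 * i),
                                      c(0, 0, 0), 0.16))
  groups <- merge_by_diameter(pop, 0.05)
  merged_total <- Reduce(`+`, lapply(groups, function(g)
    merge_sensitivities(ws[g$indices])$weights))
  individual_total <- Reduce(`+`, lapply(ws, `[[`, "weights"))
  expect_equal(merged_total, individual_total, tolerance = 1e-15)
})

test_that("fiber tables and histograms round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  dist <- study_distribution()
  write_fiber_histogram(dist, path)
  back <- read_fiber_table(path, "unmyelinated")
  expect_s3_class(back, "fiber_diameter_distribution")
  expect_identical(back$bin_edges, dist$bin_edges)
  expect_identical(back$counts, dist$counts)
})
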