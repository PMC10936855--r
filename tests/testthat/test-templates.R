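# Template generation, alignment, representation conversion, diameter grids
# and interpolation.

test_that("synthetic templates start at zero current and are charge balanced", {
  # Vm(0) is exactly the resting potential, so the derived current starts at
  # zero up to the tiny DC term removed for exact charge balance
  tpl <- tiny_template()
  first_rel <- abs(tpl$currents[1L, 1L]) / max(abs(tpl$currents))
  expect_lt(first_rel, 1e-4)
  # charge balance across diameters, kinds and parameter variations
  for (d in c(0.2, 1.0, 4.0)) {
    for (kind in c("unmyelinated", "myelinated")) {
      t2 <- generate_synthetic_template(d, kind, cv = 1,
              params = synthetic_template_params(vm_rate = 6, duration = 5))
      for (p in seq_len(ncol(t2$currents))) {
        integral <- abs(sum(t2$currents[, p]) * t2$sampling_period)
        bound <- 1e-6 * max(abs(t2$currents[, p])) * 5
        expect_lt(integral, bound)
      }
    }
  }
})

test_that("zero-amplitude waveform gives an all-zero template", {
  tpl <- generate_synthetic_template(1, "unmyelinated", cv = 0.7,
           params = synthetic_template_params(vm_amplitude = 0))
  expect_true(all(tpl$currents == 0))
})

test_that("too-short duration for Vm settling is rejected", {
  expect_error(generate_synthetic_template(1, "unmyelinated", cv = 0.7,
                 params = synthetic_template_params(duration = 0.5)),
               class = "cnapsim_validity_error")
})

test_that("myelinated synthetic templates are scaled copies of the node column", {
  tpl <- generate_synthetic_template(3, "myelinated", cv = 9.5)
  expect_identical(ncol(tpl$currents), 11L)
  for (p in 2:11)
    expect_equal(tpl$currents[, p],
                 tpl$currents[, 1L] * cnapsim:::MYELINATED_TYPE_ATTENUATION[p])
})

test_that("alignment puts the nodal maximum at t = 0 and records ref_time", {
  # forced construction: maximum at 0-based sample index 40
  x <- dnorm(seq(-2, 6, by = 0.2), mean = 0.2 * 40 - 2, sd = 0.5)
  tpl <- ap_template(matrix(x, ncol = 1), 0.0025, cv = 1, diameter = 1,
                     kind = "unmyelinated", t0 = 0)
  al <- align_template(tpl)
  expect_equal(al$ref_time, 40 * 0.0025)
  times <- al$t0 + (seq_along(x) - 1L) * al$sampling_period
  expect_equal(times[which.max(x)], 0)
  # idempotence
  expect_equal(align_template(al), al)
})

test_that("alignment is keyed to the NODE column only", {
  n <- 101
  node <- dnorm(seq_len(n), mean = 70, sd = 6)
  early <- dnorm(seq_len(n), mean = 30, sd = 6)  # non-NODE peak earlier
  cur <- cbind(node, early, early, early, early, early,
               early, early, early, early, early)
  tpl <- ap_template(cur, 0.01, cv = 10, diameter = 3, kind = "myelinated")
  al <- align_template(tpl)
  times <- al$t0 + (seq_len(n) - 1L) * al$sampling_period
  expect_equal(times[70], 0)             # anchored at the NODE maximum
})

test_that("a constant anchor column cannot be aligned", {
  tpl <- ap_template(matrix(1, 10, 1), 0.01, cv = 1, diameter = 1,
                     kind = "unmyelinated")
  expect_error(align_template(tpl), class = "cnapsim_alignment_error")
})

test_that("monopolar/dipolar conversion is an exact round trip", {
  set.seed(42)
  for (dims in list(c(5, 1), c(8, 3), c(50, 7), c(12, 11))) {
    X <- matrix(rnorm(prod(dims)), dims[1L], dims[2L])
    D <- monopolar_to_dipolar(X)
    expect_equal(dim(D), dim(X))
    expect_equal(dipolar_to_monopolar(D), X, tolerance = 1e-14)
  }
  # single compartment: dipolar is the negated input
  x1 <- matrix(rnorm(6), ncol = 1)
  expect_equal(monopolar_to_dipolar(x1), -x1)
  expect_equal(dipolar_to_monopolar(x1), -x1)
})

test_that("spatially zero-sum currents have a vanishing final dipolar column", {
  set.seed(7)
  X <- matrix(rnorm(60), 10, 6)
  X[, 6] <- -rowSums(X[, 1:5])
  D <- monopolar_to_dipolar(X)
  expect_equal(D[, 6], rep(0, 10), tolerance = 1e-13)
})

test_that("monopolar and dipolar weighted sums agree on any finite matrix", {
  set.seed(8)
  X <- matrix(rnorm(350), 50, 7)
  w <- rnorm(7)
  ws <- sensitivity_fn(matrix(w, ncol = 1), 1:7)
  dw <- differentiate_for_dipole(ws)
  f_mono <- loop_sfap(X, w)
  f_dip <- loop_sfap(monopolar_to_dipolar(X), dw$weights[, 1L])
  expect_lt(relerr(f_dip, f_mono), 1e-12)
})

test_that("geometric diameter grids reproduce the published counts", {
  g_un <- build_diameter_grid(0.105, 1.896, 3.06)
  g_my <- build_diameter_grid(1.013, 9.809, 1.19)
  expect_length(g_un, 97L)
  expect_length(g_my, 193L)
  expect_identical(g_un[c(1L, 97L)], c(0.105, 1.896))
  expect_identical(g_my[c(1L, 193L)], c(1.013, 9.809))
  # log-equispacing: consecutive ratios equal to 1e-12 relative
  for (g in list(g_un, g_my)) {
    r <- g[-1L] / g[-length(g)]
    expect_lt(max(abs(r / r[1L] - 1)), 1e-12)
  }
  # degenerate range
  expect_identical(build_diameter_grid(2, 2, 5), 2)
  expect_error(build_diameter_grid(3, 2, 5), class = "cnapsim_parameter_error")
})

test_that("interpolation is exact at grid diameters and averages between them", {
  bank <- study_bank(increment_pct = 20)
  d <- bank$diameters
  # grid diameter: stored template, bit for bit
  expect_identical(interpolate_template(bank, d[3L]), bank$templates[[3L]])
  # midpoint: elementwise mean (templates share the native grid)
  mid <- (d[2L] + d[3L]) / 2
  ti <- interpolate_template(bank, mid)
  expect_equal(ti$currents,
               (bank$templates[[2L]]$currents +
                  bank$templates[[3L]]$currents) / 2, tolerance = 1e-12)
  expect_equal(ti$cv, (bank$templates[[2L]]$cv + bank$templates[[3L]]$cv) / 2)
  expect_equal(ti$diameter, mid)
})

test_that("interpolation weights sum to one and bracket the result", {
  bank <- study_bank(increment_pct = 20)
  d <- bank$diameters
  set.seed(9)
  for (rep in 1:20) {
    i <- sample(length(d) - 1L, 1L)
    di <- runif(1, d[i], d[i + 1L])
    w1 <- (d[i + 1L] - di) / (d[i + 1L] - d[i])
    w2 <- (di - d[i]) / (d[i + 1L] - d[i])
    expect_equal(w1 + w2, 1, tolerance = 1e-12)
    ti <- interpolate_template(bank, di)
    expect_equal(ti$currents,
                 w1 * bank$templates[[i]]$currents +
                   w2 * bank$templates[[i + 1L]]$currents, tolerance = 1e-12)
    # monotone: every sample lies between the bracketing samples
    lo <- pmin(bank$templates[[i]]$currents, bank$templates[[i + 1L]]$currents)
    hi <- pmax(bank$templates[[i]]$currents, bank$templates[[i + 1L]]$currents)
    expect_true(all(ti$currents >= lo - 1e-15 & ti$currents <= hi + 1e-15))
  }
})

test_that("out-of-range diameters are never extrapolated", {
  bank <- study_bank(increment_pct = 20)
  expect_error(interpolate_template(bank, 0.1),
               class = "cnapsim_extrapolation_error")
  expect_error(interpolate_template(bank, 5),
               class = "cnapsim_extrapolation_error")
})

test_that("template bank text container round-trips exactly", {
  dir <- withr::local_tempdir()
  bank <- synthetic_template_bank("unmyelinated",
                                  diameters = build_diameter_grid(0.4, 1.2, 30))
  write_template_bank(bank, dir)
  back <- read_template_bank(dir)
  expect_equal(back$diameters, bank$diameters)
  for (i in seq_along(bank$templates)) {
    expect_identical(back$templates[[i]]$currents, bank$templates[[i]]$currents)
    expect_identical(back$templates[[i]]$cv, bank$templates[[i]]$cv)
    expect_identical(back$templates[[i]]$t0, bank$templates[[i]]$t0)
  }
})
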