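# SFAP engine: brute-force oracle, sampling-period selection, shift filters,
# time/frequency-domain reconstruction, multitype summation.

test_that("brute-force summation matches an independent double loop", {
  set.seed(20)
  values <- matrix(rnorm(40), 8, 5)
  w <- rnorm(5)
  f <- sfap_brute_force(values, w, sampling_period = 0.01)
  expect_lt(relerr(f$samples, loop_sfap(values, w)), 1e-12)
  # zero currents give a zero SFAP
  f0 <- sfap_brute_force(matrix(0, 8, 5), w, sampling_period = 0.01)
  expect_true(all(f0$samples == 0))
  # single compartment, unit sample: weight appears directly (mA * V/mA = V)
  i1 <- matrix(c(1, 0, 0), ncol = 1)
  f1 <- sfap_brute_force(i1, 2, sampling_period = 0.01)
  expect_identical(f1$samples, c(2, 0, 0))
  expect_error(sfap_brute_force(values, rnorm(4), sampling_period = 0.01),
               class = "cnapsim_contract_error")
})

test_that("sampling-period selection yields exact integer shifts", {
  # L = 1 mm at 1 m/s with T_max = 0.3 ms: 4 shifts of 0.25 ms
  cs <- choose_sampling_period(1000, 1, T_max = 0.3)
  expect_identical(cs$n_shift, 4L)
  expect_equal(cs$T_ms, 0.25)
  # minimal shift when T_max allows the full inter-compartment delay
  cs1 <- choose_sampling_period(100, 1, T_max = 0.5)
  expect_identical(cs1$n_shift, 1L)
  expect_equal(cs1$T_ms, 0.1)
  # bandwidth constraint pushes the rate up
  cs2 <- choose_sampling_period(1000, 1, T_max = 0.3,
                                template_bandwidth_khz = 10)
  expect_gte(1 / cs2$T_ms, 20)
  set.seed(21)
  for (rep in 1:25) {
    L <- runif(1, 20, 2000); V <- runif(1, 0.3, 40)
    cs <- choose_sampling_period(L, V, T_max = runif(1, 0.01, 0.4))
    s <- L * 1e-3 / (cs$T_ms * V)
    expect_lt(abs(s - round(s)), 1e-9)
  }
})

test_that("zero-inserted filters have the stated layout", {
  # M = 2, unit weights, 3 zeros inserted
  f <- build_shift_filter(c(1, 1), L = 300, T = 0.1, V = 1, K = 1)
  expect_identical(f$coefficients, c(1, 0, 0, 1))
  set.seed(22)
  for (rep in 1:20) {
    M <- sample(2:40, 1); ns <- sample(1:20, 1)
    w <- rnorm(M)
    filt <- build_shift_filter(w, L = ns * 10, T = 0.01, V = 1, K = 1)
    expect_identical(filt$n_shift, ns)
    expect_length(filt$coefficients, (M - 1L) * ns + 1L)
    expect_identical(filt$coefficients[(seq_len(M) - 1L) * ns + 1L], w)
  }
  # non-integer shift is refused, not rounded
  expect_error(build_shift_filter(c(1, 1), L = 95, T = 0.03, V = 1),
               class = "cnapsim_contract_error")
})

test_that("simultaneous arrival collapses the filter to a weight sum", {
  tpl <- tiny_template(cv = 1)
  # infinite-speed limit: L/(T*V) rounds to zero shifts
  filt <- build_shift_filter(c(0.3, 0.5, 0.2), L = 1e-9, T = 0.0025, V = 1e9)
  expect_identical(filt$n_shift, 0L)
  f <- sfap_time_domain(tpl, filt)
  expect_lt(relerr(f$samples[seq_len(nrow(tpl$currents))],
                   tpl$currents[, 1L] * 1.0), 1e-12)
})

test_that("reconstruction places shifted template copies", {
  tpl <- resample_template(tiny_template(cv = 1), 0.05)
  rec <- reconstruct_current_matrix(tpl, L = 100, M = 1, K = 1)
  expect_equal(rec$values[, 1L], tpl$currents[, 1L])
  rec5 <- reconstruct_current_matrix(tpl, L = 100, M = 5, K = 3)
  ns <- 2L  # 100 um at 1 m/s and 0.05 ms
  N <- nrow(tpl$currents)
  expect_equal(rec5$values[(3L - 1L) * ns + seq_len(N), 3L],
               tpl$currents[, 1L])
  expect_equal(rec5$t0, tpl$t0 - ns * 2 * 0.05)
})

test_that("filter SFAPs equal brute force on the reconstruction", {
  # randomized fixtures over M, n_shift, kind and representation
  set.seed(23)
  for (rep in 1:12) {
    kind <- sample(c("unmyelinated", "myelinated"), 1)
    cv <- if (kind == "unmyelinated") runif(1, 0.4, 1.2) else runif(1, 3, 30)
    d <- if (kind == "unmyelinated") runif(1, 0.2, 1.8) else runif(1, 1.2, 9)
    M <- sample(2:40, 1)
    ns <- sample(1:20, 1)
    T <- round(runif(1, 0.01, 0.08), 6)
    L <- ns * T * cv * 1e3
    K <- sample(seq_len(M), 1)
    tpl <- resample_template(
      generate_synthetic_template(d, kind, cv, sampling_period = 0.0025), T)
    w <- rnorm(M)
    for (representation in c("monopolar", "dipolar")) {
      tp <- tpl
      wf <- w
      if (representation == "dipolar") {
        tp <- cnapsim:::dipolar_template_from_monopolar(tpl, ns)
        ws <- differentiate_for_dipole(sensitivity_fn(matrix(w, ncol = 1),
                                                      seq_len(M)))
        wf <- ws$weights[, 1L]
      }
      rec <- reconstruct_current_matrix(tp, L, M, K, T)
      bf <- sfap_brute_force(rec, wf)
      filt <- build_shift_filter(wf, L, T, cv, K)
      td <- sfap_time_domain(tp, filt)
      fd <- sfap_freq_domain(tp, filt)
      expect_lt(relerr(td$samples, bf$samples), 1e-9)
      expect_lt(relerr(fd$samples, bf$samples), 1e-9)
      expect_equal(td$t0, bf$t0)
      expect_equal(fd$t0, bf$t0)
    }
  }
})

test_that("the SFAP is linear in the sensitivity weights", {
  tpl <- resample_template(tiny_template(cv = 1), 0.05)
  w <- rnorm(7)
  f1 <- sfap_time_domain(tpl, build_shift_filter(w, 100, 0.05, 1, K = 4))
  f2 <- sfap_time_domain(tpl, build_shift_filter(2 * w, 100, 0.05, 1, K = 4))
  expect_lt(relerr(f2$samples, 2 * f1$samples), 1e-12)
})

test_that("frequency- and time-domain paths agree at equal rates", {
  set.seed(24)
  tpl <- resample_template(tiny_template(cv = 0.8), 0.04)
  filt <- build_shift_filter(rnorm(12), L = 160, T = 0.04, V = 0.8, K = 5)
  td <- sfap_time_domain(tpl, filt)
  fd <- sfap_freq_domain(tpl, filt)
  expect_lt(relerr(fd$samples, td$samples), 1e-9)
  zero <- build_shift_filter(numeric(12), L = 160, T = 0.04, V = 0.8, K = 5)
  expect_true(all(abs(sfap_freq_domain(tpl, zero)$samples) < 1e-20))
})

test_that("cross-rate frequency path matches band-limited time convolution", {
  # Ricker template sampled at T_f/2; its spectrum is negligible above the
  # coarse Nyquist, so band-limited product equals plain convolution with the
  # zero-upsampled filter
  Tt <- 0.01; Tf <- 0.02
  tpl <- ricker_template(sampling_period = Tt, sigma_ms = 0.12, cv = 1)
  set.seed(25)
  M <- 6; ns <- 3L
  w <- rnorm(M)
  filt <- build_shift_filter(w, L = ns * Tf * 1e3, T = Tf, V = 1, K = 2)
  fd <- sfap_freq_domain(tpl, filt)
  expect_equal(fd$sampling_period, Tt)
  # time-domain reference at the fine rate: upsample the filter by zero
  # insertion (its impulses sit on the fine grid exactly)
  up <- numeric((length(filt$coefficients) - 1L) * 2L + 1L)
  up[(seq_along(filt$coefficients) - 1L) * 2L + 1L] <- filt$coefficients
  ref <- convolve(tpl$currents[, 1L], rev(up), type = "open")
  expect_lt(relerr(fd$samples, ref), 1e-6)
})

test_that("multitype SFAP reduces to the single-type path for a node-only w", {
  tpl <- resample_template(
    generate_synthetic_template(4, "myelinated", cv = 13.54,
                                sampling_period = 0.0025), 0.02)
  M <- 8
  w <- matrix(0, M, 11)
  w[, 1L] <- rnorm(M)
  ws <- sensitivity_fn(w, seq_len(M))
  L <- 5L * 0.02 * 13.54 * 1e3
  f_multi <- sfap_multitype(tpl, ws, L, 0.02, 13.54, K = 3)
  f_single <- sfap_freq_domain(tpl,
    build_shift_filter(w[, 1L], L, 0.02, 13.54, K = 3), type = 1L)
  expect_lt(relerr(f_multi$samples, f_single$samples), 1e-12)
})

test_that("multitype SFAP equals brute force over the full reconstruction", {
  set.seed(26)
  cv <- 13.54
  T <- 0.02
  tpl <- resample_template(
    generate_synthetic_template(4, "myelinated", cv = cv,
                                sampling_period = 0.0025), T)
  M <- 8; ns <- 5L
  L <- ns * T * cv * 1e3
  w <- matrix(rnorm(M * 11), M, 11)
  ws <- sensitivity_fn(w, seq_len(M))
  geom <- ultrastructure_geometry(4)
  offsets <- cnapsim:::compartment_type_offsets(geom)
  K <- 4L
  f_multi <- sfap_multitype(tpl, ws, L, T, cv, K, type_offsets_mm = offsets)
  # oracle: per-type reconstruction with the same fractional pre-delay,
  # brute-force weighted and summed over types
  oracle <- NULL
  for (p in 1:11) {
    tp <- tpl
    if (offsets[p] != 0)
      tp$currents[, p] <- cnapsim:::fractional_delay(tpl$currents[, p],
                                                     (offsets[p] / cv) / T)
    rec <- reconstruct_current_matrix(tp, L, M, K, T, type = p)
    f_p <- sfap_brute_force(rec, w[, p])
    oracle <- if (is.null(oracle)) f_p else cnapsim:::add_signals(oracle, f_p)
  }
  expect_lt(relerr(f_multi$samples, oracle$samples), 1e-9)
  # permuting type order together with w columns leaves the SFAP unchanged
  perm <- sample(1:11)
  tpl_p <- tpl; tpl_p$currents <- tpl$currents[, perm]
  ws_p <- sensitivity_fn(w[, perm], seq_len(M))
  f_perm <- sfap_multitype(tpl_p, ws_p, L, T, cv, K,
                           type_offsets_mm = offsets[perm])
  expect_lt(relerr(f_perm$samples, f_multi$samples), 1e-12)
})
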