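test_that("no modulation means identically zero true PPV", {
  spec <- ppv_spec(duration = 20,
                   mod_coeffs = array(0, dim = c(2, 3, 2)), noise_std = 0)
  sim <- ppv_simulate(spec)
  expect_equal(max(abs(sim$truth$ppv)), 0)
  expect_equal(max(abs(sim$truth$eps_mu - sim$truth$eps_ell)), 0)
})

test_that("default spec carries a constant 15 percent true PPV", {
  # uniform first-harmonic modulation of depth m on every partial gives
  # eps_mu/eps_ell = (1 + m)/(1 - m), i.e. PPV = 200 m = 15 % for m = 0.075
  sim <- ppv_simulate(ppv_spec(duration = 30))
  expect_equal(sim$truth$ppv, rep(15, length(sim$time)), tolerance = 1e-9)
})

test_that("per-cycle pulse pressures of the rendered waveform match the true PP envelopes", {
  # brute-force oracle: rasterize the noise-free waveform densely in time,
  # measure each beat's PP directly, and compare the per-cycle extremes
  # with the analytic PP envelope at the matching time.  A high beat-to-
  # cycle ratio keeps the discrete beats close to the modulation extrema
  # (beat quantization error ~ m (1 - cos(pi f_r / f_c)) of the swing).
  spec <- ppv_spec(duration = 50, resp_freq = 0.12, card_freq = 2.2,
                   noise_std = 0)
  fs_dense <- 400
  n <- spec$duration * fs_dense
  t <- (seq_len(n) - 1L) / fs_dense
  layout <- coef_layout(spec$n_card, spec$n_resp)
  coefs <- flatten_coefs(spec$resp_coeffs, spec$card_coeffs,
                         spec$mod_coeffs, layout)
  thr <- 2 * pi * spec$resp_freq * t
  thc <- 2 * pi * spec$card_freq * t
  y <- abp_measure(thr, thc, coefs, layout)$y
  env <- envelope_traces(coefs, thr, layout, 256)
  # beat-by-beat PP of the baseline-free waveform
  beat <- floor(thc / (2 * pi))
  pp_beat <- tapply(y - env$gamma, beat, function(z) max(z) - min(z))
  beat_mid <- tapply(t, beat, function(z) z[ceiling(length(z) / 2)])
  # per respiratory cycle, the largest/smallest beat PP occurs at the
  # modulation extremum, where the PP envelopes are flat; compare there
  cyc <- floor(thr / (2 * pi))
  beat_cyc <- floor(stats::approx(t, thr, xout = beat_mid,
                                  ties = "ordered")$y / (2 * pi))
  for (cc in unique(cyc)[2:(max(cyc) - 1)]) {
    b_in <- which(beat_cyc == cc)
    i_in <- which(cyc == cc)
    expect_lt(abs(max(pp_beat[b_in]) - max(env$eps_mu[i_in])) /
                max(env$eps_mu[i_in]), 0.005)
    expect_lt(abs(min(pp_beat[b_in]) - min(env$eps_ell[i_in])) /
                max(env$eps_mu[i_in]), 0.005)
  }
})

test_that("truth is seed-invariant while the noise realization is not", {
  s1 <- ppv_simulate(ppv_spec(duration = 10, rng_seed = 1))
  s2 <- ppv_simulate(ppv_spec(duration = 10, rng_seed = 2))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$clean, s2$clean)
  expect_false(identical(s1$signal, s2$signal))
  # and the same seed is fully reproducible
  s1b <- ppv_simulate(ppv_spec(duration = 10, rng_seed = 1))
  expect_identical(s1$signal, s1b$signal)
})

test_that("frequency profiles must stay inside the configured ranges", {
  expect_error(ppv_simulate(ppv_spec(duration = 10, resp_freq = 0.6)),
               "respiratory frequency profile")
  expect_error(
    ppv_simulate(ppv_spec(duration = 10,
                          card_freq = list(type = "chirp", from = 1,
                                           to = 2.5))),
    "cardiac frequency profile")
  expect_error(ppv_spec(mod_coeffs = array(0.6, dim = c(2, 3, 2))),
               "modulation too deep")
})

test_that("true PPV interpolates linearly between samples", {
  sim <- ppv_simulate(ppv_spec(duration = 10))
  expect_equal(truth_ppv_at(sim, sim$time[17]), sim$truth$ppv[17])
  tmid <- (sim$time[5] + sim$time[6]) / 2
  expect_equal(truth_ppv_at(sim, tmid),
               (sim$truth$ppv[5] + sim$truth$ppv[6]) / 2)
  expect_equal(truth_ppv_at(sim, c(1, 2)), c(15, 15), tolerance = 1e-9)
  expect_error(truth_ppv_at(sim, 11), "outside")
})

test_that("doubling the cardiac coefficients quadruples the cardiac band power", {
  base <- ppv_spec(duration = 60, noise_std = 0)
  double <- ppv_spec(duration = 60, noise_std = 0,
                     card_coeffs = 2 * base$card_coeffs)
  band_power <- function(sim, f_lo = 1.0, f_hi = 1.4) {
    sp <- stats::spec.pgram(stats::ts(sim$clean, frequency = 40),
                            plot = FALSE, taper = 0, detrend = TRUE)
    sum(sp$spec[sp$freq >= f_lo & sp$freq <= f_hi])
  }
  ratio <- band_power(ppv_simulate(double)) / band_power(ppv_simulate(base))
  expect_lt(abs(ratio - 4), 0.4)
})

test_that("simulated records round-trip through CSV ingestion", {
  sim <- ppv_simulate(ppv_spec(duration = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sim_csv(sim, path)
  rec <- read_signal(path)
  expect_equal(rec$fs, 40, tolerance = 1e-9)
  expect_identical(rec$samples, sim$signal)
})
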