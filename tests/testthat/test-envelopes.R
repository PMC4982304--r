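test_that("envelopes of a single unmodulated harmonic are gamma plus/minus A", {
  layout <- coef_layout(1, 1)
  x <- numeric(layout$d)
  x[layout$r1] <- 2          # gamma = 2 cos(theta_r)
  x[layout$c1] <- 5          # A = 5
  thr <- c(0, pi / 3, 1.7)
  env <- envelope_traces(x, thr, layout)
  gam <- 2 * cos(thr)
  expect_equal(env$e_mu, gam + 5, tolerance = 1e-9)
  expect_equal(env$e_ell, gam - 5, tolerance = 1e-9)
  expect_equal(env$theta_c_max, rep(0, 3), tolerance = 1e-6)
  expect_equal(env$theta_c_min, rep(pi, 3), tolerance = 1e-6)
})

test_that("degenerate cases collapse the envelopes", {
  layout <- coef_layout(3, 2)
  # all cardiac coefficients zero: both ABP envelopes equal gamma
  x <- numeric(layout$d)
  x[layout$r1] <- c(3, 1)
  thr <- seq(0, 2 * pi, length.out = 17)
  env <- envelope_traces(x, thr, layout)
  expect_equal(env$e_mu, env$gamma)
  expect_equal(env$e_ell, env$gamma)
  expect_equal(env$ppv, rep(0, 17))
  # all modulation zero: PP envelopes both equal the total PP swing
  x2 <- numeric(layout$d)
  x2[layout$c1] <- c(30, 12, 6)
  env2 <- envelope_traces(x2, thr, layout)
  swing <- rowSums(env2$kappa_max - env2$kappa_min)
  expect_equal(env2$eps_mu, swing, tolerance = 1e-9)
  expect_equal(env2$eps_ell, swing, tolerance = 1e-9)
})

test_that("single-harmonic modulation scales the PP envelopes by 1 +/- m", {
  layout <- coef_layout(1, 1)
  x <- numeric(layout$d)
  x[layout$c1] <- 10
  x[layout$m1] <- 0.1
  env <- envelope_traces(x, 0.4, layout)
  pp0 <- 20  # unmodulated swing 2 A
  expect_equal(env$eps_mu, 1.1 * pp0, tolerance = 1e-9)
  expect_equal(env$eps_ell, 0.9 * pp0, tolerance = 1e-9)
  expect_equal(env$ppv, 100 * (1.1 - 0.9) / 1, tolerance = 1e-9)
})

test_that("continuous PPV follows the normalized-swing formula", {
  expect_equal(ppv_continuous(110, 90), 20)
  expect_equal(ppv_continuous(50, 50), 0)
  expect_equal(ppv_continuous(33, 27), 20)   # scale invariance
  expect_equal(ppv_continuous(c(0, 44), c(0, 36)), c(0, 20))
  expect_error(ppv_continuous(-1, 0), "nonnegative")
})

test_that("PPV is invariant to uniform scaling of the signal", {
  layout <- coef_layout(4, 2)
  set.seed(5)
  for (rep in 1:10) {
    x <- random_coef_state(layout, amp = 3)
    thr <- runif(4, 0, 2 * pi)
    e1 <- envelope_traces(x, thr, layout)
    s <- runif(1, 0.1, 10)
    xs <- x
    xs[c(layout$r1, layout$r2, layout$c1, layout$c2)] <-
      s * x[c(layout$r1, layout$r2, layout$c1, layout$c2)]
    e2 <- envelope_traces(xs, thr, layout)
    expect_equal(e2$ppv, e1$ppv, tolerance = 1e-8)
  }
})

test_that("the signal always lies between its envelopes", {
  layout <- coef_layout(5, 2)
  set.seed(9)
  for (rep in 1:20) {
    x <- random_coef_state(layout, amp = 2)
    thr <- runif(1, 0, 2 * pi)
    thc <- runif(50, 0, 2 * pi)
    env <- envelope_traces(x, thr, layout)
    y <- abp_measure(rep(thr, 50), thc, matrix(x, 50, layout$d, byrow = TRUE),
                     layout)$y
    expect_true(all(y <= env$e_mu + 1e-9))
    expect_true(all(y >= env$e_ell - 1e-9))
  }
})

test_that("grid-plus-refine matches a dense-grid search on random states", {
  layout <- coef_layout(5, 2)
  set.seed(21)
  for (rep in 1:50) {
    x <- random_coef_state(layout, amp = 1)
    thr <- runif(1, 0, 2 * pi)
    env <- envelope_traces(x, thr, layout)
    oracle <- dense_envelope_oracle(x, thr, layout, npts = 20000L)
    scale <- max(abs(c(oracle$e_mu_card, oracle$e_ell_card)))
    expect_lt(abs((env$e_mu - env$gamma) - oracle$e_mu_card) / scale, 1e-4)
    expect_lt(abs((env$e_ell - env$gamma) - oracle$e_ell_card) / scale, 1e-4)
  }
})

test_that("per-cycle PPV implements the classic definition", {
  peaks <- data.frame(time_s = c(1, 2, 3, 4), value = c(120, 124, 116, 120))
  troughs <- data.frame(time_s = peaks$time_s - 0.4, value = rep(80, 4))
  out <- ppv_per_cycle(peaks, troughs, cycles = c(0, 5))
  expect_equal(out$pp_max, 44)
  expect_equal(out$pp_min, 36)
  expect_equal(out$ppv_pct, 100 * 8 / 40)
  # all equal pulse pressures give zero PPV
  peaks2 <- data.frame(time_s = 1:4, value = 120)
  out2 <- ppv_per_cycle(peaks2, troughs, cycles = c(0, 5))
  expect_equal(out2$ppv_pct, 0)
  # a cycle with fewer than two beats is flagged and skipped
  out3 <- ppv_per_cycle(peaks, troughs, cycles = c(0, 3.5, 3.7, 5))
  expect_false(out3$valid[2])
  expect_true(is.na(out3$ppv_pct[2]))
  expect_true(out3$valid[1])
})

test_that("cycle boundaries come from 2pi crossings of the unwrapped angle", {
  t <- seq(0, 20, by = 1 / 40)
  theta <- 2 * pi * 0.25 * t   # exactly 0.25 Hz
  b <- resp_cycle_boundaries(t, theta)
  expect_equal(b, seq(0, 20, by = 4), tolerance = 1e-9)
})
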