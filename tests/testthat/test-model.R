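test_that("frequency clip is identity inside the range and reflects overshoot", {
  expect_equal(clip_frequency(0.3, 0.1, 0.5), 0.3)
  expect_equal(clip_frequency(0.55, 0.1, 0.5), 0.45)
  expect_equal(clip_frequency(0.05, 0.1, 0.5), 0.15)
  # idempotent on in-range values, result always in (f_min, f_max]
  set.seed(42)
  f <- runif(200, 0.1 - 0.39, 0.5 + 0.39)
  g <- clip_frequency(f, 0.1, 0.5)
  expect_true(all(g > 0.1 - 1e-12 & g <= 0.5))
  expect_equal(clip_frequency(g, 0.1, 0.5), g)
  expect_error(clip_frequency(0.3, 0.5, 0.1), "bounds")
  expect_error(clip_frequency(2, 0.1, 0.5), "overshoot")
})

test_that("flattening is a bijection with the documented block order", {
  layout <- coef_layout(4, 3)
  expect_identical(layout$d, 2L * 3L + 2L * 4L + 2L * 4L * 3L)
  set.seed(7)
  for (rep in 1:20) {
    resp <- matrix(rnorm(6), 2)
    card <- matrix(rnorm(8), 2)
    mod <- array(rnorm(24), dim = c(2, 4, 3))
    x <- flatten_coefs(resp, card, mod, layout)
    back <- unflatten_coefs(x, layout)
    expect_equal(back$resp, resp)
    expect_equal(back$card, card)
    expect_equal(back$mod, mod)
  }
  # spot-check the ordering rule: m1 runs cardiac-major, respiratory-minor
  x <- flatten_coefs(matrix(0, 2, 3), matrix(0, 2, 4),
                     array(seq_len(24), dim = c(2, 4, 3)), layout)
  expect_equal(unname(x[layout$m1[1:3]]), c(1, 9, 17))  # k = 1, j = 1..3
})

test_that("measurement model reproduces the worked harmonic cases", {
  layout <- coef_layout(2, 1)
  zero <- numeric(layout$d)
  m0 <- abp_measure(0.3, 0.7, zero, layout)
  expect_equal(m0$y, 0)
  expect_equal(m0$gamma, 0)
  expect_equal(drop(m0$rho), c(1, 1))
  expect_equal(drop(m0$kappa), c(0, 0))

  x1 <- zero
  x1[layout$c1[1]] <- 1
  expect_equal(abp_measure(0, 0, x1, layout)$y, 1)

  x2 <- x1
  x2[layout$m1[1]] <- 0.5
  expect_equal(abp_measure(0, 0, x2, layout)$y, 1.5)
})

test_that("measurement is 2pi-periodic in both angles", {
  layout <- coef_layout(5, 2)
  set.seed(11)
  for (rep in 1:20) {
    x <- random_coef_state(layout)
    tr <- runif(1, 0, 2 * pi)
    tc <- runif(1, 0, 2 * pi)
    y0 <- abp_measure(tr, tc, x, layout)$y
    expect_lt(abs(abp_measure(tr + 2 * pi, tc, x, layout)$y - y0), 1e-9)
    expect_lt(abs(abp_measure(tr, tc + 2 * pi, x, layout)$y - y0), 1e-9)
  }
})

test_that("R and C++ measurement paths agree", {
  layout <- coef_layout(5, 2)
  set.seed(3)
  for (rep in 1:25) {
    x <- random_coef_state(layout)
    tr <- runif(1, 0, 2 * pi)
    tc <- runif(1, 0, 2 * pi)
    mr <- abp_measure(tr, tc, x, layout)
    mc <- ppvtrack:::cpp_measure(tr, tc, x, 5L, 2L)
    expect_equal(mr$y, mc$y, tolerance = 1e-12)
    expect_equal(drop(mr$rho), drop(mc$rho), tolerance = 1e-12)
    expect_equal(drop(mr$kappa), drop(mc$kappa), tolerance = 1e-12)
    expect_equal(unname(abp_measure_gradient(tr, tc, x, layout)),
                 drop(ppvtrack:::cpp_gradient(tr, tc, x, 5L, 2L)), tolerance = 1e-12)
  }
})

test_that("gradient has the expected structure at degenerate states", {
  layout <- coef_layout(3, 2)
  H0 <- abp_measure_gradient(0.4, 0.9, numeric(layout$d), layout)
  expect_equal(unname(H0[layout$r1]), cos(1:2 * 0.4))
  expect_equal(unname(H0[layout$r2]), sin(1:2 * 0.4))
  expect_equal(unname(H0[layout$c1]), cos(1:3 * 0.9))  # rho = 1
  expect_true(all(H0[c(layout$m1, layout$m2)] == 0))   # kappa = 0

  # m-entry equals the cardiac partial: c11 = 2 at theta = 0 gives kappa1 = 2
  x <- numeric(layout$d)
  x[layout$c1[1]] <- 2
  x[layout$m1[1]] <- 0.3
  H <- abp_measure_gradient(0, 0, x, layout)
  expect_equal(unname(H[layout$m1[1]]), 2)
})

test_that("kinematic propagation follows the angle/frequency recursions", {
  cfg <- ppv_config(sample_period = 1 / 40)
  kin <- list(f_resp = 0.25, f_card = 1, f_resp_mean = 0.25,
              f_card_mean = 1.2, theta_resp = 0.5, theta_card = 0)
  out <- propagate_kinematics(kin, cfg)
  expect_equal(out$theta_card, 2 * pi / 40)
  # fixed point: f = fbar is preserved for any ar_coeff
  for (a in c(0.5, 0.95, 1)) {
    cfg$ar_coeff <- a
    out <- propagate_kinematics(kin, cfg)
    expect_equal(out$f_resp, 0.25)
  }
  # reflection at the upper bound of the mean-frequency walk
  kin$f_card_mean <- cfg$f_card_max
  out <- propagate_kinematics(kin, cfg,
                              noise = c(u_fbar_resp = 0, u_fbar_card = 0.01,
                                        u_f_resp = 0, u_f_card = 0))
  expect_equal(out$f_card_mean, cfg$f_card_max - 0.01)
  # zero noise is deterministic and conserves the mean frequencies
  out1 <- propagate_kinematics(kin, cfg)
  out2 <- propagate_kinematics(kin, cfg)
  expect_identical(out1, out2)
  expect_equal(out1$f_resp_mean, kin$f_resp_mean)
})

test_that("coefficient prediction adds the diagonal process noise", {
  cfg <- resolve_config(ppv_config(n_cardiac_harmonics = 3,
                                   n_resp_harmonics = 2),
                        rnorm(500), sample_rate = 40)
  layout <- coef_layout(3, 2)
  st <- list(mean = rnorm(layout$d), cov = diag(0.5, layout$d))
  cfg0 <- cfg
  cfg0$q_resp_coeff <- cfg0$q_card_coeff <- cfg0$q_mod_coeff <- 0
  expect_equal(propagate_coefficients(st, cfg0, layout)$cov, st$cov)
  # after n predictions the diagonal grows by exactly n * Q
  n <- 7
  st_n <- st
  for (i in seq_len(n)) st_n <- propagate_coefficients(st_n, cfg, layout)
  expect_equal(st_n$mean, st$mean)
  expect_equal(diag(st_n$cov),
               diag(st$cov) + n * coef_process_noise(cfg, layout))
  # every cardiac-block diagonal entry grows by exactly q_card_coeff
  st1 <- propagate_coefficients(st, cfg, layout)
  expect_equal(diag(st1$cov)[layout$c1] - diag(st$cov)[layout$c1],
               rep(cfg$q_card_coeff, 3))
})
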