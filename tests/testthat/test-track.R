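resolved_cfg <- function(...) {
  resolve_config(ppv_config(...), sin(2 * pi * 1.2 * (0:799) / 40) * 20 + 90,
                 sample_rate = 40)
}

test_that("initialization spreads particles evenly with uniform scores", {
  cfg <- resolved_cfg(n_cardiac_harmonics = 3, n_resp_harmonics = 2,
                      n_particles_per_space = 5)
  st <- ppvtrack:::with_seed(1, ppv_init_state(cfg))
  grid <- seq(cfg$f_resp_min, cfg$f_resp_max, length.out = 5)
  spacing <- diff(grid)[1]
  expect_true(all(abs(st$resp$f - grid) <= 0.02 * spacing + 1e-12))
  expect_equal(st$resp$fbar, st$resp$f)
  expect_equal(st$card$theta, rep(0, 5))
  # uniform prior: logsumexp of the scores is 0
  expect_equal(log(sum(exp(st$resp$log_alpha))), 0, tolerance = 1e-12)
  expect_equal(log(sum(exp(st$card$log_alpha))), 0, tolerance = 1e-12)
  # determinism of initialization
  st2 <- ppvtrack:::with_seed(1, ppv_init_state(cfg))
  expect_identical(st, st2)
})

test_that("the EKF update reproduces textbook Kalman arithmetic", {
  # one cardiac harmonic, no respiratory block: at theta_c = 0 the model is
  # y = c11, so H = (1, 0); prior N(0, I), r = 1, y = 2
  up <- ppvtrack:::cpp_ekf_update(c(0, 0), diag(2), 0, 0, 2, 1, 1L, 0L)
  expect_equal(drop(up$mean), c(1, 0))
  expect_equal(up$cov[1, 1], 0.5)
  expect_equal(up$innovation, 2)
  expect_equal(up$S, 2)
  expect_equal(up$loglik, dnorm(2, 0, sqrt(2), log = TRUE))
  # zero innovation: mean unchanged, covariance still contracts
  up0 <- ppvtrack:::cpp_ekf_update(c(2, 0), diag(2), 0, 0, 2, 1, 1L, 0L)
  expect_equal(drop(up0$mean), c(2, 0))
  expect_lt(up0$cov[1, 1], 1)
})

test_that("ancestor search maximizes prior score plus transition density", {
  # equal transition densities: the prior score decides
  k <- ppvtrack:::cpp_search_ancestors(log(c(0.2, 0.8)), 0.25,
                                       c(0.25, 0.25), c(0.25, 0.25),
                                       0.95, 1e-6)
  expect_identical(drop(k), 2L)
  # equal scores: the transition mode decides
  k2 <- ppvtrack:::cpp_search_ancestors(c(-1, -1), 0.25,
                                        c(0.25, 0.30), c(0.25, 0.30),
                                        0.95, 1e-6)
  expect_identical(drop(k2), 1L)
  # brute-force oracle on random 10-ancestor cases
  set.seed(13)
  for (rep in 1:50) {
    la <- log(runif(10))
    fp <- runif(3, 0.1, 0.5)
    f <- runif(10, 0.1, 0.5)
    fb <- runif(10, 0.1, 0.5)
    q <- 10^runif(1, -8, -4)
    got <- ppvtrack:::cpp_search_ancestors(la, fp, f, fb, 0.95, q)
    mu <- fb + 0.95 * (f - fb)
    want <- vapply(fp, function(p) {
      which.max(la - 0.5 * (p - mu)^2 / q -
                  0.5 * log(2 * pi * q))
    }, integer(1))
    expect_identical(drop(got), want)
  }
})

test_that("the marginalized filter matches an exact Kalman filter on the linear submodel", {
  # with the modulation block frozen at zero (zero prior variance, zero
  # process noise) the measurement is linear in the remaining coefficients
  layout <- coef_layout(3, 2)
  set.seed(31)
  nsteps <- 200
  thr <- 2 * pi * 0.25 * (0:(nsteps - 1)) / 40
  thc <- 2 * pi * 1.2 * (0:(nsteps - 1)) / 40
  truth <- numeric(layout$d)
  truth[layout$c1] <- c(20, 8, 3)
  truth[layout$r1] <- c(3, 1)
  y <- abp_measure(thr, thc, truth, layout)$y + rnorm(nsteps, 0, 0.5)
  q <- numeric(layout$d)
  q[c(layout$r1, layout$r2, layout$c1, layout$c2)] <- 1e-5
  v0 <- numeric(layout$d)
  v0[c(layout$r1, layout$r2, layout$c1, layout$c2)] <- 4
  m_ekf <- m_kf <- numeric(layout$d)
  P_ekf <- P_kf <- diag(v0, layout$d)
  worst <- 0
  for (n in seq_len(nsteps)) {
    P_ekf <- P_ekf + diag(q, layout$d)
    up <- ppvtrack:::cpp_ekf_update(m_ekf, P_ekf, thr[n] %% (2 * pi),
                                    thc[n] %% (2 * pi), y[n], 0.25, 3L, 2L)
    m_ekf <- drop(up$mean)
    P_ekf <- up$cov
    H <- abp_measure_gradient(thr[n], thc[n], m_kf, layout)
    P_kf <- P_kf + diag(q, layout$d)
    kf <- linear_kf_update(m_kf, P_kf, H, y[n], 0.25)
    m_kf <- kf$mean
    P_kf <- kf$P
    worst <- max(worst, max(abs(m_ekf - m_kf)))
  }
  expect_lt(worst, 1e-8)
  # the modulation estimates never move off zero
  expect_equal(m_ekf[c(layout$m1, layout$m2)], rep(0, 12))
})

toy_state <- function(cfg, layout) {
  # arbitrary but fixed 3-particle state with distinct scores and phases
  mk <- function(f, th, la, amp) {
    d <- layout$d
    means <- matrix(0, d, 3)
    means[layout$c1[1], ] <- amp * c(1, 0.8, 1.2)
    covs <- array(0, dim = c(d, d, 3))
    for (i in 1:3) covs[, , i] <- diag(0.5 + 0.1 * i, d)
    list(f = f, fbar = f + 0.001, theta = th, log_alpha = la - max(la) -
           log(sum(exp(la - max(la)))), means = means, covs = covs)
  }
  list(resp = mk(c(0.2, 0.25, 0.3), c(0.1, 0.2, 0.3),
                 log(c(0.2, 0.5, 0.3)), 2),
       card = mk(c(1.1, 1.2, 1.3), c(0.5, 1.5, 2.5),
                 log(c(0.3, 0.4, 0.3)), 20),
       frozen = list(f_resp = 0.25, theta_resp = 0.7,
                     f_card = 1.2, theta_card = 1.1))
}

test_that("one filter step matches a straight-line enumeration", {
  cfg <- resolved_cfg(n_cardiac_harmonics = 2, n_resp_harmonics = 1,
                      n_particles_per_space = 3, rejuv_enabled = FALSE)
  layout <- coef_layout(2, 1)
  st <- toy_state(cfg, layout)
  set.seed(99)
  nz <- list(fbar_resp = rnorm(3, 0, 1e-4), f_resp = rnorm(3, 0, 1e-4),
             fbar_card = rnorm(3, 0, 1e-4), f_card = rnorm(3, 0, 1e-4))
  y_n <- 12.3
  got <- ppvtrack:::cpp_dual_mampf(
    y_n, unclass(cfg), st,
    matrix(nz$fbar_resp), matrix(nz$f_resp),
    matrix(nz$fbar_card), matrix(nz$f_card), TRUE)
  want <- enum_dual_step(y_n, cfg, st, nz, layout)
  expect_equal(drop(got$particles$resp$f), want$resp$f,
               tolerance = 1e-12)
  expect_equal(drop(got$particles$resp$theta), want$resp$theta,
               tolerance = 1e-12)
  expect_equal(drop(got$particles$resp$fbar), want$resp$fbar,
               tolerance = 1e-12)
  expect_equal(drop(got$particles$resp$log_alpha), want$resp$log_alpha,
               tolerance = 1e-10)
  expect_equal(got$particles$resp$means, want$resp$means, tolerance = 1e-10)
  expect_equal(drop(got$particles$card$log_alpha), want$card$log_alpha,
               tolerance = 1e-10)
  expect_equal(got$particles$card$means, want$card$means, tolerance = 1e-10)
  expect_equal(drop(got$particles$card$covs[, , 2]), want$card$covs[, , 2],
               tolerance = 1e-10)
  expect_identical(got$winner[1], want$winner)
  expect_equal(got$f_resp[1], want$f_resp, tolerance = 1e-12)
  expect_equal(got$f_card[1], want$f_card, tolerance = 1e-12)
  expect_equal(drop(got$coef[1, ]), unname(want$coef), tolerance = 1e-10)
  # normalization: each space's scores sum to one
  expect_equal(log(sum(exp(got$particles$resp$log_alpha))), 0,
               tolerance = 1e-10)
})

test_that("tracking is deterministic and keeps the particle budget", {
  sim <- ppv_simulate(ppv_spec(duration = 10, rng_seed = 5))
  cfg <- ppv_config(n_cardiac_harmonics = 3, n_resp_harmonics = 2,
                    n_particles_per_space = 20)
  f1 <- ppv_track(sim, config = cfg, seed = 7)
  f2 <- ppv_track(sim, config = cfg, seed = 7)
  f1$diagnostics <- f2$diagnostics <- NULL  # compare everything else too
  expect_identical(f1, f2)
  f3 <- ppv_track(sim, config = cfg, seed = 8)
  expect_false(identical(f1$f_card, f3$f_card))

  # particle budget: exactly N_p per one-dimensional space at every stage
  y <- sim$signal - mean(sim$signal)
  cfgr <- resolve_config(cfg, y, 40)
  out <- ppvtrack:::with_seed(7, {
    st <- ppv_init_state(cfgr)
    expect_length(st$resp$f, 20)
    expect_length(st$card$f, 20)
    n <- length(y)
    nz <- replicate(4, matrix(rnorm(20 * n, 0, sqrt(cfgr$q_freq_resp)),
                              20, n), simplify = FALSE)
    ppvtrack:::cpp_dual_mampf(y, unclass(cfgr), st, nz[[1]], nz[[2]],
                              nz[[3]], nz[[4]], TRUE)
  })
  expect_length(out$particles$resp$f, 20)
  expect_length(out$particles$card$f, 20)
  expect_identical(dim(out$particles$resp$means), c(cfgr$n_cardiac_harmonics *
    2L * cfgr$n_resp_harmonics + 2L * cfgr$n_cardiac_harmonics +
    2L * cfgr$n_resp_harmonics, 20L))
  # scores stay normalized and finite after the full run
  expect_equal(log(sum(exp(out$particles$resp$log_alpha))), 0,
               tolerance = 1e-9)
  expect_true(all(is.finite(out$particles$card$log_alpha)))
})

test_that("MAP frequency estimates stay inside the configured ranges", {
  sim <- ppv_simulate(ppv_spec(duration = 20, rng_seed = 2))
  cfg <- ppv_config(n_cardiac_harmonics = 3, n_resp_harmonics = 2,
                    n_particles_per_space = 30)
  fit <- ppv_track(sim, config = cfg, seed = 2)
  expect_true(all(fit$f_resp > cfg$f_resp_min - 1e-12 &
                    fit$f_resp <= cfg$f_resp_max))
  expect_true(all(fit$f_card > cfg$f_card_min - 1e-12 &
                    fit$f_card <= cfg$f_card_max))
})

test_that("fit accessors expose reconstruction, residuals and PPV prediction", {
  sim <- ppv_simulate(ppv_spec(duration = 15, rng_seed = 9))
  fit <- ppv_track(sim, config = ppv_config(n_cardiac_harmonics = 3,
                                            n_resp_harmonics = 2,
                                            n_particles_per_space = 30),
                   seed = 9)
  expect_equal(residuals(fit), fit$signal - fitted(fit))
  expect_length(coef(fit), fit$layout$d)
  expect_equal(predict(fit, t = fit$time[100]), fit$ppv[100])
  s <- summary(fit)
  expect_s3_class(s, "summary.ppv_track")
  expect_true(is.finite(s$innovation_rms))
  df <- as.data.frame(fit)
  expect_identical(nrow(df), length(sim$signal))
  expect_true(all(c("ppv_pct", "e_mu") %in% names(df)))
})

test_that("more particles do not degrade steady-state frequency recovery", {
  r50 <- recovery_suite(50)
  r250 <- recovery_suite(250)
  p90 <- function(x) unname(quantile(x, 0.9))
  slack <- 0.005  # Monte-Carlo slack, Hz
  expect_lte(p90(r250$fc_err), p90(r50$fc_err) + slack)
  expect_lte(p90(r250$fr_err), p90(r50$fr_err) + slack)
})
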