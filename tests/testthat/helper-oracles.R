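# Independent brute-force oracles used to validate the implementation paths.
# These deliberately share no code with the package internals beyond the
# exported model primitives they are checking against.

# dense-grid direct search for the ABP and PP envelope extrema of a single
# coefficient state at one respiratory angle
dense_envelope_oracle <- function(coefs, theta_r, layout, npts = 100000L) {
  grid <- 2 * pi * (seq_len(npts) - 1L) / npts
  nc <- layout$n_card
  nr <- layout$n_resp
  c1 <- coefs[layout$c1]
  c2 <- coefs[layout$c2]
  rho <- vapply(seq_len(nc), function(k) {
    jm <- (k - 1L) * nr + seq_len(nr)
    1 + sum(coefs[layout$m1[jm]] * cos(seq_len(nr) * theta_r) +
              coefs[layout$m2[jm]] * sin(seq_len(nr) * theta_r))
  }, numeric(1))
  # modulated cardiac sum over the cardiac angle
  g <- rep(0, npts)
  for (k in seq_len(nc)) {
    g <- g + rho[k] * (c1[k] * cos(k * grid) + c2[k] * sin(k * grid))
  }
  th_max <- grid[which.max(g)]
  th_min <- grid[which.min(g)]
  kmax <- c1 * cos(seq_len(nc) * th_max) + c2 * sin(seq_len(nc) * th_max)
  kmin <- c1 * cos(seq_len(nc) * th_min) + c2 * sin(seq_len(nc) * th_min)
  dk <- kmax - kmin
  # modulated PP sum over the respiratory angle
  s <- rep(sum(dk), npts)
  for (k in seq_len(nc)) {
    jm <- (k - 1L) * nr + seq_len(nr)
    varrho <- rep(0, npts)
    for (j in seq_len(nr)) {
      varrho <- varrho + coefs[layout$m1[jm[j]]] * cos(j * grid) +
        coefs[layout$m2[jm[j]]] * sin(j * grid)
    }
    s <- s + varrho * dk[k]
  }
  list(e_mu_card = max(g), e_ell_card = min(g),
       eps_mu = max(s), eps_ell = min(s))
}

# textbook linear Kalman measurement update (two-pass, no Joseph tricks)
linear_kf_update <- function(mean, P, H, y, r) {
  S <- drop(t(H) %*% P %*% H) + r
  K <- drop(P %*% H) / S
  innov <- y - drop(crossprod(H, mean))
  list(mean = mean + K * innov,
       P = P - outer(K, drop(t(H) %*% P)) - outer(drop(P %*% H), K) +
         S * outer(K, K),
       S = S, innov = innov)
}

# straight-line R enumeration of one dual MAM-PF step (both spaces), the
# same contract as the C++ core: propose own frequency, select the best
# ancestor by prior score + transition density, inherit the ancestor's
# trajectory (angle, mean frequency) and Kalman state, EKF-update, score,
# normalize, extract the per-space MAP and the winning Kalman state.
enum_dual_step <- function(y_n, cfg, state, nz, layout) {
  wrap <- function(x) x - 2 * pi * floor(x / (2 * pi))
  clip <- function(f, lo, hi) {
    if (f > hi) f <- 2 * hi - f else if (f <= lo) f <- 2 * lo - f
    f
  }
  qdiag <- coef_process_noise(cfg, layout)
  lam <- cfg$score_discount
  step_one <- function(sp, th_oth, q_freq, f_min, f_max, nz_fbar, nz_f,
                       is_resp) {
    np <- length(sp$f)
    f_new <- fbar_new <- theta_new <- score <- numeric(np)
    means_new <- sp$means
    covs_new <- sp$covs
    mu <- sp$fbar + cfg$ar_coeff * (sp$f - sp$fbar)
    for (i in seq_len(np)) {
      f_new[i] <- clip(mu[i] + nz_f[i], f_min, f_max)
      cand <- lam * sp$log_alpha - 0.5 * (f_new[i] - mu)^2 / q_freq
      k <- which.max(cand)
      tld <- -0.5 * log(2 * pi * q_freq) - 0.5 * (f_new[i] - mu[k])^2 / q_freq
      theta_new[i] <- wrap(sp$theta[k] + 2 * pi * cfg$sample_period * sp$f[k])
      fbar_new[i] <- clip(sp$fbar[k] + nz_fbar[i], f_min, f_max)
      m <- sp$means[, k]
      P <- sp$covs[, , k] + diag(qdiag, layout$d)
      th_r <- if (is_resp) theta_new[i] else th_oth
      th_c <- if (is_resp) th_oth else theta_new[i]
      H <- abp_measure_gradient(th_r, th_c, m, layout)
      yhat <- abp_measure(th_r, th_c, m, layout)$y
      innov <- y_n - yhat
      S <- drop(t(H) %*% P %*% H) + cfg$meas_noise_var
      K <- drop(P %*% H) / S
      means_new[, i] <- m + K * innov
      PH <- drop(P %*% H)
      Pn <- P - outer(K, PH) - outer(PH, K) + S * outer(K, K)
      covs_new[, , i] <- 0.5 * (Pn + t(Pn))
      ll <- -0.5 * log(2 * pi * S) - 0.5 * innov^2 / S
      score[i] <- lam * sp$log_alpha[k] + tld + ll
    }
    mx <- max(score)
    lse <- mx + log(sum(exp(score - mx)))
    list(f = f_new, fbar = fbar_new, theta = theta_new,
         log_alpha = score - lse, means = means_new, covs = covs_new,
         lse = lse, f_post_mean = sum(exp(score - lse) * f_new))
  }
  resp <- step_one(state$resp, state$frozen$theta_card, cfg$q_freq_resp,
                   cfg$f_resp_min, cfg$f_resp_max,
                   nz$fbar_resp, nz$f_resp, TRUE)
  card <- step_one(state$card, state$frozen$theta_resp, cfg$q_freq_card,
                   cfg$f_card_min, cfg$f_card_max,
                   nz$fbar_card, nz$f_card, FALSE)
  i1 <- which.max(resp$log_alpha)
  i2 <- which.max(card$log_alpha)
  la1 <- resp$log_alpha[i1] + resp$lse
  la2 <- card$log_alpha[i2] + card$lse
  winner <- if (la1 >= la2) 1L else 2L
  list(resp = resp, card = card, i1 = i1, i2 = i2, winner = winner,
       coef = if (winner == 1L) resp$means[, i1] else card$means[, i2],
       f_resp = resp$f[i1], f_card = card$f[i2],
       theta_resp = resp$theta[i1], theta_card = card$theta[i2])
}

# random coefficient state with bounded modulation depth
random_coef_state <- function(layout, amp = 1, mod_depth = 0.08) {
  resp <- matrix(stats::rnorm(2 * layout$n_resp, 0, amp), 2)
  card <- matrix(stats::rnorm(2 * layout$n_card, 0, amp), 2)
  mod <- array(stats::runif(2 * layout$n_card * layout$n_resp,
                            -mod_depth, mod_depth),
               dim = c(2, layout$n_card, layout$n_resp))
  flatten_coefs(resp, card, mod, layout)
}

# shared heavy fixture: the 20-seed default-spec recovery suite, computed
# once per test run (used by the acceptance block and the particle-budget
# scaling property)
recovery_cache <- new.env(parent = emptyenv())
recovery_suite <- function(n_particles, seeds = 1:20) {
  key <- paste0("np", n_particles)
  if (!is.null(recovery_cache[[key]])) return(recovery_cache[[key]])
  cfg <- ppv_config(n_cardiac_harmonics = 5, n_resp_harmonics = 2,
                    n_particles_per_space = n_particles)
  res <- lapply(seeds, function(s) {
    sim <- ppv_simulate(ppv_spec(duration = 120, rng_seed = s))
    fit <- ppv_track(sim, config = cfg, seed = s)
    i <- fit$time >= 60
    w <- ppv_windows(fit, n_windows = 1, anchor = 60, record = paste0("s", s))
    list(seed = s,
         fr_err = stats::median(abs(fit$f_resp[i] - 0.25)),
         fc_err = stats::median(abs(fit$f_card[i] - 1.2)),
         ppv_window = w$value,
         ppv_truth = mean(sim$truth$ppv))
  })
  out <- do.call(rbind, lapply(res, as.data.frame))
  recovery_cache[[key]] <- out
  out
}
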