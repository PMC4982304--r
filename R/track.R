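#' Initialize the dual particle filter
#'
#' Builds the initial particle population for both one-dimensional particle
#' spaces.  Mean and instantaneous frequencies are spread evenly over the
#' admissible range (a deterministic grid of `n_particles_per_space` points
#' plus a small uniform jitter of at most 2 percent of the grid spacing,
#' reflected back into the range); angles start at 0; all particles share
#' the same initial coefficient mean (zero except the first-harmonic
#' cosine amplitudes, set to the configured initial scales) and a diagonal
#' covariance built from the squared initial scales; log scores are uniform
#' (`-log N_p`, so each space's scores already normalize to 1).
#'
#' The frozen other-space kinematics used at the very first sample are the
#' midpoint of each frequency range with angle 0.
#'
#' @param cfg a fully resolved [ppv_config()] (see [resolve_config()]).
#' @return A list with per-space particle arrays (`resp`, `card`) and the
#'   initial `frozen` kinematics, in the layout the C++ core consumes.
#'   Consumes random numbers (the jitter); call inside a seeded context for
#'   reproducibility.
#' @export
ppv_init_state <- function(cfg) {
  layout <- coef_layout(cfg$n_cardiac_harmonics, cfg$n_resp_harmonics)
  np <- cfg$n_particles_per_space
  mean0 <- numeric(layout$d)
  if (layout$n_resp > 0L) mean0[layout$r1[1L]] <- cfg$init_resp_amp
  mean0[layout$c1[1L]] <- cfg$init_card_amp
  if (layout$n_resp > 0L) mean0[layout$m1[1L]] <- cfg$init_mod_amp
  var0 <- numeric(layout$d)
  var0[c(layout$r1, layout$r2)] <- cfg$init_resp_amp^2
  var0[c(layout$c1, layout$c2)] <- cfg$init_card_amp^2
  var0[c(layout$m1, layout$m2)] <- cfg$init_mod_amp^2
  cov0 <- diag(var0, layout$d)
  make_space <- function(f_min, f_max) {
    grid <- seq(f_min, f_max, length.out = np)
    spacing <- (f_max - f_min) / (np - 1L)
    jit <- stats::runif(np, -0.02 * spacing, 0.02 * spacing)
    f <- clip_frequency(grid + jit, f_min, f_max)
    list(f = f, fbar = f, theta = rep(0, np),
         log_alpha = rep(-log(np), np),
         means = matrix(mean0, layout$d, np),
         covs = array(cov0, dim = c(layout$d, layout$d, np)))
  }
  list(resp = make_space(cfg$f_resp_min, cfg$f_resp_max),
       card = make_space(cfg$f_card_min, cfg$f_card_max),
       frozen = list(f_resp = (cfg$f_resp_min + cfg$f_resp_max) / 2,
                     theta_resp = 0,
                     f_card = (cfg$f_card_min + cfg$f_card_max) / 2,
                     theta_card = 0),
       layout = layout)
}

#' Track an ABP waveform with the dual MAM-PF
#'
#' Fits the amplitude-modulated multi-harmonic waveform model to a
#' single-channel arterial blood pressure signal with a dual maximum
#' a-posteriori marginalized particle filter.  Two one-dimensional particle
#' populations track the instantaneous respiratory and cardiac frequencies;
#' each particle marginalizes the sinusoidal and modulation coefficients
#' with an extended Kalman filter; at every sample a Viterbi-style ancestor
#' search keeps the maximum a-posteriori trajectory of each particle, and
#' the per-space MAP particles provide the state estimate.  From the MAP
#' state the continuous ABP envelopes, pulse-pressure envelopes and PPV
#' index are computed.
#'
#' The signal is mean-centered before tracking (the model has no DC state);
#' the removed mean is stored and added back to the ABP envelope traces.
#' Runs are deterministic: the same signal, configuration and seed give a
#' bit-identical result.
#'
#' @param signal the waveform: a numeric vector (give `sample_rate`), a
#'   [read_signal()] record, or a [ppv_simulate()] result.
#' @param sample_rate sampling rate in Hz (only for numeric `signal`).
#' @param config a [ppv_config()]; signal-dependent fields are resolved
#'   from the data via [resolve_config()].
#' @param seed integer seed for all randomness in the run; defaults to
#'   `config$rng_seed`.
#' @param envelopes compute envelope/PPV traces (disable to get the raw
#'   state track only).
#' @return An object of class `"ppv_track"` with per-sample traces: `time`,
#'   `signal` (original units), `f_resp`, `f_card` (Hz), `theta_resp`,
#'   `theta_card` (wrapped radians), `theta_resp_unwrapped`, `coef`
#'   (MAP coefficient matrix), `fitted` (reconstructed signal, original
#'   units), `innovation`, envelope traces `e_mu`, `e_ell` (mm Hg),
#'   `eps_mu`, `eps_ell`, `ppv` (percent), plus the resolved `config`,
#'   `seed`, the removed `signal_mean` and filter `diagnostics`.
#' @seealso [ppv_windows()], [bland_altman()], [ppv_simulate()]
#' @export
#' @examples
#' \donttest{
#' sim <- ppv_simulate(ppv_spec(duration = 30))
#' fit <- ppv_track(sim, config = ppv_config(n_cardiac_harmonics = 5,
#'                                           n_resp_harmonics = 2,
#'                                           n_particles_per_space = 50))
#' summary(fit)
#' }
ppv_track <- function(signal, sample_rate = NULL, config = ppv_config(),
                      seed = config$rng_seed, envelopes = TRUE) {
  if (inherits(signal, "ppv_sim")) {
    sample_rate <- signal$spec$sample_rate
    signal <- signal$signal
  } else if (inherits(signal, "ppv_signal")) {
    sample_rate <- signal$fs
    signal <- signal$samples
  }
  y_raw <- as.numeric(signal)
  if (is.null(sample_rate)) {
    if (is.null(config$sample_period)) {
      stop("sample_rate is required for a plain numeric signal")
    }
    sample_rate <- 1 / config$sample_period
  }
  if (anyNA(y_raw) || any(!is.finite(y_raw))) {
    stop("signal contains non-finite samples; run preprocess_signal() first")
  }
  n <- length(y_raw)
  if (n < 4L) stop("signal too short to track")
  mu <- mean(y_raw)
  y <- y_raw - mu
  cfg <- resolve_config(config, y, sample_rate)
  np <- cfg$n_particles_per_space

  run <- with_seed(seed, {
    state <- ppv_init_state(cfg)
    nz <- list(
      fbar_resp = matrix(stats::rnorm(np * n, 0, sqrt(cfg$q_freq_resp)),
                         np, n),
      f_resp = matrix(stats::rnorm(np * n, 0, sqrt(cfg$q_freq_resp)), np, n),
      fbar_card = matrix(stats::rnorm(np * n, 0, sqrt(cfg$q_freq_card)),
                         np, n),
      f_card = matrix(stats::rnorm(np * n, 0, sqrt(cfg$q_freq_card)), np, n))
    core <- cpp_dual_mampf(y, unclass(cfg), state, nz$fbar_resp, nz$f_resp,
                           nz$fbar_card, nz$f_card, FALSE)
    list(core = core, layout = state$layout)
  })
  core <- run$core
  layout <- run$layout

  # smooth respiratory clock: the frozen reference angle integrating the
  # MAP respiratory frequency (monotone, used to delimit cycles)
  theta_unwrapped <- core$theta_resp_clock

  out <- list(
    time = (seq_len(n) - 1L) / sample_rate,
    signal = y_raw,
    sample_rate = sample_rate,
    signal_mean = mu,
    f_resp = core$f_resp, f_card = core$f_card,
    theta_resp = core$theta_resp, theta_card = core$theta_card,
    theta_resp_used = core$theta_resp_used,
    theta_card_used = core$theta_card_used,
    theta_resp_unwrapped = theta_unwrapped,
    coef = core$coef,
    fitted = core$yhat + mu,
    gamma_hat = core$gamma_hat,
    innovation = core$innovation,
    winner = core$winner,
    config = cfg, seed = as.integer(seed), layout = layout,
    diagnostics = list(
      log_alpha_resp_max = core$log_alpha_resp_max,
      log_alpha_card_max = core$log_alpha_card_max,
      evidence_resp = core$evidence_resp,
      evidence_card = core$evidence_card,
      rejuv_events = core$rejuv_events))
  class(out) <- "ppv_track"
  if (envelopes) {
    env <- envelope_traces(core$coef, core$theta_resp_used, layout,
                           cfg$angle_grid_size)
    out$e_mu <- env$e_mu + mu
    out$e_ell <- env$e_ell + mu
    out$eps_mu <- env$eps_mu
    out$eps_ell <- env$eps_ell
    out$ppv <- env$ppv
    out$diagnostics$n_clamped <- env$n_clamped
  }
  out
}

#' @export
print.ppv_track <- function(x, ...) {
  n <- length(x$signal)
  cat(sprintf("dual MAM-PF track: %d samples at %g Hz (%.1f s)\n",
              n, x$sample_rate, n / x$sample_rate))
  half <- seq.int(floor(n / 2) + 1L, n)
  cat(sprintf(
    "  steady-state medians: f_resp %.3f Hz, f_card %.3f Hz%s\n",
    stats::median(x$f_resp[half]), stats::median(x$f_card[half]),
    if (!is.null(x$ppv)) sprintf(", PPV %.1f %%", stats::median(x$ppv[half]))
    else ""))
  cat(sprintf("  particles: %d per space (%d total), seed %d\n",
              x$config$n_particles_per_space,
              2L * x$config$n_particles_per_space, x$seed))
  invisible(x)
}

#' @export
summary.ppv_track <- function(object, steady_from = NULL, ...) {
  n <- length(object$signal)
  if (is.null(steady_from)) steady_from <- object$time[floor(n / 2) + 1L]
  idx <- object$time >= steady_from
  res <- list(
    n = n, sample_rate = object$sample_rate, steady_from = steady_from,
    f_resp_median = stats::median(object$f_resp[idx]),
    f_card_median = stats::median(object$f_card[idx]),
    ppv_median = if (!is.null(object$ppv)) stats::median(object$ppv[idx]),
    ppv_iqr = if (!is.null(object$ppv)) stats::IQR(object$ppv[idx]),
    innovation_rms = sqrt(mean(object$innovation[idx]^2)),
    rejuv_events = object$diagnostics$rejuv_events)
  class(res) <- "summary.ppv_track"
  res
}

#' @export
print.summary.ppv_track <- function(x, ...) {
  cat(sprintf("dual MAM-PF track summary (steady state from %.1f s)\n",
              x$steady_from))
  cat(sprintf("  respiratory rate: %.3f Hz (%.1f /min)\n",
              x$f_resp_median, 60 * x$f_resp_median))
  cat(sprintf("  heart rate:       %.3f Hz (%.1f /min)\n",
              x$f_card_median, 60 * x$f_card_median))
  if (!is.null(x$ppv_median)) {
    cat(sprintf("  PPV: median %.1f %% (IQR %.1f %%)\n",
                x$ppv_median, x$ppv_iqr))
  }
  cat(sprintf("  innovation RMS: %.3g\n", x$innovation_rms))
  invisible(x)
}

#' @export
coef.ppv_track <- function(object, type = c("final", "trace"), ...) {
  type <- match.arg(type)
  cf <- object$coef
  colnames(cf) <- object$layout$names
  if (type == "final") cf[nrow(cf), ] else cf
}

#' @export
fitted.ppv_track <- function(object, ...) object$fitted

#' @export
residuals.ppv_track <- function(object, ...) object$signal - object$fitted

#' Predict the continuous PPV index at arbitrary times
#'
#' @param object a [ppv_track()] fit (with envelopes).
#' @param t times in seconds within the tracked record.
#' @param ... unused.
#' @return Linearly interpolated PPV (percent) at `t`.
#' @export
predict.ppv_track <- function(object, t = object$time, ...) {
  if (is.null(object$ppv)) stop("track was run with envelopes = FALSE")
  if (any(t < 0 | t > max(object$time))) stop("t outside the tracked record")
  stats::approx(object$time, object$ppv, xout = t, ties = "ordered")$y
}

#' Simulate replicate signals from a fitted track
#'
#' Draws measurement noise around the reconstructed signal using the
#' resolved measurement noise variance.
#'
#' @param object a [ppv_track()] fit.
#' @param nsim number of replicates.
#' @param seed integer seed.
#' @param ... unused.
#' @return A data frame with `nsim` columns of simulated signals.
#' @export
simulate.ppv_track <- function(object, nsim = 1, seed = NULL, ...) {
  n <- length(object$fitted)
  draw <- function() object$fitted +
    stats::rnorm(n, 0, sqrt(object$config$meas_noise_var))
  sims <- if (is.null(seed)) {
    replicate(nsim, draw())
  } else {
    with_seed(seed, replicate(nsim, draw()))
  }
  as.data.frame(matrix(sims, ncol = nsim,
                       dimnames = list(NULL, paste0("sim_", seq_len(nsim)))))
}

#' Plot a tracked record
#'
#' Two panels: the signal with its ABP envelopes, and the continuous PPV
#' trace.
#'
#' @param x a [ppv_track()] fit.
#' @param window optional time window `c(from, to)` in seconds for the
#'   signal panel.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ppv_track <- function(x, window = NULL, ...) {
  if (is.null(x$ppv)) stop("track was run with envelopes = FALSE")
  idx <- if (is.null(window)) {
    seq_along(x$time)
  } else {
    which(x$time >= window[1] & x$time <= window[2])
  }
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(x$time[idx], x$signal[idx], type = "l", col = "grey40",
                 xlab = "time (s)", ylab = "ABP (mm Hg)",
                 main = "signal and envelopes", ...)
  graphics::lines(x$time[idx], x$fitted[idx], col = "forestgreen")
  graphics::lines(x$time[idx], x$e_mu[idx], col = "blue")
  graphics::lines(x$time[idx], x$e_ell[idx], col = "blue")
  graphics::plot(x$time, x$ppv, type = "l", col = "forestgreen",
                 xlab = "time (s)", ylab = "PPV (%)",
                 main = "continuous PPV index")
  invisible(x)
}

#' Export a tracked record as a data frame
#'
#' One row per sample with the MAP state, reconstruction, envelope and PPV
#' traces; suitable for CSV export.
#'
#' @param x a [ppv_track()] fit.
#' @param ... unused.
#' @export
as.data.frame.ppv_track <- function(x, ...) {
  df <- data.frame(time_s = x$time, abp = x$signal, fitted = x$fitted,
                   innovation = x$innovation,
                   f_resp_hz = x$f_resp, f_card_hz = x$f_card,
                   theta_resp = x$theta_resp, theta_card = x$theta_card)
  if (!is.null(x$ppv)) {
    df$e_mu <- x$e_mu
    df$e_ell <- x$e_ell
    df$eps_mu <- x$eps_mu
    df$eps_ell <- x$eps_ell
    df$ppv_pct <- x$ppv
  }
  df
}
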