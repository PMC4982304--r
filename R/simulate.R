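#' Specification of a synthetic ABP-like signal
#'
#' Describes a forward simulation of the amplitude-modulated multi-harmonic
#' waveform model with exactly known ground truth: deterministic frequency
#' profiles (so the angle trajectories are exact integrals, not realized
#' random walks), fixed sinusoidal coefficients, a DC baseline offset and
#' additive white Gaussian noise.
#'
#' Frequency profiles are given either as a single number (constant), or as
#' a list `list(type = "chirp", from =, to =)` (linear sweep over the whole
#' duration) or `list(type = "sine", center =, amplitude =, period =)`
#' (sinusoidal drift).  Profiles must stay strictly inside the configured
#' admissible ranges.
#'
#' The defaults emulate a spontaneously breathing adult: respiration at
#' 0.25 Hz (15 breaths/min), heart rate 1.2 Hz (72 beats/min), three
#' cardiac harmonics of 30, 12 and 6 mm Hg, two respiratory baseline
#' harmonics of 3 and 1 mm Hg, a first-harmonic respiratory modulation of
#' depth 0.075 on every cardiac partial (true PPV = 15 %), a 90 mm Hg
#' baseline and 1 mm Hg measurement noise.
#'
#' @param duration signal length, seconds.
#' @param sample_rate sampling rate, Hz.
#' @param resp_freq,card_freq frequency profiles (see Details), Hz.
#' @param resp_coeffs 2 x n_resp matrix of respiratory baseline
#'   coefficients (mm Hg); row 1 cosine, row 2 sine.
#' @param card_coeffs 2 x n_card matrix of cardiac coefficients (mm Hg).
#' @param mod_coeffs array `c(2, n_card, n_resp)` of dimensionless
#'   modulation coefficients; per cardiac harmonic the absolute sum must be
#'   below 1 so modulation never inverts a partial.
#' @param baseline_offset DC offset added outside the harmonic model
#'   (mm Hg); the tracker works on mean-centered signals, so the offset is
#'   removed by preprocessing.
#' @param noise_std standard deviation of the additive measurement noise
#'   (mm Hg).
#' @param rng_seed integer seed for the noise realization.
#' @return An object of class `"ppv_spec"`.
#' @seealso [ppv_simulate()]
#' @export
ppv_spec <- function(duration = 120,
                     sample_rate = 40,
                     resp_freq = 0.25,
                     card_freq = 1.2,
                     resp_coeffs = rbind(c(3, 1), c(0, 0)),
                     card_coeffs = rbind(c(30, 12, 6), c(0, 0, 0)),
                     mod_coeffs = NULL,
                     baseline_offset = 90,
                     noise_std = 1,
                     rng_seed = 1L) {
  resp_coeffs <- matrix(as.numeric(resp_coeffs), nrow = 2L)
  card_coeffs <- matrix(as.numeric(card_coeffs), nrow = 2L)
  n_card <- ncol(card_coeffs)
  n_resp <- ncol(resp_coeffs)
  if (is.null(mod_coeffs)) {
    # depth 0.075 on every cardiac partial at the fundamental respiratory
    # harmonic: true continuous PPV = 100 * 2 * 0.075 = 15 %
    mod_coeffs <- array(0, dim = c(2L, n_card, n_resp))
    mod_coeffs[1L, , 1L] <- 0.075
  }
  mod_coeffs <- array(as.numeric(mod_coeffs), dim = c(2L, n_card, n_resp))
  stopifnot(duration > 0, sample_rate > 0, noise_std >= 0)
  mod_sum <- apply(abs(mod_coeffs), 2L, sum)
  if (any(mod_sum >= 1)) {
    stop("modulation too deep: sum of |m| per cardiac harmonic must be < 1")
  }
  spec <- list(duration = duration, sample_rate = sample_rate,
               resp_freq = resp_freq, card_freq = card_freq,
               resp_coeffs = resp_coeffs, card_coeffs = card_coeffs,
               mod_coeffs = mod_coeffs, baseline_offset = baseline_offset,
               noise_std = noise_std, rng_seed = as.integer(rng_seed),
               n_card = n_card, n_resp = n_resp)
  class(spec) <- "ppv_spec"
  spec
}

# evaluate a frequency profile and its exact angle (2 pi * integral of f)
eval_freq_profile <- function(profile, t, duration) {
  if (is.numeric(profile) && length(profile) == 1L) {
    return(list(f = rep(profile, length(t)), theta = 2 * pi * profile * t))
  }
  if (!is.list(profile) || is.null(profile$type)) {
    stop("frequency profile must be a number or a list with a 'type'")
  }
  switch(profile$type,
    chirp = {
      slope <- (profile$to - profile$from) / duration
      list(f = profile$from + slope * t,
           theta = 2 * pi * (profile$from * t + slope * t^2 / 2))
    },
    sine = {
      w <- 2 * pi / profile$period
      list(f = profile$center + profile$amplitude * sin(w * t),
           theta = 2 * pi * (profile$center * t +
                               profile$amplitude / w * (1 - cos(w * t))))
    },
    stop("unknown frequency profile type: ", profile$type)
  )
}

#' Generate a synthetic ABP signal with known ground truth
#'
#' Renders the waveform of a [ppv_spec()] sample by sample
#' (`signal = gamma + sum_k rho_k kappa_k + offset + noise`), with angle
#' trajectories computed as exact cumulative integrals of the frequency
#' profiles, and attaches the full ground truth: true angles, frequencies,
#' the noise-free signal, the true ABP and PP envelopes and the true
#' continuous PPV trace (all evaluated from the true coefficients with
#' [envelope_traces()]).
#'
#' @param spec a [ppv_spec()].
#' @param cfg a [ppv_config()] supplying the admissible frequency ranges
#'   (and the envelope search grid size); the frequency profiles must stay
#'   strictly inside those ranges.
#' @return An object of class `"ppv_sim"`: a list with `time`, `signal`
#'   (mm Hg, noisy), `clean` (noise-free, mm Hg), `truth` (list of
#'   per-sample ground-truth traces) and the originating `spec`.
#' @export
#' @examples
#' sim <- ppv_simulate(ppv_spec(duration = 30, rng_seed = 7))
#' range(sim$truth$ppv)  # constant 15 % by construction
ppv_simulate <- function(spec, cfg = ppv_config()) {
  stopifnot(inherits(spec, "ppv_spec"))
  n <- round(spec$duration * spec$sample_rate)
  t <- (seq_len(n) - 1L) / spec$sample_rate
  pr <- eval_freq_profile(spec$resp_freq, t, spec$duration)
  pc <- eval_freq_profile(spec$card_freq, t, spec$duration)
  if (any(pr$f <= cfg$f_resp_min) || any(pr$f >= cfg$f_resp_max)) {
    stop("respiratory frequency profile leaves the configured range")
  }
  if (any(pc$f <= cfg$f_card_min) || any(pc$f >= cfg$f_card_max)) {
    stop("cardiac frequency profile leaves the configured range")
  }
  layout <- coef_layout(spec$n_card, spec$n_resp)
  coefs <- flatten_coefs(spec$resp_coeffs, spec$card_coeffs,
                         spec$mod_coeffs, layout)
  parts <- abp_measure(pr$theta, pc$theta, coefs, layout)
  clean <- parts$y + spec$baseline_offset
  noise <- with_seed(spec$rng_seed, stats::rnorm(n, 0, spec$noise_std))
  env <- envelope_traces(coefs, pr$theta %% (2 * pi), layout,
                         cfg$angle_grid_size)
  truth <- list(
    theta_resp = pr$theta %% (2 * pi), theta_card = pc$theta %% (2 * pi),
    theta_resp_unwrapped = pr$theta, theta_card_unwrapped = pc$theta,
    f_resp = pr$f, f_card = pc$f,
    clean = clean,
    e_mu = env$e_mu + spec$baseline_offset,
    e_ell = env$e_ell + spec$baseline_offset,
    eps_mu = env$eps_mu, eps_ell = env$eps_ell,
    ppv = env$ppv,
    coefs = coefs, layout = layout)
  out <- list(time = t, signal = clean + noise, clean = clean,
              truth = truth, spec = spec)
  class(out) <- "ppv_sim"
  out
}

#' @export
print.ppv_sim <- function(x, ...) {
  cat(sprintf(
    "synthetic ABP signal: %.0f s at %g Hz (%d samples)\n",
    x$spec$duration, x$spec$sample_rate, length(x$signal)))
  cat(sprintf("  true PPV range: %.2f-%.2f %%\n",
              min(x$truth$ppv), max(x$truth$ppv)))
  invisible(x)
}

#' @export
as.data.frame.ppv_sim <- function(x, ...) {
  data.frame(time_s = x$time, abp_mmhg = x$signal,
             true_clean_mmhg = x$clean,
             true_f_resp_hz = x$truth$f_resp,
             true_f_card_hz = x$truth$f_card,
             true_e_mu_mmhg = x$truth$e_mu,
             true_e_ell_mmhg = x$truth$e_ell,
             true_eps_mu_mmhg = x$truth$eps_mu,
             true_eps_ell_mmhg = x$truth$eps_ell,
             true_ppv_pct = x$truth$ppv)
}

#' Interpolate the true continuous PPV trace
#'
#' @param sim a [ppv_simulate()] result.
#' @param t time(s) in seconds, within `[0, duration)`.
#' @return Linearly interpolated true PPV (percent) at `t`.
#' @export
truth_ppv_at <- function(sim, t) {
  stopifnot(inherits(sim, "ppv_sim"))
  if (any(t < 0 | t >= sim$spec$duration)) {
    stop("t outside the simulated record")
  }
  stats::approx(sim$time, sim$truth$ppv, xout = t, rule = 2,
                ties = "ordered")$y
}

#' Write a synthetic record (signal + ground truth) to CSV
#'
#' Columns: `time_s`, `abp_mmhg` and the ground-truth traces of
#' [as.data.frame.ppv_sim()].  Values are written with full double
#' precision.
#'
#' @param sim a [ppv_simulate()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sim_csv <- function(sim, path) {
  df <- as.data.frame(sim)
  write_csv_full(df, path)
  invisible(path)
}

# full-precision CSV writer (signals round-trip bit-identically)
write_csv_full <- function(df, path) {
  txt <- vapply(df, function(col) sprintf("%.17g", col), character(nrow(df)))
  if (nrow(df) == 1L) txt <- matrix(txt, nrow = 1L)
  lines <- c(paste(names(df), collapse = ","),
             apply(txt, 1L, paste, collapse = ","))
  writeLines(lines, path)
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
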