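#' Tracker configuration
#'
#' Builds the full set of user-specified design parameters for the ABP
#' waveform tracker: harmonic model orders, particle budget, admissible
#' frequency ranges, process/measurement noise variances and initial
#' coefficient scales.
#'
#' Several quantities are conventionally expressed relative to the variance
#' and standard deviation of the (mean-centered) input signal: the
#' measurement noise variance defaults to `var(y)/1e3`, the respiratory and
#' cardiac coefficient random-walk variances to `var(y) * 1e-6 * Ts`, the
#' modulation coefficient variances to `var(y) * 1e-8 * Ts`, and the initial
#' coefficient scales to `sd(y)/10` (respiratory, cardiac) and `sd(y)/1e3`
#' (modulation), where `Ts` is the sample period.  Leave those fields `NULL`
#' to have them resolved from the data when the tracker is run (see
#' [resolve_config()]); pass explicit numbers to override.
#'
#' @param n_cardiac_harmonics number of cardiac harmonic partials.
#' @param n_resp_harmonics number of respiratory harmonic partials.
#' @param n_particles_per_space particles per one-dimensional particle space;
#'   the filter uses `2 * n_particles_per_space` particles in total.
#' @param f_resp_min,f_resp_max admissible instantaneous respiratory
#'   frequency range (Hz).  Defaults 6/60 and 30/60 Hz (6-30 breaths/min).
#' @param f_card_min,f_card_max admissible instantaneous cardiac frequency
#'   range (Hz).  Defaults 50/60 and 140/60 Hz (50-140 beats/min).
#' @param sample_period sample period `Ts` in seconds, or `NULL` to take it
#'   from the signal being tracked.
#' @param meas_noise_var measurement noise variance `r` (squared signal
#'   units), or `NULL` for the `var(y)/1e3` default.
#' @param q_freq_resp,q_freq_card per-step variances of the respiratory and
#'   cardiac frequency process noises (Hz^2), or `NULL` for `1e-6 * Ts`.
#' @param q_resp_coeff,q_card_coeff,q_mod_coeff per-step random-walk
#'   variances of the respiratory, cardiac and modulation coefficients, or
#'   `NULL` for the signal-scaled defaults above.
#' @param init_resp_amp,init_card_amp,init_mod_amp initial coefficient
#'   scales, or `NULL` for the signal-scaled defaults above.
#' @param ar_coeff autoregressive coefficient of the mean-reverting
#'   instantaneous-frequency step, in (0, 1].
#' @param angle_grid_size number of grid points used by the envelope angle
#'   searches before golden-section refinement.
#' @param rng_seed integer seed for all randomness in a tracking run.
#' @param score_discount per-step exponential forgetting factor applied to
#'   the accumulated MAP scores, in (0, 1]; 1 accumulates scores over the
#'   whole record (pure Viterbi accumulation), values just below 1 give the
#'   score a finite memory (about `1/(1 - score_discount)` samples) so that
#'   the trajectory ranking reflects recent fit rather than initial
#'   transients.
#' @param ref_phase_gain,ref_freq_gain per-step gains of the phase-locked
#'   update that makes each space's shared ("frozen") kinematic reference
#'   follow the opposite space's MAP particle; small values give a smooth
#'   reference (time constant about `Ts / gain` seconds).
#' @param rejuv_enabled logical; re-spread chronically low-scoring particles
#'   over the frequency range when one mode dominates for a long stretch.
#' @param rejuv_gap log-score gap between the best and the median particle
#'   beyond which the filter is considered mode-collapsed.
#' @param rejuv_steps number of consecutive collapsed steps that triggers a
#'   re-spread of the lowest-scoring 10 percent of particles.
#'
#' @return An object of class `"ppv_config"` (a named list).
#' @seealso [resolve_config()], [read_ppv_config()], [ppv_track()]
#' @export
#' @examples
#' cfg <- ppv_config(n_particles_per_space = 50)
#' cfg$f_card_max
ppv_config <- function(n_cardiac_harmonics = 10L,
                       n_resp_harmonics = 3L,
                       n_particles_per_space = 250L,
                       f_resp_min = 6 / 60,
                       f_resp_max = 30 / 60,
                       f_card_min = 50 / 60,
                       f_card_max = 140 / 60,
                       sample_period = NULL,
                       meas_noise_var = NULL,
                       q_freq_resp = NULL,
                       q_freq_card = NULL,
                       q_resp_coeff = NULL,
                       q_card_coeff = NULL,
                       q_mod_coeff = NULL,
                       init_resp_amp = NULL,
                       init_card_amp = NULL,
                       init_mod_amp = NULL,
                       ar_coeff = 0.95,
                       angle_grid_size = 256L,
                       rng_seed = 20160811L,
                       score_discount = 0.999,
                       ref_phase_gain = 0,
                       ref_freq_gain = 0.02,
                       rejuv_enabled = TRUE,
                       rejuv_gap = 200,
                       rejuv_steps = 400L) {
  cfg <- list(
    n_cardiac_harmonics = as.integer(n_cardiac_harmonics),
    n_resp_harmonics = as.integer(n_resp_harmonics),
    n_particles_per_space = as.integer(n_particles_per_space),
    f_resp_min = f_resp_min, f_resp_max = f_resp_max,
    f_card_min = f_card_min, f_card_max = f_card_max,
    sample_period = sample_period,
    meas_noise_var = meas_noise_var,
    q_freq_resp = q_freq_resp, q_freq_card = q_freq_card,
    q_resp_coeff = q_resp_coeff, q_card_coeff = q_card_coeff,
    q_mod_coeff = q_mod_coeff,
    init_resp_amp = init_resp_amp, init_card_amp = init_card_amp,
    init_mod_amp = init_mod_amp,
    ar_coeff = ar_coeff,
    angle_grid_size = as.integer(angle_grid_size),
    rng_seed = as.integer(rng_seed),
    score_discount = score_discount,
    ref_phase_gain = ref_phase_gain,
    ref_freq_gain = ref_freq_gain,
    rejuv_enabled = isTRUE(rejuv_enabled),
    rejuv_gap = rejuv_gap,
    rejuv_steps = as.integer(rejuv_steps)
  )
  class(cfg) <- "ppv_config"
  validate_config(cfg)
  cfg
}

#' @export
print.ppv_config <- function(x, ...) {
  cat("ABP/PPV tracker configuration\n")
  cat(sprintf("  harmonics: %d cardiac, %d respiratory\n",
              x$n_cardiac_harmonics, x$n_resp_harmonics))
  cat(sprintf("  particles: %d per space (%d total)\n",
              x$n_particles_per_space, 2L * x$n_particles_per_space))
  cat(sprintf("  resp range: [%.3f, %.3f] Hz, cardiac range: [%.3f, %.3f] Hz\n",
              x$f_resp_min, x$f_resp_max, x$f_card_min, x$f_card_max))
  data_dep <- c("sample_period", "meas_noise_var", "q_freq_resp",
                "q_freq_card", "q_resp_coeff", "q_card_coeff", "q_mod_coeff",
                "init_resp_amp", "init_card_amp", "init_mod_amp")
  unresolved <- data_dep[vapply(x[data_dep], is.null, logical(1))]
  if (length(unresolved)) {
    cat("  resolved from signal at fit time:",
        paste(unresolved, collapse = ", "), "\n")
  }
  invisible(x)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "ppv_config"))
  chk <- function(ok, msg) if (!ok) stop("invalid configuration: ", msg,
                                         call. = FALSE)
  chk(cfg$n_cardiac_harmonics >= 1L, "n_cardiac_harmonics must be >= 1")
  chk(cfg$n_resp_harmonics >= 0L, "n_resp_harmonics must be >= 0")
  chk(cfg$n_particles_per_space >= 2L, "n_particles_per_space must be >= 2")
  chk(cfg$f_resp_min > 0 && cfg$f_resp_min < cfg$f_resp_max,
      "need 0 < f_resp_min < f_resp_max")
  chk(cfg$f_card_min > 0 && cfg$f_card_min < cfg$f_card_max,
      "need 0 < f_card_min < f_card_max")
  chk(is.null(cfg$sample_period) || cfg$sample_period > 0,
      "sample_period must be > 0")
  for (nm in c("meas_noise_var", "q_freq_resp", "q_freq_card",
               "q_resp_coeff", "q_card_coeff", "q_mod_coeff")) {
    v <- cfg[[nm]]
    chk(is.null(v) || (is.finite(v) && v >= 0),
        paste(nm, "must be a nonnegative number"))
  }
  chk(cfg$ar_coeff > 0 && cfg$ar_coeff <= 1, "ar_coeff must be in (0, 1]")
  chk(cfg$angle_grid_size >= 8L, "angle_grid_size must be >= 8")
  chk(cfg$score_discount > 0 && cfg$score_discount <= 1,
      "score_discount must be in (0, 1]")
  chk(cfg$ref_phase_gain >= 0 && cfg$ref_phase_gain <= 1,
      "ref_phase_gain must be in [0, 1]")
  chk(cfg$ref_freq_gain >= 0 && cfg$ref_freq_gain <= 1,
      "ref_freq_gain must be in [0, 1]")
  invisible(cfg)
}

#' Resolve signal-dependent configuration defaults
#'
#' Fills every `NULL` field of a [ppv_config()] from the statistics of a
#' concrete signal: sample period from `sample_rate`, and noise variances /
#' initial coefficient scales from `var(y)` and `sd(y)` of the mean-centered
#' samples (see [ppv_config()] for the scaling conventions).
#'
#' @param cfg a [ppv_config()].
#' @param y numeric signal samples (centering is applied internally for the
#'   variance computation).
#' @param sample_rate sampling rate in Hz; required when
#'   `cfg$sample_period` is `NULL`.
#' @return A fully-resolved `"ppv_config"` with no `NULL` fields.
#' @export
resolve_config <- function(cfg, y, sample_rate = NULL) {
  validate_config(cfg)
  if (is.null(cfg$sample_period)) {
    if (is.null(sample_rate)) {
      stop("sample_rate is required when cfg$sample_period is NULL")
    }
    cfg$sample_period <- 1 / sample_rate
  } else if (!is.null(sample_rate) &&
             abs(cfg$sample_period - 1 / sample_rate) >
               1e-9 * cfg$sample_period) {
    stop(sprintf(
      "configured sample_period (%g s) disagrees with the signal rate (%g Hz)",
      cfg$sample_period, sample_rate))
  }
  y <- as.numeric(y)
  y <- y - mean(y)
  vy <- stats::var(y)
  sy <- sqrt(vy)
  ts <- cfg$sample_period
  if (is.null(cfg$meas_noise_var)) cfg$meas_noise_var <- vy / 1e3
  if (is.null(cfg$q_freq_resp)) cfg$q_freq_resp <- 1e-6 * ts
  if (is.null(cfg$q_freq_card)) cfg$q_freq_card <- 1e-6 * ts
  if (is.null(cfg$q_resp_coeff)) cfg$q_resp_coeff <- vy * 1e-6 * ts
  if (is.null(cfg$q_card_coeff)) cfg$q_card_coeff <- vy * 1e-6 * ts
  if (is.null(cfg$q_mod_coeff)) cfg$q_mod_coeff <- vy * 1e-8 * ts
  if (is.null(cfg$init_resp_amp)) cfg$init_resp_amp <- sy / 1e1
  if (is.null(cfg$init_card_amp)) cfg$init_card_amp <- sy / 1e1
  if (is.null(cfg$init_mod_amp)) cfg$init_mod_amp <- sy / 1e3
  validate_config(cfg)
  cfg
}

#' Read a tracker configuration from a YAML or JSON file
#'
#' The file holds key-value pairs with exactly the [ppv_config()] argument
#' names; missing keys keep their defaults and unknown keys are an error.
#' Files ending in `.json` are parsed as JSON, anything else as YAML.
#'
#' @param path path to the configuration file.
#' @return A `"ppv_config"` object.
#' @export
read_ppv_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(ppv_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  }
  do.call(ppv_config, vals)
}

#' Write a tracker configuration to YAML
#'
#' @param cfg a [ppv_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ppv_config <- function(cfg, path) {
  validate_config(cfg)
  vals <- unclass(cfg)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path, precision = 17L)
  invisible(path)
}
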