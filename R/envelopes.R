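# Envelope extraction and the continuous PPV index.
#
# The ABP envelopes are the extrema of the modulated cardiac sum over the
# cardiac angle; the PP envelopes are the extrema of the modulated pulse
# pressure over the respiratory angle.  Both argmax/argmin searches use a
# coarse angle grid followed by one golden-section refinement pass.

# Vectorized golden-section maximizer of fn over per-sample brackets [a, b].
# fn(theta) must accept a vector (one angle per sample) and return the
# per-sample objective.  Returns the refined angle.
golden_refine <- function(fn, a, b, iters = 40L) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- b - gr * (b - a)
  x2 <- a + gr * (b - a)
  f1 <- fn(x1)
  f2 <- fn(x2)
  for (it in seq_len(iters)) {
    move_up <- f1 < f2
    a[move_up] <- x1[move_up]
    x1[move_up] <- x2[move_up]
    f1[move_up] <- f2[move_up]
    x2[move_up] <- a[move_up] + gr * (b[move_up] - a[move_up])
    f2[move_up] <- fn(x2)[move_up]
    dn <- !move_up
    b[dn] <- x2[dn]
    x2[dn] <- x1[dn]
    f2[dn] <- f1[dn]
    x1[dn] <- b[dn] - gr * (b[dn] - a[dn])
    f1[dn] <- fn(x1)[dn]
  }
  (a + b) / 2
}

# grid + golden-section argmax of a per-sample trigonometric polynomial.
# W1, W2: N x K weight matrices on cos(k theta), sin(k theta).
# Returns list(theta, value).  Grid ties break toward the smaller angle.
trig_argmax <- function(W1, W2, grid_size) {
  n <- nrow(W1)
  K <- ncol(W1)
  ks <- seq_len(K)
  grid <- 2 * pi * (seq_len(grid_size) - 1L) / grid_size
  vals <- W1 %*% t(cos(outer(grid, ks))) + W2 %*% t(sin(outer(grid, ks)))
  jbest <- max.col(vals, ties.method = "first")
  theta_g <- grid[jbest]
  fn <- function(theta) {
    rowSums(W1 * cos(outer(theta, ks)) + W2 * sin(outer(theta, ks)))
  }
  delta <- 2 * pi / grid_size
  theta_r <- golden_refine(fn, theta_g - delta, theta_g + delta)
  v_g <- vals[cbind(seq_len(n), jbest)]
  v_r <- fn(theta_r)
  use_grid <- v_g >= v_r
  theta <- ifelse(use_grid, theta_g, theta_r) %% (2 * pi)
  list(theta = theta, value = pmax(v_g, v_r))
}

#' Envelope and PPV traces from tracked (or true) model states
#'
#' Converts per-sample coefficient estimates and respiratory angles into the
#' continuous upper/lower ABP envelopes, upper/lower pulse-pressure (PP)
#' envelopes and the continuous PPV index.
#'
#' Per sample, the cardiac angle extremizing the modulated cardiac sum
#' \eqn{\sum_k \rho_k (c_{1k}\cos k\theta + c_{2k}\sin k\theta)} gives the
#' per-harmonic extrema \eqn{\kappa_{max,k}, \kappa_{min,k}} and the ABP
#' envelopes \eqn{e_\mu = \gamma + \sum_k \rho_k \kappa_{max,k}},
#' \eqn{e_\ell = \gamma + \sum_k \rho_k \kappa_{min,k}}.  The respiratory
#' angle extremizing
#' \eqn{\sum_k (1 + \varrho_k(\theta))(\kappa_{max,k} - \kappa_{min,k})}
#' gives the PP envelopes \eqn{\varepsilon_\mu, \varepsilon_\ell}, and
#' \deqn{PPV(\%) = 100 (\varepsilon_\mu - \varepsilon_\ell) /
#'   ((\varepsilon_\mu + \varepsilon_\ell)/2).}
#'
#' Early-transient coefficient estimates can drive a PP envelope negative;
#' PP is physically nonnegative, so the envelopes are clamped at zero and
#' the number of clamped samples is reported.
#'
#' @param coefs `N x d` matrix of per-sample flattened coefficients, or a
#'   single length-`d` vector shared by all samples.
#' @param theta_r per-sample instantaneous respiratory angle (radians).
#' @param layout a [coef_layout()].
#' @param grid_size number of coarse grid points on `[0, 2pi)` for the angle
#'   searches (golden-section refinement follows).
#' @return A list of per-sample traces: `gamma`, `rho`, `kappa_max`,
#'   `kappa_min` (`N x n_card`), ABP envelopes `e_mu`, `e_ell`, PP envelopes
#'   `eps_mu`, `eps_ell`, `ppv` (percent), the extremizing angles
#'   `theta_c_max`, `theta_c_min`, `theta_r_max`, `theta_r_min`, and
#'   `n_clamped`.
#' @export
envelope_traces <- function(coefs, theta_r, layout, grid_size = 256L) {
  if (!is.matrix(coefs)) {
    coefs <- matrix(coefs, length(theta_r), layout$d, byrow = TRUE)
  }
  n <- nrow(coefs)
  stopifnot(length(theta_r) == n, ncol(coefs) == layout$d)
  nc <- layout$n_card
  nr <- layout$n_resp

  parts <- abp_measure(theta_r, rep(0, n), coefs, layout)
  gamma <- parts$gamma
  rho <- parts$rho

  # ABP envelope: extremize the modulated cardiac sum over the cardiac angle
  W1 <- rho * coefs[, layout$c1, drop = FALSE]
  W2 <- rho * coefs[, layout$c2, drop = FALSE]
  mx <- trig_argmax(W1, W2, grid_size)
  mn <- trig_argmax(-W1, -W2, grid_size)
  theta_c_max <- mx$theta
  theta_c_min <- mn$theta
  ks <- seq_len(nc)
  kappa_max <- coefs[, layout$c1, drop = FALSE] * cos(outer(theta_c_max, ks)) +
    coefs[, layout$c2, drop = FALSE] * sin(outer(theta_c_max, ks))
  kappa_min <- coefs[, layout$c1, drop = FALSE] * cos(outer(theta_c_min, ks)) +
    coefs[, layout$c2, drop = FALSE] * sin(outer(theta_c_min, ks))
  e_mu <- gamma + rowSums(rho * kappa_max)
  e_ell <- gamma + rowSums(rho * kappa_min)

  # PP envelope: extremize sum_k (1 + rho_k(theta)) (kmax_k - kmin_k) over
  # the respiratory angle.  As a function of theta this is
  # S0 + sum_j A_j cos(j theta) + B_j sin(j theta).
  dk <- kappa_max - kappa_min
  S0 <- rowSums(dk)
  if (nr > 0L) {
    A <- matrix(0, n, nr)
    B <- matrix(0, n, nr)
    for (j in seq_len(nr)) {
      jm <- (seq_len(nc) - 1L) * nr + j
      A[, j] <- rowSums(coefs[, layout$m1[jm], drop = FALSE] * dk)
      B[, j] <- rowSums(coefs[, layout$m2[jm], drop = FALSE] * dk)
    }
    rx <- trig_argmax(A, B, grid_size)
    rn <- trig_argmax(-A, -B, grid_size)
    theta_r_max <- rx$theta
    theta_r_min <- rn$theta
    eps_mu <- S0 + rx$value
    eps_ell <- S0 - rn$value
  } else {
    theta_r_max <- theta_r_min <- rep(0, n)
    eps_mu <- eps_ell <- S0
  }

  n_clamped <- sum(eps_mu < 0) + sum(eps_ell < 0)
  eps_mu <- pmax(eps_mu, 0)
  eps_ell <- pmax(eps_ell, 0)

  list(gamma = gamma, rho = rho,
       kappa_max = kappa_max, kappa_min = kappa_min,
       e_mu = e_mu, e_ell = e_ell,
       eps_mu = eps_mu, eps_ell = eps_ell,
       ppv = ppv_continuous(eps_mu, eps_ell),
       theta_c_max = theta_c_max, theta_c_min = theta_c_min,
       theta_r_max = theta_r_max, theta_r_min = theta_r_min,
       n_clamped = n_clamped)
}

#' Continuous PPV index from the PP envelopes
#'
#' \deqn{PPV(\%) = 100 (\varepsilon_\mu - \varepsilon_\ell) /
#'   ((\varepsilon_\mu + \varepsilon_\ell)/2)}
#' evaluated per sample; defined as 0 where both envelopes are 0.
#'
#' @param eps_mu,eps_ell upper and lower PP envelope traces (nonnegative,
#'   `eps_mu >= eps_ell`).
#' @return Per-sample PPV trace, percent.
#' @export
#' @examples
#' ppv_continuous(110, 90)  # 20
ppv_continuous <- function(eps_mu, eps_ell) {
  if (any(eps_mu < 0) || any(eps_ell < 0)) {
    stop("PP envelopes must be nonnegative")
  }
  denom <- (eps_mu + eps_ell) / 2
  out <- numeric(length(denom))
  nz <- denom > 0
  out[nz] <- 100 * (eps_mu[nz] - eps_ell[nz]) / denom[nz]
  out
}

#' Traditional per-cycle PPV from beat annotations
#'
#' The manual-standard comparator: each beat contributes a pulse pressure
#' PP = systolic peak value minus the value of the immediately preceding
#' diastolic trough; per respiratory cycle, PPV(%) =
#' 100 (PPmax - PPmin) / ((PPmax + PPmin)/2) over the beats whose systolic
#' peak falls in the cycle.  Cycles containing fewer than two beats are
#' flagged invalid (NA PPV) and should be excluded downstream.
#'
#' @param peaks data frame with `time_s`, `value` of systolic peaks.
#' @param troughs data frame with `time_s`, `value` of diastolic troughs.
#' @param cycles numeric vector of respiratory cycle boundary times
#'   (length `n_cycles + 1`), e.g. from [resp_cycle_boundaries()].
#' @return Data frame with one row per cycle: `cycle_start_s`,
#'   `cycle_end_s`, `n_beats`, `pp_max`, `pp_min`, `ppv_pct`, `valid`.
#' @export
ppv_per_cycle <- function(peaks, troughs, cycles) {
  stopifnot(length(cycles) >= 2L, !is.unsorted(cycles))
  # pair each peak with the latest preceding trough
  idx <- findInterval(peaks$time_s, troughs$time_s)
  keep <- idx >= 1L
  beat_t <- peaks$time_s[keep]
  pp <- peaks$value[keep] - troughs$value[idx[keep]]
  ncyc <- length(cycles) - 1L
  out <- data.frame(cycle_start_s = cycles[-length(cycles)],
                    cycle_end_s = cycles[-1L],
                    n_beats = 0L, pp_max = NA_real_, pp_min = NA_real_,
                    ppv_pct = NA_real_, valid = FALSE)
  cyc <- findInterval(beat_t, cycles, rightmost.closed = FALSE)
  for (i in seq_len(ncyc)) {
    ppi <- pp[cyc == i]
    out$n_beats[i] <- length(ppi)
    if (length(ppi) >= 2L) {
      out$pp_max[i] <- max(ppi)
      out$pp_min[i] <- min(ppi)
      out$ppv_pct[i] <- 100 * (out$pp_max[i] - out$pp_min[i]) /
        ((out$pp_max[i] + out$pp_min[i]) / 2)
      out$valid[i] <- TRUE
    }
  }
  out
}

#' Respiratory cycle boundaries from the unwrapped respiratory angle
#'
#' Cycle boundaries are the times at which the cumulative (unwrapped)
#' respiratory angle crosses integer multiples of `2pi`, located by linear
#' interpolation between samples; the model's own respiratory clock.
#'
#' @param time per-sample times, seconds.
#' @param theta_unwrapped cumulative respiratory angle, radians
#'   (nondecreasing).
#' @return Numeric vector of boundary times (including the time of the
#'   first crossing at or after the start).
#' @export
resp_cycle_boundaries <- function(time, theta_unwrapped) {
  stopifnot(length(time) == length(theta_unwrapped))
  k0 <- ceiling(theta_unwrapped[1] / (2 * pi) - 1e-12)
  k1 <- floor(theta_unwrapped[length(theta_unwrapped)] / (2 * pi) + 1e-12)
  if (k1 < k0) return(numeric(0))
  targets <- 2 * pi * seq(k0, k1)
  stats::approx(theta_unwrapped, time, xout = targets, ties = "ordered")$y
}
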