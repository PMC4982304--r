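#' Coefficient vector layout
#'
#' The Kalman state of the tracker is the flattened vector of sinusoidal
#' coefficients.  The layout is fixed: respiratory cosine coefficients
#' `r1[k]` (k ascending), respiratory sine coefficients `r2[k]`, cardiac
#' cosine `c1[k]`, cardiac sine `c2[k]`, then modulation cosine `m1[k, j]`
#' (cardiac index k outer, respiratory index j inner) and modulation sine
#' `m2[k, j]`.  Total dimension is
#' `2 * n_resp + 2 * n_card + 2 * n_card * n_resp`.
#'
#' @param n_card number of cardiac harmonics.
#' @param n_resp number of respiratory harmonics.
#' @return A list with the harmonic counts, total dimension `d`, named index
#'   vectors `r1, r2, c1, c2, m1, m2` into the flattened vector, and a
#'   `names` vector labelling every position.
#' @export
coef_layout <- function(n_card, n_resp) {
  n_card <- as.integer(n_card)
  n_resp <- as.integer(n_resp)
  stopifnot(n_card >= 1L, n_resp >= 0L)
  d <- 2L * n_resp + 2L * n_card + 2L * n_card * n_resp
  r1 <- seq_len(n_resp)
  r2 <- n_resp + seq_len(n_resp)
  c1 <- 2L * n_resp + seq_len(n_card)
  c2 <- 2L * n_resp + n_card + seq_len(n_card)
  m1 <- 2L * n_resp + 2L * n_card + seq_len(n_card * n_resp)
  m2 <- 2L * n_resp + 2L * n_card + n_card * n_resp + seq_len(n_card * n_resp)
  nm <- character(d)
  if (n_resp > 0L) {
    nm[r1] <- paste0("r1.", seq_len(n_resp))
    nm[r2] <- paste0("r2.", seq_len(n_resp))
  }
  nm[c1] <- paste0("c1.", seq_len(n_card))
  nm[c2] <- paste0("c2.", seq_len(n_card))
  if (n_resp > 0L) {
    kj <- expand.grid(j = seq_len(n_resp), k = seq_len(n_card))
    nm[m1] <- paste0("m1.", kj$k, ".", kj$j)
    nm[m2] <- paste0("m2.", kj$k, ".", kj$j)
  }
  list(n_card = n_card, n_resp = n_resp, d = d,
       r1 = r1, r2 = r2, c1 = c1, c2 = c2, m1 = m1, m2 = m2, names = nm)
}

# position of m-coefficient (component, cardiac k, respiratory j)
m_index <- function(layout, component, k, j) {
  base <- if (component == 1L) layout$m1 else layout$m2
  base[(k - 1L) * layout$n_resp + j]
}

#' Flatten and unflatten the coefficient state
#'
#' `flatten_coefs()` maps the block-structured coefficient arrays to the
#' flattened vector used by the Kalman recursion; `unflatten_coefs()` is its
#' exact inverse.  See [coef_layout()] for the ordering rule.
#'
#' @param resp 2 x n_resp matrix of respiratory coefficients (rows:
#'   cosine, sine component).
#' @param card 2 x n_card matrix of cardiac coefficients.
#' @param mod array of dim `c(2, n_card, n_resp)` of modulation
#'   coefficients.
#' @param layout a [coef_layout()].
#' @return `flatten_coefs()`: a numeric vector of length `layout$d`;
#'   `unflatten_coefs()`: a list with elements `resp`, `card`, `mod`.
#' @export
flatten_coefs <- function(resp, card, mod, layout) {
  resp <- matrix(as.numeric(resp), nrow = 2L)
  card <- matrix(as.numeric(card), nrow = 2L)
  stopifnot(ncol(resp) == layout$n_resp, ncol(card) == layout$n_card)
  x <- numeric(layout$d)
  if (layout$n_resp > 0L) {
    x[layout$r1] <- resp[1L, ]
    x[layout$r2] <- resp[2L, ]
  }
  x[layout$c1] <- card[1L, ]
  x[layout$c2] <- card[2L, ]
  if (layout$n_resp > 0L) {
    mod <- array(as.numeric(mod), dim = c(2L, layout$n_card, layout$n_resp))
    # k outer, j inner: transpose so j runs fastest
    x[layout$m1] <- as.numeric(t(mod[1L, , , drop = TRUE]))
    x[layout$m2] <- as.numeric(t(mod[2L, , , drop = TRUE]))
  }
  names(x) <- layout$names
  x
}

#' @rdname flatten_coefs
#' @param x flattened coefficient vector of length `layout$d`.
#' @export
unflatten_coefs <- function(x, layout) {
  stopifnot(length(x) == layout$d)
  x <- unname(x)
  resp <- matrix(0, 2L, layout$n_resp)
  if (layout$n_resp > 0L) {
    resp[1L, ] <- x[layout$r1]
    resp[2L, ] <- x[layout$r2]
  }
  card <- rbind(unname(x[layout$c1]), unname(x[layout$c2]))
  mod <- array(0, dim = c(2L, layout$n_card, layout$n_resp))
  if (layout$n_resp > 0L) {
    mod[1L, , ] <- t(matrix(x[layout$m1], nrow = layout$n_resp))
    mod[2L, , ] <- t(matrix(x[layout$m2], nrow = layout$n_resp))
  }
  list(resp = resp, card = card, mod = mod)
}

#' Reflecting frequency clip
#'
#' Confines a frequency to the admissible range `(f_min, f_max]` by
#' reflecting overshoot back off the nearest bound, so that particles
#' reaching a bound bounce back into the interior instead of sticking to it
#' (a hard saturation clip would trap them there).  Values already in range
#' are returned unchanged.  Overshoot of more than one reflection (i.e.
#' beyond the width of the range) indicates a mis-scaled frequency noise
#' variance and is an error.
#'
#' @param f frequency value(s), Hz.
#' @param f_min,f_max range bounds, Hz, with `f_min < f_max`.
#' @return Clipped frequency value(s), in `(f_min - eps, f_max]`.
#' @export
#' @examples
#' clip_frequency(0.55, 0.1, 0.5)  # reflects to 0.45
clip_frequency <- function(f, f_min, f_max) {
  if (!is.finite(f_min) || !is.finite(f_max) || f_min >= f_max) {
    stop("invalid frequency bounds: need f_min < f_max")
  }
  width <- f_max - f_min
  over <- pmax(f - f_max, f_min - f, 0)
  if (any(over >= width)) {
    stop("frequency overshoot beyond one reflection; ",
         "frequency noise variance is probably mis-scaled")
  }
  hi <- f > f_max
  lo <- f <= f_min
  f[hi] <- f_max - (f[hi] - f_max)
  f[lo] <- f_min + (f_min - f[lo])
  f
}

#' Measurement model of the ABP waveform
#'
#' Evaluates the noise-free mean of the amplitude-modulated multi-harmonic
#' measurement model: the respiratory baseline \eqn{\gamma} plus the cardiac
#' harmonic series, each cardiac partial \eqn{\kappa_k} scaled by its
#' respiratory amplitude-modulation factor \eqn{\rho_k}:
#' \deqn{y = \gamma + \sum_{k=1}^{N_c} \rho_k \kappa_k}
#' with
#' \eqn{\gamma = \sum_j r_{1j}\cos(j\theta^r) + r_{2j}\sin(j\theta^r)},
#' \eqn{\rho_k = 1 + \sum_j m_{1kj}\cos(j\theta^r) + m_{2kj}\sin(j\theta^r)}
#' and
#' \eqn{\kappa_k = c_{1k}\cos(k\theta^c) + c_{2k}\sin(k\theta^c)}.
#'
#' All of `theta_r`, `theta_c` may be vectors (sample-wise evaluation);
#' `coefs` is either a single flattened coefficient vector (shared across
#' samples) or an `N x d` matrix of per-sample coefficients.
#'
#' @param theta_r instantaneous respiratory angle(s), radians.
#' @param theta_c instantaneous cardiac angle(s), radians.
#' @param coefs flattened coefficient vector (length `layout$d`) or
#'   per-sample matrix (`N x d`).
#' @param layout a [coef_layout()].
#' @return A list with per-sample elements: `y` (mean signal), `gamma`
#'   (respiratory part), `rho` (`N x n_card` modulation factors) and
#'   `kappa` (`N x n_card` cardiac partials).
#' @export
abp_measure <- function(theta_r, theta_c, coefs, layout) {
  n <- max(length(theta_r), length(theta_c))
  theta_r <- rep_len(theta_r, n)
  theta_c <- rep_len(theta_c, n)
  if (is.matrix(coefs)) {
    stopifnot(ncol(coefs) == layout$d, nrow(coefs) == n)
  } else {
    stopifnot(length(coefs) == layout$d)
    coefs <- matrix(coefs, n, layout$d, byrow = TRUE)
  }
  nc <- layout$n_card
  nr <- layout$n_resp
  cosC <- cos(outer(theta_c, seq_len(nc)))
  sinC <- sin(outer(theta_c, seq_len(nc)))
  kappa <- coefs[, layout$c1, drop = FALSE] * cosC +
    coefs[, layout$c2, drop = FALSE] * sinC
  rho <- matrix(1, n, nc)
  gamma <- numeric(n)
  if (nr > 0L) {
    cosR <- cos(outer(theta_r, seq_len(nr)))
    sinR <- sin(outer(theta_r, seq_len(nr)))
    gamma <- rowSums(coefs[, layout$r1, drop = FALSE] * cosR +
                       coefs[, layout$r2, drop = FALSE] * sinR)
    for (k in seq_len(nc)) {
      jm <- (k - 1L) * nr + seq_len(nr)
      rho[, k] <- 1 +
        rowSums(coefs[, layout$m1[jm], drop = FALSE] * cosR +
                  coefs[, layout$m2[jm], drop = FALSE] * sinR)
    }
  }
  list(y = gamma + rowSums(rho * kappa), gamma = gamma,
       rho = rho, kappa = kappa)
}

#' Gradient of the measurement mean in the coefficients
#'
#' The measurement model is bilinear in the modulation and cardiac
#' coefficients, so the extended Kalman update linearizes it around the
#' current coefficient estimate.  The gradient entries are
#' `cos(j theta_r)` / `sin(j theta_r)` for the respiratory block,
#' `rho_k cos(k theta_c)` / `rho_k sin(k theta_c)` for the cardiac block and
#' `kappa_k cos(j theta_r)` / `kappa_k sin(j theta_r)` for the modulation
#' block, evaluated at the supplied coefficients.
#'
#' @inheritParams abp_measure
#' @return For scalar angles a length-`d` gradient vector, otherwise an
#'   `N x d` matrix of per-sample gradients.
#' @export
abp_measure_gradient <- function(theta_r, theta_c, coefs, layout) {
  n <- max(length(theta_r), length(theta_c))
  theta_r <- rep_len(theta_r, n)
  theta_c <- rep_len(theta_c, n)
  if (!is.matrix(coefs)) coefs <- matrix(coefs, n, layout$d, byrow = TRUE)
  parts <- abp_measure(theta_r, theta_c, coefs, layout)
  nc <- layout$n_card
  nr <- layout$n_resp
  H <- matrix(0, n, layout$d)
  cosC <- cos(outer(theta_c, seq_len(nc)))
  sinC <- sin(outer(theta_c, seq_len(nc)))
  H[, layout$c1] <- parts$rho * cosC
  H[, layout$c2] <- parts$rho * sinC
  if (nr > 0L) {
    cosR <- cos(outer(theta_r, seq_len(nr)))
    sinR <- sin(outer(theta_r, seq_len(nr)))
    H[, layout$r1] <- cosR
    H[, layout$r2] <- sinR
    for (k in seq_len(nc)) {
      jm <- (k - 1L) * nr + seq_len(nr)
      H[, layout$m1[jm]] <- parts$kappa[, k] * cosR
      H[, layout$m2[jm]] <- parts$kappa[, k] * sinR
    }
  }
  colnames(H) <- layout$names
  if (n == 1L) drop(H) else H
}

#' One step of the kinematic process model
#'
#' Advances angles by their instantaneous frequencies, steps the mean
#' frequencies through a clipped random walk, and mean-reverts the
#' instantaneous frequencies toward the (previous) mean frequencies with
#' autoregressive coefficient `ar_coeff`:
#' \deqn{\theta_{n+1} = \theta_n + 2\pi T_s f_n}
#' \deqn{\bar f_{n+1} = g[\bar f_n + u_{\bar f}]}
#' \deqn{f_{n+1} = g[\bar f_n + \alpha (f_n - \bar f_n) + u_f]}
#' where `g` is the reflecting clip ([clip_frequency()]).  Angles are
#' returned wrapped to `[0, 2pi)`.  Noise draws are supplied by the caller,
#' which keeps the operation deterministic.
#'
#' @param kin list with fields `f_resp`, `f_card`, `f_resp_mean`,
#'   `f_card_mean` (Hz) and `theta_resp`, `theta_card` (radians).
#' @param cfg a resolved [ppv_config()] (needs `sample_period`, the
#'   frequency ranges and `ar_coeff`).
#' @param noise named list/vector with the four frequency noise draws
#'   `u_fbar_resp`, `u_fbar_card`, `u_f_resp`, `u_f_card` (Hz); all zero by
#'   default.
#' @return The advanced kinematics, same shape as `kin`.
#' @export
propagate_kinematics <- function(kin, cfg,
                                 noise = c(u_fbar_resp = 0, u_fbar_card = 0,
                                           u_f_resp = 0, u_f_card = 0)) {
  ts <- cfg$sample_period
  a <- cfg$ar_coeff
  two_pi <- 2 * pi
  out <- kin
  out$theta_resp <- (kin$theta_resp + two_pi * ts * kin$f_resp) %% two_pi
  out$theta_card <- (kin$theta_card + two_pi * ts * kin$f_card) %% two_pi
  out$f_resp_mean <- clip_frequency(kin$f_resp_mean + noise[["u_fbar_resp"]],
                                    cfg$f_resp_min, cfg$f_resp_max)
  out$f_card_mean <- clip_frequency(kin$f_card_mean + noise[["u_fbar_card"]],
                                    cfg$f_card_min, cfg$f_card_max)
  out$f_resp <- clip_frequency(
    kin$f_resp_mean + a * (kin$f_resp - kin$f_resp_mean) + noise[["u_f_resp"]],
    cfg$f_resp_min, cfg$f_resp_max)
  out$f_card <- clip_frequency(
    kin$f_card_mean + a * (kin$f_card - kin$f_card_mean) + noise[["u_f_card"]],
    cfg$f_card_min, cfg$f_card_max)
  out
}

#' Process-noise diagonal of the coefficient random walk
#'
#' @param cfg a resolved [ppv_config()].
#' @param layout a [coef_layout()] consistent with `cfg`.
#' @return Length-`d` vector of per-step random-walk variances (respiratory,
#'   cardiac and modulation blocks).
#' @export
coef_process_noise <- function(cfg, layout) {
  q <- numeric(layout$d)
  q[c(layout$r1, layout$r2)] <- cfg$q_resp_coeff
  q[c(layout$c1, layout$c2)] <- cfg$q_card_coeff
  q[c(layout$m1, layout$m2)] <- cfg$q_mod_coeff
  q
}

#' Time update of the marginalized coefficient state
#'
#' Random-walk prediction: the mean is unchanged and the covariance grows by
#' the diagonal process-noise matrix of [coef_process_noise()].
#'
#' @param state list with `mean` (length-`d` vector) and `cov`
#'   (`d x d` covariance).
#' @inheritParams coef_process_noise
#' @return The predicted state, same shape.
#' @export
propagate_coefficients <- function(state, cfg, layout) {
  q <- coef_process_noise(cfg, layout)
  state$cov <- state$cov + diag(q, layout$d)
  state
}
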