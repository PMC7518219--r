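#' Sample sensory inputs from the truncated bivariate Gaussian
#'
#' Draws i.i.d. samples of (balance, complexity) from the bivariate Gaussian
#' with the given means, standard deviations and correlation, truncated to
#' the unit square and renormalized. Sampling is exact rejection from the
#' untruncated Gaussian (acceptance is about 97% at the standard
#' parameters); if fewer than `n` of `1000 * n` proposals land in the unit
#' square the parameters are reported as degenerate.
#'
#' Uses the current R RNG stream; call `set.seed()` first for
#' reproducibility.
#'
#' @param sensory A valid [sensory_params()] object.
#' @param n Number of samples, at least 1.
#' @return A data frame with columns `u_b`, `u_c`, all values in `[0, 1]`.
#' @export
#' @examples
#' set.seed(1)
#' u <- sample_sensory(standard_parameters()$individual$sensory, 1000)
#' cor(u$u_b, u$u_c)  # negative: balanced images tend to be simpler
sample_sensory <- function(sensory, n) {
  stopifnot(inherits(sensory, "sensory_params"), n >= 1)
  if (sensory$sigma_ub <= 0 || sensory$sigma_uc <= 0 ||
      abs(sensory$rho) >= 1)
    stop("invalid sensory parameters: sigmas must be positive, |rho| < 1")
  Sigma <- covariance_matrix(sensory)
  mu <- c(sensory$mu_b, sensory$mu_c)
  out <- matrix(NA_real_, 0, 2)
  proposed <- 0L
  budget <- 1000 * n
  while (nrow(out) < n) {
    m <- min(2L * n, budget - proposed)
    if (m <= 0L)
      stop("rejection budget exceeded: sensory parameters place negligible ",
           "mass in the unit square (degenerate)")
    cand <- MASS::mvrnorm(m, mu, Sigma)
    if (m == 1L) cand <- matrix(cand, 1, 2)
    proposed <- proposed + m
    keep <- cand[, 1] >= 0 & cand[, 1] <= 1 & cand[, 2] >= 0 & cand[, 2] <= 1
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  data.frame(u_b = out[1:n, 1], u_c = out[1:n, 2])
}

#' Zero-integral normalizer of the complexity reward
#'
#' The mean complexity reward is `phi + beta * exp(-(u_c - gamma)^2 /
#' (2 * theta^2))`; `phi` is the unique constant making its integral over
#' `[0, 1]` zero, so positive and negative rewards balance. Closed form via
#' the Gaussian CDF:
#' `phi = -beta * theta * sqrt(2 * pi) * (Phi((1 - gamma) / theta) - Phi(-gamma / theta))`.
#'
#' @param reward A [reward_params()] object (only `beta`, `gamma`, `theta`
#'   are used).
#' @return The scalar `phi` (non-positive for `beta >= 0`).
#' @export
#' @examples
#' compute_phi(reward_params(0.6, 0.1, 1, 0.75, 0.1, 0.1))  # about -0.2491
compute_phi <- function(reward) {
  stopifnot(inherits(reward, "reward_params"))
  -reward$beta * reward$theta * sqrt(2 * pi) *
    (stats::pnorm((1 - reward$gamma) / reward$theta) -
       stats::pnorm(-reward$gamma / reward$theta))
}

#' Mean and sampled balance reward
#'
#' The mean balance reward is the zero-integral line `-alpha + 2 * alpha *
#' u_b`; samples add untruncated Gaussian noise with standard deviation
#' `sigma_rb`, so rewards can be negative.
#'
#' @param u_b Balance values in `[0, 1]` (vectorized).
#' @param alpha Balance-reward slope scale.
#' @return `mean_balance_reward`: mean rewards. `sample_balance_reward`:
#'   noisy draws (uses the current RNG stream).
#' @export
mean_balance_reward <- function(u_b, alpha) {
  -alpha + 2 * alpha * u_b
}

#' @rdname mean_balance_reward
#' @param reward A [reward_params()] object.
#' @export
sample_balance_reward <- function(u_b, reward) {
  stopifnot(inherits(reward, "reward_params"))
  mean_balance_reward(u_b, reward$alpha) +
    stats::rnorm(length(u_b), 0, reward$sigma_rb)
}

#' Mean and sampled complexity reward
#'
#' With the `"gaussian"` reward form (the model), the mean is the
#' zero-integral inverted-U `phi + beta * exp(-(u_c - gamma)^2 / (2 *
#' theta^2))` (see [compute_phi()]) and noise has sd `sigma_rc`. With the
#' `"linear"` ablation form the complexity reward copies the balance
#' structure: mean `-alpha + 2 * alpha * u_c`, noise sd `sigma_rb`.
#'
#' @param u_c Complexity values in `[0, 1]` (vectorized).
#' @param reward A [reward_params()] object.
#' @return `mean_complexity_reward`: mean rewards. `sample_complexity_reward`:
#'   noisy draws (uses the current RNG stream).
#' @export
mean_complexity_reward <- function(u_c, reward) {
  stopifnot(inherits(reward, "reward_params"))
  if (reward$complexity_form == "linear")
    return(-reward$alpha + 2 * reward$alpha * u_c)
  compute_phi(reward) +
    reward$beta * exp(-(u_c - reward$gamma)^2 / (2 * reward$theta^2))
}

#' @rdname mean_complexity_reward
#' @export
sample_complexity_reward <- function(u_c, reward) {
  stopifnot(inherits(reward, "reward_params"))
  sd <- if (reward$complexity_form == "linear") reward$sigma_rb else reward$sigma_rc
  mean_complexity_reward(u_c, reward) + stats::rnorm(length(u_c), 0, sd)
}

#' Total stochastic reward for sensory samples
#'
#' The two components are drawn independently given `(u_b, u_c)` and summed:
#' `r_star = r_b + r_c`.
#'
#' @param u_b,u_c Sensory values in `[0, 1]` (equal-length vectors).
#' @param reward A [reward_params()] object.
#' @return Data frame with columns `r_b`, `r_c`, `r_star`.
#' @export
total_reward <- function(u_b, u_c, reward) {
  stopifnot(length(u_b) == length(u_c))
  r_b <- sample_balance_reward(u_b, reward)
  r_c <- sample_complexity_reward(u_c, reward)
  data.frame(r_b = r_b, r_c = r_c, r_star = r_b + r_c)
}

#' Mean motivation as a function of complexity
#'
#' The mean-field motivation `m_min + (m_max - m_min) * exp(-(u_c - mu_m)^2 /
#' (2 * sigma_m^2))`: a Gaussian bump of complexity, independent of balance,
#' bounded in `[m_min, m_max]` and maximal exactly at `u_c = mu_m`.
#' Motivation gates both received reward and the learning rate; it is
#' deterministic given the input (the mean-field simplification — motivation
#' noise itself is not simulated).
#'
#' @param u_c Complexity values (vectorized).
#' @param motivation A [motivation_params()] object.
#' @return Mean motivation values in `[m_min, m_max]`.
#' @export
#' @examples
#' m <- standard_parameters()$individual$motivation
#' mean_motivation(0.65, m)  # peak: 0.6
mean_motivation <- function(u_c, motivation) {
  stopifnot(inherits(motivation, "motivation_params"))
  motivation$m_min + (motivation$m_max - motivation$m_min) *
    exp(-(u_c - motivation$mu_m)^2 / (2 * motivation$sigma_m^2))
}
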