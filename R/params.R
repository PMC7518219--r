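#' Sensory input distribution parameters
#'
#' Parameters of the bivariate Gaussian over visual balance (`u_b`) and
#' visual complexity (`u_c`), truncated to the unit square when sampled.
#' The weight/input coordinate convention throughout the package is
#' index 1 = balance, index 2 = complexity.
#'
#' @param mu_b Mean balance (unitless). A warning is emitted if outside
#'   `[0, 1]`; the mean itself is not range-restricted, only samples are.
#' @param mu_c Mean complexity (unitless), same convention as `mu_b`.
#' @param sigma_ub Balance standard deviation, must be positive.
#' @param sigma_uc Complexity standard deviation, must be positive.
#' @param rho Balance-complexity correlation, in (-1, 1).
#'
#' @return An object of class `sensory_params`.
#' @seealso [covariance_matrix()], [sample_sensory()], [standard_parameters()]
#' @export
#' @examples
#' sensory_params(0.5, 0.5, 0.2, 0.2, -0.5)
sensory_params <- function(mu_b, mu_c, sigma_ub, sigma_uc, rho) {
  stopifnot(is.numeric(mu_b), is.numeric(mu_c), is.numeric(sigma_ub),
            is.numeric(sigma_uc), is.numeric(rho))
  if (mu_b < 0 || mu_b > 1 || mu_c < 0 || mu_c > 1)
    warning("sensory means outside [0,1]; samples are still truncated to the unit square")
  structure(list(mu_b = mu_b, mu_c = mu_c, sigma_ub = sigma_ub,
                 sigma_uc = sigma_uc, rho = rho),
            class = "sensory_params")
}

#' Reward structure parameters
#'
#' The balance reward is linear in `u_b` with slope scale `alpha` and mean
#' `-alpha + 2 * alpha * u_b`, so its integral over `[0, 1]` is zero. The
#' complexity reward is an inverted-U Gaussian bump of height `beta`,
#' location `gamma` and width `theta`, shifted by the normalizer `phi` (see
#' [compute_phi()]) so that it too integrates to zero over `[0, 1]`: positive
#' and negative rewards occur in equal amounts. Both components carry
#' untruncated Gaussian noise, so sampled rewards can be negative.
#'
#' @param alpha Balance-reward slope scale, positive.
#' @param sigma_rb Balance-reward noise standard deviation, positive.
#' @param beta Complexity-reward peak height, positive.
#' @param gamma Complexity-reward peak location, in `[0, 1]`.
#' @param theta Complexity-reward peak width, positive (only `theta^2` enters
#'   the bump, so positivity is a convention, not a restriction).
#' @param sigma_rc Complexity-reward noise standard deviation, positive.
#' @param complexity_form Either `"gaussian"` (the model's inverted-U form) or
#'   `"linear"`, which replaces the complexity reward with the balance form
#'   (`-alpha + 2 * alpha * u_c`, noise `sigma_rb`). The linear form is the
#'   "identical reward structures" ablation used in the competition
#'   experiments.
#'
#' @return An object of class `reward_params`.
#' @export
#' @examples
#' reward_params(0.6, 0.1, 1, 0.75, 0.1, 0.1)
reward_params <- function(alpha, sigma_rb, beta, gamma, theta, sigma_rc,
                          complexity_form = c("gaussian", "linear")) {
  complexity_form <- match.arg(complexity_form)
  stopifnot(is.numeric(alpha), is.numeric(sigma_rb), is.numeric(beta),
            is.numeric(gamma), is.numeric(theta), is.numeric(sigma_rc))
  structure(list(alpha = alpha, sigma_rb = sigma_rb, beta = beta,
                 gamma = gamma, theta = theta, sigma_rc = sigma_rc,
                 complexity_form = complexity_form),
            class = "reward_params")
}

#' Motivation function parameters
#'
#' Mean motivation is a Gaussian bump of complexity,
#' `m_min + (m_max - m_min) * exp(-(u_c - mu_m)^2 / (2 * sigma_m^2))`,
#' independent of balance. `mu_m` is the complexity of peak motivation,
#' `sigma_m` how quickly motivation falls away from it.
#'
#' @param m_min Minimal motivation, in `[0, 1]`.
#' @param m_max Maximal motivation, in `[0, 1]`, at least `m_min`.
#' @param mu_m Complexity of peak motivation, in `[0, 1]`.
#' @param sigma_m Motivation width, positive.
#'
#' @return An object of class `motivation_params`.
#' @seealso [mean_motivation()]
#' @export
motivation_params <- function(m_min, m_max, mu_m, sigma_m) {
  stopifnot(is.numeric(m_min), is.numeric(m_max), is.numeric(mu_m),
            is.numeric(sigma_m))
  structure(list(m_min = m_min, m_max = m_max, mu_m = mu_m,
                 sigma_m = sigma_m),
            class = "motivation_params")
}

#' Bundle the parameter vectors of one simulated individual
#'
#' @param sensory A [sensory_params()] object.
#' @param reward A [reward_params()] object.
#' @param motivation A [motivation_params()] object.
#' @param background Free-form label for the social/environmental background
#'   the individual comes from. Metadata only: populations are expressed as
#'   lists of individuals with hand-set parameters, never sampled from a
#'   background distribution.
#'
#' @return An object of class `individual`.
#' @export
individual <- function(sensory, reward, motivation, background = "standard") {
  stopifnot(inherits(sensory, "sensory_params"),
            inherits(reward, "reward_params"),
            inherits(motivation, "motivation_params"))
  structure(list(sensory = sensory, reward = reward, motivation = motivation,
                 background = as.character(background)),
            class = "individual")
}

#' Learning-loop configuration
#'
#' @param w0 Initial weight pair `c(balance, complexity)`.
#' @param epsilon Learning step of the discretized delta rule, positive.
#' @param n_steps Number of update steps, non-negative integer (0 leaves the
#'   weights at `w0`).
#' @param seed RNG seed (integer) or `NULL` to use the current RNG state.
#' @param record_start First step index to record (0 records the initial
#'   weights as well).
#' @param record_stride Record every `record_stride`-th step from
#'   `record_start` on.
#' @param motivation_mode `"mean_field"` (the motivation function of
#'   complexity) or `"constant"` (fixed motivation `motivation_constant`,
#'   the constant-motivation ablation).
#' @param motivation_constant Constant motivation level in `[0, 1]`, used
#'   only when `motivation_mode = "constant"`.
#'
#' @return An object of class `learning_config`.
#' @export
learning_config <- function(w0 = c(0, 0), epsilon = 0.01, n_steps = 30000,
                            seed = NULL, record_start = 0, record_stride = 1,
                            motivation_mode = c("mean_field", "constant"),
                            motivation_constant = 1) {
  motivation_mode <- match.arg(motivation_mode)
  stopifnot(length(w0) == 2, is.numeric(w0), epsilon > 0,
            n_steps >= 0, record_start >= 0, record_stride >= 1)
  if (motivation_mode == "constant")
    stopifnot(motivation_constant >= 0, motivation_constant <= 1)
  structure(list(w0 = as.numeric(w0), epsilon = epsilon,
                 n_steps = as.integer(n_steps),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 record_start = as.integer(record_start),
                 record_stride = as.integer(record_stride),
                 motivation_mode = motivation_mode,
                 motivation_constant = motivation_constant),
            class = "learning_config")
}

#' Standard parameter set
#'
#' The standard individual and learning configuration used throughout the
#' shipped experiments: sensory `[0.5, 0.5, 0.2, 0.2, -0.5]`, reward
#' `[0.6, 0.1, 1, 0.75, 0.1, 0.1]`, motivation `[0.1, 0.6, 0.65, 0.1]`,
#' initial weights `[0, 0]`, step `epsilon = 0.01`, unit time step.
#'
#' @param n_steps Simulation horizon (default 30000).
#' @param seed Optional RNG seed forwarded to the configuration.
#' @return A list with components `individual` and `config`.
#' @export
#' @examples
#' std <- standard_parameters()
#' std$individual$motivation$m_max
standard_parameters <- function(n_steps = 30000, seed = NULL) {
  list(
    individual = individual(
      sensory    = sensory_params(0.5, 0.5, 0.2, 0.2, -0.5),
      reward     = reward_params(0.6, 0.1, 1, 0.75, 0.1, 0.1),
      motivation = motivation_params(0.1, 0.6, 0.65, 0.1)
    ),
    config = learning_config(w0 = c(0, 0), epsilon = 0.01,
                             n_steps = n_steps, seed = seed)
  )
}

#' Validate an individual's parameters
#'
#' Checks every range invariant of the three parameter vectors and returns a
#' character vector of human-readable violations (empty when the individual
#' is valid). Constructors do not enforce ranges, so that invalid candidates
#' can be constructed and reported on; samplers and analyses refuse invalid
#' parameters.
#'
#' @param ind An [individual()].
#' @return Character vector of violations, empty if valid.
#' @export
#' @examples
#' validate_individual(standard_parameters()$individual)
validate_individual <- function(ind) {
  stopifnot(inherits(ind, "individual"))
  s <- ind$sensory; r <- ind$reward; m <- ind$motivation
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(s$sigma_ub > 0, "sigma_ub must satisfy sigma_ub > 0")
  chk(s$sigma_uc > 0, "sigma_uc must satisfy sigma_uc > 0")
  chk(s$rho > -1 && s$rho < 1, "rho must satisfy -1 < rho < 1")
  chk(r$alpha > 0, "alpha must satisfy alpha > 0")
  chk(r$sigma_rb > 0, "sigma_rb must satisfy sigma_rb > 0")
  chk(r$beta > 0, "beta must satisfy beta > 0")
  chk(r$gamma >= 0 && r$gamma <= 1, "gamma must satisfy 0 <= gamma <= 1")
  chk(r$theta > 0, "theta must satisfy theta > 0")
  chk(r$sigma_rc > 0, "sigma_rc must satisfy sigma_rc > 0")
  chk(m$m_min >= 0 && m$m_min <= 1, "m_min must satisfy 0 <= m_min <= 1")
  chk(m$m_max >= 0 && m$m_max <= 1, "m_max must satisfy 0 <= m_max <= 1")
  chk(m$m_min <= m$m_max, "m_min must satisfy m_min <= m_max")
  chk(m$mu_m >= 0 && m$mu_m <= 1, "mu_m must satisfy 0 <= mu_m <= 1")
  chk(m$sigma_m > 0, "sigma_m must satisfy sigma_m > 0")
  v
}

# stop()s on the first invalid individual; used as the samplers' precondition
assert_valid <- function(ind) {
  v <- validate_individual(ind)
  if (length(v))
    stop("invalid individual parameters: ", paste(v, collapse = "; "))
  invisible(ind)
}

#' Covariance matrix of the (untruncated) sensory Gaussian
#'
#' @param sensory A [sensory_params()] object.
#' @return A symmetric 2x2 matrix.
#' @export
covariance_matrix <- function(sensory) {
  stopifnot(inherits(sensory, "sensory_params"))
  off <- sensory$rho * sensory$sigma_ub * sensory$sigma_uc
  matrix(c(sensory$sigma_ub^2, off, off, sensory$sigma_uc^2), 2, 2)
}

#' @export
print.individual <- function(x, ...) {
  cat("<individual> background:", x$background, "\n")
  cat(sprintf("  sensory    [mu_b, mu_c, sigma_ub, sigma_uc, rho] = [%g, %g, %g, %g, %g]\n",
              x$sensory$mu_b, x$sensory$mu_c, x$sensory$sigma_ub,
              x$sensory$sigma_uc, x$sensory$rho))
  cat(sprintf("  reward     [alpha, sigma_rb, beta, gamma, theta, sigma_rc] = [%g, %g, %g, %g, %g, %g] (%s complexity reward)\n",
              x$reward$alpha, x$reward$sigma_rb, x$reward$beta,
              x$reward$gamma, x$reward$theta, x$reward$sigma_rc,
              x$reward$complexity_form))
  cat(sprintf("  motivation [m_min, m_max, mu_m, sigma_m] = [%g, %g, %g, %g]\n",
              x$motivation$m_min, x$motivation$m_max, x$motivation$mu_m,
              x$motivation$sigma_m))
  invisible(x)
}
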