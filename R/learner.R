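#' Estimated reward (aesthetic value) of an input
#'
#' `v = m_bar * (w . u)`: the motivation-gated linear prediction of reward.
#'
#' @param w Weight pair `c(balance, complexity)`.
#' @param u Input pair `c(u_b, u_c)`.
#' @param m_bar Motivation in `[0, 1]`.
#' @return The scalar value `v`.
#' @export
#' @examples
#' aesthetic_value(c(1, 2), c(0.5, 0.25), 0.5)  # 0.5
aesthetic_value <- function(w, u, m_bar) {
  stopifnot(length(w) == 2, length(u) == 2)
  m_bar * sum(w * u)
}

#' One motivation-gated delta-rule update
#'
#' `w' = w + epsilon * m_bar * (r_star - w . u) * u`, the discretized
#' learning rule. With zero motivation the weights do not move: no
#' motivation, no action, no learning.
#'
#' @param w Current weight pair.
#' @param u Input pair in the unit square.
#' @param r_star Total (fully motivated) reward for this input.
#' @param m_bar Motivation in `[0, 1]`.
#' @param epsilon Learning step, positive.
#' @return The updated weight pair.
#' @export
update_step <- function(w, u, r_star, m_bar, epsilon) {
  stopifnot(length(w) == 2, length(u) == 2, epsilon > 0)
  w + epsilon * m_bar * (r_star - sum(w * u)) * u
}

#' Run the stochastic learning loop
#'
#' Executes the simulation algorithm for `config$n_steps` steps: draw a
#' sensory input from the truncated bivariate Gaussian, draw the balance and
#' complexity rewards and sum them, evaluate the mean motivation at the
#' input, and apply the delta-rule update. All stochastic draws for the run
#' are generated from one RNG stream seeded by `config$seed` (sensory
#' samples first, then balance-reward noise, then complexity-reward noise),
#' so a trajectory is bit-reproducible from its configuration.
#'
#' The recorded trajectory stores, for each recorded step `k`, the weights
#' *after* update `k` together with the input, reward, motivation,
#' prediction `v` and prediction error `delta` that produced the update
#' (`v` and `delta` are evaluated at the pre-update weights). Step 0 holds
#' the initial weights with `NA` sample columns.
#'
#' @param ind A valid [individual()].
#' @param config A [learning_config()].
#' @return An `aesthetic_trajectory`: a data frame with columns `step`,
#'   `w_b`, `w_c`, `u_b`, `u_c`, `r_star`, `m_bar`, `delta`, `v` and
#'   attributes `individual` and `config`.
#' @export
#' @examples
#' std <- standard_parameters(n_steps = 500, seed = 1)
#' traj <- run_simulation(std$individual, std$config)
#' tail(traj, 2)
run_simulation <- function(ind, config) {
  assert_valid(ind)
  stopifnot(inherits(config, "learning_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_steps
  eps <- config$epsilon

  if (n > 0) {
    u <- sample_sensory(ind$sensory, n)
    r_b <- sample_balance_reward(u$u_b, ind$reward)
    r_c <- sample_complexity_reward(u$u_c, ind$reward)
    r_star <- r_b + r_c
    m_bar <- if (config$motivation_mode == "constant")
      rep(config$motivation_constant, n)
    else
      mean_motivation(u$u_c, ind$motivation)
  }

  w <- config$w0
  rec_steps <- seq(config$record_start, n, by = config$record_stride)
  rec <- matrix(NA_real_, length(rec_steps), 8,
                dimnames = list(NULL, c("w_b", "w_c", "u_b", "u_c",
                                        "r_star", "m_bar", "delta", "v")))
  ri <- 1L
  if (length(rec_steps) && rec_steps[1] == 0L) {
    rec[1L, c("w_b", "w_c")] <- w
    ri <- 2L
  }
  if (n > 0) {
    ub <- u$u_b; uc <- u$u_c
    for (k in seq_len(n)) {
      dot <- w[1] * ub[k] + w[2] * uc[k]
      delta <- m_bar[k] * (r_star[k] - dot)
      w <- w + eps * delta * c(ub[k], uc[k])
      if (ri <= length(rec_steps) && rec_steps[ri] == k) {
        rec[ri, ] <- c(w, ub[k], uc[k], r_star[k], m_bar[k], delta,
                       m_bar[k] * dot)
        ri <- ri + 1L
      }
    }
    if (!all(is.finite(w)) || any(abs(w) > 1e6))
      stop("weights diverged (|w| > 1e6 or non-finite); ",
           "the learning step epsilon is likely too large")
  }
  out <- data.frame(step = rec_steps, rec)
  structure(out, class = c("aesthetic_trajectory", "data.frame"),
            individual = ind, config = config)
}

#' @export
print.aesthetic_trajectory <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<aesthetic_trajectory> %d recorded steps (horizon %d, epsilon %g, seed %s)\n",
              nrow(x), cfg$n_steps, cfg$epsilon,
              if (is.null(cfg$seed)) "none" else cfg$seed))
  w <- x[nrow(x), c("w_b", "w_c")]
  cat(sprintf("  final weights: w_b = %.4f, w_c = %.4f\n", w[[1]], w[[2]]))
  invisible(x)
}

#' Plot weight dynamics and the phase plane of a trajectory
#'
#' Left panel: both weights against time. Right panel: complexity weight
#' against balance weight (the phase plot in which the late-time stochastic
#' cloud is visible).
#'
#' @param x An `aesthetic_trajectory`.
#' @param ... Passed to `matplot()`.
#' @export
plot.aesthetic_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(x$step, cbind(x$w_b, x$w_c), type = "l", lty = 1,
                    col = c("steelblue", "firebrick"),
                    xlab = "step", ylab = "weight", ...)
  graphics::legend("bottomright", c("balance", "complexity"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  graphics::plot(x$w_b, x$w_c, type = "l", col = "grey40",
                 xlab = "balance weight", ylab = "complexity weight")
  invisible(x)
}
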