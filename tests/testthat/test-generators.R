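test_that("phi matches adaptive-quadrature oracle and its analytic limits", {
  cases <- list(c(1, 0.75, 0.1), c(0.5, 0.2, 0.3), c(2, 1, 0.05),
                c(1, 0, 0.5))
  for (p in cases) {
    rw <- reward_params(0.6, 0.1, p[1], p[2], p[3], 0.1)
    oracle <- -stats::integrate(function(u)
      p[1] * exp(-(u - p[2])^2 / (2 * p[3]^2)), 0, 1,
      rel.tol = 1e-12)$value
    expect_equal(compute_phi(rw), oracle, tolerance = 1e-10)
  }
  # standard parameters: the frozen quadrature value
  expect_equal(compute_phi(reward_params(0.6, 0.1, 1, 0.75, 0.1, 0.1)),
               -0.2491063, tolerance = 1e-6)
  # no bump: the zero-integral constraint forces zero
  expect_equal(compute_phi(reward_params(0.6, 0.1, 0, 0.75, 0.1, 0.1)), 0)
  # very wide bump flattens to height beta, so phi -> -beta
  expect_equal(compute_phi(reward_params(0.6, 0.1, 1, 0.5, 1e6, 0.1)), -1,
               tolerance = 1e-9)
})

test_that("both mean-reward curves integrate to zero over the unit interval", {
  rw <- std_individual()$reward
  ib <- stats::integrate(mean_balance_reward, 0, 1, alpha = rw$alpha,
                         rel.tol = 1e-13)$value
  ic <- stats::integrate(mean_complexity_reward, 0, 1, reward = rw,
                         rel.tol = 1e-13)$value
  expect_lt(abs(ib), 1e-10)
  expect_lt(abs(ic), 1e-10)
  # the linear ablation form keeps the zero-integral property
  rw$complexity_form <- "linear"
  il <- stats::integrate(mean_complexity_reward, 0, 1, reward = rw,
                         rel.tol = 1e-13)$value
  expect_lt(abs(il), 1e-10)
})

test_that("mean reward curves hit their characteristic points", {
  rw <- std_individual()$reward
  expect_equal(mean_balance_reward(0.5, 123), 0)   # midpoint of the line
  expect_equal(mean_balance_reward(1, 0.6), 0.6)
  expect_equal(mean_balance_reward(0, 0.6), -0.6)
  phi <- compute_phi(rw)
  expect_equal(mean_complexity_reward(rw$gamma, rw), phi + rw$beta)
  # 7.5 sigma from the peak the bump is negligible: mean is essentially phi
  expect_equal(mean_complexity_reward(0, rw), phi, tolerance = 1e-8)
})

test_that("reward samples have the specified first two moments", {
  rw <- std_individual()$reward
  n <- 1e5
  withr::with_seed(11, {
    rb <- sample_balance_reward(rep(0.3, n), rw)
    expect_equal(mean(rb), mean_balance_reward(0.3, rw$alpha),
                 tolerance = 4 * rw$sigma_rb / sqrt(n) /
                   abs(mean_balance_reward(0.3, rw$alpha)))
    r <- total_reward(rep(0.3, n), rep(0.6, n), rw)
    expect_equal(r$r_star, r$r_b + r$r_c)
    expect_equal(var(r$r_star), rw$sigma_rb^2 + rw$sigma_rc^2,
                 tolerance = 0.05)
    # grand mean over uniform inputs is zero: both curves integrate to zero
    u <- matrix(runif(2 * n), ncol = 2)
    g <- total_reward(u[, 1], u[, 2], rw)
    expect_lt(abs(mean(g$r_star)), 4 * sd(g$r_star) / sqrt(n))
  })
  # noiseless limit: the sample equals the mean curve
  quiet <- reward_params(0.6, 1e-15, 1, 0.75, 0.1, 1e-15)
  r0 <- total_reward(0.3, 0.6, quiet)
  expect_equal(r0$r_star,
               mean_balance_reward(0.3, 0.6) + mean_complexity_reward(0.6, quiet),
               tolerance = 1e-12)
})

test_that("mean motivation is a bounded, symmetric bump peaking at mu_m", {
  m <- std_individual()$motivation
  expect_equal(mean_motivation(m$mu_m, m), 0.6)  # peak equals m_max
  # frozen hand evaluation at u_c = 1: 0.1 + 0.5 * exp(-6.125)
  expect_equal(mean_motivation(1, m), 0.1 + 0.5 * exp(-6.125))
  expect_equal(mean_motivation(1, m), 0.1010937, tolerance = 1e-6)
  u <- seq(-0.5, 1.5, length.out = 401)
  v <- mean_motivation(u, m)
  expect_true(all(v >= m$m_min & v <= m$m_max))
  expect_equal(which.max(v), which.min(abs(u - m$mu_m)))
  expect_equal(mean_motivation(m$mu_m + 0.2, m), mean_motivation(m$mu_m - 0.2, m))
  # degenerate amplitude: constant motivation
  mc <- motivation_params(0.4, 0.4, 0.65, 0.1)
  expect_equal(mean_motivation(u, mc), rep(0.4, length(u)))
})

test_that("sensory samples are supported on the unit square and reproducible", {
  s <- std_individual()$sensory
  withr::with_seed(7, u <- sample_sensory(s, 1e5))
  expect_true(all(u$u_b >= 0 & u$u_b <= 1 & u$u_c >= 0 & u$u_c <= 1))
  expect_lt(cor(u$u_b, u$u_c), 0)  # balance and complexity anticorrelate
  withr::with_seed(7, u2 <- sample_sensory(s, 1e5))
  expect_identical(u, u2)
})

test_that("uncorrelated sensory parameters give near-zero empirical correlation", {
  s <- sensory_params(0.5, 0.5, 0.2, 0.2, 0)
  n <- 3e4
  withr::with_seed(21, u <- sample_sensory(s, n))
  expect_lt(abs(cor(u$u_b, u$u_c)), 3 / sqrt(n))
})

test_that("sensory moments match quadrature of the truncated density", {
  s <- std_individual()$sensory
  n <- 1e5
  withr::with_seed(5, u <- sample_sensory(s, n))
  # independent oracle: adaptive 2-D quadrature of the truncated density
  dens <- function(x, y) {
    zx <- (x - s$mu_b) / s$sigma_ub
    zy <- (y - s$mu_c) / s$sigma_uc
    exp(-(zx^2 - 2 * s$rho * zx * zy + zy^2) / (2 * (1 - s$rho^2)))
  }
  Z <- pracma::integral2(dens, 0, 1, 0, 1, reltol = 1e-10)$Q
  mom <- function(f) pracma::integral2(function(x, y) f(x, y) * dens(x, y),
                                       0, 1, 0, 1, reltol = 1e-10)$Q / Z
  eb <- mom(function(x, y) x); ec <- mom(function(x, y) y)
  vb <- mom(function(x, y) x^2) - eb^2
  vc <- mom(function(x, y) y^2) - ec^2
  cbc <- mom(function(x, y) x * y) - eb * ec
  expect_equal(mean(u$u_b), eb, tolerance = 4 * sqrt(vb / n) / eb)
  expect_equal(mean(u$u_c), ec, tolerance = 4 * sqrt(vc / n) / ec)
  expect_equal(cor(u$u_b, u$u_c), cbc / sqrt(vb * vc), tolerance = 0.02)
})

test_that("degenerate sensory widths collapse samples onto the mean", {
  s <- sensory_params(0.4, 0.7, 1e-9, 1e-9, 0)
  withr::with_seed(3, u <- sample_sensory(s, 100))
  expect_equal(u$u_b, rep(0.4, 100), tolerance = 1e-6)
  expect_equal(u$u_c, rep(0.7, 100), tolerance = 1e-6)
})

test_that("parameters with negligible mass in the unit square are rejected", {
  s <- suppressWarnings(sensory_params(25, 25, 0.5, 0.5, 0))
  withr::with_seed(4, expect_error(sample_sensory(s, 10), "degenerate"))
})
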