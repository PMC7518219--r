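test_that("fixed point vanishes when all mean rewards vanish", {
  ind <- modified_individual(reward = list(alpha = 1e-12, beta = 1e-12))
  fp <- fixed_point(ind)
  expect_lt(max(abs(fp$w_star)), 1e-9)
})

test_that("exchange-symmetric setups have equal fixed-point components", {
  ind <- modified_individual(reward = list(complexity_form = "linear"),
                             motivation = list(m_min = 0.5, m_max = 0.5))
  fp <- fixed_point(ind)
  expect_equal(fp$w_star[1], fp$w_star[2], tolerance = 1e-10)
  # eigen directions of the curvature align with the two diagonals
  v <- fp$A %*% c(1, 1)
  expect_lt(abs(v[1] - v[2]), 1e-12)
})

test_that("standard fixed point favours complexity over balance", {
  fp <- fixed_point(std_individual())
  expect_gt(fp$w_star[2], fp$w_star[1])
  expect_gt(fp$w_star[1], 0)
  # A w* = b within quadrature tolerance, A symmetric positive definite
  expect_lt(max(abs(fp$A %*% fp$w_star - fp$b)), 1e-12)
  expect_true(all(eigen(fp$A, symmetric = TRUE)$values > 0))
})

test_that("expected error is a convex quadratic minimized at the fixed point", {
  ind <- std_individual()
  fp <- fixed_point(ind)
  e_star <- expected_error(fp$w_star, ind)
  expect_gt(e_star, 0)  # the linear model cannot represent the bump exactly
  withr::with_seed(8, {
    for (i in 1:20) {
      d <- rnorm(2); d <- d / sqrt(sum(d^2)) * runif(1, 0.01, 1)
      expect_gte(expected_error(fp$w_star + d, ind), e_star)
    }
  })
})

test_that("quadrature error matches an independent Monte-Carlo estimate", {
  ind <- std_individual()
  eq <- expected_error(c(0, 0), ind)
  withr::with_seed(13, mc <- monte_carlo_error(c(0, 0), ind, n = 2e5))
  expect_lt(abs(eq - mc$E), 3 * mc$se)
})

test_that("quadrature moments are converged: order doubling changes nothing", {
  ind <- std_individual()
  f60 <- fixed_point(ind, order = 60)
  f120 <- fixed_point(ind, order = 120)
  expect_equal(f60$w_star, f120$w_star, tolerance = 1e-10)
  expect_equal(f60$A, f120$A, tolerance = 1e-12)
})

test_that("independent optimizer over adaptively integrated error finds w_star", {
  ind <- std_individual()
  s <- ind$sensory
  dens <- function(x, y) {
    zx <- (x - s$mu_b) / s$sigma_ub
    zy <- (y - s$mu_c) / s$sigma_uc
    exp(-(zx^2 - 2 * s$rho * zx * zy + zy^2) / (2 * (1 - s$rho^2)))
  }
  Z <- pracma::integral2(dens, 0, 1, 0, 1, reltol = 1e-9)$Q
  E_indep <- function(w) {
    f <- function(x, y) {
      rbar <- mean_balance_reward(x, ind$reward$alpha) +
        mean_complexity_reward(y, ind$reward)
      mean_motivation(y, ind$motivation) * (rbar - w[1] * x - w[2] * y)^2 *
        dens(x, y)
    }
    pracma::integral2(f, 0, 1, 0, 1, reltol = 1e-9)$Q / Z
  }
  opt <- stats::optim(c(0, 0), E_indep, method = "BFGS")
  expect_equal(opt$par, fixed_point(ind)$w_star, tolerance = 2e-4)
})

test_that("grid search over the error surface agrees with the closed-form minimizer", {
  withr::with_seed(41, {
    for (i in 1:5) {
      ind <- individual(
        sensory = sensory_params(runif(1, 0.2, 0.8), runif(1, 0.2, 0.8),
                                 runif(1, 0.1, 0.4), runif(1, 0.1, 0.4),
                                 runif(1, -0.7, 0.7)),
        reward = reward_params(runif(1, 0.2, 1.5), 0.1, runif(1, 0.3, 1.5),
                               runif(1, 0.1, 0.9), runif(1, 0.08, 0.4), 0.1),
        motivation = motivation_params(0.1, runif(1, 0.3, 1),
                                       runif(1, 0.2, 0.9), runif(1, 0.08, 0.4))
      )
      fp <- fixed_point(ind)
      gb <- seq(fp$w_star[1] - 1, fp$w_star[1] + 1, length.out = 101)
      gc <- seq(fp$w_star[2] - 1, fp$w_star[2] + 1, length.out = 101)
      surf <- error_surface(ind, w_b = gb, w_c = gc)
      cell <- c(diff(gb)[1], diff(gc)[1])
      expect_lt(abs(surf$w_min$w_b - fp$w_star[1]), cell[1] + 1e-12)
      expect_lt(abs(surf$w_min$w_c - fp$w_star[2]), cell[2] + 1e-12)
    }
  })
})

test_that("the error surface is a hammock at standard parameters", {
  surf <- error_surface(std_individual())
  expect_gte(surf$anisotropy, 1)
  expect_gt(surf$anisotropy, 5)   # strongly anisotropic, not a bowl
  expect_true(all(surf$grid$E >= 0))
  fp <- fixed_point(std_individual())
  expect_gte(min(surf$grid$E), 0)
  expect_lt(min(surf$grid$E) - expected_error(fp$w_star, std_individual()),
            1e-3)
})

test_that("hyperplane geometry encodes weight redundancy", {
  u <- c(0.4, 0.7); m <- 0.5
  h <- hyperplane(u, m, v_target = 0.2)
  expect_equal(h$a, m * u)
  # a point on the plane has zero distance
  w_on <- c(0.2 / (m * 0.4) / 2, 0.2 / (m * 0.7) / 2)
  expect_equal(sum(h$a * w_on), 0.2)
  expect_equal(hyperplane_distance(w_on, u, m, r_star = 0.2 / m), 0)
  # distinct weight pairs with equal a . w produce identical values
  w1 <- c(1, 0.2)
  w2 <- w1 + 3 * c(-h$a[2], h$a[1])  # move along the plane
  expect_equal(aesthetic_value(w1, u, m), aesthetic_value(w2, u, m))
  # undefined when motivation (or the input) vanishes
  expect_warning(d <- hyperplane_distance(c(1, 1), u, 0, 1), "undefined")
  expect_true(is.na(d))
})

test_that("value landscapes report argmax, mode and probe values", {
  m <- std_individual()$motivation
  zero <- value_landscape(c(0, 0), m, resolution = 21)
  expect_true(all(zero$grid$V == 0))

  flat_m <- motivation_params(1, 1, 0.5, 0.1)
  vb <- value_landscape(c(1, 0), flat_m, resolution = 51)
  expect_equal(vb$grid$V, vb$grid$u_b)
  expect_equal(vb$argmax$u_b, 1)

  fp <- fixed_point(std_individual())
  land <- value_landscape(fp$w_star, m, resolution = 201,
                          sensory = std_individual()$sensory,
                          probes = data.frame(u_b = 0.5, u_c = 0.5))
  expect_equal(unlist(land$mode[c("u_b", "u_c")], use.names = FALSE),
               c(0.5, 0.5))
  expect_gt(land$argmax$V, land$mode$V)      # value exaggeration
  expect_true(land$argmax$u_b != land$mode$u_b ||
                land$argmax$u_c != land$mode$u_c)
  expect_equal(land$probes$V, land$mode$V)   # probe at the mode agrees
})

test_that("value time courses start at zero and respect the motivation bound", {
  std <- standard_parameters(n_steps = 3000, seed = 9)
  tr <- run_simulation(std$individual, std$config)
  probes <- default_probes()
  tc <- value_timecourse(tr, probes)
  expect_equal(unlist(tc[1, -1], use.names = FALSE), rep(0, nrow(probes)))
  for (i in seq_len(nrow(probes))) {
    mb <- mean_motivation(probes$u_c[i], std$individual$motivation)
    bound <- mb * sqrt(tr$w_b^2 + tr$w_c^2) *
      sqrt(probes$u_b[i]^2 + probes$u_c[i]^2)
    expect_true(all(abs(tc[[i + 1]]) <= bound + 1e-12))
  }
})

test_that("competition metrics of a frozen learner reduce to the initial weights", {
  std <- standard_parameters()
  frozen <- run_simulation(std$individual,
                           std_config(n_steps = 300, seed = 1, w0 = c(0.4, 0.1),
                                      motivation_mode = "constant",
                                      motivation_constant = 0))
  m <- competition_metrics(frozen)
  expect_equal(m$separation, 0.1 - 0.4)
  expect_equal(m$divergence, 0)
  expect_true(is.na(m$increment_correlation))
  expect_error(competition_metrics(frozen, window_fraction = 2), "window")
})

test_that("degenerate motivation is reported, not silently analyzed", {
  ind <- std_individual()
  expect_error(expected_error(c(0, 0), ind, motivation_constant = 0),
               "undefined")
  expect_error(fixed_point(ind, motivation_constant = 0), "degenerate|singular")
})
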