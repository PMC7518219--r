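# Quadrature machinery for expectations under the truncated input density.
#
# All expectations are computed with a fixed-order Gauss-Legendre product
# rule on [0,1]^2. The narrow reward bump (theta = 0.1) and motivation bump
# (sigma_m = 0.1) need fine resolution, hence the default order of 80 nodes
# per axis; convergence is verified by order doubling in the test suite.

# unnormalized bivariate Gaussian density on the grid
gaussian_density_2d <- function(ub, uc, sensory) {
  zx <- (ub - sensory$mu_b) / sensory$sigma_ub
  zy <- (uc - sensory$mu_c) / sensory$sigma_uc
  r <- sensory$rho
  exp(-(zx^2 - 2 * r * zx * zy + zy^2) / (2 * (1 - r^2)))
}

# Gauss-Legendre product grid with the truncated-density probability
# weights P (summing to 1), motivation and mean total reward at the nodes.
quad_grid <- function(ind, order = 80, motivation_constant = NULL) {
  gl <- pracma::gaussLegendre(order, 0, 1)
  UB <- matrix(gl$x, order, order)        # u_b varies along rows
  UC <- t(UB)                             # u_c varies along columns
  W <- outer(gl$w, gl$w)
  D <- gaussian_density_2d(UB, UC, ind$sensory)
  Z <- sum(W * D)
  if (Z < 1e-12)
    stop("degenerate sensory density: negligible mass in the unit square")
  mbar <- if (is.null(motivation_constant))
    mean_motivation(UC, ind$motivation)
  else
    matrix(motivation_constant, order, order)
  rbar <- mean_balance_reward(UB, ind$reward$alpha) +
    mean_complexity_reward(UC, ind$reward)
  list(UB = UB, UC = UC, P = W * D / Z, mbar = mbar, rbar = rbar, Z = Z)
}

# Motivation-weighted moments defining the quadratic error functional:
# E(w) = w' A w - 2 b' w + c, with
#   A = E[mbar u u'], b = E[mbar rbar u],
#   c = E[mbar (rbar^2 + sigma_rb^2 + sigma_rc^2)].
moment_matrices <- function(ind, order = 80, motivation_constant = NULL) {
  g <- quad_grid(ind, order, motivation_constant)
  A <- matrix(c(sum(g$P * g$mbar * g$UB * g$UB),
                sum(g$P * g$mbar * g$UB * g$UC),
                sum(g$P * g$mbar * g$UB * g$UC),
                sum(g$P * g$mbar * g$UC * g$UC)), 2, 2)
  b <- c(sum(g$P * g$mbar * g$rbar * g$UB),
         sum(g$P * g$mbar * g$rbar * g$UC))
  s2 <- ind$reward$sigma_rb^2 +
    (if (ind$reward$complexity_form == "linear") ind$reward$sigma_rb^2
     else ind$reward$sigma_rc^2)
  cc <- sum(g$P * g$mbar * (g$rbar^2 + s2))
  list(A = A, b = b, c = cc)
}

#' Expected squared prediction error of a weight pair
#'
#' The motivation-conditioned error functional the learning process
#' minimizes, `E(w) = < (r - v)^2 / m >`. Because `r - v = m (r_star - w .
#' u)`, one factor of motivation cancels and the functional reduces to
#' `E_u[ mbar(u) ( (rbar(u) - w . u)^2 + sigma_rb^2 + sigma_rc^2 ) ]` under
#' the truncated input density — a positive-definite quadratic form in `w`,
#' evaluated here by Gauss-Legendre quadrature. A Monte-Carlo estimator for
#' cross-validation is available via [monte_carlo_error()]. For a constant
#' motivation of zero the functional is undefined (0/0) and an error is
#' raised.
#'
#' @param w Weight pair `c(balance, complexity)`.
#' @param ind A valid [individual()].
#' @param order Quadrature order per axis (default 80).
#' @param motivation_constant If non-`NULL`, replaces the motivation
#'   function by this constant (the constant-motivation ablation).
#' @return The scalar error `E(w) >= 0`.
#' @export
expected_error <- function(w, ind, order = 80, motivation_constant = NULL) {
  assert_valid(ind)
  stopifnot(length(w) == 2)
  if (!is.null(motivation_constant) && motivation_constant == 0)
    stop("expected error is undefined for identically zero motivation")
  m <- moment_matrices(ind, order, motivation_constant)
  drop(t(w) %*% m$A %*% w) - 2 * sum(m$b * w) + m$c
}

#' @rdname expected_error
#' @param n Number of Monte-Carlo samples.
#' @return `monte_carlo_error()`: a list with the estimate `E`, its standard
#'   error `se`, and `n`. Uses the current RNG stream.
#' @export
monte_carlo_error <- function(w, ind, n = 1e5, motivation_constant = NULL) {
  assert_valid(ind)
  u <- sample_sensory(ind$sensory, n)
  r <- total_reward(u$u_b, u$u_c, ind$reward)
  mbar <- if (is.null(motivation_constant))
    mean_motivation(u$u_c, ind$motivation) else rep(motivation_constant, n)
  e <- mbar * (r$r_star - (w[1] * u$u_b + w[2] * u$u_c))^2
  list(E = mean(e), se = stats::sd(e) / sqrt(n), n = n)
}

#' Least-squares fixed point of the learning dynamics
#'
#' The unique minimizer of the expected error: `w_star = A^{-1} b` with
#' `A = E[mbar u u']` and `b = E[mbar rbar u]` under the truncated input
#' density, both computed by quadrature. The stochastic weight trajectory is
#' mean-reverting around `w_star`; long-run time averages of simulated
#' weights estimate it.
#'
#' @param ind A valid [individual()].
#' @param order Quadrature order per axis.
#' @param motivation_constant Optional constant motivation override.
#' @return An object of class `fixed_point`: list with `w_star`, `A`, `b`,
#'   `condition` (eigenvalue ratio of `A`, the curvature anisotropy of the
#'   error surface).
#' @export
#' @examples
#' fp <- fixed_point(standard_parameters()$individual)
#' fp$w_star  # complexity weight exceeds balance weight
fixed_point <- function(ind, order = 80, motivation_constant = NULL) {
  assert_valid(ind)
  if (!is.null(motivation_constant) && motivation_constant == 0)
    stop("motivation identically zero: fixed point is degenerate (A singular)")
  m <- moment_matrices(ind, order, motivation_constant)
  ev <- eigen(m$A, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 1e-12)
    stop("second-moment matrix A is singular; parameters are degenerate")
  structure(list(w_star = solve(m$A, m$b), A = m$A, b = m$b,
                 condition = ev[1] / ev[2]),
            class = "fixed_point")
}

#' @export
print.fixed_point <- function(x, ...) {
  cat(sprintf("<fixed_point> w_star = (%.4f, %.4f), curvature anisotropy = %.2f\n",
              x$w_star[1], x$w_star[2], x$condition))
  invisible(x)
}

#' Iso-value hyperplane of a sample and signed distance to it
#'
#' Each sample defines a line (hyperplane, for general input dimension) of
#' weight pairs producing the same value: `a . w = v_target` with
#' coefficients `a_i = m_bar * u_i`. Every weight pair on it is
#' indistinguishable in value — the weight redundancy that lets weights
#' drift while value stays put. `hyperplane_distance()` gives the signed
#' Euclidean distance from `w` to the hyperplane whose target value is the
#' received reward `m_bar * r_star`; each delta-rule update moves the
#' weights along the hyperplane normal, shrinking this distance.
#'
#' @param u Input pair.
#' @param m_bar Motivation at the input; must be positive for a defined
#'   distance.
#' @param v_target Target value defining the hyperplane.
#' @return `hyperplane()`: list with coefficients `a` and `v_target`.
#' @export
hyperplane <- function(u, m_bar, v_target) {
  stopifnot(length(u) == 2)
  list(a = m_bar * u, v_target = v_target)
}

#' @rdname hyperplane
#' @param w Weight pair.
#' @param r_star Total reward of the sample; the target value is
#'   `m_bar * r_star`.
#' @return `hyperplane_distance()`: signed scalar distance, `NA` (with a
#'   warning) when `m_bar = 0` or `u = 0` makes it undefined.
#' @export
hyperplane_distance <- function(w, u, m_bar, r_star) {
  a <- m_bar * u
  na <- sqrt(sum(a^2))
  if (na == 0) {
    warning("hyperplane undefined: m_bar * u is the zero vector")
    return(NA_real_)
  }
  (m_bar * r_star - sum(a * w)) / na
}

#' Value landscape over the sensory space
#'
#' Evaluates `V(u) = mbar(u_c) * (w . u)` on a uniform grid over the unit
#' square, locates its argmax, and (when sensory parameters are supplied)
#' the mode of the truncated input density — the most typical input. The
#' value-exaggeration (peak-shift) diagnostic is the comparison of the two:
#' for the standard parameters the argmax sits away from the mode, at
#' exaggerated balance and complexity, with higher value.
#'
#' @param w Weight pair (e.g. late-time weights or a fixed point).
#' @param motivation A [motivation_params()] object.
#' @param resolution Grid points per axis, at least 2 (default 201).
#' @param sensory Optional [sensory_params()]; enables the density-mode
#'   report.
#' @param probes Optional data frame of probe points (`u_b`, `u_c`).
#' @return A `value_landscape`: list with the long-format `grid` data frame
#'   (`u_b`, `u_c`, `V`), `argmax` (row with the maximal V), `mode` (input
#'   density mode with its value, or `NULL`), and `probes` with their values.
#' @export
value_landscape <- function(w, motivation, resolution = 201, sensory = NULL,
                            probes = NULL) {
  stopifnot(length(w) == 2, resolution >= 2,
            inherits(motivation, "motivation_params"))
  g <- seq(0, 1, length.out = resolution)
  grid <- expand.grid(u_b = g, u_c = g)
  mbar <- mean_motivation(grid$u_c, motivation)
  grid$V <- mbar * (w[1] * grid$u_b + w[2] * grid$u_c)
  amax <- grid[which.max(grid$V), ]
  mode <- NULL
  if (!is.null(sensory)) {
    d <- gaussian_density_2d(grid$u_b, grid$u_c, sensory)
    mode <- grid[which.max(d), ]
  }
  pv <- NULL
  if (!is.null(probes)) {
    pv <- data.frame(u_b = probes$u_b, u_c = probes$u_c)
    pm <- mean_motivation(pv$u_c, motivation)
    pv$V <- pm * (w[1] * pv$u_b + w[2] * pv$u_c)
  }
  structure(list(grid = grid, argmax = amax, mode = mode, probes = pv,
                 w = w, motivation = motivation),
            class = "value_landscape")
}

#' @export
print.value_landscape <- function(x, ...) {
  cat(sprintf("<value_landscape> argmax V = %.4f at (%.3f, %.3f)",
              x$argmax$V, x$argmax$u_b, x$argmax$u_c))
  if (!is.null(x$mode))
    cat(sprintf("; V at density mode (%.3f, %.3f) = %.4f",
                x$mode$u_b, x$mode$u_c, x$mode$V))
  cat("\n")
  invisible(x)
}

#' Value time courses at probe points
#'
#' For each probe `p`, `V_p(t_k) = mbar(p) * (w(t_k) . p)` along the
#' recorded trajectory: how the learned value of specific stimuli evolves.
#'
#' @param trajectory An `aesthetic_trajectory`.
#' @param probes Data frame of probe points with columns `u_b`, `u_c`, all
#'   within the unit square.
#' @param motivation Motivation parameters; defaults to those of the
#'   trajectory's individual.
#' @return Data frame with `step` and one `V` column per probe
#'   (`V1`, `V2`, ...).
#' @export
value_timecourse <- function(trajectory, probes, motivation = NULL) {
  stopifnot(inherits(trajectory, "aesthetic_trajectory"))
  stopifnot(all(probes$u_b >= 0 & probes$u_b <= 1),
            all(probes$u_c >= 0 & probes$u_c <= 1))
  if (is.null(motivation))
    motivation <- attr(trajectory, "individual")$motivation
  out <- data.frame(step = trajectory$step)
  for (i in seq_len(nrow(probes))) {
    mb <- mean_motivation(probes$u_c[i], motivation)
    out[[paste0("V", i)]] <-
      mb * (trajectory$w_b * probes$u_b[i] + trajectory$w_c * probes$u_c[i])
  }
  out
}

#' Competition metrics of a recorded trajectory
#'
#' Quantifies the "apparent competition" between the two weights with two
#' complementary statistics over the recorded window:
#' \describe{
#'   \item{separation}{late-window mean of `w_c - w_b` (late window = last
#'     `window_fraction` of recorded rows): how far apart the weights end
#'     up.}
#'   \item{divergence}{late-window separation minus early-window separation
#'     (early window = first `window_fraction` of recorded rows): whether
#'     one weight is still rising while the other falls across the
#'     observation window. This is the dynamical signature of competition;
#'     a condition whose weights equilibrate quickly shows near-zero
#'     divergence even if its equilibrium separation is not zero.}
#' }
#' Also reports the late-window means themselves and the correlation of
#' successive recorded weight increments. Note that at stride 1 the
#' increment correlation is dominated by the common per-step factor
#' `epsilon * mbar * delta` (both increments are that scalar times the
#' positive input components), so it is only informative on trajectories
#' recorded at a stride longer than the fast mixing time.
#'
#' @param trajectory An `aesthetic_trajectory` (record the window of
#'   interest via `record_start`/`record_stride`).
#' @param window_fraction Fraction of recorded rows in each of the early and
#'   late windows (default 1/3).
#' @return List with `late_mean_w_b`, `late_mean_w_c`, `separation`,
#'   `divergence`, `increment_correlation`.
#' @export
competition_metrics <- function(trajectory, window_fraction = 1/3) {
  stopifnot(inherits(trajectory, "aesthetic_trajectory"))
  n <- nrow(trajectory)
  k <- ceiling(n * window_fraction)
  if (k < 1 || k > n)
    stop("window longer than the recorded trajectory")
  early <- seq_len(k)
  late <- seq.int(n - k + 1, n)
  sep_late <- mean(trajectory$w_c[late]) - mean(trajectory$w_b[late])
  sep_early <- mean(trajectory$w_c[early]) - mean(trajectory$w_b[early])
  db <- diff(trajectory$w_b)
  dc <- diff(trajectory$w_c)
  ic <- if (stats::sd(db) == 0 || stats::sd(dc) == 0) NA_real_
        else stats::cor(db, dc)
  list(late_mean_w_b = mean(trajectory$w_b[late]),
       late_mean_w_c = mean(trajectory$w_c[late]),
       separation = sep_late,
       divergence = sep_late - sep_early,
       increment_correlation = ic)
}

#' Expected-error surface over weight space
#'
#' Evaluates the quadratic error functional on a grid of weight pairs (the
#' moments are computed once, so the grid itself is cheap) and reports its
#' curvature anisotropy: the eigenvalue ratio of `A`. An anisotropy well
#' above 1 is the hammock shape — a steep transverse direction and a shallow
#' bed along which the weights drift slowly.
#'
#' @param ind A valid [individual()].
#' @param w_b,w_c Numeric vectors of grid coordinates for the two weights.
#' @param order Quadrature order per axis.
#' @param motivation_constant Optional constant motivation override.
#' @return An `error_surface`: list with the long-format `grid` data frame
#'   (`w_b`, `w_c`, `E`), `anisotropy`, `eigenvalues`,
#'   `principal_directions` (columns = eigenvectors of `A`), and `w_min`
#'   (grid point of minimal E).
#' @export
error_surface <- function(ind, w_b = seq(-1, 1, length.out = 81),
                          w_c = seq(-1, 1, length.out = 81), order = 80,
                          motivation_constant = NULL) {
  assert_valid(ind)
  m <- moment_matrices(ind, order, motivation_constant)
  grid <- expand.grid(w_b = w_b, w_c = w_c)
  grid$E <- m$A[1, 1] * grid$w_b^2 + 2 * m$A[1, 2] * grid$w_b * grid$w_c +
    m$A[2, 2] * grid$w_c^2 - 2 * (m$b[1] * grid$w_b + m$b[2] * grid$w_c) +
    m$c
  e <- eigen(m$A, symmetric = TRUE)
  structure(list(grid = grid,
                 anisotropy = e$values[1] / e$values[2],
                 eigenvalues = e$values,
                 principal_directions = e$vectors,
                 w_min = grid[which.min(grid$E), c("w_b", "w_c")]),
            class = "error_surface")
}

#' @export
print.error_surface <- function(x, ...) {
  cat(sprintf("<error_surface> grid minimum near (%.3f, %.3f), curvature anisotropy = %.2f\n",
              x$w_min$w_b, x$w_min$w_c, x$anisotropy))
  invisible(x)
}

#' Export a landscape or surface grid as CSV with JSON metadata
#'
#' Long format `x,y,value`; the sidecar `<path>.json` records what the grid
#' is and the parameters used.
#'
#' @param x A `value_landscape` or `error_surface`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(x, path) {
  if (inherits(x, "value_landscape")) {
    g <- data.frame(x = x$grid$u_b, y = x$grid$u_c, value = x$grid$V)
    meta <- list(kind = "value_landscape", w = x$w,
                 motivation = unclass(x$motivation))
  } else if (inherits(x, "error_surface")) {
    g <- data.frame(x = x$grid$w_b, y = x$grid$w_c, value = x$grid$E)
    meta <- list(kind = "error_surface", anisotropy = x$anisotropy)
  } else stop("unsupported grid object")
  utils::write.csv(g, path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
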