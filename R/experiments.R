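# Scripted versions of the shipped simulation experiments. Each function is
# fully determined by its arguments (seeds included); with `out_dir` set it
# writes CSV outputs plus a JSON manifest sufficient to re-run the
# experiment bit-identically.

write_manifest <- function(out_dir, name, args) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    c(list(experiment = name,
           package_version = as.character(utils::packageVersion("aestheval"))),
      args),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(out_dir)
}

#' Competition-ablation variants
#'
#' Builds the individual (and, where applicable, constant-motivation flag)
#' for each ablation of the competition experiment. Knob definitions:
#' removing the input correlation sets `rho = 0`; "identical rewards" gives
#' the complexity reward the linear balance form (same `alpha` and noise);
#' "constant motivation" sets `m = 1` everywhere.
#'
#' @param variant One of `"standard"`, `"no_correlation"`,
#'   `"identical_rewards"`, `"constant_motivation"`,
#'   `"constant_motivation_identical_rewards"`,
#'   `"constant_motivation_no_correlation"`,
#'   `"no_correlation_identical_rewards"`.
#' @return List with `individual` and `motivation_constant` (`NULL` for
#'   mean-field motivation).
#' @export
ablation_variant <- function(variant = c(
  "standard", "no_correlation", "identical_rewards", "constant_motivation",
  "constant_motivation_identical_rewards",
  "constant_motivation_no_correlation", "no_correlation_identical_rewards")) {
  variant <- match.arg(variant)
  ind <- standard_parameters()$individual
  has <- function(what) grepl(what, variant)
  if (has("no_correlation")) ind$sensory$rho <- 0
  if (has("identical_rewards")) ind$reward$complexity_form <- "linear"
  ind$background <- variant
  list(individual = ind,
       motivation_constant = if (has("constant_motivation")) 1 else NULL)
}

#' Learning dynamics at the standard parameters
#'
#' One standard-parameter run from `w0 = c(0, 0)`: the weight-vs-time and
#' phase-plane view in which the initial fast rise and the later slow
#' divergence of the two weights are visible.
#'
#' @param seed RNG seed.
#' @param n_steps Simulation horizon.
#' @param out_dir Optional output directory for CSVs and a manifest.
#' @return List with `trajectory` and its [competition_metrics()].
#' @export
experiment_dynamics <- function(seed = 1, n_steps = 30000, out_dir = NULL) {
  std <- standard_parameters(n_steps = n_steps, seed = seed)
  traj <- run_simulation(std$individual, std$config)
  write_manifest(out_dir, "dynamics", list(seed = seed, n_steps = n_steps))
  if (!is.null(out_dir))
    write_trajectory(traj, file.path(out_dir, "trajectory.csv"))
  list(trajectory = traj, metrics = competition_metrics(traj))
}

#' Error descent from three initial conditions
#'
#' Standard parameters with initial weights `(-1, -1)`, `(1, -0.6)` and
#' `(0, 1)`, overlaid on the expected-error surface: large initial error
#' yields a fast straight descent, small initial error a slow one, and the
#' typical case curves into the shallow bed of the hammock-shaped surface.
#'
#' @param seed Base seed; run `i` uses `seed + i - 1`.
#' @param n_steps Simulation horizon.
#' @param out_dir Optional output directory.
#' @return List with `trajectories` (list of 3), `surface` (an
#'   `error_surface`), `initial_errors` (E at the three starts) and
#'   `fixed_point`.
#' @export
experiment_error_descent <- function(seed = 1, n_steps = 30000,
                                     out_dir = NULL) {
  starts <- list(c(-1, -1), c(1, -0.6), c(0, 1))
  std <- standard_parameters()
  trajs <- lapply(seq_along(starts), function(i) {
    cfg <- learning_config(w0 = starts[[i]], n_steps = n_steps,
                           seed = seed + i - 1)
    run_simulation(std$individual, cfg)
  })
  surf <- error_surface(std$individual,
                        w_b = seq(-1.2, 1.2, length.out = 61),
                        w_c = seq(-1.2, 1.2, length.out = 61))
  e0 <- vapply(starts, expected_error, numeric(1), ind = std$individual)
  write_manifest(out_dir, "error_descent",
                 list(seed = seed, n_steps = n_steps, starts = starts))
  if (!is.null(out_dir)) {
    for (i in seq_along(trajs))
      write_trajectory(trajs[[i]],
                       file.path(out_dir, sprintf("trajectory_%d.csv", i)))
    write_grid(surf, file.path(out_dir, "error_surface.csv"))
  }
  list(trajectories = trajs, surface = surf, initial_errors = e0,
       fixed_point = fixed_point(std$individual))
}

#' Competition ablation grid
#'
#' Runs every [ablation_variant()] with the cloud-sampling window (recording
#' from step 10000 at stride 200 up to `n_steps`) across several seeds and
#' reports the seed-averaged [competition_metrics()]. The `divergence`
#' column carries the dynamical competition signature; `separation` the
#' late-window weight difference.
#'
#' @param seeds Integer vector of seeds (one run per seed per variant).
#' @param n_steps Simulation horizon.
#' @param out_dir Optional output directory.
#' @return Data frame: one row per variant with seed-averaged metrics.
#' @export
experiment_competition_ablations <- function(seeds = 1:10, n_steps = 30000,
                                             out_dir = NULL) {
  variants <- eval(formals(ablation_variant)$variant)
  rows <- lapply(variants, function(v) {
    va <- ablation_variant(v)
    ms <- lapply(seeds, function(s) {
      cfg <- learning_config(
        n_steps = n_steps, seed = s, record_start = 10000,
        record_stride = 200,
        motivation_mode = if (is.null(va$motivation_constant)) "mean_field"
                          else "constant",
        motivation_constant = if (is.null(va$motivation_constant)) 1
                              else va$motivation_constant)
      competition_metrics(run_simulation(va$individual, cfg))
    })
    avg <- function(f) mean(vapply(ms, `[[`, numeric(1), f))
    data.frame(variant = v,
               late_mean_w_b = avg("late_mean_w_b"),
               late_mean_w_c = avg("late_mean_w_c"),
               separation = avg("separation"),
               divergence = avg("divergence"),
               increment_correlation = avg("increment_correlation"))
  })
  out <- do.call(rbind, rows)
  write_manifest(out_dir, "competition_ablations",
                 list(seeds = seeds, n_steps = n_steps))
  if (!is.null(out_dir))
    utils::write.csv(out, file.path(out_dir, "ablation_metrics.csv"),
                     row.names = FALSE)
  out
}

#' Individuality sweeps over motivation peak and reward slope
#'
#' Sweeps the complexity of peak motivation (`mu_m`) and the balance-reward
#' slope (`alpha`), all other parameters standard. Weights are sampled with
#' the cloud window (from step 10000, every 200 steps, to `n_steps`); the
#' per-condition cloud center is averaged over seeds and compared with the
#' condition's quadrature fixed point. Raising `mu_m` shifts individuals
#' toward complexity (larger `w_c`); raising `alpha` shifts them toward
#' balance (larger `w_b`).
#'
#' @param seeds Integer vector of seeds per condition.
#' @param mu_m_values Motivation-peak sweep (default `c(0.4, 0.6, 0.85)`).
#' @param alpha_values Reward-slope sweep (default `c(0.5, 1.25, 1.7)`).
#' @param n_steps Simulation horizon.
#' @param out_dir Optional output directory (writes per-condition clouds).
#' @return Data frame: one row per condition with the swept parameter, cloud
#'   center (`center_w_b`, `center_w_c`) and fixed point (`wstar_b`,
#'   `wstar_c`).
#' @export
experiment_individuality <- function(seeds = 1:10,
                                     mu_m_values = c(0.4, 0.6, 0.85),
                                     alpha_values = c(0.5, 1.25, 1.7),
                                     n_steps = 30000, out_dir = NULL) {
  std <- standard_parameters()$individual
  conds <- c(lapply(mu_m_values, function(v) {
    ind <- std; ind$motivation$mu_m <- v
    list(param = "mu_m", value = v, individual = ind)
  }), lapply(alpha_values, function(v) {
    ind <- std; ind$reward$alpha <- v
    list(param = "alpha", value = v, individual = ind)
  }))
  write_manifest(out_dir, "individuality",
                 list(seeds = seeds, mu_m_values = mu_m_values,
                      alpha_values = alpha_values, n_steps = n_steps))
  rows <- lapply(conds, function(cn) {
    cloud <- do.call(rbind, lapply(seeds, function(s) {
      cfg <- learning_config(n_steps = n_steps, seed = s,
                             record_start = 10000, record_stride = 200)
      tr <- run_simulation(cn$individual, cfg)
      data.frame(seed = s, w_b = tr$w_b, w_c = tr$w_c)
    }))
    if (!is.null(out_dir))
      utils::write.csv(cloud, file.path(out_dir,
        sprintf("cloud_%s_%g.csv", cn$param, cn$value)), row.names = FALSE)
    ws <- fixed_point(cn$individual)$w_star
    data.frame(param = cn$param, value = cn$value,
               center_w_b = mean(cloud$w_b), center_w_c = mean(cloud$w_c),
               wstar_b = ws[1], wstar_c = ws[2])
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_dir))
    utils::write.csv(out, file.path(out_dir, "condition_centers.csv"),
                     row.names = FALSE)
  out
}

#' Default value probes
#'
#' One probe at the input-density mode (0.5, 0.5) and one in each quadrant
#' center of the sensory space.
#'
#' @return Data frame with columns `u_b`, `u_c`, `label`.
#' @export
default_probes <- function() {
  data.frame(u_b = c(0.5, 0.25, 0.75, 0.25, 0.75),
             u_c = c(0.5, 0.25, 0.25, 0.75, 0.75),
             label = c("mode", "low_b_low_c", "high_b_low_c",
                       "low_b_high_c", "high_b_high_c"))
}

#' Value time courses and final landscape (value exaggeration)
#'
#' A standard-parameter run; values at the probe points over time, and the
#' final value landscape with its argmax versus the input-density mode. The
#' value-exaggeration effect: the argmax lies away from the most probable
#' inputs, at exaggerated balance and complexity, with higher value than
#' the typical input attains.
#'
#' @param seed RNG seed.
#' @param probes Probe points (data frame `u_b`, `u_c`); default
#'   [default_probes()].
#' @param n_steps Simulation horizon.
#' @param resolution Landscape grid resolution per axis.
#' @param out_dir Optional output directory.
#' @return List with `trajectory`, `timecourse`, `landscape`.
#' @export
experiment_value_probes <- function(seed = 1, probes = default_probes(),
                                    n_steps = 30000, resolution = 201,
                                    out_dir = NULL) {
  std <- standard_parameters(n_steps = n_steps, seed = seed)
  traj <- run_simulation(std$individual, std$config)
  tc <- value_timecourse(traj, probes)
  w_final <- unlist(traj[nrow(traj), c("w_b", "w_c")], use.names = FALSE)
  land <- value_landscape(w_final, std$individual$motivation,
                          resolution = resolution,
                          sensory = std$individual$sensory, probes = probes)
  write_manifest(out_dir, "value_probes",
                 list(seed = seed, n_steps = n_steps,
                      resolution = resolution,
                      probes = probes[, c("u_b", "u_c")]))
  if (!is.null(out_dir)) {
    write_trajectory(traj, file.path(out_dir, "trajectory.csv"))
    utils::write.csv(tc, file.path(out_dir, "value_timecourse.csv"),
                     row.names = FALSE)
    write_grid(land, file.path(out_dir, "value_landscape.csv"))
  }
  list(trajectory = traj, timecourse = tc, landscape = land)
}
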