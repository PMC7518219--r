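#' Write an individual (and optional learning config) to a YAML file
#'
#' The file has sections `sensory`, `reward`, `motivation` (fields in the
#' order of the parameter vectors) and optionally `learning`. Numbers are
#' written with full precision so a read back reproduces every field
#' bit-exactly.
#'
#' @param ind An [individual()].
#' @param path Output file path.
#' @param config Optional [learning_config()] written as a `learning` section.
#' @return `path`, invisibly.
#' @export
write_config <- function(ind, path, config = NULL) {
  stopifnot(inherits(ind, "individual"))
  x <- list(
    sensory    = ind$sensory[c("mu_b", "mu_c", "sigma_ub", "sigma_uc", "rho")],
    reward     = ind$reward[c("alpha", "sigma_rb", "beta", "gamma", "theta",
                              "sigma_rc", "complexity_form")],
    motivation = ind$motivation[c("m_min", "m_max", "mu_m", "sigma_m")],
    background = ind$background
  )
  if (!is.null(config)) {
    stopifnot(inherits(config, "learning_config"))
    x$learning <- list(
      w0 = config$w0, epsilon = config$epsilon, n_steps = config$n_steps,
      seed = config$seed, record_start = config$record_start,
      record_stride = config$record_stride,
      motivation_mode = config$motivation_mode,
      motivation_constant = config$motivation_constant
    )
  }
  writeLines(yaml::as.yaml(x, precision = 22), path)
  invisible(path)
}

#' Read an individual (and learning config, if present) from a YAML file
#'
#' @param path File written by [write_config()] or hand-edited in the same
#'   layout.
#' @return A list with `individual` and (possibly `NULL`) `config`.
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  ind <- individual(
    sensory = do.call(sensory_params, x$sensory),
    reward = do.call(reward_params, x$reward),
    motivation = do.call(motivation_params, x$motivation),
    background = if (is.null(x$background)) "standard" else x$background
  )
  cfg <- NULL
  if (!is.null(x$learning)) cfg <- do.call(learning_config, x$learning)
  list(individual = ind, config = cfg)
}

#' Write a recorded trajectory as CSV with a JSON provenance sidecar
#'
#' The CSV has columns `step, w_b, w_c, u_b, u_c, r_star, m_bar, delta, v`.
#' The sidecar (`<path>.json`) records the full parameter set, the learning
#' configuration (including the seed), and the package version, which is
#' sufficient to re-run the simulation bit-identically.
#'
#' @param trajectory An `aesthetic_trajectory` from [run_simulation()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "aesthetic_trajectory"))
  cols <- c("step", "w_b", "w_c", "u_b", "u_c", "r_star", "m_bar", "delta", "v")
  utils::write.csv(as.data.frame(trajectory)[, cols], path, row.names = FALSE)
  ind <- attr(trajectory, "individual")
  cfg <- attr(trajectory, "config")
  manifest <- list(
    individual = list(
      sensory = ind$sensory[c("mu_b", "mu_c", "sigma_ub", "sigma_uc", "rho")],
      reward = ind$reward[c("alpha", "sigma_rb", "beta", "gamma", "theta",
                            "sigma_rc", "complexity_form")],
      motivation = ind$motivation[c("m_min", "m_max", "mu_m", "sigma_m")],
      background = ind$background
    ),
    config = cfg[c("w0", "epsilon", "n_steps", "seed", "record_start",
                   "record_stride", "motivation_mode", "motivation_constant")],
    package_version = as.character(utils::packageVersion("aestheval"))
  )
  jsonlite::write_json(manifest, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write sensory/reward/motivation samples as CSV
#'
#' Deterministic column order `u_b, u_c[, r_b, r_c, r_star, m_bar]`, matching
#' whatever columns are present in `samples`.
#'
#' @param samples Data frame of samples (e.g. from [sample_sensory()]).
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  order <- c("u_b", "u_c", "r_b", "r_c", "r_star", "m_bar")
  cols <- order[order %in% names(samples)]
  utils::write.csv(samples[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}
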