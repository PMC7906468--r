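#' Default run configuration
#'
#' A flat named list mirroring the reference parameter set plus scenario and
#' stochastic settings. [load_config()] fills missing keys from these
#' defaults; unknown keys are rejected.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(omega = 25L,
       r_min = 0.25,
       r_max = 0.5,
       p_S = 0.2,
       p_F = 0.2,
       delta = 2,
       m = 0.86,
       t_pre = 0,
       t_treat = 150,
       t_monitor = 150,
       detection_load = 1e10,
       dt_reevaluate = 15,
       relapse_reference = "max_pre",
       V = 25,
       n_replicates = 10000L,
       stochastic_t_treat = 25,
       stochastic_t_monitor = 50,
       stochastic_m = 0.722,
       init_total = 1000,
       relapse_threshold = 1000,
       seed = 1L)
}

validate_config <- function(cfg) {
  # constructors carry the invariants; build them to validate
  params <- model_params(cfg$omega, cfg$r_min, cfg$r_max, cfg$p_S, cfg$p_F)
  treatment_setting(cfg$delta, 0)
  treatment_setting(0, cfg$m)
  scenario_timing(cfg$t_pre, cfg$t_treat, cfg$t_monitor)
  stochastic_params(cfg$r_min, cfg$r_max, cfg$p_S, cfg$p_F,
                    delta = 0, m = 0, V = cfg$V)
  if (!cfg$relapse_reference %in% c("max_pre", "at_init", "absolute"))
    stop("config key 'relapse_reference' must be one of ",
         "'max_pre', 'at_init', 'absolute'", call. = FALSE)
  for (nm in c("detection_load", "dt_reevaluate", "init_total",
               "relapse_threshold", "stochastic_t_treat",
               "stochastic_t_monitor", "stochastic_m")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop(sprintf("config key '%s' must be a single non-negative number",
                   nm), call. = FALSE)
  }
  if (cfg$n_replicates < 1)
    stop("config key 'n_replicates' must be at least 1", call. = FALSE)
  invisible(params)
}

#' Load and validate a run configuration
#'
#' Reads a YAML file of configuration keys, fills unset keys from
#' [default_config()], rejects unknown keys, and validates every value with
#' key-level error messages. An empty file yields the full default
#' (reference) configuration.
#'
#' @param path path to a YAML configuration file.
#' @return Named list of configuration values.
#' @seealso [save_config()] for the inverse; a save/load round trip is the
#'   identity.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaults <- default_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, raw)
  cfg$omega <- as.integer(cfg$omega)
  cfg$n_replicates <- as.integer(cfg$n_replicates)
  cfg$seed <- as.integer(cfg$seed)
  validate_config(cfg)
  cfg
}

#' @rdname load_config
#' @param cfg a configuration list.
#' @export
save_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# Rolling polynomial hash over a character vector; gives runs a short
# content-derived id (stays below 2^26 so plain double arithmetic is exact).
content_id <- function(lines) {
  bytes <- utf8ToInt(paste(lines, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 67108859
  sprintf("%08x", h)
}

#' Write a trajectory to tidy CSV with a JSON metadata sidecar
#'
#' The CSV holds one row per (time, subpopulation) with columns
#' `time, subpopulation_index, growth_rate, abundance, total, delta_active,
#' m_active`. The sidecar records the model parameters, phase table and a
#' content-derived run id, so a stored run can be re-identified and
#' reproduced.
#'
#' @param traj a `pheno_trajectory`.
#' @param path output CSV path; the sidecar is written to
#'   `<path>.meta.json`.
#' @return Invisibly, the run id.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "pheno_trajectory"))
  df <- as.data.frame(traj)
  utils::write.csv(df, path, row.names = FALSE)
  run_id <- content_id(readLines(path))
  meta <- list(run_id = run_id,
               params = unclass(traj$params),
               phases = traj$phases,
               switch_times = traj$switch_times,
               n_output_points = length(traj$time))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(run_id)
}

#' Generate the standard input fixtures
#'
#' Writes the small plain-text inputs the tests and examples start from:
#' * `stable_start`: the 25-class exponential equilibration seed
#'   `x_i = 1e-60 exp(80 v_i)` together with the equilibrated stable
#'   frequencies (CSV).
#' * `sequence_sweep`: all 256 predefined 8-interval treatment patterns with
#'   their trait-dependent proportions (CSV, one row per pattern).
#' * `two_class_start`: the stable two-class frequencies scaled to an
#'   integer total of 1000 cells (CSV).
#'
#' @param name fixture name.
#' @param dir output directory (created if needed).
#' @return The path of the written file.
#' @export
make_fixture <- function(name = c("stable_start", "sequence_sweep",
                                  "two_class_start"),
                         dir = ".") {
  name <- match.arg(name)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0(name, ".csv"))
  switch(name,
    stable_start = {
      params <- model_params()
      grid <- trait_grid(params)
      eq <- equilibrate(params)
      utils::write.csv(
        data.frame(subpopulation_index = seq_len(params$omega),
                   v = grid$v,
                   growth_rate = grid$rates,
                   seed_abundance = 1e-60 * exp(80 * grid$v),
                   stable_frequency = eq$freqs),
        path, row.names = FALSE)
    },
    sequence_sweep = {
      seqs <- enumerate_predefined(8)
      utils::write.csv(
        data.frame(scheme_id = vapply(seqs, `[[`, "", "id"),
                   pattern = vapply(seqs, `[[`, "", "id"),
                   prop_trait_dependent = vapply(seqs, `[[`, 0, "prop_dep")),
        path, row.names = FALSE)
    },
    two_class_start = {
      f <- two_class_stable_freqs(stochastic_params())
      utils::write.csv(
        data.frame(class = c("slow", "fast"),
                   growth_rate = c(0.25, 0.5),
                   stable_frequency = f,
                   count = round(f * 1000)),
        path, row.names = FALSE)
    })
  path
}
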