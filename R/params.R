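#' Model parameters for the trait-structured tumour model
#'
#' The tumour is modelled as `omega` exponentially growing subpopulations
#' whose growth rates increase linearly from `r_min` to `r_max`. At division,
#' a daughter cell switches to the next-slower class with probability `p_S`
#' and to the next-faster class with probability `p_F`; switching rates are
#' therefore proportional to the growth rate. The defaults are the reference
#' parameter set used throughout the package.
#'
#' @param omega integer number of subpopulations (at least 2).
#' @param r_min growth rate of the slowest subpopulation (per time unit).
#' @param r_max growth rate of the fastest subpopulation (per time unit).
#' @param p_S probability that a division switches the daughter to the
#'   next-slower class, in `[0, 1)`.
#' @param p_F probability that a division switches the daughter to the
#'   next-faster class, in `[0, 1)`.
#'
#' @return An object of class `model_params`.
#' @examples
#' model_params()
#' model_params(omega = 2)
#' @export
model_params <- function(omega = 25L, r_min = 0.25, r_max = 0.5,
                         p_S = 0.2, p_F = 0.2) {
  omega <- as.integer(omega)
  if (length(omega) != 1L || is.na(omega) || omega < 2L)
    stop("'omega' must be a single integer >= 2", call. = FALSE)
  for (nm in c("r_min", "r_max", "p_S", "p_F")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
  }
  if (r_min <= 0 || r_max <= 0)
    stop("growth rates must be positive", call. = FALSE)
  if (r_min >= r_max)
    stop("'r_min' must be smaller than 'r_max'", call. = FALSE)
  if (p_S < 0 || p_F < 0 || p_S >= 1 || p_F >= 1)
    stop("switching fractions must lie in [0, 1)", call. = FALSE)
  if (p_S + p_F >= 1)
    stop("'p_S' + 'p_F' must be smaller than 1 so that net own-type ",
         "proliferation stays positive", call. = FALSE)
  structure(list(omega = omega, r_min = r_min, r_max = r_max,
                 p_S = p_S, p_F = p_F),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Trait-structured model parameters\n")
  cat(sprintf("  omega: %d subpopulations\n", x$omega))
  cat(sprintf("  growth rates: %.4g .. %.4g per time unit\n", x$r_min, x$r_max))
  cat(sprintf("  switching: p_S = %.3g (slower), p_F = %.3g (faster)\n",
              x$p_S, x$p_F))
  invisible(x)
}

#' Trait grid of subpopulation growth rates
#'
#' Builds the linear trait axis: `omega` positions `v` equally spaced on
#' `[0, 1]` and the corresponding growth rates
#' `r_i = r_min + (r_max - r_min) * v_i`.
#'
#' @param params a [model_params()] object.
#' @return An object of class `trait_grid` with elements `v` and `rates`.
#' @examples
#' trait_grid(model_params(omega = 3))$rates  # 0.25 0.375 0.5
#' @export
trait_grid <- function(params) {
  stopifnot(inherits(params, "model_params"))
  v <- seq(0, 1, length.out = params$omega)
  structure(list(v = v,
                 rates = params$r_min + (params$r_max - params$r_min) * v),
            class = "trait_grid")
}

#' @export
print.trait_grid <- function(x, ...) {
  cat(sprintf("Trait grid: %d growth rates from %.4g to %.4g\n",
              length(x$rates), x$rates[1L], x$rates[length(x$rates)]))
  invisible(x)
}

#' Treatment setting active at an instant
#'
#' A treatment setting is the pair of mortality parameters active at a moment
#' in time: `delta` scales the trait-dependent per-cell mortality
#' `delta * r_i` (chemotherapy-like) and `m` is the trait-independent
#' per-cell mortality rate (immunotherapy-like). Outside treatment phases
#' both are zero; during single-type treatment exactly one is non-zero.
#'
#' @param delta non-negative dimensionless mortality factor of the
#'   trait-dependent treatment.
#' @param m non-negative trait-independent mortality rate (per time unit).
#' @return An object of class `treatment_setting`.
#' @examples
#' trait_dependent(2)
#' trait_independent(0.86)
#' no_treatment()
#' @export
treatment_setting <- function(delta = 0, m = 0) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta < 0)
    stop("'delta' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 0)
    stop("'m' must be a single non-negative number", call. = FALSE)
  structure(list(delta = delta, m = m), class = "treatment_setting")
}

#' @rdname treatment_setting
#' @export
no_treatment <- function() treatment_setting(0, 0)

#' @rdname treatment_setting
#' @export
trait_dependent <- function(delta = 2) treatment_setting(delta = delta, m = 0)

#' @rdname treatment_setting
#' @export
trait_independent <- function(m = 0.86) treatment_setting(delta = 0, m = m)

#' @export
print.treatment_setting <- function(x, ...) {
  lab <- if (x$delta == 0 && x$m == 0) "no treatment"
         else if (x$m == 0) "trait-dependent"
         else if (x$delta == 0) "trait-independent"
         else "combined"
  cat(sprintf("Treatment setting (%s): delta = %.4g, m = %.4g\n",
              lab, x$delta, x$m))
  invisible(x)
}

#' Scenario timing: pre-detection, treatment and monitoring phases
#'
#' A scenario consists of an untreated pre-detection phase of duration
#' `t_pre` (the time origin is placed at detection, so it covers
#' `[-t_pre, 0]`), a treatment phase on `[0, t_treat]`, and an untreated
#' monitoring phase of duration `t_monitor` during which relapse is tracked.
#' The reference scenario treats for 150 time units and monitors for another
#' 150.
#'
#' @param t_pre duration of the pre-detection growth phase.
#' @param t_treat treatment duration (often denoted `T`).
#' @param t_monitor post-treatment monitoring duration.
#' @return An object of class `scenario_timing`.
#' @export
scenario_timing <- function(t_pre = 0, t_treat = 150, t_monitor = 150) {
  for (nm in c("t_pre", "t_treat", "t_monitor")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop(sprintf("'%s' must be a single non-negative number", nm),
           call. = FALSE)
  }
  structure(list(t_pre = t_pre, t_treat = t_treat, t_monitor = t_monitor),
            class = "scenario_timing")
}

#' @export
print.scenario_timing <- function(x, ...) {
  cat(sprintf("Scenario timing: pre %.4g, treatment %.4g, monitoring %.4g\n",
              x$t_pre, x$t_treat, x$t_monitor))
  invisible(x)
}

#' Population state: subpopulation abundances at one time point
#'
#' @param t time in model time units (origin at detection).
#' @param x numeric vector of non-negative subpopulation abundances.
#' @return An object of class `population_state` with elements `t`, `x`,
#'   `total` and `freqs` (`NULL` when the population is empty).
#' @export
population_state <- function(t, x) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x))
    stop("'x' must be a numeric vector without NAs", call. = FALSE)
  if (any(x < 0))
    stop("abundances must be non-negative", call. = FALSE)
  total <- sum(x)
  structure(list(t = t, x = as.numeric(x), total = total,
                 freqs = if (total > 0) x / total else NULL),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("Population state at t = %.4g: %d classes, total load %.6g\n",
              x$t, length(x$x), x$total))
  invisible(x)
}

# Resolve either a raw abundance vector or a population_state to a vector.
as_abundance <- function(x) {
  if (inherits(x, "population_state")) x$x
  else if (is.numeric(x)) as.numeric(x)
  else stop("expected a numeric vector or a 'population_state'",
            call. = FALSE)
}
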