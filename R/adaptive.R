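#' Instantaneous population mortality exerted by each treatment type
#'
#' The rate of change of the total load is
#' `dX/dt = sum((r_i - delta r_i - m) x_i)`; the two mortality terms are the
#' trait-dependent kill rate `sum(delta r_i x_i)` and the trait-independent
#' kill rate `m sum(x_i)`. Adaptive schemes compare these to pick the
#' treatment type that currently kills faster.
#'
#' @param state abundance vector or [population_state()] with positive total.
#' @param grid a [trait_grid()].
#' @param delta trait-dependent mortality factor.
#' @param m trait-independent mortality rate.
#' @return A list with `trait_dependent` and `trait_independent` mortality
#'   terms (rate times abundance).
#' @export
mortality_terms <- function(state, grid, delta, m) {
  x <- as_abundance(state)
  if (sum(x) <= 0)
    stop("mortality comparison is undefined for an empty population",
         call. = FALSE)
  list(trait_dependent = sum(delta * grid$rates * x),
       trait_independent = m * sum(x))
}

#' Mean growth-rate trait of the population
#'
#' Abundance-weighted mean growth rate `sum(r_i x_i) / sum(x_i)`. The
#' optimal adaptive scheme holds this at `m / delta`, the trait value at
#' which both treatment types exert equal population mortality.
#'
#' @inheritParams mortality_terms
#' @return The mean trait (per time unit).
#' @export
mean_trait <- function(state, grid) {
  x <- as_abundance(state)
  tot <- sum(x)
  if (tot <= 0) stop("mean trait is undefined for an empty population",
                     call. = FALSE)
  sum(grid$rates * x) / tot
}

#' Choose the treatment type with the larger instantaneous mortality
#'
#' Returns `"trait_dependent"` when `sum(delta r_i x_i) > m sum(x_i)`
#' (equivalently, when the mean trait exceeds `m / delta`), and
#' `"trait_independent"` when it is smaller. On an exact tie the `tie_rule`
#' applies; the default keeps the currently active type, which prevents
#' chattering on the equal-mortality manifold.
#'
#' @inheritParams mortality_terms
#' @param current currently active label (used by the default tie rule).
#' @param tie_rule `"current"`, `"trait_dependent"` or `"trait_independent"`.
#' @return `"trait_dependent"` or `"trait_independent"`.
#' @export
select_treatment <- function(state, grid, delta, m, current = NULL,
                             tie_rule = c("current", "trait_dependent",
                                          "trait_independent")) {
  tie_rule <- match.arg(tie_rule)
  mt <- mortality_terms(state, grid, delta, m)
  if (mt$trait_dependent > mt$trait_independent) return("trait_dependent")
  if (mt$trait_dependent < mt$trait_independent) return("trait_independent")
  if (tie_rule != "current") return(tie_rule)
  if (is.null(current))
    stop("tie with tie_rule = 'current' but no current treatment given",
         call. = FALSE)
  current
}

#' Run one predefined sequential treatment scheme
#'
#' Builds the equal-interval [sequence_schedule()] for a binary pattern,
#' simulates the full scenario and computes its outcome metrics. `m`
#' defaults to the calibrated matched mortality (see [calibrate_m()]).
#'
#' @param pattern binary pattern (or a `predefined_sequence` from
#'   [enumerate_predefined()]); `TRUE`/1/`"trait_dependent"` marks
#'   trait-dependent intervals.
#' @param params a [model_params()] object.
#' @param timing a [scenario_timing()].
#' @param delta trait-dependent mortality factor.
#' @param m trait-independent mortality rate; `NULL` calibrates it.
#' @param initial optional equilibrated [population_state()] (computed when
#'   `NULL`); pass it explicitly when running many schemes.
#' @param relapse_reference passed to [scheme_outcome()].
#' @param ... further arguments to [simulate_scenario()].
#' @return A list with `trajectory` and `outcome`.
#' @export
run_predefined <- function(pattern, params, timing = scenario_timing(),
                           delta = 2, m = NULL, initial = NULL,
                           relapse_reference = "max_pre", ...) {
  if (inherits(pattern, "predefined_sequence")) pattern <- pattern$pattern
  if (is.null(initial)) initial <- equilibrate(params)
  if (is.null(m)) m <- calibrate_m(params, delta, timing, initial = initial)
  sched <- sequence_schedule(pattern, timing$t_treat, delta, m)
  traj <- simulate_scenario(params, sched, timing, initial = initial, ...)
  list(trajectory = traj,
       outcome = scheme_outcome(traj, relapse_reference))
}

#' Run a realistic adaptive treatment scheme
#'
#' At `t = 0, dt, 2 dt, ...` the treatment type with the larger current
#' population mortality is selected (see [select_treatment()]) and kept until
#' the next reevaluation. The first decision happens at treatment start. A
#' reevaluation period of `dt >= t_treat` therefore degenerates to a
#' single-type scheme chosen by the initial trait distribution.
#'
#' @param dt reevaluation period (> 0).
#' @inheritParams run_predefined
#' @return A list with `trajectory`, `outcome` and `switch_times` (times at
#'   which the active type changed).
#' @export
run_adaptive <- function(dt, params, timing = scenario_timing(),
                         delta = 2, m = NULL, initial = NULL,
                         relapse_reference = "max_pre", ...) {
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt <= 0)
    stop("'dt' must be a single positive number", call. = FALSE)
  if (is.null(initial)) initial <- equilibrate(params)
  if (is.null(m)) m <- calibrate_m(params, delta, timing, initial = initial)
  grid <- trait_grid(params)

  x <- initial$x / sum(initial$x)
  breaks <- 0
  labels <- character()
  current <- NULL
  t <- 0
  while (t < timing$t_treat - 1e-9) {
    current <- select_treatment(x, grid, delta, m, current)
    dur <- min(dt, timing$t_treat - t)
    setting <- if (current == "trait_dependent") trait_dependent(delta)
               else trait_independent(m)
    ph <- simulate_phase(x, setting, dur, params, n_out = 2L)
    x <- ph$x[nrow(ph$x), ]
    labels <- c(labels, current)
    t <- t + dur
    breaks <- c(breaks, t)
  }
  settings <- lapply(labels, function(l)
    if (l == "trait_dependent") trait_dependent(delta)
    else trait_independent(m))
  sched <- treatment_schedule(breaks, settings)
  traj <- simulate_scenario(params, sched, timing, initial = initial, ...)
  switches <- breaks[-c(1L, length(breaks))]
  switches <- switches[labels[-1L] != labels[-length(labels)]]
  traj$switch_times <- switches
  list(trajectory = traj,
       outcome = scheme_outcome(traj, relapse_reference),
       switch_times = switches)
}

# Filippov sliding fraction: on the equal-mortality manifold g(x) = c'x = 0
# (c_i = delta r_i - m), the fraction alpha of trait-dependent treatment that
# keeps dg/dt = 0 is alpha = (c'A0x - m g) / sum(c_i^2 x_i); the denominator
# is positive whenever the population is non-empty. Enforcing dg/dt = 0
# alone leaves the constraint neutrally stable, so integration error in g
# is never pulled back and shape perturbations grow; the stabilized variant
# targets dg/dt = -kappa g instead, which restores the manifold
# exponentially and coincides with the exact fraction on it.
sliding_alpha <- function(x, A0, cvec, m, kappa = 0) {
  g <- sum(cvec * x)
  (sum(cvec * (A0 %*% x)) - m * g + kappa * g) / sum(cvec^2 * x)
}

#' Run the optimal adaptive scheme (continuous reevaluation)
#'
#' Implements the limit of vanishing reevaluation period. Starting with the
#' type selected at treatment start, the system is integrated until the two
#' mortality terms become equal (the crossing is event-located by the
#' solver). There, if each pure treatment type would push the mortality
#' balance back across the equality manifold -- which is the case at the
#' reference parameters, because trait-dependent treatment lowers the mean
#' trait while trait-independent treatment lets it rise -- continuous
#' reevaluation alternates infinitely fast and the dynamics slide along the
#' manifold. The sliding motion is integrated exactly as the Filippov convex
#' combination of the two vector fields, i.e. an effective setting
#' `(alpha * delta, (1 - alpha) * m)` with `alpha` chosen so the mean trait
#' stays pinned at `m / delta`. If the sliding fraction leaves `[0, 1]` the
#' scheme exits to the pure type favoured on the side it leaves towards.
#'
#' @inheritParams run_predefined
#' @param n_per_unit output points per time unit.
#' @return A list with `trajectory`, `outcome` and `switch_times` (pure-type
#'   switches and the sliding onset).
#' @export
run_optimal_adaptive <- function(params, timing = scenario_timing(),
                                 delta = 2, m = NULL, initial = NULL,
                                 relapse_reference = "max_pre",
                                 detection_load = 1e10, n_per_unit = 10) {
  if (is.null(initial)) initial <- equilibrate(params)
  if (is.null(m)) m <- calibrate_m(params, delta, timing, initial = initial)
  grid <- trait_grid(params)
  A0 <- system_matrix(grid, no_treatment(), params)
  cvec <- delta * grid$rates - m
  Tt <- timing$t_treat

  x <- initial$x / sum(initial$x) * detection_load
  current <- select_treatment(x, grid, delta, m, "trait_dependent")
  t <- 0
  pieces <- list()
  switches <- numeric()
  sliding <- FALSE

  kappa <- 10  # manifold restoring rate of the stabilized sliding fraction
  slide_chunk <- 5  # renormalize the decaying sliding state this often

  rhs_pure <- function(t, x, A) list(A %*% x)
  root_g <- function(t, x, A) sum(cvec * x)
  rhs_slide <- function(t, x, p) {
    a <- min(max(sliding_alpha(x, A0, cvec, m, kappa), 0), 1)
    list(as.vector(A0 %*% x) - (a * delta * grid$rates + (1 - a) * m) * x)
  }
  root_slide <- function(t, x, p) {
    a <- sliding_alpha(x, A0, cvec, m, kappa)
    c(a, 1 - a)
  }

  while (t < Tt - 1e-9) {
    if (!sliding) {
      times <- seq(t, Tt,
                   length.out = max(2L, ceiling(n_per_unit * (Tt - t)) + 1L))
      setting <- if (current == "trait_dependent") trait_dependent(delta)
                 else trait_independent(m)
      A <- system_matrix(grid, setting, params)
      out <- deSolve::lsodar(y = x, times = times, func = rhs_pure, parms = A,
                             rootfunc = root_g, rtol = .solver_rtol,
                             atol = .solver_atol, maxsteps = 100000L)
      tt <- out[, 1L]
      xx <- pmax(out[, -1L, drop = FALSE], 0)
      pieces <- c(pieces, list(new_trajectory(
        tt, xx, rep(setting$delta, length(tt)), rep(setting$m, length(tt)),
        params, grid)))
      x <- xx[nrow(xx), ]
      t <- tt[length(tt)]
      if (t >= Tt - 1e-9) break
      # hit the equal-mortality manifold: switch or start sliding
      switches <- c(switches, t)
      a <- sliding_alpha(x, A0, cvec, m)
      if (a > 0 && a < 1) {
        sliding <- TRUE
      } else {
        current <- if (current == "trait_dependent") "trait_independent"
                   else "trait_dependent"
      }
    } else {
      # Sliding regime. The state decays by tens of orders of magnitude, so
      # integrate in chunks of a normalized state (the sliding field is
      # 1-homogeneous) and carry the absolute scale separately.
      log_scale <- log(sum(x))
      u <- x / sum(x)
      exited <- FALSE
      while (t < Tt - 1e-9) {
        d <- min(slide_chunk, Tt - t)
        times <- seq(0, d, length.out = max(2L, ceiling(n_per_unit * d) + 1L))
        out <- deSolve::lsodar(y = u, times = times, func = rhs_slide,
                               parms = NULL, rootfunc = root_slide,
                               rtol = .solver_rtol, atol = .solver_atol,
                               maxsteps = 100000L)
        tt <- out[, 1L]
        xx <- pmax(out[, -1L, drop = FALSE], 0)
        alphas <- apply(xx, 1L, function(z)
          min(max(sliding_alpha(z, A0, cvec, m, kappa), 0), 1))
        pieces <- c(pieces, list(new_trajectory(
          t + tt, xx * exp(log_scale), alphas * delta, (1 - alphas) * m,
          params, grid)))
        u <- xx[nrow(xx), ]
        t <- t + tt[length(tt)]
        tot <- sum(u)
        log_scale <- log_scale + log(tot)
        u <- u / tot
        if (!is.null(attr(out, "troot")) && t < Tt - 1e-9) {
          # sliding fraction left [0, 1]: exit to the favoured pure type
          exited <- TRUE
          break
        }
      }
      x <- u * exp(log_scale)
      if (exited) {
        switches <- c(switches, t)
        sliding <- FALSE
        a <- sliding_alpha(x, A0, cvec, m)
        current <- if (a >= 1) "trait_dependent" else "trait_independent"
      }
    }
  }

  treat <- bind_trajectories(pieces)
  xT <- treat$x[nrow(treat$x), ]
  mon <- simulate_phase(xT, no_treatment(), timing$t_monitor, params,
                        n_out = max(2L, ceiling(n_per_unit * timing$t_monitor) + 1L),
                        t0 = Tt)
  traj <- bind_trajectories(list(treat, mon))
  traj$phases <- data.frame(phase = c("pre", "treatment", "monitor"),
                            start = c(-timing$t_pre, 0, Tt),
                            end = c(0, Tt, Tt + timing$t_monitor))
  traj$switch_times <- switches
  list(trajectory = traj,
       outcome = scheme_outcome(traj, relapse_reference),
       switch_times = switches)
}

#' Sweep predefined and adaptive treatment schemes
#'
#' Runs every predefined binary sequence over `n_intervals` equal intervals,
#' a family of realistic adaptive schemes over a grid of reevaluation
#' periods, and the optimal adaptive scheme, all under a shared equilibrated
#' initial state and the calibrated trait-independent mortality. This is the
#' scheme comparison behind the minimum-load / relapse-time scatter.
#'
#' @param params a [model_params()] object.
#' @param timing a [scenario_timing()].
#' @param n_intervals intervals for the predefined family (default 8, i.e.
#'   256 sequences).
#' @param dt_grid reevaluation periods for the realistic adaptive family;
#'   defaults to a sweep from `t_treat/30` up to `t_treat`.
#' @param include_optimal include the continuously reevaluated scheme.
#' @param delta trait-dependent mortality factor.
#' @param m trait-independent mortality rate; `NULL` calibrates it.
#' @param relapse_reference passed to the outcome metrics.
#' @return A data frame with one row per scheme: `scheme_id`, `family`,
#'   `pattern`, `prop_dep`, `dt`, `min_load`, `relapse_time`, `n_switches`.
#' @export
sweep_schemes <- function(params, timing = scenario_timing(),
                          n_intervals = 8, dt_grid = NULL,
                          include_optimal = TRUE, delta = 2, m = NULL,
                          relapse_reference = "max_pre") {
  initial <- equilibrate(params)
  if (is.null(m)) m <- calibrate_m(params, delta, timing, initial = initial)
  if (is.null(dt_grid))
    dt_grid <- timing$t_treat / c(30, 20, 15, 12, 10, 8, 6, 5, 4, 3, 2, 1.5, 1)

  rows <- list()
  for (sq in enumerate_predefined(n_intervals)) {
    res <- run_predefined(sq$pattern, params, timing, delta, m,
                          initial = initial,
                          relapse_reference = relapse_reference)
    rows[[length(rows) + 1L]] <- data.frame(
      scheme_id = paste0("predefined_", sq$id), family = "predefined",
      pattern = sq$id, prop_dep = sq$prop_dep, dt = NA_real_,
      min_load = res$outcome$min_load,
      relapse_time = res$outcome$relapse_time,
      n_switches = res$outcome$n_switches)
  }
  for (dt in dt_grid) {
    res <- run_adaptive(dt, params, timing, delta, m, initial = initial,
                        relapse_reference = relapse_reference)
    rows[[length(rows) + 1L]] <- data.frame(
      scheme_id = sprintf("adaptive_dt%.6g", dt), family = "adaptive",
      pattern = NA_character_, prop_dep = NA_real_, dt = dt,
      min_load = res$outcome$min_load,
      relapse_time = res$outcome$relapse_time,
      n_switches = res$outcome$n_switches)
  }
  if (include_optimal) {
    res <- run_optimal_adaptive(params, timing, delta, m, initial = initial,
                                relapse_reference = relapse_reference)
    rows[[length(rows) + 1L]] <- data.frame(
      scheme_id = "optimal_adaptive", family = "optimal",
      pattern = NA_character_, prop_dep = NA_real_, dt = 0,
      min_load = res$outcome$min_load,
      relapse_time = res$outcome$relapse_time,
      n_switches = res$outcome$n_switches)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "m") <- m
  out
}
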