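#' Right-hand side of the trait-structured growth/switching/death system
#'
#' Computes the instantaneous rate of change of each subpopulation. For an
#' interior class `i`,
#' \deqn{dx_i/dt = (1 - p_S - p_F) r_i x_i + p_S r_{i+1} x_{i+1}
#'       + p_F r_{i-1} x_{i-1} - (\delta r_i + m) x_i,}
#' i.e. own-type proliferation reduced by the fraction of divisions whose
#' daughter switches away, influx of switched daughters from both
#' neighbours, and treatment-induced death. At the slow boundary only
#' switching towards faster classes is possible, so the own-type term is
#' `(1 - p_F) r_1 x_1`; symmetrically the fast boundary uses
#' `(1 - p_S) r_omega x_omega`. Off-grid switching is a null event, which is
#' why boundary classes keep a larger share of their own divisions.
#'
#' @param state a numeric abundance vector of length `omega` or a
#'   [population_state()].
#' @param grid a [trait_grid()].
#' @param setting a [treatment_setting()].
#' @param params the [model_params()] the grid was built from.
#' @return Numeric vector of `omega` time derivatives.
#' @seealso [system_matrix()] for the equivalent linear operator.
#' @export
ode_rhs <- function(state, grid, setting, params) {
  x <- as_abundance(state)
  r <- grid$rates
  n <- length(r)
  if (length(x) != n)
    stop("state length does not match the trait grid", call. = FALSE)
  loss <- rep(params$p_S + params$p_F, n)
  loss[1L] <- params$p_F          # slowest class cannot switch slower
  loss[n] <- params$p_S           # fastest class cannot switch faster
  d <- (1 - loss) * r * x - (setting$delta * r + setting$m) * x
  d <- d + params$p_S * c(r[-1L] * x[-1L], 0)       # daughters from faster
  d + params$p_F * c(0, r[-n] * x[-n])              # daughters from slower
}

#' Linear system matrix of the trait-structured model
#'
#' The model is linear, `dx/dt = A x`. `system_matrix()` assembles the
#' tridiagonal matrix `A` for a given treatment setting: the diagonal holds
#' net own-type proliferation minus treatment mortality, the superdiagonal
#' the influx from the next-faster class (`p_S r_{i+1}`) and the subdiagonal
#' the influx from the next-slower class (`p_F r_i`).
#'
#' @inheritParams ode_rhs
#' @return A dense `omega x omega` matrix.
#' @export
system_matrix <- function(grid, setting, params) {
  r <- grid$rates
  n <- length(r)
  loss <- rep(params$p_S + params$p_F, n)
  loss[1L] <- params$p_F
  loss[n] <- params$p_S
  A <- matrix(0, n, n)
  diag(A) <- (1 - loss) * r - setting$delta * r - setting$m
  idx <- seq_len(n - 1L)
  A[cbind(idx, idx + 1L)] <- params$p_S * r[idx + 1L]
  A[cbind(idx + 1L, idx)] <- params$p_F * r[idx]
  A
}

#' Dominant eigenvalue and stable trait distribution of the system matrix
#'
#' For the untreated (or any fixed-setting) linear system the population
#' converges to exponential growth at the dominant eigenvalue `lambda*` with
#' frequencies given by the associated eigenvector. Because the matrix is
#' tridiagonal with positive off-diagonal entries, the dominant eigenvalue is
#' real and simple and its eigenvector can be chosen strictly positive
#' (Perron-Frobenius applied to `A + c I`).
#'
#' @param A a system matrix from [system_matrix()].
#' @return A list with `value` (the dominant growth rate) and `vector` (the
#'   stable frequency vector, positive, summing to 1).
#' @export
leading_eigenpair <- function(A) {
  e <- eigen(A)
  k <- which.max(Re(e$values))
  if (abs(Im(e$values[k])) > 1e-10 * max(1, abs(Re(e$values[k]))))
    stop("dominant eigenvalue is not numerically real", call. = FALSE)
  v <- Re(e$vectors[, k])
  v <- v * sign(sum(v))
  if (any(v < -1e-10 * max(abs(v))))
    stop("dominant eigenvector has mixed signs; eigen computation failed",
         call. = FALSE)
  v <- pmax(v, 0)
  list(value = Re(e$values[k]), vector = v / sum(v))
}

# Shared solver contract: stiff-capable adaptive integrator. The absolute
# tolerance must sit far below the smallest abundances that matter -- the
# equilibration seed has components at 1e-60 -- so it is set extremely small
# and accuracy is carried by the relative tolerance.
.solver_rtol <- 1e-10
.solver_atol <- 1e-60

solve_linear <- function(x0, A, times) {
  rhs <- function(t, x, A) list(A %*% x)
  out <- deSolve::ode(y = x0, times = times, func = rhs, parms = A,
                      method = "lsoda", rtol = .solver_rtol,
                      atol = .solver_atol, maxsteps = 100000L)
  if (attr(out, "istate")[1L] < 0)
    stop("ODE integration failed (lsoda istate ",
         attr(out, "istate")[1L], ")", call. = FALSE)
  out
}

#' Equilibrate to the stable trait distribution
#'
#' Integrates the untreated system for `duration` time units from the
#' exponential seed `x_i = 1e-60 * exp(80 * v_i)`, which loads almost all
#' mass close to (but not on) the fastest class. The returned state's
#' frequency vector is the stable trait distribution used as the
#' pre-detection initial condition. Integration proceeds in chunks; whenever
#' the total leaves `[1/renorm_threshold, renorm_threshold]` the state is
#' renormalized to total 1 and integration continues -- the system is linear,
#' so frequencies are unaffected and only they matter here.
#'
#' @param params a [model_params()] object.
#' @param duration burn-in duration in time units (default 200).
#' @param chunk chunk length between renormalization checks.
#' @param renorm_threshold total abundance beyond which the state is rescaled.
#' @return A [population_state()] at `t = 0` holding the equilibrated state.
#' @examples
#' eq <- equilibrate(model_params(omega = 5))
#' eq$freqs  # increasing: fast growers dominate at detection
#' @export
equilibrate <- function(params, duration = 200, chunk = 20,
                        renorm_threshold = 1e50) {
  grid <- trait_grid(params)
  A <- system_matrix(grid, no_treatment(), params)
  x <- 1e-60 * exp(80 * grid$v)
  t <- 0
  while (t < duration) {
    d <- min(chunk, duration - t)
    out <- solve_linear(x, A, c(0, d))
    x <- pmax(out[nrow(out), -1L], 0)
    t <- t + d
    tot <- sum(x)
    if (tot > renorm_threshold || tot < 1 / renorm_threshold)
      x <- x / tot
  }
  population_state(0, x)
}

new_trajectory <- function(time, x, delta, m, params, grid,
                           phases = NULL, switch_times = numeric()) {
  colnames(x) <- paste0("x", seq_len(ncol(x)))
  structure(list(time = time, x = x, delta = delta, m = m,
                 params = params, grid = grid, phases = phases,
                 switch_times = switch_times),
            class = "pheno_trajectory")
}

#' Total tumour load along a trajectory
#'
#' @param traj a `pheno_trajectory`.
#' @return Numeric vector of total abundances, one per output time.
#' @export
total_load <- function(traj) {
  stopifnot(inherits(traj, "pheno_trajectory"))
  rowSums(traj$x)
}

#' @export
print.pheno_trajectory <- function(x, ...) {
  X <- total_load(x)
  cat(sprintf("Trajectory: %d classes, %d output points, t in [%.4g, %.4g]\n",
              ncol(x$x), length(x$time), min(x$time), max(x$time)))
  cat(sprintf("  total load: %.6g (start) -> %.6g (end), minimum %.6g\n",
              X[1L], X[length(X)], min(X)))
  if (!is.null(x$phases)) {
    p <- x$phases
    cat("  phases:", paste(sprintf("%s [%.4g, %.4g]", p$phase, p$start, p$end),
                           collapse = ", "), "\n")
  }
  if (length(x$switch_times))
    cat("  treatment switches at:",
        paste(signif(x$switch_times, 6), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.pheno_trajectory <- function(x, ...) {
  n <- length(x$time)
  om <- ncol(x$x)
  data.frame(time = rep(x$time, om),
             subpopulation_index = rep(seq_len(om), each = n),
             growth_rate = rep(x$grid$rates, each = n),
             abundance = as.vector(x$x),
             total = rep(rowSums(x$x), om),
             delta_active = rep(x$delta, om),
             m_active = rep(x$m, om))
}

# Concatenate trajectory pieces; later pieces drop their first row when it
# duplicates the previous end time.
bind_trajectories <- function(pieces) {
  time <- pieces[[1L]]$time
  x <- pieces[[1L]]$x
  delta <- pieces[[1L]]$delta
  m <- pieces[[1L]]$m
  for (p in pieces[-1L]) {
    k <- if (length(time) && length(p$time) &&
             isTRUE(all.equal(p$time[1L], time[length(time)]))) -1L
         else TRUE
    time <- c(time, p$time[k])
    x <- rbind(x, p$x[k, , drop = FALSE])
    delta <- c(delta, p$delta[k])
    m <- c(m, p$m[k])
  }
  new_trajectory(time, x, delta, m, pieces[[1L]]$params, pieces[[1L]]$grid)
}

#' Simulate one constant-treatment phase
#'
#' Integrates the linear system under a fixed [treatment_setting()] for
#' `duration` time units, reporting the solution on a regular output grid.
#' Output density defaults to 10 points per time unit; event timing (relapse
#' crossings) is later refined on the interpolant, so the grid only needs to
#' bracket events.
#'
#' @param initial a [population_state()] or abundance vector at phase start.
#' @param setting the active [treatment_setting()].
#' @param duration phase duration (non-negative).
#' @param params a [model_params()] object.
#' @param n_out number of output points; defaults to
#'   `max(2, ceiling(10 * duration) + 1)`.
#' @param t0 absolute time assigned to the phase start.
#' @return A `pheno_trajectory`.
#' @export
simulate_phase <- function(initial, setting, duration, params,
                           n_out = NULL, t0 = 0) {
  if (duration < 0) stop("'duration' must be non-negative", call. = FALSE)
  grid <- trait_grid(params)
  x0 <- as_abundance(initial)
  if (length(x0) != params$omega)
    stop("initial state length does not match 'omega'", call. = FALSE)
  if (duration == 0) {
    return(new_trajectory(t0, matrix(x0, nrow = 1L),
                          setting$delta, setting$m, params, grid))
  }
  if (is.null(n_out)) n_out <- max(2L, ceiling(10 * duration) + 1L)
  A <- system_matrix(grid, setting, params)
  out <- solve_linear(x0, A, seq(0, duration, length.out = n_out))
  x <- pmax(out[, -1L, drop = FALSE], 0)
  new_trajectory(t0 + out[, 1L], x, rep(setting$delta, nrow(x)),
                 rep(setting$m, nrow(x)), params, grid)
}

#' Simulate a full detection-treatment-monitoring scenario
#'
#' Concatenates three phases: untreated pre-detection growth on
#' `[-t_pre, 0]`, treatment on `[0, t_treat]` following a piecewise-constant
#' [treatment_schedule()], and untreated monitoring on
#' `[t_treat, t_treat + t_monitor]`. The initial state defaults to the
#' equilibrated stable trait distribution rescaled to `detection_load`; the
#' absolute scale is cosmetic because the system is linear and all relative
#' outcome measures are scale-invariant.
#'
#' @param params a [model_params()] object.
#' @param schedule a [treatment_schedule()] covering `[0, t_treat]`.
#' @param timing a [scenario_timing()].
#' @param detection_load total load the initial state is rescaled to.
#' @param initial optional [population_state()] to start from (its
#'   frequencies are used and rescaled to `detection_load`); when `NULL` the
#'   model is equilibrated first.
#' @param equilibrate_duration burn-in passed to [equilibrate()].
#' @param n_per_unit output points per time unit.
#' @return A `pheno_trajectory` with a `phases` table; time origin at
#'   detection.
#' @export
simulate_scenario <- function(params, schedule,
                              timing = scenario_timing(),
                              detection_load = 1e10,
                              initial = NULL,
                              equilibrate_duration = 200,
                              n_per_unit = 10) {
  stopifnot(inherits(schedule, "treatment_schedule"))
  tb <- schedule$breakpoints
  if (abs(tb[length(tb)] - timing$t_treat) > 1e-8)
    stop("schedule does not cover [0, t_treat]", call. = FALSE)
  if (is.null(initial)) initial <- equilibrate(params, equilibrate_duration)
  x <- initial$x / sum(initial$x) * detection_load

  pieces <- list()
  if (timing$t_pre > 0) {
    pre <- simulate_phase(x, no_treatment(), timing$t_pre, params,
                          n_out = max(2L, ceiling(n_per_unit * timing$t_pre) + 1L),
                          t0 = -timing$t_pre)
    x <- pre$x[nrow(pre$x), ]
    pieces <- c(pieces, list(pre))
  }
  for (k in seq_along(schedule$settings)) {
    dur <- tb[k + 1L] - tb[k]
    ph <- simulate_phase(x, schedule$settings[[k]], dur, params,
                         n_out = max(2L, ceiling(n_per_unit * dur) + 1L),
                         t0 = tb[k])
    x <- ph$x[nrow(ph$x), ]
    pieces <- c(pieces, list(ph))
  }
  if (timing$t_monitor > 0) {
    mon <- simulate_phase(x, no_treatment(), timing$t_monitor, params,
                          n_out = max(2L, ceiling(n_per_unit * timing$t_monitor) + 1L),
                          t0 = timing$t_treat)
    pieces <- c(pieces, list(mon))
  }
  traj <- bind_trajectories(pieces)
  traj$phases <- data.frame(
    phase = c("pre", "treatment", "monitor"),
    start = c(-timing$t_pre, 0, timing$t_treat),
    end = c(0, timing$t_treat, timing$t_treat + timing$t_monitor))
  # a switch is an interior breakpoint where the active setting changes
  changed <- vapply(seq_len(length(schedule$settings) - 1L), function(k) {
    a <- schedule$settings[[k]]
    b <- schedule$settings[[k + 1L]]
    a$delta != b$delta || a$m != b$m
  }, logical(1L))
  traj$switch_times <- tb[-c(1L, length(tb))][changed]
  traj$schedule <- schedule
  traj
}
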