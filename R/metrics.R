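#' Shannon evenness of a trait distribution
#'
#' Pielou's evenness of the subpopulation frequencies:
#' `-sum(f_i log f_i) / log(omega)` over classes with `f_i > 0`
#' (with `0 log 0 := 0`). Ranges from 0 (all mass on one class) to 1
#' (uniform). A single-class population returns 0 by convention.
#'
#' @param state abundance vector or [population_state()] with positive total.
#' @return Evenness in `[0, 1]`.
#' @examples
#' shannon_evenness(rep(1, 25))   # 1
#' shannon_evenness(c(0, 5, 0))   # 0
#' @export
shannon_evenness <- function(state) {
  x <- as_abundance(state)
  tot <- sum(x)
  if (tot <= 0) stop("evenness is undefined for an empty population",
                     call. = FALSE)
  if (length(x) == 1L) return(0)
  f <- x / tot
  f <- f[f > 0]
  -sum(f * log(f)) / log(length(x))
}

# Evenness at every output time of a trajectory.
evenness_series <- function(traj) {
  apply(traj$x, 1L, shannon_evenness)
}

#' Minimum tumour load over a time window
#'
#' Minimum of the total load on the trajectory's output grid restricted to
#' `window`. Defaults to the treatment phase when the trajectory carries a
#' `phases` table. During treatment the per-capita net growth rate is
#' negative under both treatment types at the reference parameters, so the
#' load declines monotonically and the grid minimum equals the
#' end-of-interval value exactly.
#'
#' @param traj a `pheno_trajectory`.
#' @param window length-2 numeric interval; `NULL` uses the treatment phase.
#' @return The minimum total load.
#' @export
minimum_tumour_load <- function(traj, window = NULL) {
  stopifnot(inherits(traj, "pheno_trajectory"))
  if (is.null(window)) {
    if (is.null(traj$phases))
      stop("no 'window' given and the trajectory has no phase table",
           call. = FALSE)
    ph <- traj$phases[traj$phases$phase == "treatment", ]
    window <- c(ph$start, ph$end)
  }
  sel <- traj$time >= window[1L] - 1e-12 & traj$time <= window[2L] + 1e-12
  if (!any(sel)) stop("window contains no trajectory output points",
                      call. = FALSE)
  min(rowSums(traj$x[sel, , drop = FALSE]))
}

#' Relapse time of a trajectory
#'
#' First time after treatment initiation at which the total load strictly
#' exceeds a reference: the pre-treatment maximum (`"max_pre"`, default), the
#' load at treatment initiation (`"at_init"`), or an absolute cell-count
#' threshold (`"absolute"`, used for the stochastic 1000-cell definition).
#' The crossing is root-found on the log-linear interpolant of the total
#' load between the bracketing output points, which is exact up to the local
#' deviation from exponential growth (well below 1e-6 time units at the
#' default output density).
#'
#' @param traj a `pheno_trajectory` with a `phases` table (or `after` given).
#' @param reference one of `"max_pre"`, `"at_init"`, `"absolute"`.
#' @param threshold absolute reference load, required for `"absolute"`.
#' @param after only crossings at `time > after` count; defaults to the
#'   treatment start.
#' @return Crossing time, or `NA_real_` when censored (no crossing within
#'   the trajectory).
#' @export
relapse_time <- function(traj,
                         reference = c("max_pre", "at_init", "absolute"),
                         threshold = NULL, after = NULL) {
  stopifnot(inherits(traj, "pheno_trajectory"))
  reference <- match.arg(reference)
  X <- rowSums(traj$x)
  t <- traj$time
  if (is.null(after)) {
    if (is.null(traj$phases))
      stop("no 'after' given and the trajectory has no phase table",
           call. = FALSE)
    after <- traj$phases$start[traj$phases$phase == "treatment"]
  }
  ref <- switch(reference,
    max_pre = {
      pre <- t <= after + 1e-12
      if (!any(pre)) stop("no pre-treatment points to take the maximum over",
                          call. = FALSE)
      max(X[pre])
    },
    at_init = X[which.min(abs(t - after))],
    absolute = {
      if (is.null(threshold))
        stop("reference = 'absolute' requires 'threshold'", call. = FALSE)
      threshold
    })
  if (reference != "absolute" && !is.null(threshold))
    stop("'threshold' is only used with reference = 'absolute'",
         call. = FALSE)
  idx <- which(t > after & X > ref)
  idx <- idx[idx > 1L]
  if (!length(idx)) return(NA_real_)
  i <- idx[1L]
  if (X[i - 1L] > ref) return(t[i - 1L])  # already above at window start
  # log-linear interpolation of the up-crossing
  t[i - 1L] + (t[i] - t[i - 1L]) *
    (log(ref) - log(X[i - 1L])) / (log(X[i]) - log(X[i - 1L]))
}

#' Outcome metrics of one treatment scheme
#'
#' Bundles the minimum tumour load during treatment and the relapse time for
#' a simulated scenario trajectory.
#'
#' @param traj a scenario `pheno_trajectory`.
#' @param relapse_reference passed to [relapse_time()].
#' @param threshold passed to [relapse_time()] for `"absolute"`.
#' @return An object of class `scheme_outcome` with `min_load`,
#'   `relapse_time` (possibly `NA`) and `n_switches`.
#' @export
scheme_outcome <- function(traj, relapse_reference = "max_pre",
                           threshold = NULL) {
  structure(list(
    min_load = minimum_tumour_load(traj),
    relapse_time = relapse_time(traj, relapse_reference, threshold),
    n_switches = length(traj$switch_times)),
    class = "scheme_outcome")
}

#' @export
print.scheme_outcome <- function(x, ...) {
  cat(sprintf("Scheme outcome: minimum load %.6g, relapse time %s, %d switch(es)\n",
              x$min_load,
              if (is.na(x$relapse_time)) "censored"
              else sprintf("%.6g", x$relapse_time),
              x$n_switches))
  invisible(x)
}

#' Step-size statistics of stochastic two-class paths
#'
#' Pools the per-sampling-interval increments of the slow and fast classes
#' across replicate paths and reports the standard deviation of each class's
#' increments together with their normalized difference
#' `(sigma_fast - sigma_slow) / mean(sigma_slow, sigma_fast)`. Used on
#' diffusion-only paths to compare how widely each class wanders under the
#' different treatment types.
#'
#' @param paths a list of numeric matrices (time points x 2 columns, slow
#'   then fast), e.g. slices of [sde_simulate()] output.
#' @param every take increments every `every`-th output point (the reference
#'   analysis uses solver steps of 0.01 sampled every 100 steps).
#' @return An object of class `step_size_stats` with `sigma_slow`,
#'   `sigma_fast` and `delta_sigma_normalized`.
#' @export
step_size_stats <- function(paths, every = 1L) {
  if (is.matrix(paths)) paths <- list(paths)
  if (!length(paths) || !all(vapply(paths, is.matrix, logical(1L))))
    stop("'paths' must be a matrix or list of matrices", call. = FALSE)
  inc <- lapply(paths, function(p) {
    sub <- p[seq(1L, nrow(p), by = every), , drop = FALSE]
    if (nrow(sub) < 2L)
      stop("need at least two sampled points per path", call. = FALSE)
    diff(sub)
  })
  inc <- do.call(rbind, inc)
  s <- apply(inc, 2L, stats::sd)
  structure(list(sigma_slow = s[1L], sigma_fast = s[2L],
                 delta_sigma_normalized = (s[2L] - s[1L]) / mean(s)),
            class = "step_size_stats")
}

#' @export
print.step_size_stats <- function(x, ...) {
  cat(sprintf("Step sizes: sigma_slow %.4g, sigma_fast %.4g, normalized difference %.4g\n",
              x$sigma_slow, x$sigma_fast, x$delta_sigma_normalized))
  invisible(x)
}
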