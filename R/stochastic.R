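#' Parameters of the two-subpopulation stochastic model
#'
#' The stochastic counterpart of the deterministic model keeps only the two
#' extreme subpopulations, growing at `r_slow` and `r_fast`, whose dynamics
#' differ the most. `delta` and `m` are the treatment parameters active
#' during simulation (zero outside treatment phases); `V` is the system-size
#' parameter scaling the Langevin noise amplitude (`1/sqrt(V)`).
#'
#' Two microscopic switching schemes share the same mean field: with
#' `switching = "division"` (default) a dividing cell's daughter is born into
#' the adjacent class with probability `p_S`/`p_F`, tying switching to
#' division as in the deterministic model; `"moves"` instead posits plain
#' births at the full rate plus independent cell moves between classes at
#' `p_F r_slow` / `p_S r_fast` per cell. The two differ only in their noise
#' and the second is exposed for sensitivity analysis.
#'
#' @param r_slow,r_fast growth rates of the two classes (per time unit).
#' @param p_S,p_F switching fractions, as in [model_params()].
#' @param delta trait-dependent mortality factor during treatment.
#' @param m trait-independent mortality rate during treatment; the matched
#'   value for the reference stochastic scenario is 0.722 per time unit.
#' @param V system-size parameter of the Langevin scaling (> 0).
#' @param switching microscopic switching scheme, see Details.
#' @return An object of class `stochastic_params`.
#' @export
stochastic_params <- function(r_slow = 0.25, r_fast = 0.5,
                              p_S = 0.2, p_F = 0.2,
                              delta = 0, m = 0, V = 25,
                              switching = c("division", "moves")) {
  switching <- match.arg(switching)
  if (r_slow <= 0 || r_fast <= 0 || r_slow >= r_fast)
    stop("need 0 < r_slow < r_fast", call. = FALSE)
  if (p_S < 0 || p_F < 0 || p_S + p_F >= 1)
    stop("switching fractions must be non-negative with p_S + p_F < 1",
         call. = FALSE)
  if (delta < 0 || m < 0) stop("mortalities must be non-negative",
                               call. = FALSE)
  if (V <= 0) stop("'V' must be positive", call. = FALSE)
  structure(list(r_slow = r_slow, r_fast = r_fast, p_S = p_S, p_F = p_F,
                 delta = delta, m = m, V = V, switching = switching),
            class = "stochastic_params")
}

#' @export
print.stochastic_params <- function(x, ...) {
  cat(sprintf("Two-class stochastic model: r = (%.4g, %.4g), p_S = %.3g, p_F = %.3g\n",
              x$r_slow, x$r_fast, x$p_S, x$p_F))
  cat(sprintf("  treatment: delta = %.4g, m = %.4g; V = %.4g; switching at %s\n",
              x$delta, x$m, x$V, x$switching))
  invisible(x)
}

#' Microscopic reaction set of the two-class model
#'
#' Builds the birth, switching and death reactions whose mean-field drift
#' reproduces the two-class deterministic system exactly. Propensities are
#' linear in the counts, `a_j(n) = coef[j, ] %*% n`.
#'
#' @param sp a [stochastic_params()] object.
#' @return An object of class `reaction_set` with `stoich` (reactions x 2),
#'   `coef` (reactions x 2) and `labels`.
#' @export
build_reactions <- function(sp) {
  stopifnot(inherits(sp, "stochastic_params"))
  d1 <- sp$delta * sp$r_slow + sp$m
  d2 <- sp$delta * sp$r_fast + sp$m
  if (sp$switching == "division") {
    stoich <- rbind(c(1, 0),   # slow division, daughter stays slow
                    c(0, 1),   # slow division, daughter switches fast
                    c(0, 1),   # fast division, daughter stays fast
                    c(1, 0),   # fast division, daughter switches slow
                    c(-1, 0),  # slow death
                    c(0, -1))  # fast death
    coef <- rbind(c((1 - sp$p_F) * sp$r_slow, 0),
                  c(sp$p_F * sp$r_slow, 0),
                  c(0, (1 - sp$p_S) * sp$r_fast),
                  c(0, sp$p_S * sp$r_fast),
                  c(d1, 0),
                  c(0, d2))
    labels <- c("birth_slow", "switch_birth_to_fast", "birth_fast",
                "switch_birth_to_slow", "death_slow", "death_fast")
  } else {
    stoich <- rbind(c(1, 0),   # slow birth
                    c(0, 1),   # fast birth
                    c(-1, 1),  # slow cell moves to fast
                    c(1, -1),  # fast cell moves to slow
                    c(-1, 0),  # slow death
                    c(0, -1))  # fast death
    coef <- rbind(c(sp$r_slow, 0),
                  c(0, sp$r_fast),
                  c(sp$p_F * sp$r_slow, 0),
                  c(0, sp$p_S * sp$r_fast),
                  c(d1, 0),
                  c(0, d2))
    labels <- c("birth_slow", "birth_fast", "move_to_fast", "move_to_slow",
                "death_slow", "death_fast")
  }
  structure(list(stoich = stoich, coef = coef, labels = labels),
            class = "reaction_set")
}

#' @export
print.reaction_set <- function(x, ...) {
  cat(sprintf("Reaction set with %d reactions over 2 classes\n",
              nrow(x$stoich)))
  invisible(x)
}

#' Propensities, drift and diffusion of a reaction set
#'
#' `reaction_propensities()` evaluates every reaction rate at counts `n`;
#' `reaction_drift()` returns the mean-field drift
#' `sum_j a_j(n) s_j` (which equals the two-class deterministic right-hand
#' side); `diffusion_matrix()` returns
#' `sum_j a_j(n) s_j s_j^T`, the diffusion matrix of the Langevin
#' approximation before the `1/V` scaling.
#'
#' @param reactions a [build_reactions()] result.
#' @param n numeric length-2 state (counts or abundances).
#' @return A numeric vector (propensities, drift) or a 2x2 matrix.
#' @export
reaction_propensities <- function(reactions, n) {
  pmax(as.vector(reactions$coef %*% n), 0)
}

#' @rdname reaction_propensities
#' @export
reaction_drift <- function(reactions, n) {
  as.vector(t(reactions$stoich) %*% reaction_propensities(reactions, n))
}

#' @rdname reaction_propensities
#' @export
diffusion_matrix <- function(reactions, n) {
  a <- reaction_propensities(reactions, n)
  t(reactions$stoich) %*% (a * reactions$stoich)
}

#' Exact jump-process simulation of the two-class model
#'
#' Statistically exact Gillespie (direct-method) sample path of the reaction
#' set, recorded at the requested output times. The process is absorbing at
#' total count 0. Reproducibility comes from R's RNG: call `set.seed()` (or
#' pass `seed`) before simulating.
#'
#' @param reactions a [build_reactions()] result (or a
#'   [stochastic_params()], from which reactions are built).
#' @param init length-2 vector of non-negative integer initial counts.
#' @param t_end simulation horizon.
#' @param times output times (default 101 equally spaced points).
#' @param threshold record the first time the total strictly exceeds this
#'   count (default `Inf`: never).
#' @param stop_at_threshold stop the walk at that crossing.
#' @param seed optional integer seed set before simulating.
#' @return A list with `times`, `counts` (matrix, columns slow/fast),
#'   `extinction_time` and `crossing_time` (`NA` when the event did not
#'   occur).
#' @export
gillespie_simulate <- function(reactions, init, t_end, times = NULL,
                               threshold = Inf, stop_at_threshold = FALSE,
                               seed = NULL) {
  if (inherits(reactions, "stochastic_params"))
    reactions <- build_reactions(reactions)
  stopifnot(inherits(reactions, "reaction_set"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(times)) times <- seq(0, t_end, length.out = 101L)
  res <- .ssa_linear(reactions$coef, storage_int(reactions$stoich),
                     as.numeric(init), t_end, as.numeric(times),
                     threshold, stop_at_threshold)
  counts <- res$states
  colnames(counts) <- c("slow", "fast")
  list(times = as.numeric(times), counts = counts,
       extinction_time = res$extinction_time,
       crossing_time = res$crossing_time)
}

storage_int <- function(m) {
  storage.mode(m) <- "integer"
  m
}

# Closed-form square root of a symmetric psd 2x2 matrix [[a, b], [b, d]]:
# B = (M + sqrt(det) I) / sqrt(tr + 2 sqrt(det)). Vectorized over states.
sqrt2x2 <- function(a, b, d) {
  s <- sqrt(pmax(a * d - b^2, 0))
  u <- sqrt(pmax(a + d + 2 * s, 0))
  u[u == 0] <- Inf  # zero matrix -> zero root
  list(b11 = (a + s) / u, b12 = b / u, b22 = (d + s) / u)
}

sde_core <- function(sp, init, t_end, dt, n_replicates, record_every,
                     use_drift) {
  reactions <- build_reactions(sp)
  S <- reactions$stoich
  Dmat <- t(S) %*% reactions$coef            # drift = Dmat %*% x
  n_steps <- ceiling(t_end / dt)
  rec_idx <- seq(0L, n_steps, by = record_every)
  times <- rec_idx * dt
  out <- array(NA_real_, dim = c(length(rec_idx), 2L, n_replicates))

  x <- matrix(rep(as.numeric(init), each = n_replicates),
              nrow = n_replicates)               # replicates x 2
  out[1L, , ] <- t(x)
  sq1 <- S[, 1L]^2; sq2 <- S[, 2L]^2; cr <- S[, 1L] * S[, 2L]
  rec_ptr <- 2L
  scale <- sqrt(dt / sp$V)
  for (step in seq_len(n_steps)) {
    prop <- pmax(x %*% t(reactions$coef), 0)     # replicates x reactions
    a11 <- prop %*% sq1
    a22 <- prop %*% sq2
    a12 <- prop %*% cr
    B <- sqrt2x2(a11, a12, a22)
    z1 <- rnorm(n_replicates); z2 <- rnorm(n_replicates)
    inc1 <- (B$b11 * z1 + B$b12 * z2) * scale
    inc2 <- (B$b12 * z1 + B$b22 * z2) * scale
    if (use_drift) {
      dr <- x %*% t(Dmat)
      x <- x + dr * dt
    }
    x[, 1L] <- pmax(x[, 1L] + inc1, 0)           # reflect at 0 by clipping
    x[, 2L] <- pmax(x[, 2L] + inc2, 0)
    if (rec_ptr <= length(rec_idx) && step == rec_idx[rec_ptr]) {
      out[rec_ptr, , ] <- t(x)
      rec_ptr <- rec_ptr + 1L
    }
  }
  list(times = times, x = out)
}

#' Langevin (Euler-Maruyama) simulation of the two-class model
#'
#' Integrates the stochastic differential equation
#' `dx = a(x) dt + V^{-1/2} B(x) dW`, where the drift `a(x)` is the
#' two-class deterministic right-hand side and `B(x) B(x)^T` is the
#' diffusion matrix assembled from the reaction set
#' (see [diffusion_matrix()]). Paths are reflected at zero by clipping
#' negative excursions. `diffusion_only_simulate()` sets the drift to zero
#' and is used for the step-size analysis of the two classes.
#'
#' @param sp a [stochastic_params()] object.
#' @param init length-2 vector of non-negative initial abundances.
#' @param t_end simulation horizon.
#' @param dt Euler-Maruyama step (default 0.01).
#' @param n_replicates number of independent paths simulated together.
#' @param record_every record every this-many steps.
#' @param seed optional integer seed set before simulating.
#' @return A list with `times` and `x`, an array of dimension
#'   (recorded times, 2 classes, replicates).
#' @export
sde_simulate <- function(sp, init, t_end, dt = 0.01, n_replicates = 1L,
                         record_every = 1L, seed = NULL) {
  stopifnot(inherits(sp, "stochastic_params"))
  if (any(init < 0)) stop("initial abundances must be non-negative",
                          call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sde_core(sp, init, t_end, dt, n_replicates, record_every, use_drift = TRUE)
}

#' @rdname sde_simulate
#' @export
diffusion_only_simulate <- function(sp, init, t_end, dt = 0.01,
                                    n_replicates = 1L, record_every = 1L,
                                    seed = NULL) {
  stopifnot(inherits(sp, "stochastic_params"))
  if (any(init < 0)) stop("initial abundances must be non-negative",
                          call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sde_core(sp, init, t_end, dt, n_replicates, record_every, use_drift = FALSE)
}

# Stable two-class frequency vector for the given stochastic parameters.
two_class_stable_freqs <- function(sp) {
  params <- model_params(omega = 2L, r_min = sp$r_slow, r_max = sp$r_fast,
                         p_S = sp$p_S, p_F = sp$p_F)
  A <- system_matrix(trait_grid(params), no_treatment(), params)
  leading_eigenpair(A)$vector
}

#' Replicate ensemble of stochastic treatment scenarios
#'
#' Simulates `n_replicates` independent populations through a treatment
#' phase (with the treatment parameters carried by `sp`) followed by an
#' untreated monitoring phase, and classifies every replicate as extinct
#' (absorbed at 0 cells), relapsed (total count first strictly exceeds
#' `threshold` cells during monitoring), or censored. The default initial
#' state places `init_total` cells on the two classes according to the
#' stable two-class trait distribution.
#'
#' Per-replicate seeds are drawn once from the master `seed`, so any
#' replicate can be re-simulated independently and the whole ensemble is
#' reproducible.
#'
#' @param sp a [stochastic_params()] with the treatment-phase `delta`/`m`.
#' @param timing a [scenario_timing()]; the stochastic reference scenario
#'   treats for 25 time units and monitors for 50.
#' @param init optional length-2 initial counts; default derived from
#'   `init_total` and the stable two-class distribution.
#' @param init_total total initial cell count for the default state.
#' @param n_replicates number of replicate populations.
#' @param engine `"jump"` (exact SSA) or `"sde"` (Langevin).
#' @param threshold relapse threshold in cells (default 1000).
#' @param seed master seed.
#' @param dt Euler-Maruyama step for the SDE engine.
#' @return An object of class `ensemble_summary` with fates, extinction
#'   probability, relapse and extinction times.
#' @export
run_ensemble <- function(sp, timing = scenario_timing(t_pre = 0,
                                                      t_treat = 25,
                                                      t_monitor = 50),
                         init = NULL, init_total = 1000,
                         n_replicates = 100L,
                         engine = c("jump", "sde"),
                         threshold = 1000, seed = 1L, dt = 0.01) {
  engine <- match.arg(engine)
  stopifnot(inherits(sp, "stochastic_params"))
  if (n_replicates < 1L) stop("'n_replicates' must be at least 1",
                              call. = FALSE)
  if (is.null(init)) {
    f <- two_class_stable_freqs(sp)
    init <- round(f * init_total)
  }
  sp_off <- stochastic_params(sp$r_slow, sp$r_fast, sp$p_S, sp$p_F,
                              delta = 0, m = 0, V = sp$V,
                              switching = sp$switching)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)

  fates <- character(n_replicates)
  ext_times <- rep(NA_real_, n_replicates)
  rel_times <- rep(NA_real_, n_replicates)

  if (engine == "jump") {
    rx_on <- build_reactions(sp)
    rx_off <- build_reactions(sp_off)
    for (i in seq_len(n_replicates)) {
      set.seed(rep_seeds[i])
      tr <- gillespie_simulate(rx_on, init, timing$t_treat,
                               times = timing$t_treat)
      if (!is.na(tr$extinction_time)) {
        fates[i] <- "extinct"
        ext_times[i] <- tr$extinction_time
        next
      }
      endstate <- tr$counts[nrow(tr$counts), ]
      mon <- gillespie_simulate(rx_off, endstate, timing$t_monitor,
                                times = timing$t_monitor,
                                threshold = threshold,
                                stop_at_threshold = TRUE)
      if (!is.na(mon$crossing_time)) {
        fates[i] <- "relapsed"
        rel_times[i] <- timing$t_treat + mon$crossing_time
      } else if (!is.na(mon$extinction_time)) {
        fates[i] <- "extinct"
        ext_times[i] <- timing$t_treat + mon$extinction_time
      } else {
        fates[i] <- "censored"
      }
    }
  } else {
    for (i in seq_len(n_replicates)) {
      set.seed(rep_seeds[i])
      tr <- sde_simulate(sp, init, timing$t_treat, dt = dt)
      path <- tr$x[, , 1L]
      tot <- rowSums(path)
      if (any(tot <= 0)) {
        fates[i] <- "extinct"
        ext_times[i] <- tr$times[which(tot <= 0)[1L]]
        next
      }
      mon <- sde_simulate(sp_off, path[nrow(path), ], timing$t_monitor,
                          dt = dt)
      mtot <- rowSums(mon$x[, , 1L])
      cross <- which(mtot > threshold)
      dead <- which(mtot <= 0)
      if (length(cross) && (!length(dead) || cross[1L] < dead[1L])) {
        fates[i] <- "relapsed"
        rel_times[i] <- timing$t_treat + mon$times[cross[1L]]
      } else if (length(dead)) {
        fates[i] <- "extinct"
        ext_times[i] <- timing$t_treat + mon$times[dead[1L]]
      } else {
        fates[i] <- "censored"
      }
    }
  }

  structure(list(n_replicates = n_replicates,
                 engine = engine,
                 init = init,
                 fates = fates,
                 extinction_probability = mean(fates == "extinct"),
                 relapse_times = rel_times[fates == "relapsed"],
                 extinction_times = ext_times[fates == "extinct"],
                 survivor_count = sum(fates == "censored")),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("Stochastic ensemble (%s engine, %d replicates)\n",
              x$engine, x$n_replicates))
  cat(sprintf("  extinct: %d (probability %.3f)\n",
              sum(x$fates == "extinct"), x$extinction_probability))
  cat(sprintf("  relapsed: %d (mean relapse time %s)\n",
              length(x$relapse_times),
              if (length(x$relapse_times))
                sprintf("%.3f", mean(x$relapse_times)) else "-"))
  cat(sprintf("  censored: %d\n", x$survivor_count))
  invisible(x)
}
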