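test_that("reaction drift reproduces the two-class deterministic system", {
  p2 <- model_params(omega = 2)
  g2 <- trait_grid(p2)
  for (scheme in c("division", "moves")) {
    sp <- stochastic_params(delta = 2, m = 0.3, switching = scheme)
    rx <- build_reactions(sp)
    set <- treatment_setting(delta = 2, m = 0.3)
    for (x in random_states(100, 2, seed = 11)) {
      expect_equal(reaction_drift(rx, x), ode_rhs(x, g2, set, p2),
                   tolerance = 1e-12)
    }
  }
})

test_that("total event rate matches the daughter-switching bookkeeping", {
  sp <- stochastic_params(delta = 2, m = 0.5)
  rx <- build_reactions(sp)
  n <- c(13, 29)
  total <- sum(reaction_propensities(rx, n))
  r <- c(sp$r_slow, sp$r_fast)
  expect_equal(total, sum(r * n) + sum((sp$delta * r + sp$m) * n))
  # no switching/treatment: two independent Yule processes
  sp0 <- stochastic_params(p_S = 0, p_F = 0)
  rx0 <- build_reactions(sp0)
  a0 <- reaction_propensities(rx0, n)
  expect_equal(sum(a0), sum(r * n))
  expect_equal(diffusion_matrix(rx0, n), diag(r * n))
})

test_that("diffusion matrix equals the brute-force reaction sum", {
  for (scheme in c("division", "moves")) {
    sp <- stochastic_params(delta = 1.2, m = 0.4, switching = scheme)
    rx <- build_reactions(sp)
    for (x in random_states(20, 2, seed = 23)) {
      brute <- matrix(0, 2, 2)
      a <- reaction_propensities(rx, x)
      for (j in seq_along(a)) {
        s <- rx$stoich[j, ]
        brute <- brute + a[j] * (s %o% s)
      }
      expect_equal(diffusion_matrix(rx, x), brute, tolerance = 1e-12)
    }
  }
  # trait-dependent treatment raises diagonal entries proportionally to r_i
  x <- c(5, 5)
  d0 <- diag(diffusion_matrix(build_reactions(stochastic_params()), x))
  d2 <- diag(diffusion_matrix(build_reactions(stochastic_params(delta = 2)),
                              x))
  expect_equal(d2 - d0, 2 * c(0.25, 0.5) * x)
})

test_that("pure-death extinction times are exponential with mean 1/mu", {
  # single absorbing class embedded in the two-class state space
  mu <- 0.8
  rx <- structure(list(stoich = matrix(c(-1L, 0L), 1, 2),
                       coef = matrix(c(mu, 0), 1, 2),
                       labels = "death"),
                  class = "reaction_set")
  set.seed(99)
  times <- replicate(2000, gillespie_simulate(rx, c(1, 0), 100,
                                              times = 100)$extinction_time)
  expect_false(anyNA(times))
  se <- 1 / (mu * sqrt(2000))
  expect_lt(abs(mean(times) - 1 / mu), 3 * se)
})

test_that("linear birth-death extinction probabilities match theory", {
  # subcritical: birth 0.25 < death 0.5, extinction is certain
  sp_sub <- stochastic_params(r_slow = 0.25, r_fast = 0.5, p_S = 0, p_F = 0,
                              m = 0.5)
  rx_sub <- build_reactions(sp_sub)
  set.seed(17)
  ext <- replicate(300, !is.na(gillespie_simulate(rx_sub, c(1, 0), 80,
                                                  times = 80)$extinction_time))
  expect_gte(mean(ext), 0.98)
  # supercritical from one cell: extinction probability -> mu / lambda = 0.5
  sp_sup <- stochastic_params(r_slow = 0.5, r_fast = 1, p_S = 0, p_F = 0,
                              m = 0.25)
  rx_sup <- build_reactions(sp_sup)
  set.seed(18)
  ext2 <- replicate(1000, {
    r <- gillespie_simulate(rx_sup, c(1, 0), 60, times = 60, threshold = 400,
                            stop_at_threshold = TRUE)
    !is.na(r$extinction_time)
  })
  expect_lt(abs(mean(ext2) - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("ensemble means track the deterministic two-class solution", {
  p2 <- model_params(omega = 2)
  sp <- stochastic_params(delta = 2)
  rx <- build_reactions(sp)
  init <- c(300, 700)
  tgrid <- seq(2, 10, by = 2)
  nrep <- 400
  set.seed(42)
  acc <- array(0, c(length(tgrid), 2, nrep))
  for (i in seq_len(nrep))
    acc[, , i] <- gillespie_simulate(rx, init, 10, times = tgrid)$counts
  mn <- apply(acc, c(1, 2), mean)
  se <- apply(acc, c(1, 2), sd) / sqrt(nrep)
  det <- simulate_phase(init, trait_dependent(2), 10, p2, n_out = 6)
  expect_lt(max(abs(mn - det$x[-1, ]) / se), 3)
})

test_that("stochastic runs are reproducible from their seeds", {
  sp <- stochastic_params(delta = 2)
  a <- gillespie_simulate(sp, c(50, 100), 10, seed = 123)
  b <- gillespie_simulate(sp, c(50, 100), 10, seed = 123)
  expect_identical(a, b)
  s1 <- sde_simulate(sp, c(10, 20), 2, dt = 0.01, n_replicates = 3, seed = 5)
  s2 <- sde_simulate(sp, c(10, 20), 2, dt = 0.01, n_replicates = 3, seed = 5)
  expect_identical(s1, s2)
  e1 <- run_ensemble(sp, n_replicates = 50, seed = 9)
  e2 <- run_ensemble(sp, n_replicates = 50, seed = 9)
  expect_identical(e1$fates, e2$fates)
  expect_identical(e1$relapse_times, e2$relapse_times)
})

test_that("Langevin paths approach the deterministic solution as V grows", {
  p2 <- model_params(omega = 2)
  det <- simulate_phase(c(300, 700), trait_dependent(2), 5, p2, n_out = 2)
  devs <- vapply(c(10, 1000), function(V) {
    sp <- stochastic_params(delta = 2, V = V)
    r <- sde_simulate(sp, c(300, 700), 5, dt = 0.005, n_replicates = 60,
                      record_every = 1000, seed = 3)
    mean(abs(apply(r$x[2, , ], 1, mean) - det$x[2, ]))
  }, 0)
  expect_lt(devs[2], devs[1] / 2)
})

test_that("diffusion-only step sizes order as dep > none > indep", {
  get_ds <- function(sp) {
    r <- diffusion_only_simulate(sp, c(1, 1), t_end = 20, dt = 0.01,
                                 n_replicates = 20, record_every = 100,
                                 seed = 1)
    step_size_stats(lapply(1:20, function(i) r$x[, , i]))$delta_sigma_normalized
  }
  ds_none <- get_ds(stochastic_params(V = 25))
  ds_ind <- get_ds(stochastic_params(m = 1, V = 25))
  ds_dep <- get_ds(stochastic_params(delta = 2, V = 25))
  expect_gt(ds_none, 0)  # slow class takes smaller steps
  expect_gt(ds_dep, ds_none)
  expect_lt(ds_ind, ds_none)
})

test_that("matched two-class treatments: more extinction under
           trait-independent, later relapse under trait-dependent", {
  timing <- scenario_timing(0, 25, 50)
  m2 <- calibrate_m(model_params(omega = 2), delta = 2,
                    timing = scenario_timing(0, 25, 0))
  dep <- run_ensemble(stochastic_params(delta = 2), timing,
                      n_replicates = 400, seed = 7)
  ind <- run_ensemble(stochastic_params(m = m2), timing,
                      n_replicates = 400, seed = 7)
  expect_gt(ind$extinction_probability, dep$extinction_probability)
  expect_gt(mean(dep$relapse_times), mean(ind$relapse_times))
  # every replicate is classified
  expect_equal(sum(dep$fates == "extinct") + length(dep$relapse_times) +
                 dep$survivor_count, 400)
})
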