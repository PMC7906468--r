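test_that("mortality terms match direct substitution", {
  p <- ref_params()
  g <- trait_grid(p)
  x_fast <- c(rep(0, 24), 1)   # all mass at r_max = 0.5
  mt <- mortality_terms(x_fast, g, delta = 2, m = 0.86)
  expect_equal(mt$trait_dependent, 1.0)
  expect_equal(mt$trait_independent, 0.86)
  expect_gt(mt$trait_dependent, mt$trait_independent)

  x_slow <- c(1, rep(0, 24))   # all mass at r_min = 0.25
  ms <- mortality_terms(x_slow, g, delta = 2, m = 0.86)
  expect_equal(ms$trait_dependent, 0.5)
  expect_lt(ms$trait_dependent, ms$trait_independent)
  expect_error(mortality_terms(rep(0, 25), g, 2, 0.86), "empty")
})

test_that("mean trait is the abundance-weighted growth rate", {
  p2 <- model_params(omega = 2)
  g2 <- trait_grid(p2)
  expect_equal(mean_trait(c(1, 1), g2), 0.375)
  expect_equal(mean_trait(c(0, 3), g2), 0.5)
  # equal-mortality threshold at reference parameters
  expect_equal(0.86 / 2, 0.43)
})

test_that("treatment selection follows the mortality comparison and ties", {
  p <- ref_params()
  g <- trait_grid(p)
  eq <- ref_eq()
  # stable pre-treatment distribution: mean trait near r_max, pick dependent
  expect_identical(select_treatment(eq$x, g, 2, 0.86), "trait_dependent")
  expect_identical(select_treatment(c(1, rep(0, 24)), g, 2, 0.86),
                   "trait_independent")
  # exact tie: construct a state with mean trait m/delta, keep current
  x_tie <- c(rep(0, 12), 1, rep(0, 12))
  x_tie_m <- 2 * mean_trait(x_tie, g)  # tie by construction
  expect_identical(select_treatment(x_tie, g, 2, x_tie_m,
                                    current = "trait_dependent"),
                   "trait_dependent")
  expect_identical(select_treatment(x_tie, g, 2, x_tie_m,
                                    current = "trait_independent"),
                   "trait_independent")
})

test_that("selection is equivalent to the mean-trait threshold", {
  p <- ref_params()
  g <- trait_grid(p)
  for (x in random_states(100, 25, seed = 31)) {
    lab <- select_treatment(x, g, 2, 0.86, current = "trait_dependent")
    expect_identical(lab,
                     if (mean_trait(x, g) > 0.43) "trait_dependent"
                     else "trait_independent")
  }
})

test_that("predefined sequence enumeration is complete and ordered", {
  expect_length(enumerate_predefined(8), 256)
  two <- enumerate_predefined(1)
  expect_length(two, 2)
  expect_identical(vapply(two, `[[`, "", "id"), c("I", "D"))
  eight <- enumerate_predefined(3)
  expect_length(eight, 8)
  expect_setequal(vapply(eight, `[[`, 0, "prop_dep"),
                  c(0, 1/3, 2/3, 1))
  ids <- vapply(eight, `[[`, "", "id")
  expect_identical(anyDuplicated(ids), 0L)
  expect_identical(ids[c(1, 8)], c("III", "DDD"))  # binary order
  expect_error(enumerate_predefined(0), "between")
  expect_error(enumerate_predefined(21), "between")
})

test_that("schedule constructors validate and degenerate patterns match", {
  expect_error(treatment_schedule(c(1, 2), list(no_treatment())), "start at 0")
  expect_error(treatment_schedule(c(0, 1), list()), "one per interval")
  s <- sequence_schedule(c(1, 0, 1), t_treat = 30, delta = 2, m = 0.7)
  expect_equal(s$breakpoints, c(0, 10, 20, 30))
  expect_equal(s$settings[[2]]$m, 0.7)

  # an all-trait-dependent pattern is exactly the single-type scenario
  p <- model_params(omega = 5)
  timing <- scenario_timing(0, 20, 10)
  eq <- equilibrate(p)
  a <- run_predefined(rep(TRUE, 4), p, timing, m = 0.5, initial = eq)
  b <- simulate_scenario(p, single_type_schedule("trait_dependent",
                                                 t_treat = 20),
                         timing, initial = eq)
  bo <- scheme_outcome(b)
  expect_equal(a$outcome$min_load, bo$min_load, tolerance = 1e-9)
  expect_equal(a$outcome$relapse_time, bo$relapse_time, tolerance = 1e-7)
  ea <- a$trajectory$x[nrow(a$trajectory$x), ]
  eb <- b$x[nrow(b$x), ]
  expect_equal(ea, eb, tolerance = 1e-9)
})

test_that("adaptive scheme with dt >= T is the pure trait-dependent scheme", {
  p <- ref_params()
  eq <- ref_eq()
  m <- ref_m()
  timing <- scenario_timing()
  ad <- run_adaptive(200, p, timing, m = m, initial = eq)
  expect_length(ad$switch_times, 0)
  pure <- run_predefined(rep(TRUE, 1), p, timing, m = m, initial = eq)
  expect_equal(ad$outcome$min_load, pure$outcome$min_load, tolerance = 1e-8)
  expect_equal(ad$outcome$relapse_time, pure$outcome$relapse_time,
               tolerance = 1e-6)
})

test_that("optimal adaptive scheme pins the mean trait at m/delta", {
  p <- ref_params()
  eq <- ref_eq()
  m <- ref_m()
  res <- run_optimal_adaptive(p, scenario_timing(), m = m, initial = eq)
  g <- trait_grid(p)
  # switch condition: equal mortality terms at the sliding onset
  t1 <- res$switch_times[1]
  i1 <- which.min(abs(res$trajectory$time - t1))
  mt <- mortality_terms(res$trajectory$x[i1, ], g, 2, m)
  expect_equal(mt$trait_dependent, mt$trait_independent, tolerance = 1e-4)
  # post-transient mean trait sits on the equal-mortality manifold
  sel <- res$trajectory$time >= t1 + 5 & res$trajectory$time <= 150
  mts <- apply(res$trajectory$x[sel, ], 1, mean_trait, grid = g)
  expect_lt(max(abs(mts - m / 2)), 1e-6)
})

test_that("adaptive outcomes converge to the optimal scheme as dt shrinks", {
  p <- ref_params()
  eq <- ref_eq()
  m <- ref_m()
  timing <- scenario_timing()
  opt <- run_optimal_adaptive(p, timing, m = m, initial = eq)
  fine <- run_adaptive(5, p, timing, m = m, initial = eq)
  expect_equal(fine$outcome$min_load, opt$outcome$min_load, tolerance = 0.02)
  expect_equal(fine$outcome$relapse_time, opt$outcome$relapse_time,
               tolerance = 0.01)
  coarse <- run_adaptive(150, p, timing, m = m, initial = eq)
  pure <- run_predefined(1, p, timing, m = m, initial = eq)
  expect_equal(coarse$outcome$min_load, pure$outcome$min_load,
               tolerance = 1e-8)
})
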