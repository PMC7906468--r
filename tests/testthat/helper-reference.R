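# Reference objects shared across test files; memoized because equilibration
# and calibration are reused many times.
.ref_cache <- new.env(parent = emptyenv())

ref_params <- function() model_params()

ref_eq <- function() {
  if (is.null(.ref_cache$eq)) .ref_cache$eq <- equilibrate(ref_params())
  .ref_cache$eq
}

ref_m <- function() {
  if (is.null(.ref_cache$m))
    .ref_cache$m <- calibrate_m(ref_params(), delta = 2,
                                timing = scenario_timing(),
                                initial = ref_eq())
  .ref_cache$m
}

# random positive abundance vectors for property-style checks
random_states <- function(n, omega, seed = 101) {
  set.seed(seed)
  lapply(seq_len(n), function(i) runif(omega, min = 0, max = 10))
}
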