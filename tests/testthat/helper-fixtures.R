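# Shared fixtures, all generated in code.

# a small cohort specification with a fixed seed
small_spec <- function(n = 60, seed = 11, ...) {
  cohort_spec(n_subjects = n, seed = seed, ...)
}

# a noiseless specification: clamp traces recover S_true exactly
noiseless_spec <- function(n = 20, seed = 3) {
  cohort_spec(n_subjects = n,
              noise = list(glucose_cv = 0, gir_sd = 0, insulin_cv = 0,
                           ss_glucose_sd = 0),
              seed = seed)
}

# deterministic flat clamp trace: gir and glucose constant in the window
flat_trace <- function(id = "T1", gir = 700, glucose = 100,
                       times = seq(0, 100, 5), insulin_ss = 150) {
  ins <- rep(NA_real_, length(times))
  ins[match(c(0, 80, 90, 100), times)] <- c(5, insulin_ss, insulin_ss,
                                            insulin_ss)
  clamp_trace(id, times, rep(glucose, length(times)),
              rep(gir, length(times)), ins)
}
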