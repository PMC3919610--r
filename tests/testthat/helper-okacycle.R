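# Shared fixtures: the default 409-nt minicircle and small simulation
# configurations reused across test files. Everything is generated in code.

default_template <- make_minicircle()
default_params <- kinetic_params()

quick_sim <- function(seed = 1L, duration = 30, ...) {
  simulate_fork(sim_config(default_template, duration = duration, seed = seed, ...))
}

# Independent check of the simulator's exact bookkeeping identity:
# fragments and gaps tile [0, top of last fragment); the remainder up to the
# leading extent is exposed but not yet primed/synthesized.
expect_coverage_identity <- function(result) {
  fr <- result$fragments
  covered <- sum(fr$length) + sum(result$gaps$length)
  slack <- result$leading_extent - if (nrow(fr)) max(fr$end) else 0L
  expect_gte(slack, 0L)
  expect_identical(covered + slack, result$leading_extent)
}
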