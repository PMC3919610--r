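test_that("insertion rate opposite C follows Michaelis-Menten limits", {
  p <- default_params
  expect_identical(insertion_rate_opposite_c(0, "dGTP", p), 0)
  expect_equal(insertion_rate_opposite_c(p$Km_dGTP, "dGTP", p), p$v_sat / 2)
  expect_equal(insertion_rate_opposite_c(p$Km_dGDPNP, "dGDPNP", p),
               p$v_chem_dGDPNP / 2)
  # strictly increasing in substrate, saturating at v_max
  conc <- c(0.1, 1, 10, 100, 1000)
  r <- insertion_rate_opposite_c(conc, "dGTP", p)
  expect_true(all(diff(r) > 0))
  expect_lt(max(r), p$v_sat)
  # fork-coupled multiplier
  p2 <- suppressWarnings(kinetic_params(alpha_lag = 2))
  expect_equal(insertion_rate_opposite_c(100, "dGTP", p2, fork_coupled = TRUE),
               2 * insertion_rate_opposite_c(100, "dGTP", p2))
  expect_error(insertion_rate_opposite_c(-1, "dGTP", p), "negative")
})

test_that("composite velocity is the harmonic mixture with correct limits", {
  p <- default_params
  expect_identical(composite_velocity(0, 1e-9, p), p$v_sat)
  expect_equal(composite_velocity(1, 10, p), 10)
  expect_identical(composite_velocity(0.5, 0, p), 0)  # stalled, not an error
  # r_C at its physical maximum (v_sat) recovers v_sat; r_C -> 0 behaves
  # like r_C / f_C
  expect_equal(composite_velocity(0.3, p$v_sat, p), p$v_sat)
  expect_equal(composite_velocity(0.4, 1e-3, p), 1e-3 / 0.4, tolerance = 1e-3)
})

test_that("dGDPNP calibration reproduces the measured slowing anchors", {
  p <- default_params
  r30 <- insertion_rate_opposite_c(30, "dGDPNP", p)
  expect_equal(r30, 5.93, tolerance = 0.01)
  # anchor: 25% C template at 30 uM runs at 23 nt/s, a ~25-fold slowing
  expect_equal(composite_velocity(0.25, r30, p), 23, tolerance = 1e-9)
  expect_identical(round(p$v_sat / composite_velocity(0.25, r30, p)), 25)
  # prediction on the 45% C lagging template
  expect_equal(composite_velocity(0.45, r30, p), 13, tolerance = 0.01)
  expect_error(calibrate_dgdpnp(p, target_rate = 570), "calibration error")
  expect_error(calibrate_dgdpnp(p, target_rate = 600), "calibration error")

  # independent route: numeric root of the composite equation agrees with
  # the closed-form inversion used by the calibration
  f <- function(v) composite_velocity(0.25, v * 30 / (p$Km_dGDPNP + 30), p) - 23
  v_num <- uniroot(f, c(0.01, 570), tol = 1e-12)$root
  expect_equal(v_num, p$v_chem_dGDPNP, tolerance = 1e-6)
})

test_that("ddGMP termination probability is a competition in the pools", {
  p <- default_params
  expect_identical(ddgmp_termination_prob(0, 100, p), 0)
  expect_identical(ddgmp_termination_prob(2, 0, p), 1)
  p1 <- suppressWarnings(kinetic_params(f_sel = 1))
  expect_equal(ddgmp_termination_prob(50, 50, p1), 0.5)
  pr <- vapply(c(0.5, 1, 2, 4, 8), ddgmp_termination_prob, numeric(1),
               dGTP_conc = 100, params = p)
  expect_true(all(diff(pr) > 0))
  expect_true(all(pr >= 0 & pr < 1))
})

test_that("ddGTP selectivity calibration halves the expected fragment length", {
  p <- default_params
  f_C <- 200 / 409; spacing <- 1500
  p_dd <- ddgmp_termination_prob(4, 100, p)
  # independent oracle: brute-force expectation over the geometric number of
  # C positions survived before ddGMP incorporation, capped at the spacing
  k <- 0:200000
  run_nt <- pmin((k + 1) / f_C, spacing)
  e_len <- sum(run_nt * dgeom(k, p_dd))
  expect_equal(e_len, spacing / 2, tolerance = 0.005)
  # and the calibrated factor is monotone in the anchor: more ddGTP, shorter
  p_dd8 <- ddgmp_termination_prob(8, 100, p)
  e_len8 <- sum(pmin((k + 1) / f_C, spacing) * dgeom(k, p_dd8))
  expect_lt(e_len8, e_len)
})

test_that("release-time sampling matches the measured half-lives", {
  p <- default_params
  expect_identical(sample_release_time("signal", p, 5), rep(0, 5))
  set.seed(123)
  nick <- sample_release_time("nick", p, 1e5)
  expect_equal(median(nick), 120, tolerance = 0.02)
  expect_equal(mean(nick), 120 / log(2), tolerance = 0.02)
  # the 6-11 min range of stall release maps to the half-life bounds
  p6 <- kinetic_params(t_half_stall = 360)
  p11 <- kinetic_params(t_half_stall = 660)
  set.seed(1)
  expect_equal(median(sample_release_time("stall", p6, 1e5)) / 60, 6,
               tolerance = 0.02)
  expect_equal(median(sample_release_time("stall", p11, 1e5)) / 60, 11,
               tolerance = 0.02)
})

test_that("parameter constructor validates and warns on sub-unity alpha_lag", {
  expect_warning(kinetic_params(alpha_lag = 0.5), "alpha_lag")
  expect_error(kinetic_params(v_sat = -1))
  expect_error(kinetic_params(t_half_nick = 0))
  p <- kinetic_params(v_chem_dGDPNP = 10, f_sel = 0.1)
  expect_identical(p$v_chem_dGDPNP, 10)
  expect_identical(p$f_sel, 0.1)
})
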