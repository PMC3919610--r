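test_that("simulations are reproducible and bookkeeping is exact", {
  a <- quick_sim(seed = 5)
  b <- quick_sim(seed = 5)
  expect_identical(a$fragments, b$fragments)
  expect_identical(a$primers, b$primers)
  expect_identical(a$gaps, b$gaps)
  expect_false(identical(a$fragments, quick_sim(seed = 6)$fragments))

  # conservation identity over randomized configurations
  set.seed(2024)
  for (i in 1:30) {
    use_dgtp <- runif(1) < 0.7
    cfg <- sim_config(
      default_template,
      model = sample(c("signaling", "collision", "hybrid"), 1),
      priming_mode = sample(c("dnag", "exogenous"), 1),
      p_anneal = runif(1, 0.2, 1),
      pools = list(dGTP = if (use_dgtp) 100 else 0,
                   ddGTP = if (use_dgtp) sample(c(0, 2, 4), 1) else 0,
                   dGDPNP = if (use_dgtp) 0 else 30),
      duration = runif(1, 5, 40), seed = sample.int(1e6, 1))
    r <- simulate_fork(cfg)
    expect_coverage_identity(r)
    if (nrow(r$fragments)) {
      expect_true(all(r$fragments$end > r$fragments$start))
      # fragments never overlap
      expect_true(all(r$fragments$start >= c(0L, r$fragments$end[-nrow(r$fragments)])))
    }
  }
})

test_that("primase deposition is Poisson at the fork with composition-set G+U", {
  set.seed(31)
  pr <- deposit_primers_dnag(40000, 420, 420 / 1500, default_template, 12)
  sp <- diff(pr$top)
  expect_gt(nrow(pr), 1e4)
  expect_equal(mean(sp), 1500, tolerance = 0.05)
  expect_equal(sd(sp) / mean(sp), 1, tolerance = 0.05)  # exponential spacing
  # 12-mer RNA primers read G+U off the C+A content of the template
  expect_equal(mean(pr$gu_count), 12 * (303 / 409), tolerance = 0.02)
  expect_true(all(pr$gu_count <= pr$len))
})

test_that("exogenous priming produces a 409-nt ladder with geometric spacing", {
  set.seed(7)
  pr <- deposit_primers_exogenous(2000, 420, 0.23, default_template, 15)
  expect_true(all(diff(pr$top) %% 409 == 0))
  expect_equal(mean(diff(pr$top)), 409 / 0.23, tolerance = 0.05)
  expect_true(all(pr$gu_count == 0))
  pr1 <- deposit_primers_exogenous(100, 420, 1, default_template, 15)
  expect_true(all(diff(pr1$top) == 409))
  pr0 <- deposit_primers_exogenous(100, 420, 0, default_template, 15)
  expect_identical(nrow(pr0), 0L)
})

test_that("balanced signaling with regular priming leaves no gaps, all nicks", {
  # v_lag (~564 nt/s at 100 uM dGTP) exceeds v_lead (420), and with a primer
  # on every circle passage the polymerase finishes each fragment before the
  # next primer appears: every completed fragment ends in a nick and the
  # replicated region tiles with zero gaps.
  for (s in 1:5) {
    r <- simulate_fork(sim_config(default_template, model = "signaling",
                                  priming_mode = "exogenous", p_anneal = 1,
                                  duration = 40, seed = s))
    done <- r$fragments$terminated_by != "timeout"
    expect_true(all(r$fragments$terminated_by[done] == "nick"))
    expect_identical(sum(r$gaps$length[r$gaps$behind]), 0L)
  }
})

test_that("label accounting follows template composition", {
  r <- quick_sim(seed = 3, duration = 20)
  expect_identical(incorporation_totals(r, "lagging"), sum(r$fragments$dGMP_count))
  # leading label: one dCMP per template C over the leading extent
  ext <- r$leading_extent
  full <- ext %/% 409; part <- ext %% 409
  expect_identical(
    incorporation_totals(r, "leading"),
    full * 200L + sum(default_template$bases[seq_len(part)] == "C"))
  # a fragment spanning exactly one circle repeat carries n_C minus the
  # primer-covered C's
  fr <- r$fragments
  expect_identical(fr$dGMP_count,
                   okacycle:::count_template_c(default_template, fr$start,
                                               pmax(fr$start, fr$end - fr$primer_len)))
})

test_that("a starved analog pool stalls the polymerase into a timeout", {
  r <- simulate_fork(sim_config(default_template, pools = list(dGDPNP = 1e-4),
                                duration = 10, seed = 2))
  expect_true(nrow(r$fragments) >= 1)
  expect_true(any(r$fragments$terminated_by == "timeout"))
  expect_coverage_identity(r)
})

test_that("unused primers accumulate when deposition outpaces reinitiation", {
  p_slow <- kinetic_params(reinit_latency = 2)
  util <- vapply(1:10, function(s) {
    r <- simulate_fork(sim_config(default_template, duration = 120, seed = s,
                                  params = p_slow))
    mean(r$primers$used)
  }, numeric(1))
  expect_lt(mean(util), 1)
  expect_gt(mean(util), 0.3)
  # with instantaneous cycling every primer is used
  r0 <- quick_sim(seed = 4, duration = 120)
  expect_true(all(r0$primers$used))
})

test_that("cumulative synthesis curve matches the incorporation totals", {
  r <- quick_sim(seed = 9, duration = 30)
  expect_equal(lagging_curve(r, 30), sum(r$fragments$ext_nt), tolerance = 1e-9)
  # extension equals fragment length minus the primer footprint inside it
  expect_true(all(r$fragments$ext_nt ==
                    pmax(r$fragments$length - r$fragments$primer_len, 0)))
  expect_identical(lagging_curve(r, 0), 0)
  curve <- lagging_curve(r, seq(1, 30))
  expect_true(all(diff(curve) >= 0))
})

test_that("event export is time-ordered and round-trip readable", {
  r <- quick_sim(seed = 12, duration = 15)
  path <- withr::local_tempfile(fileext = ".tsv")
  ev <- export_events(r, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_identical(nrow(back), nrow(ev))
  expect_true(all(diff(back$time) >= 0))
})
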