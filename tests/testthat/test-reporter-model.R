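test_that("expected signals honour the reporter mechanism at the boundaries", {
  # no editing -> no read-through: Nluc 0, FFL = amplitude
  p0 <- reporter_params(e0 = 0, amplitude = 1e5)
  sig <- expected_signals(p0, compound_effect("inactive"), dose = 0)
  expect_equal(sig$nluc, 0)
  expect_equal(sig$ffl, 1e5)

  # full editing with a stable fusion -> ratio equals the brightness factor
  p1 <- reporter_params(e0 = 1, s = 1)
  sig1 <- expected_signals(p1, compound_effect("inactive"), dose = 0)
  expect_equal(sig1$ratio, p1$beta)

  # dose = 0 returns the unperturbed pair for any action
  pp <- reporter_params()
  base <- expected_signals(pp, compound_effect("inactive"), 0)
  for (act in c("editing_inhibitor", "editing_activator",
                "nluc_enzyme_inhibitor", "cytotoxic")) {
    at0 <- expected_signals(pp, compound_effect(act, ic50 = 1), 0)
    expect_equal(at0$ffl, base$ffl)
    expect_equal(at0$nluc, base$nluc)
  }
})

test_that("an editing inhibitor at its IC50 halves the editing fraction", {
  pp <- reporter_params(e0 = 0.39)
  eff <- compound_effect("editing_inhibitor", ic50 = 2, hill = 1,
                         max_effect = 1)
  sig <- expected_signals(pp, eff, dose = c(0, 2, 1e6))
  expect_equal(sig$editing_fraction[2], pp$e0 / 2)
  # ratio at IC50 lies strictly between the dose-0 and saturating ratios
  expect_true(sig$ratio[3] < sig$ratio[2] && sig$ratio[2] < sig$ratio[1])
})

test_that("channel monotonicity and selectivity by action class", {
  pp <- reporter_params()
  doses <- c(0, 0.1, 0.5, 1, 5, 10, 100)
  for (act in c("editing_inhibitor", "nluc_enzyme_inhibitor")) {
    sig <- expected_signals(pp, compound_effect(act, ic50 = 1), doses)
    expect_true(all(diff(sig$nluc) <= 1e-12), info = act)
  }
  # the Nluc enzyme inhibitor never touches FFL
  sig <- expected_signals(pp, compound_effect("nluc_enzyme_inhibitor",
                                              ic50 = 0.08), doses)
  expect_equal(sig$ffl, rep(sig$ffl[1], length(doses)))
})

test_that("the ratio is invariant to amplitude and to cytotoxic scaling", {
  eff <- compound_effect("cytotoxic", ic50 = 1)
  r1 <- expected_signals(reporter_params(amplitude = 1e4), eff, 5)$ratio
  r2 <- expected_signals(reporter_params(amplitude = 1e8), eff, 5)$ratio
  r0 <- expected_signals(reporter_params(amplitude = 1e4),
                         compound_effect("inactive"), 0)$ratio
  expect_equal(r1, r2)
  # cytotoxic action attenuates both channels, leaving the ratio unchanged
  expect_equal(r1, r0)
})

test_that("naive reporter arithmetic is linear in editing", {
  expect_equal(naive_ratio(0.01, 150), 1.5)
  expect_equal(naive_ratio(1, 150), 150)
  expect_equal(naive_ratio(0, 99), 0)
  e <- c(0.05, 0.1, 0.2, 0.4)
  expect_equal(naive_ratio(2 * e, 150), 2 * naive_ratio(e, 150))
  expect_error(naive_ratio(1.2, 150), "0, 1")
  expect_error(naive_ratio(-0.1, 150), "0, 1")
})

test_that("mechanistic and naive ratios agree up to the FFL depletion factor", {
  pp <- reporter_params(s = 1)  # stable fusion isolates the depletion term
  for (e0 in c(0.05, 0.2, 0.5)) {
    p <- reporter_params(s = 1, e0 = e0)
    mech <- expected_signals(p, compound_effect("inactive"), 0)$ratio
    expect_equal(mech, naive_ratio(e0, p$beta) / (1 - e0 + p$s * e0),
                 tolerance = 1e-12)
  }
})

test_that("editing saturates with an ADAR expression surrogate", {
  expect_equal(editing_dose_curve(0, 0.8, 1), 0)
  expect_equal(editing_dose_curve(1, 0.8, 1), 0.8 * (1 - exp(-1)),
               tolerance = 1e-12)
  expect_equal(editing_dose_curve(1e9, 0.8, 1), 0.8, tolerance = 1e-6)
  d <- seq(0, 10, by = 0.5)
  expect_true(all(diff(editing_dose_curve(d, 0.8, 0.7)) > 0))
})

test_that("parameter constructors reject invalid values", {
  expect_error(reporter_params(beta = -1), "beta")
  expect_error(reporter_params(s = 0), "s")
  expect_error(reporter_params(e0 = 1.5), "e0")
  expect_error(compound_effect("editing_inhibitor", ic50 = 0), "ic50")
  expect_error(compound_effect("teratogenic", ic50 = 1))
  expect_error(compound_effect("cytotoxic", ic50 = 1, max_effect = 2),
               "max_effect")
  expect_error(expected_signals(reporter_params(),
                                compound_effect("inactive"), -1), "dose")
})
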