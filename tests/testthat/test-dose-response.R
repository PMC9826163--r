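test_that("curves assembled from windows respond per endpoint", {
  sim <- simulate_trace("distal-default", duration = 1200, seed = 9)
  ev <- extract_features(sim$trace, detect_contractions(sim$trace))
  ref <- window_summary(sim$trace, c(0, 300), events = ev)
  # identical pre/post windows at all concentrations give a flat zero curve
  summ <- list(`1e-10` = window_summary(sim$trace, c(0, 300), c(0, 300), events = ev),
               `1e-9` = window_summary(sim$trace, c(0, 300), c(0, 300), events = ev),
               `1e-8` = window_summary(sim$trace, c(0, 300), c(0, 300), events = ev))
  crc <- crc_from_windows(summ, ref, endpoint = "tone")
  expect_s3_class(crc, "concentration_response")
  expect_equal(crc$response, c(0, 0, 0))
  expect_equal(crc$conc_M, c(1e-10, 1e-9, 1e-8))

  # per-endpoint extraction from the same summaries
  for (ep in c("amplitude", "frequency")) {
    crc_ep <- crc_from_windows(summ, ref, endpoint = ep)
    expect_identical(attr(crc_ep, "endpoint"), ep)
    expect_equal(crc_ep$response, c(0, 0, 0), tolerance = 1e-12)
  }
  # carbachol-normalised tone
  crc_pc <- crc_from_windows(summ, ref, endpoint = "tone", carbachol_max = 40)
  expect_equal(crc_pc$response, c(0, 0, 0))
  expect_error(crc_from_windows(summ[1:2], ref), ">= 3")
  expect_error(crc_from_windows(summ, NULL, endpoint = "amplitude"), "reference")
})

test_that("agonist simulation yields monotone tone responses vs concentration", {
  pd <- agonist_pd_model(tone = hill_params(3.16e-10, 4),
                         onset_tau_slow = 60, onset_tau_fast = 30)
  concs <- 10^seq(-11, -8, 1)
  resp <- vapply(concs, function(cc) {
    sch <- treatment_schedule(300, "AVP", cc, mode = "single")
    sim <- simulate_trace("proximal-default", duration = 1200, schedule = sch,
                          pd_models = list(AVP = pd), seed = 21)
    window_summary(sim$trace, c(900, 1200), c(0, 300))$tone_change_mN
  }, numeric(1))
  expect_true(all(diff(resp) > 0))
  expect_equal(resp[length(resp)], hill_response(1e-8, pd$tone), tolerance = 0.1)
})

test_that("Hill fit recovers generating parameters exactly from clean data", {
  hp <- avp_tone_params()
  crc <- simulate_crc_dataset(hp, decade_concs(), n_reps = 1, noise_cv = 0)
  f <- fit_hill(crc)
  expect_true(f$converged)
  expect_equal(f$pEC50, -log10(3.16e-10), tolerance = 1e-6)
  expect_equal(f$Emax, 7.1, tolerance = 1e-6)
  expect_equal(f$hill_slope, 1, tolerance = 1e-5)

  # all-zero responses cannot be fitted
  zero <- concentration_response(decade_concs(), rep(0, 8))
  expect_false(fit_hill(zero)$converged)
  expect_error(fit_hill(concentration_response(c(1e-9, 1e-8, 1e-7), c(0, 1, 2))),
               ">= 4")
})

test_that("Hill fit is deterministic and reparameterization-equivariant", {
  hp <- avp_tone_params()
  crc <- simulate_crc_dataset(hp, decade_concs(), n_reps = 5, noise_cv = 0.05,
                              seed = 31)
  f1 <- fit_hill(crc)
  f2 <- fit_hill(crc)
  expect_identical(f1$pEC50, f2$pEC50)
  expect_identical(f1$Emax, f2$Emax)

  # multiplying all concentrations by k shifts pEC50 by exactly -log10(k)
  for (k in c(10, 1000)) {
    crc_k <- crc
    crc_k$conc_M <- crc$conc_M * k
    fk <- fit_hill(crc_k)
    expect_equal(fk$pEC50, f1$pEC50 - log10(k), tolerance = 1e-4)
    expect_equal(fk$Emax, f1$Emax, tolerance = 1e-4)
  }
})

test_that("fitted pEC50 is accurate over many noisy replicate datasets", {
  hp <- avp_tone_params()
  err <- vapply(1:100, function(s) {
    crc <- simulate_crc_dataset(hp, decade_concs(), n_reps = 5, noise_cv = 0.05,
                                seed = s)
    fit_hill(crc)$pEC50 - (-log10(3.16e-10))
  }, numeric(1))
  expect_lte(stats::median(abs(err)), 0.1)
})

test_that("biphasic curves are fitted on the declared ascending limb", {
  bm <- biphasic_model(hill_params(1e-9, 5), hill_params(3e-6, -12))
  concs <- 10^seq(-11, -4, 1)
  resp <- biphasic_tone_effect(concs, bm)
  crc <- concentration_response(concs, resp)
  expect_warning(f <- fit_hill(crc, ascending_limb_only = TRUE), "ascending")
  expect_true(f$converged)
  expect_equal(f$pEC50, 9, tolerance = 0.25)
})

test_that("threshold concentration brackets the first criterion crossing", {
  crc <- concentration_response(10^seq(-12, -8, 1), c(0, 0, 0.5, 2, 5))
  th <- threshold_concentration(crc, 0.4)
  expect_equal(th$lower, 1e-11)
  expect_equal(th$upper, 1e-10)
  expect_identical(th$status, "within range")
  expect_false(th$ambiguous)

  all_above <- concentration_response(10^seq(-12, -9, 1), c(1, 2, 3, 4))
  expect_identical(threshold_concentration(all_above, 0.4)$status, "below range")
  all_below <- concentration_response(10^seq(-12, -9, 1), c(0, 0, 0, 0.1))
  expect_identical(threshold_concentration(all_below, 0.4)$status, "above range")
  wiggly <- concentration_response(10^seq(-12, -8, 1), c(0, 1, 0.1, 2, 5))
  expect_true(threshold_concentration(wiggly, 0.4)$ambiguous)
})

test_that("AVP-like thresholds fall in the sub-nanomolar decade", {
  hp <- avp_tone_params()
  crc <- simulate_crc_dataset(hp, decade_concs(), n_reps = 5, noise_cv = 0.05,
                              seed = 8)
  # criterion: twice the response SD at the lowest (vehicle-like) concentration
  crit <- 2 * stats::sd(crc$response[crc$conc_M == min(crc$conc_M)])
  th <- threshold_concentration(crc, max(crit, 0.2))
  expect_true(th$upper <= 1e-9)
  expect_true(th$lower >= 1e-12)
})

test_that("EC75 inversion matches the Hill closed form", {
  hp <- hill_params(1e-9, 10, 1)
  ec75 <- ec_fraction(hp, 0.75)
  expect_equal(hill_response(ec75, hp), 7.5, tolerance = 1e-9)
  expect_equal(ec75, 3e-9)
  hp2 <- hill_params(1e-9, 10, 2)
  expect_equal(hill_response(ec_fraction(hp2, 0.75), hp2), 7.5, tolerance = 1e-9)
})
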