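test_that("contraction kernel realizes the raised-cosine geometry", {
  sh <- contraction_shape(amplitude_C = 5, time_to_peak_E = 4.3,
                          decay_time_F = 17.2, inter_onset_interval = 22.2)
  expect_equal(contraction_kernel(4.3, sh), 5)      # peak exactly C at t = E
  expect_equal(contraction_kernel(0, sh), 0)
  expect_equal(contraction_kernel(4.3 + 17.2, sh), 0)
  expect_equal(contraction_kernel(c(-1, 100), sh), c(0, 0))
  # continuity at the peak junction
  expect_equal(contraction_kernel(4.3 - 1e-9, sh), contraction_kernel(4.3 + 1e-9, sh),
               tolerance = 1e-6)

  # area oracle: trapezoid quadrature at 1 ms resolution vs closed form
  tt <- seq(0, 4.3, by = 0.001)
  y <- contraction_kernel(tt, sh)
  dev_area <- sum((y[-1] + y[-length(y)]) / 2) * 0.001
  expect_equal(dev_area, 5 * 4.3 / 2, tolerance = 1e-6)
  tt <- seq(0, 4.3 + 17.2, by = 0.001)
  y <- contraction_kernel(tt, sh)
  total <- sum((y[-1] + y[-length(y)]) / 2) * 0.001
  expect_equal(total, 5 * (4.3 + 17.2) / 2, tolerance = 1e-6)
})

test_that("trace simulation matches counting oracle and determinism contract", {
  sim <- simulate_trace("distal-default", duration = 1200,
                        noise = noise_params(0))
  # floor(1200 / 22.2) complete events
  expect_length(sim$truth$event_onsets, 54)
  expect_true(all(diff(sim$truth$event_onsets) > 0))

  # amplitude 0 leaves a flat trace at baseline + drift
  flat <- simulate_trace(contraction_shape(0, 5, 5, 20, 20),
                         duration = 300, noise = noise_params(0, drift_rate = 0.6))
  expect_equal(flat$trace$force, 20 + 0.01 * flat$trace$time, tolerance = 1e-12)

  # identical seeds are bitwise identical; different seeds differ
  a <- simulate_trace("proximal-default", duration = 300, seed = 1)
  b <- simulate_trace("proximal-default", duration = 300, seed = 1)
  c <- simulate_trace("proximal-default", duration = 300, seed = 2)
  expect_identical(a$trace$force, b$trace$force)
  expect_false(identical(a$trace$force, c$trace$force))
})

test_that("halving the inter-onset interval doubles events per window", {
  sh1 <- contraction_shape(1, 2, 4, 20, 20)
  sh2 <- contraction_shape(1, 2, 4, 10, 20)
  s1 <- simulate_trace(sh1, duration = 400, noise = noise_params(0))
  s2 <- simulate_trace(sh2, duration = 400, noise = noise_params(0))
  w <- c(0, 200)  # window a multiple of both intervals
  n1 <- sum(s1$truth$event_onsets >= w[1] & s1$truth$event_onsets < w[2])
  n2 <- sum(s2$truth$event_onsets >= w[1] & s2$truth$event_onsets < w[2])
  expect_identical(n2, 2L * n1)
})

test_that("frequency scaling that would overlap rising phases is rejected", {
  sh <- contraction_shape(1, 10, 5, 12, 20)
  fast <- agonist_pd_model(tone = hill_params(1e-9, 0),
                           frequency_scale = hill_params(1e-12, 0.5))
  sch <- treatment_schedule(0, "X", 1e-6, mode = "single")
  expect_error(
    simulate_trace(sh, duration = 300, noise = noise_params(0),
                   schedule = sch, pd_models = list(X = fast)),
    "overlap")
})

test_that("agonist envelopes approach Hill targets and fade when transient", {
  pd <- agonist_pd_model(tone = hill_params(1e-9, 5),
                         onset_tau_slow = 60, onset_tau_fast = 60,
                         transient_threshold = 1e-7,
                         transient_half_life = 120)
  sch <- treatment_schedule(100, "AVP", 1e-6, mode = "single")
  sim <- simulate_trace(contraction_shape(0, 5, 5, 30, 20), duration = 1200,
                        noise = noise_params(0), schedule = sch,
                        pd_models = list(AVP = pd))
  tone <- sim$truth$tone
  t <- sim$trace$time
  target <- hill_response(1e-6, pd$tone)
  # first-order rise against a fading target peaks near
  # T*(exp(-l*t*) - exp(-t*/tau))/(1 - l*tau), about 0.69*T here
  expect_gt(max(tone) - 20, 0.5 * target)
  expect_lt(max(tone) - 20, target)
  # sub-threshold concentration holds its plateau (no fade)
  sch2 <- treatment_schedule(100, "AVP", 1e-9, mode = "single")
  sim2 <- simulate_trace(contraction_shape(0, 5, 5, 30, 20), duration = 1200,
                         noise = noise_params(0), schedule = sch2,
                         pd_models = list(AVP = pd))
  late2 <- sim2$truth$tone[t > 1100]
  expect_equal(mean(late2) - 20, hill_response(1e-9, pd$tone), tolerance = 0.01)
  # supra-threshold response is shorter-lived: well below its peak at the end
  late <- tone[t > 1100]
  expect_lt(mean(late) - 20, 0.25 * (max(tone) - 20))
})

test_that("simulated concentration-response data follow the shifted Hill form", {
  hp <- avp_tone_params()
  concs <- decade_concs()
  noiseless <- simulate_crc_dataset(hp, concs, n_reps = 1, noise_cv = 0)
  expect_equal(noiseless$response, hill_response(concs, hp))

  # with B = KB every response equals the control response at conc/2
  anta <- list(conc = 3.16e-10, model = antagonist_model(3.16e-10))
  shifted <- simulate_crc_dataset(hp, concs, n_reps = 1, noise_cv = 0,
                                  antagonist = anta)
  ctrl_at_half <- hill_response(concs / 2, hp)
  expect_equal(shifted$response, ctrl_at_half, tolerance = 1e-12)

  # reproducible under seed
  d1 <- simulate_crc_dataset(hp, concs, 5, 0.05, seed = 11)
  d2 <- simulate_crc_dataset(hp, concs, 5, 0.05, seed = 11)
  expect_identical(d1$response, d2$response)
  expect_error(simulate_crc_dataset(hp, numeric(0)), "empty")
})

test_that("EFS simulation evokes one scaled contraction per train", {
  efs <- efs_schedule()
  sim <- simulate_efs_trace(efs, 1, duration = 600, noise = noise_params(0))
  expect_length(sim$truth$train_starts, 10)  # 600 s at one train per minute
  expect_true(all(sim$truth$evoked_amplitude == 10))

  # abolition after t0 (TTX/atropine-like): no evoked force afterwards
  mult <- data.frame(time_s = c(0, 300), multiplier = c(1, 0))
  sim0 <- simulate_efs_trace(efs, mult, duration = 600, noise = noise_params(0))
  post <- sim0$trace$time >= 300
  expect_equal(max(abs(sim0$trace$force[post] - 20)), 0)
  expect_error(efs_schedule(train_duration = 60, train_period = 60), "train_duration")
})
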