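test_that("baseline estimator tracks flat traces, kernels and drift", {
  fs <- 10
  t <- (0:5999) / fs
  flat <- force_trace(t, rep(20, length(t)), fs = fs)
  expect_equal(estimate_baseline(flat), rep(20, length(t)))

  # a single contraction barely perturbs the local baseline under it
  tr <- single_kernel_trace(duration = 600, onset = 300)
  b <- estimate_baseline(tr)
  expect_lt(max(abs(b - 20)), 0.05)

  # pure drift at 0.1 mN/min is tracked within 0.05 mN
  drift <- force_trace(t, 20 + 0.1 * t / 60, fs = fs)
  bd <- estimate_baseline(drift)
  core <- t > 60 & t < max(t) - 60
  expect_lt(max(abs(bd[core] - (20 + 0.1 * t[core] / 60))), 0.05)

  # baseline is a lower envelope on noisy data
  set.seed(1)
  noisy <- force_trace(t, 20 + rnorm(length(t), 0, 0.1), fs = fs)
  bn <- estimate_baseline(noisy)
  expect_gte(mean(bn <= noisy$force), 0.9)
  expect_error(estimate_baseline(force_trace(0:9 / 10, rnorm(10, 20))),
               "shorter than the trace")

  # rolling-percentile core agrees with an independent rolling apply
  x <- noisy$force[1:500]
  w <- 101
  ours <- estimate_baseline(force_trace((1:500) / 10, x, fs = 10),
                            detection_config(baseline_window = 10.1,
                                             smooth_window = 0.1))
  ref <- zoo::rollapply(zoo::zoo(x), width = w,
                        function(v) quantile(v, 0.08, names = FALSE),
                        partial = TRUE, align = "center")
  smooth_ref <- as.numeric(stats::filter(ref, rep(1 / 101, 101), sides = 2))
  mid <- 150:350
  expect_equal(ours[mid], smooth_ref[mid], tolerance = 1e-6)
})

test_that("detection is exact on noise-free synthetic traces", {
  for (nm in c("proximal-default", "distal-default")) {
    sim <- simulate_trace(nm, duration = 1200, noise = noise_params(0))
    ev <- detect_contractions(sim$trace)
    expect_identical(nrow(ev), length(sim$truth$event_onsets))
    expect_lt(max(abs(ev$onset_s - sim$truth$event_onsets)), 0.1 + 1e-9)
    expect_true(all(diff(ev$peak_s) > 0))
    expect_true(all(ev$onset_s < ev$peak_s & ev$peak_s < ev$offset_s))
  }
  flat <- force_trace((0:5999) / 10, rep(20, 6000), fs = 10)
  expect_identical(nrow(detect_contractions(flat)), 0L)
})

test_that("sub-threshold noise rarely produces false positives", {
  fp <- vapply(1:100, function(s) {
    tr <- with(list(t = (0:2999) / 10), {
      set.seed(s)
      force_trace(t, 20 + rnorm(length(t), 0, 0.03), fs = 10)
    })
    nrow(detect_contractions(tr))
  }, numeric(1))
  expect_gte(mean(fp == 0), 0.99)
})

test_that("features reproduce closed-form values on noise-free kernels", {
  sim <- simulate_trace("proximal-default", duration = 1200,
                        noise = noise_params(0))
  fe <- extract_features(sim$trace, detect_contractions(sim$trace))
  expect_equal(mean(fe$C_mN), 1.1, tolerance = 0.01)
  expect_equal(mean(fe$D_s), 23.5, tolerance = 0.01)
  expect_equal(mean(fe$rate_dev), 1.1 / 11.75, tolerance = 0.02)
  expect_equal(mean(fe$rate_decay), 1.1 / 11.75, tolerance = 0.02)
  # development area approaches the closed-form raised-cosine area C*E/2
  expect_equal(mean(fe$G), 1.1 * 11.75 / 2, tolerance = 0.02)

  simd <- simulate_trace("distal-default", duration = 1200,
                         noise = noise_params(0))
  fed <- extract_features(simd$trace, detect_contractions(simd$trace))
  expect_equal(mean(fed$D_s), 21.5, tolerance = 0.01)
  # distal contractions rise several-fold faster than they decay
  expect_gt(mean(fed$F_s) / mean(fed$E_s), 3)
  expect_gt(mean(fed$rate_dev) / mean(fed$rate_decay), 3)

  # symmetric isolated kernel: development and decay areas agree
  tr <- single_kernel_trace(contraction_shape(2, 8, 8, 60, 20),
                            duration = 120, onset = 50)
  ev <- detect_contractions(tr)
  expect_identical(nrow(ev), 1L)
  fe1 <- extract_features(tr, ev)
  expect_equal(fe1$G, fe1$H, tolerance = 1e-6)
  expect_equal(fe1$C_mN, 2, tolerance = 0.01)
  expect_error(extract_features(tr, data.frame(onset_s = 1, peak_s = 1,
                                               offset_s = 2)),
               "degenerate")
})

test_that("feature identities hold on every detected event", {
  sim <- simulate_trace("distal-default", duration = 1200, seed = 5)
  fe <- extract_features(sim$trace, detect_contractions(sim$trace))
  expect_gt(nrow(fe), 0)
  expect_equal(fe$D_s, fe$E_s + fe$F_s)
  expect_equal(fe$AUC_total, fe$G + fe$H)
  expect_equal(fe$rate_dev, fe$C_mN / fe$E_s)
  expect_equal(fe$rate_decay, fe$C_mN / fe$F_s)
})

test_that("amplitude estimate is unbiased within 2% on noisy distal traces", {
  amps <- vapply(1:10, function(s) {
    sim <- simulate_trace("distal-default", duration = 1200, seed = s)
    fe <- extract_features(sim$trace, detect_contractions(sim$trace))
    mean(fe$C_mN)
  }, numeric(1))
  expect_lt(abs(mean(amps) - 5.0) / 5.0, 0.02)
})

test_that("frequency is invariant to sub-threshold baseline drift", {
  sim0 <- simulate_trace("distal-default", duration = 1200,
                         noise = noise_params(0))
  simd <- simulate_trace("distal-default", duration = 1200,
                         noise = noise_params(0, drift_rate = 0.1))
  n0 <- nrow(detect_contractions(sim0$trace))
  nd <- nrow(detect_contractions(simd$trace))
  expect_identical(n0, nd)
})

test_that("window summaries report tone change A and frequency", {
  sim <- simulate_trace("proximal-default", duration = 1200, seed = 2)
  ev <- extract_features(sim$trace, detect_contractions(sim$trace))
  ws <- window_summary(sim$trace, c(300, 600), c(300, 600), events = ev)
  expect_equal(ws$tone_change_mN, 0)        # window vs itself
  expect_equal(ws$frequency_cpm, ws$n_events / 5)
  expect_false(ws$short_window)

  # 13 complete events in 300 s is 2.6 c.p.m. by definition
  expect_equal(window_summary(sim$trace, c(0, 300), events = ev)$n_events / 5,
               window_summary(sim$trace, c(0, 300), events = ev)$frequency_cpm)

  # simulated tone step recovered as A within noise
  pd <- list(step = agonist_pd_model(tone = hill_params(1e-12, 2),
                                     onset_tau_slow = 30, onset_tau_fast = 30))
  sch <- treatment_schedule(600, "step", 1e-6, mode = "single")
  sim2 <- simulate_trace("distal-default", duration = 1200, schedule = sch,
                         pd_models = pd, seed = 3)
  ws2 <- window_summary(sim2$trace, c(900, 1200), c(300, 600))
  expect_equal(ws2$tone_change_mN, 2, tolerance = 0.05)

  expect_error(window_summary(sim$trace, c(600, 900), c(900, 1200)),
               "reference")
  expect_error(window_summary(sim$trace, c(1100, 1300)), "within the trace")
  expect_true(window_summary(sim$trace, c(300, 310), c(300, 310),
                             events = ev)$short_window)
})

test_that("carbachol normalization is a plain percentage", {
  expect_equal(percent_of_carbachol(40, 40), 100)
  expect_equal(percent_of_carbachol(2, 40), 5)
  expect_equal(percent_of_carbachol(0, 17), 0)
  expect_equal(percent_of_carbachol(-1.6, 40), -4)
  expect_error(percent_of_carbachol(2, 0), "carbachol_max")
})

test_that("EFS-evoked amplitudes and percent changes are recovered", {
  efs <- efs_schedule()
  sim <- simulate_efs_trace(efs, 1, duration = 600, noise = noise_params(0))
  r <- efs_responses(sim$trace, efs, c(0, 600))
  expect_equal(r$percent_change, rep(0, 10), tolerance = 1e-9)

  # halving the evoked amplitude reads out as -50% within 2%
  mult <- data.frame(time_s = c(0, 300), multiplier = c(1, 0.5))
  sim2 <- simulate_efs_trace(efs, mult, duration = 600,
                             noise = noise_params(0.05), seed = 4)
  r2 <- efs_responses(sim2$trace, efs, c(0, 300))
  post <- r2$train_start_s >= 300
  expect_equal(mean(r2$percent_change[post]), -50, tolerance = 0.04)
  expect_lt(max(abs(r2$percent_change[!post])), 2)
  expect_error(efs_responses(sim2$trace, efs, c(601, 700)), "pre-drug")
})
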