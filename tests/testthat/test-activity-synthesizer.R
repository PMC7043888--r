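test_that("rate profiles have the planted temporal structure", {
  pop_f <- population_params(condition = "familiar")
  pop_n <- population_params(condition = "novel")

  set.seed(1)
  zero <- make_rate_profile("excitatory", "novel",
                            population_params(exc_amplitude_scale = 0))
  expect_true(all(rate_profile_eval(zero, seq(0, 0.74, 0.01), 0) == 0))

  set.seed(2)
  vf <- make_rate_profile("vip", "familiar", pop_f)
  expect_identical(vf$type, "suppressed_ramping")
  expect_identical(vf$omission_rule, "continue_ramp")
  # pre-stimulus ramp: rate just before the next onset exceeds rate 400 ms
  # earlier (times measured from the previous onset)
  expect_gt(rate_profile_eval(vf, 0.749, 0),
            rate_profile_eval(vf, 0.349, 0))
  # monotone non-decreasing across the inter-stimulus interval
  ts <- seq(0.3, 0.749, by = 0.01)
  r <- rate_profile_eval(vf, ts, 0)
  expect_true(all(diff(r) >= -1e-12))
  # suppression after onset
  expect_lt(rate_profile_eval(vf, 0.1, 0), rate_profile_eval(vf, 0, 0))
  # omission: ramp keeps growing past the expected onset
  expect_gt(rate_profile_eval(vf, 1.0, 0), rate_profile_eval(vf, 0.749, 0))

  set.seed(3)
  vn <- make_rate_profile("vip", "novel", pop_n)
  expect_identical(vn$type, "transient")
  expect_identical(rate_profile_eval(vn, 1.0, 0), 0)  # silent in the gap
})

test_that("realized event counts match the analytic rate integral", {
  # constant stimulus drive: one cell, many identical cycles
  set.seed(4)
  prof <- make_rate_profile("excitatory", "novel",
                            population_params(noise_event_rate = 0),
                            preferred_image = 0)
  fr <- 30
  t_cycle <- (0:22) / fr                 # frames of one 0.75 s cycle
  rates <- rate_profile_eval(prof, t_cycle, 0)
  expected_per_cycle <- sum(rates) / fr  # frame-quantized rate integral
  n_cycles <- 10000
  set.seed(5)
  counts <- stats::rpois(n_cycles * length(t_cycle),
                         rep(rates, n_cycles) / fr)
  realized <- sum(counts) / n_cycles
  se <- sqrt(expected_per_cycle / n_cycles)
  expect_equal(realized, expected_per_cycle, tolerance = 4 * se)
})

test_that("synthetic traces recover the planted image preferences", {
  s <- simulate_session(short_task(420), quiet_agent(), seed = 11)
  pop <- population_params(n_excitatory = 40, n_vip = 0)
  tr <- generate_event_traces(s$stimuli, pop, seed = 12)
  expect_true(all(tr$magnitudes >= 0))
  frm <- flash_responses(tr, s$stimuli)
  est <- preferred_image(frm)
  expect_gte(mean(est == tr$cells$preferred_image), 0.95)

  # determinism under a fixed seed
  tr2 <- generate_event_traces(s$stimuli, pop, seed = 12)
  expect_identical(tr$magnitudes, tr2$magnitudes)
  expect_identical(tr$cells, tr2$cells)

  # silent configuration yields all-zero traces
  pop0 <- population_params(n_excitatory = 3, n_vip = 2,
                            exc_amplitude_scale = 0,
                            vip_amplitude_scale = 0, noise_event_rate = 0)
  tr0 <- generate_event_traces(s$stimuli, pop0, seed = 13)
  expect_true(all(tr0$magnitudes == 0))
})

test_that("familiar-mode VIP activity is higher after omitted than shown flashes", {
  s <- simulate_session(short_task(600), quiet_agent(), seed = 14)
  pop <- population_params(n_excitatory = 0, n_vip = 20,
                           condition = "familiar",
                           vip_mode_fractions = c(driven = 0,
                                                  suppressed_ramping = 1))
  tr <- generate_event_traces(s$stimuli, pop, seed = 15)
  st <- s$stimuli
  win_mean <- function(onsets) {
    mean(vapply(onsets, function(on) {
      sel <- tr$frame_times > on & tr$frame_times <= on + 0.75
      mean(tr$magnitudes[, sel])
    }, numeric(1)))
  }
  after_omitted <- win_mean(st$onset[st$is_omitted])
  after_shown <- win_mean(st$onset[!st$is_omitted & !st$is_change])
  expect_gt(after_omitted, after_shown)
})

test_that("the fluorescence forward model inverts exactly", {
  # no events, no noise: corrected trace is constant at F0, dF/F is 0
  quiet <- fake_traces(matrix(0, 2, 400))
  fp0 <- render_fluorescence(quiet, r = 0.7, F0 = 100, seed = 16)
  fc0 <- subtract_neuropil(fp0$FM[1, ], fp0$FN[1, ], 0.7)
  expect_equal(fc0, rep(100, 400), tolerance = 1e-12)
  dff <- compute_dff(fc0, frame_rate = 30, baseline_window = 5)
  expect_equal(max(abs(dff)), 0, tolerance = 1e-3)

  # single event of magnitude m peaks at m * gain and decays as exp(-t/tau)
  mags <- matrix(0, 1, 300); mags[1, 100] <- 0.5
  fp <- render_fluorescence(fake_traces(mags), kernel_tau = 0.7, r = 0.5,
                            F0 = 100, event_gain = 100, seed = 17)
  fc <- fp$FC_true[1, ] - 100
  expect_equal(fc[100], 50)
  k <- 0:30
  expect_equal(fc[100 + k], 50 * exp(-k / 30 / 0.7), tolerance = 1e-9)
  expect_true(all(fc[1:99] == 0))

  # algebraic inverse recovers the true trace to machine precision
  rec <- subtract_neuropil(fp$FM[1, ], fp$FN[1, ], fp$r)
  expect_equal(rec, fp$FC_true[1, ], tolerance = 1e-12)
})

test_that("render -> subtract -> dF/F recovers the transient amplitude", {
  mags <- matrix(0, 1, 2000)
  mags[1, c(700, 1400)] <- 0.4
  fp <- render_fluorescence(fake_traces(mags), kernel_tau = 0.7, r = 0.7,
                            F0 = 100, event_gain = 100, seed = 18)
  fc <- subtract_neuropil(fp$FM[1, ], fp$FN[1, ], fp$r)
  dff <- compute_dff(fc, frame_rate = 30, baseline_window = 20)
  # transient of 40 units over F0 = 100 -> peak dF/F of 0.4
  expect_equal(max(dff), 0.4, tolerance = 0.02)
})
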