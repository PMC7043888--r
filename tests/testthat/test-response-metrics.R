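test_that("windowed flash responses equal a direct frame-average oracle", {
  s <- simulate_session(short_task(120), quiet_agent(), seed = 50)
  set.seed(51)
  tr <- fake_traces(matrix(stats::runif(2 * 4801), 2))
  frm <- flash_responses(tr, s$stimuli)
  # exhaustive frame-enumeration oracle
  for (ci in 1:2) {
    for (pi in sample(nrow(frm$presentations), 25)) {
      p <- frm$presentations[pi, ]
      w <- if (p$is_omitted) 0.75 else 0.5
      sel <- tr$frame_times >= p$onset & tr$frame_times < p$onset + w
      expect_equal(frm$response[ci, pi], mean(tr$magnitudes[ci, sel]))
    }
  }
  # all-zero traces give all-zero responses
  z <- flash_responses(fake_traces(matrix(0, 1, 4801)), s$stimuli)
  expect_true(all(z$response == 0))

  # events at onset + 0.6 s fall outside the 500 ms stimulus window
  on1 <- s$stimuli$onset[1]
  mags <- matrix(0, 1, 4801)
  mags[1, which.min(abs(tr$frame_times - (on1 + 0.6)))] <- 5
  r <- flash_responses(fake_traces(mags), s$stimuli[1, ])
  expect_equal(r$response[1, 1], 0)
})

test_that("preferred image is the brute-force argmax with low-index ties", {
  pres <- data.frame(image_id = rep(0:7, each = 30), is_omitted = FALSE,
                     onset = 0, is_change = FALSE)
  set.seed(52)
  resp <- matrix(stats::runif(1000 * nrow(pres)), 1000)
  frm <- structure(list(response = resp, presentations = pres),
                   class = "flash_response_matrix")
  got <- preferred_image(frm)
  oracle <- apply(resp, 1, function(v) {
    means <- tapply(v, pres$image_id, mean)
    as.integer(names(means))[which.max(means)]
  })
  expect_identical(got, oracle)
  # all-zero cell: image 0 by the tie rule
  z <- structure(list(response = matrix(0, 1, nrow(pres)),
                      presentations = pres),
                 class = "flash_response_matrix")
  expect_identical(preferred_image(z), 0L)
})

test_that("responsiveness classifier handles degenerate and separable cells", {
  # all-zero cell: ties count against significance, never responsive
  set.seed(53)
  z <- classify_responsiveness(rep(0, 20), rep(0, 50), n_resamples = 1000)
  expect_true(all(z$p_values == 1))
  expect_false(z$responsive)

  # 30% of targets strictly above the null maximum: responsive at 25%
  tgt <- c(rep(100, 6), rep(0, 14))
  nul <- stats::runif(50, 0, 1)
  r <- classify_responsiveness(tgt, nul, n_resamples = 1000,
                               presentation_frac = 0.25)
  expect_true(r$responsive)
  expect_equal(sum(r$p_values == 0), 6)

  # p-values agree with a direct resampling comparison
  set.seed(54)
  tgt2 <- stats::rnorm(10)
  nul2 <- stats::rnorm(200)
  set.seed(99)
  r2 <- classify_responsiveness(tgt2, nul2, n_resamples = 500)
  set.seed(99)
  draws <- sample(nul2, 500, replace = TRUE)
  p_oracle <- vapply(tgt2, function(t) mean(draws >= t), numeric(1))
  expect_equal(r2$p_values, p_oracle)

  expect_error(classify_responsiveness(1:3, numeric(0)), "empty null")
})

test_that("lifetime sparseness matches the closed-form definition", {
  expect_equal(lifetime_sparseness(c(1, rep(0, 7))), 1)
  expect_equal(lifetime_sparseness(rep(0.3, 8)), 0)
  expect_equal(lifetime_sparseness(c(1, 1, rep(0, 6))), 0.857,
               tolerance = 0.001)
  expect_true(is.na(lifetime_sparseness(rep(0, 8))))
  expect_error(lifetime_sparseness(c(-1, 1)), "non-negative")
  # bounds on random non-negative tuning vectors
  set.seed(55)
  S <- replicate(2000, lifetime_sparseness(stats::rexp(8)))
  expect_true(all(S >= 0 & S <= 1))
})

test_that("population tuning curves average rank-sorted cell tunings", {
  pres <- data.frame(image_id = rep(0:3, each = 10), is_omitted = FALSE)
  r1 <- rep(c(0.1, 0.5, 0.2, 0.4), each = 10)
  r2 <- rep(c(0.6, 0.0, 0.3, 0.3), each = 10)
  frm <- structure(list(response = rbind(r1, r2), presentations = pres),
                   class = "flash_response_matrix")
  one <- population_tuning_curve(frm, 1, min_cells = 1)
  expect_equal(one, c(0.5, 0.4, 0.2, 0.1))
  two <- population_tuning_curve(frm, 1:2, min_cells = 1)
  expect_equal(two, (c(0.5, 0.4, 0.2, 0.1) + c(0.6, 0.3, 0.3, 0.0)) / 2)
  expect_true(all(diff(two) <= 0))    # non-increasing by construction
  expect_null(population_tuning_curve(frm, 1:2, min_cells = 10))
})

test_that("time to peak is restricted to the post-onset window", {
  # planted peak 100 ms after onset
  avg <- fake_avg(exp(-((seq(-0.4, 0.49, by = 1 / 30) - 0.1) / 0.05)^2),
                  t0 = -0.4)
  expect_equal(time_to_peak(avg), 0.1, tolerance = 1 / 30)
  # global max at 0.6 s is outside the 500 ms window; local max at 0.2 wins
  t <- seq(-0.4, 0.74, by = 1 / 30)
  v <- exp(-((t - 0.2) / 0.04)^2) + 3 * exp(-((t - 0.6) / 0.04)^2)
  avg2 <- fake_avg(v, t0 = -0.4)
  expect_equal(time_to_peak(avg2), 0.2, tolerance = 1 / 30)
  # brute-force scan oracle on random traces
  set.seed(56)
  vr <- matrix(stats::runif(5 * length(t)), 5)
  avg3 <- fake_avg(vr, t0 = -0.4)
  sel <- which(t >= 0 & t < 0.5 - 1e-9)
  oracle <- t[sel][apply(vr[, sel], 1, which.max)]
  expect_equal(time_to_peak(avg3), oracle)
})

test_that("ramp index is a signed log-ratio of late to early activity", {
  expect_equal(ramp_index(rep(3, 12), n_sub = 4), 0)
  expect_equal(ramp_index(c(1, 1, 1, 1, 2, 2, 2, 2), n_sub = 4), 1,
               tolerance = 0.01)
  # increasing trace: positive; decreasing: negative
  up <- seq(0.1, 1, length.out = 12)
  expect_gt(ramp_index(up, n_sub = 4), 0)
  expect_lt(ramp_index(rev(up), n_sub = 4), 0)
  # antisymmetry under time reversal (values well above eps)
  expect_equal(ramp_index(up, n_sub = 4), -ramp_index(rev(up), n_sub = 4))
})

test_that("ramp windows and dynamics classes follow the conventions", {
  t <- seq(-0.4, 0.49, by = 1 / 30)
  ramp_up <- pmax(0, t + 0.4) * (t < 0) + pmax(0, 0.4 - 3 * t) * (t >= 0)
  flat_then_bump <- 0.02 + 0.5 * exp(-((t - 0.15) / 0.05)^2)
  avg <- fake_avg(rbind(ramp_up, flat_then_bump), t0 = -0.4)
  ri <- ramp_indices(avg)
  expect_gt(ri$pre_stimulus_ramp_index[1], 0)   # pre-stimulus ramping cell
  expect_lt(ri$stimulus_ramp_index[1], 0)       # suppressed after onset
  expect_identical(ri$dynamics_class[1], "stimulus_suppressed")
  expect_gt(ri$stimulus_ramp_index[2], 0)       # stimulus-driven cell
  expect_identical(ri$dynamics_class[2], "stimulus_driven")
})

test_that("index correlation matches the textbook Pearson formula", {
  x <- c(1, 2, 3, 4)
  expect_equal(index_correlation(x, x)$r, 1)
  expect_equal(index_correlation(x, -x)$r, -1)
  set.seed(57)
  xr <- stats::rnorm(200); yr <- 0.4 * xr + stats::rnorm(200)
  got <- index_correlation(xr, yr)
  r_oracle <- sum((xr - mean(xr)) * (yr - mean(yr))) /
    sqrt(sum((xr - mean(xr))^2) * sum((yr - mean(yr))^2))
  expect_equal(got$r, r_oracle, tolerance = 1e-12)
  expect_equal(got$slope, r_oracle * stats::sd(yr) / stats::sd(xr),
               tolerance = 1e-12)
  expect_true(got$p < 0.05)
  expect_true(index_correlation(rep(1, 5), 1:5)$degenerate)
  expect_error(index_correlation(1, 1), "3 finite pairs")
})

test_that("cell summaries assemble the per-cell metrics coherently", {
  s <- simulate_session(short_task(420), quiet_agent(), seed = 60)
  pop <- population_params(n_excitatory = 12, n_vip = 8,
                           condition = "familiar")
  tr <- generate_event_traces(s$stimuli, pop, seed = 61)
  cs <- summarize_cells(tr, s$stimuli, n_resamples = 500, seed = 62)
  expect_s3_class(cs, "cell_summary")
  expect_equal(nrow(cs), 20)
  expect_true(all(cs$dynamics_class %in%
                    c("stimulus_driven", "stimulus_suppressed")))
  expect_true(all(is.na(cs$sparseness) | (cs$sparseness >= 0 &
                                            cs$sparseness <= 1)))
  # sparseness only reported for image-responsive cells
  expect_true(all(is.na(cs$sparseness[!cs$image_responsive])))
  expect_true(all(cs$time_to_peak >= 0 & cs$time_to_peak < 0.5))
  # deterministic under identical seeds
  cs2 <- summarize_cells(tr, s$stimuli, n_resamples = 500, seed = 62)
  expect_identical(cs, cs2)
})
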