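test_that("change-time sampler respects bounds and calibrated mean", {
  task <- task_params()
  set.seed(0)
  x <- sample_change_time(100000, task)
  expect_true(all(x >= task$change_time_min))
  expect_true(all(x <= task$change_time_max))
  expect_equal(mean(x), task$change_time_mean, tolerance = 0.02 / 4.25)

  # independent oracle: mean of the truncated exponential by numerical
  # integration at the calibrated scale must equal the configured mean
  s <- change_time_scale(task)
  L <- task$change_time_max - task$change_time_min
  Z <- 1 - exp(-L / s)
  m_num <- stats::integrate(function(t) t * exp(-t / s) / (s * Z),
                            0, L, rel.tol = 1e-12)$value
  expect_equal(m_num, task$change_time_mean - task$change_time_min,
               tolerance = 1e-8)
  expect_equal(s, 2.80, tolerance = 0.01)

  expect_error(task_params(change_time_mean = 9), "min < mean < max")
  # a mean above the truncated-distribution's attainable range is infeasible
  expect_error(change_time_scale(task_params(change_time_mean = 6.0)),
               "infeasible")
})

test_that("transition paths cover every ordered image pair exactly once", {
  set.seed(1)
  expect_identical(generate_transition_paths(1, 1)[[1]], c(0L, 0L))
  for (k in c(3, 8)) {
    paths <- generate_transition_paths(5, k)
    for (p in paths) {
      expect_length(p, k^2 + 1)
      expect_identical(p[1], p[length(p)])  # closed circuit
      pairs <- paste(p[-length(p)], p[-1])
      counts <- table(pairs)
      expect_length(counts, k^2)            # exhaustive pair-count oracle
      expect_true(all(counts == 1))
    }
  }
})

test_that("omission scheduling spares change and pre-change flashes", {
  n <- 4000
  tbl <- data.frame(flash_index = seq_len(n), onset = (seq_len(n) - 1) * 0.75,
                    offset = (seq_len(n) - 1) * 0.75 + 0.25,
                    image_id = 0L, is_change = FALSE, is_omitted = FALSE,
                    trial_id = NA_integer_)
  tbl$is_change[seq(10, n, by = 9)] <- TRUE

  set.seed(2)
  out0 <- schedule_omissions(tbl, 0)
  expect_false(any(out0$is_omitted))

  set.seed(3)
  out <- schedule_omissions(tbl, 0.05)
  pre <- c(out$is_change[-1], FALSE)
  expect_false(any(out$is_omitted & out$is_change))
  expect_false(any(out$is_omitted & pre))
  expect_true(all(is.na(out$offset[out$is_omitted])))
  n_el <- sum(!tbl$is_change & !pre)
  frac <- sum(out$is_omitted) / n_el
  expect_equal(frac, 0.05, tolerance = 3 * sqrt(0.05 * 0.95 / n_el) / 0.05)
})

test_that("trial scoring follows the response-window rules", {
  task <- task_params()
  expect_identical(score_trial(2.75, 2.25, "go", task), "HIT")
  expect_identical(score_trial(numeric(0), 2.25, "go", task), "MISS")
  expect_identical(score_trial(2.75, 2.25, "catch", task), "FALSE_ALARM")
  expect_identical(score_trial(numeric(0), 2.25, "catch", task),
                   "CORRECT_REJECTION")
  expect_identical(score_trial(1.5, 2.25, "go", task, trial_start = 0),
                   "ABORTED")
  # licks before the trial start are ignored
  expect_identical(score_trial(c(1.5, 2.75), 2.25, "go", task,
                               trial_start = 2.0), "HIT")
  # 1 ms grid scan: largest latency scored HIT is exactly the window
  lat <- (1:1000) / 1000
  hit <- vapply(lat, function(l) {
    score_trial(5 + l, 5, "go", task) == "HIT"
  }, logical(1))
  expect_equal(max(lat[hit]) * 1000, 750)
  expect_true(all(hit[lat <= 0.75]))
})

test_that("sessions tile the flash grid and honour the free-reward rules", {
  task <- short_task(600)
  s <- simulate_session(task, quiet_agent(), seed = 5)
  n_slots <- floor(600 / 0.75)
  expect_equal(nrow(s$stimuli), n_slots)
  expect_equal(s$stimuli$onset, (seq_len(n_slots) - 1) * 0.75)
  expect_false(is.unsorted(s$stimuli$onset, strictly = TRUE))

  # first trials are free-reward trials with a reward delivered
  n_free <- task$n_initial_free_rewards
  expect_identical(s$trials$trial_type[seq_len(n_free)],
                   rep("free_reward", n_free))
  expect_true(all(lengths(s$trials$reward_times[seq_len(n_free)]) == 1))

  # image identity constant between change rows
  ch <- which(s$stimuli$is_change)
  seg <- findInterval(seq_len(n_slots), ch)
  expect_true(all(tapply(s$stimuli$image_id, seg,
                         function(v) length(unique(v)) == 1)))

  # full determinism under an identical seed
  s2 <- simulate_session(task, quiet_agent(), seed = 5)
  expect_identical(s$stimuli, s2$stimuli)
  expect_identical(s$trials, s2$trials)
  expect_identical(s$streams, s2$streams)
  expect_error(simulate_session(task, quiet_agent()), "seed")
})

test_that("a never-licking agent earns an automatic reward every 10 misses", {
  s <- simulate_session(short_task(1800), quiet_agent(), seed = 0)
  tr <- s$trials
  auto <- which(tr$auto_reward)
  expect_gt(length(auto), 3)
  rewarded <- which(lengths(tr$reward_times) > 0)
  miss_between <- vapply(auto, function(a) {
    prev <- max(c(0, rewarded[rewarded < a]))
    sum(tr$outcome[(prev + 1):a] == "MISS" &
          tr$trial_type[(prev + 1):a] == "go")
  }, numeric(1))
  expect_identical(unique(miss_between), 10)
})

test_that("an always-aborting agent never exceeds the repeat limit", {
  s <- simulate_session(short_task(300),
                        agent_params(p_spontaneous_lick_per_flash = 1),
                        seed = 7)
  expect_true(all(s$trials$outcome == "ABORTED"))
  expect_true(all(s$trials$n_repeats <= 5))
  expect_true(all(s$trials$n_repeats == 5))
  expect_true(all(is.na(s$trials$change_onset)))
})

test_that("catch frequency matches the transition-path self-loop rate", {
  fracs <- vapply(1:4, function(sd) {
    s <- simulate_session(short_task(1800), agent_params(), seed = sd)
    tr <- s$trials
    done <- tr[tr$trial_type %in% c("go", "catch") &
                 tr$outcome != "ABORTED", ]
    mean(done$trial_type == "catch")
  }, numeric(1))
  expect_equal(mean(fracs), 0.125, tolerance = 0.03 / 0.125)
})

test_that("session tables round-trip to CSV", {
  s <- simulate_session(short_task(120), agent_params(), seed = 9)
  dir <- withr::local_tempdir()
  files <- write_session_tables(s, dir)
  expect_true(all(file.exists(files)))
  st <- utils::read.csv(file.path(dir, "stimulus_table.csv"))
  expect_equal(nrow(st), nrow(s$stimuli))
  expect_true(all(st$is_omitted %in% 0:1))
})
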