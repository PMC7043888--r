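#' Score a single trial from its lick times
#'
#' Applies the task's outcome rules: any lick after `trial_start` but before
#' the (sham) change aborts the trial; a go trial with a lick inside the
#' response window `(change, change + response_window]` is a HIT, otherwise
#' a MISS; a catch trial with a lick in the sham window is a FALSE_ALARM,
#' otherwise a CORRECT_REJECTION. The window is closed on the right, so a
#' lick at exactly `response_window` after the change still counts.
#'
#' @param lick_times Lick times in seconds (absolute, same clock as
#'   `change_onset`); need not be sorted.
#' @param change_onset Absolute time of the change (go) or sham change
#'   (catch).
#' @param trial_type `"go"` or `"catch"` (free-reward trials score as go).
#' @param params A [task_params()] object (supplies the response window).
#' @param trial_start Start of the trial; licks before it are ignored.
#' @return One of `"HIT"`, `"MISS"`, `"FALSE_ALARM"`, `"CORRECT_REJECTION"`,
#'   `"ABORTED"`.
#' @examples
#' task <- task_params()
#' score_trial(2.75, change_onset = 2.25, trial_type = "go", params = task)
#' @export
score_trial <- function(lick_times, change_onset,
                        trial_type = c("go", "catch"),
                        params = task_params(),
                        trial_start = -Inf) {
  trial_type <- match.arg(trial_type)
  licks <- lick_times[lick_times >= trial_start]
  if (any(licks < change_onset)) return("ABORTED")
  responded <- any(licks > change_onset &
                     licks <= change_onset + params$response_window)
  if (trial_type == "go") {
    if (responded) "HIT" else "MISS"
  } else {
    if (responded) "FALSE_ALARM" else "CORRECT_REJECTION"
  }
}

#' Flag random stimulus omissions
#'
#' Marks eligible flashes as omitted with independent per-flash probability
#' `p`. Change presentations and the presentation immediately preceding a
#' change are never omitted (so omissions cannot interfere with change
#' detection); all other flashes are eligible, and consecutive omissions are
#' allowed. Omitted flashes keep their slot -- the screen simply stays gray,
#' leaving a gap in the periodic sequence -- so `onset` is retained and
#' `offset` is set to `NA`.
#'
#' Draws come from the current RNG state; [simulate_session()] calls this
#' inside its seeded context.
#'
#' @param stimuli A stimulus table with `is_change` resolved (see
#'   [simulate_session()]).
#' @param p Per-flash omission probability.
#' @return The stimulus table with `is_omitted` and `offset` updated.
#' @export
schedule_omissions <- function(stimuli, p) {
  check_prob(p, "p")
  n <- nrow(stimuli)
  pre_change <- c(stimuli$is_change[-1], FALSE)
  eligible <- !stimuli$is_change & !pre_change
  stimuli$is_omitted <- eligible & stats::runif(n) < p
  stimuli$offset[stimuli$is_omitted] <- NA_real_
  stimuli
}

# reaction time truncated to (0, response_window]
draw_reaction_time <- function(agent, window) {
  repeat {
    rt <- stats::rnorm(1, agent$reaction_time_mean, agent$reaction_time_sd)
    if (rt > 0 && rt <= window) return(rt)
  }
}

#' Simulate a complete behavior session
#'
#' Generates a full change-detection session: the flash schedule on the
#' 750 ms grid, the trial sequence driven by a random image-transition path
#' (one transition consumed per trial, so catch trials are the
#' same-to-same transitions and occur at the configured 12.5% frequency),
#' the stochastic agent's licking, running and pupil behavior, rewards, and
#' random stimulus omissions.
#'
#' Per trial, a change time is drawn from the truncated-exponential sampler
#' and snapped to the next flash onset. Spontaneous licks before the (sham)
#' change abort the trial, which is restarted with the same scheduled change
#' time up to `max_trial_repeats` times; after that the trial is recorded
#' ABORTED and the session advances to the next transition. The first
#' `n_initial_free_rewards` trials are free-reward trials (non-contingent
#' reward at the scheduled change time), and an additional non-contingent
#' reward is delivered after `miss_streak_for_free_reward` consecutive MISS
#' trials.
#'
#' @param task A [task_params()] object.
#' @param agent An [agent_params()] object.
#' @param seed Integer seed; required (runs refuse to proceed unseeded).
#' @return An object of class `session` with elements:
#' \describe{
#'   \item{stimuli}{data.frame, one row per flash slot: `flash_index`,
#'     `onset`, `offset`, `image_id`, `is_change`, `is_omitted`,
#'     `trial_id`.}
#'   \item{trials}{data.frame, one row per trial: `trial_id`, `trial_type`
#'     (go/catch/free_reward), `start_time`, `scheduled_change_time`
#'     (seconds from trial start), `change_onset` (absolute; sham onset for
#'     catch trials), `outcome`, `n_repeats`, `reaction_time`,
#'     `auto_reward` and list-columns `lick_times`, `reward_times`.}
#'   \item{streams}{[generate_agent_behavior()] output: lick, reward,
#'     running and pupil streams.}
#'   \item{task, agent, seed}{the inputs.}
#' }
#' @examples
#' s <- simulate_session(task_params(session_duration = 120),
#'                       agent_params(), seed = 1)
#' table(s$trials$outcome)
#' @export
simulate_session <- function(task = task_params(), agent = agent_params(),
                             seed) {
  if (missing(seed)) stop("a seed is required for reproducibility",
                          call. = FALSE)
  with_seed(seed, simulate_session_impl(task, agent, seed))
}

simulate_session_impl <- function(task, agent, seed) {
  period <- task$flash_period
  n_slots <- as.integer(floor(task$session_duration / period + 1e-9))
  if (n_slots < 1L) stop("session too short for a single flash slot",
                         call. = FALSE)
  onsets <- (seq_len(n_slots) - 1) * period
  scale <- change_time_scale(task)

  paths <- generate_transition_paths(task$n_transition_paths, task$n_images)
  path <- paths[[sample.int(length(paths), 1L)]]
  pos <- 1L
  initial_image <- path[1L]

  trials <- list()
  change_slots <- integer(0)
  change_imgs <- integer(0)
  miss_streak <- 0L
  cur_slot <- 1L
  trial_id <- 0L

  while (cur_slot <= n_slots && pos < length(path)) {
    from_img <- path[pos]
    to_img <- path[pos + 1L]
    is_go <- to_img != from_img
    trial_id <- trial_id + 1L
    type <- if (trial_id <= task$n_initial_free_rewards) "free_reward"
            else if (is_go) "go" else "catch"
    sched <- sample_change_time(1L, task, scale = scale)
    attempt_slot <- cur_slot
    first_slot <- cur_slot
    n_rep <- 0L
    trial_licks <- numeric(0)
    trial_rewards <- numeric(0)
    outcome <- NA_character_
    rt <- NA_real_
    end_slot <- NA_integer_
    truncated <- FALSE

    repeat {
      t_start <- onsets[attempt_slot]
      ch_slot <- as.integer(ceiling((t_start + sched) / period - 1e-9)) + 1L
      if (ch_slot > n_slots) {
        truncated <- TRUE
        break
      }
      # spontaneous licks on the pre-change flashes of this attempt
      pre <- attempt_slot:(ch_slot - 1L)
      sp <- which(stats::runif(length(pre)) <
                    agent$p_spontaneous_lick_per_flash)
      if (length(sp)) {
        s <- pre[sp[1L]]
        t_lick <- onsets[s] + stats::runif(1, 0.05, period - 0.05)
        trial_licks <- c(trial_licks, t_lick)
        if (n_rep >= task$max_trial_repeats) {
          outcome <- "ABORTED"
          end_slot <- s
          break
        }
        n_rep <- n_rep + 1L
        if (s + 1L > n_slots) {
          truncated <- TRUE
          break
        }
        attempt_slot <- s + 1L
        next
      }
      # the (sham) change is reached
      change_onset <- onsets[ch_slot]
      p_resp <- if (type == "catch") agent$p_false_alarm_per_catch
                else agent$p_hit
      if (stats::runif(1) < p_resp) {
        rt <- draw_reaction_time(agent, task$response_window)
        trial_licks <- c(trial_licks, change_onset + rt)
      }
      outcome <- score_trial(trial_licks, change_onset,
                             if (type == "catch") "catch" else "go",
                             task, trial_start = t_start)
      if (type == "free_reward") {
        trial_rewards <- change_onset
      } else if (type == "go" && outcome == "HIT") {
        trial_rewards <- change_onset + rt
      }
      if (is_go) {           # the change is displayed whether or not licked
        change_slots <- c(change_slots, ch_slot)
        change_imgs <- c(change_imgs, to_img)
      }
      end_slot <- min(n_slots,
                      ch_slot - 1L +
                        max(1L, as.integer(ceiling(task$response_window /
                                                     period - 1e-9))))
      break
    }

    if (truncated && is.na(outcome)) break   # session ended mid-trial

    auto <- FALSE
    if (length(trial_rewards)) miss_streak <- 0L
    if (type == "go") {
      if (outcome == "MISS") {
        miss_streak <- miss_streak + 1L
        if (miss_streak >= task$miss_streak_for_free_reward) {
          trial_rewards <- c(trial_rewards,
                             change_onset + task$response_window)
          auto <- TRUE
          miss_streak <- 0L
        }
      } else if (outcome == "HIT") {
        miss_streak <- 0L
      }
    }

    trials[[trial_id]] <- list(
      trial_id = trial_id,
      trial_type = type,
      start_time = onsets[first_slot],
      first_slot = first_slot,
      end_slot = end_slot,
      scheduled_change_time = sched,
      change_onset = if (outcome == "ABORTED") NA_real_ else change_onset,
      outcome = outcome,
      n_repeats = n_rep,
      reaction_time = if (!is.na(outcome) &&
                          outcome %in% c("HIT", "FALSE_ALARM")) rt
                      else NA_real_,
      auto_reward = auto,
      lick_times = trial_licks,
      reward_times = trial_rewards
    )

    cur_slot <- end_slot + 1L
    pos <- pos + 1L
    if (pos >= length(path)) {
      path <- rotate_circuit(paths[[sample.int(length(paths), 1L)]],
                             path[length(path)])
      pos <- 1L
    }
  }

  trial_tbl <- if (length(trials)) {
    data.frame(
      trial_id = vapply(trials, `[[`, integer(1), "trial_id"),
      trial_type = vapply(trials, `[[`, character(1), "trial_type"),
      start_time = vapply(trials, `[[`, numeric(1), "start_time"),
      scheduled_change_time = vapply(trials, `[[`, numeric(1),
                                     "scheduled_change_time"),
      change_onset = vapply(trials, `[[`, numeric(1), "change_onset"),
      outcome = vapply(trials, `[[`, character(1), "outcome"),
      n_repeats = vapply(trials, `[[`, integer(1), "n_repeats"),
      reaction_time = vapply(trials, `[[`, numeric(1), "reaction_time"),
      auto_reward = vapply(trials, `[[`, logical(1), "auto_reward"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(trial_id = integer(0), trial_type = character(0),
               start_time = numeric(0), scheduled_change_time = numeric(0),
               change_onset = numeric(0), outcome = character(0),
               n_repeats = integer(0), reaction_time = numeric(0),
               auto_reward = logical(0), stringsAsFactors = FALSE)
  }
  trial_tbl$lick_times <- I(lapply(trials, `[[`, "lick_times"))
  trial_tbl$reward_times <- I(lapply(trials, `[[`, "reward_times"))

  # stimulus table: image identity is piecewise constant between changes
  image_id <- rep.int(initial_image, n_slots)
  if (length(change_slots)) {
    seg <- findInterval(seq_len(n_slots), change_slots)
    image_id <- ifelse(seg == 0L, initial_image, change_imgs[pmax(seg, 1L)])
  }
  is_change <- rep(FALSE, n_slots)
  is_change[change_slots] <- TRUE
  slot_trial <- rep(NA_integer_, n_slots)
  if (length(trials)) {
    firsts <- vapply(trials, `[[`, integer(1), "first_slot")
    ends <- vapply(trials, `[[`, integer(1), "end_slot")
    idx <- findInterval(seq_len(n_slots), firsts)
    in_trial <- idx >= 1L & seq_len(n_slots) <= ends[pmax(idx, 1L)]
    slot_trial[in_trial] <- idx[in_trial]
  }
  stimuli <- data.frame(
    flash_index = seq_len(n_slots),
    onset = onsets,
    offset = onsets + task$flash_duration,
    image_id = as.integer(image_id),
    is_change = is_change,
    is_omitted = FALSE,
    trial_id = slot_trial
  )
  stimuli <- schedule_omissions(stimuli, task$omission_probability)

  streams <- generate_agent_behavior(trial_tbl, task, agent)

  structure(list(stimuli = stimuli, trials = trial_tbl, streams = streams,
                 task = task, agent = agent, seed = seed),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("Change-detection session (seed %s): %d flash slots, %d trials\n",
              format(x$seed), nrow(x$stimuli), nrow(x$trials)))
  if (nrow(x$trials)) print(table(x$trials$outcome))
  cat(sprintf("  %d omitted flashes, %d licks, %d rewards\n",
              sum(x$stimuli$is_omitted), length(x$streams$lick_times),
              length(x$streams$reward_times)))
  invisible(x)
}

#' Assemble behavior streams for a scored trial table
#'
#' Builds the session-level behavior streams: lick and reward event times
#' collected from the trial table (the lick decisions themselves are made in
#' [simulate_session()]'s trial loop, because pre-change licks feed back
#' into trial scheduling), a bouted running-speed trace sampled at the
#' stimulus clock rate (60 Hz), and a slowly varying pupil-area trace at
#' 30 Hz. Running alternates exponential-duration bouts whose means are set
#' so the long-run running fraction equals `run_fraction`. Draws come from
#' the current RNG state.
#'
#' @param trials Trial table as produced by [simulate_session()] (with
#'   `lick_times`/`reward_times` list-columns).
#' @param task A [task_params()] object.
#' @param agent An [agent_params()] object.
#' @return An object of class `behavior_streams`: list with `lick_times`,
#'   `reward_times`, `running` (data.frame time/speed) and `pupil`
#'   (data.frame time/area).
#' @export
generate_agent_behavior <- function(trials, task, agent) {
  licks <- sort(unlist(trials$lick_times))
  rewards <- sort(unlist(trials$reward_times))

  dur <- task$session_duration
  # running at the stimulus clock (60 Hz), alternating run/stop bouts
  fs <- task$stimulus_clock_rate
  t_run <- seq(0, dur, by = 1 / fs)
  n <- length(t_run)
  speed <- numeric(n)
  f <- agent$run_fraction
  if (f > 0 && agent$run_speed_mean > 0) {
    mean_run <- 20
    mean_stop <- if (f >= 1) 0 else mean_run * (1 - f) / f
    state <- stats::runif(1) < f
    t0 <- 0
    while (t0 < dur) {
      len <- if (state) stats::rexp(1, 1 / mean_run)
             else if (mean_stop > 0) stats::rexp(1, 1 / mean_stop) else dur
      sel <- t_run >= t0 & t_run < t0 + len
      if (state && any(sel)) {
        base <- stats::rnorm(1, agent$run_speed_mean,
                             0.15 * agent$run_speed_mean)
        speed[sel] <- pmax(0, base + stats::rnorm(sum(sel), 0,
                                                  0.1 * agent$run_speed_mean))
      }
      t0 <- t0 + len
      state <- !state
    }
  }

  # pupil at 30 Hz: baseline plus slow AR(1) fluctuation, kept positive
  t_pup <- seq(0, dur, by = 1 / 30)
  ar <- as.numeric(stats::filter(stats::rnorm(length(t_pup), 0, 0.01),
                                 0.99, method = "recursive"))
  area <- agent$pupil_baseline * pmax(0.2, 1 + ar)

  structure(list(
    lick_times = licks,
    reward_times = rewards,
    running = data.frame(time = t_run, speed = speed),
    pupil = data.frame(time = t_pup, area = area)
  ), class = "behavior_streams")
}

#' Write session tables to CSV
#'
#' Writes the stimulus table, trial table and behavior streams of a session
#' to plain CSV files (`stimulus_table.csv`, `trial_table.csv`, `licks.csv`,
#' `rewards.csv`, `running.csv`, `pupil.csv`). Times are seconds, flags 0/1;
#' per-trial lick/reward lists are serialized as semicolon-joined fields.
#'
#' @param session A [simulate_session()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_session_tables <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- session$stimuli
  st$is_change <- as.integer(st$is_change)
  st$is_omitted <- as.integer(st$is_omitted)
  tr <- session$trials
  tr$lick_times <- vapply(tr$lick_times,
                          function(x) paste(format(x, digits = 10),
                                            collapse = ";"), character(1))
  tr$reward_times <- vapply(tr$reward_times,
                            function(x) paste(format(x, digits = 10),
                                              collapse = ";"), character(1))
  tr$auto_reward <- as.integer(tr$auto_reward)
  files <- file.path(dir, c("stimulus_table.csv", "trial_table.csv",
                            "licks.csv", "rewards.csv", "running.csv",
                            "pupil.csv"))
  utils::write.csv(st, files[1], row.names = FALSE)
  utils::write.csv(tr, files[2], row.names = FALSE)
  utils::write.csv(data.frame(time = session$streams$lick_times), files[3],
                   row.names = FALSE)
  utils::write.csv(data.frame(time = session$streams$reward_times), files[4],
                   row.names = FALSE)
  utils::write.csv(session$streams$running, files[5], row.names = FALSE)
  utils::write.csv(session$streams$pupil, files[6], row.names = FALSE)
  invisible(files)
}
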