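#' Compute a task-engagement mask from reward times
#'
#' A session epoch counts as engaged when the animal's reward rate, in a
#' centered rolling window, is at least `threshold` rewards per minute
#' (inclusive). The rate uses the window's effective (edge-clipped)
#' duration, so a uniformly rewarded session is engaged throughout.
#'
#' @param reward_times Reward delivery times, seconds.
#' @param duration Session duration, seconds.
#' @param window Rolling window length, seconds (default 5 min).
#' @param threshold Engagement threshold, rewards per minute.
#' @param resolution Evaluation grid step, seconds.
#' @return An object of class `engagement_mask`: data.frame with `time` and
#'   logical `engaged`, plus `window`/`threshold` attributes.
#' @examples
#' m <- compute_engagement_mask(seq(0, 600, by = 20), 600)
#' mean(m$engaged)
#' @export
compute_engagement_mask <- function(reward_times, duration, window = 300,
                                    threshold = 2, resolution = 1) {
  check_pos(duration, "duration")
  check_pos(window, "window")
  t <- seq(0, duration, by = resolution)
  lo <- pmax(t - window / 2, 0)
  hi <- pmin(t + window / 2, duration)
  rw <- sort(reward_times)
  # rewards in [lo, hi]: #{r <= hi} - #{r < lo}
  counts <- findInterval(hi, rw) - findInterval(lo, rw, left.open = TRUE)
  rate <- counts / ((hi - lo) / 60)
  structure(data.frame(time = t, engaged = rate >= threshold),
            class = c("engagement_mask", "data.frame"),
            window = window, threshold = threshold)
}

#' Look up engagement at given times
#'
#' @param mask An [compute_engagement_mask()] result.
#' @param times Times to query, seconds.
#' @return Logical vector; `NA` outside the mask's span.
#' @export
engaged_at <- function(mask, times) {
  idx <- findInterval(times, mask$time)
  out <- rep(NA, length(times))
  ok <- idx >= 1 & times <= max(mask$time)
  # nearest grid point at or before the query time
  out[ok] <- mask$engaged[idx[ok]]
  out
}

#' Behavioral response rates
#'
#' Hit rate (fraction of engaged go trials with a lick inside the response
#' window) and false-alarm rate (same for catch trials), plus optional
#' flash-wise rates: the fraction of non-change displayed flashes, omitted
#' slots, and flashes immediately following an omission with a lick within
#' the response window of their onset.
#'
#' @param trials Trial table from [simulate_session()].
#' @param mask Optional [compute_engagement_mask()]; trials are filtered by
#'   engagement at their (sham) change time. `NULL` uses all trials.
#' @param stimuli Optional stimulus table for flash-wise rates.
#' @param lick_times Lick times (required with `stimuli`).
#' @param task A [task_params()] object.
#' @return List with `hit_rate`, `false_alarm_rate`, `n_go`, `n_catch`
#'   (engaged, completed trials; rates are `NA` when a type has no trials)
#'   and, when `stimuli` is given, `flash_response_rate`,
#'   `omission_response_rate`, `post_omission_response_rate`.
#' @export
response_rates <- function(trials, mask = NULL, stimuli = NULL,
                           lick_times = NULL, task = task_params()) {
  done <- trials[trials$outcome %in%
                   c("HIT", "MISS", "FALSE_ALARM", "CORRECT_REJECTION") &
                   trials$trial_type %in% c("go", "catch"), , drop = FALSE]
  if (!is.null(mask) && nrow(done)) {
    eng <- engaged_at(mask, done$change_onset)
    done <- done[!is.na(eng) & eng, , drop = FALSE]
  }
  go <- done[done$trial_type == "go", , drop = FALSE]
  catch <- done[done$trial_type == "catch", , drop = FALSE]
  out <- list(
    hit_rate = if (nrow(go)) mean(go$outcome == "HIT") else NA_real_,
    false_alarm_rate = if (nrow(catch)) mean(catch$outcome == "FALSE_ALARM")
                       else NA_real_,
    n_go = nrow(go),
    n_catch = nrow(catch)
  )
  if (!is.null(stimuli)) {
    if (is.null(lick_times)) {
      stop("'lick_times' is required for flash-wise rates", call. = FALSE)
    }
    w <- task$response_window
    licked_after <- function(onsets) {
      if (!length(onsets)) return(NA_real_)
      lk <- sort(lick_times)
      mean(findInterval(onsets + w, lk) -
             findInterval(onsets, lk) > 0)
    }
    post_om <- which(c(FALSE, stimuli$is_omitted[-nrow(stimuli)]))
    out$flash_response_rate <-
      licked_after(stimuli$onset[!stimuli$is_change & !stimuli$is_omitted])
    out$omission_response_rate <-
      licked_after(stimuli$onset[stimuli$is_omitted])
    out$post_omission_response_rate <-
      licked_after(stimuli$onset[post_om[!stimuli$is_omitted[post_om]]])
  }
  out
}

#' Signal-detection sensitivity (d-prime)
#'
#' `d' = Z(hit rate) - Z(false-alarm rate)` with `Z` the standard-normal
#' quantile function. Rates are first clipped to
#' `[1/(2n), 1 - 1/(2n)]` of their respective trial counts so perfect
#' 0 or 1 rates give a finite value.
#'
#' @param hit_rate,false_alarm_rate Rates in `[0, 1]`.
#' @param n_go,n_catch Trial counts behind each rate.
#' @return d-prime (unitless).
#' @examples
#' dprime(0.8413, 0.5, 100, 100)  # ~1
#' @export
dprime <- function(hit_rate, false_alarm_rate, n_go, n_catch) {
  if (is.na(hit_rate) || is.na(false_alarm_rate) ||
      n_go <= 0 || n_catch <= 0) return(NA_real_)
  check_prob(hit_rate, "hit_rate")
  check_prob(false_alarm_rate, "false_alarm_rate")
  clip <- function(p, n) min(max(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  stats::qnorm(clip(hit_rate, n_go)) -
    stats::qnorm(clip(false_alarm_rate, n_catch))
}

#' Reaction times on go trials
#'
#' Latency from the change onset to the first subsequent lick of the same
#' trial (the search stops at the next trial's start, so later trials'
#' licks are never attributed); `NA` when the trial has no post-change
#' lick. Reported latencies are not truncated at the response window (HIT
#' scoring is, separately).
#'
#' @param trials Trial table from [simulate_session()] (uses `start_time`
#'   when present to bound each trial's lick search).
#' @param lick_times Session lick times, seconds.
#' @return data.frame with `trial_id` and `reaction_time` for go trials.
#' @export
reaction_times <- function(trials, lick_times) {
  has_start <- "start_time" %in% names(trials)
  bound <- if (has_start) {
    c(trials$start_time[-1], Inf)
  } else {
    rep(Inf, nrow(trials))
  }
  is_go <- trials$trial_type == "go" & !is.na(trials$change_onset)
  go <- trials[is_go, , drop = FALSE]
  go_bound <- bound[is_go]
  lk <- sort(lick_times)
  rt <- vapply(seq_len(nrow(go)), function(j) {
    on <- go$change_onset[j]
    i <- findInterval(on, lk) + 1L
    if (i <= length(lk) && lk[i] < go_bound[j]) lk[i] - on else NA_real_
  }, numeric(1))
  data.frame(trial_id = go$trial_id, reaction_time = rt)
}

#' Classify locomotor state around events
#'
#' Labels each event (stimulus presentation or omission) as `"running"`
#' when the mean running speed inside the window around it exceeds the
#' threshold (strictly), otherwise `"stationary"`. Conventional windows are
#' `c(-0.5, 0.75)` s around stimulus onset and `c(-2, 2)` s around
#' omissions, with a 5 cm/s threshold.
#'
#' @param running data.frame with `time` and `speed` (cm/s).
#' @param event_times Event times, seconds.
#' @param window Two-element window relative to each event, seconds.
#' @param threshold Speed threshold, cm/s.
#' @return Character vector of labels; `NA` when the window falls outside
#'   the trace.
#' @export
classify_locomotor_state <- function(running, event_times,
                                     window = c(-0.5, 0.75), threshold = 5) {
  stopifnot(length(window) == 2, window[1] < window[2])
  tr <- running$time
  vapply(event_times, function(e) {
    lo <- e + window[1]
    hi <- e + window[2]
    if (lo < min(tr) || hi > max(tr)) return(NA_character_)
    sel <- tr >= lo & tr <= hi
    if (!any(sel)) return(NA_character_)
    if (mean(running$speed[sel]) > threshold) "running" else "stationary"
  }, character(1))
}

#' Summarize session behavior
#'
#' Convenience wrapper computing the engaged hit/false-alarm rates, d',
#' mean reaction time and engaged-trial counts for one session.
#'
#' @param session A [simulate_session()] result.
#' @param engagement_window,engagement_threshold Passed to
#'   [compute_engagement_mask()].
#' @return One-row data.frame of session-level behavior metrics.
#' @export
behavior_summary <- function(session, engagement_window = 300,
                             engagement_threshold = 2) {
  mask <- compute_engagement_mask(session$streams$reward_times,
                                  session$task$session_duration,
                                  window = engagement_window,
                                  threshold = engagement_threshold)
  rr <- response_rates(session$trials, mask,
                       stimuli = session$stimuli,
                       lick_times = session$streams$lick_times,
                       task = session$task)
  rts <- reaction_times(session$trials, session$streams$lick_times)
  data.frame(
    hit_rate = rr$hit_rate,
    false_alarm_rate = rr$false_alarm_rate,
    d_prime = dprime(rr$hit_rate %||% NA_real_,
                     rr$false_alarm_rate %||% NA_real_,
                     rr$n_go, rr$n_catch),
    n_engaged_go_trials = rr$n_go,
    n_engaged_catch_trials = rr$n_catch,
    mean_reaction_time = mean(rts$reaction_time, na.rm = TRUE),
    flash_response_rate = rr$flash_response_rate,
    omission_response_rate = rr$omission_response_rate,
    post_omission_response_rate = rr$post_omission_response_rate
  )
}
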