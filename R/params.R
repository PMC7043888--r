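#' Task parameters for the change-detection session
#'
#' Bundles the generative constants of the go/no-go change-detection task:
#' 250 ms image flashes separated by 500 ms gray (750 ms stimulus period),
#' go/catch trials with change times drawn from a truncated exponential
#' between 2.25 and 8.25 s (mean 4.25 s), a 12.5% catch frequency arising
#' from the 8 self-transitions among the 64 ordered image transitions, and
#' 5% random omission of eligible (non-change, non-pre-change) flashes.
#'
#' @param session_duration Session length in seconds.
#' @param flash_duration Image presentation time in seconds.
#' @param gray_duration Inter-stimulus gray period in seconds.
#' @param response_window Post-change lick window in seconds.
#' @param change_time_min,change_time_max,change_time_mean Bounds and mean of
#'   the change-time distribution, seconds from trial start.
#' @param catch_fraction Long-run fraction of catch (no-change) trials.
#' @param omission_probability Per-flash probability that an eligible flash
#'   is omitted (gray screen shown in its slot).
#' @param n_images Number of images in the set.
#' @param n_transition_paths Number of pre-generated transition paths a
#'   session draws from.
#' @param max_trial_repeats Maximum number of times an aborted trial is
#'   repeated with the same scheduled change time.
#' @param n_initial_free_rewards Number of free-reward trials opening each
#'   session.
#' @param miss_streak_for_free_reward Consecutive MISS trials after which a
#'   non-contingent reward is delivered.
#' @param stimulus_clock_rate Display/behavior sampling rate, Hz.
#' @return An object of class `task_params` (a validated list).
#' @examples
#' task <- task_params(session_duration = 600)
#' task$catch_fraction
#' @export
task_params <- function(session_duration = 3600,
                        flash_duration = 0.25,
                        gray_duration = 0.5,
                        response_window = 0.75,
                        change_time_min = 2.25,
                        change_time_max = 8.25,
                        change_time_mean = 4.25,
                        catch_fraction = 0.125,
                        omission_probability = 0.05,
                        n_images = 8,
                        n_transition_paths = 1000,
                        max_trial_repeats = 5,
                        n_initial_free_rewards = 5,
                        miss_streak_for_free_reward = 10,
                        stimulus_clock_rate = 60) {
  check_pos(session_duration, "session_duration")
  check_pos(flash_duration, "flash_duration")
  check_pos(gray_duration, "gray_duration")
  check_pos(response_window, "response_window")
  check_prob(catch_fraction, "catch_fraction")
  check_prob(omission_probability, "omission_probability")
  if (!(change_time_min < change_time_mean &&
        change_time_mean < change_time_max)) {
    stop("change times must satisfy min < mean < max", call. = FALSE)
  }
  p <- list(
    session_duration = session_duration,
    flash_duration = flash_duration,
    gray_duration = gray_duration,
    response_window = response_window,
    change_time_min = change_time_min,
    change_time_max = change_time_max,
    change_time_mean = change_time_mean,
    catch_fraction = catch_fraction,
    omission_probability = omission_probability,
    n_images = check_count(n_images, "n_images"),
    n_transition_paths = check_count(n_transition_paths,
                                     "n_transition_paths"),
    max_trial_repeats = check_count(max_trial_repeats, "max_trial_repeats"),
    n_initial_free_rewards = check_count(n_initial_free_rewards,
                                         "n_initial_free_rewards"),
    miss_streak_for_free_reward = check_count(miss_streak_for_free_reward,
                                              "miss_streak_for_free_reward"),
    stimulus_clock_rate = check_pos(stimulus_clock_rate,
                                    "stimulus_clock_rate")
  )
  p$flash_period <- p$flash_duration + p$gray_duration
  structure(p, class = "task_params")
}

#' @export
print.task_params <- function(x, ...) {
  cat("Change-detection task parameters\n")
  cat(sprintf("  session %g s, %g ms flash + %g ms gray (%g ms period)\n",
              x$session_duration, 1000 * x$flash_duration,
              1000 * x$gray_duration, 1000 * x$flash_period))
  cat(sprintf("  change times %g-%g s (mean %g), catch %g%%, omission %g%%\n",
              x$change_time_min, x$change_time_max, x$change_time_mean,
              100 * x$catch_fraction, 100 * x$omission_probability))
  invisible(x)
}

#' Agent (simulated mouse) parameters
#'
#' Describes the stochastic behaving agent that stands in for the mouse:
#' detection and guessing probabilities, reaction-time distribution
#' (normal truncated to the response window), spontaneous licking that
#' aborts trials, running-bout structure and pupil baseline.
#'
#' @param p_hit Probability of licking within the response window on a go
#'   trial.
#' @param p_false_alarm_per_catch Probability of licking in the sham window
#'   on a catch trial.
#' @param p_spontaneous_lick_per_flash Per-flash probability of a
#'   task-irrelevant lick before the (sham) change, which aborts the trial.
#' @param reaction_time_mean,reaction_time_sd Reaction-time distribution in
#'   seconds; draws are truncated to (0, response_window].
#' @param run_fraction Long-run fraction of session time spent running.
#' @param run_speed_mean Mean running speed while in a running bout, cm/s.
#' @param pupil_baseline Baseline pupil area, arbitrary units.
#' @return An object of class `agent_params`.
#' @examples
#' agent_params(p_hit = 1, p_spontaneous_lick_per_flash = 0)
#' @export
agent_params <- function(p_hit = 0.8,
                         p_false_alarm_per_catch = 0.15,
                         p_spontaneous_lick_per_flash = 0.02,
                         reaction_time_mean = 0.35,
                         reaction_time_sd = 0.08,
                         run_fraction = 0.4,
                         run_speed_mean = 12,
                         pupil_baseline = 1000) {
  p <- list(
    p_hit = check_prob(p_hit, "p_hit"),
    p_false_alarm_per_catch = check_prob(p_false_alarm_per_catch,
                                         "p_false_alarm_per_catch"),
    p_spontaneous_lick_per_flash =
      check_prob(p_spontaneous_lick_per_flash,
                 "p_spontaneous_lick_per_flash"),
    reaction_time_mean = check_pos(reaction_time_mean, "reaction_time_mean"),
    reaction_time_sd = check_pos(reaction_time_sd, "reaction_time_sd",
                                 strict = FALSE),
    run_fraction = check_prob(run_fraction, "run_fraction"),
    run_speed_mean = check_pos(run_speed_mean, "run_speed_mean",
                               strict = FALSE),
    pupil_baseline = check_pos(pupil_baseline, "pupil_baseline")
  )
  structure(p, class = "agent_params")
}

#' Synthetic population parameters
#'
#' Configuration of the synthetic two-photon population: numbers of
#' excitatory and VIP cells, experience condition, imaging frame rate, and
#' the rate-model knobs. Under the `familiar` condition excitatory
#' amplitudes are scaled down (~35%) and tuning sharpened, and VIP cells are
#' predominantly in the suppressed/ramping mode; under `novel` both classes
#' are stimulus-driven. Mode fractions are realized deterministically
#' (`round(n * fraction)` cells per mode) so the configured composition is
#' exact in every population.
#'
#' @param n_excitatory,n_vip Cell counts (session-scale defaults 180 / 15).
#' @param condition `"familiar"` or `"novel"`.
#' @param frame_rate Imaging frame rate, Hz.
#' @param tuning_sharpness Controls how weak non-preferred responses are;
#'   off-preferred amplitudes are drawn uniformly below
#'   `exp(-tuning_sharpness)`.
#' @param exc_amplitude_scale Peak event rate (events/s) of an excitatory
#'   cell's preferred-image response under the novel condition.
#' @param vip_amplitude_scale Peak event rate (events/s) of VIP profiles.
#' @param vip_mode_fractions Named weights over the VIP modes `driven` and
#'   `suppressed_ramping`; must sum to 1. Defaults depend on `condition`
#'   (familiar: 60% suppressed/ramping; novel: 85% driven).
#' @param familiar_amplitude_factor Multiplier applied to excitatory
#'   amplitudes under the familiar condition.
#' @param noise_event_rate Background event rate common to all cells,
#'   events/s.
#' @param event_magnitude_mean Mean of the exponential event-magnitude mark
#'   distribution, arbitrary units.
#' @return An object of class `population_params`.
#' @examples
#' population_params(n_vip = 20, condition = "familiar")
#' @export
population_params <- function(n_excitatory = 180,
                              n_vip = 15,
                              condition = c("novel", "familiar"),
                              frame_rate = 30,
                              tuning_sharpness = NULL,
                              exc_amplitude_scale = 25,
                              vip_amplitude_scale = 12,
                              vip_mode_fractions = NULL,
                              familiar_amplitude_factor = 0.65,
                              noise_event_rate = 0.1,
                              event_magnitude_mean = 0.01) {
  condition <- match.arg(condition)
  if (is.null(tuning_sharpness)) {
    tuning_sharpness <- if (condition == "familiar") 1.4 else 0.7
  }
  if (is.null(vip_mode_fractions)) {
    vip_mode_fractions <- if (condition == "familiar") {
      c(driven = 0.4, suppressed_ramping = 0.6)
    } else {
      c(driven = 0.85, suppressed_ramping = 0.15)
    }
  }
  if (is.null(names(vip_mode_fractions)) ||
      !setequal(names(vip_mode_fractions),
                c("driven", "suppressed_ramping")) ||
      abs(sum(vip_mode_fractions) - 1) > 1e-8 ||
      any(vip_mode_fractions < 0)) {
    stop("'vip_mode_fractions' must be non-negative weights named ",
         "'driven' and 'suppressed_ramping' summing to 1", call. = FALSE)
  }
  structure(list(
    n_excitatory = check_count(n_excitatory, "n_excitatory"),
    n_vip = check_count(n_vip, "n_vip"),
    condition = condition,
    frame_rate = check_pos(frame_rate, "frame_rate"),
    tuning_sharpness = check_pos(tuning_sharpness, "tuning_sharpness"),
    exc_amplitude_scale = check_pos(exc_amplitude_scale,
                                    "exc_amplitude_scale", strict = FALSE),
    vip_amplitude_scale = check_pos(vip_amplitude_scale,
                                    "vip_amplitude_scale", strict = FALSE),
    vip_mode_fractions =
      vip_mode_fractions[c("driven", "suppressed_ramping")],
    familiar_amplitude_factor = check_pos(familiar_amplitude_factor,
                                          "familiar_amplitude_factor"),
    noise_event_rate = check_pos(noise_event_rate, "noise_event_rate",
                                 strict = FALSE),
    event_magnitude_mean = check_pos(event_magnitude_mean,
                                     "event_magnitude_mean")
  ), class = "population_params")
}
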