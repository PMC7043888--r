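# Shared fixtures: short sessions and deterministic agents keep the suite
# fast while exercising the full generative structure.

short_task <- function(duration = 300, ...) {
  task_params(session_duration = duration, n_transition_paths = 50, ...)
}

quiet_agent <- function(...) {
  agent_params(p_hit = 0, p_false_alarm_per_catch = 0,
               p_spontaneous_lick_per_flash = 0, ...)
}

perfect_agent <- function(...) {
  agent_params(p_hit = 1, p_false_alarm_per_catch = 1,
               p_spontaneous_lick_per_flash = 0, ...)
}

# minimal event-traces object from a magnitudes matrix
fake_traces <- function(mags, frame_rate = 30) {
  mags <- rbind(mags)
  list(frame_times = (seq_len(ncol(mags)) - 1) / frame_rate,
       magnitudes = mags,
       cells = data.frame(cell_id = seq_len(nrow(mags))),
       frame_rate = frame_rate)
}

# minimal triggered-average object
fake_avg <- function(values, t0, frame_rate = 30) {
  values <- rbind(values)
  list(time = t0 + (seq_len(ncol(values)) - 1) / frame_rate,
       mean = values, frame_rate = frame_rate)
}
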