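# Fixture builders used across the suite. All fixtures are constructed in
# code; no data files.

# A flock_state with fully specified truth, for deterministic scoring and
# observer tests. `status` is a character vector of "healthy"/"lame".
make_flock <- function(status, state = rep(1L, length(status)),
                       bout = rep(100, length(status)), clock = 0,
                       transitions = list(sheep_id = integer(0),
                                          from = integer(0),
                                          to = integer(0))) {
  n <- length(status)
  lame <- status == "lame"
  structure(
    list(
      sheep_id = seq_len(n),
      status = status,
      cue_leg = ifelse(lame, "front-left", NA_character_),
      cue_quickened_opposite = ifelse(lame, TRUE, NA),
      cue_head_nod = ifelse(lame, 0.5, NA_real_),
      state = as.integer(state),
      bout_remaining = as.numeric(bout),
      clock = clock,
      last_transitions = transitions
    ),
    class = "flock_state"
  )
}

# A minimal session_log wrapping a constructed flock + marks.
make_log <- function(status, marks = mark_set(), session_length = 600,
                     end_time = session_length) {
  structure(
    list(
      config = behavior_config(session_length = session_length),
      observer = NULL,
      seed = 0L,
      status = status,
      cue_leg = rep(NA_character_, length(status)),
      events = data.frame(time = numeric(0), sheep_id = integer(0),
                          event = character(0)),
      marks = marks,
      occupancy_ticks = c(graze = 0, stand = 0, walk = 0),
      session_length = session_length,
      end_time = end_time,
      ended_early = end_time < session_length
    ),
    class = "session_log"
  )
}

# Mean recall over replicated players at a fixed quit time (minutes).
mean_recall_at <- function(quit_min, n_rep, config, obs_template, seed0) {
  recalls <- vapply(seq_len(n_rep), function(i) {
    o <- obs_template
    o$quit_time <- quit_min * 60
    simulate_player(config, o, seed = seed0 + i)$recall
  }, numeric(1))
  mean(recalls, na.rm = TRUE)
}
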