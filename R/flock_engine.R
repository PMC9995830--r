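#' Initialize a flock at session start
#'
#' Creates `flock_size` sheep. Each is independently lame with probability
#' `p_lame` (the game's coin-flip assignment); lame sheep receive the full
#' early-lameness gait-cue profile — a shortened stride on one uniformly
#' random leg, a quickened stride on the opposite leg, and a slight head nod —
#' while healthy sheep carry no cues. Each sheep starts in a behaviour state
#' drawn from the stationary activity budget with an exponential residual
#' bout, so the session begins in steady state with no burn-in transient.
#'
#' @param config A [behavior_config()].
#' @param seed Optional integer seed; when supplied the draw is made under
#'   [withr::with_seed()] so the global RNG stream is untouched. When `NULL`
#'   the current RNG stream is used.
#' @return An object of class `flock_state`: parallel vectors `sheep_id`,
#'   `status` ("healthy"/"lame"), `cue_leg`, `cue_quickened_opposite`,
#'   `cue_head_nod`, `state` (integer, 1 = graze, 2 = stand, 3 = walk),
#'   `bout_remaining` (seconds), plus the session `clock` (seconds elapsed).
#' @examples
#' flock <- init_flock(behavior_config(), seed = 42)
#' table(flock$status)
#' @export
init_flock <- function(config, seed = NULL) {
  validate_behavior_config(config)
  draw <- function() {
    n <- config$flock_size
    lame <- stats::runif(n) < config$p_lame
    legs <- c("front-left", "front-right", "hind-left", "hind-right")
    cue_leg <- rep(NA_character_, n)
    if (any(lame)) {
      cue_leg[lame] <- legs[sample.int(4L, sum(lame), replace = TRUE)]
    }
    state <- sample.int(3L, n, replace = TRUE, prob = budget_vec(config))
    bout <- stats::rexp(n, rate = 1 / mean_bout_vec(config)[state])
    structure(
      list(
        sheep_id = seq_len(n),
        status = ifelse(lame, "lame", "healthy"),
        cue_leg = cue_leg,
        cue_quickened_opposite = ifelse(lame, TRUE, NA),
        cue_head_nod = ifelse(lame, 0.5, NA_real_),
        state = state,
        bout_remaining = bout,
        clock = 0,
        last_transitions = list(sheep_id = integer(0), from = integer(0),
                                to = integer(0))
      ),
      class = "flock_state"
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' @export
print.flock_state <- function(x, ...) {
  cat(sprintf("<flock_state> %d sheep (%d lame), clock %gs\n",
              length(x$sheep_id), sum(x$status == "lame"), x$clock))
  cat("  states:", paste(sprintf("%s %d", .states,
                                 tabulate(x$state, 3L)), collapse = ", "), "\n")
  invisible(x)
}

#' Advance the flock by one tick
#'
#' Decrements every sheep's bout clock by one tick. Expired bouts renew by
#' drawing the next state from the fixed entry distribution (see
#' [entry_distribution()]) and adding a fresh exponential dwell to the
#' residual; a draw of the current state silently extends the ongoing bout,
#' so observable transitions never self-loop. Sub-tick residuals carry over,
#' keeping the time accounting exact at any tick length. Net state changes
#' for the tick are returned in `$last_transitions` (used by the observer to
#' detect walking-bout ends). Status is never touched: lameness is immutable
#' for the session.
#'
#' @param flock A `flock_state` from [init_flock()].
#' @param config The [behavior_config()] the flock was built with.
#' @return The advanced `flock_state`, clock moved forward by `config$tick`.
#' @export
step_flock <- function(flock, config) {
  if (flock$clock + config$tick > config$session_length + 1e-9) {
    stop("step_flock: session over (clock ", flock$clock, "s + tick exceeds ",
         "session_length ", config$session_length, "s)", call. = FALSE)
  }
  q <- entry_distribution(config)
  means <- mean_bout_vec(config)
  state0 <- flock$state
  state <- state0
  bout <- flock$bout_remaining - config$tick
  expired <- which(bout <= 0)
  while (length(expired)) {
    nxt <- sample.int(3L, length(expired), replace = TRUE, prob = q)
    state[expired] <- nxt
    bout[expired] <- bout[expired] + stats::rexp(length(expired),
                                                 rate = 1 / means[nxt])
    expired <- expired[bout[expired] <= 0]
  }
  changed <- which(state != state0)
  flock$state <- state
  flock$bout_remaining <- bout
  flock$clock <- flock$clock + config$tick
  flock$last_transitions <- list(sheep_id = changed,
                                 from = state0[changed],
                                 to = state[changed])
  flock
}

#' Run one complete game session
#'
#' Simulates the flock from time zero until the session clock expires or the
#' attached observer quits ("Done"), logging every behaviour-state entry and
#' every marking event. With `observer = NULL` the flock simply behaves for
#' the full session and no sheep is marked. The run is bitwise reproducible
#' given `(config, observer, seed)`.
#'
#' @param config A [behavior_config()].
#' @param observer An [observer_config()] or `NULL` for an unobserved session.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return An object of class `session_log` with elements:
#'   \describe{
#'     \item{config, observer, seed}{echo of the inputs.}
#'     \item{status, cue_leg}{per-sheep ground truth.}
#'     \item{events}{data frame `(time, sheep_id, event)` — `state_enter:*`
#'       rows (including the initial states at time 0) and `marked_lame` rows,
#'       times non-decreasing.}
#'     \item{marks}{a `mark_set` of `(sheep_id, time)` pairs.}
#'     \item{occupancy_ticks}{agent-tick counts per behaviour state.}
#'     \item{end_time}{seconds simulated; `ended_early` is TRUE when the
#'       observer quit before `session_length`.}
#'   }
#' @examples
#' log <- run_session(behavior_config(session_length = 120), seed = 7)
#' head(log$events)
#' @export
run_session <- function(config, observer = NULL, seed = NULL) {
  validate_behavior_config(config)
  if (!is.null(observer)) validate_observer_config(observer, config)
  if (is.null(seed)) seed <- config$seed
  withr::with_seed(as.integer(seed),
                   run_session_impl(config, observer, as.integer(seed)))
}

run_session_impl <- function(config, observer, seed) {
  n <- config$flock_size
  tick <- config$tick
  n_ticks <- floor(config$session_length / tick + 1e-9)
  flock <- init_flock(config, seed = NULL)
  is_lame <- flock$status == "lame"

  # event buffer, grown by doubling
  cap <- max(64L, as.integer(n * (n_ticks * tick / 30) + 2L * n))
  ev_time <- numeric(cap); ev_id <- integer(cap); ev_ev <- character(cap)
  n_ev <- 0L
  push <- function(time, id, ev) {
    k <- length(id)
    if (n_ev + k > length(ev_id)) {
      grow <- max(length(ev_id), k)
      ev_time[length(ev_time) + grow] <<- 0
      ev_id[length(ev_id) + grow] <<- 0L
      ev_ev[length(ev_ev) + grow] <<- ""
    }
    idx <- n_ev + seq_len(k)
    ev_time[idx] <<- time; ev_id[idx] <<- id; ev_ev[idx] <<- ev
    n_ev <<- n_ev + k
  }
  push(0, seq_len(n), paste0("state_enter:", .states[flock$state]))

  marks <- mark_set()
  occupancy <- c(0, 0, 0)

  have_obs <- !is.null(observer)
  if (have_obs) {
    quit_tick <- if (is.null(observer$quit_time)) n_ticks else
      min(n_ticks, floor(observer$quit_time / tick + 1e-9))
    relocate_ticks <- max(1L, as.integer(round(observer$relocate_period / tick)))
    last_observed <- rep(-Inf, n)
    covered <- rep(FALSE, n)          # current walk bout fully in view so far
    view <- select_view(last_observed, marks$sheep_id, observer$attention,
                        seq_len(n))
    last_observed[view] <- 0
  } else {
    quit_tick <- n_ticks
  }

  for (t in seq_len(quit_tick)) {
    occupancy <- occupancy + tabulate(flock$state, 3L)
    flock <- step_flock(flock, config)
    tr <- flock$last_transitions
    if (length(tr$sheep_id)) {
      push(flock$clock, tr$sheep_id, paste0("state_enter:", .states[tr$to]))
    }
    if (have_obs) {
      res <- observe_tick(view, flock, observer, marks,
                          covered = covered, is_lame = is_lame)
      covered <- res$covered
      if (length(res$new_marks)) {
        push(flock$clock, res$new_marks, "marked_lame")
        marks <- res$marks
      }
      if (t %% relocate_ticks == 0L && t < quit_tick) {
        view <- select_view(last_observed, marks$sheep_id,
                            observer$attention, seq_len(n))
        covered <- covered & seq_len(n) %in% view
      }
      last_observed[view] <- flock$clock
    }
  }

  idx <- seq_len(n_ev)
  structure(
    list(
      config = config,
      observer = observer,
      seed = seed,
      status = flock$status,
      cue_leg = flock$cue_leg,
      events = data.frame(time = ev_time[idx], sheep_id = ev_id[idx],
                          event = ev_ev[idx], stringsAsFactors = FALSE),
      marks = marks,
      occupancy_ticks = stats::setNames(occupancy, .states),
      session_length = config$session_length,
      end_time = flock$clock,
      ended_early = flock$clock < config$session_length - 1e-9
    ),
    class = "session_log"
  )
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf(
    "<session_log> %d sheep (%d lame), %gs simulated%s, %d marks, seed %d\n",
    length(x$status), sum(x$status == "lame"), x$end_time,
    if (x$ended_early) " (quit early)" else "", length(x$marks$sheep_id),
    x$seed))
  invisible(x)
}

#' Empirical state occupancy of a simulated horizon
#'
#' Convenience wrapper used by the calibration checks: simulates an
#' unobserved flock for `minutes` of game time and returns the fraction of
#' agent-ticks spent in each behaviour state.
#'
#' @param config A [behavior_config()]; its `session_length` is overridden.
#' @param minutes Simulated horizon in minutes.
#' @param seed Integer seed.
#' @return Named fractions (graze, stand, walk) summing to 1, with the
#'   agent-tick count as attribute `"n_ticks"`.
#' @export
simulate_occupancy <- function(config, minutes, seed) {
  cfg <- config
  cfg$session_length <- minutes * 60
  log <- run_session(cfg, observer = NULL, seed = seed)
  counts <- log$occupancy_ticks
  structure(counts / sum(counts), n_ticks = sum(counts))
}

# JSON-lines serialization: one header record echoing the config and truth,
# then one record per event.
#' Write / read a session log as JSON lines
#'
#' The header line (`record = "header"`) echoes the behaviour and observer
#' configuration, the seed and the per-sheep ground truth; each subsequent
#' line is one event `(time, sheep_id, event)`.
#'
#' @param log A `session_log`.
#' @param path File path.
#' @return `write_session_log` returns `path` invisibly; `read_session_log`
#'   returns the reconstructed `session_log`.
#' @export
write_session_log <- function(log, path) {
  header <- list(
    record = "header",
    config = unclass(log$config),
    observer = if (is.null(log$observer)) NULL else unclass(log$observer),
    seed = log$seed,
    status = log$status,
    cue_leg = log$cue_leg,
    end_time = log$end_time,
    ended_early = log$ended_early,
    occupancy_ticks = as.list(log$occupancy_ticks)
  )
  lines <- c(
    jsonlite::toJSON(header, auto_unbox = TRUE, null = "null", digits = NA),
    vapply(seq_len(nrow(log$events)), function(i) {
      jsonlite::toJSON(list(record = "event",
                            time = log$events$time[i],
                            sheep_id = log$events$sheep_id[i],
                            event = log$events$event[i]),
                       auto_unbox = TRUE, digits = NA)
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("read_session_log: empty log file", call. = FALSE)
  parse_line <- function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) {
                      stop("read_session_log: parse error at line ", i, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    rec
  }
  header <- parse_line(1)
  if (!identical(header$record, "header")) {
    stop("read_session_log: parse error at line 1: missing header record",
         call. = FALSE)
  }
  events <- if (length(lines) > 1) {
    recs <- lapply(2:length(lines), parse_line)
    data.frame(
      time = vapply(recs, function(r) as.numeric(r$time), numeric(1)),
      sheep_id = vapply(recs, function(r) as.integer(r$sheep_id), integer(1)),
      event = vapply(recs, function(r) as.character(r$event), character(1)),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(time = numeric(0), sheep_id = integer(0),
               event = character(0), stringsAsFactors = FALSE)
  }
  cfg <- do.call(behavior_config, header$config)
  obs <- if (is.null(header$observer)) NULL else
    do.call(observer_config, c(header$observer, list(config = cfg)))
  mk <- events[events$event == "marked_lame", , drop = FALSE]
  structure(
    list(
      config = cfg,
      observer = obs,
      seed = as.integer(header$seed),
      status = as.character(header$status),
      cue_leg = as.character(header$cue_leg),
      events = events,
      marks = mark_set(mk$sheep_id, mk$time),
      occupancy_ticks = unlist(header$occupancy_ticks),
      session_length = cfg$session_length,
      end_time = as.numeric(header$end_time),
      ended_early = isTRUE(header$ended_early)
    ),
    class = "session_log"
  )
}
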