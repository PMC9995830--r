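#' Behaviour configuration for the virtual flock
#'
#' Bundles the activity-budget parameters of the simulated sheep: the long-run
#' fractions of time spent grazing, standing and walking, the mean bout
#' durations per state, the simulation tick, session length, flock size and
#' the per-sheep lameness probability. The defaults reproduce the game's
#' published activity budget (73% graze, 23.5% stand, 3.5% walk), a 24-sheep
#' flock, a 10-minute session and coin-flip lameness assignment.
#'
#' @param budget_graze,budget_stand,budget_walk Long-run occupancy fractions;
#'   must sum to 1 (within 1e-9).
#' @param mean_bout_graze,mean_bout_stand,mean_bout_walk Mean duration, in
#'   seconds, of a single exponential dwell segment in each state.
#' @param tick Simulation time step in seconds.
#' @param session_length Maximum session duration in seconds.
#' @param flock_size Number of sheep in the flock.
#' @param p_lame Probability that an individual sheep is lame at session start.
#' @param seed Default integer seed used when no seed is passed to a
#'   simulation function.
#'
#' @return An object of class `behavior_config` (a validated named list).
#' @seealso [stationary_budget()], [init_flock()], [run_session()]
#' @examples
#' cfg <- behavior_config()
#' stationary_budget(cfg)
#' @export
behavior_config <- function(budget_graze = 0.73,
                            budget_stand = 0.235,
                            budget_walk = 0.035,
                            mean_bout_graze = 60,
                            mean_bout_stand = 30,
                            mean_bout_walk = 10,
                            tick = 1,
                            session_length = 600,
                            flock_size = 24,
                            p_lame = 0.5,
                            seed = 1L) {
  cfg <- list(
    budget_graze = as.numeric(budget_graze),
    budget_stand = as.numeric(budget_stand),
    budget_walk = as.numeric(budget_walk),
    mean_bout_graze = as.numeric(mean_bout_graze),
    mean_bout_stand = as.numeric(mean_bout_stand),
    mean_bout_walk = as.numeric(mean_bout_walk),
    tick = as.numeric(tick),
    session_length = as.numeric(session_length),
    flock_size = as.integer(flock_size),
    p_lame = as.numeric(p_lame),
    seed = as.integer(seed)
  )
  class(cfg) <- "behavior_config"
  validate_behavior_config(cfg)
  cfg
}

validate_behavior_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("budget_graze", "budget_stand", "budget_walk",
              "mean_bout_graze", "mean_bout_stand", "mean_bout_walk",
              "tick", "session_length", "p_lame")) {
    if (!num1(cfg[[f]])) {
      stop("behavior_config: field '", f, "' must be a finite number",
           call. = FALSE)
    }
  }
  budgets <- c(cfg$budget_graze, cfg$budget_stand, cfg$budget_walk)
  if (any(budgets < 0)) {
    stop("behavior_config: field 'budget_*' values must be non-negative",
         call. = FALSE)
  }
  if (abs(sum(budgets) - 1) > 1e-9) {
    stop("behavior_config: fields 'budget_graze' + 'budget_stand' + ",
         "'budget_walk' must sum to 1 (got ", format(sum(budgets), digits = 12),
         ")", call. = FALSE)
  }
  for (f in c("mean_bout_graze", "mean_bout_stand", "mean_bout_walk")) {
    if (cfg[[f]] <= 0) {
      stop("behavior_config: field '", f, "' must be > 0", call. = FALSE)
    }
  }
  if (cfg$tick <= 0) {
    stop("behavior_config: field 'tick' must be > 0", call. = FALSE)
  }
  if (cfg$session_length <= 0) {
    stop("behavior_config: field 'session_length' must be > 0", call. = FALSE)
  }
  if (cfg$p_lame < 0 || cfg$p_lame > 1) {
    stop("behavior_config: field 'p_lame' must lie in [0, 1]", call. = FALSE)
  }
  if (is.na(cfg$flock_size) || cfg$flock_size < 1L) {
    stop("behavior_config: field 'flock_size' must be >= 1", call. = FALSE)
  }
  if (is.na(cfg$seed)) {
    stop("behavior_config: field 'seed' must be an integer", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.behavior_config <- function(x, ...) {
  cat("<behavior_config>\n")
  cat(sprintf("  budgets (graze/stand/walk): %.3f / %.3f / %.3f\n",
              x$budget_graze, x$budget_stand, x$budget_walk))
  cat(sprintf("  mean bouts (s):             %g / %g / %g\n",
              x$mean_bout_graze, x$mean_bout_stand, x$mean_bout_walk))
  cat(sprintf("  tick %gs, session %gs, flock %d, p_lame %.2f, seed %d\n",
              x$tick, x$session_length, x$flock_size, x$p_lame, x$seed))
  invisible(x)
}

# Internal state bookkeeping: states are integer-coded 1 = graze, 2 = stand,
# 3 = walk throughout the engine.
.states <- c("graze", "stand", "walk")

budget_vec <- function(cfg) {
  c(cfg$budget_graze, cfg$budget_stand, cfg$budget_walk)
}

mean_bout_vec <- function(cfg) {
  c(cfg$mean_bout_graze, cfg$mean_bout_stand, cfg$mean_bout_walk)
}

#' Entry distribution of the behaviour chain
#'
#' The engine renews behaviour in exponential dwell segments; at every segment
#' expiry the next state is drawn from a fixed entry distribution
#' `q[s] = (budget[s] / mean_bout[s]) / sum(budget / mean_bout)`, independent
#' of the current state. A draw equal to the current state silently extends
#' the ongoing bout (by exponential memorylessness the realized bout remains
#' exponential), so the logged transition kernel has no self-transitions and
#' equals `q` renormalized over the two other states, while the stationary
#' occupancy equals the configured budgets exactly.
#'
#' @param config A [behavior_config()].
#' @return Numeric length-3 probability vector named graze/stand/walk.
#' @keywords internal
entry_distribution <- function(config) {
  r <- budget_vec(config) / mean_bout_vec(config)
  q <- r / sum(r)
  names(q) <- .states
  q
}

#' Closed-form stationary activity budget
#'
#' Analytic long-run occupancy of the configured semi-Markov behaviour chain:
#' occupancy is proportional to the entry rate into each state times its mean
#' dwell, `occupancy[s] ~ q[s] * mean_bout[s]`, normalized to 1. Because the
#' entry distribution is constructed from the configured budgets (see
#' [entry_distribution()]) this closed form reproduces them; it is the
#' analytic anchor that the Monte-Carlo occupancy tests are checked against.
#'
#' @param config A [behavior_config()].
#' @return Named numeric vector of occupancy fractions (graze, stand, walk)
#'   summing to 1.
#' @examples
#' stationary_budget(behavior_config())
#' @export
stationary_budget <- function(config) {
  validate_behavior_config(config)
  occ <- entry_distribution(config) * mean_bout_vec(config)
  occ <- occ / sum(occ)
  names(occ) <- .states
  occ
}
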