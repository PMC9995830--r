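#' Specification for a synthetic participant cohort
#'
#' Describes how to generate a cohort table with the statistical structure
#' of the study population: questionnaire covariates with realistic
#' marginals, time played spanning 1.45–10 minutes, and a recall score that
#' is either produced mechanistically (each row is a simulated player with
#' the shipped default observer) or statistically (a linear model on the
#' arcsine square-root scale with a planted Cohen's f-squared, or a null).
#'
#' @param mode `"statistical"` or `"mechanistic"`.
#' @param planted_f2 Effect size of the time-played-on-recall relationship
#'   in statistical mode; 0 plants a null. Ignored in mechanistic mode.
#' @param linked_covariate Covariate driving recall in statistical mode.
#' @param n Number of participants (>= 10); default 63, the study's size.
#' @param seed Integer seed.
#' @param sigma Residual standard deviation on the arcsine scale.
#' @param intercept Mean transformed recall at the covariate mean
#'   (defaults to `asin(sqrt(0.5))`, i.e. 50% recall).
#' @param covariate_profile Named list overriding any of the default
#'   covariate distribution parameters (see Details).
#'
#' @details Overridable `covariate_profile` entries and defaults:
#' `p_experience = 0.5` (about half the cohort has farming experience);
#' `years_meanlog = log(10)`, `years_sdlog = 0.75` (log-normal years with
#' sheep, median 10, experienced rows only); `prevalence_levels` /
#' `prevalence_probs` (mode "5-10%"); `sign_rate_experienced = 0.65` and
#' `sign_rate_inexperienced = 0.45` (per-sign look-for probabilities);
#' `time_range = c(1.45, 10)` minutes (uniform); `p_control_problems = 0.3`.
#' Engagement categories are uniform over their levels.
#'
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(mode = c("statistical", "mechanistic"),
                        planted_f2 = 0,
                        linked_covariate = "time_played",
                        n = 63,
                        seed = 1L,
                        sigma = 0.18,
                        intercept = asin(sqrt(0.5)),
                        covariate_profile = list()) {
  mode <- match.arg(mode)
  profile <- utils::modifyList(default_covariate_profile(), covariate_profile)
  spec <- structure(
    list(mode = mode,
         planted_f2 = as.numeric(planted_f2),
         linked_covariate = linked_covariate,
         n = as.integer(n),
         seed = as.integer(seed),
         sigma = as.numeric(sigma),
         intercept = as.numeric(intercept),
         covariate_profile = profile),
    class = "effect_spec"
  )
  validate_effect_spec(spec)
  spec
}

validate_effect_spec <- function(spec) {
  if (spec$planted_f2 < 0) {
    stop("effect_spec: field 'planted_f2' must be >= 0", call. = FALSE)
  }
  if (is.na(spec$n) || spec$n < 10L) {
    stop("effect_spec: field 'n' must be >= 10", call. = FALSE)
  }
  if (!spec$linked_covariate %in% setdiff(cohort_columns()$name,
                                          c("accuracy", "recall"))) {
    stop("effect_spec: field 'linked_covariate' ('", spec$linked_covariate,
         "') is not a cohort covariate", call. = FALSE)
  }
  if (spec$sigma <= 0) {
    stop("effect_spec: field 'sigma' must be > 0", call. = FALSE)
  }
  invisible(spec)
}

default_covariate_profile <- function() {
  list(
    p_experience = 0.5,
    years_meanlog = log(10),
    years_sdlog = 0.75,
    prevalence_levels = c("<5%", "5-10%", ">10%"),
    prevalence_probs = c(0.3, 0.5, 0.2),
    sign_rate_experienced = 0.65,
    sign_rate_inexperienced = 0.45,
    time_range = c(1.45, 10),
    p_control_problems = 0.3,
    times_played_levels = c("0", "1", "2-5", "6-10", ">10"),
    observing_levels = c("systematic scan", "followed movement", "unsystematic"),
    moving_levels = c("stationary", "perimeter", "through flock", "mixed"),
    tutorial_levels = c("completed", "partial", "skipped"),
    device_levels = c("mouse", "trackpad", "touchscreen")
  )
}

#' Draw the covariate block of a synthetic cohort
#'
#' Generates every cohort column except the scores (left `NA`): farming
#' experience, years with sheep, perceived lameness prevalence band, the
#' nine looked-for lameness-sign indicators (more often looked for by
#' experienced rows), engagement covariates, and time played.
#'
#' @param spec An [effect_spec()].
#' @param seed Optional seed overriding `spec$seed`.
#' @return A cohort data frame of `spec$n` rows (see [cohort_columns()]).
#' @export
sample_covariates <- function(spec, seed = NULL) {
  validate_effect_spec(spec)
  if (is.null(seed)) seed <- spec$seed
  withr::with_seed(as.integer(seed), sample_covariates_impl(spec))
}

sample_covariates_impl <- function(spec) {
  p <- spec$covariate_profile
  n <- spec$n
  exper <- stats::runif(n) < p$p_experience
  years <- rep(NA_real_, n)
  years[exper] <- round(stats::rlnorm(sum(exper), p$years_meanlog,
                                      p$years_sdlog), 1)
  prev <- rep(NA_character_, n)
  prev[exper] <- sample(p$prevalence_levels, sum(exper), replace = TRUE,
                        prob = p$prevalence_probs)
  sign_rate <- ifelse(exper, p$sign_rate_experienced,
                      p$sign_rate_inexperienced)
  draw_sign <- function() stats::runif(n) < sign_rate
  df <- data.frame(
    participant_id = seq_len(n),
    farming_experience = exper,
    years_with_sheep = years,
    lameness_prevalence_band = prev,
    sign_uneven_posture = draw_sign(),
    sign_shortened_stride = draw_sign(),
    sign_quickened_opposite = draw_sign(),
    sign_head_nod = draw_sign(),
    sign_limp = draw_sign(),
    sign_raised_leg = draw_sign(),
    sign_reluctance_to_move = draw_sign(),
    sign_grazing_on_knees = draw_sign(),
    sign_other = stats::runif(n) < 0.15,
    times_played_before = sample(p$times_played_levels, n, replace = TRUE),
    control_problems = stats::runif(n) < p$p_control_problems,
    observing_type = sample(p$observing_levels, n, replace = TRUE),
    moving_type = sample(p$moving_levels, n, replace = TRUE),
    tutorial_completed = sample(p$tutorial_levels, n, replace = TRUE),
    pointing_device = sample(p$device_levels, n, replace = TRUE),
    time_played = stats::runif(n, p$time_range[1], p$time_range[2]),
    accuracy = NA_real_,
    recall = NA_real_,
    stringsAsFactors = FALSE
  )
  df
}

#' Generate a complete synthetic cohort
#'
#' In statistical mode, recall is generated on the arcsine square-root scale
#' as `y = intercept + beta * (x - mean(x)) + eps`, `eps ~ N(0, sigma^2)`,
#' with `beta` set so that the realized noncentrality of the single-predictor
#' F test equals `planted_f2 * n` — the same convention as [solve_f2()] — and
#' back-transformed to a percentage (clamped to `[0, 100]`, with a warning if
#' more than 5% of rows clamp). Accuracy is drawn as a negatively skewed,
#' mostly-above-50% distribution, matching how engaged (non-"shotgun")
#' players score. In mechanistic mode each row is a full [simulate_player()]
#' run with the shipped [default_observer()], quitting at its `time_played`.
#'
#' @param spec An [effect_spec()].
#' @param config A [behavior_config()] (mechanistic mode only).
#' @return A cohort data frame; deterministic given `spec` (and `config`).
#' @examples
#' cohort <- generate_cohort(effect_spec(planted_f2 = 0.21, seed = 9))
#' cor(cohort$time_played, cohort$recall)
#' @export
generate_cohort <- function(spec, config = behavior_config()) {
  validate_effect_spec(spec)
  cohort <- sample_covariates(spec)
  if (spec$mode == "statistical") {
    withr::with_seed(spec$seed + 1L, {
      x <- cohort[[spec$linked_covariate]]
      if (!is.numeric(x)) {
        stop("generate_cohort: statistical mode needs a continuous ",
             "linked_covariate (got '", spec$linked_covariate, "')",
             call. = FALSE)
      }
      ss_x <- sum((x - mean(x))^2)
      beta <- if (spec$planted_f2 > 0) {
        spec$sigma * sqrt(spec$planted_f2 * spec$n / ss_x)
      } else 0
      y <- spec$intercept + beta * (x - mean(x)) +
        stats::rnorm(spec$n, 0, spec$sigma)
      clamped <- y < 0 | y > pi / 2
      if (mean(clamped) > 0.05) {
        warning("generate_cohort: ", round(100 * mean(clamped)),
                "% of rows clamped to [0, 100]; effect/noise specification ",
                "may be unrealistic", call. = FALSE)
      }
      y <- pmin(pi / 2, pmax(0, y))
      cohort$recall <- 100 * sin(y)^2
      a <- pmin(pi / 2, pmax(0, stats::rnorm(spec$n, 1.25, 0.22)))
      cohort$accuracy <- 100 * sin(a)^2
    })
  } else {
    withr::with_seed(spec$seed + 1L, {
      session_seeds <- sample.int(.Machine$integer.max - 1L, spec$n)
    })
    for (i in seq_len(spec$n)) {
      quit_s <- min(round(cohort$time_played[i] * 60), config$session_length)
      obs <- default_observer(config, quit_time = quit_s)
      rec <- simulate_player(config, obs, seed = session_seeds[i],
                             participant_id = i)
      cohort$time_played[i] <- rec$time_played
      cohort$accuracy[i] <- rec$accuracy
      cohort$recall[i] <- rec$recall
    }
  }
  cohort
}
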