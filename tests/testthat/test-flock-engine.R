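test_that("behavior_config validates fields and names the offender", {
  expect_s3_class(behavior_config(), "behavior_config")
  expect_error(behavior_config(budget_graze = 0.8), "budget")
  expect_error(behavior_config(p_lame = 1.2), "p_lame")
  expect_error(behavior_config(mean_bout_walk = 0), "mean_bout_walk")
  expect_error(behavior_config(tick = -1), "tick")
  expect_error(behavior_config(flock_size = 0), "flock_size")
  expect_error(behavior_config(session_length = 0), "session_length")
})

test_that("stationary_budget returns the configured budgets in closed form", {
  eq <- behavior_config(budget_graze = 1 / 3, budget_stand = 1 / 3,
                        budget_walk = 1 / 3, mean_bout_graze = 20,
                        mean_bout_stand = 20, mean_bout_walk = 20)
  expect_equal(unname(stationary_budget(eq)), rep(1 / 3, 3))
  expect_equal(unname(stationary_budget(behavior_config())),
               c(0.73, 0.235, 0.035))
  # entry distribution weights budget/mean_bout
  q <- woolsim:::entry_distribution(behavior_config())
  r <- c(0.73 / 60, 0.235 / 30, 0.035 / 10)
  expect_equal(unname(q), r / sum(r))
})

test_that("lameness assignment respects degenerate probabilities and cues", {
  all_lame <- init_flock(behavior_config(p_lame = 1), seed = 1)
  expect_true(all(all_lame$status == "lame"))
  expect_true(all(all_lame$cue_leg %in%
                    c("front-left", "front-right", "hind-left", "hind-right")))
  expect_true(all(all_lame$cue_quickened_opposite))
  expect_true(all(all_lame$cue_head_nod >= 0 & all_lame$cue_head_nod <= 1))

  none_lame <- init_flock(behavior_config(p_lame = 0), seed = 1)
  expect_true(all(none_lame$status == "healthy"))
  expect_true(all(is.na(none_lame$cue_leg)))
  expect_true(all(is.na(none_lame$cue_head_nod)))
})

test_that("mean lame fraction over many seeds matches the coin-flip rate", {
  cfg <- behavior_config()
  frac <- vapply(1:2000, function(s) {
    mean(init_flock(cfg, seed = s)$status == "lame")
  }, numeric(1))
  # SE of the mean fraction = sqrt(0.25/24)/sqrt(2000) ~ 0.23%
  expect_lt(abs(mean(frac) - 0.5), 0.01)
})

test_that("lame counts are Binomial(flock_size, p_lame)", {
  cfg <- behavior_config()
  counts <- vapply(1:10000, function(s) {
    sum(init_flock(cfg, seed = s)$status == "lame")
  }, numeric(1))
  # chi-squared GOF against Binomial(24, 0.5), tails pooled
  probs <- dbinom(0:24, 24, 0.5)
  bins <- pmin(pmax(0:24, 7), 17)
  expected <- tapply(probs, bins, sum)
  observed <- table(factor(pmin(pmax(counts, 7), 17), levels = names(expected)))
  stat <- sum((observed - 10000 * expected)^2 / (10000 * expected))
  expect_lt(stat, qchisq(0.99, length(expected) - 1))
})

test_that("a bout in progress just counts down; pure-graze budgets trap", {
  cfg <- behavior_config()
  flock <- make_flock(c("healthy", "lame"), state = c(3L, 1L),
                      bout = c(2, 50))
  set.seed(1)
  stepped <- step_flock(flock, cfg)
  expect_identical(stepped$state, flock$state)
  expect_equal(stepped$bout_remaining, c(1, 49))
  expect_equal(stepped$clock, 1)
  expect_length(stepped$last_transitions$sheep_id, 0)

  graze_only <- behavior_config(budget_graze = 1, budget_stand = 0,
                                budget_walk = 0)
  f <- init_flock(graze_only, seed = 2)
  expect_true(all(f$state == 1L))
  set.seed(3)
  for (i in 1:500) f <- step_flock(f, graze_only)
  expect_true(all(f$state == 1L))
})

test_that("status is immutable across stepping and session end", {
  cfg <- behavior_config(session_length = 120)
  f <- init_flock(cfg, seed = 4)
  before <- f$status
  set.seed(5)
  for (i in 1:120) f <- step_flock(f, cfg)
  expect_identical(f$status, before)
  expect_error(step_flock(f, cfg), "session over")
})

test_that("unobserved sessions span the full clock with zero marks", {
  cfg <- behavior_config(session_length = 600)
  log <- run_session(cfg, observer = NULL, seed = 6)
  expect_equal(log$end_time, 600)
  expect_false(log$ended_early)
  expect_length(log$marks$sheep_id, 0)
  expect_equal(sum(log$occupancy_ticks), 600 * 24)
  expect_true(all(diff(log$events$time) >= 0))
  # initial states logged at time 0 for every sheep
  expect_equal(sum(log$events$time == 0), 24)
})

test_that("identical seeds reproduce sessions exactly", {
  cfg <- behavior_config(session_length = 300)
  obs <- default_observer(cfg, quit_time = 240)
  a <- run_session(cfg, observer = obs, seed = 7)
  b <- run_session(cfg, observer = obs, seed = 7)
  expect_identical(a, b)
  c <- run_session(cfg, observer = obs, seed = 8)
  expect_false(identical(a$events, c$events))
})

test_that("session logs round-trip through JSON lines", {
  cfg <- behavior_config(session_length = 180)
  obs <- default_observer(cfg, quit_time = 150)
  log <- run_session(cfg, observer = obs, seed = 9)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_session_log(log, path)
  back <- read_session_log(path)
  expect_identical(back$events, log$events)
  expect_identical(back$status, log$status)
  expect_equal(back$marks$sheep_id, log$marks$sheep_id)
  expect_equal(back$config, log$config)
  expect_error(read_session_log(withr::local_tempfile(lines = "{}")),
               "line 1")
})

test_that("Monte-Carlo occupancy matches the analytic budget at 3 sigma", {
  configs <- list(
    behavior_config(),
    behavior_config(budget_graze = 0.5, budget_stand = 0.3,
                    budget_walk = 0.2, mean_bout_graze = 40,
                    mean_bout_stand = 25, mean_bout_walk = 15),
    behavior_config(budget_graze = 0.1, budget_stand = 0.6,
                    budget_walk = 0.3, mean_bout_graze = 12,
                    mean_bout_stand = 80, mean_bout_walk = 7)
  )
  for (cfg in configs) {
    per_seed <- t(vapply(1:8, function(s) {
      as.numeric(simulate_occupancy(cfg, minutes = 60, seed = 100 + s))
    }, numeric(3)))
    mc <- colMeans(per_seed)
    se <- apply(per_seed, 2, sd) / sqrt(nrow(per_seed))
    expect_true(all(abs(mc - stationary_budget(cfg)) < 3 * se + 1e-12),
                info = paste("budgets", paste(round(mc, 4), collapse = "/")))
  }
})
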