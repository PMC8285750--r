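test_that("spawned targets stay inside the spawn area and balance direction", {
  cfg <- task_config()
  params <- level_params(default_table(), 1)
  set.seed(11)
  draws <- do.call(rbind, lapply(1:10000, function(i)
    spawn_target(cfg, params)))
  expect_true(all(draws$azimuth_deg >= -60 & draws$azimuth_deg <= 60))
  expect_true(all(draws$elevation_deg >= -50 & draws$elevation_deg <= 50))
  # binomial: 0.5 +/- ~4 sd at n = 1e4
  expect_lt(abs(mean(draws$direction == 1) - 0.5), 0.02)
  expect_identical(unique(draws$speed_deg_s), params$speed)
  expect_identical(unique(draws$lifetime_s), params$lifetime)
  # hemispace tie-break: negative azimuth is left, zero or positive right
  expect_true(all((draws$azimuth_deg < 0) == (draws$hemispace == "left")))
  # determinism under seeding
  set.seed(99); a <- spawn_target(cfg, params)
  set.seed(99); b <- spawn_target(cfg, params)
  expect_identical(a, b)
})

test_that("the patient speed floor overrides the level-1 speed", {
  cfg <- task_config(speed_floor_override = 0.1)
  tab <- default_table()
  set.seed(1)
  r1 <- run_round(fast_agent(), cfg, tab, level = 1)
  expect_equal(unique(r1$events$speed_deg_s), 0.1)
  # the per-level delta still applies on top of the override
  r3 <- run_round(fast_agent(), cfg, tab, level = 3)
  expect_equal(unique(r3$events$speed_deg_s), 0.1 + 2 * 2.36)
})

test_that("target trials follow the closed-form response model", {
  agent <- agent_profile(base_latency = 0.4, scan_speed = 30,
                         aim_time = 0.1, noise_sigma = 0)
  res <- simulate_target_trial(agent, make_target(30))
  expect_true(res$found)
  expect_equal(res$search_time_s, 1.5)
  # symmetric at zero bias
  res_l <- simulate_target_trial(agent, make_target(-30))
  expect_equal(res_l$search_time_s, 1.5)
  # left-hemispace penalty factor is exact
  biased <- agent_profile(base_latency = 0.4, scan_speed = 30,
                          aim_time = 0.1, noise_sigma = 0,
                          lateral_bias = 0.5, bias_gain = 2)
  res_b <- simulate_target_trial(biased, make_target(-30))
  expect_equal(res_b$search_time_s, 3.0)
  # right hemispace untouched by the bias
  expect_equal(simulate_target_trial(biased, make_target(30))$search_time_s,
               1.5)
  # misses carry no search time
  miss <- simulate_target_trial(hopeless_agent(), make_target(10))
  expect_false(miss$found)
  expect_true(is.na(miss$search_time_s))
})

test_that("left search time grows monotonically with the bias, right is flat", {
  lambdas <- seq(0, 1, by = 0.2)
  left <- vapply(lambdas, function(l) {
    a <- agent_profile(0.4, 30, 0.1, noise_sigma = 0, lateral_bias = l,
                       bias_gain = 2)
    # lifetime long enough that the trial always resolves as found
    simulate_target_trial(a, make_target(-30, lifetime = 100))$search_time_s
  }, numeric(1))
  right <- vapply(lambdas, function(l) {
    a <- agent_profile(0.4, 30, 0.1, noise_sigma = 0, lateral_bias = l,
                       bias_gain = 2)
    simulate_target_trial(a, make_target(30, lifetime = 100))$search_time_s
  }, numeric(1))
  expect_true(all(diff(left) > 0))
  expect_equal(right, rep(1.5, length(lambdas)))
})

test_that("rounds conserve targets and sequence spawns by ISI", {
  cfg <- task_config()
  tab <- default_table()
  set.seed(3)
  rec <- run_round(fast_agent(), cfg, tab, level = 1)
  expect_equal(nrow(rec$events), 30L)
  expect_equal(rec$outcome$n_found + sum(!rec$events$found), 30)
  expect_equal(rec$outcome$n_found, 30) # deterministic fast agent
  # each spawn = previous resolution + isi
  ev <- rec$events
  dwell <- ifelse(ev$found, ev$search_time_s, ev$lifetime_s)
  expect_equal(ev$spawn_time_s[-1],
               (ev$spawn_time_s + dwell + cfg$isi)[-nrow(ev)])
  # an agent that can never respond in time finds nothing
  set.seed(4)
  rec0 <- run_round(hopeless_agent(), cfg, tab, level = 1)
  expect_equal(rec0$outcome$n_found, 0)
  expect_true(all(is.na(rec0$events$search_time_s)))
})

test_that("session level trajectories follow the switching rule", {
  tab <- default_table()
  # ever-successful agent: promotion every round, clamped at 15
  s_up <- run_session(fast_agent(), task_config(starting_level = 8L),
                      tab, seed = 5, hand_trace = FALSE)
  expect_identical(s_up$level_trajectory,
                   c(8:15, 15L, 15L))
  # hopeless agent: demotion every round, clamped at 1
  s_down <- run_session(hopeless_agent(), task_config(starting_level = 3L),
                        tab, seed = 6, hand_trace = FALSE)
  expect_identical(s_down$level_trajectory,
                   c(3L, 2L, rep(1L, 8)))
  # every consecutive pair satisfies the next_level relation
  set.seed(7)
  s_mid <- run_session(agent_profile(0.5, 15, 0.3, noise_sigma = 0.4),
                       task_config(starting_level = 5L), tab,
                       hand_trace = FALSE)
  for (r in seq_len(length(s_mid$rounds) - 1)) {
    out <- s_mid$rounds[[r]]$outcome
    expect_identical(
      s_mid$level_trajectory[r + 1],
      next_level(tab, s_mid$level_trajectory[r],
                 percent_found(out$n_found, out$n_targets)))
  }
  # conservation in every round
  for (rr in s_mid$rounds) {
    expect_equal(rr$outcome$n_found + sum(!rr$events$found),
                 task_config()$targets_per_round)
  }
})

test_that("zero-bias agents search both hemispaces equally fast", {
  agent <- agent_profile(0.4, 35, 0.3, noise_sigma = 0.3)
  cfg <- task_config(n_rounds = 67L, starting_level = 1L) # 2010 targets
  s <- run_session(agent, cfg, seed = 21, hand_trace = FALSE)
  ev <- s$events
  expect_gte(nrow(ev), 2000)
  l <- ev$search_time_s[ev$found & ev$hemispace == "left"]
  r <- ev$search_time_s[ev$found & ev$hemispace == "right"]
  se <- sqrt(var(l) / length(l) + var(r) / length(r))
  expect_lt(abs(mean(l) - mean(r)), 3 * se)
})

test_that("stationary agents settle at a balance point", {
  cfg <- task_config(n_rounds = 30L, starting_level = 5L)
  profiles <- list(
    agent_profile(0.4, 40, 0.35, noise_sigma = 0.3),
    agent_profile(0.5, 30, 0.25, noise_sigma = 0.6),
    agent_profile(0.5, 15, 0.3, noise_sigma = 0))
  for (i in seq_along(profiles)) {
    s <- run_session(profiles[[i]], cfg, seed = 30 + i,
                     hand_trace = FALSE)
    t10 <- tail(s$level_trajectory, 10)
    expect_lte(max(t10) - min(t10), 2)
  }
})

test_that("hand traces stay in the workspace and mirror the bias", {
  cfg <- task_config(n_rounds = 3L, starting_level = 1L)
  s0 <- run_session(agent_profile(0.4, 35, 0.3, noise_sigma = 0.2), cfg,
                    seed = 41)
  expect_true(all(abs(s0$hand_trace$x_m) <= 1))
  expect_true(all(abs(s0$hand_trace$y_m) <= 1))
  expect_lt(abs(mean(s0$hand_trace$x_m)), 0.05) # symmetric at zero bias
  s9 <- run_session(agent_profile(0.8, 10, 0.4, noise_sigma = 0.2,
                                  lateral_bias = 0.9), cfg, seed = 42)
  expect_gt(mean(s9$hand_trace$x_m), 0) # rightward shift under neglect
  # empty sessions yield empty traces
  empty <- structure(list(events = data.frame(),
                          agent = agent_profile()),
                     class = "session_record")
  expect_equal(nrow(generate_hand_trace(empty)), 0L)
})

test_that("cohort generation is sized, seeded, and parameterized correctly", {
  spec <- young_cohort(n = 21)
  a <- generate_cohort(spec, seed = 8, hand_trace = FALSE)
  expect_length(a, 21)
  b <- generate_cohort(spec, seed = 8, hand_trace = FALSE)
  expect_equal(a, b) # same master seed, identical cohort
  ng <- generate_cohort(neglect_cohort(n = 6, lateral_bias = c(0.1, 0.9)),
                        seed = 9, hand_trace = FALSE)
  lam <- vapply(ng, function(s) s$metadata$lateral_bias, numeric(1))
  expect_true(all(lam > 0.1 & lam < 0.9))
  # neglect sessions carry a simulated CoC and the patient config
  expect_true(all(vapply(ng, function(s) is.numeric(s$metadata$coc),
                         logical(1))))
  expect_equal(ng[[1]]$config$speed_floor_override, 0.1)
  expect_error(cohort_spec(5, "x", base_latency = c(2, 1), scan_speed = 10,
                           aim_time = 0.1, noise_sigma = 0),
               "min > max")
})
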