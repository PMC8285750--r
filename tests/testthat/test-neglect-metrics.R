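test_that("the default sheet has the standard counts and symmetric layout", {
  sh <- default_sheet()
  expect_equal(nrow(sh$targets), 40L)
  expect_equal(nrow(sh$distractors), 240L)
  # left-right mirror symmetry of the target columns about the center
  devs <- sort(sh$targets$x - sh$width / 2)
  expect_equal(devs, -rev(devs))
})

test_that("CoC is 0 for full marking, +1 for rightmost-only, and bounded", {
  sh <- default_sheet()
  expect_equal(coc(sh, seq_len(40))$coc, 0)
  rightmost <- which(sh$targets$x == max(sh$targets$x))
  expect_equal(coc(sh, rightmost)$coc, 1)
  leftmost <- which(sh$targets$x == min(sh$targets$x))
  expect_equal(coc(sh, leftmost)$coc, -1)
  set.seed(13)
  for (i in 1:200) {
    marks <- sample(40, sample(1:40, 1))
    v <- coc(sh, marks)$coc
    expect_gte(v, -1); expect_lte(v, 1)
  }
  expect_error(coc(sh, integer(0)), "undefined")
  expect_error(coc(sh, c(1, 1)), "unique")
  expect_error(coc(sh, 41), "valid")
})

test_that("adding a mark right of the current CoC never decreases it", {
  sh <- default_sheet()
  xt_order <- order(sh$targets$x)
  set.seed(17)
  for (i in 1:50) {
    marks <- sample(40, sample(1:30, 1))
    v <- coc(sh, marks)$coc
    # candidate marks strictly to the right of the current mean
    cand <- setdiff(which((sh$targets$x - sh$width / 2) >
                            v * (max(sh$targets$x) - sh$width / 2)),
                    marks)
    if (length(cand) > 0) {
      expect_gte(coc(sh, c(marks, cand[1]))$coc, v)
    }
  }
})

test_that("unbiased marking has zero expected CoC", {
  sh <- default_sheet()
  set.seed(19)
  vals <- replicate(10000, {
    marks <- which(runif(40) < 0.5)
    if (length(marks) == 0) marks <- sample(40, 1)
    coc(sh, marks)$coc
  })
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)))
})

test_that("the 0.081 classification boundary is inclusive", {
  # sheet built so a single mark sits exactly at normalized 81/1000
  targets <- data.frame(x = c(0, 1081, 2000), y = c(10, 10, 10))
  sh <- cancellation_sheet(targets, data.frame(x = numeric(0),
                                               y = numeric(0)),
                           width = 2000, height = 20)
  at_cut <- coc(sh, 2L)
  expect_equal(at_cut$coc, 0.081)
  expect_true(at_cut$significant_left_neglect)
  expect_false(coc(sh, 1L)$significant_left_neglect) # coc -1
  expect_true(coc(sh, 3L)$significant_left_neglect)  # coc +1
})

test_that("simulated cancellation omits leftward targets as bias grows", {
  sh <- default_sheet()
  set.seed(23)
  expect_equal(sort(simulate_cancellation(0, sh)), 1:40) # p = 1 everywhere
  # lambda = 1: leftmost column never marked, CoC pushed rightward
  m1 <- simulate_cancellation(1, sh)
  expect_false(any(sh$targets$x[m1] == min(sh$targets$x)))
  expect_gt(coc(sh, m1)$coc, 0)
  # median CoC is non-decreasing in lambda over Monte-Carlo replicates
  med <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(l) {
    stats::median(replicate(200, coc(sh, simulate_cancellation(l, sh))$coc))
  }, numeric(1))
  expect_true(all(diff(med) >= 0))
  expect_error(simulate_cancellation(1.2), "\\[0, 1\\]")
})

test_that("search-time means exclude misses and split by hemispace", {
  ev <- data.frame(
    hemispace = c("left", "left", "right", "right", "left"),
    found = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    search_time_s = c(1, 2, 3, NA, NA))
  expect_equal(mean_search_time(ev), 2)
  expect_equal(hemispace_search_times(ev), c(left = 1.5, right = 3))
  # hemispace with no found target reports NA, not an error
  ev2 <- ev[ev$hemispace == "right", ]
  expect_equal(hemispace_search_times(ev2), c(left = NA_real_, right = 3))
  ev3 <- transform(ev, found = FALSE, search_time_s = NA_real_)
  expect_error(mean_search_time(ev3), "no found targets")
})

test_that("deterministic session means match the closed-form oracle", {
  agent <- agent_profile(0.5, 20, 0.2, noise_sigma = 0,
                         lateral_bias = 0.4, bias_gain = 2)
  s <- run_session(agent, task_config(n_rounds = 2L, starting_level = 1L),
                   seed = 29, hand_trace = FALSE)
  ev <- s$events[s$events$found, ]
  expected <- vapply(ev$azimuth_deg, function(a)
    oracle_search_time(agent, a), numeric(1))
  expect_equal(mean(ev$search_time_s), mean(expected))
  hemi <- hemispace_search_times(s)
  expect_equal(unname(hemi["left"]),
               mean(expected[ev$azimuth_deg < 0]))
  # mirrored pairs: the left mean is exactly (1 + gain * lambda) times
  # the right mean for targets at mirrored azimuths
  lt <- simulate_target_trial(agent, make_target(-25, lifetime = 100))
  rt <- simulate_target_trial(agent, make_target(25, lifetime = 100))
  expect_equal(lt$search_time_s / rt$search_time_s, 1 + 2 * 0.4)
})

test_that("severity recovery links CoC to left-hemispace slowing", {
  rec <- severity_recovery(n = 20, seed = 1)
  expect_gt(rec$r_left$r, 0)
  expect_gt(rec$r_left$r, rec$r_right$r)
  expect_equal(nrow(rec$metrics), 20L)
  expect_true(all(rec$metrics$lateral_bias > 0.1 &
                    rec$metrics$lateral_bias < 0.9))
})
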