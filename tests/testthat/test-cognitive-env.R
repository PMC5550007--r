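test_that("trial timings reconstruct the published totals", {
  rt <- trial_timing("realtime")
  x2 <- trial_timing("x2")
  x6 <- trial_timing("x6")
  for (tm in list(rt, x2, x6))
    expect_equal(tm$total_s, tm$select_s + tm$stimulus_s + tm$delay_s +
                   tm$feedback_s + tm$wait_s)
  expect_equal(c(rt$total_s, x2$total_s, x6$total_s), c(20, 13, 8))
  expect_equal(unlist(rt[2:6], use.names = FALSE), c(3, 6, 6, 2, 3))
})

test_that("intermittent time-to-target follows the stated formula", {
  expect_equal(time_to_target_intermittent(1), 15)
  expect_equal(time_to_target_intermittent(3), 55)
  expect_error(time_to_target_intermittent(0), ">= 1")
})

test_that("block schedules satisfy the stated target counts", {
  cont <- build_block_schedule("continuous", seed = 1)
  expect_equal(unique(cont$filter[cont$block == 1]), "impulse")
  expect_setequal(cont$filter, c("impulse", "hrf", "blur", "delay"))
  for (b in 1:4) {
    blk <- cont[cont$block == b, ]
    expect_equal(blk$target[1:3], c(45, 90, 135))
    expect_true(all(blk$visible[1:3]))
    hidden <- table(blk$target[!blk$visible])
    expect_equal(sum(hidden), 14)
    expect_lte(max(hidden) - min(hidden), 1)
  }
  inter <- build_block_schedule("intermittent", seed = 2)
  expect_equal(nrow(inter), 63)
  expect_equal(max(inter$block), 7)
  per_ori <- table(inter$target)
  expect_lte(max(per_ori) - min(per_ori), 1)
  expect_equal(as.vector(table(inter$filter)), rep(21, 3))
  expect_identical(build_block_schedule("intermittent", seed = 2), inter)
})

test_that("an omniscient agent succeeds at the earliest possible check", {
  s <- run_continuous_search(agent_jump_to_target(45), 45, "impulse",
                             noisefree_model, mini_classifier8, seed = 1)
  expect_true(s$success)
  expect_equal(s$n_tr, 3)
  expect_equal(s$time_to_target_s, 6)
})

test_that("a motionless agent never reaches an orthogonal target", {
  # grating stays at 0; target 90 deg away pins feedback at 1/16 < 0.85
  s <- run_continuous_search(agent_hold_still(), 90, "impulse",
                             noisefree_model, mini_classifier8, max_tr = 30,
                             seed = 1)
  expect_false(s$success)
  expect_true(all(abs(s$per_tr$orientation) < 1e-9))
  expect_true(all(s$per_tr$feedback < 0.85))
})

test_that("continuous searches are deterministic given the seed", {
  s1 <- run_continuous_search(agent_greedy(), 90, "hrf", mini_model,
                              mini_classifier8, max_tr = 40, seed = 5)
  s2 <- run_continuous_search(agent_greedy(), 90, "hrf", mini_model,
                              mini_classifier8, max_tr = 40, seed = 5)
  expect_identical(s1$per_tr, s2$per_tr)
})

test_that("rotation kinematics leave orientation unchanged without a command", {
  # one TR with a hold-still agent: per-TR orientation equals the start
  s <- run_continuous_search(agent_hold_still(), 0, "impulse",
                             noisefree_model, mini_classifier8, max_tr = 3,
                             seed = 1)
  expect_true(s$success)  # target is the start orientation
  expect_equal(s$per_tr$orientation, rep(0, 3))
})

test_that("under the impulse filter feedback has no temporal mixing", {
  # TR-wise feedback equals the noise-free feedback of the TR-mean
  # orientation when spontaneous activity is off
  s <- run_continuous_search(agent_greedy(), 67.5, "impulse",
                             noisefree_model, mini_classifier8, max_tr = 15,
                             seed = 6)
  for (i in seq_len(nrow(s$per_tr))) {
    want <- cognitive_feedback(
      predict_proba(mini_classifier8,
                    stimulus_pattern(noisefree_model, s$per_tr$orientation[i])),
      67.5)
    expect_equal(s$per_tr$feedback[i], want, tolerance = 1e-9)
  }
})

test_that("binary-search agents find noise-free targets within the log bound", {
  bound <- ceiling(log2(8)) + 1
  for (target in seq(0, 157.5, by = 22.5)) {
    s <- run_intermittent_search(agent_binary_search(), target, "delay",
                                 noisefree_model, mini_classifier8,
                                 max_trials = 10, seed = 7)
    expect_true(s$success)
    expect_lte(s$n_trials, bound)
  }
})

test_that("a target-selecting agent succeeds on the first noise-free trial", {
  s <- run_intermittent_search(agent_fixed_orientation(45), 45, "delay",
                               noisefree_model, mini_classifier8, seed = 8)
  expect_true(s$success)
  expect_equal(s$n_trials, 1)
  expect_equal(s$time_to_target_s, 15)
})

test_that("acceleration factors change bookkeeping but not trial scores", {
  runs <- lapply(c("realtime", "x2", "x6"), function(acc) {
    run_intermittent_search(agent_binary_search(), 112.5, "hrf", mini_model,
                            mini_classifier8, timing = trial_timing(acc),
                            max_trials = 12, seed = 9)
  })
  expect_identical(runs[[1]]$per_trial, runs[[2]]$per_trial)
  expect_identical(runs[[1]]$per_trial, runs[[3]]$per_trial)
  expect_equal(runs[[1]]$elapsed_s / runs[[1]]$n_trials, 20)
  expect_equal(runs[[3]]$elapsed_s / runs[[3]]$n_trials, 8)
  expect_error(run_intermittent_search(agent_fixed_orientation(0), 0,
                                       "impulse", mini_model,
                                       mini_classifier8, seed = 1), "impulse")
})
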