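# Expanded-sum reference implementation of the continuous learning rule: keeps
# the full activity history and evaluates the lagged sums explicitly, serving
# as the independent oracle for both the stepwise functions and the engine.
reference_continuous <- function(classifier, target_class, h, m, alpha, a_s) {
  n_steps <- ncol(a_s)
  V <- nrow(a_s)
  a_hist <- matrix(0, V, n_steps)
  a_c <- numeric(V)
  f_prev <- 1 / classifier$n_classes
  f_out <- numeric(n_steps)
  for (n in seq_len(n_steps)) {
    a_hist[, n] <- a_s[, n] + a_c
    p <- numeric(V)
    for (j in seq_along(h)) if (n - j + 1 >= 1) p <- p + h[j] * a_hist[, n - j + 1]
    f <- unname(predict_proba(classifier, p)[target_class])
    l <- f - f_prev
    credited <- numeric(V)
    for (j in seq_along(m)) if (n - j + 1 >= 1)
      credited <- credited + m[j] * a_hist[, n - j + 1]
    a_c <- a_c + alpha * l * credited
    f_prev <- f
    f_out[n] <- f
  }
  list(f = f_out, a_c = a_c)
}

test_that("stepwise, expanded-sum and engine implementations agree exactly", {
  set.seed(31)
  cl <- mini_classifier3
  V <- mini_model$n_voxels
  a_s <- matrix(rnorm(V * 40, 0, 0.5), V, 40)
  h <- make_filter("hrf")$weights
  m <- make_filter("blur")$weights
  ref <- reference_continuous(cl, 1, h, m, alpha = 0.05, a_s)
  # stepwise buffer implementation
  st <- learner_state(V, 3)
  for (n in 1:40)
    st <- step_continuous(st, cl, 1, "hrf", "blur", 0.05, a_s = a_s[, n])
  expect_equal(st$f_history, ref$f, tolerance = 1e-12)
  expect_equal(st$a_c, ref$a_c, tolerance = 1e-12)
  # compiled engine with the same supplied noise
  res <- neurofb:::condition_batch(cl, 1, "hrf", "blur", "continuous",
                                   n_steps = 40, reps = 1, alpha = 0.05,
                                   noise = a_s, keep_patterns = TRUE)
  expect_equal(as.numeric(res$f), ref$f, tolerance = 1e-12)
  expect_equal(as.numeric(res$final_patterns), ref$a_c, tolerance = 1e-12)
})

test_that("impulse-impulse continuous learning reduces to the undelayed rule", {
  set.seed(32)
  a_s <- matrix(rnorm(2 * 30, 0, 0.25), 2, 30)
  cl <- two_voxel_classifier()
  s1 <- learner_state(2, 2)
  s2 <- learner_state(2, 2)
  for (n in 1:30) {
    s1 <- step_impulse(s1, cl, 1, alpha = 1, a_s = a_s[, n])
    s2 <- step_continuous(s2, cl, 1, "impulse", "impulse", 1, a_s = a_s[, n])
  }
  expect_identical(s1$f_history, s2$f_history)
  expect_identical(s1$a_c, s2$a_c)
})

test_that("a single undelayed step matches the closed-form arithmetic", {
  # a = (1,-1), f_prev = 0.5: l = softmax(2,-2) - 0.5, increment l * a
  st <- learner_state(2, 2)
  st <- step_impulse(st, two_voxel_classifier(), 1, alpha = 1, a_s = c(1, -1))
  l <- exp(2) / (exp(2) + exp(-2)) - 0.5
  expect_equal(st$a_c, c(l, -l), tolerance = 1e-12)
  expect_equal(l, 0.482, tolerance = 1e-3)
})

test_that("intermittent trials gate conditioned activity on the cue", {
  set.seed(33)
  cl <- mini_classifier3
  V <- mini_model$n_voxels
  # engine vs stepwise on supplied noise
  n_trials <- 12
  a_s <- matrix(rnorm(V * 6 * n_trials, 0, 0.5), V)
  st <- learner_state(V, 3)
  for (k in seq_len(n_trials))
    st <- run_intermittent_trial(st, cl, 1, "hrf", 0.05,
                                 a_s = a_s[, (k - 1) * 6 + 1:6])
  res <- neurofb:::condition_batch(cl, 1, "hrf", schedule = "intermittent",
                                   n_steps = n_trials, reps = 1, alpha = 0.05,
                                   noise = a_s, keep_patterns = TRUE)
  expect_equal(as.numeric(res$f), st$f_history, tolerance = 1e-12)
  expect_equal(as.numeric(res$final_patterns), st$a_c, tolerance = 1e-12)
  # zero learning signal leaves a_c unchanged: feed a trial engineered to
  # reproduce the previous feedback exactly (identical noise both trials)
  st0 <- learner_state(V, 3)
  trial_noise <- matrix(rnorm(V * 6, 0, 0.5), V, 6)
  st1 <- run_intermittent_trial(st0, cl, 1, "hrf", 0.5, a_s = trial_noise)
  st1$a_c <- numeric(V)  # reset conditioning so the trial replays identically
  st2 <- run_intermittent_trial(st1, cl, 1, "hrf", 0.5, a_s = trial_noise)
  expect_equal(st2$a_c, numeric(V))
  # conditioned activity is present only during cue TRs: in the noise-free
  # limit the decoded output outside cue windows stays at baseline
  stq <- learner_state(V, 3)
  stq$a_c <- stimulus_pattern(mini_model, 10)
  trial <- run_intermittent_trial(stq, cl, 1, "delay", 0, a_s = matrix(0, V, 6))
  # delay filter: wait TR 6 sees lag-3 activity = cue TR 3 (gated on);
  # a trial with zero cue gating would stay at chance -- verify via impulse
  # physio, whose wait TRs see only the (zero) wait activity
  trial0 <- run_intermittent_trial(stq, cl, 1, "impulse", 0,
                                   a_s = matrix(0, V, 6))
  baseline <- unname(predict_proba(cl, numeric(V))[1])  # softmax of intercepts
  expect_equal(tail(trial0$f_history, 1), baseline, tolerance = 1e-9)
  expect_gt(tail(trial$f_history, 1), baseline)
})

test_that("zero learning rate is exactly stationary", {
  cur <- run_two_voxel_demo("impulse", "impulse", n_steps = 200, reps = 100,
                            alpha = 0, seed = 34)
  expect_equal(mean(cur$f), 0.5, tolerance = 0.01)
  expect_true(all(cur$final_patterns == 0))
})

test_that("feedback climbs monotonically to its ceiling on a pure signal", {
  # spontaneous activity replaced by a fixed copy of the target pattern
  cl <- two_voxel_classifier()
  a_s <- matrix(rep(c(1, -1), 30), 2, 30)
  st <- learner_state(2, 2)
  for (n in 1:30) st <- step_impulse(st, cl, 1, alpha = 1, a_s = a_s[, n])
  expect_true(all(diff(st$f_history) >= 0))     # saturates at the ceiling
  expect_true(all(diff(st$f_history[1:5]) > 0)) # strictly rising before it
  expect_gt(tail(st$f_history, 1), 0.99)
})

test_that("experiments are reproducible and sized by the stated conventions", {
  c1 <- run_two_voxel_demo("hrf", "hrf", n_steps = 50, reps = 20, seed = 35)
  c2 <- run_two_voxel_demo("hrf", "hrf", n_steps = 50, reps = 20, seed = 35)
  expect_identical(c1$f, c2$f)
  expect_identical(c1$final_patterns, c2$final_patterns)
  # 1 simulated hour: 1800 TRs continuous (alpha 0.001/TR), 180 trials
  # intermittent (alpha 0.01/trial)
  cont <- run_conditioning_experiment(mini_model, mini_classifier3, 10,
                                      "impulse", "impulse", "continuous",
                                      hours = 0.05, reps = 5, seed = 36)
  expect_equal(nrow(cont$f), 0.05 * 1800)
  expect_equal(cont$time_s[2] - cont$time_s[1], 2)
  inter <- run_conditioning_experiment(mini_model, mini_classifier3, 10,
                                       "hrf", schedule = "intermittent",
                                       hours = 0.05, reps = 5, seed = 36)
  expect_equal(nrow(inter$f), 0.05 * 180)
  expect_equal(inter$chance, 1 / 3)
  expect_error(run_conditioning_experiment(mini_model, mini_classifier3, 10,
                                           "hrf", schedule = "continuous",
                                           hours = 0.05, reps = 2, seed = 1),
               "internal model")
  expect_error(run_conditioning_experiment(mini_model, mini_classifier3, 33,
                                           "hrf", "hrf", hours = 0.05,
                                           reps = 2, seed = 1),
               "class orientation")
})

test_that("learning-curve aggregation and smoothing behave", {
  cur <- run_two_voxel_demo("impulse", "impulse", n_steps = 100, reps = 50,
                            seed = 37)
  expect_true(all(cur$ci25 <= cur$mean + 1e-12))
  expect_true(all(cur$mean <= cur$ci75 + 1e-12))
  sm <- smooth_learning_curve(cur, window_s = 20)
  expect_equal(length(sm$mean), length(cur$mean))
  expect_lt(sd(diff(sm$mean)), sd(diff(cur$mean)))
})
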