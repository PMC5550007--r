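#' Intermittent trial timings
#'
#' Component durations of one intermittent feedback trial under each
#' acceleration factor. Real-time trials take 20 s (3 s orientation selection,
#' 6 s stimulus, 6 s physiological delay, 2 s feedback, 3 s inter-trial wait);
#' the accelerated protocols shorten the stimulus, delay and wait periods
#' (totals 13 s and 8 s) while the trial-by-trial feedback signal is still
#' simulated according to the real-time protocol, so acceleration changes
#' bookkeeping durations only, never the feedback values.
#'
#' @param acceleration `"realtime"`, `"x2"` or `"x6"`.
#' @return List with `acceleration`, `select_s`, `stimulus_s`, `delay_s`,
#'   `feedback_s`, `wait_s` and `total_s`.
#' @export
trial_timing <- function(acceleration = c("realtime", "x2", "x6")) {
  acceleration <- match.arg(acceleration)
  p <- switch(acceleration,
    realtime = c(3, 6, 6, 2, 3),
    x2 = c(3, 3, 3, 2, 2),
    x6 = c(3, 1, 1, 2, 1))
  list(acceleration = acceleration, select_s = p[1], stimulus_s = p[2],
       delay_s = p[3], feedback_s = p[4], wait_s = p[5], total_s = sum(p))
}

#' Time-to-target for intermittent searches
#'
#' Converts a trial count to the equivalent real-time search duration:
#' 20 s per trial minus a 5 s cost (no wait period before the first trial,
#' 3 s, and success registers at the feedback period, 2 s before trial end).
#'
#' @param n_trials Number of trials needed to reach the target (>= 1).
#' @return Seconds.
#' @export
time_to_target_intermittent <- function(n_trials) {
  if (any(n_trials < 1)) stop("n_trials must be >= 1")
  20 * n_trials - 5
}

#' Target/filter schedules for a cognitive session
#'
#' Continuous sessions: four blocks, one per physiological filter, the impulse
#' block always first (familiarization) and the other three counterbalanced;
#' each block opens with three visible training targets at 45, 90 and 135
#' degrees followed by 14 hidden targets drawn as evenly as possible across
#' the eight class orientations (counts differ by at most 1), in random
#' order. Intermittent sessions: seven blocks of nine targets (63 total),
#' again spread evenly over the orientations, each target randomly assigned
#' one of the three capturable filters (hrf, delay, blur) in equal
#' proportion.
#'
#' @param mode `"continuous"` or `"intermittent"`.
#' @param seed Optional seed for the counterbalancing.
#' @return A data frame with columns `block`, `filter`, `trial`, `target`,
#'   `visible`.
#' @export
build_block_schedule <- function(mode = c("continuous", "intermittent"),
                                 seed = NULL) {
  mode <- match.arg(mode)
  orients <- seq(0, 157.5, by = 22.5)
  with_seed_if(seed, {
    if (mode == "continuous") {
      filters <- c("impulse", sample(c("hrf", "blur", "delay")))
      do.call(rbind, lapply(seq_along(filters), function(b) {
        targets <- c(45, 90, 135, sample(rep(orients, length.out = 14)))
        data.frame(block = b, filter = filters[b], trial = seq_along(targets),
                   target = targets, visible = seq_along(targets) <= 3)
      }))
    } else {
      n_targets <- 63
      targets <- sample(rep(orients, length.out = n_targets))
      filt <- sample(rep(c("hrf", "delay", "blur"), length.out = n_targets))
      data.frame(block = rep(1:7, each = 9), filter = filt,
                 trial = rep(1:9, 7), target = targets,
                 visible = seq_len(n_targets) <= 3)
    }
  })
}

# signed angular difference to rotate `from` onto `to` on the 180-deg circle
signed_orientation_step <- function(from, to) {
  d <- (to - from) %% 180
  ifelse(d > 90, d - 180, d)
}

circular_mean_orientation <- function(theta) {
  # period-180 data: double the angles, average on the circle, halve
  r <- theta * pi / 90
  (atan2(mean(sin(r)), mean(cos(r))) * 90 / pi) %% 180
}

#' Run a continuous-feedback target search
#'
#' Simulates one target search under continuous feedback with a pluggable
#' agent standing in for the participant. The grating starts horizontal (0
#' degrees); at each control tick the agent returns a rotation command in
#' \{-1, 0, +1\} and the grating rotates at `rotation_dps` degrees per second
#' (opposing commands cancel, so 0 leaves it in place). Every TR the circular
#' mean orientation over the TR (computed on doubled angles, as orientation is
#' periodic with period 180) stimulates the model, spontaneous activity is
#' added, the physiological filter is applied to the accumulated activity
#' history, the pattern is decoded, and [cognitive_feedback()] is scored
#' against the target. The search ends when [check_success()] fires (checked
#' every TR) or after `max_tr` TRs.
#'
#' @param agent Continuous agent: `function(feedback_history, orientation,
#'   elapsed_tr)` returning -1, 0 or +1.
#' @param target Target orientation (one of the classifier's classes).
#' @param filter Physiological filter.
#' @param model An `nf_voxel_model`.
#' @param classifier The 8-way cognitive `nf_classifier`.
#' @param max_tr Give up after this many TRs.
#' @param threshold Success threshold for [check_success()].
#' @param rotation_dps Rotation rate while a key is held (deg/s).
#' @param control_hz Agent control rate (ticks per second; any rate of at
#'   least one tick per TR is accepted).
#' @param seed Optional seed for the spontaneous activity.
#' @return An `nf_session`: `per_tr` data frame (`tr`, `orientation`,
#'   `feedback`), decoded probabilities `probs`, `success`, `n_tr`,
#'   `time_to_target_s` (NA if the target was not reached), plus the setup.
#' @export
run_continuous_search <- function(agent, target, filter, model, classifier,
                                  max_tr = 300, threshold = 0.85,
                                  rotation_dps = 45, control_hz = 60,
                                  seed = NULL) {
  filter <- as_nf_filter(filter)
  stopifnot(control_hz * filter$tr_seconds >= 1)
  ori_classes <- classifier$class_orientations
  with_seed_if(seed, {
    nf <- noise_sampler(model)
    orientation <- 0
    ticks_per_tr <- round(control_hz * filter$tr_seconds)
    step_deg <- rotation_dps / control_hz
    fb <- numeric(0)
    tr_orient <- numeric(0)
    probs_log <- matrix(NA_real_, max_tr, classifier$n_classes)
    buffer <- matrix(0, filter$L + 1, model$n_voxels)
    success <- FALSE
    n_tr <- max_tr
    for (tr in seq_len(max_tr)) {
      tick_orients <- numeric(ticks_per_tr)
      for (t in seq_len(ticks_per_tr)) {
        cmd <- agent(fb, orientation, tr - 1L)
        orientation <- (orientation + sign(cmd) * step_deg) %% 180
        tick_orients[t] <- orientation
      }
      mean_ori <- circular_mean_orientation(tick_orients)
      a <- stimulus_pattern(model, mean_ori) + drop(nf(1))
      buffer <- rbind(a, buffer[-nrow(buffer), , drop = FALSE])
      p <- drop(crossprod(buffer, head_weights(filter, tr)))
      pr <- predict_proba(classifier, p)
      score <- cognitive_feedback(pr, target, ori_classes)
      fb <- c(fb, score)
      tr_orient <- c(tr_orient, mean_ori)
      probs_log[tr, ] <- pr
      if (check_success(fb, threshold)) { success <- TRUE; n_tr <- tr; break }
    }
    structure(list(
      per_tr = data.frame(tr = seq_along(fb), orientation = tr_orient,
                          feedback = fb),
      probs = probs_log[seq_along(fb), , drop = FALSE],
      success = success, n_tr = n_tr,
      time_to_target_s = if (success) n_tr * filter$tr_seconds else NA_real_,
      target = target, filter = filter$kind, mode = "continuous"),
      class = "nf_session")
  })
}

head_weights <- function(filter, tr) {
  w <- filter$weights
  if (tr <= filter$L) w[seq_len(filter$L + 1) > tr] <- 0  # pre-session zeros
  w
}

#' Run an intermittent-feedback target search
#'
#' One target search under intermittent feedback: each trial the agent selects
#' a grating orientation (standing in for the 3-s selection period), the trial
#' score is computed by [intermittent_feedback_score()], and the search
#' succeeds when the score strictly exceeds the threshold. The acceleration
#' timing affects only the recorded durations -- trial scores are identical
#' across acceleration factors for the same seed.
#'
#' @param agent Intermittent agent: `function(history)` receiving the data
#'   frame of previous trials (`orientation`, `score`) and returning the next
#'   orientation.
#' @param timing A [trial_timing()] list.
#' @param max_trials Give up after this many trials.
#' @inheritParams run_continuous_search
#' @return An `nf_session` with a `per_trial` data frame (`trial`,
#'   `orientation`, `score`, `success`), `n_trials`, `success`,
#'   `time_to_target_s` (by [time_to_target_intermittent()]), and
#'   `elapsed_s` under the chosen acceleration.
#' @export
run_intermittent_search <- function(agent, target, filter, model, classifier,
                                    timing = trial_timing("realtime"),
                                    max_trials = 50, threshold = 0.85,
                                    seed = NULL) {
  filter <- as_nf_filter(filter)
  if (filter$kind == "impulse")
    stop("the impulse response is not captured by the intermittent feedback ",
         "calculation (no stimulus signal remains in the post-stimulus window)")
  with_seed_if(seed, {
    hist <- data.frame(trial = integer(), orientation = numeric(),
                       score = numeric(), success = logical())
    success <- FALSE
    for (k in seq_len(max_trials)) {
      orientation <- agent(hist)
      score <- intermittent_feedback_score(model, classifier, filter,
                                           orientation, target)
      success <- score > threshold
      hist <- rbind(hist, data.frame(trial = k, orientation = orientation,
                                     score = score, success = success))
      if (success) break
    }
    structure(list(
      per_trial = hist, success = success, n_trials = nrow(hist),
      time_to_target_s = if (success) time_to_target_intermittent(nrow(hist))
                         else NA_real_,
      elapsed_s = nrow(hist) * timing$total_s,
      timing = timing, target = target, filter = filter$kind,
      mode = "intermittent"), class = "nf_session")
  })
}

#' @export
print.nf_session <- function(x, ...) {
  cat("<nf_session> ", x$mode, ", filter ", x$filter, ", target ", x$target,
      " deg\n", sep = "")
  if (x$mode == "continuous")
    cat("  ", x$n_tr, " TRs, success: ", x$success, "\n", sep = "")
  else
    cat("  ", x$n_trials, " trials, success: ", x$success, "\n", sep = "")
  if (!is.na(x$time_to_target_s))
    cat("  time to target: ", x$time_to_target_s, " s\n", sep = "")
  invisible(x)
}
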