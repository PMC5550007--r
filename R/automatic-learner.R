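#' Initialize the state of the automatic learner
#'
#' The automatic learner conditions spontaneous activity: total activity is
#' `a = a_s + a_c`, where `a_s` is fresh spontaneous activity each TR and
#' `a_c` is conditioned activity accumulated by rewarding or punishing past
#' activity with changes in the decoded feedback signal `l[n] = f[n] - f[n-1]`.
#' The feedback baseline `f_prev` starts at chance (`1/n_classes`) so the
#' first learning signal is the deviation from chance and a zero learning rate
#' is exactly stationary.
#'
#' @param n_voxels Number of voxels.
#' @param n_classes Number of decoder classes (sets the chance level).
#' @param buffer_length Number of past TRs of activity kept in memory (at
#'   least the support of the physiological and internal filters).
#' @return An object of class `nf_learner_state`: fields `a_c`, `f_prev`,
#'   `buffer` (rows = most recent TRs of total activity), `f_history`, `tr`.
#' @export
learner_state <- function(n_voxels, n_classes, buffer_length = 15) {
  structure(list(a_c = numeric(n_voxels), f_prev = 1 / n_classes,
                 buffer = matrix(0, buffer_length, n_voxels),
                 f_history = numeric(0), tr = 0L),
            class = "nf_learner_state")
}

buffer_weighted_sum <- function(buffer, weights, tr) {
  # buffer row 1 = current TR, row j+1 = lag j; lags before session start are 0
  usable <- min(length(weights), tr)
  out <- numeric(ncol(buffer))
  for (j in seq_len(usable)) out <- out + weights[j] * buffer[j, ]
  out
}

#' Single TR of continuous automatic learning
#'
#' Advances the learner by one TR under a physiological response `physio` and
#' an internal model `internal`: draw (or accept) spontaneous activity, form
#' total activity `a = a_s + a_c`, filter the activity history with `physio`
#' to obtain the measured pattern, decode the target-class probability `f`,
#' and update the conditioned activity with the learning signal times the
#' internally-weighted memory of past activity:
#' `a_c <- a_c + alpha * (f - f_prev) * sum_j m[j] a[n-j]`.
#' The conditioned increment accumulates across TRs; saturation emerges as the
#' feedback approaches its ceiling and the learning signal shrinks, not from
#' any clipping.
#'
#' With impulse filters for both `physio` and `internal` this reduces to the
#' undelayed learning rule ([step_impulse()]).
#'
#' @param state An `nf_learner_state`.
#' @param classifier An `nf_classifier`.
#' @param target_class Column index of the target class in the classifier.
#' @param physio,internal Filters (`nf_filter` or kind strings).
#' @param alpha Learning rate per TR.
#' @param a_s Spontaneous activity for this TR; drawn from `sigma` if omitted.
#' @param sigma Spontaneous-activity SD used when `a_s` is not supplied
#'   (i.i.d. Gaussian; pass a pre-drawn `a_s` for other noise models).
#' @return The updated `nf_learner_state`.
#' @export
step_continuous <- function(state, classifier, target_class, physio, internal,
                            alpha, a_s = NULL, sigma = NULL) {
  physio <- as_nf_filter(physio); internal <- as_nf_filter(internal)
  V <- length(state$a_c)
  if (is.null(a_s)) {
    stopifnot(!is.null(sigma))
    a_s <- rnorm(V, 0, sigma)
  }
  a <- a_s + state$a_c
  if (nrow(state$buffer) < max(physio$L, internal$L) + 1)
    stop("learner buffer shorter than the filter support")
  state$buffer <- rbind(a, state$buffer[-nrow(state$buffer), , drop = FALSE])
  state$tr <- state$tr + 1L
  p <- buffer_weighted_sum(state$buffer, physio$weights, state$tr)
  f <- unname(predict_proba(classifier, p)[target_class])
  l <- f - state$f_prev
  credited <- buffer_weighted_sum(state$buffer, internal$weights, state$tr)
  state$a_c <- state$a_c + alpha * l * credited
  state$f_prev <- f
  state$f_history <- c(state$f_history, f)
  state
}

#' Single TR of undelayed (impulse) automatic learning
#'
#' The base reinforcement rule with no physiological delay and no internal
#' model: feedback is instantaneous to the underlying activity and the current
#' activity itself is credited, `a_c <- a_c + alpha * (f - f_prev) * a`.
#'
#' @inheritParams step_continuous
#' @return The updated `nf_learner_state`.
#' @export
step_impulse <- function(state, classifier, target_class, alpha, a_s = NULL,
                         sigma = NULL) {
  step_continuous(state, classifier, target_class, make_filter("impulse"),
                  make_filter("impulse"), alpha, a_s, sigma)
}

#' One intermittent (cue-gated) conditioning trial
#'
#' In intermittent conditioning a cue gates the conditioned activity: during
#' the cue TRs total activity is `a_s + a_c`, outside the cue it is `a_s`
#' alone. The trial feedback is the mean target-class probability of the
#' physiologically filtered activity over the wait TRs, and the trial-level
#' learning signal `l[k] = f[k] - f[k-1]` reinforces the mean cue-period
#' activity: `a_c <- a_c + alpha * l[k] * a_bar`. Physiological carryover is
#' reset between trials (the real-time protocol's return-to-baseline wait
#' exists precisely to justify this).
#'
#' @inheritParams step_continuous
#' @param physio Physiological filter.
#' @param cue_tr,wait_tr Cue and wait durations in TRs.
#' @param a_s Spontaneous activity for the whole trial, voxels x
#'   `(cue_tr + wait_tr)`; drawn from `sigma` if omitted.
#' @return The updated `nf_learner_state` (`f_history` gains the trial score).
#' @export
run_intermittent_trial <- function(state, classifier, target_class, physio,
                                   alpha, a_s = NULL, sigma = NULL,
                                   cue_tr = 3, wait_tr = 3) {
  physio <- as_nf_filter(physio)
  V <- length(state$a_c)
  n_tr <- cue_tr + wait_tr
  if (is.null(a_s)) {
    stopifnot(!is.null(sigma))
    a_s <- matrix(rnorm(V * n_tr, 0, sigma), V, n_tr)
  }
  A <- a_s
  A[, seq_len(cue_tr)] <- A[, seq_len(cue_tr)] + state$a_c
  p <- apply_filter(t(A), physio)                    # TRs x voxels
  wait_idx <- cue_tr + seq_len(wait_tr)
  probs <- predict_proba(classifier, t(p[wait_idx, , drop = FALSE]))
  fk <- mean(probs[, target_class])
  l <- fk - state$f_prev
  a_bar <- rowMeans(A[, seq_len(cue_tr), drop = FALSE])
  state$a_c <- state$a_c + alpha * l * a_bar
  state$f_prev <- fk
  state$f_history <- c(state$f_history, fk)
  state$tr <- state$tr + as.integer(n_tr)
  state
}

# Vectorized Monte-Carlo engine: all replicates advance in lockstep inside
# compiled code (src/conditioning.cpp), including the spontaneous-activity
# generation, which runs on an explicit 64-bit seed. `noise` is either a
# spec from engine_noise_spec() or a pre-drawn voxels x (reps * TRs) matrix
# (columns replicate-fastest) for exact equivalence tests.
condition_batch <- function(classifier, target_class, physio, internal = NULL,
                            schedule = c("continuous", "intermittent"),
                            n_steps, reps, alpha, noise,
                            cue_tr = 3, wait_tr = 3, keep_patterns = FALSE) {
  schedule <- match.arg(schedule)
  physio <- as_nf_filter(physio)
  if (is.matrix(noise)) {
    spec <- list(type = 3L, seed = 0)
    supplied <- noise
  } else {
    spec <- noise
    supplied <- matrix(0, 0, 0)
  }
  m_w <- if (schedule == "continuous") as_nf_filter(internal)$weights
         else numeric(0)
  cc_run(classifier$W, classifier$intercepts, target_class, physio$weights,
         m_w, if (schedule == "continuous") 0L else 1L, as.integer(n_steps),
         as.integer(reps), alpha, as.integer(cue_tr), as.integer(wait_tr),
         spec, supplied, keep_patterns)
}

# Noise specification handed to the engine. The engine seed is drawn from R's
# RNG so that experiment-level seeding governs it.
engine_noise_spec <- function(model_or_sigma, seed = NULL) {
  engine_seed <- with_seed_if(seed, sample.int(.Machine$integer.max, 1))
  if (is.numeric(model_or_sigma))
    return(list(type = 0L, sigma = model_or_sigma, seed = engine_seed))
  model <- model_or_sigma
  sigma <- model$noise_sigma
  if (sigma == 0 || model$noise_kind == "iid")
    return(list(type = 0L, sigma = sigma, seed = engine_seed))
  if (model$noise_kind == "grf") {
    gk <- grf_scale_and_kernels(model)
    ks <- gk$kernels
    while (length(ks) < 3) ks <- c(ks, list(matrix(1, 1, 1)))
    list(type = 1L, seed = engine_seed, K1 = ks[[1]],
         K2kron = kronecker(ks[[2]], diag(nrow(ks[[1]]))), K3 = ks[[3]],
         mult = sigma / gk$scale)
  } else {
    tuned <- which(model$tuning_assignment > 0)
    pref <- model$tuned_orientations[model$tuning_assignment[tuned]]
    ew <- (15 / 16) / log(16)
    ew2 <- (255 / 256) / (2 * log(16))
    list(type = 2L, seed = engine_seed, g_sd = sigma / sqrt(2),
         c_mix = sigma / sqrt(2 * (ew2 - ew^2)), tuned = tuned - 1L,
         pref = pref)
  }
}

#' Run a Monte-Carlo automatic conditioning experiment
#'
#' Simulates many independent learners ("simulated participants") under one
#' condition of the conditioning grid: a physiological response, and either a
#' continuous schedule with an internal temporal model or an intermittent
#' cue-gated schedule (3-TR cue, 3-TR wait, one feedback per 20-s trial).
#' The learning rate is specified per 20 s of simulated time, giving
#' `alpha_per_20s * tr/20` per TR for continuous feedback and `alpha_per_20s`
#' per trial for intermittent feedback. Five simulated hours correspond to
#' 9000 TRs (continuous) or 900 trials (intermittent).
#'
#' Replicates are simulated in lockstep from a single seeded stream; results
#' are reproducible given `(seed, reps)`.
#'
#' @param model An `nf_voxel_model` supplying the spontaneous-activity
#'   distribution.
#' @param classifier An `nf_classifier` trained on the model's patterns.
#' @param target Target class: an orientation in degrees if the classifier has
#'   class orientations, otherwise a column index.
#' @param physio Physiological response filter.
#' @param internal Internal model filter (continuous schedule only).
#' @param schedule `"continuous"` or `"intermittent"`.
#' @param hours Simulated duration in hours.
#' @param reps Number of simulated participants.
#' @param alpha_per_20s Learning rate per 20 s of simulated time.
#' @param tr_seconds TR in seconds.
#' @param keep_patterns Keep the final conditioned pattern of every replicate
#'   (voxels x reps matrix) for pattern-correlation analysis.
#' @param seed Optional seed (the engine's own generator is seeded from it).
#' @return An `nf_learning_curve`: `time_s`, `mean`, `ci25`/`ci75` (the 50%
#'   confidence band, i.e. 25th-75th percentile across replicates), the full
#'   per-replicate feedback matrix `f`, `chance`, the condition description,
#'   and `final_patterns` when requested.
#' @export
run_conditioning_experiment <- function(model, classifier, target, physio,
                                        internal = NULL,
                                        schedule = c("continuous", "intermittent"),
                                        hours = 5, reps = 1000,
                                        alpha_per_20s = 0.01, tr_seconds = 2,
                                        keep_patterns = FALSE, seed = NULL) {
  schedule <- match.arg(schedule)
  physio <- as_nf_filter(physio, tr_seconds)
  target_class <- match_target_class(classifier, target)
  if (schedule == "continuous") {
    if (is.null(internal)) stop("continuous conditioning requires an internal model")
    n_steps <- round(hours * 3600 / tr_seconds)
    alpha <- alpha_per_20s * tr_seconds / 20
    step_s <- tr_seconds
  } else {
    n_steps <- round(hours * 3600 / 20)
    alpha <- alpha_per_20s
    step_s <- 20
  }
  spec <- engine_noise_spec(model, seed)
  res <- condition_batch(classifier, target_class, physio,
                         if (!is.null(internal)) as_nf_filter(internal, tr_seconds),
                         schedule, n_steps, reps, alpha, spec,
                         keep_patterns = keep_patterns)
  new_learning_curve(res$f, step_s, 1 / classifier$n_classes,
                     condition = list(
                       physio = physio$kind,
                       internal = if (schedule == "continuous")
                         as_nf_filter(internal)$kind else "cue",
                       schedule = schedule, hours = hours, reps = reps,
                       alpha_per_20s = alpha_per_20s, target = target),
                     final_patterns = res$final_patterns)
}

match_target_class <- function(classifier, target) {
  ori <- classifier$class_orientations
  if (!is.null(ori)) {
    k <- which(circular_orientation_distance(ori, target) < 1e-9)
    if (length(k) != 1) stop("target (", target,
                             " deg) is not a classifier class orientation")
    k
  } else {
    stopifnot(target %in% seq_len(classifier$n_classes))
    as.integer(target)
  }
}

new_learning_curve <- function(f, step_s, chance, condition, final_patterns = NULL) {
  structure(list(
    time_s = seq_len(nrow(f)) * step_s,
    mean = rowMeans(f),
    ci25 = apply(f, 1, quantile, 0.25, names = FALSE),
    ci75 = apply(f, 1, quantile, 0.75, names = FALSE),
    f = f, chance = chance, condition = condition,
    final_patterns = final_patterns), class = "nf_learning_curve")
}

#' @export
print.nf_learning_curve <- function(x, ...) {
  cond <- x$condition
  cat("<nf_learning_curve> ", cond$physio, "-", cond$internal, " (",
      cond$schedule, "), ", ncol(x$f), " reps x ", nrow(x$f), " steps\n",
      sep = "")
  n <- length(x$mean)
  cat(sprintf("  final feedback: mean %.3f, 50%% CI [%.3f, %.3f], chance %.3f\n",
              x$mean[n], x$ci25[n], x$ci75[n], x$chance))
  invisible(x)
}

#' Moving-average smoothing of a learning curve
#'
#' Applies a centered moving average (window in seconds of simulated time) to
#' the aggregated mean and confidence band; a display aid only -- the
#' underlying per-replicate feedback is untouched.
#'
#' @param curve An `nf_learning_curve`.
#' @param window_s Smoothing window in seconds (default 200).
#' @return The curve with smoothed `mean`, `ci25`, `ci75`.
#' @export
smooth_learning_curve <- function(curve, window_s = 200) {
  stopifnot(inherits(curve, "nf_learning_curve"))
  step <- curve$time_s[1]
  w <- max(1, round(window_s / step))
  ma <- function(v) as.numeric(stats::filter(v, rep(1 / w, w), sides = 2))
  for (fld in c("mean", "ci25", "ci75")) {
    sm <- ma(curve[[fld]])
    curve[[fld]] <- ifelse(is.na(sm), curve[[fld]], sm)
  }
  curve
}

#' Two-voxel demonstration of automatic learning
#'
#' The minimal system showing the reinforcement rule at work: two voxels, two
#' classes, hand-set weights `W = [(1,-1), (-1,1)]` (target class first),
#' learning rate 1 and spontaneous SD 0.25. Under an impulse response the
#' target-class probability climbs from chance (0.5) toward 1; under an HRF
#' response with no internal model (impulse) it stays at chance; mismatched
#' internal models can anti-learn.
#'
#' @param physio,internal Filters for the continuous schedule, or
#'   `schedule = "intermittent"` for cue-gated trials.
#' @param schedule `"continuous"` or `"intermittent"`.
#' @param n_steps TRs (continuous) or trials (intermittent).
#' @param reps Simulated runs.
#' @param alpha Learning rate per step.
#' @param sigma Spontaneous-activity SD.
#' @param seed Optional seed.
#' @return An `nf_learning_curve`.
#' @export
run_two_voxel_demo <- function(physio = "impulse", internal = "impulse",
                               schedule = c("continuous", "intermittent"),
                               n_steps = 300, reps = 1000, alpha = 1,
                               sigma = 0.25, seed = NULL) {
  schedule <- match.arg(schedule)
  cl <- two_voxel_classifier()
  spec <- engine_noise_spec(sigma, seed)
  res <- condition_batch(cl, 1L, as_nf_filter(physio),
                         if (schedule == "continuous") as_nf_filter(internal),
                         schedule, n_steps, reps, alpha, spec,
                         keep_patterns = TRUE)
  new_learning_curve(res$f, if (schedule == "continuous") 2 else 20, 0.5,
                     condition = list(physio = as_nf_filter(physio)$kind,
                                      internal = if (schedule == "continuous")
                                        as_nf_filter(internal)$kind else "cue",
                                      schedule = schedule, reps = reps,
                                      alpha = alpha, sigma = sigma,
                                      target = 1),
                     final_patterns = res$final_patterns)
}

#' @rdname run_two_voxel_demo
#' @export
two_voxel_classifier <- function() {
  pattern_classifier(cbind(target = c(1, -1), other = c(-1, 1)))
}
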