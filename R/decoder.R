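#' Construct a pattern classifier from explicit weights
#'
#' Low-level constructor used for hand-specified decoders (e.g. the two-voxel
#' demonstration) and by [train_classifier()]. The decision function is the
#' affine map `scores = t(W) %*% pattern + intercepts` passed through a
#' softmax.
#'
#' @param W Weight matrix, voxels x classes.
#' @param intercepts Per-class offsets (default zero).
#' @param class_orientations Optional orientation (degrees) of each class.
#' @return An object of class `nf_classifier`.
#' @export
pattern_classifier <- function(W, intercepts = rep(0, ncol(W)),
                               class_orientations = NULL) {
  W <- as.matrix(W)
  stopifnot(length(intercepts) == ncol(W))
  if (!is.null(class_orientations)) {
    stopifnot(length(class_orientations) == ncol(W))
    colnames(W) <- as.character(class_orientations)
  }
  structure(list(W = W, intercepts = as.numeric(intercepts),
                 class_orientations = class_orientations,
                 n_classes = ncol(W)), class = "nf_classifier")
}

#' @export
print.nf_classifier <- function(x, ...) {
  cat("<nf_classifier> ", nrow(x$W), " voxels -> ", x$n_classes, " classes",
      sep = "")
  if (!is.null(x$class_orientations))
    cat(" (", paste(x$class_orientations, collapse = ", "), " deg)", sep = "")
  cat("\n  nonzero weights: ", sum(x$W != 0), " / ", length(x$W), "\n", sep = "")
  invisible(x)
}

#' Train a sparse multinomial classifier on simulated patterns
#'
#' Fits L1-penalized (lasso) multinomial logistic regression via
#' [glmnet::cv.glmnet()], with the penalty weight selected by cross-validation
#' on the training set (`lambda.min`). The L1 penalty plays the role of the
#' sparse voxel selection of sparse logistic regression: a strict subset of
#' voxel weights is exactly zero in the trained decoder. Intercepts are fit
#' and retained so downstream feedback computations use the full affine
#' decision function.
#'
#' @param patterns Training examples, rows = examples, columns = voxels (as
#'   returned by [generate_training_examples()]).
#' @param labels Class labels; if coercible to numeric they are interpreted as
#'   class orientations in degrees.
#' @param lambda Optional fixed penalty; by default chosen by cross-validation.
#' @param nfolds Folds for cross-validation.
#' @param seed Optional seed (fold assignment is random).
#' @return An `nf_classifier` with the selected `lambda` attached.
#' @export
train_classifier <- function(patterns, labels, lambda = NULL, nfolds = 10,
                             seed = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes to train a classifier")
  stopifnot(nrow(patterns) == length(labels))
  fit <- with_seed_if(seed, {
    if (is.null(lambda)) {
      cv <- glmnet::cv.glmnet(patterns, labels, family = "multinomial",
                              alpha = 1, nfolds = nfolds)
      lambda <- cv$lambda.min
      cv$glmnet.fit
    } else {
      glmnet::glmnet(patterns, labels, family = "multinomial", alpha = 1)
    }
  })
  co <- coef(fit, s = lambda)
  W <- do.call(cbind, lapply(co, function(b) as.numeric(b)[-1]))
  intercepts <- vapply(co, function(b) as.numeric(b)[1], numeric(1))
  ori <- suppressWarnings(as.numeric(levels(labels)))
  cl <- pattern_classifier(W, intercepts,
                           if (!anyNA(ori)) ori else NULL)
  cl$lambda <- lambda
  cl
}

#' Class probabilities for activity patterns
#'
#' Softmax of the classifier's affine scores: nonnegative, summing to 1 per
#' pattern.
#'
#' @param classifier An `nf_classifier`.
#' @param pattern Per-voxel activity vector, or a voxels x n matrix.
#' @return Probability vector (single pattern) or an n x classes matrix.
#' @export
predict_proba <- function(classifier, pattern) {
  stopifnot(inherits(classifier, "nf_classifier"))
  vec <- is.null(dim(pattern))
  P <- if (vec) matrix(pattern) else pattern
  if (nrow(P) != nrow(classifier$W))
    stop("pattern length ", nrow(P), " does not match classifier voxel count ",
         nrow(classifier$W))
  S <- crossprod(classifier$W, P) + classifier$intercepts
  S <- sweep(S, 2, apply(S, 2, max))
  E <- exp(S)
  pr <- sweep(E, 2, colSums(E), "/")
  rownames(pr) <- colnames(classifier$W)
  if (vec) drop(pr) else t(pr)
}

#' Feedback tuning curve over class orientations
#'
#' The decaying-exponential tuning curve circularly shifted to peak (value 1)
#' at the target class, evaluated at each class orientation; the class
#' orthogonal to the target receives 1/16. Its dot product with the decoded
#' class probabilities yields a smooth feedback score over the whole
#' orientation range instead of one that is zero everywhere off target.
#'
#' @param target Target orientation; must equal one of `class_orientations`.
#' @param class_orientations Orientations of the classifier's classes.
#' @return Weight vector over classes, in `[1/16, 1]`.
#' @export
feedback_tuning_curve <- function(target, class_orientations = seq(0, 157.5, by = 22.5)) {
  d <- circular_orientation_distance(class_orientations, target)
  if (min(d) > 1e-9)
    stop("target (", target, " deg) is not one of the class orientations")
  (1 / 16)^(d / 90)
}

#' Cognitive feedback score
#'
#' Dot product of the decoded class probabilities with the target-shifted
#' feedback tuning curve; always in `(0, 1]`, so it can be displayed directly
#' on a thermometer. With all probability mass on the class 22.5 / 45 degrees
#' from the target the score is 0.50 / 0.25.
#'
#' @param probs Probability vector over the classes (must sum to 1).
#' @param target Target orientation (one of `class_orientations`).
#' @param class_orientations Orientations of the classes `probs` refers to.
#' @return Scalar feedback score.
#' @export
cognitive_feedback <- function(probs, target,
                               class_orientations = seq(0, 157.5, by = 22.5)) {
  stopifnot(length(probs) == length(class_orientations))
  if (abs(sum(probs) - 1) > 1e-6) stop("probs must sum to 1")
  sum(probs * feedback_tuning_curve(target, class_orientations))
}

#' Trial success from recent feedback scores
#'
#' A target search succeeds when the mean feedback over the 3 most recent TRs
#' strictly exceeds the threshold (ties fail). With fewer than 3 scores the
#' check returns `FALSE` rather than erroring.
#'
#' @param feedback_history Numeric vector of per-TR feedback scores.
#' @param threshold Success threshold (default 0.85).
#' @return Logical.
#' @export
check_success <- function(feedback_history, threshold = 0.85) {
  if (length(feedback_history) < 3) return(FALSE)
  mean(tail(feedback_history, 3)) > threshold
}

#' Intermittent feedback score for a selected orientation
#'
#' Simulates the intermittent feedback calculation: the V1 model is stimulated
#' with the selected orientation for 3 TRs (6 s), followed by 3 rest TRs;
#' spontaneous activity is added throughout, the physiological filter is
#' applied, and the mean [cognitive_feedback()] over the 3 post-stimulus TRs
#' is returned. The impulse filter carries no stimulus signal into that
#' window, so it is rejected.
#'
#' @param model An `nf_voxel_model`.
#' @param classifier An `nf_classifier` over the cognitive class orientations.
#' @param filter Physiological filter (`"hrf"`, `"delay"` or `"blur"`).
#' @param orientation Selected grating orientation (degrees).
#' @param target Target orientation (one of the class orientations).
#' @param seed Optional seed for the spontaneous activity.
#' @return Scalar score in `(0, 1]`.
#' @export
intermittent_feedback_score <- function(model, classifier, filter, orientation,
                                        target, seed = NULL) {
  filter <- as_nf_filter(filter)
  if (filter$kind == "impulse")
    stop("the impulse response is not captured by the intermittent feedback ",
         "calculation (no stimulus signal remains in the post-stimulus window)")
  stim <- stimulus_pattern(model, orientation)
  series <- rbind(matrix(stim, 3, model$n_voxels, byrow = TRUE),
                  matrix(0, 3, model$n_voxels))
  noise <- with_seed_if(seed, t(noise_sampler(model)(6)))
  filtered <- apply_filter(series + noise, filter)
  probs <- predict_proba(classifier, t(filtered[4:6, , drop = FALSE]))
  ori <- classifier$class_orientations
  mean(apply(probs, 1, cognitive_feedback, target = target,
             class_orientations = ori))
}

#' Export classifier weights as CSV
#'
#' Long-format `(class, voxel_index, weight)` table including intercepts
#' (voxel_index 0), used for weight-map analyses.
#'
#' @param classifier An `nf_classifier`.
#' @param path File path.
#' @export
write_classifier_csv <- function(classifier, path) {
  stopifnot(inherits(classifier, "nf_classifier"))
  cls <- colnames(classifier$W)
  if (is.null(cls)) cls <- as.character(seq_len(classifier$n_classes))
  df <- data.frame(
    class = rep(cls, each = nrow(classifier$W) + 1),
    voxel_index = rep(0:nrow(classifier$W), classifier$n_classes),
    weight = as.vector(rbind(classifier$intercepts, classifier$W)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
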