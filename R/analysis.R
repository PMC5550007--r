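#' Categorize a learning curve
#'
#' Classifies a Monte-Carlo conditioning outcome against chance using the
#' final 50% confidence band and the time trend of the replicate-mean curve:
#'
#' * `successful`: the final 50% CI lies entirely above chance;
#' * `anti`: the final 50% CI lies entirely below chance;
#' * `none`: neither, and the OLS slope of the mean curve over time is not
#'   significantly positive (two-sided test at 0.05);
#' * `trending`: increasing, but with a final CI that still straddles chance.
#'
#' The boundaries are admittedly coarse, so the mean final value is returned
#' alongside for ranking conditions.
#'
#' @param curve An `nf_learning_curve`.
#' @param chance Chance level (defaults to the curve's own).
#' @return List with `category`, `final_mean`, `final_ci`, `slope`,
#'   `slope_p`.
#' @export
categorize_learning <- function(curve, chance = curve$chance) {
  stopifnot(inherits(curve, "nf_learning_curve"))
  n <- length(curve$mean)
  ci <- c(curve$ci25[n], curve$ci75[n])
  fit <- summary(lm(curve$mean ~ curve$time_s))$coefficients
  slope <- fit[2, 1]; p <- fit[2, 4]
  category <- if (ci[1] > chance) "successful"
    else if (ci[2] < chance) "anti"
    else if (slope > 0 && p < 0.05) "trending"
    else "none"
  list(category = category, final_mean = curve$mean[n], final_ci = ci,
       slope = slope, slope_p = p)
}

#' Correlate conditioned patterns with reference maps
#'
#' Pearson correlation of each conditioned pattern (one column per simulated
#' participant) with each reference map (e.g. the true noise-free stimulus
#' patterns and the classifier weight maps of each orientation). The summary
#' is the mean of the per-pattern correlations -- not the correlation of the
#' mean pattern. Patterns or references with zero variance yield undefined
#' correlations; these are reported as `NA`, excluded from the mean, and
#' counted.
#'
#' @param conditioned Voxels x replicates matrix of final conditioned
#'   patterns.
#' @param references Named list of per-voxel reference vectors.
#' @return An `nf_correlation_report`: `per_pattern` (replicates x references
#'   matrix of r), `summary` data frame (`reference`, `mean_r`, `n_used`,
#'   `n_undefined`).
#' @export
pattern_correlations <- function(conditioned, references) {
  conditioned <- as.matrix(conditioned)
  stopifnot(is.list(references), !is.null(names(references)))
  per <- vapply(references, function(ref) {
    stopifnot(length(ref) == nrow(conditioned))
    if (stats::sd(ref) == 0) return(rep(NA_real_, ncol(conditioned)))
    r <- suppressWarnings(cor(conditioned, ref))
    as.numeric(r)
  }, numeric(ncol(conditioned)))
  per <- matrix(per, ncol = length(references),
                dimnames = list(NULL, names(references)))
  summ <- data.frame(
    reference = names(references),
    mean_r = colMeans(per, na.rm = TRUE),
    n_used = colSums(!is.na(per)),
    n_undefined = colSums(is.na(per)),
    row.names = NULL)
  structure(list(per_pattern = per, summary = summ),
            class = "nf_correlation_report")
}

#' @export
print.nf_correlation_report <- function(x, ...) {
  cat("<nf_correlation_report> mean per-pattern Pearson r over",
      nrow(x$per_pattern), "patterns\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Random surface placement for pattern display
#'
#' Conditioned patterns, true orientation patterns and classifier weight maps
#' are visualized by placing the voxels onto a square surface through one
#' random bijection per simulated participant; the same placement must be
#' applied to every map so that correlations are preserved (a permutation
#' leaves Pearson r unchanged).
#'
#' @param n_voxels Number of voxels to place (must equal `side^2`).
#' @param side Voxels per surface edge.
#' @param seed Optional seed.
#' @return An integer permutation: surface cell `i` (column-major) shows
#'   voxel `placement[i]`.
#' @export
surface_placement <- function(n_voxels, side = 20, seed = NULL) {
  stopifnot(n_voxels == side^2)
  with_seed_if(seed, sample.int(n_voxels))
}

#' @rdname surface_placement
#' @param values Per-voxel vector to project.
#' @param placement A permutation from [surface_placement()].
#' @return `project_to_surface()`: a `side` x `side` matrix.
#' @export
project_to_surface <- function(values, placement, side = 20) {
  stopifnot(length(values) == length(placement))
  matrix(values[placement], side, side)
}

#' Conditioning of spatial patterns with and without orientation-structured
#' spontaneous activity
#'
#' Runs the surface-model conditioning experiment: a 20 x 20 (400-voxel)
#' surface carrying the 200 tuned voxels (25 per orientation), a 3-way sparse
#' classifier (10, 70, 130 degrees) trained on 210 simulated examples at
#' SNR 2, and intermittent cue-gated conditioning with the HRF physiological
#' response (5 simulated hours = 900 trials at 1% learning rate per trial,
#' feedback from the 10-degree class). Spontaneous activity during
#' conditioning is either purely random Gaussian noise or the half-and-half
#' orientation mixture of [sample_orientation_mixture()]. Final conditioned
#' patterns are correlated with the true (noise-free) orientation patterns
#' and the classifier weight maps of all three classes.
#'
#' @param noise_kind `"iid"` (no spontaneous-activity correlations) or
#'   `"orientation_mixture"`.
#' @param reps Simulated participants.
#' @param hours Simulated conditioning duration (900 trials at 5 hours).
#' @param snr Voxelwise SNR (noise SD = 1/snr).
#' @param seed Optional seed (controls classifier training and conditioning).
#' @param classifier Optionally reuse a trained classifier (with its model) to
#'   share the decoder between the two noise conditions.
#' @param model The surface model to use; built internally by default.
#' @return List: `correlations` (an `nf_correlation_report`),
#'   `final_patterns` (voxels x reps), `curve` (`nf_learning_curve`),
#'   `classifier`, `model`, `references`.
#' @export
run_fig8_experiment <- function(noise_kind = c("iid", "orientation_mixture"),
                                reps = 1000, hours = 5, snr = 2, seed = NULL,
                                classifier = NULL, model = NULL) {
  noise_kind <- match.arg(noise_kind)
  orientations <- c(10, 70, 130)
  with_seed_if(seed, {
    if (is.null(model))
      model <- voxel_model(grid_shape = c(20, 20), fraction_tuned = 0.5,
                          noise_sigma = 1 / snr, noise_kind = "iid")
    if (is.null(classifier)) {
      train <- suppressMessages(
        generate_training_examples(model, orientations, n_per_class = 70,
                                   snr = snr))
      classifier <- train_classifier(train$patterns, train$labels)
    }
    cond_model <- model
    cond_model$noise_kind <- noise_kind
    curve <- run_conditioning_experiment(
      cond_model, classifier, target = 10, physio = "hrf",
      schedule = "intermittent", hours = hours, reps = reps,
      alpha_per_20s = 0.01, keep_patterns = TRUE)
    refs <- c(
      stats::setNames(lapply(orientations, stimulus_pattern, model = model),
                      paste0("true_", orientations)),
      stats::setNames(lapply(seq_along(orientations),
                             function(k) classifier$W[, k]),
                      paste0("weights_", orientations)))
    list(correlations = pattern_correlations(curve$final_patterns, refs),
         final_patterns = curve$final_patterns, curve = curve,
         classifier = classifier, model = model, references = refs,
         noise_kind = noise_kind)
  })
}
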