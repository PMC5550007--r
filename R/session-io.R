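#' Export / import a voxel-model configuration
#'
#' The model specification (not the sampled noise) serializes losslessly to
#' JSON; patterns can be written as CSV with voxel coordinates for external
#' tools.
#'
#' @param model An `nf_voxel_model`.
#' @param path File path.
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "nf_voxel_model"))
  cfg <- model[c("grid_shape", "voxel_size_mm", "tuned_orientations",
                 "tuning_assignment", "fraction_tuned", "noise_sigma",
                 "noise_kind", "grf_fwhm_mm")]
  jsonlite::write_json(cfg, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- voxel_model(grid_shape = cfg$grid_shape,
                   voxel_size_mm = cfg$voxel_size_mm,
                   tuned_orientations = cfg$tuned_orientations,
                   fraction_tuned = cfg$fraction_tuned,
                   noise_sigma = cfg$noise_sigma,
                   noise_kind = cfg$noise_kind,
                   grf_fwhm_mm = cfg$grf_fwhm_mm)
  m$tuning_assignment <- as.integer(cfg$tuning_assignment)
  m
}

#' @rdname write_model_config
#' @param pattern Per-voxel activity vector.
#' @export
write_pattern_csv <- function(model, pattern, path) {
  stopifnot(length(pattern) == model$n_voxels)
  df <- data.frame(voxel_index = seq_along(pattern),
                   x_mm = model$coords_mm[, 1], y_mm = model$coords_mm[, 2],
                   z_mm = model$coords_mm[, 3], value = pattern)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

write_curve_csv <- function(curve, path) {
  df <- data.frame(time_s = curve$time_s, mean = curve$mean,
                   ci25 = curve$ci25, ci75 = curve$ci75)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run a named experiment and write its outputs
#'
#' Reproduces the package's standard experiments as output bundles under
#' `out_dir` (CSV data plus a JSON manifest recording the resolved
#' configuration and seed). Available experiments:
#'
#' * `"fig5"`: two-voxel demonstrations -- undelayed learning and the HRF
#'   response with no internal model.
#' * `"fig6"`: two-voxel continuous matched/mismatched internal models plus
#'   intermittent cue-gated learning, all under the HRF response.
#' * `"fig7"`: the full-V1 conditioning grid (16 continuous filter-model
#'   combinations + 4 intermittent), one learning-curve file per condition.
#' * `"fig8"`: surface-model conditioning under Gaussian and
#'   orientation-mixture spontaneous activity with pattern correlations.
#' * `"cognitive-continuous"` / `"cognitive-intermittent"`: reference-agent
#'   target searches across the applicable physiological filters.
#'
#' @param name Experiment name (see above).
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; every source of randomness derives from it.
#' @param reps Replicates for the Monte-Carlo experiments (defaults keep the
#'   bundle quick; the headline analyses use 1000).
#' @return Invisibly, the vector of files written.
#' @export
run_named_experiment <- function(name = c("fig5", "fig6", "fig7", "fig8",
                                          "cognitive-continuous",
                                          "cognitive-intermittent"),
                                 out_dir, seed = 1, reps = 100) {
  name <- match.arg(name)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit_curve <- function(curve, label) {
    f <- file.path(out_dir, paste0(label, ".csv"))
    write_curve_csv(curve, f)
    files <<- c(files, f)
  }
  started <- Sys.time()
  cfg <- list(experiment = name, seed = seed, reps = reps,
              package_version = as.character(utils::packageVersion("neurofb")))

  if (name == "fig5") {
    emit_curve(run_two_voxel_demo("impulse", "impulse", reps = reps,
                                  seed = seed), "twovoxel_impulse")
    emit_curve(run_two_voxel_demo("hrf", "impulse", reps = reps,
                                  seed = seed + 1), "twovoxel_hrf_nointernal")
  } else if (name == "fig6") {
    emit_curve(run_two_voxel_demo("hrf", "hrf", reps = reps, seed = seed),
               "twovoxel_hrf_hrf")
    emit_curve(run_two_voxel_demo("hrf", "delay", reps = reps, seed = seed + 1),
               "twovoxel_hrf_delay")
    emit_curve(run_two_voxel_demo("hrf", schedule = "intermittent",
                                  n_steps = 100, reps = reps, seed = seed + 2),
               "twovoxel_hrf_cue")
  } else if (name == "fig7") {
    setup <- v1_conditioning_setup(seed)
    kinds <- c("impulse", "hrf", "delay", "blur")
    i <- 0
    for (ph in kinds) {
      for (im in kinds) {
        i <- i + 1
        emit_curve(run_conditioning_experiment(
          setup$model, setup$classifier, 10, ph, im, "continuous",
          reps = reps, seed = seed + 10 + i), paste0("continuous_", ph, "_", im))
      }
      i <- i + 1
      emit_curve(run_conditioning_experiment(
        setup$model, setup$classifier, 10, ph, schedule = "intermittent",
        reps = reps, seed = seed + 10 + i), paste0("intermittent_", ph, "_cue"))
    }
  } else if (name == "fig8") {
    base <- run_fig8_experiment("iid", reps = reps, seed = seed)
    mix <- run_fig8_experiment("orientation_mixture", reps = reps,
                               seed = seed + 1, classifier = base$classifier,
                               model = base$model)
    for (res in list(base, mix)) {
      f <- file.path(out_dir, paste0("correlations_", res$noise_kind, ".csv"))
      write.csv(res$correlations$summary, f, row.names = FALSE)
      files <- c(files, f)
    }
    placement <- surface_placement(base$model$n_voxels, 20, seed = seed + 2)
    ex <- project_to_surface(base$final_patterns[, 1], placement)
    f <- file.path(out_dir, "example_conditioned_surface.csv")
    write.table(ex, f, sep = ",", row.names = FALSE, col.names = FALSE)
    files <- c(files, f)
  } else {
    mode <- sub("cognitive-", "", name)
    setup <- cognitive_setup(seed)
    filters <- if (mode == "continuous") c("impulse", "hrf", "delay", "blur")
               else c("hrf", "delay", "blur")
    rows <- list()
    for (filt in filters) {
      for (target in setup$classifier$class_orientations) {
        if (mode == "continuous") {
          s <- run_continuous_search(agent_greedy(), target, filt,
                                     setup$model, setup$classifier,
                                     seed = seed + round(target * 2))
          rows[[length(rows) + 1]] <- data.frame(
            filter = filt, target = target, success = s$success,
            steps = s$n_tr, time_to_target_s = s$time_to_target_s)
        } else {
          s <- run_intermittent_search(agent_binary_search(), target, filt,
                                       setup$model, setup$classifier,
                                       seed = seed + round(target * 2))
          rows[[length(rows) + 1]] <- data.frame(
            filter = filt, target = target, success = s$success,
            steps = s$n_trials, time_to_target_s = s$time_to_target_s)
        }
      }
    }
    f <- file.path(out_dir, "searches.csv")
    write.csv(do.call(rbind, rows), f, row.names = FALSE)
    files <- c(files, f)
  }

  cfg$wall_time_s <- as.numeric(difftime(Sys.time(), started, units = "secs"))
  cfg$files <- basename(files)
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(cfg, manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(files, manifest))
}

#' Standard model + decoder setups for the headline experiments
#'
#' `v1_conditioning_setup()` builds the full 1000-voxel GRF model with the
#' 3-way decoder used for automatic conditioning (210 training examples -- 70
#' per orientation at 10, 70, 130 degrees -- at SNR 2).
#' `cognitive_setup()` builds the same model with the 8-way decoder of the
#' cognitive protocols (100 examples per tuned orientation at SNR 2) and then
#' raises the runtime SNR to 10 (sigma 0.1), the feedback-reliability setting
#' of the target-search experiments.
#'
#' @param seed Master seed (model assignment, training noise, CV folds).
#' @param n_per_class Training examples per class.
#' @param runtime_snr Runtime SNR of the cognitive environment.
#' @return List with `model` and `classifier`.
#' @export
v1_conditioning_setup <- function(seed = 1, n_per_class = 70) {
  model <- voxel_model(seed = seed)
  train <- suppressMessages(generate_training_examples(
    model, c(10, 70, 130), n_per_class = n_per_class, snr = 2,
    seed = seed + 1))
  classifier <- train_classifier(train$patterns, train$labels, seed = seed + 2)
  list(model = model, classifier = classifier)
}

#' @rdname v1_conditioning_setup
#' @export
cognitive_setup <- function(seed = 1, n_per_class = 100, runtime_snr = 10) {
  model <- voxel_model(seed = seed)
  train <- generate_training_examples(model, n_per_class = n_per_class,
                                      snr = 2, seed = seed + 1)
  classifier <- train_classifier(train$patterns, train$labels, seed = seed + 2)
  model$noise_sigma <- 1 / runtime_snr
  list(model = model, classifier = classifier)
}

#' Write the deterministic fixture bundle
#'
#' Emits the small plain-text bundle used for exact regression checks and as
#' worked input data: the four filter weight tables, a miniature (50-voxel)
#' V1 model configuration with a trained 3-way mini-classifier, the two-voxel
#' demo classifier, and a 20-TR filtered trajectory. Regeneration with the
#' same seed is byte-identical.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @return Invisibly, the files written.
#' @export
generate_fixtures <- function(out_dir, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (kind in c("impulse", "hrf", "delay", "blur")) {
    f <- file.path(out_dir, paste0("filter_", kind, ".csv"))
    write_filter_csv(make_filter(kind), f)
    files <- c(files, f)
  }
  mini <- voxel_model(grid_shape = c(5, 5, 2), fraction_tuned = 0.32,
                      seed = seed)
  f <- file.path(out_dir, "mini_model.json")
  write_model_config(mini, f)
  files <- c(files, f)

  train <- suppressMessages(generate_training_examples(
    mini, c(10, 70, 130), n_per_class = 40, snr = 4, seed = seed + 1))
  mini_cl <- train_classifier(train$patterns, train$labels, seed = seed + 2)
  f <- file.path(out_dir, "mini_classifier.csv")
  write_classifier_csv(mini_cl, f)
  files <- c(files, f)

  f <- file.path(out_dir, "twovoxel_classifier.csv")
  write_classifier_csv(two_voxel_classifier(), f)
  files <- c(files, f)

  traj <- with_seed_if(seed + 3, {
    stim <- stimulus_pattern(mini, 10)
    series <- matrix(rep(stim, each = 20), 20) *
      rep(rep(c(1, 0), each = 5), 2) + t(noise_sampler(mini)(20))
    apply_filter(series, make_filter("hrf"))
  })
  f <- file.path(out_dir, "mini_trajectory_hrf.csv")
  write.table(round(traj, 10), f, sep = ",", row.names = FALSE,
              col.names = paste0("v", seq_len(ncol(traj))))
  files <- c(files, f)
  invisible(files)
}
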