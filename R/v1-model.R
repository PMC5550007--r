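#' Circular distance between grating orientations
#'
#' Grating orientations live on a circle of period 180 degrees, so the largest
#' possible separation between two orientations is 90 degrees (orthogonal
#' gratings). Inputs are reduced modulo 180 before the distance is taken.
#'
#' @param theta1,theta2 Orientations in degrees. Recycled to a common length.
#' @return Distance(s) in degrees, in `[0, 90]`.
#' @examples
#' circular_orientation_distance(0, 180)   # 0
#' circular_orientation_distance(170, 10)  # 20
#' @export
circular_orientation_distance <- function(theta1, theta2) {
  d <- abs(theta1 - theta2) %% 180
  pmin(d, 180 - d)
}

#' Orientation tuning curve
#'
#' Response of a voxel tuned to `preferred` when stimulated at `stimulus`:
#' a decaying exponential with full output (1, arbitrary units) at the tuned
#' orientation falling to 1/16 at the orthogonal orientation, i.e.
#' `(1/16)^(d / 90)` with `d` the circular orientation distance.
#'
#' @param preferred,stimulus Orientations in degrees (vectorized).
#' @return Activity in `[1/16, 1]`.
#' @export
tuning_response <- function(preferred, stimulus) {
  d <- circular_orientation_distance(preferred, stimulus)
  (1 / 16)^(d / 90)
}

#' Construct a voxel model of early visual cortex
#'
#' Builds the simulated "brain": a grid of voxels of which a fixed fraction are
#' tuned to one of a set of grating orientations (split equally, up to
#' rounding) and the rest are untuned. Tuned voxels respond to a stimulus
#' through [tuning_response()]; untuned voxels carry no stimulus-driven signal.
#' All voxels have additive spontaneous activity with per-voxel standard
#' deviation `noise_sigma`, drawn under one of three noise models:
#'
#' * `"grf"`: a Gaussian random field -- i.i.d. Gaussian noise smoothed with a
#'   Gaussian spatial kernel of full width at half maximum `grf_fwhm_mm`
#'   (the neuroimaging convention for "kernel size"), then re-standardized so
#'   every voxel keeps marginal SD `noise_sigma` exactly.
#' * `"iid"`: spatially independent Gaussian noise.
#' * `"orientation_mixture"`: a half-and-half mixture of i.i.d. Gaussian noise
#'   and a random orientation signal -- see [sample_orientation_mixture()].
#'
#' Which tuned orientation each voxel receives is assigned at random over the
#' grid (seedable via `seed`), so that spatial noise correlations and tuning
#' are independent, and the voxel-to-index mapping (first grid axis fastest,
#' i.e. column-major) is recorded in `coords_mm`.
#'
#' @param grid_shape Integer vector of voxels per axis (2 or 3 axes).
#' @param voxel_size_mm Edge length of a voxel in mm.
#' @param tuned_orientations Orientations (degrees, distinct mod 180) that
#'   tuned voxels prefer.
#' @param fraction_tuned Fraction of all voxels that are tuned.
#' @param noise_sigma Spontaneous-activity SD per voxel (arbitrary activity
#'   units; the tuning-curve peak is 1, so SNR = 1 / noise_sigma).
#' @param noise_kind One of `"grf"`, `"iid"`, `"orientation_mixture"`.
#' @param grf_fwhm_mm FWHM of the spatial smoothing kernel for `"grf"` noise.
#' @param seed Optional seed for the random tuning assignment.
#' @return An object of class `nf_voxel_model`.
#' @export
voxel_model <- function(grid_shape = c(10, 10, 10),
                        voxel_size_mm = 3,
                        tuned_orientations = seq(0, 157.5, by = 22.5),
                        fraction_tuned = 0.20,
                        noise_sigma = 0.5,
                        noise_kind = c("grf", "iid", "orientation_mixture"),
                        grf_fwhm_mm = 5,
                        seed = NULL) {
  noise_kind <- match.arg(noise_kind)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) %in% 2:3, all(grid_shape >= 1),
            fraction_tuned >= 0, fraction_tuned <= 1)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  tuned_orientations <- as.numeric(tuned_orientations) %% 180
  if (anyDuplicated(tuned_orientations))
    stop("tuned_orientations must be distinct modulo 180 degrees")

  n_voxels <- prod(grid_shape)
  n_tuned <- round(fraction_tuned * n_voxels)
  n_class <- length(tuned_orientations)
  # equal split with remainder spread over the first classes (counts +/- 1)
  per <- rep(n_tuned %/% n_class, n_class)
  if (n_tuned %% n_class > 0) per[seq_len(n_tuned %% n_class)] <- per[1] + 1
  labels <- rep(seq_len(n_class), times = per)

  assignment <- integer(n_voxels) # 0 = untuned
  idx <- with_seed_if(seed, sample.int(n_voxels, n_tuned))
  assignment[idx] <- labels

  shape3 <- c(grid_shape, rep(1L, 3 - length(grid_shape)))
  coords <- as.matrix(expand.grid(x = seq_len(shape3[1]), y = seq_len(shape3[2]),
                                  z = seq_len(shape3[3])))
  structure(list(
    grid_shape = grid_shape,
    voxel_size_mm = voxel_size_mm,
    n_voxels = n_voxels,
    tuned_orientations = tuned_orientations,
    tuning_assignment = assignment,
    fraction_tuned = fraction_tuned,
    noise_sigma = noise_sigma,
    noise_kind = noise_kind,
    grf_fwhm_mm = grf_fwhm_mm,
    coords_mm = (coords - 1) * voxel_size_mm
  ), class = "nf_voxel_model")
}

#' @export
print.nf_voxel_model <- function(x, ...) {
  cat("<nf_voxel_model> ", paste(x$grid_shape, collapse = "x"),
      " grid (", x$n_voxels, " voxels, ", x$voxel_size_mm, " mm)\n", sep = "")
  cat("  tuned: ", sum(x$tuning_assignment > 0), " voxels over ",
      length(x$tuned_orientations), " orientations\n", sep = "")
  cat("  noise: ", x$noise_kind, ", sigma = ", x$noise_sigma, "\n", sep = "")
  invisible(x)
}

#' Noise-free activity pattern evoked by a grating stimulus
#'
#' Tuned voxels respond with [tuning_response()] of their preferred
#' orientation to the stimulus; untuned voxels stay at zero. Deterministic.
#'
#' @param model An `nf_voxel_model`.
#' @param orientation Stimulus orientation in degrees.
#' @return Numeric vector of per-voxel activity.
#' @export
stimulus_pattern <- function(model, orientation) {
  stopifnot(inherits(model, "nf_voxel_model"), length(orientation) == 1)
  out <- numeric(model$n_voxels)
  tuned <- model$tuning_assignment > 0
  pref <- model$tuned_orientations[model$tuning_assignment[tuned]]
  out[tuned] <- tuning_response(pref, orientation)
  out
}

# Separable Gaussian smoothing of an array of grid-shaped noise draws, exact
# per-voxel re-standardization via the factorized row norms of the kernel.
grf_scale_and_kernels <- function(model) {
  shape <- model$grid_shape
  sigma_mm <- model$grf_fwhm_mm / (2 * sqrt(2 * log(2)))
  kernels <- lapply(shape, function(n) {
    d <- outer(seq_len(n), seq_len(n), function(i, j) (i - j) * model$voxel_size_mm)
    exp(-d^2 / (2 * sigma_mm^2))
  })
  rn <- lapply(kernels, function(K) sqrt(rowSums(K^2)))
  scale <- Reduce(`%o%`, rn)
  list(kernels = kernels, scale = as.vector(scale))
}

smooth_separable <- function(z, kernels) {
  # z: array with dim = c(grid_shape, n_draws); kernels: one matrix per axis
  d <- dim(z)
  nd <- length(d)
  for (ax in seq_along(kernels)) {
    perm <- c(ax, setdiff(seq_len(nd), ax))
    z <- aperm(z, perm)
    dp <- dim(z)
    z <- array(kernels[[ax]] %*% matrix(z, nrow = dp[1]), dp)
    z <- aperm(z, order(perm))
  }
  z
}

# Internal: a function(n) drawing n spontaneous-activity patterns (voxels x n)
# from the model's noise distribution, using the current RNG stream.
noise_sampler <- function(model) {
  V <- model$n_voxels
  sigma <- model$noise_sigma
  if (sigma == 0) return(function(n) matrix(0, V, n))
  switch(model$noise_kind,
    iid = function(n) matrix(rnorm(V * n, 0, sigma), V, n),
    grf = {
      gk <- grf_scale_and_kernels(model)
      mult <- sigma / gk$scale
      shape <- model$grid_shape
      function(n) {
        z <- array(rnorm(V * n), c(shape, n))
        matrix(smooth_separable(z, gk$kernels), V, n) * mult
      }
    },
    orientation_mixture = {
      tuned <- which(model$tuning_assignment > 0)
      pref <- model$tuned_orientations[model$tuning_assignment[tuned]]
      # Var of the tuning weight under theta ~ U[0,180): d/90 ~ U[0,1]
      ew <- (15 / 16) / log(16)
      ew2 <- (255 / 256) / (2 * log(16))
      c_mix <- sigma / sqrt(2 * (ew2 - ew^2))
      g_sd <- sigma / sqrt(2)
      function(n) {
        out <- matrix(rnorm(V * n, 0, g_sd), V, n)
        theta <- runif(n, 0, 180)
        d <- outer(pref, theta, circular_orientation_distance)
        out[tuned, ] <- out[tuned, ] + c_mix * (1 / 16)^(d / 90)
        out
      }
    })
}

#' Sample spatially correlated spontaneous activity
#'
#' Draws zero-mean Gaussian-random-field spontaneous activity on the model
#' grid: i.i.d. Gaussian noise smoothed with a Gaussian kernel of FWHM
#' `model$grf_fwhm_mm` and re-standardized so each voxel's marginal SD equals
#' `model$noise_sigma` exactly. Neighboring voxels are positively correlated,
#' with correlation decaying with inter-voxel distance. For a model with
#' `noise_kind = "iid"` the smoothing step is skipped.
#'
#' @param model An `nf_voxel_model` with `noise_kind` `"grf"` or `"iid"`.
#' @param n Number of independent patterns to draw.
#' @param seed Optional seed.
#' @return Matrix of per-voxel activity, `n_voxels` x `n`.
#' @export
sample_spontaneous <- function(model, n = 1, seed = NULL) {
  stopifnot(inherits(model, "nf_voxel_model"))
  if (!model$noise_kind %in% c("grf", "iid"))
    stop("sample_spontaneous() requires noise_kind 'grf' or 'iid'; see sample_orientation_mixture()")
  with_seed_if(seed, noise_sampler(model)(n))
}

#' Sample orientation-structured spontaneous activity
#'
#' Draws the half-and-half mixture of random Gaussian noise and a random
#' orientation signal: each pattern is `g + c * stimulus_pattern(model, theta)`
#' with `theta ~ Uniform[0, 180)` redrawn independently for every pattern. The
#' scalar `c` is chosen so that on tuned voxels the Gaussian part and the
#' orientation part contribute equal variance and their variances sum to
#' `noise_sigma^2` (untuned voxels receive only the Gaussian half). This
#' emulates spontaneous activity that carries visual structure without any
#' bias toward a particular orientation.
#'
#' @inheritParams sample_spontaneous
#' @return Matrix of per-voxel activity, `n_voxels` x `n`.
#' @export
sample_orientation_mixture <- function(model, n = 1, seed = NULL) {
  stopifnot(inherits(model, "nf_voxel_model"))
  m <- model
  m$noise_kind <- "orientation_mixture"
  with_seed_if(seed, noise_sampler(m)(n))
}

#' Generate labeled training examples for the pattern decoder
#'
#' Simulates `n_per_class` noisy presentations of each orientation in
#' `orientations`: the noise-free stimulus pattern plus spontaneous activity at
#' the SD implied by the voxelwise signal-to-noise ratio (`sigma = peak/snr`
#' with tuning-curve peak 1). Spontaneous activity uses the model's `"grf"` or
#' `"iid"` noise (training always uses plain Gaussian spontaneous activity).
#' Orientations outside the model's tuned set are permitted (the tuning curve
#' still applies) but are flagged with a message.
#'
#' @param model An `nf_voxel_model`.
#' @param orientations Class orientations in degrees.
#' @param n_per_class Examples per class.
#' @param snr Voxelwise signal-to-noise ratio (> 0); `Inf` gives noise-free
#'   examples.
#' @param seed Optional seed.
#' @return List with `patterns` (examples x voxels matrix) and `labels`
#'   (factor of orientations).
#' @export
generate_training_examples <- function(model, orientations = model$tuned_orientations,
                                       n_per_class = 100, snr = 2, seed = NULL) {
  stopifnot(inherits(model, "nf_voxel_model"), snr > 0, n_per_class >= 1)
  novel <- setdiff(orientations %% 180, model$tuned_orientations)
  if (length(novel))
    message("orientations not in the model's tuned set (tuning curve still applies): ",
            paste(novel, collapse = ", "))
  noise_model <- model
  noise_model$noise_sigma <- 1 / snr
  if (noise_model$noise_kind == "orientation_mixture") noise_model$noise_kind <- "iid"
  n_total <- n_per_class * length(orientations)
  stim <- vapply(orientations, function(o) stimulus_pattern(model, o),
                 numeric(model$n_voxels))
  with_seed_if(seed, {
    noise <- if (is.finite(snr)) noise_sampler(noise_model)(n_total) else
      matrix(0, model$n_voxels, n_total)
    lab <- rep(seq_along(orientations), each = n_per_class)
    patterns <- t(stim[, lab, drop = FALSE] + noise)
    list(patterns = patterns, labels = factor(orientations[lab], levels = orientations))
  })
}
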