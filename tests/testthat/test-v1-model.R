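test_that("circular orientation distance is periodic, symmetric and bounded", {
  expect_equal(circular_orientation_distance(0, 180), 0)
  expect_equal(circular_orientation_distance(10, 100), 90)
  expect_equal(circular_orientation_distance(170, 10), 20)
  theta <- runif(50, -360, 360)
  phi <- runif(50, -360, 360)
  d <- circular_orientation_distance(theta, phi)
  expect_equal(d, circular_orientation_distance(phi, theta))
  expect_true(all(d >= 0 & d <= 90))
  expect_equal(circular_orientation_distance(theta, theta + 180), rep(0, 50))
})

test_that("tuning curve hits its stated anchors and decreases with distance", {
  expect_equal(tuning_response(0, 0), 1)
  expect_equal(tuning_response(0, 90), 1 / 16)
  expect_equal(tuning_response(0, 45), 0.25)
  expect_equal(tuning_response(0, 22.5), 0.5)
  d <- seq(0, 90, by = 5)
  expect_true(all(diff(tuning_response(0, d)) < 0))
})

test_that("voxel model splits tuned voxels equally across orientations", {
  m <- voxel_model(seed = 1)
  counts <- table(m$tuning_assignment[m$tuning_assignment > 0])
  expect_length(counts, 8)
  expect_true(all(counts == 25))
  expect_equal(sum(m$tuning_assignment > 0), 0.20 * 1000)
  # uneven splits stay within 1 of each other
  m2 <- voxel_model(grid_shape = c(5, 5, 2), fraction_tuned = 0.26, seed = 2)
  counts2 <- table(factor(m2$tuning_assignment[m2$tuning_assignment > 0],
                          levels = 1:8))
  expect_lte(max(counts2) - min(counts2), 1)
  expect_equal(sum(counts2), round(0.26 * 50))
  expect_error(voxel_model(tuned_orientations = c(0, 180)), "distinct")
  expect_error(voxel_model(noise_sigma = -1), "noise_sigma")
})

test_that("stimulus patterns follow the tuning curve and 180-deg periodicity", {
  p45 <- stimulus_pattern(mini_model, 45)
  expect_equal(p45, stimulus_pattern(mini_model, 225))
  expect_true(all(p45[mini_model$tuning_assignment == 0] == 0))
  tuned45 <- mini_model$tuning_assignment ==
    which(mini_model$tuned_orientations == 45)
  expect_true(all(p45[tuned45] == 1))
  # orthogonal stimuli scale tuned voxels reciprocally: 1 <-> 1/16
  p135 <- stimulus_pattern(mini_model, 135)
  expect_equal(p135[tuned45], rep(1 / 16, sum(tuned45)))
})

test_that("spontaneous GRF activity is standardized and spatially correlated", {
  expect_equal(sample_spontaneous(noisefree_model, 3), matrix(0, 50, 3))
  s <- sample_spontaneous(mini_model, 4000, seed = 7)
  sds <- apply(s, 1, sd)
  expect_true(all(abs(sds - 0.5) / 0.5 < 0.05))
  expect_true(all(abs(rowMeans(s)) < 0.05))
  # neighbours (3 mm apart) correlate more than voxels >= 15 mm apart
  d <- as.matrix(dist(mini_model$coords_mm))
  cc <- cor(t(s))
  near <- mean(cc[d > 0 & d <= 3.01])
  far <- mean(cc[d >= 15])
  expect_gt(near, far)
  expect_gt(near, 0.3)
  # reproducibility by seed
  expect_identical(s, sample_spontaneous(mini_model, 4000, seed = 7))
})

test_that("orientation-mixture activity has the stated mean and variance split", {
  s <- sample_orientation_mixture(mini_model, 8000, seed = 8)
  tuned <- mini_model$tuning_assignment > 0
  sigma <- mini_model$noise_sigma
  # analytic moments of the tuning weight under theta ~ U[0, 180)
  ew <- (15 / 16) / log(16)
  ew2 <- (255 / 256) / (2 * log(16))
  c_mix <- sigma / sqrt(2 * (ew2 - ew^2))
  expect_equal(mean(rowMeans(s[tuned, , drop = FALSE])), c_mix * ew,
               tolerance = 0.02)
  expect_equal(mean(apply(s[tuned, ], 1, var)), sigma^2, tolerance = 0.05)
  expect_equal(mean(apply(s[!tuned, ], 1, var)), sigma^2 / 2, tolerance = 0.05)
  # untuned voxels carry only the Gaussian half, mean zero
  expect_lt(max(abs(rowMeans(s[!tuned, ]))), 0.05)
})

test_that("drawn mixture orientations are circularly uniform", {
  # recover theta per draw from the two most responsive tuned classes is
  # overkill; instead check the class-mean signature: with theta uniform the
  # mean added signal is identical for every preferred orientation
  s <- sample_orientation_mixture(mini_model, 8000, seed = 9)
  by_class <- vapply(seq_len(8), function(k) {
    mean(s[mini_model$tuning_assignment == k, , drop = FALSE])
  }, numeric(1))
  expect_lt(max(by_class) - min(by_class), 0.04)
})

test_that("training example generation obeys counts, SNR and determinism", {
  ex <- suppressMessages(generate_training_examples(
    mini_model, c(10, 70, 130), n_per_class = 5, snr = 2, seed = 1))
  expect_equal(dim(ex$patterns), c(15, 50))
  expect_equal(as.vector(table(ex$labels)), rep(5, 3))
  ex8 <- generate_training_examples(mini_model, n_per_class = 4, seed = 1)
  expect_equal(nrow(ex8$patterns), 32)
  # infinite SNR: all examples of a class identical and noise-free
  ex0 <- suppressMessages(generate_training_examples(
    mini_model, c(10, 70, 130), n_per_class = 3, snr = Inf, seed = 1))
  expect_equal(ex0$patterns[1, ], ex0$patterns[2, ])
  expect_equal(ex0$patterns[1, ], stimulus_pattern(mini_model, 10))
  # non-tuned orientations are flagged
  expect_message(generate_training_examples(mini_model, c(10, 70, 130), 2,
                                            seed = 1), "tuned set")
})

test_that("engine noise generator matches the model's noise contracts", {
  spec <- neurofb:::engine_noise_spec(mini_model, seed = 5)
  s <- neurofb:::cc_noise_sample(spec, mini_model$n_voxels, 4000, 1)
  sds <- apply(s, 1, sd)
  expect_true(all(abs(sds - 0.5) / 0.5 < 0.05))
  d <- as.matrix(dist(mini_model$coords_mm))
  cc <- cor(t(s))
  expect_gt(mean(cc[d > 0 & d <= 3.01]), mean(cc[d >= 15]))
  # mixture spec
  mix <- mini_model
  mix$noise_kind <- "orientation_mixture"
  sm <- neurofb:::cc_noise_sample(neurofb:::engine_noise_spec(mix, seed = 6),
                                  mix$n_voxels, 8000, 1)
  tuned <- mix$tuning_assignment > 0
  expect_equal(mean(apply(sm[tuned, ], 1, var)), 0.25, tolerance = 0.05)
  expect_equal(mean(apply(sm[!tuned, ], 1, var)), 0.125, tolerance = 0.05)
  # same spec, same draws
  expect_identical(s, neurofb:::cc_noise_sample(spec, 50, 4000, 1))
})
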