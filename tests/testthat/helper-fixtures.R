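# Shared miniature fixtures, built once per test run. The mini model keeps
# every structural property of the full 1000-voxel cube (8 tuned
# orientations, GRF noise) at 50 voxels so decoders train in seconds.
mini_model <- voxel_model(grid_shape = c(5, 5, 2), fraction_tuned = 0.32,
                          noise_sigma = 0.5, seed = 42)

mini_train3 <- suppressMessages(generate_training_examples(
  mini_model, c(10, 70, 130), n_per_class = 40, snr = 4, seed = 43))
mini_classifier3 <- train_classifier(mini_train3$patterns, mini_train3$labels,
                                     seed = 44)

mini_train8 <- generate_training_examples(mini_model, n_per_class = 30,
                                          snr = 4, seed = 45)
mini_classifier8 <- train_classifier(mini_train8$patterns, mini_train8$labels,
                                     seed = 46)

# noise-free variant for the closed-form search examples
noisefree_model <- local({
  m <- mini_model
  m$noise_sigma <- 0
  m
})

# brute-force causal convolution oracle (double loop)
conv_oracle <- function(x, weights) {
  n <- length(x)
  y <- numeric(n)
  for (t in seq_len(n)) {
    for (j in seq_along(weights)) {
      if (t - j + 1 >= 1) y[t] <- y[t] + weights[j] * x[t - j + 1]
    }
  }
  y
}
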