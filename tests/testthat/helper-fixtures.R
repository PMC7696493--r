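# Shared fixtures, all generated in code.

# Short ride for unit tests.
small_recording <- function(seed = 1, n_cycles = 5, snr_db = 10) {
  generate_recording(sim_config(n_cycles = n_cycles, vibration_snr_db = snr_db,
                                seed = seed))
}

# Four well-separated Gaussian clusters in 5-D, one per phase.
toy_clusters <- function(n_per_class = 20, sd = 0.15, seed = 42) {
  centers <- rbind(c(2, 0, 0, 0, 0), c(0, 2, 0, 0, 0),
                   c(0, 0, 2, 0, 0), c(0, 0, 0, 2, 0))
  set.seed(seed)
  x <- do.call(rbind, lapply(1:4, function(k)
    sweep(matrix(rnorm(n_per_class * 5, sd = sd), n_per_class, 5), 2,
          centers[k, ], "+")))
  labeled_dataset(x, rep(1:4, each = n_per_class),
                  cycle = rep(seq_len(n_per_class), times = 4))
}

# Two linearly separable clusters with +/-1 labels.
toy_binary <- function(n = 20, gap = 4, seed = 7) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * 5 / 2, mean = gap / 2, sd = 0.3), n / 2, 5),
             matrix(rnorm(n * 5 / 2, mean = -gap / 2, sd = 0.3), n / 2, 5))
  list(x = x, y = rep(c(1L, -1L), each = n / 2))
}

# Hand-built binary SVM node with known parameters (for decision-rule tests).
manual_node <- function(sv, coef, b, kernel = kernel_spec("rbf", gamma = 1)) {
  structure(list(sv = sv, coef = coef, b = b, C = 1, kernel = kernel),
            class = "svm_binary")
}
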