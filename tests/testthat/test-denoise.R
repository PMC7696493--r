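test_that("noise-scale estimator is exact on fixtures and consistent on Gaussians", {
  expect_identical(estimate_tau(rep(0, 8)), 0)
  expect_equal(estimate_tau(c(-0.6745, 0.6745)), 1.0)
  set.seed(1)
  expect_gte(estimate_tau(rnorm(1e4)), 0.95)
  expect_lte(estimate_tau(rnorm(1e4)), 1.05)
  expect_error(estimate_tau(numeric(0)), "non-empty")
})

test_that("universal threshold follows tau * sqrt(2 ln D)", {
  expect_identical(universal_threshold(0, 1000), 0)
  expect_identical(universal_threshold(5, 1), 0)
  expect_equal(universal_threshold(1, exp(2)), 2.0)
  expect_equal(universal_threshold(2, 1024), 2 * sqrt(2 * log(1024)),
               tolerance = 1e-12)
  expect_equal(universal_threshold(2, 1024), 7.4466, tolerance = 1e-4)
  expect_error(universal_threshold(1, 0), "D")
})

test_that("combined soft-hard shrinkage matches its defining cases", {
  expect_equal(shrink(2.0, 1.0, 0), 2.0)        # hard threshold keeps
  expect_equal(shrink(0.5, 1.0, 0.7), 0)        # below threshold kills
  expect_equal(shrink(-2.0, 1.0, 0.5), -1.5)    # combined rule, default k
  expect_equal(shrink(3.0, 1.0, 1), 2.0)        # soft threshold shrinks by alpha
  expect_error(shrink(1, 1, 1.5), "k must")
  expect_error(shrink(1, -1, 0.5), "alpha")
})

test_that("vectorized shrinkage equals the scalar-loop oracle", {
  set.seed(11)
  for (rep in 1:5) {
    g <- rnorm(200, sd = 2)
    alpha <- runif(1, 0, 2)
    k <- runif(1)
    oracle <- vapply(g, function(gi)
      if (abs(gi) > alpha) sign(gi) * (abs(gi) - k * alpha) else 0, numeric(1))
    expect_identical(shrink(g, alpha, k), oracle)
  }
})

test_that("shrinkage is nonexpansive, odd and monotone in k", {
  set.seed(12)
  g <- rnorm(1e4, sd = 3)
  for (k in c(0, 0.3, 1)) {
    G <- shrink(g, 1, k)
    expect_true(all(abs(G) <= abs(g)))
    expect_equal(shrink(-g, 1, k), -G)
  }
  ks <- seq(0, 1, by = 0.1)
  mags <- sapply(ks, function(k) abs(shrink(2.5, 1, k)))
  expect_true(all(diff(mags) <= 0))
})

test_that("wavelet-packet transform reconstructs exactly for every basis", {
  set.seed(3)
  for (wv in c("haar", "db2", "db4", "db8")) {
    for (n in c(128, 250, 333)) {
      x <- rnorm(n)
      sb <- wp_decompose(x, wv, 3)
      expect_length(sb$bands, 8)
      expect_equal(wp_reconstruct(sb), x, tolerance = 1e-10)
    }
  }
  expect_error(wp_decompose(rnorm(4), "db4", 3), "too short")
  expect_error(wp_decompose(rnorm(64), "nosuch", 2), "unknown wavelet")
})

test_that("zero threshold is the identity and thresholding removes energy", {
  set.seed(4)
  x <- sin(2 * pi * (0:499) / 50) + rnorm(500, sd = 0.3)
  out <- denoise_channel(x, shrinkage_spec(alpha = 0))
  expect_equal(out, x, tolerance = 1e-8)

  noise <- rnorm(512)
  out_n <- denoise_channel(noise, shrinkage_spec(k = 0.5))
  expect_lt(rms(out_n), rms(noise))
  expect_error(denoise_channel(rnorm(4), shrinkage_spec(level = 3)), "too short")
})

test_that("denoising raises the SNR of a noisy sinusoid", {
  set.seed(5)
  t <- (0:2047) / 100
  clean <- sin(2 * pi * 1 * t) + 0.4 * sin(2 * pi * 2 * t)
  noisy <- clean + rnorm(length(t), sd = rms(clean) * 10^(-10 / 20))
  for (per_sb in c(FALSE, TRUE)) {
    out <- denoise_channel(noisy, shrinkage_spec(per_subband = per_sb))
    expect_gt(snr_db(clean, out), snr_db(clean, noisy))
  }
})

test_that("recording denoise treats the knee angle as exempt", {
  rec <- small_recording(seed = 6, n_cycles = 4)
  # inject noise into the angle channel: it must come back untouched
  rec$a <- rec$a + rnorm(nrow(rec), sd = 2)
  out <- denoise_recording(rec)
  expect_identical(out$a, rec$a)
  expect_identical(out$label, rec$label)
  expect_identical(out$t, rec$t)
  expect_false(identical(out$kx, rec$kx))

  # near-identity on a noiseless recording
  rec0 <- generate_recording(sim_config(n_cycles = 4, vibration_snr_db = Inf))
  out0 <- denoise_recording(rec0)
  for (ch in c("kx", "ky", "hx", "hy"))
    expect_gt(snr_db(rec0[[ch]], out0[[ch]]), 30)
})
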