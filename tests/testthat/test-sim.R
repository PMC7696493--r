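test_that("crank trajectory follows the linear constant-cadence model", {
  cfg <- sim_config(cadence_rpm = 60, sample_rate_hz = 100, n_cycles = 1)
  phi <- crank_trajectory(cfg)
  expect_length(phi, 100)                       # period = 60/cadence = 1 s
  expect_equal(diff(range(attr(phi, "t"))), 0.99)
  # one full 360-degree sweep: consecutive increments all equal
  expect_equal(unique(round(diff(phi) %% 360, 10)), 3.6)

  cfg30 <- sim_config(cadence_rpm = 30, n_cycles = 1)
  expect_length(crank_trajectory(cfg30), 200)   # period 2 s at 100 Hz

  # direct evaluation of the linear model
  phi0 <- crank_trajectory(sim_config(cadence_rpm = 60), phi0 = 0)
  t <- attr(phi0, "t")
  expect_equal(phi0[which(t == 0.25)], 90)

  expect_error(sim_config(cadence_rpm = 0), "cadence")
  expect_error(sim_config(sample_rate_hz = -1), "sample_rate")
})

test_that("crank-angle quadrants map to the four phases", {
  expect_identical(label_from_crank(0), 1L)     # pedaling
  expect_identical(label_from_crank(180), 3L)   # relaxation
  expect_identical(label_from_crank(270), 2L)   # lower buffer
  expect_identical(label_from_crank(90), 4L)    # upper buffer
  # exhaustive sweep: four contiguous 90-degree bands tiling the circle
  sweep_labels <- label_from_crank(0:359)
  expect_equal(unname(table(sweep_labels)), rep(90L, 4) , ignore_attr = TRUE)
  expect_identical(label_from_crank(c(45, 45.001)), c(1L, 4L))
  expect_identical(label_from_crank(-45 + 360 * 5 + 0.5), 1L)
  expect_error(label_from_crank(NaN), "finite")
})

test_that("knee-angle waveform passes through its anchors and stays in range", {
  anchors <- c(85.5, 107, 96.5, 74.5)
  onsets <- c(45, 315, 225, 135)   # pedaling, lower buffer, relaxation, upper
  expect_equal(knee_angle_waveform(onsets, anchors), anchors, tolerance = 1e-10)
  # constant anchors give a constant waveform
  expect_equal(knee_angle_waveform(seq(0, 359), rep(90, 4)), rep(90, 360))
  # global max sits at the lower-buffer anchor
  dense <- knee_angle_waveform(seq(0, 360, by = 0.05), anchors)
  expect_gte(max(dense), 106)
  expect_lte(max(dense), 108)
  expect_true(all(dense >= 74.5 - 1e-9 & dense <= 107 + 1e-9))
  expect_error(knee_angle_waveform(0, c(107, 85.5, 96.5, 74.5)), "anchors")
})

test_that("generated recordings are labeled, deterministic and phase-ordered", {
  rec <- small_recording(seed = 3, n_cycles = 1)
  # each phase occupies a quarter of the cycle (give or take one sample)
  expect_true(all(abs(tabulate(rec$label, 4) - 25) <= 1))
  # phases appear in the narrative order pedaling -> lower buffer ->
  # relaxation -> upper buffer as time advances
  rec3 <- small_recording(seed = 3, n_cycles = 3)
  changes <- rle(rec3$label)$values
  expect_identical(changes[1:8], rep(1:4, 2))

  expect_identical(small_recording(seed = 9), small_recording(seed = 9))
  rec_a <- small_recording(seed = 9)
  rec_b <- small_recording(seed = 10)
  expect_false(identical(rec_a$kx, rec_b$kx))
})

test_that("vibration noise hits the requested per-channel SNR", {
  rec <- small_recording(seed = 2, n_cycles = 10, snr_db = 10)
  clean <- attr(rec, "clean")
  for (ch in c("kx", "ky", "hx", "hy"))
    expect_equal(snr_db(clean[, ch], rec[[ch]]), 10, tolerance = 0.5)
})

test_that("a noiseless recording is exactly periodic with the crank period", {
  rec <- generate_recording(sim_config(n_cycles = 3, vibration_snr_db = Inf))
  per <- 100  # samples per cycle at 60 rpm, 100 Hz
  for (ch in c("kx", "ky", "hx", "hy", "a"))
    expect_equal(rec[[ch]][1:per], rec[[ch]][per + (1:per)], tolerance = 1e-9)
})

test_that("recordings survive a CSV round trip", {
  rec <- small_recording(seed = 5, n_cycles = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_s3_class(back, "cycling_recording")
  expect_equal(back$kx, rec$kx, tolerance = 1e-12)
  expect_identical(back$label, rec$label)
})
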