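# Synthetic cycling-kinematics simulator.
#
# Conventions. The crank angle phi_c is the angle between the pedal crank and
# the horizontal plane, and the four phases tile the circle in quadrants:
# pedaling (-45, 45], upper buffer (45, 135], relaxation (135, 225] and
# lower buffer (225, 315] (the one quadrant left over once the other three
# are fixed). Under this geometric convention a forward-pedaling crank sweeps
# phi_c *downwards*, so the simulator integrates the crank with direction -1;
# that is what makes the labels cycle pedaling -> lower buffer -> relaxation
# -> upper buffer in time. `crank_trajectory()` defaults to direction +1 so
# that it is the plain linear model phi_c(t) = (6*cadence*t + phi0) mod 360.

#' Simulation configuration
#'
#' Parameters of the synthetic crank-driven recording. The four knee-angle
#' anchors are the knee angles at the four phase onsets (pedaling, lower
#' buffer, relaxation, upper buffer), in degrees; defaults are the midpoints
#' of the ranges observed in static experiments with prosthesis wearers
#' (84--87, 106--108, 95--98, 73--76). The default amplitude 6.7 m/s^2 is the
#' centripetal acceleration of a 0.17 m pedal circle at 60 rpm.
#'
#' @param cadence_rpm pedaling cadence, rotations per minute (> 0)
#' @param sample_rate_hz sampling rate in Hz (> 0)
#' @param n_cycles number of full crank revolutions (integer >= 1)
#' @param knee_angle_anchors four knee angles (degrees) at the phase onsets,
#'   in order pedaling, lower buffer, relaxation, upper buffer; the lower
#'   buffer anchor must be the maximum and the upper buffer anchor the
#'   minimum (non-strictly)
#' @param accel_amplitude ankle acceleration amplitude in m/s^2
#' @param vibration_snr_db per-channel SNR (dB) of the added band-limited
#'   vibration noise; `Inf` for a noiseless recording
#' @param seed integer RNG seed; with a fixed seed the recording is
#'   bit-identical across runs
#' @return object of class `sim_config`
#' @export
sim_config <- function(cadence_rpm = 60, sample_rate_hz = 100, n_cycles = 50,
                       knee_angle_anchors = c(pedaling = 85.5, lower_buffer = 107,
                                              relaxation = 96.5, upper_buffer = 74.5),
                       accel_amplitude = 6.7, vibration_snr_db = 10, seed = 1L) {
  if (!is.numeric(cadence_rpm) || length(cadence_rpm) != 1 || cadence_rpm <= 0)
    stop_config("cadence_rpm must be a single positive number")
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 || sample_rate_hz <= 0)
    stop_config("sample_rate_hz must be a single positive number")
  if (!is.numeric(n_cycles) || length(n_cycles) != 1 || n_cycles < 1 ||
      n_cycles != round(n_cycles))
    stop_config("n_cycles must be a positive integer")
  if (length(knee_angle_anchors) != 4 || !all(is.finite(knee_angle_anchors)))
    stop_config("knee_angle_anchors must be four finite angles")
  a <- unname(knee_angle_anchors)
  if (a[2] < max(a[1], a[3]) || a[4] > min(a[1], a[3]))
    stop_config("anchors must peak at the lower-buffer onset and trough at the upper-buffer onset")
  if (!is.numeric(accel_amplitude) || accel_amplitude <= 0)
    stop_config("accel_amplitude must be positive")
  structure(list(cadence_rpm = cadence_rpm, sample_rate_hz = sample_rate_hz,
                 n_cycles = as.integer(n_cycles), knee_angle_anchors = a,
                 accel_amplitude = accel_amplitude,
                 vibration_snr_db = vibration_snr_db, seed = as.integer(seed)),
            class = "sim_config")
}

#' Constant-cadence crank trajectory
#'
#' Linear crank model `phi_c(t) = (360 * cadence/60 * t * direction + phi0)
#' mod 360`, sampled at the configured rate for `n_cycles` revolutions.
#' The default `phi0` places t = 0 at the pedaling-phase onset for the given
#' direction (-45 deg for direction +1, +45 deg for direction -1).
#'
#' @param config a [sim_config()]
#' @param phi0 initial crank angle in degrees (default: pedaling onset)
#' @param direction +1 for increasing phi_c, -1 for the physical forward
#'   rotation used by [generate_recording()]
#' @return numeric vector of crank angles in [0, 360), one per sample, with
#'   the sample times (seconds) in attribute `"t"`
#' @export
crank_trajectory <- function(config, phi0 = NULL, direction = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (!direction %in% c(-1, 1)) stop_config("direction must be +1 or -1")
  if (is.null(phi0)) phi0 <- if (direction > 0) -45 else 45
  n <- round(config$n_cycles * config$sample_rate_hz * 60 / config$cadence_rpm)
  t <- (seq_len(n) - 1) / config$sample_rate_hz
  phi <- (360 * config$cadence_rpm / 60 * t * direction + phi0) %% 360
  attr(phi, "t") <- t
  phi
}

#' Phase label from crank angle
#'
#' Quadrant phase map on the geometric crank angle: pedaling (1) for
#' phi_c in (-45, 45], upper buffer (4) for (45, 135], relaxation (3) for
#' (135, 225], lower buffer (2) for (225, 315]; angles are reduced mod 360
#' into (-45, 315].
#'
#' @param phi_c crank angle(s) in degrees
#' @return integer phase labels in {1, 2, 3, 4}
#' @export
label_from_crank <- function(phi_c) {
  if (!is.numeric(phi_c) || any(!is.finite(phi_c)))
    stop("phi_c must be finite numeric")
  r <- phi_c %% 360
  r[r > 315] <- r[r > 315] - 360
  ifelse(r <= 45, 1L, ifelse(r <= 135, 4L, ifelse(r <= 225, 3L, 2L)))
}

# Cycle position in [0, 1): 0 at pedaling onset, increasing along the
# physical (direction -1) rotation.
crank_to_cycle_pos <- function(phi_c) ((45 - phi_c) %% 360) / 360

#' Knee-angle waveform from crank angle
#'
#' Smooth periodic knee-angle curve passing through the four anchor values at
#' the four phase-onset crank angles (pedaling 45 deg, lower buffer 315 deg,
#' relaxation 225 deg, upper buffer 135 deg). Monotone piecewise-cubic
#' (PCHIP) in cycle position between anchors, so the global maximum is the
#' lower-buffer anchor and the global minimum the upper-buffer anchor,
#' attained exactly at their onsets.
#'
#' @param phi_c crank angle(s), degrees
#' @param anchors four knee angles (degrees): pedaling, lower buffer,
#'   relaxation, upper buffer onset values
#' @return knee angle(s) in degrees
#' @export
knee_angle_waveform <- function(phi_c, anchors) {
  if (length(anchors) != 4 || !all(is.finite(anchors)))
    stop_config("anchors must be four finite angles")
  a <- unname(anchors)
  if (a[2] < max(a[1], a[3]) || a[4] > min(a[1], a[3]))
    stop_config("anchors must peak at the lower-buffer onset and trough at the upper-buffer onset")
  s <- crank_to_cycle_pos(phi_c)
  xs <- c(-0.25, 0, 0.25, 0.5, 0.75, 1, 1.25)
  ys <- c(a[4], a[1], a[2], a[3], a[4], a[1], a[2])
  if (length(unique(ys)) == 1) return(rep(ys[1], length(s)))
  pracma::pchip(xs, ys, s)
}

#' Generate a labeled synthetic cycling recording
#'
#' Simulates one constant-cadence ride. The ankle rides the pedal circle
#' (pure first harmonic of the crank frequency); the knee accelerations are a
#' smaller first plus second harmonic (amplitudes 0.45 and 0.20 of the ankle
#' amplitude, phase-shifted per channel so every channel is phase
#' informative). Vibration noise is Gaussian white noise band-pass filtered
#' to 5--20 Hz (4th-order Butterworth, zero-phase) and scaled per channel to
#' `vibration_snr_db`; it is added to the four acceleration channels only,
#' since the knee-angle sensor is interference-proof. Ground-truth labels
#' come from the crank angle via [label_from_crank()].
#'
#' @param config a [sim_config()]
#' @return a `cycling_recording`: data frame with columns `t`, `crank`,
#'   `kx`, `ky` (knee horizontal/vertical acceleration), `hx`, `hy` (ankle),
#'   `a` (knee angle, degrees) and integer `label`; the clean acceleration
#'   channels are kept in attribute `"clean"` for SNR bookkeeping
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sample_rate_hz
  phi <- crank_trajectory(config, direction = -1)
  t <- attr(phi, "t")
  n <- length(t)
  theta <- 2 * pi * config$cadence_rpm / 60 * t
  A <- config$accel_amplitude
  clean <- cbind(
    kx = 0.45 * A * cos(theta + 0.6) + 0.20 * A * cos(2 * theta + 1.1),
    ky = 0.45 * A * sin(theta + 0.3) + 0.20 * A * sin(2 * theta + 0.9),
    hx = A * cos(theta),
    hy = A * sin(theta))
  noisy <- clean
  snr <- config$vibration_snr_db
  if (is.finite(snr)) {
    if (fs <= 42)
      stop_config("sample_rate_hz too low for the 5-20 Hz vibration band")
    bf <- signal::butter(4, c(5, 20) / (fs / 2), type = "pass")
    noise <- with_seed(config$seed, matrix(rnorm(n * 4), n, 4))
    for (j in 1:4) {
      e <- signal::filtfilt(bf, noise[, j])
      e <- e * (rms(clean[, j]) * 10^(-snr / 20)) / rms(e)
      noisy[, j] <- clean[, j] + e
    }
  }
  rec <- data.frame(t = t, crank = as.numeric(phi),
                    kx = noisy[, "kx"], ky = noisy[, "ky"],
                    hx = noisy[, "hx"], hy = noisy[, "hy"],
                    a = knee_angle_waveform(phi, config$knee_angle_anchors),
                    label = label_from_crank(phi))
  class(rec) <- c("cycling_recording", "data.frame")
  attr(rec, "sample_rate_hz") <- fs
  attr(rec, "cadence_rpm") <- config$cadence_rpm
  attr(rec, "clean") <- clean
  rec
}

recording_channels <- c("kx", "ky", "hx", "hy")

#' Write / read a cycling recording as CSV
#'
#' Columns `t,crank,kx,ky,hx,hy,a,label`, header row, UTF-8, '.' decimal.
#'
#' @param rec a `cycling_recording`
#' @param path file path
#' @return `read_recording` returns a `cycling_recording`
#' @export
write_recording <- function(rec, path) {
  cols <- c("t", "crank", recording_channels, "a", "label")
  stopifnot(all(cols %in% names(rec)))
  write.csv(as.data.frame(rec)[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  rec <- read.csv(path)
  cols <- c("t", "crank", recording_channels, "a")
  if (!all(cols %in% names(rec)))
    stop("recording CSV must have columns t,crank,kx,ky,hx,hy,a[,label]")
  if (is.null(rec$label)) rec$label <- NA_integer_ else rec$label <- as.integer(rec$label)
  class(rec) <- c("cycling_recording", "data.frame")
  rec
}

#' @export
print.cycling_recording <- function(x, ...) {
  cat(sprintf("<cycling_recording> %d samples, %d channels + knee angle\n",
              nrow(x), length(recording_channels)))
  if (!all(is.na(x$label)))
    cat("  labels:", paste(sprintf("%d:%d", 1:4, tabulate(x$label, 4)), collapse = " "), "\n")
  invisible(x)
}
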