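# Combined soft-hard threshold wavelet-packet denoising.
#
# The shrinkage rule interpolates between the classical hard (k = 0) and
# soft (k = 1) thresholds: coefficients at or below the threshold alpha are
# zeroed; those above it keep their sign and lose k*alpha of magnitude.
# The threshold is the universal threshold alpha = tau * sqrt(2 * ln D) for
# D coefficients, with the noise scale tau estimated robustly (MAD / 0.6745)
# from the finest-level detail coefficients.

#' Shrinkage specification
#'
#' @param k soft-hard mix factor in [0, 1]: 0 is the hard threshold, 1 the
#'   soft threshold; 0.5 (default) is the combined rule that best preserves
#'   signal features while suppressing vibration noise
#' @param tau noise scale (signal units); `NULL` to estimate from the data
#' @param alpha threshold (signal units, >= 0); `NULL` to derive from `tau`
#'   via the universal threshold
#' @param wavelet basis name (see [wp_decompose()])
#' @param level decomposition depth
#' @param per_subband if `TRUE`, estimate tau and alpha separately per
#'   detail subband instead of one global threshold
#' @return object of class `shrinkage_spec`
#' @export
shrinkage_spec <- function(k = 0.5, tau = NULL, alpha = NULL,
                           wavelet = "db4", level = 3, per_subband = FALSE) {
  if (!is.numeric(k) || length(k) != 1 || k < 0 || k > 1)
    stop("k must be in [0, 1]")
  if (!is.null(alpha) && alpha < 0) stop("alpha must be >= 0")
  if (!is.null(tau) && tau < 0) stop("tau must be >= 0")
  if (level < 1 || level != round(level)) stop_config("level must be a positive integer")
  get_filters(wavelet)  # validate name
  structure(list(k = k, tau = tau, alpha = alpha, wavelet = wavelet,
                 level = as.integer(level), per_subband = isTRUE(per_subband)),
            class = "shrinkage_spec")
}

#' Robust noise-scale estimate
#'
#' `tau = median(|coeffs|) / 0.6745`, the median-absolute-deviation estimate
#' of the noise standard deviation, computed on finest-level detail
#' coefficients where the signal contributes little.
#'
#' @param detail_coeffs numeric vector of detail coefficients
#' @return noise scale tau
#' @export
estimate_tau <- function(detail_coeffs) {
  if (length(detail_coeffs) == 0) stop("detail_coeffs must be non-empty")
  median(abs(detail_coeffs)) / 0.6745
}

#' Universal threshold
#'
#' `alpha = tau * sqrt(2 * ln(D))` for `D` coefficients with noise scale
#' `tau` (Donoho-Johnstone).
#'
#' @param tau noise scale (>= 0)
#' @param D coefficient count (>= 1)
#' @return threshold alpha
#' @export
universal_threshold <- function(tau, D) {
  if (D < 1) stop("D must be >= 1")
  if (tau < 0) stop("tau must be >= 0")
  tau * sqrt(2 * log(D))
}

#' Combined soft-hard threshold shrinkage
#'
#' `G = sign(g) * (|g| - k*alpha)` when `|g| > alpha`, else 0. Vectorized
#' elementwise over `g`.
#'
#' @param g wavelet coefficient(s)
#' @param alpha threshold (>= 0)
#' @param k soft-hard mix factor in [0, 1]
#' @return shrunk coefficient(s)
#' @export
shrink <- function(g, alpha, k) {
  if (!is.numeric(k) || length(k) != 1 || k < 0 || k > 1)
    stop("k must be in [0, 1]")
  if (alpha < 0) stop("alpha must be >= 0")
  ifelse(abs(g) > alpha, sign(g) * (abs(g) - k * alpha), 0)
}

#' Denoise one channel
#'
#' Wavelet-packet decompose to `spec$level`, shrink every subband except the
#' all-lowpass (approximation) band with the combined soft-hard rule, and
#' reconstruct. Unless fixed in `spec`, tau is estimated once from the
#' first-level detail (highpass) coefficients and alpha is the universal
#' threshold for the subband coefficient count; with `per_subband = TRUE`
#' each detail subband gets its own tau and alpha.
#'
#' @param x numeric signal (length >= 2^level)
#' @param spec a [shrinkage_spec()]
#' @return denoised signal, same length as `x`
#' @export
denoise_channel <- function(x, spec = shrinkage_spec()) {
  stopifnot(inherits(spec, "shrinkage_spec"))
  if (length(x) < 2^spec$level)
    stop("signal too short for decomposition level ", spec$level)
  sb <- wp_decompose(x, spec$wavelet, spec$level)
  nb <- length(sb$bands)
  if (!spec$per_subband) {
    tau <- spec$tau
    if (is.null(tau)) {
      f <- get_filters(spec$wavelet)
      xe <- if (length(x) %% 2) c(x, x[length(x)]) else x
      tau <- estimate_tau(wp_ana_step(xe, f$hi))
    }
    alpha <- spec$alpha
    if (is.null(alpha)) alpha <- universal_threshold(tau, length(sb$bands[[2]]))
    for (i in 2:nb) sb$bands[[i]] <- shrink(sb$bands[[i]], alpha, spec$k)
  } else {
    for (i in 2:nb) {
      tau_i <- if (is.null(spec$tau)) estimate_tau(sb$bands[[i]]) else spec$tau
      alpha_i <- if (is.null(spec$alpha))
        universal_threshold(tau_i, length(sb$bands[[i]])) else spec$alpha
      sb$bands[[i]] <- shrink(sb$bands[[i]], alpha_i, spec$k)
    }
  }
  wp_reconstruct(sb)
}

#' Denoise the acceleration channels of a recording
#'
#' Applies [denoise_channel()] to `kx`, `ky`, `hx`, `hy`. The knee angle `a`
#' is passed through unchanged (the angle sensor is interference-proof and
#' needs no noise reduction); timestamps, crank angles and labels are
#' preserved.
#'
#' @param rec a `cycling_recording`
#' @param spec a [shrinkage_spec()]
#' @return the recording with denoised acceleration channels
#' @export
denoise_recording <- function(rec, spec = shrinkage_spec()) {
  stopifnot(inherits(rec, "data.frame"))
  if (!all(recording_channels %in% names(rec)))
    stop("recording must have channels kx, ky, hx, hy")
  for (ch in recording_channels) rec[[ch]] <- denoise_channel(rec[[ch]], spec)
  rec
}
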