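# Orthogonal wavelet-packet transform, decimated, with periodized boundaries.
# Analysis and synthesis are exact transposes of one another, so the full
# packet tree reconstructs the input to machine precision. Inputs whose
# length is not a multiple of 2^level are symmetric-padded at the tail first
# and truncated after reconstruction.

# Daubechies lowpass decomposition filters (orthonormal, sum = sqrt(2)).
wavelet_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255126037, 0.2241438680420134,
          0.8365163037378079, 0.48296291314453416),
  db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965),
  db8 = c(-0.00011747678412476953, 0.0006754494064505693,
          -0.00039174037337694705, -0.004870352993451574,
          0.008746094047405777, 0.013981027917398282,
          -0.044088253930794755, -0.017369301001807547,
          0.12874742662047847, 0.0004724845739132828,
          -0.2840155429615469, -0.015829105256349306,
          0.5853546836542067, 0.6756307362972898,
          0.31287159091429995, 0.05441584224310401))

get_filters <- function(wavelet) {
  lo <- wavelet_filters[[wavelet]]
  if (is.null(lo))
    stop_config("unknown wavelet '", wavelet, "'; available: ",
                paste(names(wavelet_filters), collapse = ", "))
  L <- length(lo)
  list(lo = lo, hi = (-1)^(0:(L - 1)) * rev(lo), len = L)
}

# One periodized analysis step: length-n input -> length-n/2 band.
wp_ana_step <- function(x, h) {
  n <- length(x)
  n2 <- n %/% 2
  out <- numeric(n2)
  base <- 2 * (0:(n2 - 1))
  for (m in seq_along(h)) out <- out + h[m] * x[((base + m - 1) %% n) + 1]
  out
}

# Transpose of wp_ana_step for a low/high band pair.
wp_syn_step <- function(a, d, lo, hi) {
  n <- 2 * length(a)
  y <- numeric(n)
  base <- 2 * (0:(length(a) - 1))
  for (m in seq_along(lo)) {
    idx <- ((base + m - 1) %% n) + 1
    y[idx] <- y[idx] + lo[m] * a + hi[m] * d
  }
  y
}

#' Wavelet-packet decomposition
#'
#' Decimated orthogonal wavelet-packet transform to a fixed depth. Subbands
#' are returned in natural (Paley) order; the first subband is the
#' all-lowpass (approximation) path. `level` halvings require the padded
#' length per subband to stay at least the filter length.
#'
#' @param x numeric signal
#' @param wavelet basis name: one of `"haar"`, `"db2"`, `"db4"`, `"db8"`
#' @param level decomposition depth (integer >= 1)
#' @return object of class `subband_set`: list with `bands` (list of 2^level
#'   coefficient vectors, named `L<level>.<index>`), the original length,
#'   wavelet and level
#' @export
wp_decompose <- function(x, wavelet = "db4", level = 3) {
  if (!is.numeric(x)) stop("x must be numeric")
  if (level < 1 || level != round(level)) stop_config("level must be a positive integer")
  f <- get_filters(wavelet)
  n <- length(x)
  if (n < 2^level) stop("signal too short for decomposition level ", level)
  block <- 2^level
  n_pad <- ceiling(n / block) * block
  if (n_pad / block < f$len)
    n_pad <- block * f$len
  if (n_pad > n) {
    # symmetric (reflected) tail padding
    refl <- rev(x)[seq_len(min(n, n_pad - n))]
    while (length(refl) < n_pad - n) refl <- c(refl, rev(refl))[seq_len(n_pad - n)]
    x <- c(x, refl)
  }
  bands <- list(x)
  for (l in seq_len(level)) {
    nb <- vector("list", 2 * length(bands))
    for (i in seq_along(bands)) {
      nb[[2 * i - 1]] <- wp_ana_step(bands[[i]], f$lo)
      nb[[2 * i]] <- wp_ana_step(bands[[i]], f$hi)
    }
    bands <- nb
  }
  names(bands) <- sprintf("L%d.%d", level, seq_along(bands))
  structure(list(bands = bands, n = n, wavelet = wavelet, level = level),
            class = "subband_set")
}

#' Wavelet-packet reconstruction
#'
#' Inverse of [wp_decompose()]; output is truncated to the original signal
#' length. Reconstructing unmodified subbands reproduces the input to
#' numerical precision.
#'
#' @param sb a `subband_set`
#' @return numeric signal of the original length
#' @export
wp_reconstruct <- function(sb) {
  stopifnot(inherits(sb, "subband_set"))
  f <- get_filters(sb$wavelet)
  bands <- sb$bands
  while (length(bands) > 1) {
    nb <- vector("list", length(bands) / 2)
    for (i in seq_along(nb))
      nb[[i]] <- wp_syn_step(bands[[2 * i - 1]], bands[[2 * i]], f$lo, f$hi)
    bands <- nb
  }
  bands[[1]][seq_len(sb$n)]
}
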