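# Shared internal helpers.

#' Root-mean-square of a numeric vector
#' @param x numeric vector
#' @return scalar RMS
#' @export
rms <- function(x) sqrt(mean(x^2))

#' Signal-to-noise ratio in decibels
#'
#' SNR of `noisy` relative to the known clean component, defined on RMS:
#' `20*log10(rms(clean) / rms(noisy - clean))`.
#'
#' @param clean clean signal
#' @param noisy observed signal (same length)
#' @return SNR in dB (`Inf` when the two are identical)
#' @export
snr_db <- function(clean, noisy) {
  if (length(clean) != length(noisy)) stop("clean and noisy must have equal length")
  r <- rms(noisy - clean)
  if (r == 0) return(Inf)
  20 * log10(rms(clean) / r)
}

#' Round half away from zero
#'
#' Display rounding used for the percent tables: ties go up (e.g. 94.655 ->
#' 94.66), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric
#' @param digits decimal places
#' @return rounded numeric
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate expr with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_config <- function(...) stop(..., call. = FALSE)
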