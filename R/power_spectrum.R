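#' Construct a power spectrum object
#'
#' A `power_spectrum` holds a frequency grid together with power values for one
#' channel/condition. Power is stored in log10 units by default, which is the
#' scale on which the parameterization algorithm operates.
#'
#' @param freqs Numeric vector of frequencies in Hz, strictly increasing.
#' @param power Numeric vector of power values, same length as `freqs`.
#' @param scale_tag Either `"log"` (log10 power, the default) or `"linear"`.
#' @param n_epochs_used Number of epochs averaged into this spectrum (`NA` for
#'   model-generated spectra).
#' @return An object of class `power_spectrum`.
#' @export
power_spectrum <- function(freqs, power, scale_tag = c("log", "linear"),
                           n_epochs_used = NA_integer_) {
  scale_tag <- match.arg(scale_tag)
  freqs <- as.numeric(freqs)
  power <- as.numeric(power)
  if (length(freqs) != length(power)) {
    stop("`freqs` and `power` must have the same length", call. = FALSE)
  }
  if (length(freqs) < 2L || any(diff(freqs) <= 0)) {
    stop("`freqs` must be strictly increasing with at least two bins", call. = FALSE)
  }
  if (!all(is.finite(power))) {
    stop("`power` must be finite at every bin", call. = FALSE)
  }
  if (scale_tag == "linear" && any(power <= 0)) {
    stop("linear-scale power must be strictly positive", call. = FALSE)
  }
  structure(
    list(freqs = freqs, power = power, scale_tag = scale_tag,
         n_epochs_used = n_epochs_used),
    class = "power_spectrum"
  )
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, %.2f-%.2f Hz (%s scale)\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$scale_tag))
  invisible(x)
}

#' Convert a power spectrum between log10 and linear scales
#'
#' The log10 transform and its inverse round-trip exactly; linear power is
#' strictly positive by construction.
#'
#' @param spectrum A [power_spectrum].
#' @param scale_tag Target scale, `"log"` or `"linear"`.
#' @return A [power_spectrum] on the requested scale.
#' @export
spectrum_rescale <- function(spectrum, scale_tag = c("log", "linear")) {
  scale_tag <- match.arg(scale_tag)
  stopifnot(inherits(spectrum, "power_spectrum"))
  if (spectrum$scale_tag == scale_tag) return(spectrum)
  pw <- if (scale_tag == "linear") 10^spectrum$power else log10(spectrum$power)
  power_spectrum(spectrum$freqs, pw, scale_tag, spectrum$n_epochs_used)
}

# index range of band within grid, endpoints inclusive (with fp tolerance)
band_index <- function(freqs, band) {
  if (length(band) != 2L || band[2] < band[1]) {
    stop("`band` must be c(lo, hi) with lo <= hi", call. = FALSE)
  }
  eps <- 1e-9
  idx <- which(freqs >= band[1] - eps & freqs <= band[2] + eps)
  if (length(idx) == 0L) stop("band does not overlap the frequency grid", call. = FALSE)
  idx
}
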