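#' Construct an epoched EEG signal
#'
#' Samples are stored as an `n_epochs x n_samples` matrix in microvolts for a
#' single channel. All epochs have equal length and `fs * epoch_length` must be
#' an integer number of samples.
#'
#' @param samples Numeric matrix, one row per epoch, in uV.
#' @param fs Sampling rate in Hz.
#' @param epoch_length Epoch length in seconds (default 2).
#' @return An object of class `epoched_signal`.
#' @export
epoched_signal <- function(samples, fs, epoch_length = 2) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 1L) stop("at least one epoch is required", call. = FALSE)
  n <- fs * epoch_length
  if (abs(n - round(n)) > 1e-9 || ncol(samples) != round(n)) {
    stop("fs * epoch_length must be an integer equal to the epoch sample count",
         call. = FALSE)
  }
  structure(list(samples = samples, fs = fs, epoch_length = epoch_length),
            class = "epoched_signal")
}

#' @export
print.epoched_signal <- function(x, ...) {
  cat(sprintf("<epoched_signal> %d epochs of %.3gs at %g Hz\n",
              nrow(x$samples), x$epoch_length, x$fs))
  invisible(x)
}

#' Reject high-amplitude epochs
#'
#' An epoch is kept only if every sample lies strictly within
#' `(-threshold, +threshold)` uV; an epoch containing a sample at exactly the
#' threshold is kept (the rule is strictly greater/less than). A subject is
#' flagged for exclusion when more than half of the epochs are rejected.
#'
#' @param signal An [epoched_signal].
#' @param threshold Amplitude threshold in uV (default 90).
#' @return A list with `kept` (logical mask over epochs), `fraction_rejected`,
#'   and `subject_excluded` (`TRUE` iff `fraction_rejected > 0.5`).
#' @export
reject_epochs <- function(signal, threshold = 90) {
  stopifnot(inherits(signal, "epoched_signal"))
  mx <- apply(signal$samples, 1L, function(x) max(abs(x)))
  kept <- mx <= threshold          # strict: only samples > +thr or < -thr reject
  frac <- mean(!kept)
  list(kept = kept, fraction_rejected = frac, subject_excluded = frac > 0.5)
}

#' Welch power spectral density of an epoched signal
#'
#' One modified periodogram per kept epoch: the epoch is Hamming-tapered,
#' zero-padded to reach the requested frequency resolution, and its one-sided
#' periodogram is computed; periodograms are averaged across epochs, restricted
#' to the analysis range, and log10-transformed. Zero padding of the 2 s
#' windows to 4 s yields the default 0.25 Hz resolution.
#'
#' @param signal An [epoched_signal].
#' @param kept Logical mask of epochs to use (e.g. from [reject_epochs()]);
#'   `NULL` uses all epochs.
#' @param resolution Frequency resolution in Hz (default 0.25).
#' @param freq_range Output range in Hz (default `c(2, 40)`).
#' @return A [power_spectrum] on the log10 scale with `n_epochs_used` set.
#' @export
welch_psd <- function(signal, kept = NULL, resolution = 0.25,
                      freq_range = c(2, 40)) {
  stopifnot(inherits(signal, "epoched_signal"))
  if (is.null(kept)) kept <- rep(TRUE, nrow(signal$samples))
  if (!any(kept)) {
    stop("no epochs left after rejection; cannot estimate a spectrum",
         call. = FALSE)
  }
  x <- signal$samples[kept, , drop = FALSE]
  n <- ncol(x)
  fs <- signal$fs
  nfft <- round(fs / resolution)
  if (nfft < n) stop("requested resolution finer than the epoch allows requires nfft >= epoch length", call. = FALSE)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))  # Hamming
  norm <- fs * sum(w^2)
  nf <- nfft %/% 2L
  acc <- numeric(nf)
  for (e in seq_len(nrow(x))) {
    xe <- c(x[e, ] * w, numeric(nfft - n))
    X <- stats::fft(xe)[2:(nf + 1L)]
    acc <- acc + (2 / norm) * (Re(X)^2 + Im(X)^2)
  }
  pxx <- acc / nrow(x)
  freqs <- seq_len(nf) * resolution
  idx <- band_index(freqs, freq_range)
  power_spectrum(freqs[idx], log10(pxx[idx]), "log",
                 n_epochs_used = sum(kept))
}
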