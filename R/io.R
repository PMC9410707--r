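#' Read a delimited sample matrix as an epoched signal
#'
#' Adapter for plain-text recordings: a delimited file holding one channel's
#' samples in microvolts (single column or single row), segmented here into
#' consecutive equal-length epochs. Any leading/trailing samples that do not
#' fill a complete epoch are discarded, as is an optional fixed trim at each
#' end of the recording (e.g. to drop instruction/transition periods).
#'
#' @param path Delimited text file of numeric samples.
#' @param fs Sampling rate in Hz.
#' @param epoch_length Epoch length in seconds (default 2).
#' @param trim Seconds discarded from each end before epoching (default 0).
#' @param sep Field separator (default: any whitespace).
#' @return An [epoched_signal].
#' @export
read_signal_delim <- function(path, fs, epoch_length = 2, trim = 0, sep = "") {
  x <- as.numeric(unlist(utils::read.table(path, sep = sep)))
  if (trim > 0) {
    k <- round(trim * fs)
    if (2 * k >= length(x)) stop("trim removes the whole recording", call. = FALSE)
    x <- x[(k + 1L):(length(x) - k)]
  }
  n <- round(fs * epoch_length)
  n_ep <- length(x) %/% n
  if (n_ep < 1L) stop("recording shorter than one epoch", call. = FALSE)
  epoched_signal(matrix(x[seq_len(n_ep * n)], n_ep, n, byrow = TRUE),
                 fs = fs, epoch_length = epoch_length)
}

#' Write / read power spectra as CSV
#'
#' The on-disk format is a frequency column followed by one log10-power column
#' per channel, the layout used for precomputed spectra.
#'
#' @param spectra A [power_spectrum] or a named list of them (shared grid).
#' @param path CSV file path.
#' @return `write_psd_csv` returns `path` invisibly; `read_psd_csv` returns a
#'   named list of [power_spectrum] objects.
#' @export
write_psd_csv <- function(spectra, path) {
  if (inherits(spectra, "power_spectrum")) spectra <- list(power = spectra)
  freqs <- spectra[[1]]$freqs
  for (sp in spectra) {
    stopifnot(inherits(sp, "power_spectrum"))
    if (length(sp$freqs) != length(freqs) ||
        max(abs(sp$freqs - freqs)) > 1e-9) {
      stop("all spectra must share one frequency grid", call. = FALSE)
    }
  }
  df <- data.frame(frequency = freqs)
  for (nm in names(spectra)) {
    df[[nm]] <- spectrum_rescale(spectra[[nm]], "log")$power
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psd_csv
#' @export
read_psd_csv <- function(path) {
  df <- utils::read.csv(path)
  if (names(df)[1] != "frequency") stop("first column must be 'frequency'", call. = FALSE)
  out <- lapply(names(df)[-1], function(nm) {
    power_spectrum(df$frequency, df[[nm]], "log")
  })
  names(out) <- names(df)[-1]
  out
}
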