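#' Logarithmically spaced Hilbert filter bank
#'
#' Thirty bandpass FIR filters with center frequencies logarithmically
#' spaced on 1-30 Hz. Each filter has 1/3 fractional bandwidth rounded up
#' to the nearest 1 Hz and capped at 5 Hz (`bw = min(ceiling(fc/3), 5)`),
#' with passband edges `fc - bw/2` and `fc + bw/2`. Filters are
#' windowed-sinc (Hamming) designs of order equal to three cycles of the
#' lower passband edge, and are applied forward-backward (zero phase), so
#' only the squared magnitude response matters.
#'
#' @param fs sample rate (Hz).
#' @param n_filters number of filters (default 30).
#' @param f_range frequency range (Hz) spanned by the centers.
#' @return An object of class `filter_bank`: a list with `info` (data.frame
#'   of center, bandwidth, edges, band membership, taps length) and `taps`
#'   (list of FIR coefficient vectors).
#' @export
filter_bank <- function(fs = 250, n_filters = 30, f_range = c(1, 30)) {
  fc <- 10^seq(log10(f_range[1]), log10(f_range[2]), length.out = n_filters)
  bw <- pmin(ceiling(fc / 3), 5)
  lo <- fc - bw / 2
  hi <- fc + bw / 2
  ntaps <- round(3 * fs / lo)           # three cycles of the lower edge
  taps <- lapply(seq_along(fc), function(i) {
    signal::fir1(ntaps[i], c(max(lo[i], 0.01), hi[i]) / (fs / 2),
                 type = "pass")
  })
  info <- data.frame(filter = seq_along(fc), center = fc, bandwidth = bw,
                     lo = lo, hi = hi, band = band_of(fc),
                     ntaps = ntaps + 1)
  structure(list(info = info, taps = taps, fs = fs), class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat("<filter_bank>", nrow(x$info), "filters,",
      sprintf("%.2f-%.2f Hz centers, fs %g Hz\n",
              min(x$info$center), max(x$info$center), x$fs))
  invisible(x)
}

#' Frequency-band definitions
#'
#' The four analysis bands: delta `[1, 4)`, theta `[4, 10)`, alpha
#' `[10, 15)` and beta `[15, 30]` Hz. A filter belongs to the band
#' containing its center frequency; edges are half-open (beta closes at
#' 30) so membership is unique.
#'
#' @return named list of `c(lo, hi)` band edges (Hz).
#' @export
eeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 10), alpha = c(10, 15),
       beta = c(15, 30))
}

band_of <- function(f) {
  bands <- eeg_bands()
  out <- rep(NA_character_, length(f))
  for (b in names(bands)) {
    lo <- bands[[b]][1]; hi <- bands[[b]][2]
    sel <- if (b == "beta") f >= lo & f <= hi else f >= lo & f < hi
    out[sel] <- b
  }
  out
}

# Squared-magnitude response of each filter on an N-point FFT grid,
# i.e. the transfer function of the forward-backward (zero-phase)
# application, times the analytic-signal mask.
bank_gains <- function(bank, n) {
  h <- rep(0, n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[2:(n / 2)] <- 2
    h[n / 2 + 1] <- 1
  } else h[2:((n + 1) / 2)] <- 2
  lapply(bank$taps, function(tp) {
    H <- fft(c(tp, rep(0, n - length(tp))))
    Mod(H)^2 * h
  })
}

# Analytic signal via FFT (one-sided spectrum doubling).
hilbert_analytic <- function(x) {
  n <- length(x)
  h <- rep(0, n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[2:(n / 2)] <- 2
    h[n / 2 + 1] <- 1
  } else h[2:((n + 1) / 2)] <- 2
  fft(fft(x) * h, inverse = TRUE) / n
}
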