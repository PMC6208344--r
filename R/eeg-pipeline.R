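#' Two-channel EEG recording container
#'
#' @param a1,a2 numeric vectors: the two ear-referenced channels (A1-Cz and
#'   A2-Cz), equal length.
#' @param fs sample rate (Hz), 250 by default.
#' @param labels channel labels.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(a1, a2, fs = 250, labels = c("A1", "A2")) {
  stopifnot(length(a1) == length(a2), fs > 60)
  structure(list(data = cbind(a1, a2), fs = fs, labels = labels),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s, %.1f s at %g Hz\n",
              paste(x$labels, collapse = "/"),
              nrow(x$data) / x$fs, x$fs))
  invisible(x)
}

#' Read / write a two-channel EEG recording as delimited text
#'
#' Plain tab-separated interchange format: a comment header line
#' `# fs=<Hz>` followed by a header row and two numeric columns (one per
#' channel).
#'
#' @param path file path.
#' @return [read_eeg_tsv()] returns an `eeg_recording`.
#' @export
read_eeg_tsv <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^#\\s*fs=", first)) stop("missing '# fs=' header line")
  fs <- as.numeric(sub("^#\\s*fs=", "", first))
  d <- read.delim(path, skip = 1)
  if (ncol(d) < 2) stop("need two channel columns")
  eeg_recording(d[[1]], d[[2]], fs = fs, labels = colnames(d)[1:2])
}

#' @param rec an `eeg_recording`.
#' @rdname read_eeg_tsv
#' @export
write_eeg_tsv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g", rec$fs), con)
  d <- as.data.frame(rec$data)
  colnames(d) <- rec$labels
  write.table(format(d, digits = 7, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

# zero-phase FIR applied spectrally over the whole recording
zero_phase_fir <- function(x, taps) {
  n <- length(x)
  H <- fft(c(taps, rep(0, n - length(taps))))
  Re(fft(fft(x) * Mod(H)^2, inverse = TRUE) / n)
}

#' Pre-filter a recording and remove the 6 Hz cardiac component
#'
#' Applies zero-phase FIR high-pass (0.5 Hz) and low-pass (50 Hz) filters,
#' then minimizes the 6 Hz electrocardiogram artifact by fitting the 6 Hz
#' discrete Fourier component (least-squares sinusoid over the whole
#' recording, per channel) and subtracting it.
#'
#' @param rec an [eeg_recording()].
#' @param hp,lp high-pass and low-pass corner frequencies (Hz).
#' @param ecg_freq cardiac artifact frequency (Hz); `NULL` disables
#'   removal.
#' @return the filtered `eeg_recording`.
#' @export
preprocess_eeg <- function(rec, hp = 0.5, lp = 50, ecg_freq = 6) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  n <- nrow(rec$data)
  if (n < 30 * fs) stop("need at least 30 s of data")
  hp_taps <- signal::fir1(round(3 * fs / hp), hp / (fs / 2), type = "high")
  lp_taps <- signal::fir1(round(3 * fs / 5), lp / (fs / 2), type = "low")
  for (ch in 1:2) {
    x <- rec$data[, ch]
    x <- zero_phase_fir(x, hp_taps)
    x <- zero_phase_fir(x, lp_taps)
    if (!is.null(ecg_freq)) {
      tt <- 2 * pi * ecg_freq * (seq_len(n) - 1) / fs
      cs <- cos(tt); sn <- sin(tt)
      x <- x - cs * (2 * sum(x * cs) / n) - sn * (2 * sum(x * sn) / n)
    }
    rec$data[, ch] <- x
  }
  rec
}

#' Split a recording into non-overlapping 2 s epochs
#'
#' @param rec an [eeg_recording()].
#' @param epoch_s epoch length in seconds (default 2).
#' @return list with `n_epochs`, `len` (samples per epoch) and `starts`
#'   (sample index of each epoch start); a trailing partial segment is
#'   dropped.
#' @export
make_epochs <- function(rec, epoch_s = 2) {
  len <- round(epoch_s * rec$fs)
  n_ep <- floor(nrow(rec$data) / len)
  list(n_epochs = n_ep, len = len,
       starts = (seq_len(n_ep) - 1) * len + 1)
}

#' Stage-1 artifact rejection: analytic-amplitude bursts
#'
#' Computes the channel-mean analytic amplitude of the whole recording and
#' flags epochs containing a contiguous run longer than 10 ms (at least 3
#' samples at 250 Hz) above mean + `k` standard deviations of that
#' statistic over the total recording.
#'
#' @param rec preprocessed [eeg_recording()].
#' @param epochs from [make_epochs()].
#' @param k threshold in standard deviations (default 5).
#' @param min_ms minimum excursion duration (ms) for rejection; a run must
#'   strictly exceed this.
#' @return logical vector: `TRUE` = epoch discarded.
#' @export
reject_amplitude_artifacts <- function(rec, epochs, k = 5, min_ms = 10) {
  amp <- (Mod(hilbert_analytic(rec$data[, 1])) +
          Mod(hilbert_analytic(rec$data[, 2]))) / 2
  if (sd(amp) == 0) {
    warning("zero-variance recording: no amplitude rejections")
    return(rep(FALSE, epochs$n_epochs))
  }
  thr <- mean(amp) + k * sd(amp)
  min_run <- floor(min_ms / 1000 * rec$fs) + 1   # > min_ms
  over <- amp > thr
  vapply(seq_len(epochs$n_epochs), function(i) {
    o <- over[epochs$starts[i]:(epochs$starts[i] + epochs$len - 1)]
    if (!any(o)) return(FALSE)
    r <- rle(o)
    any(r$lengths[r$values] >= min_run)
  }, logical(1))
}

# Filter-bank analytic signals for all epochs of one channel.
# Returns a list (one per filter) of complex matrices [len x n_epochs]
# restricted to the original epoch span (padding removed).
epoch_analytic <- function(x, epochs, bank, pad_s = 10) {
  n_pad <- round(pad_s * bank$fs)
  lead <- floor((n_pad - epochs$len) / 2)        # symmetric zero-padding
  span <- lead + seq_len(epochs$len)
  ep <- matrix(0, n_pad, epochs$n_epochs)
  for (i in seq_len(epochs$n_epochs))
    ep[span, i] <- x[epochs$starts[i]:(epochs$starts[i] + epochs$len - 1)]
  X <- stats::mvfft(ep)
  gains <- bank_gains(bank, n_pad)
  lapply(gains, function(g) {
    z <- stats::mvfft(X * g, inverse = TRUE) / n_pad
    z[span, , drop = FALSE]
  })
}

#' Per-epoch, per-filter, per-channel band power
#'
#' Each 2 s epoch is zero-padded symmetrically to 10 s, passed through the
#' zero-phase filter bank, and the squared Hilbert analytic amplitude is
#' averaged over the original 2 s span (padding excluded).
#'
#' @param rec preprocessed [eeg_recording()].
#' @param epochs from [make_epochs()].
#' @param bank a [filter_bank()].
#' @param pad_s padded length in seconds (default 10).
#' @return An `epoch_power` object: list with `power` (array
#'   `[n_epochs, n_filters, 2]`) and `analytic` (per channel, per filter
#'   complex matrices, reused by the coherence step).
#' @export
epoch_band_power <- function(rec, epochs, bank, pad_s = 10) {
  az <- lapply(1:2, function(ch)
    epoch_analytic(rec$data[, ch], epochs, bank, pad_s))
  nf <- nrow(bank$info)
  pw <- array(NA_real_, c(epochs$n_epochs, nf, 2))
  # halved squared envelope = time-averaged power of the real signal
  # (a sinusoid of amplitude a reports a^2/2)
  for (ch in 1:2)
    for (f in seq_len(nf))
      pw[, f, ch] <- colMeans(Mod(az[[ch]][[f]])^2) / 2
  structure(list(power = pw, analytic = az, n_epochs = epochs$n_epochs),
            class = "epoch_power")
}

#' Stage-2 artifact rejection: epoch power outliers
#'
#' Per-epoch power is averaged across filters and channels and z-scored
#' against all (amplitude-clean) epochs; epochs with z above `k` (one
#' sided: artifact power is an excess) are discarded.
#'
#' @param ep an [epoch_band_power()] result.
#' @param keep logical vector of epochs that survived stage 1.
#' @param k z-score threshold (default 2, i.e. alpha < 0.05 one-tailed).
#' @return logical vector over all epochs: `TRUE` = discarded by this
#'   stage (always `FALSE` for epochs already removed in stage 1).
#' @export
reject_power_outliers <- function(ep, keep = rep(TRUE, ep$n_epochs), k = 2) {
  avg <- rowMeans(ep$power[, , 1, drop = FALSE] +
                  ep$power[, , 2, drop = FALSE]) / 2
  out <- rep(FALSE, ep$n_epochs)
  idx <- which(keep)
  if (length(idx) < 3) stop("fewer than 3 epochs survive amplitude rejection")
  z <- (avg[idx] - mean(avg[idx])) / sd(avg[idx])
  if (is.finite(sd(avg[idx])) && sd(avg[idx]) > 0)
    out[idx] <- z > k
  if (sum(keep & !out) < 3) stop("fewer than 3 clean epochs remain")
  out
}

#' Band relative power from clean epochs
#'
#' Power is averaged per filter and channel over clean epochs; band power
#' is the sum over member filters, averaged across the two channels, and
#' expressed as a percentage of total 1-30 Hz power.
#'
#' @param ep an [epoch_band_power()] result.
#' @param bank the [filter_bank()] used.
#' @param clean logical vector of clean epochs.
#' @return data.frame: band, relative power (%), per-channel filter means
#'   attached as attribute `"filter_power"`.
#' @export
band_relative_power <- function(ep, bank, clean) {
  fp <- apply(ep$power[clean, , , drop = FALSE], c(2, 3), mean)
  band <- bank$info$band
  tot <- sum(fp)
  bands <- names(eeg_bands())
  rel <- vapply(bands, function(b) 100 * sum(fp[band == b, ]) / tot,
                numeric(1))
  out <- data.frame(band = bands, rel_power = unname(rel))
  attr(out, "filter_power") <- fp
  out
}

#' Interhemispheric real coherence per filter and band
#'
#' For each filter, the time-domain coherency between the two channels'
#' complex analytic signals is computed over clean epochs. The default
#' `"pooled"` estimator accumulates `sum(z1 * Conj(z2))` and the analytic
#' powers over all clean-epoch samples before normalizing — the classical
#' cross-spectral estimator, unbiased at the 2 s epoch length even for
#' the narrowest (1 Hz) filters. Two per-epoch variants (epoch coherency
#' `sum(z1 * Conj(z2)) / sqrt(sum(|z1|^2) * sum(|z2|^2))` averaged as a
#' complex number or as real parts) are available; they shrink low
#' time-bandwidth bins toward zero by a few percent. The real part is
#' reported. Per band, the median across member filters is returned (the
#' median, rather than the mean, minimizes outlier effects from the
#' platykurtic within-band distributions).
#'
#' @param ep an [epoch_band_power()] result.
#' @param bank the [filter_bank()] used.
#' @param clean logical vector of clean epochs.
#' @param mode `"pooled"` (accumulate across epochs, then normalize),
#'   `"complex-mean"` (average per-epoch complex coherency, then real
#'   part) or `"real-mean"` (average of per-epoch real parts).
#' @return list with `filters` (data.frame: filter, center, band, real
#'   coherence) and `bands` (data.frame: band, median real coherence).
#' @export
band_coherence <- function(ep, bank, clean, mode = c("pooled",
                                                     "complex-mean",
                                                     "real-mean")) {
  mode <- match.arg(mode)
  if (sum(clean) < 3) stop("need at least 3 clean epochs")
  nf <- nrow(bank$info)
  coh <- vapply(seq_len(nf), function(f) {
    z1 <- ep$analytic[[1]][[f]][, clean, drop = FALSE]
    z2 <- ep$analytic[[2]][[f]][, clean, drop = FALSE]
    p1 <- colSums(Mod(z1)^2)
    p2 <- colSums(Mod(z2)^2)
    ok <- p1 > 0 & p2 > 0
    if (!any(ok)) return(NA_real_)
    if (mode == "pooled") {
      cross <- sum(colSums(z1 * Conj(z2))[ok])
      return(Re(cross) / sqrt(sum(p1[ok]) * sum(p2[ok])))
    }
    cc <- colSums(z1 * Conj(z2))[ok] / sqrt(p1[ok] * p2[ok])
    if (mode == "complex-mean") Re(mean(cc)) else mean(Re(cc))
  }, numeric(1))
  filters <- data.frame(filter = bank$info$filter,
                        center = bank$info$center,
                        band = bank$info$band, coherence = coh)
  bands <- data.frame(
    band = names(eeg_bands()),
    coherence = vapply(names(eeg_bands()), function(b)
      median(coh[bank$info$band == b], na.rm = TRUE), numeric(1)),
    row.names = NULL)
  list(filters = filters, bands = bands)
}

#' Run the full interhemispheric EEG analysis
#'
#' Pre-filtering, 6 Hz cardiac removal, 2 s epoching, two-stage artifact
#' rejection (analytic-amplitude bursts, then power outliers), filter-bank
#' Hilbert power, band relative power, and time-domain real coherence.
#'
#' @param rec an [eeg_recording()] (raw).
#' @param bank a [filter_bank()]; defaults to the standard 30-filter bank
#'   at the recording's sample rate.
#' @param coherence_mode passed to [band_coherence()].
#' @param preprocess set `FALSE` if `rec` is already filtered.
#' @return An object of class `eeg_summary`: list with `bands` (band,
#'   median real coherence, relative power %), `filters` (per-filter
#'   table), `retained` (% of data kept), and `rejections` (per-epoch
#'   log).
#' @export
analyze_eeg <- function(rec, bank = filter_bank(rec$fs),
                        coherence_mode = "pooled",
                        preprocess = TRUE) {
  if (preprocess) rec <- preprocess_eeg(rec)
  epochs <- make_epochs(rec)
  if (epochs$n_epochs < 3) stop("recording too short: need >= 3 epochs")
  amp_rej <- reject_amplitude_artifacts(rec, epochs)
  ep <- epoch_band_power(rec, epochs, bank)
  pow_rej <- reject_power_outliers(ep, keep = !amp_rej)
  clean <- !amp_rej & !pow_rej
  rp <- band_relative_power(ep, bank, clean)
  co <- band_coherence(ep, bank, clean, mode = coherence_mode)
  bands <- merge(co$bands, rp, by = "band", sort = FALSE)
  bands <- bands[match(names(eeg_bands()), bands$band), ]
  rownames(bands) <- NULL
  structure(list(
    bands = bands,
    filters = cbind(co$filters,
                    power_a1 = attr(rp, "filter_power")[, 1],
                    power_a2 = attr(rp, "filter_power")[, 2]),
    retained = 100 * sum(clean) / epochs$n_epochs,
    rejections = data.frame(
      epoch = seq_len(epochs$n_epochs),
      flag = ifelse(amp_rej, "amplitude-artifact",
                    ifelse(pow_rej, "power-outlier", "clean")))),
    class = "eeg_summary")
}

#' @export
print.eeg_summary <- function(x, ...) {
  cat("Interhemispheric EEG summary (", sprintf("%.1f%%", x$retained),
      " of data retained)\n", sep = "")
  print(x$bands, row.names = FALSE)
  invisible(x)
}
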