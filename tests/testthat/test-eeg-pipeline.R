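fs <- 250
tt <- function(dur) (seq_len(dur * fs) - 1) / fs

test_that("preprocessing removes the 6 Hz cardiac component and drift", {
  t <- tt(120)
  base <- sin(2 * pi * 10 * t)
  rec <- eeg_recording(base + 2 * sin(2 * pi * 6 * t),
                       base + 2 * sin(2 * pi * 6 * t + 0.3))
  out <- preprocess_eeg(rec)
  # residual 6 Hz amplitude < 1% of injected
  resid6 <- function(x) {
    n <- length(x)
    2 * Mod(sum(x * exp(-2i * pi * 6 * t))) / n
  }
  expect_lt(resid6(out$data[, 1]), 0.02)
  expect_lt(resid6(out$data[, 2]), 0.02)

  # 0.1 Hz drift attenuated > 20 dB
  drift <- sin(2 * pi * 0.1 * t)
  outd <- preprocess_eeg(eeg_recording(drift, drift), ecg_freq = NULL)
  mid <- (30 * fs):(90 * fs)        # avoid edges
  expect_lt(sd(outd$data[mid, 1]) / sd(drift[mid]), 0.1)

  # 10 Hz passband amplitude preserved within 5%
  outp <- preprocess_eeg(eeg_recording(base, base), ecg_freq = NULL)
  expect_equal(sd(outp$data[mid, 1]) / sd(base[mid]), 1, tolerance = 0.05)

  expect_error(preprocess_eeg(eeg_recording(rnorm(100), rnorm(100))),
               "30 s")
})

test_that("epoching drops trailing partial segments", {
  mk <- function(sec) eeg_recording(rnorm(sec * fs), rnorm(sec * fs))
  expect_equal(make_epochs(mk(60))$n_epochs, 30)
  expect_equal(make_epochs(mk(61))$n_epochs, 30)
  expect_equal(make_epochs(eeg_recording(rnorm(475), rnorm(475)))$n_epochs, 0)
  expect_equal(make_epochs(mk(60))$len, 500)
})

test_that("amplitude-artifact rejection follows the 5 SD / >10 ms rule", {
  set.seed(21)
  x1 <- rnorm(120 * fs); x2 <- rnorm(120 * fs)
  # 50 ms burst at 20 SD inside epoch 10
  i0 <- 9 * 500 + 200
  x1[i0:(i0 + 12)] <- x1[i0:(i0 + 12)] + 20
  x2[i0:(i0 + 12)] <- x2[i0:(i0 + 12)] + 20
  # single-sample (4 ms) spike inside epoch 20: its envelope run is too
  # short to reject
  x1[19 * 500 + 100] <- 8
  rec <- eeg_recording(x1, x2)
  ep <- make_epochs(rec)
  rej <- reject_amplitude_artifacts(rec, ep)
  expect_true(rej[10])
  expect_false(rej[20])
  # clean gaussian recording keeps >= 95% of epochs
  clean <- eeg_recording(rnorm(120 * fs), rnorm(120 * fs))
  expect_gte(mean(!reject_amplitude_artifacts(clean, make_epochs(clean))),
             0.95)
  # zero-variance recording: warning, nothing rejected
  z <- eeg_recording(rep(0, 30 * fs), rep(0, 30 * fs))
  expect_warning(r0 <- reject_amplitude_artifacts(z, make_epochs(z)),
                 "zero-variance")
  expect_false(any(r0))
})

test_that("epoch band power recovers sinusoid power and rejects off-band", {
  bank <- filter_bank(fs)
  a <- 2
  i <- 25                                  # center ~16.7 Hz (short taps)
  f0 <- bank$info$center[i]
  x <- a * sin(2 * pi * f0 * tt(60))
  rec <- eeg_recording(x, x)
  ep <- make_epochs(rec)
  pw <- epoch_band_power(rec, ep, bank)
  inband <- mean(pw$power[, i, 1])
  expect_equal(inband, a^2 / 2, tolerance = 0.1)
  # a far-away filter passes < 1% of the in-band power
  expect_lt(mean(pw$power[, 5, 1]), 0.01 * inband)
  # zero input -> zero power everywhere
  z <- eeg_recording(rep(0, 10 * fs), rep(0, 10 * fs))
  pz <- epoch_band_power(z, make_epochs(z), bank)
  expect_equal(max(pz$power), 0)
})

test_that("power-outlier rejection is a one-sided 2 SD rule", {
  set.seed(5)
  x <- rnorm(100 * fs)
  rec <- eeg_recording(x, x)
  ep <- make_epochs(rec)
  bank <- filter_bank(fs)
  pw <- epoch_band_power(rec, ep, bank)
  # inflate epoch 7 by 10x power
  pw$power[7, , ] <- pw$power[7, , ] * 10
  rej <- reject_power_outliers(pw)
  expect_true(rej[7])
  # identical epochs: nothing rejected
  pw2 <- pw
  pw2$power[] <- 1
  expect_false(any(reject_power_outliers(pw2)))
  # clean gaussian: a few % rejected, one-sided
  rej3 <- reject_power_outliers(pw)
  expect_lt(mean(rej3), 0.1)
  expect_error(reject_power_outliers(pw, keep = c(TRUE, TRUE,
                                                  rep(FALSE, 48))),
               "fewer than 3")
})

test_that("band relative power sums to 100 and tracks spectral content", {
  set.seed(8)
  bank <- filter_bank(fs)
  wn <- eeg_recording(rnorm(60 * fs), rnorm(60 * fs))
  ep <- make_epochs(wn)
  pw <- epoch_band_power(wn, ep, bank)
  rp <- band_relative_power(pw, bank, rep(TRUE, ep$n_epochs))
  expect_equal(sum(rp$rel_power), 100, tolerance = 1e-6)

  # pure 2 Hz sinusoid: delta holds >= 95%
  x2 <- sin(2 * pi * 2 * tt(60))
  r2 <- eeg_recording(x2, x2)
  p2 <- epoch_band_power(r2, make_epochs(r2), bank)
  rp2 <- band_relative_power(p2, bank, rep(TRUE, 30))
  expect_gte(rp2$rel_power[rp2$band == "delta"], 95)

  # 1/f^2 background: delta > theta > alpha > beta
  n <- 120 * fs
  X <- fft(rnorm(n))
  f <- pmin((0:(n - 1)) * fs / n, fs - (0:(n - 1)) * fs / n)
  shape <- ifelse(f >= 0.5, f^-1, 0)
  pink <- Re(fft(X * shape, inverse = TRUE) / n)
  rp3 <- band_relative_power(
    epoch_band_power(eeg_recording(pink, pink), make_epochs(
      eeg_recording(pink, pink)), bank),
    bank, rep(TRUE, 60))
  ordered <- rp3$rel_power[match(c("delta", "theta", "alpha", "beta"),
                                 rp3$band)]
  expect_true(all(diff(ordered) < 0))
})

test_that("real coherence is exact for identical and inverted channels", {
  set.seed(13)
  x <- rnorm(120 * fs)
  bank <- filter_bank(fs)
  same <- eeg_recording(x, x)
  ep <- make_epochs(same)
  pw <- epoch_band_power(same, ep, bank)
  co <- band_coherence(pw, bank, rep(TRUE, ep$n_epochs))
  expect_equal(co$filters$coherence, rep(1, 30), tolerance = 1e-9)
  inv <- eeg_recording(x, -x)
  pwi <- epoch_band_power(inv, ep, bank)
  coi <- band_coherence(pwi, bank, rep(TRUE, ep$n_epochs))
  expect_equal(coi$filters$coherence, rep(-1, 30), tolerance = 1e-9)
  expect_true(all(abs(co$filters$coherence) <= 1 + 1e-12))
})

test_that("coherence of independent noise shrinks toward zero", {
  set.seed(17)
  rec <- eeg_recording(rnorm(600 * fs), rnorm(600 * fs))
  ep <- make_epochs(rec)
  pw <- epoch_band_power(rec, ep, filter_bank(fs))
  co <- band_coherence(pw, filter_bank(fs), rep(TRUE, ep$n_epochs))
  expect_true(all(abs(co$bands$coherence) < 0.1))
})

test_that("band median is more robust than the mean to a contaminated bin", {
  bank <- filter_bank(fs)
  theta_ix <- which(bank$info$band == "theta")
  coh <- rep(0.6, length(theta_ix))
  contaminated <- coh
  contaminated[1] <- -0.9
  shift_median <- abs(median(contaminated) - median(coh))
  shift_mean <- abs(mean(contaminated) - mean(coh))
  expect_lt(shift_median, shift_mean)
})

test_that("analyze_eeg produces a coherent summary and rejection log", {
  set.seed(30)
  cfg <- eeg_gen_config(duration_s = 120, seed = 3)
  rec <- generate_eeg_pair(cfg)
  s <- analyze_eeg(rec)
  expect_s3_class(s, "eeg_summary")
  expect_equal(s$bands$band, c("delta", "theta", "alpha", "beta"))
  expect_equal(sum(s$bands$rel_power), 100, tolerance = 1e-6)
  expect_true(all(abs(s$bands$coherence) <= 1))
  expect_true(s$retained > 0 && s$retained <= 100)
  expect_equal(nrow(s$rejections), 60)
  expect_setequal(setdiff(unique(s$rejections$flag), "clean"),
                  intersect(unique(s$rejections$flag),
                            c("amplitude-artifact", "power-outlier")))
})

test_that("recordings round-trip through the delimited text format", {
  set.seed(2)
  rec <- eeg_recording(rnorm(500), rnorm(500))
  path <- tempfile(fileext = ".tsv")
  write_eeg_tsv(rec, path)
  back <- read_eeg_tsv(path)
  expect_equal(back$fs, 250)
  expect_equal(back$data[, 1], rec$data[, 1], tolerance = 1e-5,
               ignore_attr = TRUE)
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("x\ty", "1\t2"), bad)
  expect_error(read_eeg_tsv(bad), "fs")
})
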