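#' Configuration for the synthetic two-channel EEG generator
#'
#' @param duration_s recording length (s); at least 60 s for analysis use.
#' @param fs sample rate (Hz).
#' @param coherence named vector of target real coherence per band
#'   (delta/theta/alpha/beta), each in `[0, 1]`.
#' @param weights per-band relative power weights (%); the default is the
#'   control band-power profile (delta 61.9, theta 27.2, alpha 6.1, beta
#'   4.7).
#' @param spectral_exponent within-band 1/f^a tilt of the band noise
#'   sources (a = 2 approximates the steep low-frequency background).
#' @param ecg_amplitude amplitude of the common 6 Hz cardiac sinusoid, in
#'   multiples of the background SD.
#' @param artifact_rate transient artifacts per minute (Poisson).
#' @param artifact_amp_sd artifact amplitude range, multiples of the
#'   background SD.
#' @param artifact_ms artifact duration range (ms).
#' @param seed RNG seed; every output is a pure function of (config,
#'   seed).
#' @return An object of class `eeg_gen_config`.
#' @export
eeg_gen_config <- function(duration_s = 600, fs = 250,
                           coherence = c(delta = 0.8, theta = 0.8,
                                         alpha = 0.7, beta = 0.6),
                           weights = c(delta = 61.9, theta = 27.2,
                                       alpha = 6.1, beta = 4.7),
                           spectral_exponent = 2,
                           ecg_amplitude = 0.5,
                           artifact_rate = 1,
                           artifact_amp_sd = c(10, 20),
                           artifact_ms = c(50, 200),
                           seed = 1) {
  bands <- names(eeg_bands())
  stopifnot(all(bands %in% names(coherence)),
            all(bands %in% names(weights)),
            duration_s >= 60)
  if (any(coherence < 0 | coherence > 1))
    stop("band coherence targets must be in [0, 1]")
  if (any(weights <= 0)) stop("band weights must be positive")
  structure(list(duration_s = duration_s, fs = fs,
                 coherence = coherence[bands], weights = weights[bands],
                 spectral_exponent = spectral_exponent,
                 ecg_amplitude = ecg_amplitude,
                 artifact_rate = artifact_rate,
                 artifact_amp_sd = artifact_amp_sd,
                 artifact_ms = artifact_ms, seed = seed),
            class = "eeg_gen_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

band_noise <- function(n, fs, lo, hi, alpha, trans = 0.25) {
  # unit-variance band-limited noise with a 1/f^alpha in-band tilt.
  # The band edges are sharp (raised-cosine transitions of width `trans`
  # Hz): the per-band coherence contract requires that one band's source
  # carries no power inside a neighboring band, which an FIR design with
  # a transition band of several hertz would violate.
  x <- rnorm(n)
  X <- fft(x)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  ramp <- function(z) 0.5 - 0.5 * cospi(pmin(pmax(z, 0), 1))
  # transitions lie inside [lo, hi], so adjacent band sources never overlap
  H <- ramp((f - lo) / trans) * ramp((hi - f) / trans)
  # tilt clamped at the band's lower edge: an unclamped 1/f^a weight
  # would amplify near-DC leakage into the dominant variance term
  tilt <- pmax(f, lo)^(-alpha / 2)
  y <- Re(fft(X * H * tilt, inverse = TRUE) / n)
  y / sd(y)
}

#' Generate a coherence-controlled two-channel EEG pair
#'
#' For each band b a shared source `s_b` and two independent noises are
#' band-filtered and mixed as
#' `ch_i = sum_b w_b * (sqrt(c_b) * s_b + sqrt(1 - c_b) * n_ib)`, so the
#' population real coherence in band b equals the target `c_b`. A common
#' 6 Hz cardiac sinusoid and Poisson-placed high-amplitude transient
#' bursts are then added.
#'
#' @param cfg an [eeg_gen_config()].
#' @return an [eeg_recording()]; the injected artifact windows are
#'   attached as attribute `"artifacts"` (data.frame of start/end sample).
#' @export
generate_eeg_pair <- function(cfg) {
  stopifnot(inherits(cfg, "eeg_gen_config"))
  with_seed(cfg$seed, {
    n <- round(cfg$duration_s * cfg$fs)
    bands <- eeg_bands()
    ch1 <- numeric(n); ch2 <- numeric(n)
    for (b in names(bands)) {
      lo <- bands[[b]][1]; hi <- bands[[b]][2]
      s <- band_noise(n, cfg$fs, lo, hi, cfg$spectral_exponent)
      n1 <- band_noise(n, cfg$fs, lo, hi, cfg$spectral_exponent)
      n2 <- band_noise(n, cfg$fs, lo, hi, cfg$spectral_exponent)
      cb <- cfg$coherence[[b]]
      w <- sqrt(cfg$weights[[b]])
      ch1 <- ch1 + w * (sqrt(cb) * s + sqrt(1 - cb) * n1)
      ch2 <- ch2 + w * (sqrt(cb) * s + sqrt(1 - cb) * n2)
    }
    bg_sd <- sd(ch1)
    if (cfg$ecg_amplitude > 0) {
      ph <- runif(1, 0, 2 * pi)
      ecg <- cfg$ecg_amplitude * bg_sd *
        sin(2 * pi * 6 * (seq_len(n) - 1) / cfg$fs + ph)
      ch1 <- ch1 + ecg
      ch2 <- ch2 + ecg
    }
    n_art <- rpois(1, cfg$artifact_rate * cfg$duration_s / 60)
    arts <- data.frame(start = integer(0), end = integer(0))
    if (n_art > 0) {
      for (k in seq_len(n_art)) {
        dur <- round(runif(1, cfg$artifact_ms[1], cfg$artifact_ms[2]) /
                       1000 * cfg$fs)
        st <- sample.int(n - dur, 1)
        amp <- runif(1, cfg$artifact_amp_sd[1], cfg$artifact_amp_sd[2])
        idx <- st:(st + dur - 1)
        ch1[idx] <- ch1[idx] + amp * bg_sd * rnorm(dur)
        ch2[idx] <- ch2[idx] + amp * bg_sd * rnorm(dur)
        arts <- rbind(arts, data.frame(start = st, end = st + dur - 1))
      }
    }
    rec <- eeg_recording(ch1, ch2, fs = cfg$fs)
    attr(rec, "artifacts") <- arts
    rec
  })
}

#' Generate a synthetic EEG cohort with a mutant theta-coherence deficit
#'
#' Builds per-animal recordings for two groups (control and mutant at 12
#' months). The mutant theta coherence target is `theta_ratio` times the
#' control target; all other bands are identical across groups.
#'
#' @param n_per_group animals per group.
#' @param control_coherence named per-band targets for controls.
#' @param theta_ratio mutant/control theta coherence ratio (0.73: the
#'   deficit magnitude observed in 12-month mutants).
#' @param duration_s recording length per animal (s).
#' @param seed cohort seed; per-animal seeds are derived from it.
#' @param ... further arguments to [eeg_gen_config()].
#' @return list with `recordings` (named list of `eeg_recording`s) and
#'   `truth` (data.frame: animal, group, per-band coherence targets).
#' @export
generate_cohort <- function(n_per_group = 8,
                            control_coherence = c(delta = 0.8, theta = 0.8,
                                                  alpha = 0.7, beta = 0.6),
                            theta_ratio = 0.73,
                            duration_s = 120, seed = 1, ...) {
  stopifnot(n_per_group >= 1, theta_ratio > 0, theta_ratio <= 1)
  mut <- control_coherence
  mut[["theta"]] <- mut[["theta"]] * theta_ratio
  groups <- list(control = control_coherence, mutant = mut)
  recordings <- list()
  truth <- NULL
  i <- 0
  for (g in names(groups)) {
    for (a in seq_len(n_per_group)) {
      i <- i + 1
      id <- sprintf("%s_%02d", g, a)
      cfg <- eeg_gen_config(duration_s = duration_s,
                            coherence = groups[[g]],
                            seed = seed * 10000 + i, ...)
      recordings[[id]] <- generate_eeg_pair(cfg)
      truth <- rbind(truth,
                     data.frame(animal = id, group = g,
                                t(groups[[g]])))
    }
  }
  list(recordings = recordings, truth = truth)
}
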