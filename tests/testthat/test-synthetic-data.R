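test_that("generator config validates its inputs", {
  expect_error(eeg_gen_config(coherence = c(delta = 1.2, theta = .5,
                                            alpha = .5, beta = .5)),
               "\\[0, 1\\]")
  expect_error(eeg_gen_config(duration_s = 10), "60")
  expect_error(eeg_gen_config(weights = c(delta = -1, theta = 1,
                                          alpha = 1, beta = 1)),
               "positive")
})

test_that("full coherence with no noise sources gives identical channels", {
  cfg <- eeg_gen_config(duration_s = 60,
                        coherence = c(delta = 1, theta = 1, alpha = 1,
                                      beta = 1),
                        ecg_amplitude = 0, artifact_rate = 0, seed = 4)
  rec <- generate_eeg_pair(cfg)
  expect_equal(rec$data[, 1], rec$data[, 2], ignore_attr = TRUE)
})

test_that("zero coherence targets yield near-zero measured coherence", {
  cfg <- eeg_gen_config(duration_s = 600,
                        coherence = c(delta = 0, theta = 0, alpha = 0,
                                      beta = 0),
                        ecg_amplitude = 0, artifact_rate = 0, seed = 10)
  s <- analyze_eeg(generate_eeg_pair(cfg), preprocess = FALSE)
  expect_true(all(abs(s$bands$coherence) < 0.1))
})

test_that("generated pairs are a pure function of (config, seed)", {
  cfg <- eeg_gen_config(duration_s = 60, seed = 77)
  r1 <- generate_eeg_pair(cfg)
  r2 <- generate_eeg_pair(cfg)
  expect_identical(r1$data, r2$data)
  r3 <- generate_eeg_pair(eeg_gen_config(duration_s = 60, seed = 78))
  expect_false(identical(r1$data, r3$data))
  # the generator does not disturb the caller's RNG stream
  set.seed(1); a <- rnorm(3)
  set.seed(1); invisible(generate_eeg_pair(cfg)); b <- rnorm(3)
  expect_identical(a, b)
})

test_that("pipeline recovers the generator's band coherence targets", {
  tgt <- c(delta = 0.8, theta = 0.6, alpha = 0.7, beta = 0.5)
  cfg <- eeg_gen_config(duration_s = 600, coherence = tgt, seed = 42)
  s <- analyze_eeg(generate_eeg_pair(cfg))
  got <- setNames(s$bands$coherence, s$bands$band)
  expect_equal(got[names(tgt)], tgt, tolerance = 0.05 / max(tgt))
  for (b in names(tgt)) expect_lt(abs(got[[b]] - tgt[[b]]), 0.05)
})

test_that("injected artifact count is Poisson-distributed across seeds", {
  rate <- 2                               # per minute
  counts <- vapply(1:150, function(s) {
    cfg <- eeg_gen_config(duration_s = 60, artifact_rate = rate, seed = s)
    nrow(attr(generate_eeg_pair(cfg), "artifacts"))
  }, numeric(1))
  lambda <- rate * 1
  # chi-square GOF against Poisson(lambda), pooled tails
  breaks <- c(-0.5, 0.5, 1.5, 2.5, 3.5, Inf)
  obs <- table(cut(counts, breaks))
  pr <- diff(ppois(c(-1, 0, 1, 2, 3, Inf), lambda))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("cohort generator encodes the 0.73 mutant theta ratio", {
  coh <- generate_cohort(n_per_group = 2, duration_s = 60, seed = 3)
  expect_length(coh$recordings, 4)
  tr <- coh$truth
  expect_equal(tr$theta[tr$group == "mutant"][1] /
                 tr$theta[tr$group == "control"][1], 0.73)
  expect_equal(tr$delta[tr$group == "mutant"][1],
               tr$delta[tr$group == "control"][1])
  # control theta 0.8 -> mutant target 0.584
  expect_equal(tr$theta[tr$group == "mutant"][1], 0.584)
  coh2 <- generate_cohort(n_per_group = 2, duration_s = 60, seed = 3)
  expect_identical(coh$recordings[[1]]$data, coh2$recordings[[1]]$data)
})

test_that("screen-series generator injects rule-consistent deficits", {
  g <- generate_screen_series(n_animals = 25, n_weeks = 40,
                              p_event = 12 / 1000, seed = 12)
  expect_equal(dim(g$scores), c(40, 25))
  expect_true(all(g$scores > 0))
  # every injected event is found (recall 1 by construction)
  found <- do.call(rbind, lapply(seq_len(25), function(a) {
    ev <- detect_transient_deficits(g$scores[, a], animal = a)
    ev[, c("animal", "week")]
  }))
  expect_true(nrow(merge(g$truth, found)) == nrow(g$truth))
  # injected count is near the binomial expectation
  expect_gt(nrow(g$truth), 0)
  expect_lt(nrow(g$truth), 30)

  z <- generate_screen_series(n_animals = 10, p_event = 0, seed = 1)
  expect_equal(nrow(z$truth), 0)
  expect_equal(nrow(do.call(rbind, lapply(1:10, function(a)
    detect_transient_deficits(z$scores[, a])))), 0)

  g2 <- generate_screen_series(n_animals = 25, n_weeks = 40,
                               p_event = 12 / 1000, seed = 12)
  expect_identical(g$scores, g2$scores)
})

test_that("clean screen series rarely trigger false detections", {
  # false-positive rate below ~1 per 800 tests on clean synthetic series
  g <- generate_screen_series(n_animals = 60, n_weeks = 40, p_event = 0,
                              seed = 99)
  fp <- sum(vapply(seq_len(60), function(a)
    nrow(detect_transient_deficits(g$scores[, a])), numeric(1)))
  expect_lte(fp / (60 * 40), 1 / 800)
})
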