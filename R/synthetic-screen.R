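#' Generate weekly inverted-screen score series with transient deficits
#'
#' Weekly median hang scores per animal: a stable baseline with mild
#' multiplicative noise, plus rare injected transient-deficit events. An
#' injected event drops the weekly median by more than 3-fold for exactly
#' one week, with recovery at the following test, so every injected event
#' satisfies the detection rule of [detect_transient_deficits()] by
#' construction.
#'
#' @param n_animals number of animals.
#' @param n_weeks weekly tests per animal (default 40: weekly testing
#'   from 2 to 12 months of age).
#' @param p_event per-test event probability (control cohorts: 1/800;
#'   mutant cohorts: 12/1000).
#' @param baseline median hang score (s).
#' @param cv coefficient of variation of the weekly multiplicative noise.
#' @param drop_range event drop factor range (> 3-fold by construction;
#'   the factor is drawn uniformly in this range and the dropped score is
#'   clamped below a third of the previous week's score).
#' @param seed RNG seed.
#' @return list with `scores` (matrix `[n_weeks x n_animals]`) and
#'   `truth` (data.frame: animal, week of each injected event).
#' @export
generate_screen_series <- function(n_animals, n_weeks = 40,
                                   p_event = 12 / 1000, baseline = 60,
                                   cv = 0.1, drop_range = c(4, 8),
                                   seed = 1) {
  stopifnot(p_event >= 0, p_event <= 1, n_weeks >= 3)
  with_seed(seed, {
    scores <- matrix(baseline * exp(rnorm(n_weeks * n_animals, 0, cv)),
                     n_weeks, n_animals)
    truth <- data.frame(animal = integer(0), week = integer(0))
    for (a in seq_len(n_animals)) {
      # events only where the drop and the recovery week both exist, and
      # never in adjacent weeks
      ev <- which(runif(n_weeks) < p_event)
      ev <- ev[ev >= 2 & ev <= n_weeks - 1]
      if (length(ev) > 1) ev <- ev[c(TRUE, diff(ev) > 2)]
      for (w in ev) {
        fac <- runif(1, drop_range[1], drop_range[2])
        scores[w, a] <- min(scores[w, a] / fac,
                            scores[w - 1, a] / 3 * 0.99)
        truth <- rbind(truth, data.frame(animal = a, week = w))
      }
    }
    list(scores = scores, truth = truth)
  })
}
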