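#' Calibrate the global sodium-density scale
#'
#' Adjusts the global sodium multiplier `nav_scale` by scalar root-finding
#' so that the fully myelinated AIS-length sweep spans the target AP
#' threshold-current range (default 400 pA over 3-60 um). The calibrated
#' threshold curve must also increase with AIS length; calibration fails
#' with a diagnostic otherwise. Deterministic: the same configuration
#' always yields the same scale.
#'
#' @param chans starting [channel_densities()].
#' @param target_range target max-minus-min AP threshold (pA) across the
#'   sweep.
#' @param lengths AIS lengths (um) used during calibration; the default
#'   endpoints suffice because the calibrated curve is monotone.
#' @param scale_bounds search interval for `nav_scale`.
#' @param morph_fn function(ais_length) -> [morphology_spec()].
#' @param protocol clamp protocol template.
#' @param tol root-finding tolerance on the range (pA).
#' @return the calibrated `channel_densities` with attributes
#'   `"calibration"` (achieved range, scale, thresholds).
#' @export
calibrate_model <- function(chans = channel_densities(),
                            target_range = 400,
                            lengths = c(3, 60),
                            scale_bounds = c(0.5, 2),
                            morph_fn = morphology_spec,
                            protocol = stimulus_protocol(),
                            tol = 2) {
  thr_at <- function(scale) {
    ch <- chans
    ch$nav_scale <- scale
    vapply(lengths, function(L) {
      m <- build_cell(morph_fn(L), ch, myelin_spec(10, morph_fn(L)$axon_diam))
      ft <- find_threshold(m, "ap", protocol = protocol)
      if (ft$unexcitable) stop("calibration: model unexcitable at AIS ",
                               L, " um (scale ", signif(scale, 4), ")")
      ft$threshold
    }, numeric(1))
  }
  f <- function(scale) {
    th <- thr_at(scale)
    diff(range(th)) - target_range
  }
  lo <- f(scale_bounds[1])
  hi <- f(scale_bounds[2])
  if (sign(lo) == sign(hi))
    stop("calibration failure: threshold range is ",
         round(lo + target_range), "-", round(hi + target_range),
         " pA over nav_scale in [", scale_bounds[1], ", ", scale_bounds[2],
         "]; the target ", target_range, " pA is not bracketed")
  root <- uniroot(f, scale_bounds, f.lower = lo, f.upper = hi, tol = 1e-3)
  scale <- root$root
  th <- thr_at(scale)
  if (th[length(th)] <= th[1])
    stop("calibration failure: AP threshold does not increase with AIS ",
         "length at the calibrated scale")
  out <- chans
  out$nav_scale <- scale
  attr(out, "calibration") <- list(nav_scale = scale,
                                   achieved_range = diff(range(th)),
                                   lengths = lengths, thresholds = th,
                                   target_range = target_range)
  out
}

sweep_point <- function(model, protocol, bap_ref, upper = 2000) {
  settled <- settle_model(model)
  ta <- find_threshold(model, "ap", settled = settled, protocol = protocol,
                       upper = upper)
  tb <- find_threshold(model, "bap", settled = settled, protocol = protocol,
                       bap_ref = bap_ref, upper = upper)
  amp <- if (!tb$unexcitable)
    measure_bap_amplitude(model, tb$threshold, settled = settled,
                          protocol = protocol) else NA_real_
  data.frame(bap_threshold = tb$threshold, ap_threshold = ta$threshold,
             bap_amplitude = amp,
             conduction_block = ta$unexcitable,
             bap_unattainable = tb$unexcitable)
}

#' Sweep the AIS length
#'
#' Builds the model at each AIS length (with the given uniform wrap count)
#' and reports the bAP and AP threshold currents and the bAP amplitude at
#' threshold. The full-amplitude reference for each length is its own
#' fully myelinated (10-wrap) variant. A cubic fit to the AP threshold
#' curve is attached as attribute `"poly_fit"` (with its R-squared).
#'
#' @param chans (calibrated) [channel_densities()].
#' @param lengths AIS grid (um), each in `[3, 60]`, strictly increasing.
#' @param wraps uniform wrap count for the sweep.
#' @param morph_fn function(ais_length) -> [morphology_spec()].
#' @param protocol clamp protocol template.
#' @return data.frame (class `sweep_result`) with one row per length.
#' @export
ais_length_sweep <- function(chans, lengths = c(3, 5, 10, 15, 16.8, 20.3,
                                                25, 30, 40, 50, 60),
                             wraps = 10, morph_fn = morphology_spec,
                             protocol = stimulus_protocol()) {
  if (length(lengths) == 0)
    return(structure(data.frame(ais_length = numeric(0)),
                     class = c("sweep_result", "data.frame")))
  if (any(lengths < 3 | lengths > 60)) stop("AIS lengths must be in [3, 60]")
  if (is.unsorted(lengths, strictly = TRUE))
    stop("lengths must be strictly increasing")
  upper <- 2000                  # warm-started from the previous grid point
  rows <- lapply(lengths, function(L) {
    mo <- morph_fn(L)
    ref <- bap_reference_amplitude(mo, chans, protocol = protocol)
    model <- if (wraps == 10) ref$model
             else build_cell(mo, chans, myelin_spec(wraps, mo$axon_diam))
    pt <- sweep_point(model, protocol, ref$amplitude, upper = upper)
    thr <- suppressWarnings(max(pt$ap_threshold, pt$bap_threshold, na.rm = TRUE))
    if (is.finite(thr)) upper <<- max(100, 1.5 * thr)
    cbind(ais_length = L, pt, bap_ref = ref$amplitude)
  })
  out <- do.call(rbind, rows)
  ok <- is.finite(out$ap_threshold)
  if (sum(ok) >= 4) {
    fit <- lm(ap_threshold ~ poly(ais_length, 3),
              data = out[ok, , drop = FALSE])
    attr(out, "poly_fit") <- list(r_squared = summary(fit)$r.squared,
                                  degree = 3)
  }
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Sweep the myelin wrap count
#'
#' At a fixed AIS length, varies the wrap count over `wraps_grid` — either
#' uniformly along the whole axon (default) or restricted to `lesion`
#' internodes with the rest fully myelinated — and reports thresholds and
#' bAP amplitude per wrap count. Conduction block (no distal-node spike at
#' any current up to the cap) is flagged.
#'
#' @param chans (calibrated) [channel_densities()].
#' @param ais_length AIS length (um).
#' @param wraps_grid wrap counts, each in 0..10.
#' @param lesion optional internode index set to which the wrap change is
#'   restricted (e.g. `1:20` for a proximal lesion).
#' @param morph_fn function(ais_length) -> [morphology_spec()].
#' @param protocol clamp protocol template.
#' @return data.frame (class `sweep_result`) with one row per wrap count.
#' @export
myelin_wrap_sweep <- function(chans, ais_length = 20.3, wraps_grid = 0:10,
                              lesion = NULL, morph_fn = morphology_spec,
                              protocol = stimulus_protocol()) {
  if (any(wraps_grid < 0 | wraps_grid > 10))
    stop("wrap counts must be in 0..10")
  mo <- morph_fn(ais_length)
  ref <- bap_reference_amplitude(mo, chans, protocol = protocol)
  upper <- 2000
  rows <- lapply(wraps_grid, function(w) {
    model <- if (is.null(lesion))
      build_cell(mo, chans, myelin_spec(w, mo$axon_diam))
    else apply_demyelination(ref$model, lesion, w)
    pt <- sweep_point(model, protocol, ref$amplitude, upper = upper)
    thr <- suppressWarnings(max(pt$ap_threshold, pt$bap_threshold, na.rm = TRUE))
    if (is.finite(thr)) upper <<- max(100, 1.5 * thr)
    cbind(wraps = w, pt)
  })
  out <- do.call(rbind, rows)
  out$ais_length <- ais_length
  attr(out, "bap_ref") <- ref$amplitude
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Proximal demyelinating-lesion experiment
#'
#' Strips (or partially remyelinates) the first 20 internodes — a proximal
#' Type-I lesion at the grey/white-matter border — across wrap counts
#' 0..10, and reports AP propagation status and the threshold currents.
#' At 0 wraps the AP is conduction-blocked while the bAP persists with
#' diminished amplitude and a near-normal threshold; conduction is
#' restored with the first wrap at an elevated AP threshold that
#' approaches the fully myelinated value by three wraps.
#'
#' @inheritParams myelin_wrap_sweep
#' @param n_lesion number of proximal internodes in the lesion.
#' @return `sweep_result` data.frame, one row per wrap count.
#' @export
proximal_lesion_experiment <- function(chans, ais_length = 20.3,
                                       wraps_grid = 0:10, n_lesion = 20,
                                       morph_fn = morphology_spec,
                                       protocol = stimulus_protocol()) {
  myelin_wrap_sweep(chans, ais_length, wraps_grid,
                    lesion = seq_len(n_lesion),
                    morph_fn = morph_fn, protocol = protocol)
}

#' Distal demyelinating-lesion experiment
#'
#' Strips internodes beyond the proximal 20 (white-matter pathology in the
#' external capsule / corpus callosum). Initiation thresholds for bAPs and
#' APs remain essentially normal, but at 0 wraps the spike fails across
#' the demyelinated segment (no distal-node spike).
#'
#' @inheritParams proximal_lesion_experiment
#' @param from_internode first lesioned internode.
#' @return `sweep_result` data.frame, one row per wrap count.
#' @export
distal_lesion_experiment <- function(chans, ais_length = 20.3,
                                     wraps_grid = 0:10,
                                     from_internode = 21,
                                     morph_fn = morphology_spec,
                                     protocol = stimulus_protocol()) {
  n_int <- morph_fn(ais_length)$n_internodes
  myelin_wrap_sweep(chans, ais_length, wraps_grid,
                    lesion = from_internode:n_int,
                    morph_fn = morph_fn, protocol = protocol)
}

#' Partition an AIS sweep into stability zones
#'
#' Classifies every grid point of an AIS-length sweep into exactly one of
#' three zones: the short-AIS *uncoupling* zone, where the AP threshold
#' exceeds the bAP threshold by more than the search resolution (bAPs are
#' cheaper to evoke than propagated APs); the long-AIS *diminished-bAP*
#' zone, where the somatic depolarization never reaches the full-amplitude
#' criterion; and the mid-range *Goldilocks* zone, where bAP and AP stay
#' coupled at full amplitude.
#'
#' @param sweep an [ais_length_sweep()] result.
#' @param resolution threshold-search resolution (pA).
#' @return list of data.frame `zones` (ais_length, zone) and per-zone
#'   length vectors `uncoupling`, `diminished`, `goldilocks`.
#' @export
goldilocks_zones <- function(sweep, resolution = 0.1) {
  stopifnot(inherits(sweep, "sweep_result"))
  if (!all(c("bap_threshold", "ap_threshold") %in% colnames(sweep)))
    stop("sweep must contain both event classes")
  zone <- vapply(seq_len(nrow(sweep)), function(i) {
    if (isTRUE(sweep$bap_unattainable[i])) return("diminished")
    ap <- sweep$ap_threshold[i]
    if (isTRUE(sweep$conduction_block[i]) ||
        (is.finite(ap) && ap - sweep$bap_threshold[i] > resolution))
      return("uncoupling")
    "goldilocks"
  }, character(1))
  list(zones = data.frame(ais_length = sweep$ais_length, zone = zone),
       uncoupling = sweep$ais_length[zone == "uncoupling"],
       diminished = sweep$ais_length[zone == "diminished"],
       goldilocks = sweep$ais_length[zone == "goldilocks"])
}
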