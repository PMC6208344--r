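#' Somatic current-clamp protocol
#'
#' A single rectangular current pulse injected at the soma, recorded at the
#' standard sites (dendrite midpoint, soma, AIS distal end, mid-axon node,
#' distal node).
#'
#' @param amplitude clamp amplitude (pA).
#' @param onset,duration pulse onset and duration (ms). The default 150 ms
#'   step is a rheobase-style stimulus: near threshold it elicits a single
#'   AP/bAP. The quasi-steady approach lets the slow AIS Kv7 conductance
#'   reach its sub-threshold operating point (which couples the threshold
#'   current to AIS length) and makes the threshold a conductance
#'   criterion, insensitive to the capacitance changes produced by
#'   demyelination.
#' @param t_stop simulation end (ms); must leave >= 20 ms after the pulse
#'   for propagation and event detection.
#' @param dt integration step (ms), at most 0.025.
#' @param record_sites names of standard sites to record.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(amplitude = 0, onset = 2, duration = 150,
                              t_stop = 180, dt = 0.02,
                              record_sites = c("dendrite", "soma", "ais_end",
                                               "mid_node", "distal_node")) {
  stopifnot(dt > 0, dt <= 0.025, onset + duration <= t_stop)
  structure(list(amplitude = amplitude, onset = onset, duration = duration,
                 t_stop = t_stop, dt = dt, record_sites = record_sites),
            class = "stimulus_protocol")
}

#' Settle a model to its resting state
#'
#' Integrates the model without stimulus from the nominal resting potential
#' (with gating at steady state) until the membrane equilibrates, and
#' returns the settled state plus the per-site resting potentials. The
#' settled state is reused across repeated protocol runs, e.g. during
#' threshold bisection.
#'
#' @param model a `cable_model`.
#' @param t_settle settling time (ms).
#' @param dt settling step (ms); the implicit scheme permits a coarse step.
#' @return list with `state` (full integrator state), `pars` (absolute
#'   electrical parameters) and `rest` (named per-site resting mV).
#' @export
settle_model <- function(model, t_settle = 100, dt = 0.025) {
  pars <- cable_pars(model)
  v0 <- rep(model$chans$e_rest, model$n)
  st <- cable_init_gating(v0, pars$kinetics, pars$tadj)
  res <- cable_run(st, pars, dt, as.integer(round(t_settle / dt)),
                   0, model$sites[["soma"]] - 1L, 0L, 0L,
                   model$sites - 1L)
  rest <- res$state$v[model$sites]
  names(rest) <- names(model$sites)
  list(state = res$state, pars = pars, rest = rest)
}

#' Integrate a current-clamp protocol
#'
#' Runs the implicit (backward Euler) cable integration of the model under
#' the given protocol. With zero stimulus, all sites stay within 0.5 mV of
#' rest.
#'
#' @param model a `cable_model`.
#' @param protocol a [stimulus_protocol()].
#' @param settled optional result of [settle_model()] to reuse; computed on
#'   the fly otherwise.
#' @return An object of class `voltage_trace`: `time` (ms), matrix `v`
#'   (mV, one column per record site) and the per-site resting potentials.
#' @export
integrate_cable <- function(model, protocol, settled = NULL) {
  stopifnot(inherits(model, "cable_model"),
            inherits(protocol, "stimulus_protocol"))
  if (is.null(settled)) settled <- settle_model(model)
  sites <- model$sites[protocol$record_sites]
  if (anyNA(sites)) stop("unknown record site")
  dt <- protocol$dt
  n_steps <- as.integer(round(protocol$t_stop / dt))
  res <- cable_run(settled$state, settled$pars, dt, n_steps,
                   protocol$amplitude * 1e-3,      # pA -> nA
                   model$sites[["soma"]] - 1L,
                   as.integer(round(protocol$onset / dt)),
                   as.integer(round((protocol$onset + protocol$duration) / dt)),
                   as.integer(sites) - 1L)
  v <- res$trace
  colnames(v) <- names(sites)
  structure(list(time = seq(0, by = dt, length.out = n_steps + 1),
                 v = v, rest = settled$rest[names(sites)],
                 protocol = protocol),
            class = "voltage_trace")
}

has_spike <- function(x, thresh = 0) {
  any(x[-1] >= thresh & x[-length(x)] < thresh)
}

#' Classify the somatic/axonal events in a trace
#'
#' A spike at a site is an upward crossing of 0 mV. An AP is counted as
#' propagated when the distal-most node spikes. The somatic response is a
#' back-propagating AP (bAP) when its peak depolarization from rest reaches
#' the full-amplitude criterion (a fraction, default 70%, of the fully
#' myelinated same-morphology bAP peak `bap_ref`); depolarizations above
#' 10 mV that fall short of the criterion are spikelets.
#'
#' @param trace a [integrate_cable()] trace containing at least the soma and
#'   distal node.
#' @param bap_ref reference full bAP somatic amplitude (mV depolarization
#'   from rest), from [bap_reference_amplitude()].
#' @param bap_frac fraction of `bap_ref` defining "full amplitude".
#' @return list with `class` (none / spikelet / bAP_only / bAP_and_AP),
#'   `bap_amplitude` (mV), `ap_propagated`, and per-site spike flags.
#' @export
detect_events <- function(trace, bap_ref, bap_frac = 0.7) {
  stopifnot(inherits(trace, "voltage_trace"))
  need <- c("soma", "distal_node")
  if (!all(need %in% colnames(trace$v)))
    stop("trace must record soma and distal_node")
  spikes <- vapply(colnames(trace$v),
                   function(s) has_spike(trace$v[, s]), logical(1))
  amp <- max(trace$v[, "soma"]) - trace$rest[["soma"]]
  ap <- spikes[["distal_node"]]
  bap <- amp >= bap_frac * bap_ref
  cls <- if (bap && ap) "bAP_and_AP" else if (bap) "bAP_only"
         else if (amp > 10) "spikelet" else "none"
  list(class = cls, bap_amplitude = unname(amp), ap_propagated = unname(ap),
       spikes = spikes)
}

event_predicate <- function(event, bap_ref = NULL, bap_frac = 0.7) {
  switch(event,
    ap = function(trace) {
      has_spike(trace$v[, "distal_node"])
    },
    bap = {
      if (is.null(bap_ref)) stop("bap threshold search needs bap_ref")
      function(trace)
        (max(trace$v[, "soma"]) - trace$rest[["soma"]]) >= bap_frac * bap_ref
    },
    soma_spike = function(trace) has_spike(trace$v[, "soma"]),
    stop("unknown event class: ", event))
}

#' Find the threshold clamp current for an event class
#'
#' Bisects the somatic clamp amplitude to the smallest current (to within
#' `resolution`, default 0.1 pA) that elicits the requested event: `"ap"`
#' (spike at the distal-most node), `"bap"` (full-amplitude somatic
#' depolarization) or `"soma_spike"`. If no event occurs even at `cap` the
#' model is reported unexcitable for that event (used to flag conduction
#' block for AP thresholds).
#'
#' @param model a `cable_model`.
#' @param event `"ap"`, `"bap"` or `"soma_spike"`.
#' @param lower,upper initial bracket (pA); the upper bound auto-expands up
#'   to `cap`.
#' @param cap largest clamp amplitude tried (pA).
#' @param resolution bisection resolution (pA).
#' @param protocol template [stimulus_protocol()]; its amplitude is swept.
#' @param settled optional [settle_model()] result to reuse.
#' @param bap_ref reference bAP amplitude for the `"bap"` criterion.
#' @param bap_frac full-amplitude fraction.
#' @return list with `event`, `threshold` (pA; NA if unexcitable),
#'   `unexcitable`, `resolution`, and the bracketing evidence (somatic
#'   amplitudes just below and at threshold).
#' @export
find_threshold <- function(model, event = c("ap", "bap", "soma_spike"),
                           lower = 0, upper = 2000, cap = 5000,
                           resolution = 0.1, protocol = stimulus_protocol(),
                           settled = NULL, bap_ref = NULL, bap_frac = 0.7) {
  event <- match.arg(event)
  if (is.null(settled)) settled <- settle_model(model)
  pred <- event_predicate(event, bap_ref, bap_frac)
  run <- function(amp) {
    protocol$amplitude <- amp
    integrate_cable(model, protocol, settled)
  }
  soma_amp <- function(trace) max(trace$v[, "soma"]) - trace$rest[["soma"]]

  tr <- run(upper)
  while (!pred(tr) && upper < cap) {
    lower <- upper
    upper <- min(2 * upper, cap)
    tr <- run(upper)
  }
  if (!pred(tr)) {
    return(list(event = event, threshold = NA_real_, unexcitable = TRUE,
                resolution = resolution, cap = cap,
                evidence = c(sub = soma_amp(tr), supra = NA_real_)))
  }
  supra <- tr
  while (upper - lower > resolution) {
    mid <- (upper + lower) / 2
    tr <- run(mid)
    if (pred(tr)) {
      upper <- mid
      supra <- tr
    } else {
      lower <- mid
    }
  }
  sub <- run(lower)
  list(event = event, threshold = upper, unexcitable = FALSE,
       resolution = resolution, cap = cap,
       evidence = c(sub = soma_amp(sub), supra = soma_amp(supra)))
}

#' Somatic bAP amplitude at a given clamp current
#'
#' Runs the protocol at `clamp_current` and returns the somatic peak
#' depolarization from rest. Errors if the current elicits no somatic
#' event (depolarization of at most 10 mV).
#'
#' @inheritParams find_threshold
#' @param clamp_current clamp amplitude (pA), typically the event's
#'   threshold current.
#' @return amplitude (mV).
#' @export
measure_bap_amplitude <- function(model, clamp_current,
                                  protocol = stimulus_protocol(),
                                  settled = NULL) {
  if (is.null(settled)) settled <- settle_model(model)
  protocol$amplitude <- clamp_current
  tr <- integrate_cable(model, protocol, settled)
  amp <- max(tr$v[, "soma"]) - tr$rest[["soma"]]
  if (amp <= 10)
    stop("no somatic event at ", clamp_current, " pA (peak depolarization ",
         round(amp, 2), " mV)")
  unname(amp)
}

#' Reference full-amplitude bAP for a morphology
#'
#' The somatic bAP peak of the fully myelinated (10 wraps everywhere)
#' version of a morphology, measured at its somatic-spike threshold. This
#' anchors the full-amplitude criterion used to separate bAPs from
#' spikelets in demyelinated variants of the same morphology.
#'
#' @param morph a [morphology_spec()].
#' @param chans a [channel_densities()].
#' @param ... passed to [find_threshold()].
#' @return list with `amplitude` (mV), `threshold` (pA) and the settled
#'   full-myelin model (reusable by callers).
#' @export
bap_reference_amplitude <- function(morph, chans, ...) {
  model <- build_cell(morph, chans, myelin_spec(10, morph$axon_diam))
  settled <- settle_model(model)
  thr <- find_threshold(model, "soma_spike", settled = settled, ...)
  if (thr$unexcitable) stop("fully myelinated model is unexcitable at cap")
  amp <- measure_bap_amplitude(model, thr$threshold, settled = settled)
  list(amplitude = amp, threshold = thr$threshold, model = model,
       settled = settled)
}
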