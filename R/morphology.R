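#' Morphology specification for the model neuron
#'
#' Defines the one-dimensional geometry of a deep-layer myelinated pyramidal
#' neuron: a passive dendrite, a soma, an axon initial segment (AIS) of
#' adjustable length, and an alternating chain of myelinated internodes and
#' nodes of Ranvier long enough to project through the underlying white
#' matter.
#'
#' @param ais_length AIS length in micrometers, between 3 and 60. The
#'   wild-type value in rostral entorhinal layer-5 neurons is 20.3 um and the
#'   mutant value 16.8 um.
#' @param soma_length,soma_diam soma dimensions (um).
#' @param dend_length,dend_diam dendrite dimensions (um).
#' @param ais_diam AIS diameter (um).
#' @param n_internodes number of internodes; at least 40 so the axon spans
#'   the white matter below the cortex.
#' @param internode_length,node_length,axon_diam axon dimensions (um).
#' @param compartment_size maximum spatial discretization step (um); the AIS
#'   is always discretized at 1 um or finer.
#' @return An object of class `morphology_spec`.
#' @export
morphology_spec <- function(ais_length = 20.3,
                            soma_length = 25, soma_diam = 25,
                            dend_length = 800, dend_diam = 6,
                            ais_diam = 1.2,
                            n_internodes = 50,
                            internode_length = 100,
                            node_length = 1,
                            axon_diam = 1,
                            compartment_size = 5) {
  stopifnot(ais_length >= 3, ais_length <= 60)
  vals <- c(soma_length, soma_diam, dend_length, dend_diam, ais_length,
            ais_diam, internode_length, node_length, axon_diam,
            compartment_size)
  if (any(vals <= 0)) stop("all lengths and diameters must be positive")
  if (n_internodes < 40)
    stop("n_internodes must be >= 40 (axon must span the white matter)")
  # the AIS and nodes are always discretized at their own finer step
  if (compartment_size > min(soma_length, dend_length, internode_length))
    stop("compartment_size exceeds the shortest section")
  structure(list(soma_length = soma_length, soma_diam = soma_diam,
                 dend_length = dend_length, dend_diam = dend_diam,
                 ais_length = ais_length, ais_diam = ais_diam,
                 n_internodes = n_internodes,
                 internode_length = internode_length,
                 node_length = node_length, axon_diam = axon_diam,
                 compartment_size = compartment_size),
            class = "morphology_spec")
}

#' Channel densities and gating parameters
#'
#' Conductance densities (S/cm2) for the compartmental model. The AIS
#' carries two sodium isoforms with asymmetric placement: a high-threshold
#' isoform (Nav1.2-like) peaking at the proximal end, which drives the
#' back-propagating somatic depolarization, and a low-threshold isoform
#' (Nav1.6-like, activation shifted ~13 mV hyperpolarized) peaking distally,
#' where action potentials initiate.
#'
#' @param nav_soma somatic sodium density (Nav1.2-like kinetics).
#' @param nav12_ais_peak proximal-AIS peak sodium density, specified at the
#'   reference AIS length `ais_ref_length`.
#' @param nav16_ais_peak distal-AIS peak sodium density at the reference
#'   AIS length.
#' @param ais_ref_length reference AIS length (um) at which the AIS peak
#'   densities are specified. The AIS sodium-channel complement is treated
#'   as a conserved pool under AIS plasticity: when the AIS is built at
#'   length L, peak densities are multiplied by `ais_ref_length / L`, so
#'   the total number of AIS channels is length-invariant and lengthening
#'   dilutes the density at the initiation site.
#' @param nav_node nodal sodium density (Nav1.6-like kinetics).
#' @param kv7_ais slow non-inactivating (M-type/Kv7-like) AIS density.
#' @param kdr_soma delayed-rectifier density at soma and AIS.
#' @param g_leak passive leak density of soma, dendrite and AIS.
#' @param g_leak_internode leak density of the *bare* internodal axolemma;
#'   demyelination exposes leaky (juxtaparanodal K-rich) membrane, so this
#'   is much larger than `g_leak`. The effective internodal leak is this
#'   value times the myelin membrane scale factor `1/(1+2*wraps)`.
#' @param e_rest resting/leak reversal potential (mV).
#' @param nav_scale,leak_scale global multipliers: `nav_scale` scales the
#'   somatodendritic and AIS sodium densities (the excitability knob
#'   adjusted by [calibrate_model()]; nodal density is a separate axonal
#'   parameter and is not rescaled), `leak_scale` scales all leak
#'   densities.
#' @param g_leak_node nodal leak density (bare nodal membrane is leakier
#'   than the soma).
#' @param kinetics named list of gating parameters: `vs_act12`, `vs_inact12`,
#'   `vs_act16`, `vs_inact16` (mV shifts of the two isoforms' activation and
#'   inactivation curves), `temp_C`, `q10` (rate temperature adjustment),
#'   `ena`, `ek` (reversals, mV).
#' @return An object of class `channel_densities`.
#' @export
channel_densities <- function(nav_soma = 0.03,
                              nav12_ais_peak = 1.20,
                              nav16_ais_peak = 0.80,
                              nav_node = 0.10,
                              kv7_ais = 0.60,
                              kdr_soma = 0.015,
                              g_leak = 1.5e-4,
                              g_leak_internode = 1e-5,
                              e_rest = -78,
                              nav_scale = 1,
                              leak_scale = 1,
                              g_leak_node = 0.003,
                              ais_ref_length = 20.3,
                              kinetics = list(vs_act12 = 0, vs_inact12 = 0,
                                              vs_act16 = -13, vs_inact16 = 0,
                                              temp_C = 37, q10 = 2.3,
                                              ena = 60, ek = -90)) {
  dens <- c(nav_soma, nav12_ais_peak, nav16_ais_peak, nav_node, kv7_ais,
            kdr_soma, g_leak, g_leak_internode, g_leak_node, nav_scale,
            leak_scale, ais_ref_length)
  if (any(dens < 0)) stop("densities and scales must be non-negative")
  structure(list(nav_soma = nav_soma, nav12_ais_peak = nav12_ais_peak,
                 nav16_ais_peak = nav16_ais_peak, nav_node = nav_node,
                 kv7_ais = kv7_ais, kdr_soma = kdr_soma, g_leak = g_leak,
                 g_leak_internode = g_leak_internode,
                 e_rest = e_rest, nav_scale = nav_scale,
                 leak_scale = leak_scale, g_leak_node = g_leak_node,
                 ais_ref_length = ais_ref_length,
                 kinetics = kinetics),
            class = "channel_densities")
}

#' Myelin wrap specification
#'
#' Wrap counts per internode and the electrical consequences of compact
#' myelin. Each wrap (lamella) adds two membranes in series, so the
#' effective internodal specific capacitance and leak conductance scale by
#' `1/(1 + 2*wraps)`. The default lamella thickness is chosen so that 10
#' wraps yield the wild-type g-ratio of 0.8 (0 wraps = bare axon, g = 1).
#'
#' @param wraps_per_internode integer vector (recycled to `n_internodes` at
#'   build time), each entry in 0..10.
#' @param axon_diam axon diameter (um), used to derive lamella thickness.
#' @param lamella_thickness radial thickness of one wrap (um); default
#'   `axon_diam / 80` solves d/(d + 2*10*t) = 0.8.
#' @return An object of class `myelin_spec`.
#' @export
myelin_spec <- function(wraps_per_internode = 10, axon_diam = 1,
                        lamella_thickness = axon_diam / 80) {
  w <- wraps_per_internode
  if (any(w < 0) || any(w > 10) || any(w != round(w)))
    stop("wraps_per_internode must be integers in 0..10")
  stopifnot(lamella_thickness > 0)
  structure(list(wraps_per_internode = as.integer(w),
                 lamella_thickness = lamella_thickness),
            class = "myelin_spec")
}

#' g-ratio of a myelinated fiber
#'
#' The g-ratio is the axon diameter divided by the outer fiber diameter
#' (axon plus myelin sheath). With the default lamella thickness of
#' `axon_diam/80`, 0 wraps give g = 1 (demyelinated) and 10 wraps give the
#' wild-type g = 0.8.
#'
#' @param wraps number of myelin wraps (non-negative).
#' @param axon_diam axon diameter (um).
#' @param lamella_thickness thickness of one wrap (um).
#' @return g-ratio in (0, 1].
#' @examples
#' wraps_to_gratio(0)   # 1 (bare axon)
#' wraps_to_gratio(10)  # 0.8 (wild-type myelin)
#' @export
wraps_to_gratio <- function(wraps, axon_diam = 1,
                            lamella_thickness = axon_diam / 80) {
  if (any(wraps < 0)) stop("wraps must be non-negative")
  axon_diam / (axon_diam + 2 * wraps * lamella_thickness)
}

#' Myelin membrane scale factor
#'
#' Factor applied to internodal specific capacitance and leak conductance:
#' each wrap adds two membranes in series with the axolemma, giving
#' `1/(1 + 2*wraps)`. Equal to 1 at 0 wraps and strictly decreasing.
#'
#' @param wraps number of myelin wraps (non-negative).
#' @export
myelin_membrane_scale <- function(wraps) {
  if (any(wraps < 0)) stop("wraps must be non-negative")
  1 / (1 + 2 * wraps)
}
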