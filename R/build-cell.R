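#' Build the compartmental neuron model
#'
#' Discretizes the morphology into a linear chain of iso-potential
#' compartments (dendrite - soma - AIS - alternating internodes and nodes)
#' and attaches electrical parameters. Internodal specific capacitance and
#' leak are scaled by [myelin_membrane_scale()] of the local wrap count.
#' The AIS sodium profile is a linear crossover: the high-threshold proximal
#' isoform falls from its peak at the soma end to zero distally while the
#' low-threshold distal isoform rises from zero to its peak at the distal
#' end; the profile stretches with AIS length.
#'
#' @param morph a [morphology_spec()].
#' @param chans a [channel_densities()].
#' @param myelin a [myelin_spec()].
#' @param ra axial resistivity (Ohm cm).
#' @param cm base specific membrane capacitance (uF/cm2).
#' @return An object of class `cable_model`: a list with the compartment
#'   table (`comp`), the input specs, and named indices of the standard
#'   recording sites (`sites`).
#' @export
build_cell <- function(morph, chans, myelin, ra = 150, cm = 1) {
  stopifnot(inherits(morph, "morphology_spec"),
            inherits(chans, "channel_densities"),
            inherits(myelin, "myelin_spec"))
  wraps <- rep_len(myelin$wraps_per_internode, morph$n_internodes)

  seg <- function(section, total_len, diam, step, number = NA_integer_) {
    ns <- ceiling(total_len / step)
    data.frame(section = section, number = number,
               length = rep(total_len / ns, ns), diam = diam,
               pos = (seq_len(ns) - 0.5) / ns)
  }
  step <- morph$compartment_size
  ais_step <- min(1, step)

  parts <- list(
    seg("dendrite", morph$dend_length, morph$dend_diam, step),
    seg("soma", morph$soma_length, morph$soma_diam, step),
    seg("AIS", morph$ais_length, morph$ais_diam, ais_step))
  for (k in seq_len(morph$n_internodes)) {
    parts[[length(parts) + 1L]] <-
      seg("internode", morph$internode_length, morph$axon_diam, step, k)
    parts[[length(parts) + 1L]] <-
      seg("node", morph$node_length, morph$axon_diam,
          min(step, morph$node_length), k)
  }
  comp <- do.call(rbind, parts)
  n <- nrow(comp)
  comp$area <- pi * comp$diam * comp$length * 1e-8   # cm2

  ns <- chans$nav_scale
  ls <- chans$leak_scale
  comp$cm <- cm
  comp$gleak <- chans$g_leak * ls
  comp$gna12 <- 0
  comp$gna16 <- 0
  comp$gkdr <- 0
  comp$gkv7 <- 0
  comp$wraps <- NA_integer_

  is_soma <- comp$section == "soma"
  comp$gna12[is_soma] <- chans$nav_soma * ns
  comp$gkdr[is_soma] <- chans$kdr_soma

  is_ais <- comp$section == "AIS"
  x <- comp$pos[is_ais]                      # normalized AIS position
  # conserved channel pool: peak density dilutes as the AIS lengthens
  pool <- chans$ais_ref_length / morph$ais_length
  comp$gna12[is_ais] <- chans$nav12_ais_peak * pool * ns * (1 - x)
  comp$gna16[is_ais] <- chans$nav16_ais_peak * pool * ns * x
  comp$gkdr[is_ais] <- chans$kdr_soma
  comp$gkv7[is_ais] <- chans$kv7_ais

  is_node <- comp$section == "node"
  # nodal density is an axonal parameter, outside the somatodendritic/AIS
  # excitability scale adjusted by calibration
  comp$gna16[is_node] <- chans$nav_node
  comp$gleak[is_node] <- chans$g_leak_node * ls
  comp$gkdr[is_node] <- chans$kdr_soma

  is_int <- comp$section == "internode"
  msc <- myelin_membrane_scale(wraps)[comp$number[is_int]]
  comp$cm[is_int] <- cm * msc
  comp$gleak[is_int] <- chans$g_leak_internode * ls * msc
  comp$wraps[is_int] <- wraps[comp$number[is_int]]

  ais_idx <- which(is_ais)
  soma_idx <- which(is_soma)
  node_numbers <- comp$number[is_node]
  sites <- c(
    dendrite = which(comp$section == "dendrite")[
      ceiling(sum(comp$section == "dendrite") / 2)],
    soma = soma_idx[ceiling(length(soma_idx) / 2)],
    ais_end = ais_idx[length(ais_idx)],
    mid_node = which(is_node)[node_numbers == ceiling(morph$n_internodes / 2)],
    distal_node = which(is_node)[node_numbers == morph$n_internodes])

  structure(list(comp = comp, morph = morph, chans = chans,
                 myelin = myelin, wraps = wraps, ra = ra, cm_base = cm,
                 n = n, sites = sites),
            class = "cable_model")
}

#' @export
print.cable_model <- function(x, ...) {
  cat("<cable_model> ", x$n, " compartments; AIS ",
      x$morph$ais_length, " um; ", x$morph$n_internodes,
      " internodes (wraps: ", paste(range(x$wraps), collapse = "-"),
      ")\n", sep = "")
  invisible(x)
}

#' Apply a demyelinating (or remyelinating) lesion
#'
#' Replaces the wrap count of the listed internodes, rescaling only their
#' compartments' capacitance and leak; every other compartment is left
#' untouched.
#'
#' @param model a [build_cell()] model.
#' @param internode_indices internode numbers (1-based) to modify; an empty
#'   set returns the model unchanged.
#' @param wraps new wrap count (0..10) for those internodes.
#' @return The modified `cable_model`.
#' @export
apply_demyelination <- function(model, internode_indices, wraps) {
  stopifnot(inherits(model, "cable_model"), length(wraps) == 1,
            wraps >= 0, wraps <= 10, wraps == round(wraps))
  if (length(internode_indices) == 0) return(model)
  ni <- model$morph$n_internodes
  if (any(internode_indices < 1) || any(internode_indices > ni))
    stop("internode index out of range 1..", ni)
  model$wraps[internode_indices] <- as.integer(wraps)
  sel <- model$comp$section == "internode" &
    model$comp$number %in% internode_indices
  msc <- myelin_membrane_scale(wraps)
  model$comp$cm[sel] <- model$cm_base * msc
  model$comp$gleak[sel] <-
    model$chans$g_leak_internode * model$chans$leak_scale * msc
  model$comp$wraps[sel] <- as.integer(wraps)
  model
}

# Absolute electrical parameters for the integrator.
# C nF, conductances uS, axial couplings uS between adjacent compartments.
cable_pars <- function(model) {
  comp <- model$comp
  kin <- model$chans$kinetics
  area <- comp$area
  xarea <- pi * (comp$diam * 1e-4)^2 / 4          # cross-section, cm2
  half_r <- model$ra * (comp$length * 1e-4) / (2 * xarea)  # Ohm
  n <- model$n
  ga <- 1e6 / (half_r[-n] + half_r[-1])           # uS
  list(C = comp$cm * area * 1e3,
       gL = comp$gleak * area * 1e6,
       eL = rep(model$chans$e_rest, n),
       gna12 = comp$gna12 * area * 1e6,
       gna16 = comp$gna16 * area * 1e6,
       gkdr = comp$gkdr * area * 1e6,
       gkv7 = comp$gkv7 * area * 1e6,
       ga = ga,
       ena = kin$ena, ek = kin$ek,
       tadj = kin$q10^((kin$temp_C - 23) / 10),
       kinetics = kin[c("vs_act12", "vs_inact12", "vs_act16", "vs_inact16")])
}
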