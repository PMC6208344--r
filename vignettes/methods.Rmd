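---
title: "Models and methods: demyelination simulations and interhemispheric EEG coherence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(demyelin)
```

This package has two computational arms: a compartmental model of a
myelinated deep-layer cortical pyramidal neuron, used to ask how axon
initial segment (AIS) length and myelin wrap count shape action-potential
(AP) and back-propagating action-potential (bAP) threshold currents and
amplitudes under demyelination and remyelination; and a two-channel
interhemispheric EEG pipeline measuring band-limited relative power and
time-domain real coherence, with seeded synthetic-data generators and the
small statistics used around both arms. This vignette documents the
models, the tunable parameters and their defaults, the numerical choices,
and what the synthetic data can and cannot establish.

## 1. The neuron model

### Geometry

The cell is a one-dimensional chain: a passive dendritic equivalent
cylinder (800 x 6 um), a soma (25 x 25 um), an AIS of adjustable length
(3-60 um, 1.2 um diameter), and 50 internode/node pairs (100 um
internodes, 1 um nodes) so the axon spans the white matter beneath the
cortex. The dendrite is deliberately a large equivalent cylinder: a
layer-5 pyramidal neuron carries tens of thousands of square micrometers
of dendritic membrane, and the threshold-current scale of the
experiments (hundreds of picoamperes spanning a ~400 pA range across AIS
lengths) is only reachable with a realistic somatodendritic load. A
morphology with a token dendrite produces thresholds an order of
magnitude too small and compresses the AIS-length dependence into a few
tens of picoamperes.

Spatial discretization is 5 um (1 um in the AIS and nodes). Total axial
resistance per section and total AIS channel content are invariant to
refining the step (tested), so results do not hinge on the grid.

### Channels

Gating uses Mainen-style trap-function rate equations at 37 °C (Q10 2.3
applied to all rates; reversals +60/-90 mV). Five conductances are
placed:

* **Somatic Nav** (high-threshold, Nav1.2-like kinetics) - spike
  regeneration at the soma.
* **Proximal AIS Nav** (Nav1.2-like), peaking at the somatic end of the
  AIS and falling linearly to zero distally. This pool drives the
  somatic full-amplitude depolarization (the bAP).
* **Distal AIS Nav** (Nav1.6-like: activation shifted 13 mV
  hyperpolarized, inactivation unshifted), rising linearly from zero at
  the somatic end to its peak distally. APs initiate here. The
  orientation - low-threshold isoform distal - follows the standard
  picture of AIS channel segregation; the asymmetry is what lets a
  somatic current clamp produce both an orthodromic AP and an antidromic
  full somatic depolarization with nearly identical threshold currents.
* **Delayed-rectifier K** at soma, AIS and nodes - repolarization.
* **Kv7-like slow K (M-current)** on the AIS - the slow, sub-threshold
  activating conductance that couples threshold current to AIS length
  (below).

### The conserved AIS channel pool

AIS peak sodium densities are specified at the reference length of
20.3 um and scaled by `20.3 / ais_length` when the cell is built, so the
*total* AIS sodium complement is invariant as the AIS lengthens or
shortens and the density at the initiation site dilutes with length.
This models AIS plasticity as a redistribution of a fixed channel pool.
It is also the choice that reproduces the observed direction of the
threshold-length relation: with fixed *density*, a longer AIS simply has
more sodium and its threshold current falls with length - the opposite
of what the study's simulations show. With a conserved pool plus the
Kv7 load growing in proportion to AIS area, the AP threshold rises with
AIS length across the whole 3-60 um range, approximately as a low-order
polynomial.

### Myelin

Each myelin wrap adds two membranes in series with the internodal
axolemma, so internodal specific capacitance and leak are scaled by
`1/(1 + 2*wraps)` (the standard double-cable simplification). The
lamella thickness defaults to `axon_diam/80`, which makes 10 wraps
correspond exactly to the wild-type g-ratio of 0.8 and 0 wraps to a bare
axon (g = 1). The *bare* internodal axolemma has its own leak density
(`g_leak_internode`), distinct from and larger than the somatodendritic
leak: demyelination exposes leaky (juxtaparanodal K-channel-rich)
internodal membrane. Conduction failure across a demyelinated stretch
arises jointly from this exposed leak and from the 21-fold rise in
exposed capacitance, against which the deliberately modest nodal sodium
density provides little safety margin - which is exactly the regime in
which one wrap of myelin restores conduction.

### Resting potential and stability

`e_rest` is -78 mV. The model must sit at a stable rest with all gating
at steady state; with the low-threshold distal-AIS/nodal Nav isoform, a
rest near -70 mV leaves enough standing window current to ignite tonic
firing, so the anesthetized-cortex value is used and stability is
enforced by test (every site within 0.5 mV over a full zero-stimulus
run after settling). The somatodendritic leak density (1/4000 S/cm2) is
a high-conductance (in-vivo-like) membrane: beyond realism, it sets the
denominator that keeps the threshold footprint of lesioned axon
segments below the 5% invariance bound for bAP thresholds.

### Clamp protocol

The default protocol is a 150 ms somatic step (dt 0.02 ms, full run
180 ms), i.e. a rheobase-style stimulus; thresholds are bisected to
0.1 pA. Near threshold it elicits a single early spike. Two properties
motivated the long step over a brief pulse. First, the AIS Kv7
conductance is slow; only a quasi-steady approach to threshold lets its
sub-threshold activation (the AIS-length-proportional load) govern the
threshold current, which is what spreads the AP threshold over a
~400 pA range across 3-60 um. Second, at quasi-steady state the
threshold is set by conductances alone, so the large *capacitance*
changes produced by demyelination are invisible to the threshold while
remaining fully visible to the spike itself - reproducing the observed
dissociation in which bAP threshold currents are refractory to myelin
pathology while bAP amplitudes and AP conduction are not. With a brief
(few-ms) pulse both properties are lost: the threshold becomes a purely
capacitive charge criterion, nearly independent of AIS length, and
strongly dependent on lesion capacitance.

### Event definitions

A spike at a site is an upward 0 mV crossing. An AP is "propagated" if
the distal-most node spikes. "Full-amplitude" somatic depolarization
means a somatic peak of at least 70% of the peak of the same
morphology's fully myelinated (10-wrap) variant at its somatic-spike
threshold; somatic peaks above 10 mV depolarization but below that
criterion are spikelets. The 70% figure operationalizes a verbal
distinction; conclusions are insensitive to it because somatic
responses in practice either exceed ~80% of the reference or stay below
~40%.

### Calibration

`calibrate_model()` adjusts one global sodium-density multiplier
(applied to the somatodendritic and AIS pools; the nodal density is an
axonal parameter outside the calibrated excitability scale, so
conduction-safety margins are independent of calibration) by bisection
so the fully myelinated AIS sweep spans a 400 pA AP-threshold range
(the anchor the study prints), then verifies the curve increases with
AIS length. Calibration is deterministic and its achieved range,
scale and sweep thresholds are recorded on the returned object. All
other densities are package defaults chosen once, as described above;
the exact published parameter set behind the original simulations is
not public, so the calibrated anchors - threshold range, conduction
block and restoration, plateau onsets, threshold invariances - are the
reproducible content.

### Numerical scheme

The cable equation is integrated by backward Euler on the tridiagonal
chain system (Thomas algorithm, compiled code), with gating advanced by
exact exponential update at the pre-step voltage - the standard
staggered scheme; it is unconditionally stable, so the 100 ms settling
phase can run at a coarse step. Convergence is tested: halving dt moves
thresholds by less than 0.5 pA, and doubling the simulated window does
not change them. Thresholds are bit-reproducible for a fixed model and
protocol.

## 2. The EEG pipeline

The pipeline reproduces a two-channel (A1/A2 referenced to Cz, 250 Hz)
resting-EEG analysis chain:

1. Zero-phase FIR high-pass (0.5 Hz) and low-pass (50 Hz); the 6 Hz
   cardiac artifact is removed by fitting and subtracting the 6 Hz
   Fourier component over the whole recording.
2. Non-overlapping 2 s epochs; trailing partial epochs dropped.
3. Stage-1 artifact rejection: an epoch is discarded if the channel-mean
   broadband analytic amplitude exceeds mean + 5 SD of the whole
   recording for a contiguous run longer than 10 ms (>= 3 samples at
   250 Hz).
4. A 30-filter bank, centers log-spaced on 1-30 Hz, bandwidth
   `min(ceiling(fc/3), 5)` Hz. Filters are Hamming windowed-sinc FIR
   designs, order three cycles of the lower passband edge, applied
   forward-backward (zero phase). Each epoch is zero-padded
   symmetrically to 10 s before filtering; power and coherence use only
   the original 2 s span. Power is the halved squared Hilbert envelope
   (so a sinusoid of amplitude a reports a^2/2). Filtering and the
   analytic signal are applied spectrally on the padded window - the
   exact frequency response of the forward-backward FIR, computed
   efficiently.
5. Stage-2 rejection: per-epoch power averaged over filters and
   channels, z-scored across surviving epochs; z > 2 (one-sided - an
   artifact is a power excess) is discarded. Fewer than 3 surviving
   epochs aborts the pipeline.
6. Band relative power: filter powers averaged over clean epochs and
   channels, summed into delta [1,4), theta [4,10), alpha [10,15) and
   beta [15,30] Hz by filter center (half-open edges prevent double
   counting), expressed as % of the 1-30 Hz total - the four bands sum
   to 100 by construction.
7. Real coherence: per filter, the real part of the normalized
   cross-channel analytic-signal coherency, pooled over clean epochs;
   per band, the *median* across member filters. The median is
   motivated by the platykurtic distribution of within-band coherence
   values (excess kurtosis is typically negative): it moves less than
   the mean when a single filter bin is contaminated.

**Choice of coherency estimator.** The exact time-domain coherence
formula behind the original analysis is not published. Three estimators
are implemented: `"pooled"` (default) accumulates cross- and
auto-products over all clean-epoch samples before normalizing;
`"complex-mean"` and `"real-mean"` first normalize within each 2 s epoch
and then average. The per-epoch variants shrink estimates toward zero by
roughly `c(1-c^2)/2` per degree of freedom; for delta filters (1 Hz
bandwidth x 2 s epochs) that is a systematic ~0.04-0.05 downward bias,
which would defeat parameter-recovery testing at the +-0.05 level. The
pooled estimator is unbiased across all bands at this epoch length,
which is why it is the default.

## 3. Synthetic data

`generate_eeg_pair()` builds each channel as a weighted sum over the four
analysis bands of `sqrt(c_b) * shared + sqrt(1-c_b) * own-noise`
band-limited unit-variance sources, so the population real coherence in
band b is exactly `c_b` and the band power proportions follow the
weights (defaults: the control profile delta 61.9, theta 27.2, alpha
6.1, beta 4.7%). The sources are shaped spectrally with sharp
raised-cosine band edges (transitions inside the band): soft FIR-style
transition bands would let one band's source carry power - and its
coherence target - inside a neighboring band, which both breaks the
generator's per-band contract and creates spurious between-group
differences in bands that are nominally null. Within each band the
sources carry a 1/f^2 spectral tilt, clamped at the band's lower edge -
clamping matters, because an unclamped 1/f weight amplifies near-DC
spectral leakage into the dominant variance term and corrupts the
realized coherence. On top of
the background go a common 6 Hz cardiac sinusoid and Poisson-placed
50-200 ms noise bursts at 10-20x the background SD, which the two
rejection stages must catch. Everything is a pure function of (config,
seed), and the generator restores the caller's RNG state.

`generate_cohort()` encodes the study contrast: the 12-month mutant
group's theta coherence target is 0.73x the control target (0.8 ->
0.584 by default); all other bands are identical across groups.
Recordings default to 120 s per animal; the power analysis in the
acceptance suite uses 60 s, which at n = 8/group already separates a
0.73x theta ratio with near-certain significance while leaving delta
null. The 2-12-month weekly inverted-screen series use a 60 s baseline
hang score with 10% multiplicative log-normal noise; injected transient
deficits drop one week's median by a uniform 4-8-fold factor (clamped
below a third of the previous week) and recover by the next test, so
generator truth and the detection rule agree by construction.

What the synthetic data does *not* emulate: volume conduction and
reference-electrode structure, non-stationary anesthesia depth, real
artifact morphologies (chewing, movement), spatially structured cortical
sources, or any physiological coupling between bands. Passing
parameter-recovery tests therefore demonstrates that the pipeline
measures what its own forward model generates - a consistency check and
a power analysis, not evidence about real EEG.

## 4. Statistics

* `fisher_exact_2x2()` - exact two-sided p by full hypergeometric
  enumeration with the point-probability rule (tables at most as
  probable as the observed one), the convention of standard references.
  On the study's transient-deficit table (1 event/800 control tests vs
  12/1000 mutant tests) it gives p = 0.0089 < 0.01.
* `bky_fdr()` - the two-stage adaptive linear step-up FDR procedure:
  stage 1 at `q' = Q/(1+Q)`, null-count estimate `m0 = m - r1`, stage 2
  at `q' * m / m0`. Adjusted q-values are defined as the smallest Q at
  which the whole two-stage procedure rejects, found by bisection
  (rejection is monotone in Q on the grid used). Note the two-stage
  procedure is guaranteed to contain the rejections of the plain
  step-up at `q'` (not at `Q`): near the boundary it can reject
  slightly fewer than plain BH at `Q`, a property the tests state
  precisely.
* `detect_transient_deficits()` - a deficit at week t requires
  `score[t] < score[t-1]/3` and recovery `score[t+1] >= score[t-1]/3`;
  weekly testing makes "recovery within 7 days" equal to recovery at
  the next observation.
* `excess_kurtosis()` - bias-corrected sample excess kurtosis. The
  theoretical minimum is -2; printed values below that in the source
  material presumably reflect a different kurtosis convention, and this
  package simply uses the standard definition.
* `compare_bands()` - per-band two-sample location test on per-animal
  median coherences (Wilcoxon by default - robust, in keeping with the
  platykurtosis concern; Welch optional), with the two-stage FDR across
  bands. This is the desk-scale analogue of the original repeated-
  measures analysis, applied at a single age.

## 5. Problem sizes and determinism

The acceptance experiments run at the sizes the package documents as its
standard study conditions: AIS sweeps over {3, 10, 20, 30, 40, 50, 60}
um (calibration on the 3/60 um endpoints, which suffices because the
calibrated curve is monotone); wrap sweeps over 0..10 at 20.3 and
16.8 um; proximal lesions over internodes 1-20 and distal lesions over
21-50; 10-minute synthetic recordings for single-recording parameter
recovery; and 100 seeded replicates of an n = 8/group, 60 s/animal
cohort for the power check. Simulation experiments are deterministic
given the configuration; every stochastic step takes an explicit seed.

## 6. Known limitations

* The neuron model is a calibrated mechanism model, not a parameter
  reproduction: channel kinetics and densities stand in for an
  unpublished set, and only the printed anchors constrain it.
* The "plateau" (within 5% of the 10-wrap value) and "approximates wild
  type" (within 10%) rules quantify verbal descriptions; the wrap at
  which a curve crosses a 5% band is inherently sensitive near the
  boundary.
* Single equivalent-cylinder dendrite: no dendritic nonlinearities, no
  synaptic input, no network context.
* The EEG arm analyzes exactly two channels; no source modeling, sleep
  staging or longitudinal (repeated-measures) machinery.
* Kv7 density changes at the AIS can be explored through
  `channel_densities()`, but no quantitative claims are attached to
  them.
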