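---
title: "colorspike: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{colorspike: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific question

Macaque V1/V2 contains patchy clusters of color-selective neurons. This
package implements a spiking model of how such clusters can self-organize:
color patches drive trichromatic photoreceptors; their signals are combined
into a luminance channel (L = R+G) and two opponent channels (red/green
C1 = R−G, blue/yellow C2 = (R+G)−B) at the LGN; the channels project
topographically onto layered V1 populations (L4, L2/3, L5) of
Hodgkin–Huxley neurons with short-range lateral excitation, longer-range
lateral inhibition, and 1 ms (excitatory) / 4 ms (inhibitory) transmission
delays. All feed-forward weights above the retina are learned with
spike-timing-dependent plasticity (STDP) under layer-wide mean
normalization; photoreceptor→LGN wiring is fixed. The package also ships
the analysis suite used to characterize the trained model (a spatial
clustering coefficient, single- and multiple-cell stimulus information,
ON/OFF and opponent-cell selection), two executable "toy" opponent
microcircuits, a synthetic color-patch generator, and experiment presets.

# The neuron and synapse model

Cells are single cylindrical compartments (30 × 10 µm, area ≈ 9.42 × 10⁻⁶
cm²) with squid-axon Na⁺/K⁺ channels (ḡ_Na = 120, ḡ_K = 36 mS/cm², the
canonical constants; the source names the channels but not their
densities), leak, and conductance synapses: AMPA (τ = 5 ms, E = 0 mV) and
GABA (τ = 10 ms, E = −80 mV), each an instantaneous conductance increment
followed by exponential decay, with current `g·(V − E)`.

Two printed membrane constants cannot be taken literally, and
`membraneParams()` keeps them as an explicit `convention = "literal"`
alternative rather than defaults:

* a leak reversal of 0 mV is a shifted-convention value that is
  incompatible with the absolute AMPA/GABA reversals printed next to it;
  the default is the absolute convention, `e_leak = −65 mV`, leak density
  0.1 mS/cm² (the printed absolute 0.001 nS over this compartment gives a
  ~9 s membrane time constant);
* a capacitance density of 10 µF/cm² combined with standard squid kinetics
  admits at most a single spike followed by depolarization block at any
  drive strength (we verified this numerically up to 500 µA/cm²); since
  the model's whole premise is sustained 40 Hz-driven firing, the default
  is the standard 1 µF/cm².

Integration is fixed-step: exponential-Euler gating toward the steady state
at the start-of-step voltage, forward-Euler voltage on start-of-step
currents, dt = 0.025 ms. A spike is an upward crossing of 0 mV outside a
2 ms lockout. The compiled network engine uses a 0.01 mV lookup table for
the gating rates; the R-level single-neuron stepper (`advanceNeuron()`)
uses exact rates and serves as the reference path in the tests. Halving dt
moves driven spike times by well under 0.5 ms per spike.

# Stimuli

RGB values in [0, 1] map to cone rates with a 40 Hz ceiling:
S = 40·B, M = 40·(G + 0.7R + 0.25B)/1.95, L = 40·(R + 0.7G + 0.25B)/1.95 —
so "red" also drives the M cone strongly, as in primate vision. The
photoreceptor grids are named R/G/B after the channel that dominates them
but carry the L/M/S cone rates respectively.

Input cells emit clock-like trains at their cone rate, each cell phase
shifted by a fixed onset delay drawn once at construction, uniform over one
interspike interval of the ceiling rate (≤ 25 ms). The "10% random noise"
of the drive has two readings, both implemented:

* **rate mode** (default): the rate of each train is scaled by a
  per-presentation factor in ±10%. Used for training and rate-based
  testing.
* **jitter mode**: the rate is exact and each spike is displaced by up to
  ±10% of one interval. This preserves the phase alignment of the trains,
  on which the spike-timing experiments depend: under rate noise the
  accumulated phase drift across a 240 ms presentation exceeds a full
  interval, which by itself staggers the final input spikes and makes the
  delay-ablation comparison meaningless. `onOffProtocol()` therefore
  defaults to jitter mode.

The synthetic patch generator (`synthPatchSampler()`) stands in for crops
of natural scenes. The default `smooth_field` style upsamples a coarse
random control grid per channel, giving spatially correlated patches whose
hues span the RGB cube with long-run channel means near 0.5. It emulates
the spatial-correlation and hue-coverage statistics of natural crops, not
their higher-order structure (edges, objects, illuminant correlations), so
passing tests speak to the self-organization mechanism, not to performance
on real imagery.

# Learning

STDP follows the pair-based exponential window (potentiation
τ = 17 ms, depression τ = 34 ms; zero lag is undefined by the rule and
contributes nothing), with nearest-neighbour pairing: each postsynaptic
spike pairs with the closest preceding presynaptic spike and vice versa.
All-to-all pairing is deliberately not offered — with regular 40 Hz trains
it couples every spike to every other and the update loses locality.
Deltas are computed from the whole 300 ms trial raster and applied at trial
end; at the default learning rate (10⁻³·w_max per pairing) the within-trial
weight motion is ~0.1% of the range, so this is indistinguishable from
online application. After every iteration each plastic projection is
rescaled multiplicatively (with clipping, iterated to a 10⁻⁶ tolerance) so
its mean sits at mid-range — the normalization that prevents runaway
excitation. The Hebbian control potentiates a weight once per presentation
whenever both endpoints fired, regardless of order — co-activation with
the timing information removed.

# Calibration choices

The source fixes the architecture and the constants listed above but not
the connection gains, lateral radii, feed-forward spread, or learning rate.
These were chosen once, as follows, and are all exposed in `runConfig()`:

* feed-forward convergence radius r_ff = 1 (a 3×3 source region), the
  smallest radius that makes receptive fields grow through the hierarchy;
* photoreceptor→LGN gain 4 nS: a single EPSP relays reliably, so the LGN
  acts as a relay;
* plastic weight range [0, 0.2 nS]: V1 cells then integrate tens of inputs
  and the untrained L5 sits at low single-digit Hz under full-field drive
  (the reported pre-training mean rate, ~2 Hz, is the order-of-magnitude
  guide here);
* Mexican hat r_exc = 1, r_inh = 3, connection probability 0.5, weights
  2 nS (AMPA) / 10 nS (GABA): the regime in which single-trial V1 activity
  forms spatial bubbles rather than salt-and-pepper;
* learning rate 10⁻³·w_max per pairing for the 2000-iteration full run;
  the 200-iteration desk presets scale it tenfold so the total plasticity
  per session is comparable.

# Scaled-down study sizes

The full configuration (10×10 photoreceptor grids, 30×30 LGN and V1
grids, 5700 cells, 2000 × 300 ms iterations) builds and runs, but the
package's end-to-end claims are validated on the `desk_small` preset:
5×5 photoreceptors, 10×10 LGN and V1 grids (675 cells), 200 iterations,
three seeds — chosen so a full replicate study (STDP + Hebbian control +
delay ablation, with testing) completes in a few minutes on one core.
`runDeskStudy()` runs the whole thing and returns seed-averaged summaries.

# The analysis suite and its numerical choices

**Clustering coefficient.** For each cell and stimulus, the mean pairwise
product of firing rates over the cell's 3×3 neighborhood (including the
cell; borders truncate the neighborhood and the pair count `C(k_i, 2)`
adjusts), averaged over cells and stimuli. This is a spatial co-activation
statistic, not the graph-theoretic coefficient. The defining sums use raw
rates; `clusteringCoefficient()` also offers min-max (default) and
max normalization. The choice matters: training under STDP raises mean
rates and sharpens peaks (naive→trained L5 mean rate rises, mirroring the
reported 2.165 → 3.966 Hz), and the raw statistic tracks exactly that
growth — seed-averaged desk runs give L5 ≈ 68 (naive) → 92 (STDP) versus
78 (Hebbian control). Min-max normalization removes the rate component,
and because binarized weights also *sparsify* responses, the normalized
variant actually favors the homogeneous activity of the Hebbian control
and inverts the contrast. The package therefore evaluates the
training-dynamics claim on the raw statistic and documents both.

**Single-cell information.** Responses of a cell are binned into 8
equal-width bins over its observed range (bin count exposed; the source
does not state one); I(s) = Σ_r P(r|s) log₂ P(r|s)/P(r), with P(r|s)
estimated over a stimulus's transforms. Ceiling log₂(nStims) = 3 bits for
the 8 test colors (the corners of the RGB cube, each also presented as
±1% transforms). A zero-range cell carries 0 bits by convention.

**Multiple-cell information.** Cells are added in decreasing order of
single-cell information; each presentation is decoded with a Bayesian
decoder under independent per-cell Gaussian likelihoods (mean and SD over
the stimulus's transforms; SD floored at 10⁻³ Hz, since silent cells are
routine and would otherwise produce degenerate posteriors). The posterior
mass accumulates into the (actual, decoded) confusion distribution whose
mutual information is reported. Likelihoods are evaluated on the same
transform set that estimates the response models (no held-out split); with
8 transforms the optimism is modest and identical for the naive/trained
comparison the measure serves.

**ON/OFF and opponent cells.** Each color is presented full-field for
240 ms followed by 60 ms of silence. ON cells are the top responders in
the first 60 ms, OFF cells in the 60 ms after removal, ties broken by cell
id. Opponent cells are found in two stages: the ON pool for the primary
color (100 cells — at desk scale that spans the whole 100-cell L5 layer),
then the strongest OFF responders to the opponent color within the pool.
The final list size is scaled to the desk layer (3 = 30·100/900); a list
that cannot be filled is flagged short, which is precisely the signature
of the no-delay ablation. Because single protocol runs contain few OFF
spikes, `runDeskStudy()` averages the search over three protocol
repetitions per network.

**Weight bimodality.** The fraction of weights within 10% of either bound
(0.2 for a uniform distribution, 1 for a binary one) plus Sarle's
bimodality coefficient (γ² + 1)/κ. A dedicated dip-test package is not a
dependency; the near-bound fraction carries the trained-network claim
(desk runs reach ≈ 0.78 under STDP while the Hebbian control falls to
≈ 0.04, concentrating at mid-range).

# The toy opponent microcircuits

The two microcircuits make the proposed ON/OFF mechanism explicit with a
handful of named cells. Both use the full neuron/synapse model. The
starred "delayed" edges of the schematics are implemented as an extra
transmission delay so that an input's trailing spikes outlast stimulus
removal. The worked 24 ms offset in the source corresponds to one
interspike interval *at the 40 Hz ceiling*; the toys are driven through
the cone transform, whose opponent-channel rates are ~14–35 Hz, and at
those rates a 24 ms offset leaves essentially no trailing deliveries in
the OFF window (we verified by grid and random search over the fixture
space that the contrasts are unreachable there). The shipped default is
75 ms ≈ 1.5 opponent-channel intervals, which places two trailing
deliveries inside the OFF window. Synaptic weights and the three input
phase offsets are hand-tuned fixture constants — the schematics fix signs
and topology only — derived with `inst/scripts/tune_toycircuits.R`.
Window counts are averaged over 5 repetitions per evaluation
(single-trial counts are 0–2 spikes). Residual cross-talk (ON activity
persisting briefly after removal, OFF cells firing during presentation)
is expected and tolerated; all assertions are window-count inequalities.

# Reproducibility and degenerate inputs

Every simulation is a pure function of (configuration, seeds): network
wiring and onset delays from the network seed, patches from the input
seed, per-presentation noise from the ambient RNG stream. Identical seeds
give bit-identical rasters. Degenerate cases are defined rather than
fatal: a black patch is silence; an all-equal rate map normalizes to its
constant value with a warning; an all-zero weight vector resets uniformly
to mid-range; a zero-variance response model is floored.

# Known limitations

* The desk-scale study reproduces the qualitative training phenomena, not
  printed full-scale numbers; in particular the cells-to-plateau ordering
  across layers reproduces only partially (L5 needs the fewest cells, as
  reported, but the desk-scale L2/3 — which merges the koniocellular
  stream with L4 across only 100 cells — needs slightly *more* cells than
  L4, not fewer).
* Naive networks here are already fairly informative about the eight
  saturated test colors (the corner palette is easy); the trained-vs-naive
  information gap is real but smaller than with natural-image training.
* Single-compartment neurons: no dendritic filtering, no stochastic
  channels, no orientation selectivity, no V1→LGN feedback.
* The synthetic patch ensemble does not contain object or edge structure;
  claims about natural images are outside what the tests establish.
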