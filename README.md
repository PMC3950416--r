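# colorspike

Spiking-network model of how color-selective neuronal clusters
self-organize in primary visual cortex, with the analysis suite needed to
demonstrate it.

Color input enters as RGB patches, is transduced into trichromatic cone
rates with a 40 Hz ceiling,

    S = 40·B,  M = 40·(G + 0.7R + 0.25B)/1.95,  L = 40·(R + 0.7G + 0.25B)/1.95,

and is combined at the LGN into a luminance channel **L = R + G** and two
opponent channels, red/green **C1 = R − G** and blue/yellow
**C2 = (R + G) − B** (negative terms realized as GABA synapses). The
channels project topographically onto V1 layers 4, 2/3 and 5 — the
koniocellular C2 pathway bypasses L4 — built from single-compartment
Hodgkin–Huxley neurons with conductance synapses (AMPA τ = 5 ms,
GABA τ = 10 ms), 1 ms excitatory / 4 ms inhibitory transmission delays and
Mexican-hat lateral connectivity. Feed-forward weights are learned with
pair-based STDP,

    Δw = +LR·exp(−Δt/17 ms)   for Δt = t_post − t_pre > 0
    Δw = −LR·exp(+Δt/34 ms)   for Δt < 0,

under layer-wide mean normalization to mid-range after every 300 ms
iteration. The analysis suite implements the spatial clustering
coefficient of stimulus-evoked rates, single-cell stimulus information,
Bayesian multiple-cell (population) information, ON/OFF-cell and
color-opponent-cell selection, and two executable "toy" opponent
microcircuits that isolate the proposed delay-based OFF mechanism.

Who it is for: computational neuroscientists studying self-organizing
cortical maps, spike-timing plasticity, and color opponency, who want a
compact, fully scripted, deterministic re-implementation they can train
and probe at desk scale.

## Worked example

Build the desk-scale network, train it briefly with STDP, and look at the
weights and the trained responses:

```r
library(colorspike)
cfg <- preset("desk_small", network_seed = 1, input_seed = 101, noise_seed = 201)
net <- buildNetwork(cfg)
net
#> NetworkModel: 675 cells in 9 layers
#>   layers: R(5x5) G(5x5) B(5x5) L(10x10) C1(10x10) C2(10x10) V1L4(10x10) V1L23(10x10) V1L5(10x10)
#>   synapses: 9493 (3920 plastic, 5573 fixed)
#>   projections: R->L, G->L, R->C1, G->C1, R->C2, G->C2, B->C2, L->V1L4, C1->V1L4,
#>     C2->V1L23, V1L4->V1L23, V1L23->V1L5, V1L4 lateral, V1L23 lateral, V1L5 lateral
#>   input delays: randomized

fit <- trainNetwork(net, n_iterations = 40, trace = FALSE)
weightBimodality(fit$weights_final, cfg$w_min, cfg$w_max)$near_bound_fraction
#> near-bound weight fraction after 40 iterations: 0.42 (started at 0.22)

set.seed(301)
rt <- testColors(fit$network, n_transforms = 4)   # 8 RGB-cube corners
clusteringCoefficient(rt, layer = "V1L5", normalize = "none")$C
#> V1 L5 clustering coefficient (raw rates): 75.2
max(singleCellInfo(rt, layer = "V1L5")$max_info)
#> best single-cell information: 3.00 bits (ceiling 3)
multipleCellInfo(rt, max_cells = 10, layer = "V1L5")$info
#> 0.95 1.20 1.22 1.51 1.56 1.60 1.62 1.62 1.63 1.62
```

The near-bound fraction climbing from ~0.2 (uniform initialization) toward
1 is the weight binarization that accompanies training; the information
curve shows how many ranked cells a Bayesian decoder needs to identify
which of the eight test colors was shown (3 bits = perfect). The full
replicate study — STDP vs the order-blind Hebbian control vs the
no-input-delay ablation, three seeds, with ON/OFF and opponent-cell
searches — is one call: `runDeskStudy()`. Figure-by-figure recipes live in
`figureRecipes()`, and `vignette("colorspike-methods")` documents the
model, parameters and design choices.

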