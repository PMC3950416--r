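## Executable simplified opponent ON/OFF microcircuits. Both circuits use
## the same neuron and synapse models as the full network; the starred
## "delayed" edges of the schematics are implemented as an extra
## transmission delay (delayed_ms) so that an input's trailing spikes
## outlast stimulus removal. Weights and input phases are hand-tuned
## fixture constants (the schematics fix only signs and topology); see
## inst/scripts/tune_toycircuits.R for how the defaults were derived.

#' Default toy-circuit parameters
#'
#' @param w_in input -> LGN excitatory weight, uS.
#' @param w_in_inh input -> LGN inhibitory weight, uS (twice the
#'   excitatory weight so an opponent cell's inhibitory channel can veto
#'   its excitatory drive).
#' @param w_ff relay excitatory weight, uS.
#' @param w_ff_target weight of the edges that must drive the target
#'   against lateral inhibition (C1 -> target, N1 -> target), uS.
#' @param w_nb neighbor-cell inhibitory weight, uS.
#' @param delayed_ms extra delay of the starred edges, ms. The offset
#'   must exceed one interspike interval of the source at the tested
#'   drive rates for the trailing spikes to outlast stimulus removal; the
#'   default (75 ms, about 1.5 intervals at the ~20 Hz opponent-channel
#'   rates) places two trailing deliveries inside the OFF window. The
#'   ceiling-rate worked example corresponds to about 24 ms.
#' @param onset input phase offsets (ms) for the R, G, B input cells.
#' @param membrane,ampa,gaba model parameters.
#' @param noise_frac input rate noise.
#' @param dt integration step, ms.
#' @return named list.
#' @export
toyParams <- function(w_in = 0.006, w_in_inh = 0.04, w_ff = 0.006,
                      w_ff_target = 0.02, w_nb = 0.06, delayed_ms = 75,
                      onset = c(R = 5, G = 23, B = 0),
                      membrane = membraneParams(),
                      ampa = synapseParams("ampa"), gaba = synapseParams("gaba"),
                      noise_frac = 0.1, dt = 0.025) {
  list(w_in = w_in, w_in_inh = w_in_inh, w_ff = w_ff,
       w_ff_target = w_ff_target, w_nb = w_nb,
       delayed_ms = delayed_ms, onset = onset, membrane = membrane,
       ampa = ampa, gaba = gaba, noise_frac = noise_frac, dt = dt)
}

.toy_circuit <- function(cells, edges, target, label, params) {
  new("ToyCircuit",
      cells = data.frame(name = cells$name, kind = cells$kind,
                         channel = cells$channel, stringsAsFactors = FALSE),
      synapses = edges, target = target, label = label, params = params)
}

.toy_edge <- function(src, tgt, weight, kind, delayed = FALSE) {
  data.frame(src = src, tgt = tgt, weight = weight, kind = kind,
             delayed = delayed, stringsAsFactors = FALSE)
}

#' Build the red-ON/green-OFF microcircuit
#'
#' Three photoreceptor inputs (R, G, B), three LGN cells -- C1 (red/green
#' opponent, excited by R and inhibited by G), L1 and L2 (luminance,
#' R + G) -- and two output cells: the scored R_ON/G_OFF target (excited
#' by C1 and L1) and its neighbor N (excited by L2), which inhibits the
#' target. L1's green input is the starred delayed edge: after green is
#' removed, L1 keeps receiving its trailing green spikes while L2 (and
#' hence N's inhibition) stops, releasing the target.
#'
#' @param params [toyParams()].
#' @return a [ToyCircuit-class].
#' @export
buildRGCircuit <- function(params = toyParams()) {
  cells <- data.frame(
    name = c("R", "G", "B", "C1", "L1", "L2", "N", "target"),
    kind = c("input", "input", "input", rep("hh", 5)),
    channel = c("L", "M", "S", rep(NA, 5)))
  p <- params
  edges <- rbind(
    .toy_edge("R", "C1", p$w_in, "ampa"),
    .toy_edge("G", "C1", p$w_in_inh, "gaba"),
    .toy_edge("R", "L1", p$w_in, "ampa"),
    .toy_edge("G", "L1", p$w_in, "ampa", delayed = TRUE),
    .toy_edge("R", "L2", p$w_in, "ampa"),
    .toy_edge("G", "L2", p$w_in, "ampa"),
    .toy_edge("C1", "target", p$w_ff_target, "ampa"),
    .toy_edge("L1", "target", p$w_ff, "ampa"),
    .toy_edge("L2", "N", p$w_ff, "ampa"),
    .toy_edge("N", "target", p$w_nb, "gaba"))
  .toy_circuit(cells, edges, "target", "R_ON/G_OFF", p)
}

#' Build the yellow-ON/blue-OFF microcircuit
#'
#' Three photoreceptor inputs and three blue/yellow opponent LGN cells
#' C2_1..C2_3, each excited by R and G and inhibited by B; C2_2's R and G
#' edges are delayed, C2_3's R, G *and* B edges are delayed. Three output
#' cells: the scored Y_ON/B_OFF target (excited by C2_1), N1 (excited by
#' C2_2, excites the target) and N2 (excited by C2_3, inhibits N1). After
#' blue is removed, C2_2 loses its (undelayed) blue inhibition while its
#' delayed excitation trails on, driving the target via N1; C2_3's blue
#' inhibition is itself delayed, keeping N2 silent through the OFF window.
#'
#' @param params [toyParams()].
#' @return a [ToyCircuit-class].
#' @export
buildYBCircuit <- function(params = toyParams()) {
  cells <- data.frame(
    name = c("R", "G", "B", "C2_1", "C2_2", "C2_3", "N1", "N2", "target"),
    kind = c("input", "input", "input", rep("hh", 6)),
    channel = c("L", "M", "S", rep(NA, 6)))
  p <- params
  edges <- rbind(
    .toy_edge("R", "C2_1", p$w_in, "ampa"),
    .toy_edge("G", "C2_1", p$w_in, "ampa"),
    .toy_edge("B", "C2_1", p$w_in_inh, "gaba"),
    .toy_edge("R", "C2_2", p$w_in, "ampa", delayed = TRUE),
    .toy_edge("G", "C2_2", p$w_in, "ampa", delayed = TRUE),
    .toy_edge("B", "C2_2", p$w_in_inh, "gaba"),
    .toy_edge("R", "C2_3", p$w_in, "ampa", delayed = TRUE),
    .toy_edge("G", "C2_3", p$w_in, "ampa", delayed = TRUE),
    .toy_edge("B", "C2_3", p$w_in_inh, "gaba", delayed = TRUE),
    .toy_edge("C2_1", "target", p$w_ff, "ampa"),
    .toy_edge("C2_2", "N1", p$w_ff, "ampa"),
    .toy_edge("C2_3", "N2", p$w_ff, "ampa"),
    .toy_edge("N2", "N1", p$w_nb, "gaba"),
    .toy_edge("N1", "target", p$w_ff_target, "ampa"))
  .toy_circuit(cells, edges, "target", "Y_ON/B_OFF", p)
}

## adapter: express a toy circuit as a NetworkModel so the compiled engine
## and the stimulus front end can run it (every cell is its own 1x1 layer)
.toy_network <- function(circuit) {
  cl <- circuit@cells
  p <- circuit@params
  layers <- data.frame(name = cl$name, rows = 1L, cols = 1L, kind = cl$kind,
                       offset = seq_len(nrow(cl)) - 1L, stringsAsFactors = FALSE)
  idx <- setNames(layers$offset, layers$name)
  e <- circuit@synapses
  base <- ifelse(e$kind == "ampa", 1, 4)
  syn <- data.frame(src = idx[e$src], tgt = idx[e$tgt], weight = e$weight,
                    delay = base + ifelse(e$delayed, p$delayed_ms, 0),
                    kind = e$kind, plastic = FALSE,
                    projection = paste0(e$src, "->", e$tgt))
  onset <- p$onset[c("R", "G", "B")]
  cfg <- runConfig(pr_rows = 1, pr_cols = 1, lgn_rows = 1, lgn_cols = 1,
                   v1_rows = 1, v1_cols = 1, dt = p$dt,
                   noise_frac = p$noise_frac, membrane = p$membrane,
                   ampa = p$ampa, gaba = p$gaba)
  new("NetworkModel", layers = layers, synapses = syn,
      membrane = p$membrane, synParams = list(ampa = p$ampa, gaba = p$gaba),
      inputDelays = as.numeric(onset), config = cfg)
}

#' Run a toy circuit through the ON/OFF protocol
#'
#' Presents a full-field color for `on_ms` (each input cell driven by its
#' cone channel of the color at the 40 Hz ceiling, with phase-preserving
#' per-spike jitter and its fixture phase offset) followed by `off_ms` of
#' silence, and returns the raster of every named cell.
#'
#' @param circuit a [ToyCircuit-class].
#' @param color RGB triple in `[0, 1]^3`.
#' @param on_ms,off_ms stimulation and silence durations, ms.
#' @return a [SpikeRaster-class] whose `layer` column holds the cell
#'   names; metadata records the color and window bounds.
#' @examples
#' set.seed(1)
#' r <- runToy(buildRGCircuit(), c(1, 0, 0))
#' nrow(spikes(r, layer = "target", window = c(0, 60)))
#' @export
runToy <- function(circuit, color, on_ms = 240, off_ms = 60) {
  stopifnot(length(color) == 3, all(color >= 0 & color <= 1))
  net <- .toy_network(circuit)
  p <- circuit@params
  drive <- rgbToConeRates(colorPatch(color, c(1, 1)))
  ins <- generateInputSpikes(net, drive, on_ms, p$noise_frac, mode = "jitter")
  sim <- .cs_simulate(net, ins, on_ms + off_ms, p$dt)
  new("SpikeRaster", events = sim$events, duration = on_ms + off_ms,
      metadata = list(stimulus = paste(color, collapse = ","),
                      on_ms = on_ms, off_ms = off_ms, label = circuit@label))
}

#' Score a toy circuit's ON/OFF contrast
#'
#' Runs the circuit on two colors and counts the target cell's spikes in
#' the ON window (first `win_ms` of stimulation) and the OFF window (the
#' `win_ms` after removal).
#'
#' Window counts are averaged over `n_reps` repetitions (fresh input
#' noise each time, same circuit), the usual peristimulus averaging: a
#' single 60 ms window holds only one or two spikes at the toy's drive
#' rates, so single-trial counts are too quantized to compare.
#'
#' @param circuit a [ToyCircuit-class].
#' @param color_on color expected to drive the ON response.
#' @param color_off color expected to drive the OFF response.
#' @param win_ms scoring window, ms.
#' @param on_ms,off_ms protocol durations.
#' @param n_reps repetitions averaged per color (default 5).
#' @return data.frame with one row per color: `on_count`, `off_count`
#'   (mean spikes per window over repetitions).
#' @export
toyContrast <- function(circuit, color_on, color_off, win_ms = 60,
                        on_ms = 240, off_ms = 60, n_reps = 5) {
  score <- function(color) {
    on <- off <- 0
    for (i in seq_len(n_reps)) {
      r <- runToy(circuit, color, on_ms, off_ms)
      on <- on + nrow(spikes(r, layer = circuit@target, window = c(0, win_ms)))
      off <- off + nrow(spikes(r, layer = circuit@target,
                               window = c(on_ms, on_ms + win_ms)))
    }
    data.frame(on_count = on / n_reps, off_count = off / n_reps)
  }
  out <- rbind(score(color_on), score(color_off))
  out$color <- c(paste(color_on, collapse = ","), paste(color_off, collapse = ","))
  out
}
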