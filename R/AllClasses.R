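#' @import methods
#' @importFrom stats runif rnorm rexp setNames approx uniroot sd dnorm quantile
#' @importFrom utils head tail write.table read.table
NULL

#' Network model of the early color-vision pathway
#'
#' Holds the nine layer grids (photoreceptors R/G/B, LGN L/C1/C2, V1 L4,
#' L2/3, L5), the full synapse table, the shared membrane/synapse parameter
#' sets, per-input-cell onset delays and the run configuration the network
#' was built from. Cells are numbered globally, 0-based and row-major within
#' each layer. Construct with [buildNetwork()], not with `new()`.
#'
#' @slot layers data.frame with one row per layer: `name`, `rows`, `cols`,
#'   `kind` (`"input"` or `"hh"`) and `offset`, the global id of the layer's
#'   first cell.
#' @slot synapses data.frame with columns `src`, `tgt` (global 0-based ids),
#'   `weight` (uS), `delay` (ms), `kind` (`"ampa"`/`"gaba"`), `plastic`
#'   (logical) and `projection` (character label).
#' @slot membrane membrane parameter list, see [membraneParams()].
#' @slot synParams list with `ampa` and `gaba` entries, see [synapseParams()].
#' @slot inputDelays numeric vector, one onset delay (ms) per photoreceptor
#'   cell, drawn once at construction (all zero when input delays are
#'   disabled).
#' @slot config the run configuration list the network was built from.
#'
#' @seealso [buildNetwork()], [runTrial()], [trainNetwork()]
#' @export
setClass("NetworkModel",
  representation(layers = "data.frame", synapses = "data.frame",
                 membrane = "list", synParams = "list",
                 inputDelays = "numeric", config = "list"))

setValidity("NetworkModel", function(object) {
  ly <- object@layers
  sy <- object@synapses
  msg <- character()
  need <- c("name", "rows", "cols", "kind", "offset")
  if (!all(need %in% names(ly))) msg <- c(msg, "layers is missing columns")
  if (any(ly$rows <= 0) || any(ly$cols <= 0)) msg <- c(msg, "layer dims must be positive")
  n <- sum(ly$rows * ly$cols)
  if (nrow(sy)) {
    if (any(sy$src < 0 | sy$src >= n | sy$tgt < 0 | sy$tgt >= n))
      msg <- c(msg, "synapse endpoints out of range")
    if (any(sy$weight < 0)) msg <- c(msg, "weights must be non-negative")
    if (any(sy$delay <= 0)) msg <- c(msg, "delays must be positive")
    if (!all(sy$kind %in% c("ampa", "gaba"))) msg <- c(msg, "unknown synapse kind")
  }
  if (length(msg)) msg else TRUE
})

#' Spike raster
#'
#' All spike events of one simulated trial: the universal analysis input.
#'
#' @slot events data.frame with columns `layer`, `cell` (global id), `row`,
#'   `col` (0-based grid coordinates) and `time` (ms), sorted by time.
#' @slot duration trial duration in ms.
#' @slot metadata list of trial annotations (stimulus label, transform
#'   index, on/off window bounds, ...).
#'
#' @seealso [runTrial()], [onOffProtocol()], [selectOnOffCells()]
#' @export
setClass("SpikeRaster",
  representation(events = "data.frame", duration = "numeric", metadata = "list"))

setValidity("SpikeRaster", function(object) {
  ev <- object@events
  msg <- character()
  if (!all(c("layer", "cell", "row", "col", "time") %in% names(ev)))
    msg <- c(msg, "events is missing columns")
  if (nrow(ev)) {
    if (any(ev$time < 0) || any(ev$time > object@duration + 1e-9))
      msg <- c(msg, "spike times outside [0, duration]")
    if (is.unsorted(ev$time)) msg <- c(msg, "events must be sorted by time")
  }
  if (length(msg)) msg else TRUE
})

#' Mean firing rates per cell and stimulus presentation
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] with
#' one assay `"rate"` (Hz): rows are cells (rowData: `layer`, `row`, `col`,
#' `cell`), columns are presentations (colData: `stimulus`, `transform`).
#' This is the input to every rate-based statistic
#' ([clusteringCoefficient()], [singleCellInfo()], [multipleCellInfo()]).
#'
#' @seealso [testColors()], [rateTable()]
#' @export
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
setClass("RateTable", contains = "SummarizedExperiment")

setValidity("RateTable", function(object) {
  msg <- character()
  if (!"rate" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "missing 'rate' assay")
  else if (any(SummarizedExperiment::assay(object, "rate") < 0))
    msg <- c(msg, "rates must be non-negative")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("stimulus", "transform") %in% names(cd)))
    msg <- c(msg, "colData needs 'stimulus' and 'transform'")
  if (length(msg)) msg else TRUE
})

#' Simplified opponent ON/OFF microcircuit
#'
#' A handful of named cells wired with signed, delayed edges; the
#' executable counterpart of the red-ON/green-OFF and yellow-ON/blue-OFF
#' schematics. Construct with [buildRGCircuit()] or [buildYBCircuit()].
#'
#' @slot cells data.frame: `name`, `kind` (`"input"`/`"hh"`), `channel`
#'   (for input cells: which cone drive feeds it, `NA` otherwise).
#' @slot synapses data.frame: `src`, `tgt` (cell names), `weight` (uS),
#'   `delay` (ms), `kind` (`"ampa"`/`"gaba"`), `delayed` (logical flag for
#'   the starred phase-offset edges).
#' @slot target name of the scored output cell.
#' @slot label circuit label, `"R_ON/G_OFF"` or `"Y_ON/B_OFF"`.
#' @slot params list of membrane/synapse parameters and the phase-offset
#'   magnitude `delayed_ms`.
#' @export
setClass("ToyCircuit",
  representation(cells = "data.frame", synapses = "data.frame",
                 target = "character", label = "character", params = "list"))

setValidity("ToyCircuit", function(object) {
  msg <- character()
  if (!object@target %in% object@cells$name) msg <- c(msg, "target cell not present")
  if (!all(object@synapses$src %in% object@cells$name) ||
      !all(object@synapses$tgt %in% object@cells$name))
    msg <- c(msg, "synapse endpoints must be named cells")
  if (length(msg)) msg else TRUE
})
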