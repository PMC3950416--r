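#' @rdname nCells
#' @export
setGeneric("nCells", function(object, ...) standardGeneric("nCells"))

#' @rdname synapses
#' @export
setGeneric("synapses", function(object, ...) standardGeneric("synapses"))

#' @rdname layerNames
#' @export
setGeneric("layerNames", function(object) standardGeneric("layerNames"))

#' @rdname spikes
#' @export
setGeneric("spikes", function(object, ...) standardGeneric("spikes"))

#' @rdname rates
#' @export
setGeneric("rates", function(object, ...) standardGeneric("rates"))

#' Number of cells
#'
#' Total cell count of a network (or one layer of it).
#'
#' @param object a [NetworkModel-class]
#' @param layer optional layer name; if given, only that layer is counted.
#' @param ... unused.
#' @return integer cell count.
#' @rdname nCells
#' @export
setMethod("nCells", "NetworkModel", function(object, layer = NULL, ...) {
  ly <- object@layers
  if (!is.null(layer)) ly <- ly[ly$name %in% layer, , drop = FALSE]
  as.integer(sum(ly$rows * ly$cols))
})

#' Synapse table
#'
#' The full edge table of a network, optionally restricted to one named
#' projection.
#'
#' @param object a [NetworkModel-class]
#' @param projection optional projection label, e.g. `"C2->V1L23"`.
#' @param ... unused.
#' @return data.frame of synapses (see [NetworkModel-class]).
#' @rdname synapses
#' @export
setMethod("synapses", "NetworkModel", function(object, projection = NULL, ...) {
  sy <- object@synapses
  if (!is.null(projection)) sy <- sy[sy$projection %in% projection, , drop = FALSE]
  sy
})

#' Layer names
#' @param object a [NetworkModel-class]
#' @return character vector of layer names in hierarchical order.
#' @rdname layerNames
#' @export
setMethod("layerNames", "NetworkModel", function(object) object@layers$name)

#' Spike events
#' @param object a [SpikeRaster-class]
#' @param layer optional layer name filter.
#' @param window optional `c(from, to)` ms window filter.
#' @param ... unused.
#' @return data.frame of spike events.
#' @rdname spikes
#' @export
setMethod("spikes", "SpikeRaster", function(object, layer = NULL, window = NULL, ...) {
  ev <- object@events
  if (!is.null(layer)) ev <- ev[ev$layer %in% layer, , drop = FALSE]
  if (!is.null(window)) ev <- ev[ev$time >= window[1] & ev$time < window[2], , drop = FALSE]
  ev
})

#' Rate matrix
#' @param object a [RateTable-class]
#' @param layer optional layer name filter (rows).
#' @param ... unused.
#' @return numeric matrix of rates in Hz, cells x presentations.
#' @rdname rates
#' @export
setMethod("rates", "RateTable", function(object, layer = NULL, ...) {
  x <- SummarizedExperiment::assay(object, "rate")
  if (!is.null(layer)) {
    keep <- SummarizedExperiment::rowData(object)$layer %in% layer
    x <- x[keep, , drop = FALSE]
  }
  x
})

setMethod("show", "NetworkModel", function(object) {
  ly <- object@layers
  cat("NetworkModel:", sum(ly$rows * ly$cols), "cells in", nrow(ly), "layers\n")
  cat("  layers:", paste(sprintf("%s(%dx%d)", ly$name, ly$rows, ly$cols),
                         collapse = " "), "\n")
  sy <- object@synapses
  cat("  synapses:", nrow(sy),
      sprintf("(%d plastic, %d fixed)", sum(sy$plastic), sum(!sy$plastic)), "\n")
  cat("  projections:", paste(unique(sy$projection), collapse = ", "), "\n")
  cat("  input delays:", if (any(object@inputDelays > 0)) "randomized" else "off", "\n")
})

setMethod("show", "SpikeRaster", function(object) {
  cat("SpikeRaster:", nrow(object@events), "spikes over", object@duration, "ms\n")
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
  if (nrow(object@events)) {
    tab <- table(object@events$layer)
    cat("  per layer:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                              collapse = " "), "\n")
  }
})

setMethod("show", "ToyCircuit", function(object) {
  cat("ToyCircuit", object@label, "with", nrow(object@cells), "cells and",
      nrow(object@synapses), "edges; target:", object@target, "\n")
})
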