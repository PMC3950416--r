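## File interfaces: YAML run configurations, TSV spike rasters with a JSON
## metadata sidecar, JSON weight snapshots.

#' Write / read a run configuration
#'
#' Round-trips a [runConfig()] through YAML. Nested parameter lists
#' (membrane, synapses) are preserved.
#'
#' @param config a [runConfig()].
#' @param path file path.
#' @return `readRunConfig` returns a [runConfig()] list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("membrane", "ampa", "gaba"))
    if (!is.null(raw[[f]])) raw[[f]] <- as.list(raw[[f]])
  do.call(runConfig, raw[setdiff(names(raw), "lr_default")])
}

#' Write / read a spike raster
#'
#' The raster goes to a tab-separated file with columns
#' `layer cell_row cell_col time_ms` (plus the global `cell` id); trial
#' metadata goes to a JSON sidecar `<path>.meta.json`.
#'
#' @param raster a [SpikeRaster-class].
#' @param path file path (e.g. `raster.tsv`).
#' @return `readSpikeRaster` returns a [SpikeRaster-class].
#' @export
writeSpikeRaster <- function(raster, path) {
  ev <- raster@events
  out <- data.frame(layer = ev$layer, cell_row = ev$row, cell_col = ev$col,
                    time_ms = ev$time, cell = ev$cell)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(raster@metadata, list(duration = raster@duration))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeSpikeRaster
#' @export
readSpikeRaster <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  dur <- as.numeric(meta$duration)
  meta$duration <- NULL
  ev <- data.frame(layer = tab$layer, cell = tab$cell, row = tab$cell_row,
                   col = tab$cell_col, time = tab$time_ms)
  ev <- ev[order(ev$time, ev$cell), ]
  rownames(ev) <- NULL
  new("SpikeRaster", events = ev, duration = dur, metadata = as.list(meta))
}

#' Write / read a weight snapshot
#'
#' Stores the plastic weights of a network per projection as JSON.
#'
#' @param net a [NetworkModel-class].
#' @param path file path.
#' @return `readWeightSnapshot` returns a named list of numeric vectors.
#' @export
writeWeightSnapshot <- function(net, path) {
  sy <- net@synapses[net@synapses$plastic, ]
  snap <- split(sy$weight, sy$projection)
  jsonlite::write_json(snap, path, digits = NA)
  invisible(path)
}

#' @rdname writeWeightSnapshot
#' @export
readWeightSnapshot <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
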