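## Shared fixtures. The desk-scale preset pipeline run is expensive (~20 s),
## so it is computed once per session and reused across test files.

.fixtures <- new.env(parent = emptyenv())

presetSim <- function(seed = 1L) {
  key <- paste0("sim", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- simulateWaxDataset(seed = seed)
  .fixtures[[key]]
}

presetConfig <- function() pipelineConfig(fitTarget = 0.8)

presetRun <- function(seed = 1L) {
  key <- paste0("run", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- suppressWarnings(
      runWaxPipeline(presetSim(seed), presetConfig()))
  .fixtures[[key]]
}

## planted module index that a detected module color corresponds to
## (majority vote over the planted partition)
plantedModuleOf <- function(run, sim, color) {
  lab <- moduleLabels(run$assignment)
  part <- truthModulePartition(sim$truth, names(lab))
  genes <- names(lab)[lab == match(color, moduleColors(run$assignment))]
  as.integer(names(which.max(table(part[genes]))))
}

## adjusted Rand index of the detected partition against the planted one
presetARI <- function(run, sim) {
  part <- truthModulePartition(sim$truth, rownames(run$expression))
  mclust::adjustedRandIndex(part, moduleLabels(run$assignment))
}

## build a WeightedNetwork from vectors (wraps the package's canonical form
## via the Cytoscape round trip to avoid reaching into internals)
makeNet <- function(from, to, weight, nodes = sort(unique(c(from, to))),
                    module = "") {
  ef <- tempfile(fileext = ".tsv")
  nf <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(ef, nf)))
  df <- data.frame(fromNode = from, toNode = to,
                   weight = sprintf("%.17g", weight),
                   direction = rep("undirected", length(from)),
                   fromAltName = rep("NA", length(from)),
                   toAltName = rep("NA", length(from)))
  utils::write.table(df, ef, sep = "\t", quote = FALSE, row.names = FALSE)
  readCytoscapeEdges(ef, nodes = nodes, module = module)
}
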