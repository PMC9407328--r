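#' @rdname SoftThresholdScan-class
#' @param object,x a \linkS4class{SoftThresholdScan}, \linkS4class{ModuleAssignment}
#'   or \linkS4class{WeightedNetwork} object, as appropriate.
#' @export
setGeneric("chosenPower", function(object) standardGeneric("chosenPower"))

#' @rdname SoftThresholdScan-class
#' @export
setGeneric("scanTable", function(object) standardGeneric("scanTable"))

#' @rdname ModuleAssignment-class
#' @export
setGeneric("moduleLabels", function(object) standardGeneric("moduleLabels"))

#' @rdname ModuleAssignment-class
#' @export
setGeneric("moduleColors", function(object) standardGeneric("moduleColors"))

#' @rdname ModuleAssignment-class
#' @export
setGeneric("moduleSizes", function(object) standardGeneric("moduleSizes"))

#' @rdname ModuleAssignment-class
#' @export
setGeneric("geneColors", function(object) standardGeneric("geneColors"))

#' @rdname WeightedNetwork-class
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))

#' @rdname WeightedNetwork-class
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @rdname HubReport-class
#' @param object a \linkS4class{HubReport}.
#' @export
setGeneric("hubGenes", function(object) standardGeneric("hubGenes"))

#' @rdname SoftThresholdScan-class
#' @export
setMethod("chosenPower", "SoftThresholdScan", function(object) object@power)

#' @rdname SoftThresholdScan-class
#' @export
setMethod("scanTable", "SoftThresholdScan", function(object) object@scan)

#' @rdname ModuleAssignment-class
#' @export
setMethod("moduleLabels", "ModuleAssignment", function(object) object@labels)

#' @rdname ModuleAssignment-class
#' @export
setMethod("moduleColors", "ModuleAssignment", function(object) object@colors)

#' @rdname ModuleAssignment-class
#' @export
setMethod("moduleSizes", "ModuleAssignment", function(object) {
  stats::setNames(object@sizes, object@colors)
})

#' Per-gene module colors
#'
#' @return `geneColors()` returns a character vector, one color per gene,
#'   with `"grey"` for unassigned genes.
#' @rdname ModuleAssignment-class
#' @export
setMethod("geneColors", "ModuleAssignment", function(object) {
  cols <- c("grey", object@colors)
  stats::setNames(cols[object@labels + 1L], names(object@labels))
})

#' @rdname WeightedNetwork-class
#' @export
setMethod("networkNodes", "WeightedNetwork", function(object) object@nodes)

#' @rdname WeightedNetwork-class
#' @export
setMethod("networkEdges", "WeightedNetwork", function(object) object@edges)

#' @rdname HubReport-class
#' @export
setMethod("hubGenes", "HubReport", function(object) object@hubs)

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport\n")
  cat(sprintf("  input genes        : %d\n", object@nInputGenes))
  cat(sprintf("  all-zero removed   : %d\n", object@nZeroRemoved))
  cat(sprintf("  after zero removal : %d\n", object@nAfterZero))
  cat(sprintf("  retained by MAD    : %d (top %.0f%%, MAD > %g)\n",
              object@nRetainedMad, 100 * object@madFraction, object@madFloor))
})

setMethod("show", "SoftThresholdScan", function(object) {
  cat(sprintf("SoftThresholdScan over %d powers\n", nrow(object@scan)))
  cat(sprintf("  chosen power: %d (fit target %.2f, %s)\n", object@power,
              object@fitTarget,
              if (object@reachedTarget) "target reached"
              else "target not reached; best fit used"))
  best <- object@scan[object@scan$power == object@power, ]
  cat(sprintf("  fit at chosen power: %.3f, mean connectivity: %.2f\n",
              best$fit, best$meanK))
})

setMethod("show", "ModuleAssignment", function(object) {
  m <- length(object@sizes)
  cat(sprintf("ModuleAssignment: %d genes, %d modules, %d unassigned (grey)\n",
              length(object@labels), m, sum(object@labels == 0L)))
  if (m) {
    sz <- utils::head(stats::setNames(object@sizes, object@colors), 10L)
    cat("  sizes:", paste(sprintf("%s=%d", names(sz), sz), collapse = ", "),
        if (m > 10L) "..." else "", "\n")
  }
})

setMethod("show", "WeightedNetwork", function(object) {
  cat(sprintf("WeightedNetwork%s: %d nodes, %d edges\n",
              if (nzchar(object@module)) sprintf(" [%s]", object@module) else "",
              length(object@nodes), nrow(object@edges)))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(
    "SyntheticTruth: %d genes, %d modules, %d background, seed %d\n",
    length(object@moduleOfGene), nrow(object@factor),
    sum(object@moduleOfGene == 0L), object@seed))
  if (length(object@outlierSampleIds))
    cat("  planted outlier:", paste(object@outlierSampleIds, collapse = ", "), "\n")
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  for (sl in slotNames(object)) {
    v <- slot(object, sl)
    v <- if (length(v) > 6) paste0(paste(utils::head(v, 6), collapse = ","), ",...")
         else paste(v, collapse = ",")
    cat(sprintf("  %-16s %s\n", sl, v))
  }
})

setMethod("show", "HubReport", function(object) {
  mods <- unique(object@hubs$module)
  cat(sprintf("HubReport: %d hub genes in %d module(s) (top %.0f%%)\n",
              nrow(object@hubs), length(mods), 100 * object@hubFraction))
  for (m in mods) {
    h <- object@hubs[object@hubs$module == m, ]
    cat(sprintf("  %s: %s%s\n", m,
                paste(utils::head(h$gene, 5), collapse = ", "),
                if (nrow(h) > 5) ", ..." else ""))
  }
})
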