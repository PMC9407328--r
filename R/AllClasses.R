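#' @import methods
NULL

#' Gene filtering report
#'
#' Bookkeeping for the expression-cleaning stage: how many genes entered,
#' how many all-zero rows were dropped, and how many genes survived the
#' median-absolute-deviation (MAD) filter. The class validity enforces the
#' conservation identities, so a report can be trusted arithmetically.
#'
#' @slot nInputGenes number of genes in the raw table.
#' @slot nZeroRemoved all-zero rows removed.
#' @slot nAfterZero genes remaining after zero-row removal.
#' @slot nRetainedMad genes surviving the MAD filter.
#' @slot madFraction fraction of genes (ranked by MAD, descending) eligible
#'   for retention.
#' @slot madFloor minimum MAD a retained gene must exceed.
#'
#' @examples
#' sim <- simulateWaxDataset(seed = 1)
#' res <- removeZeroGenes(sim$expression)
#' madFilter(res$expression)$report
#' @export
setClass("FilterReport",
  representation(
    nInputGenes = "integer",
    nZeroRemoved = "integer",
    nAfterZero = "integer",
    nRetainedMad = "integer",
    madFraction = "numeric",
    madFloor = "numeric"
  )
)

setValidity("FilterReport", function(object) {
  msg <- character()
  if (object@nInputGenes != object@nZeroRemoved + object@nAfterZero)
    msg <- c(msg, "nInputGenes must equal nZeroRemoved + nAfterZero")
  if (object@nRetainedMad > object@nAfterZero)
    msg <- c(msg, "nRetainedMad cannot exceed nAfterZero")
  if (object@madFraction <= 0 || object@madFraction > 1)
    msg <- c(msg, "madFraction must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Soft-threshold scan result
#'
#' Scale-free topology fit and connectivity statistics over a grid of
#' candidate soft-thresholding powers, together with the chosen power.
#'
#' @slot scan data.frame with columns `power`, `fit` (signed scale-free fit
#'   index), `meanK`, `medianK`, `maxK`.
#' @slot power the selected soft-thresholding power.
#' @slot fitTarget the fit index the selection aimed for.
#' @slot reachedTarget whether any power reached the target.
#'
#' @seealso [pickSoftThreshold()]
#' @export
setClass("SoftThresholdScan",
  representation(
    scan = "data.frame",
    power = "integer",
    fitTarget = "numeric",
    reachedTarget = "logical"
  )
)

setValidity("SoftThresholdScan", function(object) {
  need <- c("power", "fit", "meanK", "medianK", "maxK")
  if (!all(need %in% names(object@scan)))
    return(sprintf("scan must have columns %s", paste(need, collapse = ", ")))
  if (any(abs(object@scan$fit) > 1 + 1e-8))
    return("signed fit index must lie in [-1, 1]")
  if (!object@power %in% object@scan$power)
    return("chosen power must appear in the scan grid")
  TRUE
})

#' Module assignment
#'
#' Gene-to-module labels after tree cutting (and optionally merging), with
#' module sizes and the canonical module color names. Label 0 is the
#' "grey" pool of unassigned genes; labels 1..M are numbered in decreasing
#' module size.
#'
#' @slot labels named integer vector, one entry per gene (0 = unassigned).
#' @slot colors character vector mapping label 1..M to a color name;
#'   label 0 is always "grey".
#' @slot sizes integer vector of module sizes (labels 1..M).
#'
#' @seealso [cutGeneTree()], [mergeCloseModules()], [assignModuleColors()]
#' @export
setClass("ModuleAssignment",
  representation(
    labels = "integer",
    colors = "character",
    sizes = "integer"
  )
)

setValidity("ModuleAssignment", function(object) {
  lab <- object@labels
  m <- length(object@colors)
  if (length(object@sizes) != m)
    return("colors and sizes must have one entry per module")
  if (length(lab) && max(lab) > m)
    return("labels refer to more modules than colors are defined for")
  if (any(lab < 0)) return("labels must be >= 0")
  if (m > 0) {
    tab <- tabulate(lab, nbins = m)
    if (!identical(as.integer(tab), object@sizes))
      return("sizes must tabulate the labels")
    if (is.unsorted(rev(object@sizes)))
      return("modules must be numbered in decreasing size")
  }
  if (is.null(names(lab))) return("labels must be named by gene ID")
  TRUE
})

#' Weighted undirected coexpression network
#'
#' Edge-list representation of an (intra-module) topological-overlap
#' network: node IDs, undirected weighted edges, and the module color the
#' network was extracted from. Edges are stored canonically with
#' `from < to` (lexicographic), so duplicates and self-loops are
#' structurally impossible and two networks with the same edges compare
#' identical.
#'
#' @slot nodes character vector of node (gene) IDs, including isolated nodes.
#' @slot edges data.frame with columns `from`, `to`, `weight`.
#' @slot module color tag of the source module ("" if not applicable).
#'
#' @seealso [moduleNetwork()], [writeCytoscapeNetwork()]
#' @export
setClass("WeightedNetwork",
  representation(
    nodes = "character",
    edges = "data.frame",
    module = "character"
  )
)

setValidity("WeightedNetwork", function(object) {
  e <- object@edges
  if (!all(c("from", "to", "weight") %in% names(e)))
    return("edges must have columns from, to, weight")
  if (anyDuplicated(object@nodes)) return("duplicate node IDs")
  if (nrow(e)) {
    if (any(e$from == e$to)) return("self-loops are not allowed")
    if (any(e$from > e$to)) return("edges must be stored with from < to")
    if (anyDuplicated(paste(e$from, e$to, sep = "\r"))) return("duplicate edges")
    if (any(!is.finite(e$weight)) || any(e$weight <= 0))
      return("edge weights must be finite and positive")
    if (!all(c(e$from, e$to) %in% object@nodes))
      return("edge endpoints must be listed in nodes")
  }
  TRUE
})

#' Ground truth of a simulated dataset
#'
#' Everything the generator planted: the module of each gene, factor
#' loadings, the condition-level latent factors, trait coefficients, the
#' outlier sample, the per-module hub genes, and the genes planted as
#' all-zero or near-constant rows.
#'
#' @slot moduleOfGene named integer vector (0 = background).
#' @slot loading named numeric vector of factor loadings, 0 for background.
#' @slot factor matrix (module x sample) of latent factor values.
#' @slot traitCoefficients numeric vector, one per module (0 for modules
#'   that do not drive the trait).
#' @slot outlierSampleIds character vector (empty if no outlier planted).
#' @slot plantedHubIds list of character vectors, one per module.
#' @slot zeroGeneIds genes planted as all-zero rows.
#' @slot lowMadGeneIds genes planted as near-constant rows.
#' @slot seed integer seed the dataset was generated from.
#'
#' @seealso [simulateWaxDataset()], [truthModulePartition()]
#' @export
setClass("SyntheticTruth",
  representation(
    moduleOfGene = "integer",
    loading = "numeric",
    factor = "matrix",
    traitCoefficients = "numeric",
    outlierSampleIds = "character",
    plantedHubIds = "list",
    zeroGeneIds = "character",
    lowMadGeneIds = "character",
    seed = "integer"
  )
)

setValidity("SyntheticTruth", function(object) {
  if (is.null(names(object@moduleOfGene))) return("moduleOfGene must be named")
  nm <- nrow(object@factor)
  if (length(object@traitCoefficients) != nm)
    return("one trait coefficient per module is required")
  if (length(object@plantedHubIds) != nm)
    return("one hub list per module is required")
  TRUE
})

#' Pipeline configuration
#'
#' All tunables of the pipeline in one validated object. Every field is
#' checked against its legal range at construction time, before any stage
#' runs, so a misconfigured run fails fast. See [pipelineConfig()] for the
#' fields, defaults and units.
#'
#' @seealso [pipelineConfig()], [readPipelineConfig()]
#' @export
setClass("PipelineConfig",
  representation(
    madFraction = "numeric",
    madFloor = "numeric",
    madScaleConstant = "numeric",
    cutHeight = "numeric",
    minClusterSize = "integer",
    powers = "integer",
    fitTarget = "numeric",
    networkSign = "character",
    minModuleSize = "integer",
    deepSplit = "integer",
    pamStage = "logical",
    mergeCutHeight = "numeric",
    moduleAlpha = "numeric",
    pAdjust = "character",
    exportThreshold = "numeric",
    topK = "integer",
    hubFraction = "numeric",
    maxGenes = "integer",
    seed = "integer"
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  chk <- function(ok, what) if (!ok) msg <<- c(msg, what)
  chk(object@madFraction > 0 && object@madFraction <= 1,
      "madFraction must be in (0, 1]")
  chk(object@madFloor >= 0, "madFloor must be >= 0")
  chk(object@madScaleConstant > 0, "madScaleConstant must be > 0")
  chk(is.na(object@cutHeight) || object@cutHeight > 0,
      "cutHeight must be > 0 (or NA for automatic)")
  chk(object@minClusterSize >= 1, "minClusterSize must be >= 1")
  chk(length(object@powers) >= 1 && all(object@powers >= 1) &&
        !is.unsorted(object@powers, strictly = TRUE),
      "powers must be an ascending vector of integers >= 1")
  chk(object@fitTarget >= 0 && object@fitTarget <= 1,
      "fitTarget must be in [0, 1]")
  chk(object@networkSign %in% c("unsigned", "signed"),
      "networkSign must be 'unsigned' or 'signed'")
  chk(object@minModuleSize >= 2, "minModuleSize must be >= 2")
  chk(object@deepSplit %in% 0:3, "deepSplit must be in 0..3")
  chk(object@mergeCutHeight >= 0 && object@mergeCutHeight < 1,
      "mergeCutHeight must be in [0, 1)")
  chk(object@moduleAlpha > 0 && object@moduleAlpha <= 1,
      "moduleAlpha must be in (0, 1]")
  chk(object@pAdjust %in% c("none", "BH"), "pAdjust must be 'none' or 'BH'")
  chk(object@exportThreshold >= 0 && object@exportThreshold < 1,
      "exportThreshold must be in [0, 1)")
  chk(object@topK >= 1, "topK must be >= 1")
  chk(object@hubFraction > 0 && object@hubFraction <= 1,
      "hubFraction must be in (0, 1]")
  chk(object@maxGenes >= 2, "maxGenes must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Hub screening report
#'
#' The outcome of the two-stage centrality screen: per significant module,
#' the ranked hub genes with their weighted degree and eigenvector
#' centralities and annotation, plus the degree-vs-eigenvector top-list
#' comparison.
#'
#' @slot hubs data.frame with columns `module`, `rank`, `gene`,
#'   `weightedDegree`, `eigenvector`, `dcRank`, `ecRank`, `description`.
#' @slot comparisons named list (per module) from [compareRankings()].
#' @slot hubFraction fraction of the screened subnetwork reported as hubs.
#'
#' @seealso [screenHubs()], [selectHubs()]
#' @export
setClass("HubReport",
  representation(
    hubs = "data.frame",
    comparisons = "list",
    hubFraction = "numeric"
  )
)
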