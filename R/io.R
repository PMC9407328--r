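## All tables are tab-separated, UTF-8, "." decimal, unquoted -- the plain-text
## dialect the study's supplementary tables use.

#' Read a gene expression table
#'
#' Reads a TSV/CSV table of FPKM values with one header row of IDs and one ID
#' column, and returns a genes-by-samples numeric matrix. On disk the
#' conventional orientation is genes in rows; tables stored samples-in-rows
#' are transposed on read so that downstream code always sees genes x samples.
#'
#' @param path path to the table.
#' @param orientation `"genes-in-rows"` (default) or `"samples-in-rows"`.
#' @param sep field separator; `"\t"` by default, use `","` for CSV.
#' @return numeric matrix, genes in rows, IDs preserved in file order.
#' @details Duplicate gene or sample IDs and non-numeric cells are rejected
#'   with an error naming the offending ID or cell. All values must be finite
#'   and non-negative (FPKM are normalized counts).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeExpression(matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3),
#'                                                   c("s1", "s2"))), f)
#' readExpression(f)
#' @export
readExpression <- function(path,
                           orientation = c("genes-in-rows", "samples-in-rows"),
                           sep = "\t") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          row.names = NULL, check.names = FALSE,
                          colClasses = "character", comment.char = "")
  if (ncol(df) < 2) stop("expression table needs an ID column and >= 1 value column")
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicate row ID in ", path, ": '", dup, "'")
  }
  colIds <- colnames(df)[-1]
  if (anyDuplicated(colIds)) {
    dup <- colIds[duplicated(colIds)][1]
    stop("duplicate column ID in ", path, ": '", dup, "'")
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at row '%s', column '%s' in %s: '%s'",
                 ids[bad[1, 1]], colIds[bad[1, 2]], path,
                 vals[bad[1, 1], bad[1, 2]]))
  }
  dimnames(num) <- list(ids, colIds)
  if (orientation == "samples-in-rows") num <- t(num)
  validateExpression(num)
  num
}

## shared invariant checks for an expression matrix
validateExpression <- function(x) {
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must have gene and sample IDs")
  if (anyDuplicated(rownames(x))) stop("duplicate gene IDs")
  if (anyDuplicated(colnames(x))) stop("duplicate sample IDs")
  if (any(!is.finite(x))) stop("expression values must all be finite")
  if (any(x < 0)) stop("expression values must be non-negative")
  invisible(x)
}

#' Write a gene expression table
#'
#' @param expr genes-by-samples numeric matrix with dimnames.
#' @param path output path.
#' @param idColumn name for the leading ID column.
#' @return `path`, invisibly.
#' @details Values are written with full precision (`format(..., digits = 17)`
#'   would lose trailing structure; `sprintf("%.17g")` is used) so that a
#'   write/read round trip reproduces the matrix bitwise.
#' @export
writeExpression <- function(expr, path, idColumn = "gene_id") {
  validateExpression(expr)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c(idColumn, colnames(expr)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(expr)), function(i) {
    paste(c(rownames(expr)[i], sprintf("%.17g", expr[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read / write the per-sample trait table
#'
#' The trait is the wax secretion of each sample, in mg per individual
#' insect. The file is a two-column TSV (`sample_id`, `wax_secretion`).
#'
#' @param path path to the table.
#' @return `readTrait()`: a named non-negative numeric vector.
#' @export
readTrait <- function(path) {
  if (!file.exists(path)) stop("trait file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, comment.char = "")
  if (ncol(df) < 2) stop("trait table needs sample_id and value columns")
  v <- suppressWarnings(as.numeric(df[[2]]))
  if (any(is.na(v))) stop("non-numeric trait value for sample '",
                          df[[1]][which(is.na(v))[1]], "'")
  names(v) <- as.character(df[[1]])
  validateTrait(v)
  v
}

validateTrait <- function(v) {
  if (anyDuplicated(names(v))) stop("duplicate sample IDs in trait table")
  if (any(!is.finite(v))) stop("trait values must be finite")
  if (any(v < 0)) stop("wax secretion must be non-negative (mg/individual)")
  invisible(v)
}

#' @rdname readTrait
#' @param trait named numeric vector of wax secretion values.
#' @export
writeTrait <- function(trait, path) {
  validateTrait(trait)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("sample_id\twax_secretion", con)
  writeLines(sprintf("%s\t%.17g", names(trait), trait), con)
  invisible(path)
}

#' Read / write the gene annotation table
#'
#' Maps gene IDs to Swiss-Prot accessions and free-text descriptions.
#' Genes absent from the table (or with an empty/NA accession) count as
#' unannotated.
#'
#' @param path path to the three-column TSV
#'   (`gene_id`, `swissprot_id`, `description`).
#' @return `readAnnotation()`: a data.frame with those three character columns.
#' @export
readAnnotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, comment.char = "",
                          colClasses = "character")
  if (ncol(df) < 3) stop("annotation table needs gene_id, swissprot_id, description")
  names(df)[1:3] <- c("gene_id", "swissprot_id", "description")
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene ID in annotation table: '",
         df$gene_id[duplicated(df$gene_id)][1], "'")
  df[df == ""] <- NA_character_
  df
}

#' @rdname readAnnotation
#' @param annotation annotation data.frame as returned by [readAnnotation()].
#' @export
writeAnnotation <- function(annotation, path) {
  utils::write.table(annotation[, c("gene_id", "swissprot_id", "description")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Assemble expression, trait and annotation into one experiment object
#'
#' Bundles the three input tables into a [SummarizedExperiment], the
#' Bioconductor container for matrix-shaped assays: the FPKM matrix becomes
#' the `"fpkm"` assay, the wax trait goes into `colData`, and the annotation
#' into `rowData`. Sample order follows the expression matrix; every
#' expression sample must have a trait value.
#'
#' @param expr genes-by-samples FPKM matrix.
#' @param trait named numeric vector (see [readTrait()]).
#' @param annotation optional annotation data.frame (see [readAnnotation()]).
#' @return a `SummarizedExperiment`.
#' @examples
#' sim <- simulateWaxDataset(seed = 1)
#' se <- coexDataset(sim$expression, sim$trait, sim$annotation)
#' se
#' @export
coexDataset <- function(expr, trait, annotation = NULL) {
  validateExpression(expr)
  validateTrait(trait)
  missing <- setdiff(colnames(expr), names(trait))
  if (length(missing))
    stop("samples missing from the trait table: ",
         paste(missing, collapse = ", "))
  cd <- S4Vectors::DataFrame(wax_secretion = trait[colnames(expr)],
                             row.names = colnames(expr))
  rd <- S4Vectors::DataFrame(swissprot_id = rep(NA_character_, nrow(expr)),
                             description = rep(NA_character_, nrow(expr)),
                             row.names = rownames(expr))
  if (!is.null(annotation)) {
    idx <- match(rownames(expr), annotation$gene_id)
    rd$swissprot_id <- annotation$swissprot_id[idx]
    rd$description <- annotation$description[idx]
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = expr), colData = cd, rowData = rd)
}

#' Export a module network for Cytoscape
#'
#' Writes the edge and node files Cytoscape imports. The edge file has the
#' columns `fromNode`, `toNode`, `weight`, `direction`, `fromAltName`,
#' `toAltName` (direction is always `"undirected"`); the node file has
#' `nodeName`, `altName`, `nodeAttr` (the module color). The alternative
#' name is the gene's annotation description, or `"NA"` when unannotated.
#'
#' @param net a \linkS4class{WeightedNetwork}.
#' @param edgePath,nodePath output paths.
#' @param annotation optional annotation data.frame (see [readAnnotation()]).
#' @return invisibly, a list with the two paths.
#' @seealso [readCytoscapeEdges()] to re-read the edge file.
#' @export
writeCytoscapeNetwork <- function(net, edgePath, nodePath, annotation = NULL) {
  altOf <- function(ids) {
    if (is.null(annotation)) return(rep("NA", length(ids)))
    d <- annotation$description[match(ids, annotation$gene_id)]
    ifelse(is.na(d), "NA", d)
  }
  e <- networkEdges(net)
  edf <- data.frame(fromNode = e$from, toNode = e$to,
                    weight = sprintf("%.17g", e$weight),
                    direction = rep("undirected", nrow(e)),
                    fromAltName = altOf(e$from), toAltName = altOf(e$to))
  utils::write.table(edf, edgePath, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  nn <- networkNodes(net)
  ndf <- data.frame(nodeName = nn, altName = altOf(nn),
                    nodeAttr = rep(if (nzchar(net@module)) net@module
                                   else "NA", length(nn)))
  utils::write.table(ndf, nodePath, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(list(edges = edgePath, nodes = nodePath))
}

#' Re-read a Cytoscape edge file as a weighted network
#'
#' Inverse of [writeCytoscapeNetwork()] for the edge file; reconstructs the
#' identical weighted graph (node set = edge endpoints plus any `nodes`
#' supplied, e.g. from the node file, to recover isolated nodes).
#'
#' @param edgePath edge file path.
#' @param nodes optional character vector of node IDs to include even if
#'   isolated.
#' @param module module color tag for the resulting network.
#' @return a \linkS4class{WeightedNetwork}.
#' @export
readCytoscapeEdges <- function(edgePath, nodes = NULL, module = "") {
  df <- utils::read.table(edgePath, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, comment.char = "",
                          colClasses = "character")
  w <- as.numeric(df$weight)
  allNodes <- sort(unique(c(df$fromNode, df$toNode, nodes)))
  makeWeightedNetwork(allNodes, df$fromNode, df$toNode, w, module = module)
}

#' Pipeline configuration constructor
#'
#' Builds a validated \linkS4class{PipelineConfig}. Every argument is a
#' tunable of one pipeline stage; all are checked against their legal range
#' before any stage runs.
#'
#' @param madFraction fraction of genes retained by the MAD filter
#'   (ranked descending); study value 0.75.
#' @param madFloor minimum MAD a retained gene must exceed; study value 0.01.
#' @param madScaleConstant multiplier applied to the raw median absolute
#'   deviation; 1.4826 reproduces R's `mad()` (consistency with the normal
#'   distribution), set 1 for the raw MAD.
#' @param cutHeight static cut height (Euclidean distance units) for outlier
#'   sample removal; `NA` lets [suggestCutHeight()] pick one from the sample
#'   dendrogram.
#' @param minClusterSize smallest sample cluster kept by the static cut;
#'   default 3, the replicate count.
#' @param powers candidate soft-thresholding powers.
#' @param fitTarget scale-free fit index the power selection aims for.
#' @param networkSign `"unsigned"` (|cor|^beta) or `"signed"`
#'   (((1+cor)/2)^beta) adjacency.
#' @param minModuleSize smallest gene module reported.
#' @param deepSplit module-splitting sensitivity, 0 (coarse) to 3 (fine).
#' @param pamStage reassign leftover genes to their nearest module?
#' @param mergeCutHeight eigengene dissimilarity (1 - cor) below which
#'   modules are merged.
#' @param moduleAlpha p-value threshold for trait-significant modules.
#' @param pAdjust `"none"` (raw p, as in the study) or `"BH"`.
#' @param exportThreshold minimum TOM for an exported edge.
#' @param topK subnetwork size for the second screening stage.
#' @param hubFraction fraction of the subnetwork reported as hubs.
#' @param maxGenes guard: error if the network stage is asked to correlate
#'   more genes than this (dense matrices grow quadratically).
#' @param seed integer seed used by any stage that randomizes.
#' @return a \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(madFraction = 0.75, madFloor = 0.01,
                           madScaleConstant = 1.4826, cutHeight = NA_real_,
                           minClusterSize = 3L, powers = 1:20,
                           fitTarget = 0.9, networkSign = "unsigned",
                           minModuleSize = 20L, deepSplit = 2L,
                           pamStage = TRUE, mergeCutHeight = 0.15,
                           moduleAlpha = 0.05, pAdjust = "none",
                           exportThreshold = 0.02, topK = 100L,
                           hubFraction = 0.10, maxGenes = 25000L, seed = 1L) {
  new("PipelineConfig", madFraction = madFraction, madFloor = madFloor,
      madScaleConstant = madScaleConstant, cutHeight = as.numeric(cutHeight),
      minClusterSize = as.integer(minClusterSize),
      powers = as.integer(powers), fitTarget = fitTarget,
      networkSign = networkSign, minModuleSize = as.integer(minModuleSize),
      deepSplit = as.integer(deepSplit), pamStage = pamStage,
      mergeCutHeight = mergeCutHeight, moduleAlpha = moduleAlpha,
      pAdjust = pAdjust, exportThreshold = exportThreshold,
      topK = as.integer(topK), hubFraction = hubFraction,
      maxGenes = as.integer(maxGenes), seed = as.integer(seed))
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path. Keys mirror the [pipelineConfig()] arguments;
#'   missing keys take their defaults, unknown keys are an error.
#' @return `readPipelineConfig()`: a \linkS4class{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, vals)
}

#' @rdname readPipelineConfig
#' @param config a \linkS4class{PipelineConfig}.
#' @export
writePipelineConfig <- function(config, path) {
  vals <- lapply(slotNames(config), function(sl) slot(config, sl))
  names(vals) <- slotNames(config)
  yaml::write_yaml(vals, path)
  invisible(path)
}

## Append "key: value" parameter/count lines to a stage log. Timestamps are
## deliberately omitted so two identical runs produce identical logs.
logStage <- function(logPath, stage, ...) {
  if (is.null(logPath)) return(invisible(NULL))
  kv <- list(...)
  lines <- c(sprintf("[%s]", stage),
             vapply(names(kv), function(k)
               sprintf("  %s: %s", k, paste(kv[[k]], collapse = ",")),
               character(1)))
  cat(lines, file = logPath, sep = "\n", append = TRUE)
  invisible(NULL)
}
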