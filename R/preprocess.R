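#' Remove genes with zero expression in every sample
#'
#' @param expr genes-by-samples FPKM matrix.
#' @return list with `expression` (all-zero rows dropped, survivor order
#'   preserved) and `nRemoved`.
#' @export
removeZeroGenes <- function(expr) {
  validateExpression(expr)
  zero <- rowSums(expr != 0) == 0
  list(expression = expr[!zero, , drop = FALSE],
       nRemoved = as.integer(sum(zero)))
}

#' Median absolute deviation of a vector
#'
#' `median(|x - median(x)|) * scaleConstant`. The default scale constant
#' 1.4826 reproduces R's `mad()` (consistency with the standard deviation
#' under normality); pass `scaleConstant = 1` for the raw MAD. The choice
#' interacts with the 0.01 filtering floor, which is why it is exposed.
#'
#' @param x numeric vector, nonempty, no NA/NaN.
#' @param scaleConstant multiplier on the raw MAD.
#' @return the scaled MAD.
#' @examples
#' geneMad(c(1, 2, 3, 4, 5))      # 1 * 1.4826
#' geneMad(1:5, scaleConstant = 1) # raw MAD 1
#' @export
geneMad <- function(x, scaleConstant = 1.4826) {
  if (!length(x)) stop("cannot take the MAD of an empty vector")
  if (any(!is.finite(x))) stop("MAD input must be finite (no NA/NaN)")
  stats::median(abs(x - stats::median(x))) * scaleConstant
}

#' MAD-based expression filter
#'
#' Keeps the genes that are both within the top `ceiling(topFraction * n)`
#' by MAD (descending, ties broken by input order) and have MAD strictly
#' greater than `floor`. Survivor order equals input order.
#'
#' @param expr genes-by-samples matrix (zero rows already removed).
#' @param topFraction fraction of genes eligible by rank; study value 0.75.
#' @param floor minimum MAD; study value 0.01.
#' @param scaleConstant see [geneMad()].
#' @param nInputGenes gene count before zero-row removal, for the report;
#'   defaults to `nrow(expr)` (i.e. no zero rows were removed).
#' @param nZeroRemoved all-zero rows removed upstream, for the report.
#' @return list with `expression` and `report`
#'   (a \linkS4class{FilterReport}).
#' @export
madFilter <- function(expr, topFraction = 0.75, floor = 0.01,
                      scaleConstant = 1.4826,
                      nInputGenes = nrow(expr) + nZeroRemoved,
                      nZeroRemoved = 0L) {
  if (topFraction <= 0 || topFraction > 1)
    stop("topFraction must be in (0, 1]")
  mads <- apply(expr, 1, geneMad, scaleConstant = scaleConstant)
  nKeep <- ceiling(topFraction * nrow(expr))
  ## order() is stable: ties keep input order
  topIdx <- order(-mads)[seq_len(nKeep)]
  keep <- logical(nrow(expr))
  keep[topIdx] <- TRUE
  keep <- keep & (mads > floor)
  report <- new("FilterReport",
                nInputGenes = as.integer(nInputGenes),
                nZeroRemoved = as.integer(nZeroRemoved),
                nAfterZero = nrow(expr),
                nRetainedMad = as.integer(sum(keep)),
                madFraction = topFraction, madFloor = floor)
  list(expression = expr[keep, , drop = FALSE], report = report)
}

#' Euclidean distance between two sample profiles
#'
#' `sqrt(sum((x - y)^2))` over genes: the distance used for sample
#' clustering.
#'
#' @param x,y numeric vectors of equal length.
#' @return non-negative scalar, zero iff `x == y`.
#' @export
euclideanDistance <- function(x, y) {
  if (length(x) != length(y))
    stop("profiles must have equal length (", length(x), " vs ",
         length(y), ")")
  sqrt(sum((x - y)^2))
}

#' Cluster samples by Euclidean distance, UPGMA linkage
#'
#' Hierarchical clustering of samples on their gene-expression profiles
#' with Euclidean distance and unweighted average linkage (UPGMA), used to
#' spot outlier samples before network construction.
#'
#' @param expr genes-by-samples matrix (typically post-MAD-filter).
#' @return an [stats::hclust] tree over the samples.
#' @export
clusterSamples <- function(expr) {
  if (ncol(expr) < 2) stop("sample clustering needs at least 2 samples")
  stats::hclust(stats::dist(t(expr), method = "euclidean"),
                method = "average")
}

#' Suggest a static cut height from a sample dendrogram
#'
#' Midpoint between the two largest merge heights: the natural place to
#' cut when a single sample (or small group) joins the tree far above
#' everything else.
#'
#' @param dend an [stats::hclust] tree.
#' @return a cut height in the tree's distance units.
#' @export
suggestCutHeight <- function(dend) {
  h <- sort(dend$height, decreasing = TRUE)
  if (length(h) < 2) return(h[1] / 2)
  mean(h[1:2])
}

#' Remove outlier samples with a static tree cut
#'
#' Cuts the sample dendrogram at a fixed height and keeps only samples in
#' connected components of at least `minClusterSize` members (default 3,
#' the replicate count: a valid condition keeps all of its replicates).
#' Expression and trait tables are restricted consistently; retained values
#' are untouched.
#'
#' @param dend sample tree from [clusterSamples()].
#' @param expr genes-by-samples matrix the tree was built from.
#' @param trait named trait vector (may cover more samples than `expr`).
#' @param cutHeight static cut height (> 0), e.g. from [suggestCutHeight()].
#' @param minClusterSize smallest component kept.
#' @return list with `expression`, `trait`, `removed` (IDs).
#' @export
removeOutlierSamples <- function(dend, expr, trait, cutHeight,
                                 minClusterSize = 3L) {
  if (!is.numeric(cutHeight) || is.na(cutHeight) || cutHeight <= 0)
    stop("cutHeight must be > 0")
  comp <- stats::cutree(dend, h = cutHeight)
  sizes <- table(comp)
  keepIds <- names(comp)[sizes[as.character(comp)] >= minClusterSize]
  if (!length(keepIds)) stop("cut height removes every sample")
  removed <- setdiff(colnames(expr), keepIds)
  keep <- colnames(expr)[colnames(expr) %in% keepIds]
  list(expression = expr[, keep, drop = FALSE],
       trait = trait[keep[keep %in% names(trait)]],
       removed = removed)
}
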