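## Canonical module color sequence (the order the field assigns colors to
## size-ranked modules). "grey" is reserved for unassigned genes.
.moduleColorPalette <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta")

#' The canonical module color sequence
#'
#' @param n how many colors; beyond the named palette, deterministic
#'   `"extra-1"`, `"extra-2"`, ... names are appended.
#' @return character vector of length `n`.
#' @export
moduleColorSequence <- function(n) {
  if (n <= length(.moduleColorPalette)) return(.moduleColorPalette[seq_len(n)])
  c(.moduleColorPalette,
    sprintf("extra-%d", seq_len(n - length(.moduleColorPalette))))
}

#' Cluster genes on topological-overlap dissimilarity
#'
#' Average-linkage hierarchical clustering of genes on
#' `dissTOM = 1 - TOM`. The resulting dendrogram is the substrate for
#' module detection.
#'
#' @param tom TOM similarity matrix from [tomSimilarity()].
#' @return an [stats::hclust] tree over genes.
#' @export
clusterGenes <- function(tom) {
  if (nrow(tom) < 2) stop("gene clustering needs at least 2 genes")
  stats::hclust(stats::as.dist(1 - tom), method = "average")
}

#' Dynamic tree cut of the gene dendrogram
#'
#' Detects modules by a staged dynamic cut, a native variant of the
#' hybrid dynamic tree cut family:
#'
#' 1. The dendrogram is cut at an adaptive height
#'    `h5 + frac * (max height - h5)` where `h5` is the 5th percentile of
#'    merge heights and `frac` depends on `deepSplit`
#'    (0.98 / 0.965 / 0.95 / 0.92 for deepSplit 0..3) -- a deeper split
#'    cuts lower and resolves finer branches.
#' 2. Branches smaller than `minModuleSize` are dissolved into the
#'    unassigned pool (label 0), as are branches whose median internal
#'    topological overlap does not clearly exceed their overlap with the
#'    rest of the network -- clusters of merely chance-correlated genes
#'    sit near that boundary and do not qualify as modules.
#' 3. If `pamStage`, each unassigned gene is offered to the module it is
#'    closest to by average dissimilarity, and accepted only if its
#'    overlap with that module exceeds the `fenceQuantile` quantile of the
#'    overlaps the other unassigned genes have with it -- it must stand
#'    out from its current surroundings, not merely be nearest to some
#'    module.
#'
#' Comparisons are made on overlap similarities (`1 - diss`) as ratios or
#' quantiles, which keeps the rules invariant to the similarity
#' compression the soft-thresholding power induces. The contract of this
#' implementation is planted-module recovery (see the package tests), not
#' label-for-label agreement with any particular reference
#' implementation; [mergeCloseModules()] afterwards refines membership on
#' eigengene correlation.
#'
#' @param dend gene tree from [clusterGenes()].
#' @param diss dissimilarity matrix (`1 - TOM`) the tree was built from;
#'   required for the tightness filter and the PAM stage.
#' @param minModuleSize smallest reported module.
#' @param deepSplit 0 (coarse) .. 3 (fine).
#' @param pamStage run the assignment stage?
#' @param fenceQuantile quantile of the unassigned pool's overlap that a
#'   rescued gene must exceed in the PAM stage.
#' @return named integer vector of raw module labels (0 = unassigned),
#'   numbered in order of appearance along the dendrogram.
#' @export
cutGeneTree <- function(dend, diss = NULL, minModuleSize = 20L,
                        deepSplit = 2L, pamStage = TRUE,
                        fenceQuantile = 0.98) {
  if (minModuleSize < 2) stop("minModuleSize must be >= 2")
  if (!deepSplit %in% 0:3) stop("deepSplit must be 0, 1, 2 or 3")
  n <- length(dend$order)
  h <- dend$height
  h5 <- stats::quantile(h, 0.05, names = FALSE)
  frac <- c(0.98, 0.965, 0.95, 0.92)[deepSplit + 1L]
  cutH <- h5 + frac * (max(h) - h5)
  raw <- stats::cutree(dend, h = cutH)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= minModuleSize])
  ## tightness requirement: a genuine module must be markedly more
  ## overlapping within itself than with the rest of the network.
  ## Comparing topological overlap similarities (1 - diss) as a ratio
  ## makes the criterion invariant to the similarity compression the
  ## soft-thresholding power induces; branches of merely
  ## chance-correlated genes sit near ratio 1 and are dissolved.
  if (length(keep) && !is.null(diss) && length(keep) < n) {
    tight <- vapply(keep, function(kk) {
      idx <- which(raw == kk)
      d <- diss[idx, idx]
      simIn <- 1 - stats::median(d[upper.tri(d)])
      simOut <- 1 - stats::median(diss[idx, -idx])
      simIn >= 2 * simOut
    }, logical(1))
    keep <- keep[tight]
  }
  labels <- ifelse(raw %in% keep, raw, 0L)
  ## renumber surviving branches in dendrogram-order of first appearance
  if (length(keep)) {
    first <- order(vapply(keep, function(k) min(which(labels == k)),
                          integer(1)))
    remap <- integer(max(keep))
    remap[keep[first]] <- seq_along(keep)
    labels[labels > 0L] <- remap[labels[labels > 0L]]
  }
  names(labels) <- dend$labels

  if (pamStage && any(labels > 0L) && any(labels == 0L)) {
    if (is.null(diss)) stop("the PAM stage needs the dissimilarity matrix")
    mods <- sort(unique(labels[labels > 0L]))
    members <- lapply(mods, function(m) which(labels == m))
    unassigned <- which(labels == 0L)
    avgD <- vapply(members, function(idx) {
      rowMeans(diss[unassigned, idx, drop = FALSE])
    }, numeric(length(unassigned)))
    avgD <- matrix(avgD, nrow = length(unassigned))
    best <- max.col(-avgD, ties.method = "first")
    bestD <- avgD[cbind(seq_along(unassigned), best)]
    ## a rescued gene must overlap its nearest module beyond what the
    ## rest of the unassigned pool reaches with that module
    fence <- vapply(seq_along(members), function(j) {
      stats::quantile(1 - avgD[, j], fenceQuantile, names = FALSE)
    }, numeric(1))
    accept <- (1 - bestD) >= fence[best]
    labels[unassigned[accept]] <- mods[best[accept]]
  }
  labels
}

#' Merge modules with similar eigengenes
#'
#' Clusters module eigengenes on the dissimilarity `1 - cor(E_I, E_J)`
#' (average linkage) and merges every group of modules closer than
#' `mergeCutHeight`; the merged partition is then renumbered and colored
#' by decreasing size. `mergeCutHeight = 0` never merges.
#'
#' With `refine = TRUE` (the default) module membership is afterwards
#' consolidated on the eigengene-correlation scale: a gene stays in (or
#' joins) a module only if its correlation with the module eigengene is
#' significant under the Student asymptotic test at level 0.01 -- the
#' exact null for a gene fluctuating independently of the module. This
#' releases genes the tree cut swept in on chance topological overlap and
#' rescues peripheral members, independently of the soft-thresholding
#' power.
#'
#' @param expr genes-by-samples matrix the labels refer to.
#' @param labels named raw labels, e.g. from [cutGeneTree()].
#' @param mergeCutHeight eigengene dissimilarity below which modules merge.
#' @param refine run the eigengene-correlation membership refinement?
#' @return a \linkS4class{ModuleAssignment}.
#' @export
mergeCloseModules <- function(expr, labels, mergeCutHeight = 0.15,
                              refine = TRUE) {
  if (mergeCutHeight < 0 || mergeCutHeight >= 1)
    stop("mergeCutHeight must be in [0, 1)")
  mods <- sort(unique(labels[labels > 0L]))
  if (length(mods) >= 2 && mergeCutHeight > 0) {
    me <- vapply(mods, function(m) {
      moduleEigengene(expr[names(labels)[labels == m], , drop = FALSE])
    }, numeric(ncol(expr)))
    dissME <- 1 - stats::cor(me)
    grp <- stats::cutree(stats::hclust(stats::as.dist(dissME),
                                       method = "average"),
                         h = mergeCutHeight)
    relabel <- stats::setNames(grp, mods)
    labels[labels > 0L] <- relabel[as.character(labels[labels > 0L])]
  }
  if (refine) labels <- refineByEigengene(expr, labels)
  assignModuleColors(labels)
}

## Membership refinement on eigengene correlation (kME), the scale the
## soft-thresholding power cannot distort. A gene belongs to a module only
## if its correlation with the module eigengene is significant under the
## Student asymptotic test -- the exact null for a gene that merely
## fluctuates independently of the module. Members failing the test are
## released to grey; unassigned genes passing it for their best-matching
## module are taken in. A few passes let the eigengenes purify when the
## tree cut swept chance-correlated genes into a module.
refineByEigengene <- function(expr, labels, alpha = 0.01, maxPasses = 3L) {
  n <- ncol(expr)
  if (n < 5) return(labels)
  for (pass in seq_len(maxPasses)) {
    mods <- sort(unique(labels[labels > 0L]))
    if (!length(mods)) return(labels)
    me <- vapply(mods, function(m) {
      moduleEigengene(expr[names(labels)[labels == m], , drop = FALSE])
    }, numeric(n))
    kme <- abs(stats::cor(t(expr[names(labels), , drop = FALSE]), me))
    sig <- matrix(corPvalueStudent(kme, n) < alpha, nrow = nrow(kme))
    out <- labels
    for (j in seq_along(mods)) {
      memb <- names(labels)[labels == mods[j]]
      out[memb[!sig[match(memb, rownames(kme)), j]]] <- 0L
    }
    grey <- names(labels)[labels == 0L]
    if (length(grey)) {
      gi <- match(grey, rownames(kme))
      bestMod <- max.col(kme[gi, , drop = FALSE], ties.method = "first")
      take <- sig[cbind(gi, bestMod)]
      out[grey[take]] <- mods[bestMod[take]]
    }
    if (identical(out, labels)) return(out)
    labels <- out
  }
  labels
}

#' Number and color modules by size
#'
#' Renumbers raw labels so that label 1 is the largest module, and assigns
#' the canonical color sequence in that order; ties in size are broken by
#' the input order of each module's first member gene, so the coloring is
#' stable across runs. Label 0 stays "grey".
#'
#' @param labels named integer vector of raw labels (0 = unassigned).
#' @return a \linkS4class{ModuleAssignment}.
#' @examples
#' lab <- setNames(rep(c(3L, 1L, 0L), c(5, 8, 2)), paste0("g", 1:15))
#' moduleSizes(assignModuleColors(lab))  # turquoise=8, blue=5
#' @export
assignModuleColors <- function(labels) {
  if (is.null(names(labels))) stop("labels must be named by gene ID")
  labels <- as.integer(labels) |> stats::setNames(names(labels))
  mods <- sort(unique(labels[labels > 0L]))
  if (!length(mods)) {
    return(new("ModuleAssignment", labels = labels * 0L,
               colors = character(), sizes = integer()))
  }
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
  firstMember <- vapply(mods, function(m) min(which(labels == m)), integer(1))
  ord <- order(-sizes, firstMember)
  remap <- integer(max(mods))
  remap[mods[ord]] <- seq_along(mods)
  newLabels <- labels
  newLabels[labels > 0L] <- remap[labels[labels > 0L]]
  new("ModuleAssignment", labels = newLabels,
      colors = moduleColorSequence(length(mods)),
      sizes = sizes[ord])
}
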