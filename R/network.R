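#' Gene-gene Pearson correlation matrix
#'
#' Coexpression similarity: the Pearson correlation of every gene pair
#' across samples. Inputs must be complete (no NA) and free of constant
#' genes -- guaranteed after the MAD filter with a positive floor.
#'
#' @param expr genes-by-samples matrix.
#' @param maxGenes guard against accidentally correlating a full-size
#'   transcriptome into a dense matrix; raise it deliberately for large
#'   runs (quadratic memory, documented as slow).
#' @return symmetric gene x gene matrix, unit diagonal, entries in [-1, 1].
#' @export
correlationMatrix <- function(expr, maxGenes = 25000L) {
  if (ncol(expr) < 3) stop("correlation needs at least 3 samples")
  if (nrow(expr) > maxGenes)
    stop("refusing to build a dense ", nrow(expr), "-gene correlation ",
         "matrix (guard maxGenes = ", maxGenes, "); raise maxGenes to override")
  if (any(!is.finite(expr))) stop("expression must be complete and finite")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0))
    stop("constant gene encountered: '", rownames(expr)[sds == 0][1],
         "' (run the MAD filter with a positive floor first)")
  cc <- stats::cor(t(expr))
  ## clamp rounding spill and force an exact unit diagonal
  cc[cc > 1] <- 1; cc[cc < -1] <- -1
  diag(cc) <- 1
  cc
}

#' Soft-thresholded adjacency
#'
#' Raises the coexpression similarity to the soft-thresholding power beta:
#' unsigned `a_ij = |cor_ij|^beta`, signed `a_ij = ((1 + cor_ij)/2)^beta`.
#' The diagonal is forced to 1.
#'
#' @param cor correlation matrix from [correlationMatrix()].
#' @param beta soft-thresholding power (>= 1).
#' @param mode `"unsigned"` (default) or `"signed"`.
#' @return adjacency matrix with entries in [0, 1] and unit diagonal.
#' @examples
#' adjacencyFromCor(matrix(c(1, .8, .8, 1), 2), beta = 5)[1, 2]  # 0.32768
#' @export
adjacencyFromCor <- function(cor, beta, mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  if (beta < 1) stop("beta must be >= 1")
  a <- switch(mode,
              unsigned = abs(cor)^beta,
              signed = ((1 + cor) / 2)^beta)
  diag(a) <- 1
  a
}

#' Scale-free topology fit of an adjacency matrix
#'
#' Measures how well the network's connectivity distribution follows a
#' power law. Connectivities `k_i = sum_{j != i} a_ij` are binned into
#' `nBins` equal-width bins; the log10 mean frequency per bin is regressed
#' on the log10 mean connectivity per bin over nonempty bins, and the
#' signed fit index is `-sign(slope) * R^2` -- positive when frequency
#' falls with connectivity, as scale-free topology requires.
#'
#' @param adj adjacency matrix.
#' @param nBins number of connectivity bins.
#' @return list with `fit` (signed R^2), `meanK`, `medianK`, `maxK`,
#'   `slope`.
#' @export
scaleFreeFit <- function(adj, nBins = 10L) {
  k <- rowSums(adj) - diag(adj)
  kstats <- list(meanK = mean(k), medianK = stats::median(k), maxK = max(k))
  if (diff(range(k)) == 0) {
    warning("all connectivities identical; scale-free fit undefined, ",
            "returning 0")
    return(c(list(fit = 0, slope = 0), kstats))
  }
  bins <- cut(k, breaks = nBins, include.lowest = TRUE)
  freq <- tapply(k, bins, length) / length(k)
  kMean <- tapply(k, bins, mean)
  ok <- !is.na(freq) & kMean > 0
  if (sum(ok) < 2) {
    warning("fewer than 2 usable connectivity bins; returning 0")
    return(c(list(fit = 0, slope = 0), kstats))
  }
  fitLm <- stats::lm(log10(freq[ok]) ~ log10(kMean[ok]))
  slope <- unname(stats::coef(fitLm)[2])
  r2 <- summary(fitLm)$r.squared
  c(list(fit = -sign(slope) * r2, slope = slope), kstats)
}

#' Scan soft-thresholding powers and pick one
#'
#' For each candidate power, builds the adjacency and evaluates the signed
#' scale-free fit index and connectivity statistics; selects the lowest
#' power whose fit reaches `fitTarget`. If none does, the power with the
#' maximal fit is chosen and a warning is issued.
#'
#' @param expr genes-by-samples matrix (post-preprocessing).
#' @param powers ascending candidate powers.
#' @param fitTarget target signed fit index; the study used 0.9.
#' @param mode adjacency sign mode, see [adjacencyFromCor()].
#' @param nBins connectivity bins for [scaleFreeFit()].
#' @param maxGenes see [correlationMatrix()].
#' @return a \linkS4class{SoftThresholdScan}.
#' @export
pickSoftThreshold <- function(expr, powers = 1:20, fitTarget = 0.9,
                              mode = c("unsigned", "signed"), nBins = 10L,
                              maxGenes = 25000L) {
  mode <- match.arg(mode)
  powers <- as.integer(powers)
  if (!length(powers) || is.unsorted(powers, strictly = TRUE))
    stop("powers must be nonempty and strictly ascending")
  cc <- correlationMatrix(expr, maxGenes = maxGenes)
  rows <- lapply(powers, function(b) {
    sf <- suppressWarnings(scaleFreeFit(adjacencyFromCor(cc, b, mode), nBins))
    data.frame(power = b, fit = sf$fit, meanK = sf$meanK,
               medianK = sf$medianK, maxK = sf$maxK)
  })
  scan <- do.call(rbind, rows)
  hit <- which(scan$fit >= fitTarget)
  reached <- length(hit) > 0
  chosen <- if (reached) scan$power[hit[1]] else scan$power[which.max(scan$fit)]
  if (!reached)
    warning(sprintf(
      "no power reached fit target %.2f; using power %d (best fit %.3f)",
      fitTarget, chosen, max(scan$fit)))
  new("SoftThresholdScan", scan = scan, power = as.integer(chosen),
      fitTarget = fitTarget, reachedTarget = reached)
}

#' Topological overlap matrix
#'
#' The TOM similarity of the (unsigned) adjacency:
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`;
#' the diagonal is 1. Computed with dense matrix algebra.
#'
#' @param adj adjacency matrix (entries in [0, 1], unit diagonal).
#' @return symmetric TOM matrix in [0, 1] with unit diagonal.
#' @examples
#' a <- matrix(0.5, 3, 3); diag(a) <- 1
#' tomSimilarity(a)[1, 2]  # (0.25 + 0.5) / (1 + 1 - 0.5) = 0.5
#' @export
tomSimilarity <- function(adj) {
  a <- adj
  diag(a) <- 0
  l <- a %*% a          # (i,j): sum_u a_iu a_uj; u = i,j contribute 0
  k <- rowSums(a)
  minK <- outer(k, k, pmin)
  tom <- (l + a) / (minK + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}
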