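#' Module eigengene
#'
#' The representative expression profile of a module: each member gene is
#' standardized to mean 0 / variance 1 across samples, and the eigengene is
#' the first principal component of the resulting samples x genes matrix,
#' scaled to unit sample variance. The sign is fixed so that the eigengene
#' correlates non-negatively with the mean standardized module expression,
#' which makes downstream membership signs reproducible.
#'
#' @param exprModule genes-by-samples matrix restricted to one module.
#' @return named numeric vector, one value per sample, variance 1.
#' @export
moduleEigengene <- function(exprModule) {
  if (ncol(exprModule) < 2) stop("an eigengene needs at least 2 samples")
  if (!nrow(exprModule)) stop("module is empty")
  std <- t(scale(t(exprModule)))
  if (any(!is.finite(std)))
    stop("constant gene in module: '",
         rownames(exprModule)[which(apply(exprModule, 1, stats::sd) == 0)[1]],
         "'")
  n <- ncol(exprModule)
  sv <- svd(t(std), nu = 1, nv = 0)
  e <- sv$u[, 1] * sqrt(n - 1)   # columns of t(std) are mean zero
  avg <- colMeans(std)
  s <- sum(e * avg)
  if (s < 0) e <- -e
  stats::setNames(e, colnames(exprModule))
}

#' Eigengenes of every module
#'
#' @param expr genes-by-samples matrix.
#' @param assign a \linkS4class{ModuleAssignment} on the same genes.
#' @return samples x modules matrix; columns named by module color,
#'   ordered by module label (decreasing size). Grey is excluded.
#' @export
moduleEigengenes <- function(expr, assign) {
  labels <- moduleLabels(assign)
  cols <- moduleColors(assign)
  if (!length(cols)) stop("no modules to compute eigengenes for")
  me <- vapply(seq_along(cols), function(m) {
    moduleEigengene(expr[names(labels)[labels == m], , drop = FALSE])
  }, numeric(ncol(expr)))
  dimnames(me) <- list(colnames(expr), cols)
  me
}

#' Student asymptotic p-value of a correlation
#'
#' Two-sided p-value of a Pearson correlation `r` observed on `n` samples,
#' from `t = r * sqrt(n - 2) / sqrt(1 - r^2)` referred to a Student t
#' distribution with `n - 2` degrees of freedom; `|r| = 1` gives p = 0.
#'
#' @param r correlation(s), in [-1, 1]; vectorized.
#' @param n number of samples (>= 3).
#' @return p-value(s) in [0, 1].
#' @examples
#' corPvalueStudent(0, 17)    # 1
#' corPvalueStudent(0.8, 17)  # t = 5.16398 on 15 df
#' @export
corPvalueStudent <- function(r, n) {
  if (any(n < 3)) stop("the Student p-value needs n >= 3")
  if (any(abs(r) > 1 + 1e-12)) stop("|r| must be <= 1")
  r <- pmin(pmax(r, -1), 1)
  p <- numeric(length(r))
  exact <- abs(r) == 1
  t <- r[!exact] * sqrt(n - 2) / sqrt(1 - r[!exact]^2)
  p[!exact] <- 2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
  p[exact] <- 0
  p
}

#' Module-trait correlation table
#'
#' Pearson correlation of every module eigengene with the quantitative
#' trait, with the Student asymptotic p-value of each correlation.
#'
#' @param eigengenes samples x modules matrix from [moduleEigengenes()].
#' @param trait named trait vector covering the eigengene samples.
#' @param pAdjust `"none"` (raw p, as a plain p < alpha rule uses) or
#'   `"BH"` for Benjamini-Hochberg adjusted p-values.
#' @return data.frame with columns `module`, `r`, `p`, `n`.
#' @export
moduleTraitRelation <- function(eigengenes, trait, pAdjust = c("none", "BH")) {
  pAdjust <- match.arg(pAdjust)
  missing <- setdiff(rownames(eigengenes), names(trait))
  if (length(missing))
    stop("samples missing from the trait table: ",
         paste(missing, collapse = ", "))
  tv <- trait[rownames(eigengenes)]
  n <- length(tv)
  r <- as.vector(stats::cor(eigengenes, tv))
  p <- corPvalueStudent(r, n)
  if (pAdjust == "BH") p <- stats::p.adjust(p, method = "BH")
  data.frame(module = colnames(eigengenes), r = r, p = p, n = n,
             row.names = NULL)
}

#' Trait-significant modules
#'
#' Modules whose eigengene-trait correlation p-value falls below `alpha`,
#' ordered by ascending p. Grey (unassigned) never qualifies.
#'
#' @param moduleTrait data.frame from [moduleTraitRelation()].
#' @param alpha significance threshold.
#' @return character vector of module colors.
#' @export
selectSignificantModules <- function(moduleTrait, alpha = 0.05) {
  mt <- moduleTrait[moduleTrait$module != "grey" & moduleTrait$p < alpha, ]
  mt$module[order(mt$p)]
}

#' Gene significance and module membership
#'
#' GS is the absolute correlation between a gene's expression and the
#' trait; MM is the (signed) correlation between the gene and its own
#' module's eigengene. Unassigned (grey) genes get MM = NA.
#'
#' @param expr genes-by-samples matrix.
#' @param trait named trait vector covering the samples.
#' @param eigengenes samples x modules matrix from [moduleEigengenes()].
#' @param assign the \linkS4class{ModuleAssignment}.
#' @return data.frame with columns `gene`, `module`, `GS`, `MM`.
#' @export
geneTraitStats <- function(expr, trait, eigengenes, assign) {
  missing <- setdiff(colnames(expr), names(trait))
  if (length(missing))
    stop("samples missing from the trait table: ",
         paste(missing, collapse = ", "))
  tv <- trait[colnames(expr)]
  labels <- moduleLabels(assign)[rownames(expr)]
  gs <- abs(as.vector(stats::cor(t(expr), tv)))
  mm <- rep(NA_real_, nrow(expr))
  for (m in seq_along(moduleColors(assign))) {
    idx <- which(labels == m)
    if (length(idx))
      mm[idx] <- as.vector(stats::cor(t(expr[idx, , drop = FALSE]),
                                      eigengenes[, m]))
  }
  data.frame(gene = rownames(expr), module = geneColors(assign)[rownames(expr)],
             GS = gs, MM = mm, row.names = NULL)
}

#' Eigengene dissimilarity and adjacency
#'
#' From the pairwise eigengene correlations: dissimilarity
#' `1 - cor(E_I, E_J)` (diagonal 0) and adjacency `(1 + cor(E_I, E_J)) / 2`
#' (diagonal 1). The two are linked by the identity `A = 1 - diss / 2`.
#'
#' @param eigengenes samples x modules matrix (>= 2 modules).
#' @return list with matrices `dissimilarity` and `adjacency`.
#' @export
eigengeneNetwork <- function(eigengenes) {
  if (ncol(eigengenes) < 2)
    stop("an eigengene network needs at least 2 modules")
  cc <- stats::cor(eigengenes)
  diss <- 1 - cc
  diag(diss) <- 0
  adj <- (1 + cc) / 2
  diag(adj) <- 1
  list(dissimilarity = diss, adjacency = adj)
}
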