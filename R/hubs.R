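## canonical constructor: order endpoints, sort edges, validate
makeWeightedNetwork <- function(nodes, from, to, weight, module = "") {
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  ord <- order(from, to, method = "radix")
  edges <- data.frame(from = as.character(from[ord]),
                      to = as.character(to[ord]),
                      weight = as.numeric(weight[ord]),
                      row.names = NULL, stringsAsFactors = FALSE)
  new("WeightedNetwork", nodes = as.character(nodes), edges = edges,
      module = module)
}

#' Extract a module's topological-overlap network
#'
#' Builds the intra-module weighted network: nodes are the module's genes
#' and edges connect every gene pair whose TOM similarity is at least
#' `threshold`, weighted by that TOM value.
#'
#' The default threshold (0.02) is deliberately low: hub screening assumes
#' a near-complete module network (in such networks every betweenness
#' centrality is 0), and the threshold changes degree ranks, so it is
#' logged prominently by the pipeline.
#'
#' @param tom TOM matrix over all genes.
#' @param assign a \linkS4class{ModuleAssignment}.
#' @param module module color to extract.
#' @param threshold minimum TOM for an edge, in [0, 1).
#' @return a \linkS4class{WeightedNetwork}.
#' @export
moduleNetwork <- function(tom, assign, module, threshold = 0.02) {
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  lab <- match(module, moduleColors(assign))
  if (is.na(lab)) stop("no such module: '", module, "'")
  genes <- names(moduleLabels(assign))[moduleLabels(assign) == lab]
  if (!length(genes)) stop("module '", module, "' is empty")
  sub <- tom[genes, genes, drop = FALSE]
  idx <- which(upper.tri(sub) & sub >= threshold, arr.ind = TRUE)
  makeWeightedNetwork(genes, genes[idx[, 1]], genes[idx[, 2]],
                      sub[idx], module = module)
}

#' Drop unannotated nodes from a network
#'
#' Keeps only nodes with a Swiss-Prot annotation (non-missing accession)
#' and the edges among them; screening operates on annotatable genes only.
#'
#' @param net a \linkS4class{WeightedNetwork}.
#' @param annotation annotation data.frame (see [readAnnotation()]).
#' @return the filtered \linkS4class{WeightedNetwork}.
#' @export
filterAnnotated <- function(net, annotation) {
  ok <- annotation$gene_id[!is.na(annotation$swissprot_id)]
  nodes <- networkNodes(net)[networkNodes(net) %in% ok]
  if (!length(nodes))
    stop("no annotated nodes remain in module '", net@module, "'")
  e <- networkEdges(net)
  keep <- e$from %in% nodes & e$to %in% nodes
  makeWeightedNetwork(nodes, e$from[keep], e$to[keep], e$weight[keep],
                      module = net@module)
}

#' Node degree
#'
#' Unweighted degree is the neighbor count `|N_u|`; weighted degree is the
#' sum of incident edge weights `sum_{v in N_u} W(u, v)`.
#'
#' @param net a \linkS4class{WeightedNetwork}.
#' @param weighted sum weights instead of counting edges?
#' @return named numeric vector over all nodes (0 for isolated nodes).
#' @export
nodeDegree <- function(net, weighted = FALSE) {
  nodes <- networkNodes(net)
  e <- networkEdges(net)
  d <- stats::setNames(numeric(length(nodes)), nodes)
  if (nrow(e)) {
    w <- if (weighted) e$weight else rep(1, nrow(e))
    inc <- tapply(c(w, w), c(e$from, e$to), sum)
    d[names(inc)] <- inc
  }
  d
}

## deterministic node ranking: primary key descending, secondary key
## descending, then lexicographic node ID
rankNodes <- function(primary, secondary, ids) {
  ord <- order(-primary, -secondary, ids, method = "radix")
  rk <- integer(length(ids))
  rk[ord] <- seq_along(ids)
  stats::setNames(rk, ids)
}

#' Induced subnetwork of the top-k nodes by degree
#'
#' Stage one of the hub screen: rank nodes by unweighted degree
#' (descending; ties broken by higher weighted degree, then lexicographic
#' node ID), keep the top `k`, and return the induced subgraph -- every
#' retained edge has both endpoints retained.
#'
#' @param net a \linkS4class{WeightedNetwork}.
#' @param k subnetwork size; `k >=` node count returns the whole network.
#' @return a \linkS4class{WeightedNetwork}.
#' @export
topKSubnetwork <- function(net, k = 100L) {
  if (k < 1) stop("k must be >= 1")
  nodes <- networkNodes(net)
  deg <- nodeDegree(net, weighted = FALSE)
  wdeg <- nodeDegree(net, weighted = TRUE)
  ord <- order(-deg, -wdeg, nodes, method = "radix")
  top <- sort(nodes[ord[seq_len(min(k, length(nodes)))]])
  e <- networkEdges(net)
  keep <- e$from %in% top & e$to %in% top
  makeWeightedNetwork(top, e$from[keep], e$to[keep], e$weight[keep],
                      module = net@module)
}

## dense weighted adjacency of a network, nodes in networkNodes() order
networkAdjacency <- function(net) {
  nodes <- networkNodes(net)
  a <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  e <- networkEdges(net)
  if (nrow(e)) {
    i <- match(e$from, nodes); j <- match(e$to, nodes)
    a[cbind(i, j)] <- e$weight
    a[cbind(j, i)] <- e$weight
  }
  a
}

networkIgraph <- function(net) {
  igraph::graph_from_data_frame(networkEdges(net), directed = FALSE,
                                vertices = networkNodes(net))
}

#' Weighted eigenvector centrality
#'
#' Principal eigenvector of the weighted adjacency matrix, computed by
#' power iteration and normalized so the maximum entry is 1. On a
#' disconnected network the centrality is computed on the largest
#' connected component (a warning is issued) and all other nodes get 0.
#'
#' @param net a \linkS4class{WeightedNetwork}.
#' @param tol relative convergence tolerance of the power iteration.
#' @param maxIter iteration cap; non-convergence is an error reporting it.
#' @return named numeric vector, entries in [0, 1], max 1.
#' @export
eigenvectorCentrality <- function(net, tol = 1e-10, maxIter = 10000L) {
  nodes <- networkNodes(net)
  res <- stats::setNames(numeric(length(nodes)), nodes)
  if (!nrow(networkEdges(net))) {
    warning("edgeless network: eigenvector centrality is 0 everywhere")
    return(res)
  }
  comp <- igraph::components(networkIgraph(net))
  use <- nodes[comp$membership == which.max(comp$csize)]
  if (length(use) < length(nodes))
    warning("network is disconnected; eigenvector centrality computed on ",
            "the largest component (", length(use), " of ", length(nodes),
            " nodes), others set to 0")
  a <- networkAdjacency(net)[use, use, drop = FALSE]
  ## spectral shift: iterating on A + sI keeps the eigenvectors but makes
  ## the leading eigenvalue strictly dominant (bipartite graphs such as
  ## stars otherwise oscillate between +/- the spectral radius)
  shift <- 0.1 * max(rowSums(a))
  diag(a) <- diag(a) + shift
  x <- rep(1 / length(use), length(use))
  for (it in seq_len(maxIter)) {
    xn <- as.vector(a %*% x)
    xn <- xn / max(xn)
    if (max(abs(xn - x)) <= tol * max(abs(xn))) {
      res[use] <- xn / max(xn)
      return(res)
    }
    x <- xn
  }
  stop("eigenvector centrality did not converge in ", maxIter, " iterations")
}

#' Betweenness centrality
#'
#' Counts, for each node, the (fractional) number of shortest paths
#' between other node pairs that pass through it. Paths are unweighted --
#' every edge counts as one hop -- and equally short paths split the count
#' evenly, the standard convention. On a complete network every value is 0.
#'
#' @param net a \linkS4class{WeightedNetwork}.
#' @return named numeric vector.
#' @export
betweennessCentrality <- function(net) {
  g <- networkIgraph(net)
  b <- igraph::betweenness(g, directed = FALSE, weights = NA)
  stats::setNames(as.numeric(b), igraph::V(g)$name)[networkNodes(net)]
}

#' Centrality table of a network
#'
#' Computes unweighted and weighted degree, eigenvector and betweenness
#' centrality for every node, plus the deterministic rank of each node
#' under weighted degree and under eigenvector centrality (descending;
#' ties broken by the other index, then node ID).
#'
#' @param net a \linkS4class{WeightedNetwork}.
#' @return data.frame with columns `node`, `degree`, `weightedDegree`,
#'   `eigenvector`, `betweenness`, `dcRank`, `ecRank`.
#' @export
centralityTable <- function(net) {
  nodes <- networkNodes(net)
  deg <- nodeDegree(net, weighted = FALSE)
  wdeg <- nodeDegree(net, weighted = TRUE)
  ec <- suppressWarnings(eigenvectorCentrality(net))
  bc <- betweennessCentrality(net)
  data.frame(node = nodes, degree = as.integer(deg),
             weightedDegree = unname(wdeg), eigenvector = unname(ec[nodes]),
             betweenness = unname(bc[nodes]),
             dcRank = unname(rankNodes(wdeg, ec[nodes], nodes)),
             ecRank = unname(rankNodes(ec[nodes], wdeg, nodes)),
             row.names = NULL)
}

#' Select hub genes from a centrality table
#'
#' Stage two of the screen: the top `ceiling(hubFraction * n)` nodes by
#' the chosen index, descending (ties broken by the other index, then
#' node ID), with both ranks reported per hub.
#'
#' @param centrality data.frame from [centralityTable()].
#' @param sortKey `"weighted_degree"` (the study's choice) or
#'   `"eigenvector"`.
#' @param hubFraction fraction of nodes reported, in (0, 1].
#' @return data.frame of the hubs, ordered by the sort key, with columns
#'   of `centrality` plus `rank`.
#' @export
selectHubs <- function(centrality,
                       sortKey = c("weighted_degree", "eigenvector"),
                       hubFraction = 0.10) {
  sortKey <- match.arg(sortKey)
  if (hubFraction <= 0 || hubFraction > 1)
    stop("hubFraction must be in (0, 1]")
  rk <- if (sortKey == "weighted_degree") centrality$dcRank
        else centrality$ecRank
  nHub <- ceiling(hubFraction * nrow(centrality))
  out <- centrality[order(rk), , drop = FALSE][seq_len(nHub), , drop = FALSE]
  out$rank <- seq_len(nHub)
  rownames(out) <- NULL
  out
}

#' Compare two centrality rankings
#'
#' Checks whether the top-`topN` gene sets under two rankings coincide and
#' reports the signed rank displacement of each top gene (the "arrows" of
#' a side-by-side ranking table): positive displacement means the gene
#' ranks lower (larger rank number) under the second ranking.
#'
#' @param rankA,rankB named rank vectors over the same node universe
#'   (e.g. `dcRank` and `ecRank` from [centralityTable()]).
#' @param topN how many top genes to compare.
#' @return list with `sameSet` (logical) and `displacement` (named integer
#'   vector over the union of the two top lists, `rankB - rankA`).
#' @export
compareRankings <- function(rankA, rankB, topN = 10L) {
  if (!setequal(names(rankA), names(rankB)))
    stop("the two rankings must cover the same nodes")
  rankB <- rankB[names(rankA)]
  topA <- names(rankA)[rankA <= topN]
  topB <- names(rankB)[rankB <= topN]
  both <- union(topA, topB)
  disp <- as.integer(rankB[both] - rankA[both])
  list(sameSet = setequal(topA, topB),
       displacement = stats::setNames(disp, both))
}

#' Two-stage centrality hub screen over significant modules
#'
#' The complete screening procedure: for each trait-significant module,
#' extract its TOM network, drop unannotated genes, keep the induced
#' subnetwork of the `topK` highest-(unweighted-)degree nodes, compute the
#' weighted centrality table, and report the top `hubFraction` of nodes as
#' hub genes together with the degree-vs-eigenvector ranking comparison.
#'
#' @param tom TOM matrix over all genes.
#' @param assign a \linkS4class{ModuleAssignment}.
#' @param annotation annotation data.frame (see [readAnnotation()]).
#' @param modules character vector of module colors to screen
#'   (typically from [selectSignificantModules()]).
#' @param threshold minimum TOM for an edge, see [moduleNetwork()].
#' @param topK stage-one subnetwork size.
#' @param hubFraction fraction of the subnetwork reported as hubs.
#' @param sortKey hub ranking index, see [selectHubs()].
#' @return a \linkS4class{HubReport}.
#' @export
screenHubs <- function(tom, assign, annotation, modules, threshold = 0.02,
                       topK = 100L, hubFraction = 0.10,
                       sortKey = "weighted_degree") {
  if (!length(modules)) stop("no modules to screen")
  hubRows <- list()
  comparisons <- list()
  for (m in modules) {
    net <- moduleNetwork(tom, assign, m, threshold = threshold)
    net <- filterAnnotated(net, annotation)
    sub <- topKSubnetwork(net, k = topK)
    ct <- centralityTable(sub)
    hubs <- selectHubs(ct, sortKey = sortKey, hubFraction = hubFraction)
    cmp <- compareRankings(
      stats::setNames(ct$dcRank, ct$node),
      stats::setNames(ct$ecRank, ct$node),
      topN = nrow(hubs))
    desc <- annotation$description[match(hubs$node, annotation$gene_id)]
    hubRows[[m]] <- data.frame(
      module = m, rank = hubs$rank, gene = hubs$node,
      weightedDegree = hubs$weightedDegree, eigenvector = hubs$eigenvector,
      dcRank = hubs$dcRank, ecRank = hubs$ecRank,
      description = ifelse(is.na(desc), "NA", desc), row.names = NULL)
    comparisons[[m]] <- cmp
  }
  new("HubReport", hubs = do.call(rbind, c(hubRows, make.row.names = FALSE)),
      comparisons = comparisons, hubFraction = hubFraction)
}
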