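test_that("module networks are thresholded TOM subgraphs", {
  run <- presetRun()
  topCol <- moduleColors(run$assignment)[1]

  ## threshold above the maximal off-diagonal TOM -> edgeless
  lab <- moduleLabels(run$assignment)
  genes <- names(lab)[lab == 1L]
  sub <- run$tom[genes, genes]
  hi <- max(sub[upper.tri(sub)])
  net0 <- moduleNetwork(run$tom, run$assignment, topCol,
                        threshold = min(hi + 1e-6, 0.999999))
  expect_equal(nrow(networkEdges(net0)), 0)

  ## threshold 0 -> complete graph
  netC <- moduleNetwork(run$tom, run$assignment, topCol, threshold = 0)
  n <- length(genes)
  expect_equal(nrow(networkEdges(netC)), n * (n - 1) / 2)
  expect_error(moduleNetwork(run$tom, run$assignment, "no-such-color"),
               "no such module")

  ## hand-counted 3-node case
  net3 <- makeNet(c("a", "a", "b"), c("b", "c", "c"), rep(0.5, 3))
  expect_equal(nrow(networkEdges(net3)), 3)
})

test_that("annotation filtering keeps annotated nodes and their edges only", {
  ## complete graph on 5 nodes, 2 unannotated -> K3: 3 nodes, 3 edges
  nodes <- letters[1:5]
  pairs <- t(combn(nodes, 2))
  net <- makeNet(pairs[, 1], pairs[, 2], runif(nrow(pairs), 0.2, 0.9))
  ann <- data.frame(gene_id = c("a", "c", "e"),
                    swissprot_id = paste0("P", 1:3),
                    description = paste("protein", c("a", "c", "e")))
  f <- filterAnnotated(net, ann)
  expect_setequal(networkNodes(f), c("a", "c", "e"))
  expect_equal(nrow(networkEdges(f)), 3)
  ## conservation: no edge touches a removed node
  expect_true(all(c(networkEdges(f)$from, networkEdges(f)$to) %in%
                    networkNodes(f)))
  ## all annotated -> identity
  annAll <- data.frame(gene_id = nodes, swissprot_id = paste0("P", 1:5),
                       description = nodes)
  expect_identical(networkEdges(filterAnnotated(net, annAll)),
                   networkEdges(net))
  expect_error(filterAnnotated(net, ann[0, ]), "no annotated")
})

test_that("degrees match hand sums and a per-node loop oracle", {
  net <- makeNet(c("a", "a"), c("b", "c"), c(0.5, 0.5),
                 nodes = c("a", "b", "c", "iso"))
  d <- nodeDegree(net); dw <- nodeDegree(net, weighted = TRUE)
  expect_equal(unname(d["a"]), 2)
  expect_equal(unname(dw["a"]), 1.0)
  expect_equal(unname(d["iso"]), 0)
  expect_equal(unname(dw["iso"]), 0)

  set.seed(31)
  nodes <- sprintf("n%02d", 1:15)
  pairs <- t(combn(nodes, 2))
  pick <- runif(nrow(pairs)) < 0.4
  w <- runif(sum(pick), 0.1, 1)
  g <- makeNet(pairs[pick, 1], pairs[pick, 2], w, nodes = nodes)
  dg <- nodeDegree(g); dwg <- nodeDegree(g, weighted = TRUE)
  e <- networkEdges(g)
  for (v in nodes) {
    cnt <- 0; tot <- 0
    for (i in seq_len(nrow(e))) {
      if (e$from[i] == v || e$to[i] == v) { cnt <- cnt + 1; tot <- tot + e$weight[i] }
    }
    expect_equal(unname(dg[v]), cnt)
    expect_equal(unname(dwg[v]), tot, tolerance = 1e-12)
  }
})

test_that("the top-k subnetwork ranks by degree with deterministic ties", {
  ## star with 5 leaves, equal weights: k = 2 keeps hub + smallest-ID leaf
  net <- makeNet(rep("hub", 5), paste0("leaf", 1:5), rep(0.5, 5))
  top2 <- topKSubnetwork(net, k = 2L)
  expect_setequal(networkNodes(top2), c("hub", "leaf1"))
  expect_equal(nrow(networkEdges(top2)), 1)

  ## k >= node count returns the whole network; idempotence
  all6 <- topKSubnetwork(net, k = 10L)
  expect_identical(networkEdges(all6), networkEdges(net))
  expect_identical(networkEdges(topKSubnetwork(all6, k = 10L)),
                   networkEdges(all6))

  ## induced-subgraph property on a random network
  set.seed(17)
  nodes <- sprintf("n%02d", 1:20)
  pairs <- t(combn(nodes, 2))
  pick <- runif(nrow(pairs)) < 0.3
  g <- makeNet(pairs[pick, 1], pairs[pick, 2],
               runif(sum(pick), 0.1, 1), nodes = nodes)
  sub <- topKSubnetwork(g, k = 8L)
  e <- networkEdges(sub)
  expect_true(all(c(e$from, e$to) %in% networkNodes(sub)))
  expect_length(networkNodes(sub), 8)
})

test_that("eigenvector centrality matches closed forms and a dense eigensolver", {
  ## complete graph with equal weights: all centralities 1
  nodes <- letters[1:6]
  pairs <- t(combn(nodes, 2))
  kc <- makeNet(pairs[, 1], pairs[, 2], rep(0.7, nrow(pairs)))
  expect_equal(unname(eigenvectorCentrality(kc)), rep(1, 6), tolerance = 1e-9)

  ## weighted star: center 1, all leaves equal to 1/sqrt(n) < 1
  st <- makeNet(rep("hub", 6), paste0("leaf", 1:6), rep(0.4, 6))
  ec <- eigenvectorCentrality(st)
  expect_equal(unname(ec["hub"]), 1)
  expect_equal(unname(ec[paste0("leaf", 1:6)]), rep(1 / sqrt(6), 6),
               tolerance = 1e-9)

  ## random weighted graph vs dense eigen() oracle
  set.seed(23)
  nodes <- sprintf("n%02d", 1:12)
  pairs <- t(combn(nodes, 2))
  pick <- runif(nrow(pairs)) < 0.5
  g <- makeNet(pairs[pick, 1], pairs[pick, 2],
               runif(sum(pick), 0.1, 1), nodes = nodes)
  ecg <- suppressWarnings(eigenvectorCentrality(g))
  a <- matrix(0, 12, 12, dimnames = list(nodes, nodes))
  e <- networkEdges(g)
  for (i in seq_len(nrow(e))) {
    a[e$from[i], e$to[i]] <- e$weight[i]
    a[e$to[i], e$from[i]] <- e$weight[i]
  }
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    a > 0, mode = "undirected"))
  main <- nodes[comp$membership == which.max(comp$csize)]
  v <- eigen(a[main, main], symmetric = TRUE)$vectors[, 1]
  v <- abs(v) / max(abs(v))
  expect_equal(unname(ecg[main]), unname(v), tolerance = 1e-8)
  expect_true(all(ecg[setdiff(nodes, main)] == 0))
})

test_that("betweenness matches hand values and exhaustive enumeration", {
  ## path a - b - c: BC(b) = 1, ends 0
  p <- makeNet(c("a", "b"), c("b", "c"), c(0.5, 0.5))
  bc <- betweennessCentrality(p)
  expect_equal(unname(bc[c("a", "b", "c")]), c(0, 1, 0))

  ## complete network: every BC is 0
  nodes <- letters[1:7]
  pairs <- t(combn(nodes, 2))
  kc <- makeNet(pairs[, 1], pairs[, 2], runif(nrow(pairs), 0.1, 1))
  expect_equal(unname(betweennessCentrality(kc)), rep(0, 7))

  ## random graph (<= 12 nodes) vs exhaustive shortest-path enumeration
  set.seed(41)
  nodes <- sprintf("n%02d", 1:10)
  pairs <- t(combn(nodes, 2))
  pick <- runif(nrow(pairs)) < 0.35
  g <- makeNet(pairs[pick, 1], pairs[pick, 2],
               runif(sum(pick), 0.1, 1), nodes = nodes)
  bcg <- betweennessCentrality(g)

  ## oracle: enumerate all simple paths per pair, keep the shortest ones
  adj <- lapply(setNames(nm = nodes), function(v) {
    e <- networkEdges(g)
    c(e$to[e$from == v], e$from[e$to == v])
  })
  allPaths <- function(from, to) {
    out <- list()
    grow <- function(path) {
      last <- path[length(path)]
      if (last == to) { out[[length(out) + 1]] <<- path; return() }
      for (nb in adj[[last]]) if (!nb %in% path) grow(c(path, nb))
    }
    grow(from)
    out
  }
  oracle <- setNames(numeric(length(nodes)), nodes)
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    paths <- allPaths(nodes[i], nodes[j])
    if (!length(paths)) next
    lens <- lengths(paths)
    sp <- paths[lens == min(lens)]
    for (p in sp) for (v in setdiff(p, c(nodes[i], nodes[j])))
      oracle[v] <- oracle[v] + 1 / length(sp)
  }
  expect_equal(unname(bcg), unname(oracle), tolerance = 1e-10)
})

test_that("hub selection takes the top fraction with both ranks reported", {
  run <- presetRun()
  hr <- run$hubReport
  expect_s4_class(hr, "HubReport")
  hubs <- hubGenes(hr)
  ## two significant modules, both larger than topK = 100 after annotation:
  ## ceiling(0.1 * 100) = 10 hubs each
  expect_equal(unname(table(hubs$module)),
               rep(10L, length(unique(hubs$module))), ignore_attr = TRUE)
  ## ordering strictly by the sort key
  for (m in unique(hubs$module)) {
    h <- hubs[hubs$module == m, ]
    expect_true(all(diff(h$weightedDegree) <= 1e-12))
    expect_identical(h$rank, seq_len(nrow(h)))
  }

  ## fraction 1 ranks the whole table
  topCol <- moduleColors(run$assignment)[1]
  net <- filterAnnotated(moduleNetwork(run$tom, run$assignment, topCol,
                                       0.02),
                         presetSim()$annotation)
  ct <- centralityTable(topKSubnetwork(net, 100L))
  all <- selectHubs(ct, hubFraction = 1)
  expect_equal(nrow(all), nrow(ct))
  expect_identical(sort(all$rank), seq_len(nrow(ct)))
})

test_that("weighted-degree order equals TOM row sums on a complete module net", {
  run <- presetRun()
  col <- moduleColors(run$assignment)[2]
  net <- moduleNetwork(run$tom, run$assignment, col, threshold = 0)
  wd <- nodeDegree(net, weighted = TRUE)
  lab <- moduleLabels(run$assignment)
  genes <- names(lab)[lab == 2L]
  rs <- rowSums(run$tom[genes, genes]) - 1  # exclude the unit diagonal
  expect_equal(wd[genes], rs, tolerance = 1e-9)
})

test_that("ranking comparison reports set equality and displacements", {
  ra <- setNames(1:6, letters[1:6])
  cmp <- compareRankings(ra, ra, topN = 3)
  expect_true(cmp$sameSet)
  expect_true(all(cmp$displacement == 0))

  rb <- setNames(c(3, 2, 1, 4, 5, 6), letters[1:6])  # reversed top-3
  cmp2 <- compareRankings(ra, rb, topN = 3)
  expect_true(cmp2$sameSet)
  expect_equal(unname(cmp2$displacement[c("a", "c")]), c(2, -2))

  rc <- setNames(c(1, 2, 6, 4, 5, 3), letters[1:6])
  expect_false(compareRankings(ra, rc, topN = 3)$sameSet)
  expect_error(compareRankings(ra, rb[-1]), "same nodes")
})

test_that("near-rank-1 module networks give the same DC and EC top set", {
  run <- presetRun()
  for (m in unique(hubGenes(run$hubReport)$module)) {
    expect_true(run$hubReport@comparisons[[m]]$sameSet)
  }
})
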