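test_that("all-zero rows are removed and counted", {
  m <- matrix(1, 5, 3, dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  m["g3", ] <- 0
  res <- removeZeroGenes(m)
  expect_equal(res$nRemoved, 1L)
  expect_identical(rownames(res$expression), c("g1", "g2", "g4", "g5"))
})

test_that("MAD matches hand computation under both scalings", {
  expect_equal(geneMad(rep(7, 10)), 0)
  ## {1..5}: median 3, abs devs {2,1,0,1,2}, median 1
  expect_equal(geneMad(c(1, 2, 3, 4, 5), scaleConstant = 1), 1)
  expect_equal(geneMad(c(1, 2, 3, 4, 5)), 1.4826)
  expect_error(geneMad(c(1, NaN, 3)), "finite")
  expect_error(geneMad(numeric()), "empty")
})

test_that("the MAD filter keeps the top fraction above the floor", {
  ## 8 genes, MADs {10,9,8,7,6,5,0.005,0.004}: top 75% = 6 genes, all > 0.01
  vals <- c(10, 9, 8, 7, 6, 5, 0.005, 0.004)
  m <- t(vapply(vals, function(v) c(-v, 0, v) / 1.4826 + 10, numeric(3)))
  dimnames(m) <- list(paste0("g", 1:8), paste0("s", 1:3))
  res <- madFilter(m)
  expect_equal(res$report@nRetainedMad, 6L)
  expect_identical(rownames(res$expression), paste0("g", 1:6))

  ## identity when nothing can be filtered
  res2 <- madFilter(m[1:6, ], topFraction = 1, floor = 0)
  expect_identical(res2$expression, m[1:6, ])

  ## all genes constant -> nothing retained
  mc <- matrix(3, 4, 3, dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  expect_equal(madFilter(mc)$report@nRetainedMad, 0L)
})

test_that("filter reports reconcile and violations are caught by validity", {
  r <- madFilter(matrix(runif(30), 10, 3,
                        dimnames = list(paste0("g", 1:10),
                                        paste0("s", 1:3))),
                 nInputGenes = 12L, nZeroRemoved = 2L)$report
  expect_equal(r@nInputGenes, r@nZeroRemoved + r@nAfterZero)
  expect_lte(r@nRetainedMad, r@nAfterZero)
  expect_error(methods::new("FilterReport", nInputGenes = 5L,
                            nZeroRemoved = 1L, nAfterZero = 5L,
                            nRetainedMad = 2L, madFraction = 0.75,
                            madFloor = 0.01),
               "nInputGenes")
})

test_that("Euclidean distance matches a loop oracle and its axioms", {
  expect_equal(euclideanDistance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euclideanDistance(c(0, 3), c(4, 0)), 5)  # 3-4-5 triangle
  expect_error(euclideanDistance(1:3, 1:4), "length")

  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10)
    acc <- 0
    for (k in 1:10) acc <- acc + (x[k] - y[k])^2   # independent loop oracle
    expect_equal(euclideanDistance(x, y), sqrt(acc), tolerance = 1e-12)
    expect_equal(euclideanDistance(x, y), euclideanDistance(y, x))
  }
})

test_that("UPGMA sample clustering merges in the expected order", {
  ## 4 one-gene samples on a line at 0, 1, 10, 11
  m <- matrix(c(0, 1, 10, 11), 1, 4,
              dimnames = list("g1", c("a", "b", "c", "d")))
  m <- rbind(m, m * 0 + 1)  # second constant gene so ncol/nrow are sane
  rownames(m) <- c("g1", "g2")
  hc <- clusterSamples(m)
  merged <- cutree(hc, k = 2)
  expect_equal(unname(merged[c("a", "b")]), c(1, 1))
  expect_equal(unname(merged[c("c", "d")]), c(2, 2))

  ## duplicated samples merge first; the distant one joins last
  m2 <- matrix(c(1, 1, 1, 1, 100, 100), 2, 3,
               dimnames = list(c("g1", "g2"), c("s1", "s2", "out")))
  hc2 <- clusterSamples(m2)
  expect_equal(hc2$height[1], 0)
  expect_equal(unname(cutree(hc2, k = 2)["out"]), 2)
  expect_error(clusterSamples(m2[, 1, drop = FALSE]), "2 samples")
})

test_that("static cut removes exactly the planted outlier and keeps values intact", {
  sim <- presetSim()
  zr <- removeZeroGenes(sim$expression)
  mf <- madFilter(zr$expression)
  hc <- clusterSamples(mf$expression)
  ## the planted outlier is the last-merging leaf
  topSplit <- cutree(hc, k = 2)
  expect_equal(sum(topSplit == topSplit[["EA1"]]), 1L)

  cutH <- suggestCutHeight(hc)
  out <- removeOutlierSamples(hc, mf$expression, sim$trait, cutH)
  expect_identical(out$removed, "EA1")
  expect_equal(ncol(out$expression), 17)
  expect_length(out$trait, 17)
  ## retained entries are untouched
  expect_identical(out$expression, mf$expression[, colnames(out$expression)])

  ## cutting above the root removes nothing
  all <- removeOutlierSamples(hc, mf$expression, sim$trait,
                              max(hc$height) * 2, minClusterSize = 1L)
  expect_length(all$removed, 0)
  ## a cut that removes everything is an error
  expect_error(removeOutlierSamples(hc, mf$expression, sim$trait, 1e-9,
                                    minClusterSize = 3L),
               "every sample")
})

test_that("planted zero and low-MAD genes are exactly the filtered ones", {
  sim <- presetSim()
  zr <- removeZeroGenes(sim$expression)
  expect_setequal(setdiff(rownames(sim$expression), rownames(zr$expression)),
                  sim$truth@zeroGeneIds)
  mf <- madFilter(zr$expression)
  expect_setequal(setdiff(rownames(zr$expression), rownames(mf$expression)),
                  sim$truth@lowMadGeneIds)
  ## survivor order equals input order
  expect_identical(rownames(mf$expression),
                   rownames(sim$expression)[rownames(sim$expression) %in%
                                              rownames(mf$expression)])
})
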