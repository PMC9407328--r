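test_that("the eigengene matches a rank-1 module and an independent oracle", {
  set.seed(5)
  ## single gene: eigengene is that gene standardized
  x <- matrix(rnorm(8), 1, 8, dimnames = list("g1", paste0("s", 1:8)))
  e <- moduleEigengene(x)
  expect_equal(unname(e), as.vector(scale(x[1, ])), tolerance = 1e-12)

  ## identical genes: the common standardized profile
  xx <- rbind(g1 = x[1, ], g2 = x[1, ], g3 = x[1, ])
  expect_equal(unname(moduleEigengene(xx)), as.vector(scale(x[1, ])),
               tolerance = 1e-12)

  ## random module vs an independent spectral oracle (eigen on the sample
  ## covariance of the standardized matrix, a different code path than svd)
  m <- matrix(rexp(6 * 10), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  e6 <- moduleEigengene(m)
  std <- t(scale(t(m)))
  ev <- eigen(crossprod(std), symmetric = TRUE)$vectors[, 1]
  oracle <- ev * sqrt(10 - 1) / sqrt(sum(ev^2))
  if (sum(oracle * colMeans(std)) < 0) oracle <- -oracle
  expect_equal(unname(e6), oracle, tolerance = 1e-10)

  ## unit sample variance and the sign rule
  expect_equal(var(e6), 1, tolerance = 1e-12)
  expect_gte(cor(e6, colMeans(std)), 0)
  expect_error(moduleEigengene(m[, 1, drop = FALSE]), "2 samples")
})

test_that("the Student correlation p-value matches its closed forms", {
  expect_equal(corPvalueStudent(0, 17), 1)
  expect_equal(corPvalueStudent(1, 9), 0)
  expect_equal(corPvalueStudent(-1, 9), 0)
  expect_error(corPvalueStudent(0.5, 2), "n >= 3")

  ## r = 0.8, n = 17: t = 0.8 * sqrt(15) / 0.6 = 5.16398 on 15 df
  t <- 0.8 * sqrt(15) / sqrt(1 - 0.64)
  expect_equal(t, 5.16398, tolerance = 1e-5)
  ## independent tail route: p = I_{1-r^2}((n-2)/2, 1/2) (incomplete beta)
  pBeta <- pbeta(1 - 0.8^2, 15 / 2, 1 / 2)
  expect_equal(corPvalueStudent(0.8, 17), pBeta, tolerance = 1e-12)

  ## monotone in |r| for fixed n, and in n for fixed |r| > 0
  rs <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(corPvalueStudent(rs, 12)) < 0))
  ns <- c(5, 10, 20, 50, 200)
  expect_true(all(diff(vapply(ns, function(n) corPvalueStudent(0.4, n),
                              numeric(1))) < 0))
})

test_that("null module-trait p-values are uniform, not inflated", {
  set.seed(99)
  ps <- replicate(200, {
    e <- rnorm(17); tr <- rnorm(17)
    corPvalueStudent(cor(e, tr), 17)
  })
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
  expect_lt(mean(ps < 0.05), 0.10)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("module-trait relation flags exactly the planted trait modules", {
  run <- presetRun(); sim <- presetSim()
  mt <- run$moduleTrait
  expect_true(all(abs(mt$r) <= 1))
  expect_true(all(mt$p > 0 | abs(mt$r) == 1))
  expect_equal(unique(mt$n), 17)

  sig <- run$significantModules
  planted <- sort(unname(vapply(sig,
                                function(col) plantedModuleOf(run, sim, col),
                                integer(1))))
  expect_equal(planted, c(1L, 3L))
  nonsig <- setdiff(mt$module, sig)
  expect_true(all(mt$p[mt$module %in% nonsig] > 0.05))

  ## a trait equal to an eigengene gives r = 1, p = 0 for that module
  fakeTrait <- run$eigengenes[, 1] - min(run$eigengenes[, 1])
  mt1 <- moduleTraitRelation(run$eigengenes, fakeTrait)
  expect_equal(mt1$r[1], 1, tolerance = 1e-12)
  expect_equal(mt1$p[1], 0)

  expect_error(moduleTraitRelation(run$eigengenes, run$trait[-1]), "missing")
})

test_that("selection orders by p and never returns grey", {
  mt <- data.frame(module = c("blue", "grey", "tan", "cyan"),
                   r = c(0.9, 0.95, 0.5, 0.7),
                   p = c(0.001, 1e-5, 0.2, 0.01), n = 17)
  expect_identical(selectSignificantModules(mt), c("blue", "cyan"))
  expect_identical(selectSignificantModules(mt, alpha = 1e-4), character())
})

test_that("GS and MM behave at their fixed points and correlate in a module", {
  run <- presetRun()
  gs <- run$geneStats
  expect_true(all(gs$GS >= 0 & gs$GS <= 1))
  expect_true(all(abs(gs$MM) <= 1, na.rm = TRUE))
  expect_true(all(is.na(gs$MM[gs$module == "grey"])))

  ## gene identical to the trait -> GS = 1; identical to eigengene -> MM = 1
  e1 <- run$eigengenes[, 1]
  expr <- rbind(gTrait = unname(run$trait) + 1,
                gEig = e1 - min(e1) + 1)
  colnames(expr) <- names(run$trait)
  asn <- assignModuleColors(setNames(c(0L, 1L), rownames(expr)))
  eig1 <- matrix(e1, ncol = 1,
                 dimnames = list(names(e1), moduleColors(asn)))
  st <- geneTraitStats(expr, run$trait, eig1, asn)
  expect_equal(st$GS[st$gene == "gTrait"], 1, tolerance = 1e-12)
  expect_equal(abs(st$MM[st$gene == "gEig"]), 1, tolerance = 1e-12)

  ## within the strongest trait module, GS and MM correlate significantly
  top <- run$significantModules[1]
  inMod <- gs[gs$module == top, ]
  ct <- cor.test(inMod$GS, abs(inMod$MM))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)
})

test_that("eigengene network satisfies its algebraic identity", {
  run <- presetRun()
  en <- run$eigengeneNetwork
  expect_equal(en$adjacency, 1 - en$dissimilarity / 2, tolerance = 1e-15)
  expect_equal(unname(diag(en$adjacency)), rep(1, ncol(en$adjacency)))
  expect_equal(unname(diag(en$dissimilarity)), rep(0, ncol(en$adjacency)))

  ## perfectly correlated / anticorrelated eigengenes
  e <- cbind(a = 1:6, b = 1:6, c = 6:1) + 0
  en2 <- eigengeneNetwork(e)
  expect_equal(en2$dissimilarity["a", "b"], 0)
  expect_equal(en2$adjacency["a", "b"], 1)
  expect_equal(en2$dissimilarity["a", "c"], 2)
  expect_equal(en2$adjacency["a", "c"], 0)
})

test_that("trait modules are selected consistently across 50 generator seeds", {
  ## module-trait stage on the planted partition (network detection is
  ## exercised elsewhere; this isolates the selection operating
  ## characteristics)
  hits <- matrix(NA, 50, 5)
  for (s in 1:50) {
    sim <- simulateWaxDataset(seed = s + 1000)
    zr <- removeZeroGenes(sim$expression)
    mf <- madFilter(zr$expression)
    hc <- clusterSamples(mf$expression)
    out <- removeOutlierSamples(hc, mf$expression, sim$trait,
                                suggestCutHeight(hc))
    part <- truthModulePartition(sim$truth, rownames(out$expression))
    asn <- assignModuleColors(part)
    eig <- moduleEigengenes(out$expression, asn)
    mt <- moduleTraitRelation(eig, out$trait)
    sig <- selectSignificantModules(mt)
    ## map each planted module to its color under the truth assignment
    for (m in 1:5) {
      col <- geneColors(asn)[names(part)[part == m][1]]
      hits[s, m] <- col %in% sig
    }
  }
  traitRate <- colMeans(hits[, c(1, 3)])
  otherRate <- colMeans(hits[, c(2, 4, 5)])
  expect_true(all(traitRate >= 0.95))
  expect_true(all(otherRate <= 0.10))
})
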