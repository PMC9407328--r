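#' Simulate a wax-scale-insect style expression study
#'
#' Generates an FPKM expression matrix, a wax-secretion trait table, a
#' partial Swiss-Prot style annotation table and the planted ground truth,
#' with the statistical structure the coexpression analysis assumes: a
#' balanced multi-condition design with replicates, latent-factor gene
#' modules with graded loadings (so hub identity is unambiguous), a trait
#' driven by a subset of modules, planted all-zero and near-constant genes,
#' an optional global-shift outlier sample, and partial annotation coverage.
#'
#' @details
#' The model works on the log scale. Each module `m` has a condition-level
#' latent profile; the profiles of different modules are drawn mutually
#' orthonormal (QR decomposition of a centred Gaussian matrix), which keeps
#' planted modules distinguishable at any seed. The profile is repeated
#' across the replicates of each condition with a small replicate jitter
#' (sd `0.1 * factorSd`) to give per-sample factors `f[m, s]`. A gene `g` of module `m`
#' with loading `lambda_g` has
#' `log FPKM = mu_g + lambda_g * f[m, s] + eps`, `eps ~ N(0, noiseSd^2)`,
#' with gene baselines `mu_g ~ N(log 20, 1)`; background genes are pure
#' noise around their baseline. FPKM values are the exponentials, so the
#' pipeline (which never log-transforms) still sees strongly correlated
#' module genes. Loadings decrease within a module with a deliberate gap
#' between the `nHubs` hub genes (0.90--1) and the remaining members
#' (0.32--0.42), large enough that correlation-based centrality ranks the
#' hubs first despite estimation noise at the design's sample size. The trait is
#' `base + sum_m c_m * f[m, s] + eta`, `eta ~ N(0, traitNoiseSd^2)`,
#' in mg/individual, truncated at zero. If `outlier = TRUE` one replicate
#' of the third condition (sample `"EA1"` under the default naming) is
#' multiplied by a large global factor, which separates it cleanly in a
#' Euclidean sample dendrogram. Planted hub genes are always annotated;
#' the remaining annotated genes are a random draw to reach
#' `annotationFrac` coverage.
#'
#' @param nConditions,nReps experimental design; 6 conditions x 3 replicates
#'   by default. With 6 conditions the samples are named FF/SF/EA/LA/FM/SM
#'   1..3 (instar/sex groups of the study design this emulates).
#' @param nGenes total genes.
#' @param moduleSizes sizes of the planted modules; their sum plus the
#'   planted zero/low-MAD genes must not exceed `nGenes`. At most
#'   `nConditions - 1` modules can be planted (their condition profiles are
#'   orthogonalized).
#' @param noiseSd per-gene log-scale noise sd.
#' @param factorSd per-condition sd of the latent factors on the log scale.
#'   The default 0.5 keeps module expression swings in a realistic FPKM
#'   range (about an e-fold up or down for the strongest genes) and the
#'   exponentiation mild enough that raw-scale correlations stay close to
#'   the planted log-scale ones.
#' @param traitModules indices of the modules that drive the trait.
#' @param traitNoiseSd trait noise sd (mg/individual).
#' @param zeroGeneFrac fraction of genes planted as all-zero rows.
#' @param lowMadFrac fraction of genes planted as near-constant rows
#'   (MAD well below 0.01).
#' @param annotationFrac fraction of genes with a synthetic Swiss-Prot
#'   annotation.
#' @param outlier plant the global-shift outlier sample?
#' @param nHubs planted hub genes per module.
#' @param hubLoading,memberLoading loading ranges (start, end) for the hub
#'   genes and the remaining members of each module; the gap between the
#'   two keeps hub identity unambiguous.
#' @param seed integer seed; the same seed reproduces the dataset bitwise.
#' @return a list with elements `expression` (genes x samples FPKM matrix),
#'   `trait` (named vector, mg/individual), `annotation` (data.frame) and
#'   `truth` (a \linkS4class{SyntheticTruth}).
#' @examples
#' sim <- simulateWaxDataset(nGenes = 300, moduleSizes = c(60, 40),
#'                           traitModules = 1, seed = 7)
#' dim(sim$expression)
#' sim$truth
#' @export
simulateWaxDataset <- function(nConditions = 6L, nReps = 3L, nGenes = 2000L,
                               moduleSizes = c(300L, 200L, 150L, 120L, 100L),
                               noiseSd = 0.10, traitModules = c(1L, 3L),
                               traitNoiseSd = 0.25, zeroGeneFrac = 0.10,
                               lowMadFrac = 0.225, annotationFrac = 0.8,
                               outlier = TRUE, nHubs = 10L, factorSd = 0.5,
                               hubLoading = c(1.0, 0.90),
                               memberLoading = c(0.42, 0.32), seed = 1L) {
  nConditions <- as.integer(nConditions); nReps <- as.integer(nReps)
  nGenes <- as.integer(nGenes); moduleSizes <- as.integer(moduleSizes)
  nModules <- length(moduleSizes)
  for (f in c(zeroGeneFrac, lowMadFrac, annotationFrac))
    if (f < 0 || f > 1) stop("fractions must be in [0, 1]")
  if (any(moduleSizes < 1)) stop("module sizes must be positive")
  if (nModules > nConditions - 1L)
    stop("at most nConditions - 1 modules can be planted")
  if (length(traitModules) && any(!traitModules %in% seq_len(nModules)))
    stop("traitModules must index the planted modules")
  nZero <- round(zeroGeneFrac * nGenes)
  nLow <- round(lowMadFrac * nGenes)
  nBackground <- nGenes - sum(moduleSizes) - nZero - nLow
  if (nBackground < 0)
    stop("infeasible sizes: modules + zero + low-MAD genes exceed nGenes")

  set.seed(as.integer(seed))
  condNames <- if (nConditions == 6L) c("FF", "SF", "EA", "LA", "FM", "SM")
               else sprintf("C%d", seq_len(nConditions))
  sampleIds <- as.vector(t(outer(condNames, seq_len(nReps), paste0)))
  condOf <- rep(seq_len(nConditions), each = nReps)
  nSamples <- length(sampleIds)
  geneIds <- sprintf("G%05d", seq_len(nGenes))

  ## gene roles, scattered over the matrix: k = module index, -1 zero,
  ## -2 near-constant, 0 background
  roles <- sample(c(rep(seq_len(nModules), moduleSizes),
                    rep(-1L, nZero), rep(-2L, nLow), rep(0L, nBackground)))

  ## condition-level factors, orthonormal and orthogonal to the constant
  ## vector (=> mean zero), scaled to per-condition sd = factorSd
  F0 <- matrix(stats::rnorm(nConditions * nModules), nConditions, nModules)
  Q <- qr.Q(qr(cbind(1, F0)))[, -1, drop = FALSE]
  Q <- sweep(Q, 2, sign(Q[1, ] + (Q[1, ] == 0)), "*")
  condFactor <- Q * sqrt(nConditions - 1) * factorSd
  ## per-sample factors: condition profile + small replicate jitter
  fac <- t(condFactor[condOf, , drop = FALSE]) +
    matrix(stats::rnorm(nModules * nSamples, 0, 0.1 * factorSd),
           nModules, nSamples)
  dimnames(fac) <- list(NULL, sampleIds)

  ## loadings: decreasing within module, gap between hubs and the rest
  loading <- numeric(nGenes)
  plantedHubIds <- vector("list", nModules)
  for (m in seq_len(nModules)) {
    idx <- which(roles == m)
    s <- length(idx)
    h <- min(nHubs, s)
    lam <- c(seq(hubLoading[1], hubLoading[2], length.out = h),
             if (s > h) seq(memberLoading[1], memberLoading[2],
                            length.out = s - h))
    loading[idx] <- lam
    plantedHubIds[[m]] <- geneIds[idx[seq_len(h)]]
  }

  mu <- stats::rnorm(nGenes, log(20), 1)
  logExpr <- matrix(0, nGenes, nSamples, dimnames = list(geneIds, sampleIds))
  for (m in seq_len(nModules)) {
    idx <- which(roles == m)
    logExpr[idx, ] <- mu[idx] + outer(loading[idx], rep(1, nSamples)) *
      matrix(fac[m, ], length(idx), nSamples, byrow = TRUE) +
      matrix(stats::rnorm(length(idx) * nSamples, 0, noiseSd),
             length(idx), nSamples)
  }
  ## background: independent biological noise, sd 0.3 on the log scale --
  ## the replicate-level variability of a non-regulated gene. Keeping it
  ## mild also keeps raw-scale FPKM correlations light-tailed, so the
  ## background does not form shared-outlier pseudo-modules.
  bg <- which(roles == 0L)
  if (length(bg))
    logExpr[bg, ] <- mu[bg] +
      matrix(stats::rnorm(length(bg) * nSamples, 0, 0.3), length(bg), nSamples)
  fpkm <- exp(logExpr)

  low <- which(roles == -2L)
  if (length(low)) {
    lev <- stats::runif(length(low), 0.5, 5)
    fpkm[low, ] <- pmax(lev + matrix(stats::rnorm(length(low) * nSamples,
                                                  0, 1e-4),
                                     length(low), nSamples), 0)
  }
  zero <- which(roles == -1L)
  fpkm[zero, ] <- 0

  outlierIds <- character()
  if (isTRUE(outlier)) {
    outlierIds <- paste0(condNames[min(3L, nConditions)], 1L)
    fpkm[, outlierIds] <- fpkm[, outlierIds] * exp(1.5)
  }

  traitCoefficients <- numeric(nModules)
  traitCoefficients[traitModules] <- 2
  trait <- pmax(20 + as.vector(crossprod(fac / factorSd, traitCoefficients)) +
                  stats::rnorm(nSamples, 0, traitNoiseSd), 0)
  names(trait) <- sampleIds

  nAnnot <- round(annotationFrac * nGenes)
  hubGeneIds <- unlist(plantedHubIds)
  pool <- setdiff(geneIds, hubGeneIds)
  extra <- sample(pool, max(0L, nAnnot - length(hubGeneIds)))
  annotated <- geneIds[geneIds %in% c(hubGeneIds, extra)]
  annotation <- data.frame(
    gene_id = annotated,
    swissprot_id = sprintf("P%05d", match(annotated, geneIds)),
    description = sprintf("synthetic protein %s", annotated),
    stringsAsFactors = FALSE)

  moduleOfGene <- ifelse(roles > 0L, roles, 0L)
  names(moduleOfGene) <- geneIds
  lnamed <- loading; names(lnamed) <- geneIds
  truth <- new("SyntheticTruth",
               moduleOfGene = as.integer(moduleOfGene) |>
                 stats::setNames(geneIds),
               loading = lnamed, factor = fac,
               traitCoefficients = traitCoefficients,
               outlierSampleIds = outlierIds,
               plantedHubIds = plantedHubIds,
               zeroGeneIds = geneIds[zero], lowMadGeneIds = geneIds[low],
               seed = as.integer(seed))
  list(expression = fpkm, trait = trait, annotation = annotation,
       truth = truth)
}

#' Reference module partition from the planted truth
#'
#' Returns the planted gene-to-module labels in the form used to score a
#' detected partition (e.g. with the Adjusted Rand Index): background,
#' all-zero and near-constant genes carry the unassigned label 0.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param genes optional gene IDs to restrict/order the partition by.
#' @return named integer vector of labels.
#' @export
truthModulePartition <- function(truth, genes = NULL) {
  part <- truth@moduleOfGene
  if (!is.null(genes)) {
    missing <- setdiff(genes, names(part))
    if (length(missing))
      stop("genes absent from the truth: ", paste(utils::head(missing, 3),
                                                  collapse = ", "))
    part <- part[genes]
  }
  part
}

#' Save planted ground truth
#'
#' Writes the per-gene truth (module, loading, planted zero/low-MAD/hub
#' status) as a TSV and the non-tabular part (factors, trait coefficients,
#' outlier, seed) as a JSON sidecar.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param tsvPath,jsonPath output paths.
#' @return invisibly, a list with the two paths.
#' @export
writeSyntheticTruth <- function(truth, tsvPath, jsonPath) {
  ids <- names(truth@moduleOfGene)
  df <- data.frame(
    gene_id = ids,
    module = as.integer(truth@moduleOfGene),
    loading = truth@loading[ids],
    zero = ids %in% truth@zeroGeneIds,
    low_mad = ids %in% truth@lowMadGeneIds,
    hub = ids %in% unlist(truth@plantedHubIds))
  utils::write.table(df, tsvPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  side <- list(seed = truth@seed,
               trait_coefficients = truth@traitCoefficients,
               outlier_sample_ids = truth@outlierSampleIds,
               planted_hub_ids = truth@plantedHubIds,
               factor = truth@factor,
               factor_samples = colnames(truth@factor))
  jsonlite::write_json(side, jsonPath, digits = NA, auto_unbox = FALSE)
  invisible(list(tsv = tsvPath, json = jsonPath))
}
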