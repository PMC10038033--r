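## End-to-end synthetic pipeline orchestration: simulate -> preprocess ->
## differential -> regression -> enrichment -> immune scores -> subtyping
## -> survival -> network, with TSV artifacts and a run manifest.

#' Pipeline configuration
#'
#' Bundles the analysis thresholds (transcribed from the standard workflow:
#' p 0.05, |delta| 0.1, 40% missingness, hub degree 10, maxstat minimum
#' group proportion 0.1), the permutation/resampling depths, the synthetic
#' generator settings and the master seed. Every output file records the
#' seed and thresholds in its header, and all randomness derives from the
#' seed, so a config reproduces a run byte for byte.
#'
#' @param seed master integer seed.
#' @param pCut,deltaCut,maxMissing,nesAlpha,hubMinDegree,maxstatMinProp
#'   analysis thresholds.
#' @param nPerm,nResamples permutation and resampling depths.
#' @param k subtype count for consensus clustering.
#' @param nProbes,nTumor,nNormal,fracHyper,fracHypo,deltaMean,noiseSd,
#'   missingRate,nSubtypes synthetic generator settings.
#' @param varEqual,regressionSamples,fdr,clusterer method flags.
#' @param withExpression simulate/use expression (regression, enrichment
#'   and immune-score stages are skipped when \code{FALSE}).
#' @return named list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(seed = 1L, pCut = 0.05, deltaCut = 0.1,
                           maxMissing = 0.4, nesAlpha = 0.05,
                           hubMinDegree = 10, maxstatMinProp = 0.1,
                           nPerm = 200, nResamples = 150, k = 4,
                           nProbes = 3000, nTumor = 32, nNormal = 32,
                           fracHyper = 0.05, fracHypo = 0.05,
                           deltaMean = 0.3, noiseSd = 0.05,
                           missingRate = 0.02, nSubtypes = 4,
                           varEqual = FALSE,
                           regressionSamples = "tumor", fdr = "BH",
                           clusterer = "kmeans", withExpression = TRUE) {
  cfg <- as.list(environment())
  stopifnot(cfg$pCut > 0, cfg$pCut <= 1, cfg$deltaCut >= 0,
            cfg$maxMissing >= 0, cfg$maxMissing <= 1,
            cfg$hubMinDegree >= 1, cfg$maxstatMinProp > 0,
            cfg$maxstatMinProp < 0.5)
  class(cfg) <- "pipelineConfig"
  cfg
}

.hdr <- function(cfg) {
  sprintf("seed=%d pCut=%g deltaCut=%g maxMissing=%g nesAlpha=%g hubMinDegree=%g maxstatMinProp=%g",
          cfg$seed, cfg$pCut, cfg$deltaCut, cfg$maxMissing, cfg$nesAlpha,
          cfg$hubMinDegree, cfg$maxstatMinProp)
}

#' Run the full synthetic pipeline
#'
#' Generates a synthetic methylation experiment with planted truth, then
#' runs every analysis stage and writes all artifacts plus a run manifest
#' (stage log with probe/gene counts after each filter) under
#' \code{outDir}. The run is fully deterministic for a fixed config: two
#' runs with the same config produce byte-identical files. When
#' \code{config$withExpression} is \code{FALSE}, the regression, enrichment
#' and immune-score stages are skipped with a logged reason and the
#' methylation-only outputs are still produced.
#'
#' @param outDir output directory (created if needed).
#' @param config a \code{\link{pipelineConfig}}.
#' @return invisibly, a list with the in-memory stage results.
#' @export
runPipeline <- function(outDir, config = pipelineConfig()) {
  stopifnot(inherits(config, "pipelineConfig"))
  cfg <- config
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hdr <- .hdr(cfg)
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))

  ## --- simulate -------------------------------------------------------
  sim <- simulateMethylation(
    nProbes = cfg$nProbes, nTumor = cfg$nTumor, nNormal = cfg$nNormal,
    fracHyper = cfg$fracHyper, fracHypo = cfg$fracHypo,
    deltaMean = cfg$deltaMean, noiseSd = cfg$noiseSd,
    missingRate = cfg$missingRate, nSubtypes = cfg$nSubtypes,
    seed = cfg$seed)
  mexp <- sim$experiment
  truth <- sim$truth
  writeMatrixTsv(betaValues(mexp), file.path(outDir, "beta.tsv"),
                 idColumn = "probe_id", header = hdr)
  writeTableTsv(probeAnnotation(mexp), file.path(outDir, "annotation.tsv"),
                header = hdr)
  writeTableTsv(sampleSheet(mexp), file.path(outDir, "sample_sheet.tsv"),
                header = hdr)
  writeTruth(truth["differential_probes"],
             file.path(outDir, "truth.json"))
  note("simulate: ", nrow(mexp), " probes, ", ncol(mexp), " samples, ",
       nrow(truth$differential_probes), " planted differential probes")

  ## --- preprocess -----------------------------------------------------
  filt <- filterProbes(mexp)
  note("filterProbes: ", nrow(filt), "/", nrow(mexp), " probes kept")
  filt <- filterImputeMissing(filt, maxMissing = cfg$maxMissing)
  note("filterImputeMissing: ", nrow(filt), " probes kept, 0 missing cells")
  ann <- probeAnnotation(filt)
  sheet <- sampleSheet(filt)
  beta <- betaValues(filt)
  pm <- mapPromoterProbes(ann)
  note("mapPromoterProbes: ", length(pm), " genes with promoter probes")

  ## --- differential methylation ---------------------------------------
  dm <- differentialMethylation(filt, pCut = cfg$pCut,
                                deltaCut = cfg$deltaCut,
                                varEqual = cfg$varEqual)
  writeTableTsv(dm, file.path(outDir, "diffmeth.tsv"), header = hdr)
  ctx <- contextSummary(dm, ann)
  writeTableTsv(ctx$region, file.path(outDir, "context_region.tsv"),
                header = hdr)
  writeTableTsv(ctx$island, file.path(outDir, "context_island.tsv"),
                header = hdr)
  gl <- suppressMessages(geneLevelDifferential(dm, pm))
  writeTableTsv(gl, file.path(outDir, "gene_level.tsv"), header = hdr)
  note("diffmeth: ", sum(dm$status == "hyper"), " hyper, ",
       sum(dm$status == "hypo"), " hypo of ", nrow(dm), " probes")

  reg <- ranking <- enr <- scores <- NULL
  tumorIds <- sheet$sample_id[sheet$condition == "tumor"]
  if (isTRUE(cfg$withExpression)) {
    ## --- expression + regression --------------------------------------
    planted <- truth$differential_probes$probe_id
    regGenes <- list()
    for (g in names(pm)) {
      hit <- intersect(pm[[g]], planted)
      hit <- intersect(hit, rownames(beta))
      if (length(hit))  # methylation represses: negative planted coefficients
        regGenes[[g]] <- stats::setNames(rep(-2, length(hit)), hit)
    }
    expr <- simulateExpression(beta, regGenes,
                               unregulatedGenes = names(pm),
                               includeImmuneGenes = TRUE,
                               seed = cfg$seed + 101L)
    writeMatrixTsv(expr, file.path(outDir, "expression.tsv"),
                   idColumn = "gene", header = hdr)
    note("simulateExpression: ", nrow(expr), " genes (",
         length(regGenes), " methylation-regulated)")
    geneDelta <- stats::setNames(gl$mean_delta, gl$gene)
    reg <- suppressMessages(fitGeneRegression(
      expr, beta, pm, sheet, pCut = cfg$pCut,
      samples = cfg$regressionSamples, geneDelta = geneDelta))
    regOut <- reg[setdiff(colnames(reg), "coefficients")]
    regOut$coefficients <- vapply(reg$coefficients, function(cf)
      paste(sprintf("%s=%.6g", names(cf), cf), collapse = ";"),
      character(1))
    writeTableTsv(regOut, file.path(outDir, "regression.tsv"),
                  header = hdr)
    note("fitGeneRegression: ", nrow(reg), " genes fitted, ",
         sum(reg$significant), " significant")
    ranking <- rankGenes(reg[!is.na(reg$rs), c("gene", "rs")])
    writeRnk(ranking, file.path(outDir, "ranking.rnk"))

    ## --- enrichment ----------------------------------------------------
    set.seed(cfg$seed + 202L)
    universe <- ranking$gene
    hypoGenes <- reg$gene[reg$delta < 0 & reg$gene %in% names(regGenes)]
    sets <- list()
    if (length(hypoGenes) >= 5)
      sets$PLANTED_HYPO_REGULATED <- hypoGenes
    for (i in 1:5)
      sets[[sprintf("RANDOM_SET_%d", i)]] <-
        sample(universe, min(25, max(5, length(universe) %/% 10)))
    writeGmt(sets, file.path(outDir, "gene_sets.gmt"))
    enr <- runEnrichment(ranking, sets, nPerm = cfg$nPerm, fdr = cfg$fdr,
                         seed = cfg$seed + 303L)
    enrOut <- enr[setdiff(colnames(enr), "leading_edge")]
    writeTableTsv(enrOut, file.path(outDir, "enrichment.tsv"),
                  header = hdr)
    note("runEnrichment: ", nrow(enr), " sets, ",
         sum(enr$p_adjusted <= cfg$nesAlpha), " significant")

    ## --- immune scores -------------------------------------------------
    set.seed(cfg$seed + 404L)
    subt <- truth$subtype_labels
    tmb <- stats::setNames(
      stats::rlnorm(length(tumorIds), meanlog = 2, sdlog = 0.4),
      tumorIds)
    if (!is.null(subt))  # lower TMB in subtype 2, the hypomethylated-like arm
      tmb[names(subt)[subt == 2]] <- tmb[names(subt)[subt == 2]] * 0.6
    scores <- immuneScoreTable(expr[, tumorIds, drop = FALSE], tmb = tmb)
    writeTableTsv(scores, file.path(outDir, "immune_scores.tsv"),
                  header = hdr)
    note("immuneScoreTable: ", nrow(scores), " tumor samples scored")
  } else {
    note("expression stages skipped: withExpression = FALSE")
  }

  ## --- subtyping ------------------------------------------------------
  subtype <- NULL
  diffProbes <- dm$probe_id[dm$status != "ns"]
  if (length(diffProbes) >= 5 && length(tumorIds) >= 2 * cfg$k) {
    feats <- beta[diffProbes, tumorIds, drop = FALSE]
    subtype <- consensusCluster(feats, k = cfg$k,
                                nResamples = cfg$nResamples,
                                clusterer = cfg$clusterer,
                                seed = cfg$seed + 505L)
    writeMatrixTsv(consensusMatrix(subtype),
                   file.path(outDir, "consensus_matrix.tsv"),
                   idColumn = "sample_id", header = hdr)
    asn <- clusterAssignments(subtype)
    writeTableTsv(data.frame(sample_id = names(asn), cluster = asn),
                  file.path(outDir, "assignments.tsv"), header = hdr)
    note("consensusCluster: k=", cfg$k, " on ", length(diffProbes),
         " differential probes")
    cmpIn <- data.frame(sample_id = tumorIds,
                        mean_beta = colMeans(feats),
                        stringsAsFactors = FALSE)
    if (!is.null(scores))
      cmpIn <- merge(cmpIn, scores, by = "sample_id", sort = TRUE)
    cmp <- suppressMessages(compareSubtypes(cmpIn, asn))
    writeTableTsv(cmp, file.path(outDir, "subtype_tests.tsv"),
                  header = hdr)
    note("compareSubtypes: ", nrow(cmp), " pairwise tests")
  } else {
    note("subtyping skipped: too few differential probes or samples")
  }

  ## --- survival -------------------------------------------------------
  surv <- NULL
  survProbes <- utils::head(intersect(truth$differential_probes$probe_id,
                                      rownames(beta)), 5)
  if (length(survProbes) == 5 && length(tumorIds) >= 20) {
    survCoefTrue <- stats::setNames(c(2, -2, 1.5, -1.5, 1), survProbes)
    bsub <- beta[survProbes, tumorIds, drop = FALSE]
    riskTrue <- as.numeric(crossprod(survCoefTrue, bsub))
    riskTrue <- riskTrue - mean(riskTrue)
    so <- simulateSurvival(stats::setNames(riskTrue, tumorIds),
                           baselineHazard = 0.005, censorRate = 0.2,
                           seed = cfg$seed + 606L)
    fit <- coxRiskScore(bsub, time = so$time, event = so$event)
    grp <- survivalGrouping(fit$scores, so$time, so$event,
                            minProp = cfg$maxstatMinProp)
    lr <- logrankTest(grp)
    writeTableTsv(
      data.frame(sample_id = grp@sampleId, risk_score = grp@riskScore,
                 group = as.character(grp@group), time = grp@time,
                 event = grp@event),
      file.path(outDir, "survival_groups.tsv"),
      header = c(hdr, sprintf("cutoff=%.6g logrank_chisq=%.6g logrank_p=%.6g",
                              riskCutoff(grp), lr$chi_square, lr$p_value)))
    for (g in c("high", "low")) {
      km <- kmCurve(grp@time[grp@group == g], grp@event[grp@group == g])
      writeTableTsv(km, file.path(outDir, sprintf("km_%s.tsv", g)),
                    header = hdr)
    }
    surv <- list(fit = fit, grouping = grp, logrank = lr)
    note("survival: cutoff=", signif(riskCutoff(grp), 4),
         ", logrank p=", signif(lr$p_value, 4))
  } else {
    note("survival skipped: insufficient planted probes or samples")
  }

  ## --- network --------------------------------------------------------
  seeds <- utils::head(sort(unique(unlist(
    strsplit(ann$genes, ";", fixed = TRUE)))), 60)
  ppi <- simulatePpi(nBackground = 300, seedGenes = seeds, nHubs = 5,
                     hubDegreeMin = max(12, cfg$hubMinDegree + 2),
                     seed = cfg$seed + 707L)
  writeTableTsv(ppi$edges, file.path(outDir, "background_edges.tsv"),
                header = hdr)
  net <- buildSeedNetwork(ppi$edges, seeds)
  writeTableTsv(networkNodes(net), file.path(outDir, "network_nodes.tsv"),
                header = hdr)
  writeTableTsv(networkEdges(net), file.path(outDir, "network_edges.tsv"),
                header = hdr)
  hubs <- extractHubs(net, minDegree = cfg$hubMinDegree)
  writeTableTsv(hubs, file.path(outDir, "hubs.tsv"), header = hdr)
  writeTableTsv(degreeDistribution(net),
                file.path(outDir, "degree_distribution.tsv"), header = hdr)
  note("network: ", nrow(networkNodes(net)), " nodes, ",
       nrow(networkEdges(net)), " edges, ", nrow(hubs), " hubs")

  ## --- manifest -------------------------------------------------------
  manifest <- c(sprintf("# methylImmune pipeline manifest"),
                sprintf("# %s", hdr),
                sprintf("# R %s, methylImmune %s", getRversion(),
                        as.character(utils::packageVersion("methylImmune"))),
                log)
  writeLines(manifest, file.path(outDir, "manifest.txt"))

  invisible(list(experiment = filt, truth = truth, diffmeth = dm,
                 gene_level = gl, regression = reg, ranking = ranking,
                 enrichment = enr, immune_scores = scores,
                 subtype = subtype, survival = surv, network = net,
                 hubs = hubs))
}
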