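## Synthetic-data generators: every input the pipeline consumes, with
## recorded ground truth, so downstream stages are testable offline.

#' Immune gene panels used by the scoring module
#'
#' MHC class I antigen presentation core set (9 genes), cytolytic activity
#' pair (GZMA, PRF1) and cytotoxic T lymphocyte triple (GZMA, GZMB, PRF1).
#' @keywords internal
.MHC_GENES <- c("HLA-A", "PSMB9", "HLA-B", "PSMB8", "HLA-C", "B2M",
                "TAP2", "NLRC5", "TAP1")
.CYT_GENES <- c("GZMA", "PRF1")
.CTL_GENES <- c("GZMA", "GZMB", "PRF1")

## truncated Beta sampler by rejection; bounds are loose enough that
## acceptance is high for the pools used here
.rbeta_trunc <- function(n, shape1, shape2, lo = 0, hi = 1) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rbeta(2L * (n - length(out)) + 10L, shape1, shape2)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Simulate an HM450K-style methylation experiment with planted truth
#'
#' Baseline probe methylation follows a bimodal mixture: a hypomethylated
#' pool Beta(2, 8) and a hypermethylated pool Beta(8, 2), reproducing the
#' two-peaked methylome of 450K arrays. Planted hypermethylation effects are
#' applied to low-pool probes (baseline mean kept at or below 0.5) and
#' planted hypomethylation effects to high-pool probes (baseline at or above
#' 0.7), so that abnormal shifts occur where they are observed in tumours.
#' Tumour samples of planted probes are shifted by \code{+/- deltaMean};
#' per-sample Gaussian noise is added and values clipped to \eqn{[0,1]};
#' missing entries are injected completely at random. Planted probes are
#' always autosomal and never SNP-flagged so they survive probe filtering.
#'
#' When \code{nSubtypes > 1}, tumour samples are partitioned into balanced
#' subtypes and each planted differential probe additionally shifts (in the
#' direction of its effect) in the tumours of one subtype by
#' \code{subtypeDelta}, planting recoverable methylation subtypes on the
#' differential probes.
#'
#' @param nProbes,nTumor,nNormal dimensions of the experiment.
#' @param fracHyper,fracHypo fractions of probes planted as hyper-/
#'   hypomethylated in tumours; must satisfy \code{fracHyper + fracHypo <= 1}.
#' @param deltaMean planted mean tumour-normal beta difference (beta units).
#' @param noiseSd per-sample Gaussian noise sd (beta units), > 0.
#' @param missingRate fraction of cells set missing.
#' @param nSubtypes number of planted tumour subtypes (1 = none).
#' @param subtypeDelta extra within-subtype shift (beta units).
#' @param probesPerGene average promoter size used when assigning probes to
#'   genes.
#' @param seed integer seed; identical seeds reproduce identical output.
#' @return list with elements \code{experiment} (a
#'   \linkS4class{MethylExperiment}) and \code{truth}, a list with
#'   \code{differential_probes} (data.frame probe_id/direction/true_delta),
#'   \code{subtype_labels} (named integer vector over tumour samples, or
#'   \code{NULL}), \code{pools} (probe baseline pool) and
#'   \code{baseline_mean}.
#' @export
simulateMethylation <- function(nProbes, nTumor, nNormal,
                                fracHyper = 0.05, fracHypo = 0.05,
                                deltaMean = 0.3, noiseSd = 0.05,
                                missingRate = 0.0, nSubtypes = 1L,
                                subtypeDelta = 0.2, probesPerGene = 5,
                                seed = 1L) {
  if (nProbes <= 0 || nTumor <= 0 || nNormal <= 0)
    stop("dimensions must be positive")
  if (fracHyper < 0 || fracHypo < 0 || fracHyper > 1 || fracHypo > 1 ||
      fracHyper + fracHypo > 1)
    stop("fractions must lie in [0,1] with fracHyper + fracHypo <= 1")
  if (noiseSd <= 0) stop("noiseSd must be > 0")
  if (missingRate < 0 || missingRate > 1)
    stop("missingRate must lie in [0,1]")
  set.seed(as.integer(seed))

  probes <- sprintf("cg%08d", seq_len(nProbes))
  samples <- c(sprintf("T%04d", seq_len(nTumor)),
               sprintf("N%04d", seq_len(nNormal)))
  condition <- rep(c("tumor", "normal"), c(nTumor, nNormal))

  nHyper <- round(fracHyper * nProbes)
  nHypo <- round(fracHypo * nProbes)
  idxHyper <- if (nHyper) seq_len(nHyper) else integer(0)
  idxHypo <- if (nHypo) nHyper + seq_len(nHypo) else integer(0)

  ## pools: planted hyper probes start low, planted hypo probes start high;
  ## the rest split evenly between the two baseline pools
  pool <- character(nProbes)
  pool[idxHyper] <- "low"
  pool[idxHypo] <- "high"
  rest <- setdiff(seq_len(nProbes), c(idxHyper, idxHypo))
  pool[rest] <- sample(c("low", "high"), length(rest), replace = TRUE)

  base <- numeric(nProbes)
  nLow <- sum(pool == "low"); nHigh <- sum(pool == "high")
  base[pool == "low"] <- .rbeta_trunc(nLow, 2, 8, hi = 0.5)
  base[pool == "high"] <- .rbeta_trunc(nHigh, 8, 2, lo = 0.7)

  delta <- numeric(nProbes)
  delta[idxHyper] <- deltaMean
  delta[idxHypo] <- -deltaMean

  mu <- matrix(base, nProbes, nTumor + nNormal)
  mu[, condition == "tumor"] <- mu[, condition == "tumor"] + delta

  subtypeLabels <- NULL
  if (nSubtypes > 1) {
    subtypeLabels <- rep_len(seq_len(nSubtypes), nTumor)
    names(subtypeLabels) <- samples[condition == "tumor"]
    planted <- c(idxHyper, idxHypo)
    if (length(planted)) {
      markerSubtype <- rep_len(seq_len(nSubtypes), length(planted))
      tumorCols <- which(condition == "tumor")
      for (s in seq_len(nSubtypes)) {
        pr <- planted[markerSubtype == s]
        cols <- tumorCols[subtypeLabels == s]
        mu[pr, cols] <- mu[pr, cols] + sign(delta[pr]) * subtypeDelta
      }
    }
  }

  beta <- mu + matrix(stats::rnorm(length(mu), 0, noiseSd), nrow(mu))
  beta <- pmin(pmax(beta, 0), 1)
  dimnames(beta) <- list(probes, samples)
  if (missingRate > 0)
    beta[stats::runif(length(beta)) < missingRate] <- NA_real_

  ## annotation: genes tile consecutive probes; planted probes stay on
  ## autosomes without SNP flags so probe filtering never removes them
  nGenes <- max(1L, ceiling(nProbes / probesPerGene))
  geneOf <- sprintf("GENE%05d", rep(seq_len(nGenes),
                                    each = probesPerGene)[seq_len(nProbes)])
  region <- sample(.REGION_LEVELS, nProbes, replace = TRUE,
                   prob = c(0.15, 0.05, 0.15, 0.25, 0.2, 0.2))
  chr <- sample(paste0("chr", 1:22), nProbes, replace = TRUE)
  sex <- stats::runif(nProbes) < 0.03
  chr[sex] <- sample(c("chrX", "chrY"), sum(sex), replace = TRUE,
                     prob = c(0.8, 0.2))
  snp <- stats::runif(nProbes) < 0.02
  plantedIdx <- c(idxHyper, idxHypo)
  chr[plantedIdx] <- sample(paste0("chr", 1:22), length(plantedIdx),
                            replace = TRUE)
  snp[plantedIdx] <- FALSE
  annotation <- data.frame(
    probe_id = probes, chr = chr,
    pos = sample.int(5e7, nProbes, replace = TRUE),
    genes = geneOf, regions = region,
    island_relation = sample(.ISLAND_LEVELS, nProbes, replace = TRUE,
                             prob = c(0.3, 0.25, 0.1, 0.35)),
    snp_flag = snp, stringsAsFactors = FALSE)

  sheet <- data.frame(sample_id = samples, condition = condition,
                      cancer_type = "SYNTH", stringsAsFactors = FALSE)

  truthDf <- data.frame(
    probe_id = probes[plantedIdx],
    direction = rep(c("hyper", "hypo"), c(length(idxHyper),
                                          length(idxHypo))),
    true_delta = delta[plantedIdx], stringsAsFactors = FALSE)
  if (nSubtypes > 1 && length(plantedIdx))
    truthDf$subtype <- rep_len(seq_len(nSubtypes), length(plantedIdx))

  list(experiment = MethylExperiment(beta, annotation, sheet),
       truth = list(differential_probes = truthDf,
                    subtype_labels = subtypeLabels,
                    pools = setNames(pool, probes),
                    baseline_mean = setNames(base, probes)))
}

#' Simulate expression regulated by promoter methylation
#'
#' Runs the promoter-regression model forward: for each regulated gene g and
#' sample n, \code{expr = intercept + sum_p coef[g, p] * beta[p, n] + noise};
#' unregulated genes are intercept plus noise. Units are read as
#' log2(RPKM+1). Optionally appends the immune score panel genes (MHC core
#' set, GZMA, GZMB, PRF1) as unregulated rows so downstream immune scoring
#' has its inputs.
#'
#' @param beta probes x samples beta matrix (no missing values for regulated
#'   probes).
#' @param regulatoryGenes named list: gene -> named numeric vector of
#'   coefficients over promoter probe ids present in \code{beta}.
#' @param unregulatedGenes character vector of gene symbols to simulate as
#'   unregulated (intercept plus noise).
#' @param nUnregulated extra anonymous unregulated genes (named GENEU...).
#' @param intercept baseline expression (log2(RPKM+1) units).
#' @param noiseSd Gaussian noise sd (expression units).
#' @param includeImmuneGenes append the immune panel rows.
#' @param seed integer seed.
#' @return genes x samples numeric matrix.
#' @export
simulateExpression <- function(beta, regulatoryGenes = list(),
                               unregulatedGenes = character(0),
                               nUnregulated = 0L, intercept = 5,
                               noiseSd = 0.5, includeImmuneGenes = FALSE,
                               seed = 1L) {
  set.seed(as.integer(seed))
  beta <- as.matrix(beta)
  nS <- ncol(beta)
  allProbes <- unlist(lapply(regulatoryGenes, names))
  if (length(allProbes) && !all(allProbes %in% rownames(beta)))
    stop("regulatoryGenes reference probe id(s) absent from beta")
  rows <- list()
  for (g in names(regulatoryGenes)) {
    coef <- regulatoryGenes[[g]]
    x <- beta[names(coef), , drop = FALSE]
    rows[[g]] <- intercept + as.numeric(crossprod(coef, x))
  }
  extra <- setdiff(unregulatedGenes, names(regulatoryGenes))
  if (nUnregulated > 0)
    extra <- c(extra, sprintf("GENEU%04d", seq_len(nUnregulated)))
  if (includeImmuneGenes)
    extra <- c(extra, unique(c(.MHC_GENES, .CTL_GENES)))
  for (g in extra) rows[[g]] <- rep(intercept, nS)
  if (!length(rows)) stop("nothing to simulate: no genes requested")
  expr <- do.call(rbind, rows)
  expr <- expr + matrix(stats::rnorm(length(expr), 0, noiseSd), nrow(expr))
  dimnames(expr) <- list(names(rows), colnames(beta))
  expr
}

#' Simulate survival outcomes from per-sample risk scores
#'
#' Event times are exponential with hazard
#' \code{baselineHazard * exp(riskScore)}. Censoring is administrative: an
#' independent uniform censoring horizon \code{C ~ U(0, H)} with H solved so
#' that the expected censoring fraction equals \code{censorRate} under the
#' average hazard; \code{censorRate = 0} disables censoring and
#' \code{censorRate = 1} censors every record at time zero.
#'
#' @param riskScores numeric vector of per-sample log-hazard offsets.
#' @param baselineHazard baseline event rate, > 0.
#' @param censorRate expected fraction censored, in \eqn{[0,1]}.
#' @param seed integer seed.
#' @return data.frame with \code{time} and \code{event} (1 = observed).
#' @export
simulateSurvival <- function(riskScores, baselineHazard = 0.01,
                             censorRate = 0.2, seed = 1L) {
  if (baselineHazard <= 0) stop("baselineHazard must be > 0")
  if (censorRate < 0 || censorRate > 1)
    stop("censorRate must lie in [0,1]")
  set.seed(as.integer(seed))
  n <- length(riskScores)
  rate <- baselineHazard * exp(riskScores)
  t_event <- stats::rexp(n, rate)
  if (censorRate == 0) {
    out <- data.frame(time = t_event, event = rep(1, n))
  } else if (censorRate >= 1) {
    out <- data.frame(time = rep(0, n), event = rep(0, n))
  } else {
    lam <- baselineHazard * mean(exp(riskScores))
    ## censoring fraction for horizon H: (1 - exp(-lam H)) / (lam H)
    f <- function(H) (1 - exp(-lam * H)) / (lam * H) - censorRate
    H <- stats::uniroot(f, lower = 1e-8 / lam, upper = 1e8 / lam,
                        tol = 1e-10)$root
    cens <- stats::runif(n, 0, H)
    out <- data.frame(time = pmin(t_event, cens),
                      event = as.numeric(t_event <= cens))
  }
  if (!is.null(names(riskScores))) rownames(out) <- names(riskScores)
  out
}

#' Simulate a background PPI edge list with planted hubs
#'
#' Planted hub genes (drawn from the seed list) each receive at least
#' \code{hubDegreeMin} distinct partners; the remaining nodes get sparse
#' Erdos-Renyi-style background edges with expected degree well below the
#' hub threshold. The edge list is undirected, deduplicated and free of
#' self-loops.
#'
#' @param nBackground number of non-seed background genes.
#' @param seedGenes character vector of seed gene symbols.
#' @param nHubs number of seeds planted as hubs; \code{<= length(seedGenes)}.
#' @param hubDegreeMin guaranteed minimum degree of each planted hub.
#' @param backgroundDegree expected degree of non-hub nodes.
#' @param seed integer seed.
#' @return list with \code{edges} (data.frame from/to) and \code{hub_nodes}
#'   (character vector of planted hubs).
#' @export
simulatePpi <- function(nBackground, seedGenes, nHubs = 0L,
                        hubDegreeMin = 12L, backgroundDegree = 1.5,
                        seed = 1L) {
  if (nHubs > length(seedGenes))
    stop("nHubs exceeds the number of seed genes")
  set.seed(as.integer(seed))
  bg <- sprintf("BG%05d", seq_len(nBackground))
  nodes <- unique(c(seedGenes, bg))
  hubs <- if (nHubs > 0) sample(seedGenes, nHubs) else character(0)
  edges <- list()
  for (h in hubs) {
    partners <- sample(setdiff(nodes, h), hubDegreeMin)
    edges[[h]] <- data.frame(from = h, to = partners,
                             stringsAsFactors = FALSE)
  }
  nRand <- round(backgroundDegree * length(nodes) / 2)
  nonHub <- setdiff(nodes, hubs)
  if (nRand > 0 && length(nonHub) >= 2) {
    a <- sample(nonHub, nRand, replace = TRUE)
    b <- sample(nonHub, nRand, replace = TRUE)
    keep <- a != b
    edges[["bg"]] <- data.frame(from = a[keep], to = b[keep],
                                stringsAsFactors = FALSE)
  }
  e <- do.call(rbind, edges)
  swap <- e$from > e$to
  tmp <- e$from[swap]; e$from[swap] <- e$to[swap]; e$to[swap] <- tmp
  e <- e[!duplicated(paste(e$from, e$to)), , drop = FALSE]
  rownames(e) <- NULL
  list(edges = e, hub_nodes = hubs)
}
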