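## Differential CpG methylation between tumour and normal samples and
## genomic-context summaries of the calls.

## row-wise two-sample t-test, Welch by default; returns p and delta.
## vectorised over probes; zero-variance-in-both-groups rows get p = 1.
.rowTTest <- function(b, isTumor, varEqual = FALSE) {
  x <- b[, isTumor, drop = FALSE]
  y <- b[, !isTumor, drop = FALSE]
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  delta <- mx - my
  if (varEqual) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- rep(nx + ny - 2, length(se))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  tstat <- delta / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  ## zero variance in both groups: t is undefined; define p = 1 rather than
  ## propagate NaN
  p[vx == 0 & vy == 0] <- 1
  data.frame(p_value = p, delta = delta, row.names = rownames(b))
}

#' Call differentially methylated CpG sites
#'
#' Two-sample t-test per probe between tumour and normal beta values with a
#' joint significance/effect-size gate: a probe is \code{hyper} when
#' \code{p <= pCut} and \code{delta >= deltaCut}, \code{hypo} when
#' \code{p <= pCut} and \code{delta <= -deltaCut}, otherwise \code{ns},
#' where \code{delta = mean(tumor) - mean(normal)}. Welch's unequal-variance
#' test is the default (group sizes are rarely balanced); a pooled-variance
#' test is available via \code{varEqual = TRUE}. Probes with zero variance
#' in both groups and no mean difference get \code{p = 1}. No
#' multiple-testing correction is applied at the CpG level (the raw-p +
#' effect-size gate is the standard criterion here); \code{adjust = "BH"}
#' adds a Benjamini-Hochberg column and gates on it instead.
#'
#' @param object a \linkS4class{MethylExperiment} with no missing values
#'   (run \code{\link{filterImputeMissing}} first).
#' @param pCut,deltaCut significance and effect thresholds (defaults 0.05,
#'   0.1).
#' @param varEqual use the pooled-variance t-test.
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return data.frame with columns \code{probe_id}, \code{p_value},
#'   \code{delta}, \code{status} (\code{hyper}/\code{hypo}/\code{ns}), plus
#'   \code{p_adjusted} when \code{adjust = "BH"}.
#' @export
differentialMethylation <- function(object, pCut = 0.05, deltaCut = 0.1,
                                    varEqual = FALSE, adjust = "none") {
  stopifnot(is(object, "MethylExperiment"))
  adjust <- match.arg(adjust, c("none", "BH"))
  b <- betaValues(object)
  if (anyNA(b))
    stop("beta matrix contains missing values; impute first")
  isTumor <- sampleSheet(object)$condition == "tumor"
  nT <- sum(isTumor); nN <- sum(!isTumor)
  if (nT < 2 || nN < 2)
    stop("need at least 2 tumor and 2 normal samples")
  if (nN < 4)
    warning("fewer than 4 normal samples; differential calls may be unstable")
  tt <- .rowTTest(b, isTumor, varEqual = varEqual)
  pGate <- if (adjust == "BH") stats::p.adjust(tt$p_value, "BH")
           else tt$p_value
  status <- rep("ns", nrow(tt))
  status[pGate <= pCut & tt$delta >= deltaCut] <- "hyper"
  status[pGate <= pCut & tt$delta <= -deltaCut] <- "hypo"
  out <- data.frame(probe_id = rownames(b), p_value = tt$p_value,
                    delta = tt$delta, status = status,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (adjust == "BH") out$p_adjusted <- pGate
  out
}

#' Genomic-context summary of differential calls
#'
#' Cross-tabulates hyper-/hypomethylated probes against transcript-region
#' labels and against CpG-island relation, reporting counts and
#' within-status percentages. A probe annotated with k region labels
#' contributes 1/k to each label, so totals are preserved without double
#' counting.
#'
#' @param results output of \code{\link{differentialMethylation}}.
#' @param annotation probe annotation covering every probe in
#'   \code{results}.
#' @return list of two data.frames, \code{region} (status, region, count,
#'   pct) and \code{island} (status, island_relation, count, pct);
#'   percentages are within status.
#' @export
contextSummary <- function(results, annotation) {
  annotation <- as.data.frame(annotation)
  if (!all(results$probe_id %in% annotation$probe_id))
    stop("unannotated probe id(s) in results")
  ann <- annotation[match(results$probe_id, annotation$probe_id), ]
  sig <- results$status %in% c("hyper", "hypo")
  regionTab <- expand.grid(status = c("hyper", "hypo"),
                           region = .REGION_LEVELS,
                           stringsAsFactors = FALSE)
  regionTab$count <- 0
  islandTab <- expand.grid(status = c("hyper", "hypo"),
                           island_relation = .ISLAND_LEVELS,
                           stringsAsFactors = FALSE)
  islandTab$count <- 0
  if (any(sig)) {
    regs <- strsplit(as.character(ann$regions[sig]), ";", fixed = TRUE)
    w <- 1 / lengths(regs)
    long <- data.frame(status = rep(results$status[sig], lengths(regs)),
                       region = unlist(regs),
                       weight = rep(w, lengths(regs)))
    agg <- stats::aggregate(weight ~ status + region, long, sum)
    m <- match(paste(agg$status, agg$region),
               paste(regionTab$status, regionTab$region))
    regionTab$count[m[!is.na(m)]] <- agg$weight[!is.na(m)]
    agg2 <- stats::aggregate(
      list(count = rep(1, sum(sig))),
      list(status = results$status[sig],
           island_relation = ann$island_relation[sig]), sum)
    m2 <- match(paste(agg2$status, agg2$island_relation),
                paste(islandTab$status, islandTab$island_relation))
    islandTab$count[m2[!is.na(m2)]] <- agg2$count[!is.na(m2)]
  }
  pctWithin <- function(tab) {
    tot <- stats::ave(tab$count, tab$status, FUN = sum)
    ifelse(tot > 0, 100 * tab$count / tot, 0)
  }
  regionTab$pct <- pctWithin(regionTab)
  islandTab$pct <- pctWithin(islandTab)
  list(region = regionTab, island = islandTab)
}

#' Summarise differential methylation at the gene/promoter level
#'
#' For each gene with promoter probes surviving upstream filters: the mean
#' promoter-probe delta (the gene-level delta feeding the RS score), counts
#' of hyper/hypo promoter probes, and the fraction of promoter probes called
#' differential. Genes with none of their promoter probes present in the
#' results are omitted with a message.
#'
#' @param results output of \code{\link{differentialMethylation}}.
#' @param promoterMap named list gene -> probe ids (see
#'   \code{\link{mapPromoterProbes}}).
#' @return data.frame with columns \code{gene}, \code{mean_delta},
#'   \code{n_probes}, \code{n_hyper}, \code{n_hypo}, \code{fraction_diff}.
#' @export
geneLevelDifferential <- function(results, promoterMap) {
  if (!length(promoterMap)) stop("promoterMap is empty")
  rows <- lapply(names(promoterMap), function(g) {
    idx <- match(promoterMap[[g]], results$probe_id)
    idx <- idx[!is.na(idx)]
    if (!length(idx)) return(NULL)
    st <- results$status[idx]
    data.frame(gene = g, mean_delta = mean(results$delta[idx]),
               n_probes = length(idx), n_hyper = sum(st == "hyper"),
               n_hypo = sum(st == "hypo"),
               fraction_diff = mean(st != "ns"),
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    message(dropped, " gene(s) had no promoter probes in the results")
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), mean_delta = numeric(),
                      n_probes = integer(), n_hyper = integer(),
                      n_hypo = integer(), fraction_diff = numeric())
  rownames(out) <- NULL
  out
}
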