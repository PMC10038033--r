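## From-scratch pre-ranked gene-set enrichment: weighted Kolmogorov-Smirnov
## running sum, gene-label permutation null, sign-matched NES, BH/FDR-q.

## ES from sorted hit positions without materialising the full running sum.
## The running sum changes slope only at hits, so its extrema occur either
## just before or just after a hit; both candidate sets are O(m).
.esFromPositions <- function(pos, w, N) {
  m <- length(pos)
  pos <- sort(pos)
  hw <- w[pos]
  sw <- sum(hw)
  if (sw == 0) {            # all-zero weights: fall back to unweighted hits
    hw <- rep(1, m); sw <- m
  }
  up <- cumsum(hw) / sw
  missStep <- 1 / (N - m)
  after <- up - (pos - seq_len(m)) * missStep
  before <- c(0, up[-m]) - (pos - 1 - (seq_len(m) - 1)) * missStep
  hi <- max(after, 0)
  lo <- min(before, 0)
  if (hi >= -lo) hi else lo
}

#' Weighted running-sum enrichment score for one gene set
#'
#' Walks the ranked list: positions occupied by set members ("hits")
#' increment the running sum by \code{|rs|^weight} normalised by the total
#' hit weight; non-members decrement it by \code{1/(N - n_hits)}. The
#' enrichment score is the signed extremum of the walk. The leading edge is
#' the set members at or before the extremum for positive ES, and at or
#' after it for negative ES. \code{weight = 0} reduces to the classic
#' unweighted Kolmogorov-Smirnov statistic on ranks.
#'
#' @param ranking data.frame (gene, rs) sorted by decreasing rs (see
#'   \code{\link{rankGenes}}).
#' @param geneSet character vector of member gene symbols.
#' @param weight exponent on \code{|rs|} for hit increments (default 1).
#' @return list with \code{es}, \code{running_sum} (length-N numeric) and
#'   \code{leading_edge} (character).
#' @export
enrichmentScore <- function(ranking, geneSet, weight = 1) {
  if (!nrow(ranking)) stop("empty ranking")
  N <- nrow(ranking)
  hit <- ranking$gene %in% geneSet
  m <- sum(hit)
  if (m == 0) stop("gene set has no overlap with the ranking")
  if (m >= N) stop("gene set covers the whole ranking")
  w <- abs(ranking$rs)^weight
  hw <- w * hit
  sw <- sum(hw)
  if (sw == 0) { hw <- as.numeric(hit); sw <- m }
  step <- hw / sw - (!hit) / (N - m)
  rsum <- cumsum(step)
  hi <- max(rsum, 0); lo <- min(rsum, 0)
  es <- if (hi >= -lo) hi else lo
  if (es >= 0) {
    peak <- which.max(rsum)
    le <- ranking$gene[seq_len(peak)][hit[seq_len(peak)]]
  } else {
    trough <- which.min(rsum)
    idx <- trough:N
    le <- ranking$gene[idx][hit[idx]]
  }
  list(es = es, running_sum = rsum, leading_edge = le)
}

#' Permutation-normalised enrichment over a gene-set collection
#'
#' For each set, a null ES distribution is built from \code{nPerm} random
#' gene-label draws at the same set size. NES normalises the observed ES by
#' the mean |null ES| of matching sign (positive and negative nulls are
#' normalised separately, as in published pre-ranked GSEA); the nominal p is
#' the one-sided permutation fraction of matching sign with add-one
#' smoothing (minimum p = 1/(nPerm+1)); the adjusted p is Benjamini-Hochberg
#' across sets by default, or the permutation FDR q-value with
#' \code{fdr = "qvalue"}. Fixed seed gives bitwise-identical output.
#'
#' @param ranking data.frame (gene, rs) sorted by decreasing rs.
#' @param geneSets named list of character vectors (e.g. from
#'   \code{\link{readGmt}}).
#' @param weight hit-weight exponent (default 1).
#' @param nPerm number of permutations, >= 100 (default 1000).
#' @param fdr \code{"BH"} (default) or \code{"qvalue"} (GSEA-style
#'   permutation FDR on NES).
#' @param seed integer seed for the permutation null.
#' @return data.frame with columns \code{set_name}, \code{n_hits},
#'   \code{es}, \code{nes}, \code{p_nominal}, \code{p_adjusted} and list
#'   column \code{leading_edge}, ordered as the input collection.
#' @export
runEnrichment <- function(ranking, geneSets, weight = 1, nPerm = 1000,
                          fdr = c("BH", "qvalue"), seed = 1L) {
  fdr <- match.arg(fdr)
  if (nPerm < 100) stop("nPerm must be at least 100")
  N <- nrow(ranking)
  w <- abs(ranking$rs)^weight
  set.seed(as.integer(seed))
  res <- lapply(names(geneSets), function(nm) {
    members <- geneSets[[nm]]
    m <- sum(ranking$gene %in% members)
    if (m == 0) {
      message("set ", nm, ": no overlap with ranking, skipped")
      return(NULL)
    }
    if (m >= N) stop("set ", nm, " covers the whole ranking")
    obs <- enrichmentScore(ranking, members, weight)
    null <- vapply(seq_len(nPerm), function(i)
      .esFromPositions(sample.int(N, m), w, N), numeric(1))
    pos <- null[null >= 0]; neg <- null[null < 0]
    if (obs$es >= 0) {
      nes <- if (length(pos) && mean(pos) > 0) obs$es / mean(pos) else NA_real_
      p <- (1 + sum(pos >= obs$es)) / (1 + length(pos))
    } else {
      nes <- if (length(neg)) obs$es / mean(abs(neg)) else NA_real_
      p <- (1 + sum(neg <= obs$es)) / (1 + length(neg))
    }
    nullNes <- c(if (length(pos) && mean(pos) > 0) pos / mean(pos),
                 if (length(neg)) neg / mean(abs(neg)))
    list(set_name = nm, n_hits = m, es = obs$es, nes = nes,
         p_nominal = p, leading_edge = obs$leading_edge,
         null_nes = nullNes)
  })
  res <- Filter(Negate(is.null), res)
  if (!length(res))
    return(data.frame(set_name = character(), n_hits = integer(),
                      es = numeric(), nes = numeric(),
                      p_nominal = numeric(), p_adjusted = numeric()))
  out <- data.frame(
    set_name = vapply(res, `[[`, character(1), "set_name"),
    n_hits = vapply(res, `[[`, numeric(1), "n_hits"),
    es = vapply(res, `[[`, numeric(1), "es"),
    nes = vapply(res, `[[`, numeric(1), "nes"),
    p_nominal = vapply(res, `[[`, numeric(1), "p_nominal"),
    stringsAsFactors = FALSE, row.names = NULL)
  if (fdr == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_nominal, "BH")
  } else {
    ## permutation FDR q: fraction of pooled null NES at least as extreme,
    ## relative to the fraction of observed NES at least as extreme
    allNull <- unlist(lapply(res, `[[`, "null_nes"))
    out$p_adjusted <- vapply(seq_len(nrow(out)), function(i) {
      nes <- out$nes[i]
      if (is.na(nes)) return(NA_real_)
      if (nes >= 0) {
        num <- mean(allNull >= nes)
        den <- mean(out$nes >= nes, na.rm = TRUE)
      } else {
        num <- mean(allNull <= nes)
        den <- mean(out$nes <= nes, na.rm = TRUE)
      }
      min(1, num / max(den, 1e-12))
    }, numeric(1))
    out$p_adjusted <- pmax(out$p_adjusted, out$p_nominal)
  }
  out$leading_edge <- lapply(res, `[[`, "leading_edge")
  out
}

#' Immune-cell marker-set enrichment with differential-marker fractions
#'
#' Runs the pre-ranked engine on immune-cell marker gene sets (e.g. the 22
#' LM22-style cell types), keeps cell types significant at \code{alpha} on
#' the nominal p, and reports for every cell type the fraction of its
#' markers called differentially methylated. Marker sets with no overlap
#' with the ranking are skipped with a message.
#'
#' @param ranking data.frame (gene, rs) sorted by decreasing rs.
#' @param markerSets named list of marker gene vectors.
#' @param diffGenes character vector of differentially methylated gene
#'   symbols (e.g. genes with any hyper/hypo promoter probe).
#' @param alpha significance gate on the nominal p (default 0.05).
#' @param nPerm,weight,seed passed to \code{\link{runEnrichment}}.
#' @return list with \code{enrichment} (significant rows of the
#'   \code{\link{runEnrichment}} table) and \code{marker_fractions}
#'   (data.frame cell_type, n_markers, n_differential, fraction).
#' @export
immuneInfiltrationEnrichment <- function(ranking, markerSets, diffGenes,
                                         alpha = 0.05, nPerm = 1000,
                                         weight = 1, seed = 1L) {
  enr <- runEnrichment(ranking, markerSets, weight = weight,
                       nPerm = nPerm, seed = seed)
  fr <- data.frame(
    cell_type = names(markerSets),
    n_markers = lengths(markerSets),
    n_differential = vapply(markerSets, function(g)
      sum(g %in% diffGenes), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  fr$fraction <- ifelse(fr$n_markers > 0,
                        fr$n_differential / fr$n_markers, 0)
  list(enrichment = enr[!is.na(enr$p_nominal) & enr$p_nominal <= alpha, ,
                        drop = FALSE],
       marker_fractions = fr)
}
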