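## Resampling consensus clustering of tumour samples on differential
## methylation features, and rank-sum comparisons across subtypes.

#' Resampling consensus clustering
#'
#' Repeatedly subsamples the samples (and optionally the features), runs a
#' base clusterer on each draw, and aggregates co-assignments into a
#' consensus matrix: entry (i, j) is the fraction of draws containing both
#' samples in which they landed in the same cluster. Final subtype labels
#' come from average-linkage hierarchical clustering of
#' \code{1 - consensus} cut at k. The base clusterer is k-means with
#' multiple restarts (deterministic under the seed and fast); Euclidean
#' average-linkage hierarchical clustering is available via
#' \code{clusterer = "hclust"}. Resamples in which k-means cannot place k
#' centres (fewer than k distinct points) are redrawn.
#'
#' @param features numeric matrix, features (e.g. differential probes) x
#'   samples.
#' @param k number of clusters, >= 2 and < n * sampleFrac.
#' @param nResamples resampling iterations (default 500).
#' @param sampleFrac fraction of samples drawn per iteration, without
#'   replacement (default 0.8).
#' @param featureFrac fraction of features drawn per iteration (default 1).
#' @param clusterer \code{"kmeans"} (default) or \code{"hclust"}.
#' @param seed integer seed.
#' @return a \linkS4class{ConsensusResult}.
#' @export
consensusCluster <- function(features, k, nResamples = 500,
                             sampleFrac = 0.8, featureFrac = 1.0,
                             clusterer = c("kmeans", "hclust"),
                             seed = 1L) {
  clusterer <- match.arg(clusterer)
  features <- as.matrix(features)
  n <- ncol(features)
  if (k < 2) stop("k must be at least 2")
  if (k >= n * sampleFrac)
    stop("k must be smaller than the resampled sample count")
  set.seed(as.integer(seed))
  nSub <- max(k + 1, floor(sampleFrac * n))
  co <- matrix(0, n, n)
  tog <- matrix(0, n, n)
  i <- 0L
  while (i < nResamples) {
    cols <- sort(sample.int(n, nSub))
    rows <- if (featureFrac < 1)
      sample.int(nrow(features), max(2, floor(featureFrac * nrow(features))))
    else seq_len(nrow(features))
    x <- t(features[rows, cols, drop = FALSE])
    if (nrow(unique(x)) < k) next  # degenerate draw, redraw
    cl <- if (clusterer == "kmeans") {
      km <- try(stats::kmeans(x, centers = k, nstart = 5,
                              iter.max = 50), silent = TRUE)
      if (inherits(km, "try-error")) next
      km$cluster
    } else {
      stats::cutree(stats::hclust(stats::dist(x), "average"), k)
    }
    same <- outer(cl, cl, "==")
    co[cols, cols] <- co[cols, cols] + same
    tog[cols, cols] <- tog[cols, cols] + 1
    i <- i + 1L
  }
  cons <- ifelse(tog > 0, co / tog, 0)
  diag(cons) <- 1
  dimnames(cons) <- list(colnames(features), colnames(features))
  hc <- stats::hclust(stats::as.dist(1 - cons), "average")
  assign <- stats::cutree(hc, k)
  new("ConsensusResult", k = as.integer(k), consensusMatrix = cons,
      assignments = assign, nResamples = as.integer(nResamples))
}

#' Consensus CDF sweep over candidate k
#'
#' Runs \code{\link{consensusCluster}} for each k and reports the area under
#' the consensus-entry CDF and its increment, the usual aid for choosing k.
#'
#' @inheritParams consensusCluster
#' @param kRange integer vector of candidate cluster counts.
#' @return data.frame (k, auc, delta_auc).
#' @export
consensusSweep <- function(features, kRange = 2:8, nResamples = 200,
                           sampleFrac = 0.8, seed = 1L) {
  auc <- vapply(kRange, function(k) {
    cr <- consensusCluster(features, k, nResamples = nResamples,
                           sampleFrac = sampleFrac, seed = seed)
    m <- consensusMatrix(cr)
    v <- sort(m[upper.tri(m)])
    cdf <- seq_along(v) / length(v)
    sum(diff(v) * cdf[-length(cdf)])
  }, numeric(1))
  data.frame(k = kRange, auc = auc,
             delta_auc = c(NA, diff(auc) / pmax(auc[-length(auc)], 1e-12)))
}

#' Pairwise rank-sum comparison of variables across subtypes
#'
#' For every pair of clusters and every supplied variable, a two-sided
#' Wilcoxon rank-sum test (exact where the sample sizes allow, mid-rank
#' normal approximation otherwise, as in \code{stats::wilcox.test}) with the
#' direction of the median difference. Clusters with fewer than 2 samples
#' are excluded with a message.
#'
#' @param scores data.frame with a \code{sample_id} column and numeric
#'   variable columns (e.g. mean beta plus \code{\link{immuneScoreTable}}).
#' @param assignments named vector, sample id -> cluster label.
#' @return data.frame (variable, cluster_a, cluster_b, statistic, p_value,
#'   direction), direction in \{"a<b", "a>b", "none"\} by median.
#' @export
compareSubtypes <- function(scores, assignments) {
  scores <- as.data.frame(scores)
  vars <- setdiff(colnames(scores), "sample_id")
  cl <- assignments[scores$sample_id]
  ok <- !is.na(cl)
  scores <- scores[ok, , drop = FALSE]; cl <- cl[ok]
  sizes <- table(cl)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    message("excluding cluster(s) with < 2 samples: ",
            paste(small, collapse = ", "))
    keep <- !(cl %in% small)
    scores <- scores[keep, , drop = FALSE]; cl <- cl[keep]
  }
  labs <- sort(unique(cl))
  if (length(labs) < 2) stop("need at least two clusters with >= 2 samples")
  rows <- list()
  for (v in vars) {
    for (i in seq_along(labs)) for (j in seq_along(labs)) {
      if (j <= i) next
      a <- scores[[v]][cl == labs[i]]
      b <- scores[[v]][cl == labs[j]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2 || length(b) < 2) next
      wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL))
      dmed <- stats::median(a) - stats::median(b)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, cluster_a = labs[i], cluster_b = labs[j],
        statistic = unname(wt$statistic), p_value = wt$p.value,
        direction = if (dmed < 0) "a<b" else if (dmed > 0) "a>b" else "none",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
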