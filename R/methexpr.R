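## Promoter methylation -> expression regression and the RS ranking score.

#' Regress gene expression on promoter-probe methylation
#'
#' Ordinary least squares of each gene's expression (log2(RPKM+1)) on the
#' beta values of its promoter probes across samples, with the overall
#' F-test p-value as the per-gene significance measure. By default only
#' tumour samples enter the fit: the tumour/normal contrast is already
#' captured by delta, and mixing conditions would confound the within-tumour
#' association; \code{samples = "all"} fits on every shared sample instead.
#' Collinear (aliased) probes are dropped from the design with a message;
#' genes with too few samples for their design are skipped with a message.
#'
#' When \code{geneDelta} is supplied (gene-level mean promoter delta, see
#' \code{\link{geneLevelDifferential}}), the signed RS ranking score
#' \code{-log10(model_p) * sign(delta)} is attached.
#'
#' @param expr genes x samples expression matrix.
#' @param beta probes x samples beta matrix (imputed, no missing values).
#' @param promoterMap named list gene -> promoter probe ids.
#' @param sheet sample sheet data.frame (sample_id, condition).
#' @param pCut significance threshold on the model p-value (default 0.05).
#' @param samples \code{"tumor"} (default) or \code{"all"}.
#' @param geneDelta optional named numeric vector of gene-level deltas.
#' @return data.frame with columns \code{gene}, \code{n_probes},
#'   \code{model_p}, \code{significant}, \code{intercept}; list column
#'   \code{coefficients} (named per-probe vectors); and, when
#'   \code{geneDelta} is given, \code{delta} and \code{rs}.
#' @export
fitGeneRegression <- function(expr, beta, promoterMap, sheet,
                              pCut = 0.05, samples = c("tumor", "all"),
                              geneDelta = NULL) {
  samples <- match.arg(samples)
  expr <- as.matrix(expr); beta <- as.matrix(beta)
  sheet <- as.data.frame(sheet)
  shared <- intersect(colnames(expr), colnames(beta))
  if (samples == "tumor") {
    tum <- sheet$sample_id[sheet$condition == "tumor"]
    shared <- intersect(shared, tum)
  }
  if (length(shared) < 3)
    stop("fewer than 3 shared samples between expression and methylation")
  genes <- intersect(rownames(expr), names(promoterMap))
  rows <- vector("list", length(genes))
  names(rows) <- genes
  skipped <- 0L
  for (g in genes) {
    pr <- intersect(promoterMap[[g]], rownames(beta))
    if (!length(pr)) { skipped <- skipped + 1L; next }
    X <- t(beta[pr, shared, drop = FALSE])
    y <- expr[g, shared]
    ## drop collinear probes via QR rank of the full design
    qrd <- qr(cbind(1, X))
    if (qrd$rank < ncol(X) + 1) {
      keep <- sort(setdiff(qrd$pivot[seq_len(qrd$rank)], 1L)) - 1L
      message("gene ", g, ": dropped ", ncol(X) - length(keep),
              " collinear probe(s)")
      X <- X[, keep, drop = FALSE]
      pr <- pr[keep]
    }
    if (length(shared) <= ncol(X) + 1) {
      skipped <- skipped + 1L
      message("gene ", g, ": skipped (n <= p + 1)")
      next
    }
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    p <- ncol(X); n <- length(y)
    if (tss == 0 || rss >= tss || p == 0) {
      modelP <- 1
    } else {
      fstat <- ((tss - rss) / p) / (rss / (n - p - 1))
      modelP <- stats::pf(fstat, p, n - p - 1, lower.tail = FALSE)
    }
    cf <- fit$coefficients[-1]
    names(cf) <- pr
    rows[[g]] <- list(gene = g, n_probes = length(pr), model_p = modelP,
                      intercept = unname(fit$coefficients[1]),
                      coefficients = cf)
  }
  rows <- Filter(Negate(is.null), rows)
  out <- data.frame(
    gene = vapply(rows, `[[`, character(1), "gene"),
    n_probes = vapply(rows, `[[`, numeric(1), "n_probes"),
    model_p = vapply(rows, `[[`, numeric(1), "model_p"),
    intercept = vapply(rows, `[[`, numeric(1), "intercept"),
    stringsAsFactors = FALSE, row.names = NULL)
  out$significant <- out$model_p <= pCut
  out$coefficients <- lapply(rows, `[[`, "coefficients")
  if (!is.null(geneDelta)) {
    out$delta <- unname(geneDelta[out$gene])
    out$rs <- computeRS(out$model_p, out$delta)
  }
  out
}

#' Signed regulation score RS
#'
#' \code{rs = -log10(p) * sign(delta)}: large positive for genes whose
#' promoters are significantly hypermethylated, large negative for
#' significant hypomethylation; \code{delta = 0} gives 0 and \code{p = 1}
#' gives 0. Zero p-values are floored at 1e-300 before the log so ranks stay
#' finite while remaining extreme.
#'
#' @param p model p-values in \eqn{(0, 1]} (zeros are floored).
#' @param delta gene-level promoter deltas in \eqn{[-1, 1]}.
#' @return numeric vector of RS scores.
#' @examples
#' computeRS(0.001, -0.2)  # -3
#' @export
computeRS <- function(p, delta) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  p <- pmax(p, 1e-300)
  -log10(p) * sign(delta)
}

#' Rank genes by RS for pre-ranked enrichment
#'
#' Sorts descending by RS with deterministic alphabetical tie-breaking, the
#' .rnk-style input of the pre-ranked enrichment engine. Duplicate gene
#' symbols are an error.
#'
#' @param results data.frame with columns \code{gene} and \code{rs} (e.g.
#'   from \code{\link{fitGeneRegression}} with \code{geneDelta}).
#' @return data.frame (gene, rs) sorted by decreasing rs.
#' @export
rankGenes <- function(results) {
  if (!nrow(results))
    return(data.frame(gene = character(), rs = numeric()))
  if (anyDuplicated(results$gene))
    stop("duplicate gene symbols in ranking input")
  ord <- order(-results$rs, results$gene)
  data.frame(gene = results$gene[ord], rs = results$rs[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}
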