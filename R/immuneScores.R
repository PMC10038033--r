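## MHC / CYT / CTL immune response scores on log2(RPKM+1) expression.

.matchGenes <- function(expr, genes) {
  rn <- toupper(rownames(expr))
  idx <- match(toupper(genes), rn)
  names(idx) <- genes
  idx
}

#' MHC class I antigen presentation score
#'
#' Mean log2(RPKM+1) expression of the nine-gene MHC-I core set (HLA-A,
#' PSMB9, HLA-B, PSMB8, HLA-C, B2M, TAP2, NLRC5, TAP1) per sample. If some
#' of the nine are absent the mean is taken over the available genes with a
#' warning (the panel is large enough to degrade gracefully); none present
#' is an error. Gene matching is case-insensitive exact symbol matching.
#'
#' @param expr genes x samples expression matrix, log2(RPKM+1).
#' @return named numeric vector, one score per sample.
#' @export
mhcScore <- function(expr) {
  idx <- .matchGenes(expr, .MHC_GENES)
  found <- idx[!is.na(idx)]
  if (!length(found))
    stop("none of the nine MHC genes present in the expression matrix")
  if (length(found) < length(idx))
    warning("MHC score over ", length(found), "/9 genes; missing: ",
            paste(names(idx)[is.na(idx)], collapse = ", "))
  colMeans(expr[found, , drop = FALSE])
}

#' Cytolytic activity score
#'
#' \code{(GZMA + PRF1) / 2} per sample. Both genes are required: with only
#' two constituents there is no redundancy to degrade over.
#'
#' @inheritParams mhcScore
#' @return named numeric vector.
#' @export
cytScore <- function(expr) {
  idx <- .matchGenes(expr, .CYT_GENES)
  if (anyNA(idx))
    stop("CYT score requires gene(s): ",
         paste(names(idx)[is.na(idx)], collapse = ", "))
  colMeans(expr[idx, , drop = FALSE])
}

#' Cytotoxic T lymphocyte score
#'
#' \code{(GZMA + GZMB + PRF1) / 3} per sample; all three genes required.
#'
#' @inheritParams mhcScore
#' @return named numeric vector.
#' @export
ctlScore <- function(expr) {
  idx <- .matchGenes(expr, .CTL_GENES)
  if (anyNA(idx))
    stop("CTL score requires gene(s): ",
         paste(names(idx)[is.na(idx)], collapse = ", "))
  colMeans(expr[idx, , drop = FALSE])
}

#' Immune score table
#'
#' Convenience wrapper assembling MHC, CYT and CTL scores (and TMB when
#' provided) into one per-sample table for subtype comparisons.
#'
#' @inheritParams mhcScore
#' @param tmb optional named numeric vector of tumour mutation burden.
#' @return data.frame (sample_id, mhc, cyt, ctl[, tmb]).
#' @export
immuneScoreTable <- function(expr, tmb = NULL) {
  out <- data.frame(sample_id = colnames(expr),
                    mhc = unname(mhcScore(expr)),
                    cyt = unname(cytScore(expr)),
                    ctl = unname(ctlScore(expr)),
                    stringsAsFactors = FALSE)
  if (!is.null(tmb)) out$tmb <- unname(tmb[out$sample_id])
  out
}
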