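## Quantification rules: beta from intensities, probe filtering,
## missingness handling, promoter mapping.

#' Compute beta values from methylated/unmethylated intensities
#'
#' Element-wise \eqn{\beta = M / (M + U)}. Cells where both intensities are
#' zero have an undefined ratio and become missing rather than a fabricated
#' methylation call; downstream imputation handles them.
#'
#' @param meth,unmeth non-negative numeric matrices of methylated and
#'   unmethylated signal, identical dimnames.
#' @return numeric matrix of beta values in \eqn{[0,1]} with \code{NA} where
#'   \code{M + U == 0}.
#' @examples
#' computeBeta(matrix(100), matrix(300))  # 0.25
#' @export
computeBeta <- function(meth, unmeth) {
  meth <- as.matrix(meth); unmeth <- as.matrix(unmeth)
  if (!identical(dim(meth), dim(unmeth)) ||
      !identical(dimnames(meth), dimnames(unmeth)))
    stop("meth and unmeth must share dimensions and dimnames")
  if (any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  tot <- meth + unmeth
  beta <- meth / tot
  beta[tot == 0] <- NA_real_
  beta
}

#' Remove sex-chromosome and SNP-overlapping probes
#'
#' Probes mapped to chrX or chrY and probes flagged as overlapping a SNP are
#' unstable and removed before analysis. Probe order is preserved. An empty
#' result warns rather than errors so callers can report odd inputs.
#'
#' @param object a \linkS4class{MethylExperiment}.
#' @return the filtered \linkS4class{MethylExperiment}.
#' @export
filterProbes <- function(object) {
  stopifnot(is(object, "MethylExperiment"))
  ann <- probeAnnotation(object)
  keep <- !(ann$chr %in% c("chrX", "chrY")) & !ann$snp_flag
  if (!any(keep))
    warning("all probes removed by sex-chromosome/SNP filtering")
  object[keep, ]
}

#' Drop high-missingness probes and mean-impute the rest
#'
#' Probes whose missing fraction is at or above \code{maxMissing} are
#' dropped (retained sites have missingness strictly below the threshold);
#' remaining missing cells are filled with that probe's across-sample mean,
#' computed jointly over tumour and normal samples. The output contains no
#' missing values, and imputation leaves each retained probe's observed mean
#' unchanged.
#'
#' @param object a \linkS4class{MethylExperiment}.
#' @param maxMissing missing-fraction threshold in \eqn{[0,1]}; default 0.4.
#' @return the imputed \linkS4class{MethylExperiment}.
#' @export
filterImputeMissing <- function(object, maxMissing = 0.4) {
  stopifnot(is(object, "MethylExperiment"),
            maxMissing >= 0, maxMissing <= 1)
  b <- betaValues(object)
  missFrac <- rowMeans(is.na(b))
  keep <- missFrac < maxMissing
  if (!any(keep))
    warning("all probes removed by the missingness filter")
  object <- object[keep, ]
  b <- betaValues(object)
  if (anyNA(b)) {
    mns <- rowMeans(b, na.rm = TRUE)
    idx <- which(is.na(b), arr.ind = TRUE)
    b[idx] <- mns[idx[, 1]]
    SummarizedExperiment::assay(object, "beta") <- b
  }
  object
}

#' Map genes to their promoter probes
#'
#' The promoter region is defined as the union of the 1stExon, 5'UTR,
#' TSS1500 and TSS200 transcript regions. Each probe carrying one of these
#' labels for a gene is listed under that gene; probes labelled only
#' Body/3'UTR appear nowhere. A probe annotated to several genes (via the
#' parallel \code{genes}/\code{regions} lists) appears under each gene whose
#' label is promoter-type. Probes within a gene are ordered by genomic
#' position.
#'
#' @param annotation probe annotation data.frame (see
#'   \linkS4class{MethylExperiment}); \code{genes} and \code{regions} are
#'   \code{";"}-joined parallel lists.
#' @return named list: gene symbol -> character vector of probe ids.
#' @export
mapPromoterProbes <- function(annotation) {
  annotation <- as.data.frame(annotation)
  genes <- strsplit(as.character(annotation$genes), ";", fixed = TRUE)
  regions <- strsplit(as.character(annotation$regions), ";", fixed = TRUE)
  nlab <- lengths(genes)
  if (!all(nlab == lengths(regions)))
    stop("genes and regions must be parallel ';'-joined lists")
  df <- data.frame(
    probe_id = rep(annotation$probe_id, nlab),
    pos = rep(annotation$pos, nlab),
    gene = unlist(genes), region = unlist(regions),
    stringsAsFactors = FALSE)
  df <- df[df$region %in% .PROMOTER_REGIONS & nzchar(df$gene), ,
           drop = FALSE]
  df <- unique(df[c("probe_id", "pos", "gene")])
  df <- df[order(df$gene, df$pos, df$probe_id), ]
  split(df$probe_id, df$gene)
}
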