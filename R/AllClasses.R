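#' @import methods
#' @importFrom stats setNames
NULL

#' MethylExperiment: beta values with probe annotation and sample sheet
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a single
#' \code{"beta"} assay (CpG probes in rows, samples in columns, values in
#' \eqn{[0,1]} or \code{NA}), HM450K-manifest-style probe annotation in
#' \code{rowData} and the sample sheet (condition, survival, TMB) in
#' \code{colData}.
#'
#' Required \code{rowData} columns: \code{probe_id}, \code{chr}, \code{pos},
#' \code{genes} (\code{";"}-joined symbols), \code{regions} (\code{";"}-joined
#' transcript-region labels, parallel to \code{genes}),
#' \code{island_relation} (one of Island/Shore/Shelf/OpenSea),
#' \code{snp_flag} (logical).
#' Required \code{colData} columns: \code{sample_id}, \code{condition}
#' (\code{"tumor"}/\code{"normal"}); optional \code{time}, \code{event},
#' \code{tmb}, \code{cancer_type}.
#'
#' @aliases MethylExperiment-class
#' @exportClass MethylExperiment
setClass("MethylExperiment", contains = "SummarizedExperiment")

.ISLAND_LEVELS <- c("Island", "Shore", "Shelf", "OpenSea")
.REGION_LEVELS <- c("1stExon", "3'UTR", "5'UTR", "Body", "TSS1500", "TSS200")
.PROMOTER_REGIONS <- c("1stExon", "5'UTR", "TSS1500", "TSS200")

setValidity("MethylExperiment", function(object) {
  msg <- character()
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'beta' is required")
  else {
    b <- SummarizedExperiment::assay(object, "beta")
    v <- b[!is.na(b)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      msg <- c(msg, "non-missing beta values must lie in [0, 1]")
  }
  rd <- SummarizedExperiment::rowData(object)
  need <- c("probe_id", "chr", "pos", "genes", "regions",
            "island_relation", "snp_flag")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste0("rowData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  if ("probe_id" %in% colnames(rd) && anyDuplicated(rd$probe_id))
    msg <- c(msg, "probe_id values must be unique")
  if ("island_relation" %in% colnames(rd) &&
      !all(rd$island_relation %in% .ISLAND_LEVELS))
    msg <- c(msg, "island_relation outside {Island, Shore, Shelf, OpenSea}")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("sample_id", "condition") %in% colnames(cd)))
    msg <- c(msg, "colData needs sample_id and condition columns")
  else {
    if (anyDuplicated(cd$sample_id))
      msg <- c(msg, "sample_id values must be unique")
    if (!all(cd$condition %in% c("tumor", "normal")))
      msg <- c(msg, "condition must be 'tumor' or 'normal'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MethylExperiment
#'
#' @param beta numeric matrix of beta values (probes x samples), rownames are
#'   probe ids and colnames sample ids; \code{NA} encodes missing calls.
#' @param annotation data.frame of probe annotation with columns
#'   \code{probe_id}, \code{chr}, \code{pos}, \code{genes}, \code{regions},
#'   \code{island_relation}, \code{snp_flag}; matched to \code{beta} rows by
#'   \code{probe_id}.
#' @param sampleSheet data.frame with columns \code{sample_id},
#'   \code{condition} and optionally \code{cancer_type}, \code{time},
#'   \code{event}, \code{tmb}; matched to \code{beta} columns by
#'   \code{sample_id}.
#' @return A \linkS4class{MethylExperiment}.
#' @examples
#' b <- matrix(c(0.1, 0.9, 0.2, 0.8), 2,
#'             dimnames = list(c("cg1", "cg2"), c("s1", "s2")))
#' ann <- data.frame(probe_id = c("cg1", "cg2"), chr = "chr1", pos = c(10, 20),
#'                   genes = "G1", regions = "TSS200",
#'                   island_relation = "Island", snp_flag = FALSE)
#' sheet <- data.frame(sample_id = c("s1", "s2"),
#'                     condition = c("tumor", "normal"))
#' MethylExperiment(b, ann, sheet)
#' @export
MethylExperiment <- function(beta, annotation, sampleSheet) {
  beta <- as.matrix(beta)
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("beta must have probe-id rownames and sample-id colnames")
  annotation <- as.data.frame(annotation)
  sampleSheet <- as.data.frame(sampleSheet)
  if (!all(rownames(beta) %in% annotation$probe_id))
    stop("unannotated probe id(s): ",
         paste(utils::head(setdiff(rownames(beta), annotation$probe_id), 5),
               collapse = ", "))
  if (!all(colnames(beta) %in% sampleSheet$sample_id))
    stop("sample(s) absent from sample sheet")
  annotation <- annotation[match(rownames(beta), annotation$probe_id), ,
                           drop = FALSE]
  sampleSheet <- sampleSheet[match(colnames(beta), sampleSheet$sample_id), ,
                             drop = FALSE]
  rownames(annotation) <- annotation$probe_id
  rownames(sampleSheet) <- sampleSheet$sample_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = beta),
    rowData = S4Vectors::DataFrame(annotation),
    colData = S4Vectors::DataFrame(sampleSheet))
  new("MethylExperiment", se)
}

#' @describeIn MethylExperiment beta-value assay accessor
#' @param object,x a MethylExperiment
#' @export
setGeneric("betaValues", function(object) standardGeneric("betaValues"))

#' @rdname MethylExperiment
#' @export
setMethod("betaValues", "MethylExperiment", function(object)
  SummarizedExperiment::assay(object, "beta"))

#' @describeIn MethylExperiment probe annotation as a data.frame
#' @export
setGeneric("probeAnnotation",
           function(object) standardGeneric("probeAnnotation"))

#' @rdname MethylExperiment
#' @export
setMethod("probeAnnotation", "MethylExperiment", function(object)
  as.data.frame(SummarizedExperiment::rowData(object)))

#' @describeIn MethylExperiment sample sheet as a data.frame
#' @export
setGeneric("sampleSheet", function(object) standardGeneric("sampleSheet"))

#' @rdname MethylExperiment
#' @export
setMethod("sampleSheet", "MethylExperiment", function(object)
  as.data.frame(SummarizedExperiment::colData(object)))

setMethod("show", "MethylExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("MethylExperiment:", nrow(object), "probes x", ncol(object),
      "samples\n")
  cat("  tumor:", sum(cd$condition == "tumor"),
      " normal:", sum(cd$condition == "normal"), "\n")
  b <- SummarizedExperiment::assay(object, "beta")
  cat(sprintf("  missing: %.2f%%\n", 100 * mean(is.na(b))))
})

#' ConsensusResult: resampling consensus clustering output
#'
#' Holds the samples-by-samples co-assignment proportion matrix, the final
#' cluster assignments obtained by hierarchical clustering of
#' \code{1 - consensus}, the requested cluster count and the number of
#' resampling iterations aggregated.
#'
#' @slot k integer cluster count.
#' @slot consensusMatrix symmetric numeric matrix in \eqn{[0,1]} with unit
#'   diagonal.
#' @slot assignments named integer vector, sample id to cluster label in
#'   \code{1..k}.
#' @slot nResamples integer resampling iterations.
#' @aliases ConsensusResult-class
#' @exportClass ConsensusResult
setClass("ConsensusResult",
         representation(k = "integer", consensusMatrix = "matrix",
                        assignments = "integer", nResamples = "integer"))

setValidity("ConsensusResult", function(object) {
  msg <- character()
  cm <- object@consensusMatrix
  if (!isSymmetric(unname(cm), tol = 1e-8))
    msg <- c(msg, "consensus matrix must be symmetric")
  if (any(cm < -1e-12 | cm > 1 + 1e-12))
    msg <- c(msg, "consensus entries must lie in [0,1]")
  if (any(abs(diag(cm) - 1) > 1e-12))
    msg <- c(msg, "consensus diagonal must be 1")
  if (length(object@assignments) != nrow(cm))
    msg <- c(msg, "one assignment per clustered sample required")
  if (length(unique(object@assignments)) != object@k)
    msg <- c(msg, "assignments must use k distinct labels")
  if (length(msg)) msg else TRUE
})

#' @describeIn ConsensusResult co-assignment proportion matrix
#' @param object a ConsensusResult
#' @export
setGeneric("consensusMatrix",
           function(object) standardGeneric("consensusMatrix"))

#' @rdname ConsensusResult
#' @export
setMethod("consensusMatrix", "ConsensusResult",
          function(object) object@consensusMatrix)

#' @describeIn ConsensusResult named cluster assignments
#' @export
setGeneric("clusterAssignments",
           function(object) standardGeneric("clusterAssignments"))

#' @rdname ConsensusResult
#' @export
setMethod("clusterAssignments", "ConsensusResult",
          function(object) object@assignments)

setMethod("show", "ConsensusResult", function(object) {
  cat("ConsensusResult: k =", object@k, "over", object@nResamples,
      "resamples\n")
  print(table(cluster = object@assignments))
})

#' SurvivalGrouping: risk scores dichotomised at a maxstat cutoff
#'
#' @slot sampleId character sample ids.
#' @slot riskScore numeric per-sample risk scores.
#' @slot group factor with levels \code{low}, \code{high}; \code{high} iff
#'   score strictly exceeds the cutoff.
#' @slot cutoff numeric selected threshold.
#' @slot time,event numeric survival time (days) and 0/1 event indicator.
#' @slot maxstat numeric standardized log-rank statistic at the cutoff.
#' @aliases SurvivalGrouping-class
#' @exportClass SurvivalGrouping
setClass("SurvivalGrouping",
         representation(sampleId = "character", riskScore = "numeric",
                        group = "factor", cutoff = "numeric",
                        time = "numeric", event = "numeric",
                        maxstat = "numeric"))

setValidity("SurvivalGrouping", function(object) {
  msg <- character()
  n <- length(object@riskScore)
  if (length(object@group) != n || length(object@time) != n ||
      length(object@event) != n)
    msg <- c(msg, "riskScore, group, time, event must be parallel")
  if (!identical(levels(object@group), c("low", "high")))
    msg <- c(msg, "group levels must be c('low','high')")
  if (n > 0) {
    if (!all((object@riskScore > object@cutoff) ==
             (object@group == "high")))
      msg <- c(msg, "group 'high' must equal riskScore > cutoff")
    if (length(unique(object@group)) < 2)
      msg <- c(msg, "both risk groups must be non-empty")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SurvivalGrouping per-sample risk scores
#' @param object a SurvivalGrouping
#' @export
setGeneric("riskScores", function(object) standardGeneric("riskScores"))

#' @rdname SurvivalGrouping
#' @export
setMethod("riskScores", "SurvivalGrouping",
          function(object) setNames(object@riskScore, object@sampleId))

#' @describeIn SurvivalGrouping high/low group labels
#' @export
setGeneric("riskGroups", function(object) standardGeneric("riskGroups"))

#' @rdname SurvivalGrouping
#' @export
setMethod("riskGroups", "SurvivalGrouping",
          function(object) setNames(object@group, object@sampleId))

#' @describeIn SurvivalGrouping the selected cutoff
#' @export
setGeneric("riskCutoff", function(object) standardGeneric("riskCutoff"))

#' @rdname SurvivalGrouping
#' @export
setMethod("riskCutoff", "SurvivalGrouping", function(object) object@cutoff)

setMethod("show", "SurvivalGrouping", function(object) {
  cat("SurvivalGrouping:", length(object@riskScore), "samples, cutoff",
      signif(object@cutoff, 4), "\n")
  cat("  high:", sum(object@group == "high"),
      " low:", sum(object@group == "low"),
      " events:", sum(object@event), "\n")
})

#' PpiNetwork: seed-anchored protein-protein interaction subnetwork
#'
#' Undirected simple graph restricted to edges incident to at least one seed
#' node. Nodes carry a category label (\code{transcription_factor},
#' \code{cytokine}, \code{inhibitory_receptor}, \code{common_seed} or
#' \code{neighbor}) and their degree within the stored edge set.
#'
#' @slot nodes data.frame with columns \code{gene}, \code{category},
#'   \code{degree}.
#' @slot edges data.frame with columns \code{from}, \code{to}
#'   (lexicographically ordered endpoints, no duplicates, no self-loops).
#' @aliases PpiNetwork-class
#' @exportClass PpiNetwork
setClass("PpiNetwork",
         representation(nodes = "data.frame", edges = "data.frame"))

setValidity("PpiNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (nrow(e)) {
    if (any(e$from == e$to)) msg <- c(msg, "self-loops are not allowed")
    if (anyDuplicated(paste(e$from, e$to)))
      msg <- c(msg, "duplicate undirected edges are not allowed")
    if (any(e$from > e$to))
      msg <- c(msg, "edge endpoints must be stored in sorted order")
  }
  deg <- table(c(e$from, e$to))
  want <- setNames(object@nodes$degree, object@nodes$gene)
  got <- as.numeric(deg[names(want)])
  got[is.na(got)] <- 0
  if (length(want) && any(got != want))
    msg <- c(msg, "stored degrees disagree with incident edge counts")
  if (sum(object@nodes$degree) != 2L * nrow(e))
    msg <- c(msg, "handshake identity violated: sum(degree) != 2|E|")
  if (length(msg)) msg else TRUE
})

#' @describeIn PpiNetwork node table (gene, category, degree)
#' @param object a PpiNetwork
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))

#' @rdname PpiNetwork
#' @export
setMethod("networkNodes", "PpiNetwork", function(object) object@nodes)

#' @describeIn PpiNetwork edge table (from, to)
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @rdname PpiNetwork
#' @export
setMethod("networkEdges", "PpiNetwork", function(object) object@edges)

setMethod("show", "PpiNetwork", function(object) {
  cat("PpiNetwork:", nrow(object@nodes), "nodes,", nrow(object@edges),
      "edges\n")
  print(table(category = object@nodes$category))
})
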