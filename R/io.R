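## Readers/writers for the pipeline's plain-text exchange formats: TSV
## matrices, annotation and sample sheets, GMT gene sets, .rnk rankings,
## edge lists, and the synthetic-truth sidecar.

#' Read / write a numeric matrix as TSV
#'
#' First column holds row ids, header row holds column ids; missing values
#' are encoded as \code{NA}. Lines starting with \code{#} are ignored on
#' read; \code{header} adds such comment lines on write (used by the
#' pipeline to record seed and thresholds).
#'
#' @param path file path.
#' @param x numeric matrix with dimnames.
#' @param idColumn name written for the id column.
#' @param header optional character vector of comment lines (without
#'   \code{#}).
#' @return \code{readMatrixTsv}: numeric matrix.
#' @export
readMatrixTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' @rdname readMatrixTsv
#' @export
writeMatrixTsv <- function(x, path, idColumn = "id", header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c(idColumn, colnames(x)), collapse = "\t"), con)
  utils::write.table(data.frame(rownames(x), x, check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write probe annotation, sample sheets and generic tables
#'
#' Plain TSV with a header row; \code{#} lines are comments.
#' @param path file path.
#' @param x data.frame.
#' @param header optional comment lines.
#' @return \code{readTableTsv}: data.frame.
#' @export
readTableTsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' @rdname readTableTsv
#' @export
writeTableTsv <- function(x, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  suppressWarnings(utils::write.table(x, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' GMT: one set per line, tab-separated name, description, then members.
#' Reading is delegated to \code{fgsea::gmtPathways}.
#'
#' @param path file path.
#' @param sets named list of character vectors.
#' @param descriptions optional character vector parallel to \code{sets}.
#' @return \code{readGmt}: named list of character vectors.
#' @export
readGmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname readGmt
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a ranking in .rnk dialect
#'
#' Two-column TSV (gene, score), no header, sorted by decreasing score.
#' @param path file path.
#' @param ranking data.frame (gene, rs).
#' @return \code{readRnk}: data.frame (gene, rs).
#' @export
readRnk <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  stats::setNames(df[, 1:2], c("gene", "rs"))
}

#' @rdname readRnk
#' @export
writeRnk <- function(ranking, path) {
  utils::write.table(ranking[, c("gene", "rs")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read the synthetic-truth sidecar
#'
#' The recorded ground truth of the generators, serialised as JSON (a
#' documented plain-text key-value format) so tests and re-runs can score
#' recovery without regenerating.
#'
#' @param truth list as returned in \code{simulateMethylation()$truth}.
#' @param path file path.
#' @return \code{readTruth}: the truth list.
#' @export
writeTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
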