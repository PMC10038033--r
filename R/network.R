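## Seed-anchored PPI subnetwork, degrees, hub extraction.

#' Build a seed-anchored PPI subnetwork
#'
#' Retains exactly the background edges with at least one seed endpoint
#' (edges between two non-seed nodes are excluded; set
#' \code{induced = TRUE} to instead keep the full induced subgraph on the
#' retained nodes). Self-loops are dropped and undirected duplicates are
#' stored once with lexicographically ordered endpoints. Gene symbols are
#' uppercased. Seed nodes carry their supplied category (defaulting to
#' \code{common_seed}); non-seed endpoints are labelled \code{neighbor}.
#'
#' @param backgroundEdges data.frame with two character columns (from, to).
#' @param seeds non-empty character vector of seed gene symbols.
#' @param categories optional named character vector gene -> category in
#'   \{transcription_factor, cytokine, inhibitory_receptor, common_seed\}.
#' @param induced keep neighbor-neighbor edges among retained nodes.
#' @return a \linkS4class{PpiNetwork}.
#' @examples
#' bg <- data.frame(from = c("A", "B", "C"), to = c("B", "C", "D"))
#' buildSeedNetwork(bg, seeds = "A")  # single edge A-B
#' @export
buildSeedNetwork <- function(backgroundEdges, seeds, categories = NULL,
                             induced = FALSE) {
  if (!length(seeds)) stop("seeds must be non-empty")
  e <- data.frame(from = toupper(as.character(backgroundEdges[[1]])),
                  to = toupper(as.character(backgroundEdges[[2]])),
                  stringsAsFactors = FALSE)
  seeds <- unique(toupper(seeds))
  e <- e[e$from != e$to, , drop = FALSE]
  swap <- e$from > e$to
  tmp <- e$from[swap]; e$from[swap] <- e$to[swap]; e$to[swap] <- tmp
  e <- e[!duplicated(paste(e$from, e$to)), , drop = FALSE]
  keep <- e$from %in% seeds | e$to %in% seeds
  if (!any(keep)) stop("no background edge touches a seed node")
  sub <- e[keep, , drop = FALSE]
  nodes <- unique(c(sub$from, sub$to))
  if (induced)
    sub <- e[e$from %in% nodes & e$to %in% nodes, , drop = FALSE]
  rownames(sub) <- NULL
  deg <- table(factor(c(sub$from, sub$to), levels = nodes))
  cat <- rep("neighbor", length(nodes))
  names(cat) <- nodes
  cat[nodes %in% seeds] <- "common_seed"
  if (!is.null(categories)) {
    names(categories) <- toupper(names(categories))
    known <- intersect(nodes[nodes %in% seeds], names(categories))
    cat[known] <- unname(categories[known])
  }
  nodeDf <- data.frame(gene = nodes, category = unname(cat),
                       degree = as.integer(deg),
                       stringsAsFactors = FALSE)
  new("PpiNetwork", nodes = nodeDf, edges = sub)
}

#' Extract hub genes
#'
#' Nodes whose degree is at least \code{minDegree} (default 10), sorted by
#' decreasing degree then symbol, with their category annotation.
#'
#' @param network a \linkS4class{PpiNetwork}.
#' @param minDegree hub threshold (default 10).
#' @return data.frame (gene, degree, category); zero rows when no node
#'   qualifies.
#' @export
extractHubs <- function(network, minDegree = 10) {
  nd <- networkNodes(network)
  hubs <- nd[nd$degree >= minDegree, , drop = FALSE]
  hubs <- hubs[order(-hubs$degree, hubs$gene), c("gene", "degree",
                                                 "category")]
  rownames(hubs) <- NULL
  hubs
}

#' Degree distribution
#'
#' Histogram of node degrees; counts sum to the number of nodes.
#'
#' @param network a \linkS4class{PpiNetwork}.
#' @return data.frame (degree, count) over observed degrees.
#' @export
degreeDistribution <- function(network) {
  tab <- table(networkNodes(network)$degree)
  data.frame(degree = as.integer(names(tab)), count = as.integer(tab))
}
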