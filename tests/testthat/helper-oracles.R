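# Independent oracles and tiny fixtures shared across tests.

# Literal walk of the weighted running sum, position by position.
# Kept deliberately naive (loop, no shortcuts) so it is an independent
# check on the package's enrichment-score implementation.
bruteForceES <- function(ranking, geneSet, weight = 1) {
  N <- nrow(ranking)
  hit <- ranking$gene %in% geneSet
  m <- sum(hit)
  w <- abs(ranking$rs)^weight
  denom <- sum(w[hit])
  if (denom == 0) { w <- rep(1, N); denom <- m }
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) w[i] / denom else -1 / (N - m)
    # extremum by magnitude; an exact +/- tie resolves to the positive peak
    if (abs(run) > abs(best) || (abs(run) == abs(best) && run > best))
      best <- run
  }
  best
}

# Exact two-sided rank-sum p by complete enumeration of group assignments.
exactWilcoxonP <- function(a, b) {
  n <- length(a); m <- length(b)
  v <- c(a, b)
  r <- rank(v)
  obs <- sum(r[seq_len(n)])
  idx <- utils::combn(n + m, n)
  null <- apply(idx, 2, function(i) sum(r[i]))
  mu <- n * (n + m + 1) / 2
  mean(abs(null - mu) >= abs(obs - mu) - 1e-9)
}

# Adjusted Rand index between two labelings (closed form on the
# contingency table).
adjRandIndex <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * cc / choose(n, 2)
  maxidx <- (b + cc) / 2
  if (maxidx == expected) return(1)
  (a - expected) / (maxidx - expected)
}

# Minimal hand-built MethylExperiment.
tinyMethylExperiment <- function(beta = NULL) {
  if (is.null(beta))
    beta <- matrix(c(0.8, 0.2, 0.82, 0.22, 0.78, 0.18, 0.81, 0.21),
                   nrow = 2,
                   dimnames = list(c("cg1", "cg2"),
                                   c("t1", "t2", "t3", "t4")))
  ann <- data.frame(probe_id = rownames(beta), chr = "chr1",
                    pos = seq_len(nrow(beta)) * 100,
                    genes = "GENE1", regions = "TSS200",
                    island_relation = "Island", snp_flag = FALSE,
                    stringsAsFactors = FALSE)
  sheet <- data.frame(sample_id = colnames(beta),
                      condition = rep(c("tumor", "normal"),
                                      length.out = ncol(beta)),
                      stringsAsFactors = FALSE)
  MethylExperiment(beta, ann, sheet)
}

# Group-structured experiment: nT tumors then nN normals, constant rows.
groupedMethylExperiment <- function(beta, nT, nN) {
  ann <- data.frame(probe_id = rownames(beta), chr = "chr1",
                    pos = seq_len(nrow(beta)), genes = "GENE1",
                    regions = "TSS200", island_relation = "OpenSea",
                    snp_flag = FALSE, stringsAsFactors = FALSE)
  sheet <- data.frame(sample_id = colnames(beta),
                      condition = rep(c("tumor", "normal"), c(nT, nN)),
                      stringsAsFactors = FALSE)
  MethylExperiment(beta, ann, sheet)
}
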