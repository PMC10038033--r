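rankingOf <- function(rs, genes = sprintf("G%02d", seq_along(rs))) {
  rankGenes(data.frame(gene = genes, rs = rs))
}

test_that("ES matches the brute-force running-sum oracle exhaustively", {
  # all subsets of size <= 3 of a length-10 ranking with rs 10..1
  r <- rankingOf(10:1)
  idx <- seq_len(10)
  subsets <- c(lapply(idx, function(i) i),
               combn(idx, 2, simplify = FALSE),
               combn(idx, 3, simplify = FALSE))
  for (s in subsets) {
    set <- r$gene[s]
    expect_equal(enrichmentScore(r, set, weight = 1)$es,
                 bruteForceES(r, set, weight = 1), tolerance = 1e-12)
  }
  # random rankings of length <= 12, both weights
  set.seed(1)
  for (i in 1:20) {
    N <- sample(5:12, 1)
    r <- rankingOf(round(rnorm(N), 3))
    m <- sample(1:3, 1)
    set <- sample(r$gene, m)
    for (w in c(0, 1))
      expect_equal(enrichmentScore(r, set, weight = w)$es,
                   bruteForceES(r, set, weight = w), tolerance = 1e-12)
  }
})

test_that("top- and bottom-loaded sets give extreme signed ES", {
  r <- rankingOf(seq(5, -5, length.out = 40))
  top <- r$gene[1:5]
  bottom <- rev(r$gene)[1:5]
  esTop <- enrichmentScore(r, top)$es
  esBottom <- enrichmentScore(r, bottom)$es
  expect_gt(esTop, 0)
  expect_lt(esBottom, 0)
  # a perfectly top-loaded set beats random sets of the same size
  set.seed(2)
  others <- replicate(30, enrichmentScore(r, sample(r$gene, 5))$es)
  expect_true(all(esTop >= others))
  # leading edge of the top set is the set itself
  expect_setequal(enrichmentScore(r, top)$leading_edge, top)
})

test_that("weight 0 reduces to the unweighted KS statistic on ranks", {
  set.seed(3)
  for (i in 1:50) {
    N <- sample(20:60, 1)
    r <- rankingOf(rnorm(N))
    m <- sample(3:8, 1)
    set <- sample(r$gene, m)
    hit <- r$gene %in% set
    # direct KS-style statistic: max deviation between hit and miss ECDFs
    d <- cumsum(hit / m - (!hit) / (N - m))
    ks <- d[which.max(abs(d))]
    expect_equal(enrichmentScore(r, set, weight = 0)$es, ks,
                 tolerance = 1e-12)
  }
})

test_that("reversing the ranking negates ES at weight 0 and flips sign at weight 1", {
  set.seed(4)
  r <- rankingOf(rnorm(30))
  set <- sample(r$gene, 6)
  rev_r <- r[rev(seq_len(nrow(r))), ]
  expect_equal(enrichmentScore(rev_r, set, weight = 0)$es,
               -enrichmentScore(r, set, weight = 0)$es, tolerance = 1e-12)
  expect_equal(sign(enrichmentScore(rev_r, set, weight = 1)$es),
               -sign(enrichmentScore(r, set, weight = 1)$es))
})

test_that("ES agrees with the fgsea reference on random cases", {
  set.seed(5)
  for (i in 1:20) {
    N <- sample(50:200, 1)
    r <- rankingOf(sort(rnorm(N), decreasing = TRUE))
    set <- sample(r$gene, sample(5:15, 1))
    ref <- fgsea::calcGseaStat(setNames(r$rs, r$gene),
                               which(r$gene %in% set), gseaParam = 1)
    expect_equal(enrichmentScore(r, set, weight = 1)$es, ref,
                 tolerance = 1e-8)
  }
})

test_that("permutation NES pipeline is deterministic and errors sensibly", {
  set.seed(6)
  r <- rankingOf(rnorm(100))
  sets <- list(S1 = sample(r$gene, 10), S2 = sample(r$gene, 15))
  a <- runEnrichment(r, sets, nPerm = 200, seed = 99)
  b <- runEnrichment(r, sets, nPerm = 200, seed = 99)
  expect_identical(a, b)
  expect_true(all(abs(a$es) <= 1))
  expect_true(all(sign(a$nes) == sign(a$es)))
  expect_true(all(a$p_adjusted >= a$p_nominal - 1e-12))
  expect_error(enrichmentScore(r, c("NOPE1", "NOPE2")), "no overlap")
  expect_error(runEnrichment(r, sets, nPerm = 50), "at least 100")
  expect_message(runEnrichment(r, list(S3 = "NOPE"), nPerm = 100),
                 "skipped")
})

test_that("BH adjustment is monotone in the nominal p", {
  set.seed(7)
  r <- rankingOf(rnorm(200))
  sets <- lapply(1:8, function(i) sample(r$gene, 12))
  names(sets) <- paste0("SET", 1:8)
  res <- runEnrichment(r, sets, nPerm = 200, seed = 1)
  o <- order(res$p_nominal)
  expect_true(all(diff(res$p_adjusted[o]) >= -1e-12))
})

test_that("a tail-planted set is significantly negatively enriched", {
  set.seed(8)
  rs <- sort(rnorm(300), decreasing = TRUE)
  r <- rankingOf(rs)
  planted <- rev(r$gene)[1:20]  # the most-negative tail
  sets <- c(list(PLANTED = planted),
            setNames(lapply(1:4, function(i) sample(r$gene, 20)),
                     paste0("RAND", 1:4)))
  res <- runEnrichment(r, sets, nPerm = 1000, seed = 2)
  p <- res[res$set_name == "PLANTED", ]
  expect_lt(p$nes, 0)
  expect_lte(p$p_adjusted, 0.05)
})

test_that("immune marker enrichment reports differential fractions", {
  set.seed(9)
  r <- rankingOf(sort(rnorm(100), decreasing = TRUE))
  markers <- list(CELL_A = rev(r$gene)[1:10],
                  CELL_B = sample(r$gene, 20))
  diffGenes <- c(markers$CELL_B[1:4], "OTHER")
  out <- immuneInfiltrationEnrichment(r, markers, diffGenes,
                                      nPerm = 500, seed = 3)
  fr <- out$marker_fractions
  expect_equal(fr$fraction[fr$cell_type == "CELL_B"], 0.2)
  expect_true("CELL_A" %in% out$enrichment$set_name)
  expect_lt(out$enrichment$nes[out$enrichment$set_name == "CELL_A"], 0)
})
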