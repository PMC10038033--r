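test_that("single-probe regression reduces to the simple OLS slope", {
  set.seed(3)
  n <- 40
  x <- runif(n)
  y <- 4 - 1.5 * x + rnorm(n, 0, 0.2)
  beta <- matrix(x, 1, n, dimnames = list("cg1", sprintf("s%02d", 1:n)))
  expr <- matrix(y, 1, n, dimnames = list("GENE1", colnames(beta)))
  sheet <- data.frame(sample_id = colnames(beta), condition = "tumor")
  fit <- fitGeneRegression(expr, beta, list(GENE1 = "cg1"), sheet)
  expect_equal(unname(fit$coefficients[[1]]["cg1"]),
               cov(x, y) / var(x), tolerance = 1e-10)
  ref <- summary(lm(y ~ x))
  expect_equal(fit$model_p,
               unname(pf(ref$fstatistic[1], ref$fstatistic[2],
                         ref$fstatistic[3], lower.tail = FALSE)),
               tolerance = 1e-10)
})

test_that("planted coefficients are recovered within tolerance", {
  set.seed(11)
  n <- 100
  b <- matrix(runif(2 * n, 0.1, 0.9), 2, n,
              dimnames = list(c("cg1", "cg2"), sprintf("s%03d", 1:n)))
  e <- simulateExpression(b, list(GENE1 = c(cg1 = -2, cg2 = 1)),
                          noiseSd = 0.1, seed = 12)
  sheet <- data.frame(sample_id = colnames(b), condition = "tumor")
  fit <- fitGeneRegression(e, b, list(GENE1 = c("cg1", "cg2")), sheet)
  cf <- fit$coefficients[[1]]
  expect_lt(abs(cf["cg1"] + 2), 0.15)
  expect_lt(abs(cf["cg2"] - 1), 0.15)
  expect_lt(fit$model_p, 1e-6)
  expect_true(fit$significant)
})

test_that("collinear promoter probes are dropped before fitting", {
  set.seed(4)
  n <- 30
  x <- runif(n)
  b <- rbind(cg1 = x, cg2 = x)  # perfectly collinear
  colnames(b) <- sprintf("s%02d", 1:n)
  e <- matrix(5 - 2 * x + rnorm(n, 0, 0.1), 1, n,
              dimnames = list("GENE1", colnames(b)))
  sheet <- data.frame(sample_id = colnames(b), condition = "tumor")
  expect_message(
    fit <- fitGeneRegression(e, b, list(GENE1 = c("cg1", "cg2")), sheet),
    "collinear")
  expect_equal(fit$n_probes, 1)
})

test_that("genes with too few samples are skipped with a message", {
  b <- matrix(runif(12), 4, 3,
              dimnames = list(paste0("cg", 1:4), paste0("s", 1:3)))
  e <- matrix(runif(3), 1, 3, dimnames = list("GENE1", colnames(b)))
  sheet <- data.frame(sample_id = colnames(b), condition = "tumor")
  expect_message(
    fit <- fitGeneRegression(e, b, list(GENE1 = paste0("cg", 1:4)), sheet),
    "skipped")
  expect_equal(nrow(fit), 0)
})

test_that("RS is -log10(p) signed by delta, with guards", {
  expect_equal(computeRS(0.001, -0.2), -3)
  expect_equal(computeRS(0.01, 0.3), 2)
  expect_equal(computeRS(1, 0.5), 0)
  expect_equal(computeRS(0.001, 0), 0)
  expect_true(is.finite(computeRS(0, 0.2)))  # floored, not infinite
  expect_error(computeRS(1.2, 0.1), "lie in")
  # |rs| is monotone decreasing in p for fixed sign
  ps <- c(1e-6, 1e-4, 0.01, 0.2, 0.9)
  rs <- computeRS(ps, rep(-0.5, 5))
  expect_true(all(diff(abs(rs)) < 0))
  expect_true(all(sign(rs) == -1))
})

test_that("ranking sorts by rs with alphabetical tie-breaking", {
  res <- data.frame(gene = c("B", "A", "C", "D"),
                    rs = c(2, 1.0, -3, 1.0))
  r <- rankGenes(res)
  expect_identical(r$gene, c("B", "A", "D", "C"))
  expect_identical(r$rs, c(2, 1.0, 1.0, -3))
  expect_equal(nrow(rankGenes(res[0, ])), 0)
  expect_error(rankGenes(data.frame(gene = c("A", "A"), rs = 1:2)),
               "duplicate")
})

test_that("regression is calibrated under the null", {
  set.seed(23)
  n <- 50; nGenes <- 300
  b <- matrix(runif(2 * n, 0.1, 0.9), 2, n,
              dimnames = list(c("cg1", "cg2"), sprintf("s%03d", 1:n)))
  expr <- matrix(rnorm(nGenes * n, 5, 1), nGenes, n,
                 dimnames = list(sprintf("G%03d", 1:nGenes), colnames(b)))
  sheet <- data.frame(sample_id = colnames(b), condition = "tumor")
  pm <- setNames(rep(list(c("cg1", "cg2")), nGenes), rownames(expr))
  fit <- fitGeneRegression(expr, b, pm, sheet)
  expect_gt(ks.test(fit$model_p, "punif")$p.value, 0.01)
  expect_lt(mean(fit$significant), 0.10)
})

test_that("hypo-regulated genes occupy the negative tail of the ranking", {
  s <- simulateMethylation(1500, 30, 30, fracHyper = 0, fracHypo = 0.1,
                           deltaMean = 0.3, noiseSd = 0.05, seed = 31)
  me <- filterImputeMissing(filterProbes(s$experiment))
  pm <- mapPromoterProbes(probeAnnotation(me))
  beta <- betaValues(me)
  planted <- intersect(s$truth$differential_probes$probe_id,
                       rownames(beta))
  regGenes <- list()
  for (g in names(pm)) {
    hit <- intersect(pm[[g]], planted)
    if (length(hit)) regGenes[[g]] <- setNames(rep(-2, length(hit)), hit)
  }
  expr <- simulateExpression(beta, regGenes, unregulatedGenes = names(pm),
                             noiseSd = 0.1, seed = 32)
  dm <- differentialMethylation(me)
  gl <- suppressMessages(geneLevelDifferential(dm, pm))
  fit <- suppressMessages(fitGeneRegression(
    expr, beta, pm, sampleSheet(me),
    geneDelta = setNames(gl$mean_delta, gl$gene)))
  lab <- fit$gene %in% names(regGenes)
  # AUC of -rs as a detector of regulated genes
  r <- rank(-fit$rs)
  auc <- (sum(r[lab]) - sum(lab) * (sum(lab) + 1) / 2) /
    (sum(lab) * sum(!lab))
  expect_gt(auc, 0.9)
})
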