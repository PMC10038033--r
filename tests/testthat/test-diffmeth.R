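test_that("large shifts are called with the correct delta and status", {
  beta <- matrix(c(0.8, 0.82, 0.78, 0.81, 0.2, 0.22, 0.18, 0.21), 1,
                 dimnames = list("cg1", paste0("s", 1:8)))
  me <- groupedMethylExperiment(beta, 4, 4)
  dm <- differentialMethylation(me)
  expect_equal(dm$delta, 0.60)
  expect_equal(dm$status, "hyper")
  ref <- t.test(beta[1, 1:4], beta[1, 5:8])
  expect_equal(dm$p_value, ref$p.value, tolerance = 1e-12)
  expect_lt(dm$p_value, 0.05)
})

test_that("both thresholds must hold for a differential call", {
  # significant but tiny effect: 0 < delta < 0.1 stays ns
  set.seed(7)
  n <- 60
  beta <- matrix(c(rnorm(n, 0.55, 0.01), rnorm(n, 0.50, 0.01)), 1)
  beta <- pmin(pmax(beta, 0), 1)
  dim(beta) <- c(1, 2 * n)
  dimnames(beta) <- list("cg1", paste0("s", seq_len(2 * n)))
  me <- groupedMethylExperiment(beta, n, n)
  dm <- differentialMethylation(me)
  expect_lt(dm$p_value, 0.05)
  expect_lt(abs(dm$delta), 0.1)
  expect_equal(dm$status, "ns")

  # no effect at all
  same <- matrix(rep(c(0.31, 0.29, 0.30, 0.32), 2), 1,
                 dimnames = list("cg1", paste0("s", 1:8)))
  expect_equal(differentialMethylation(
    groupedMethylExperiment(same, 4, 4))$status, "ns")
})

test_that("row-wise t-test matches stats::t.test in both variants", {
  set.seed(42)
  beta <- matrix(runif(100 * 14), 100, 14,
                 dimnames = list(sprintf("cg%03d", 1:100),
                                 paste0("s", 1:14)))
  me <- groupedMethylExperiment(beta, 8, 6)
  for (ve in c(FALSE, TRUE)) {
    dm <- differentialMethylation(me, varEqual = ve)
    ref <- apply(beta, 1, function(x)
      t.test(x[1:8], x[9:14], var.equal = ve)$p.value)
    expect_equal(dm$p_value, unname(ref), tolerance = 1e-10)
  }
})

test_that("swapping condition labels negates delta and preserves p", {
  set.seed(5)
  beta <- matrix(runif(50 * 12), 50, 12,
                 dimnames = list(sprintf("cg%02d", 1:50), paste0("s", 1:12)))
  meA <- groupedMethylExperiment(beta, 6, 6)
  sheetB <- sampleSheet(meA)
  sheetB$condition <- rev(sheetB$condition)
  meB <- MethylExperiment(beta, probeAnnotation(meA), sheetB)
  a <- differentialMethylation(meA)
  b <- differentialMethylation(meB)
  expect_equal(a$delta, -b$delta)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("degenerate zero-variance probes get p = 1 and ns", {
  beta <- matrix(0.4, 1, 8, dimnames = list("cg1", paste0("s", 1:8)))
  dm <- differentialMethylation(groupedMethylExperiment(beta, 4, 4))
  expect_equal(dm$p_value, 1)
  expect_equal(dm$status, "ns")
})

test_that("too few samples error; few normals warn", {
  beta <- matrix(runif(10 * 3), 10, 3,
                 dimnames = list(sprintf("cg%02d", 1:10), paste0("s", 1:3)))
  me <- groupedMethylExperiment(beta, 2, 1)
  expect_error(differentialMethylation(me), "at least 2")
  beta2 <- matrix(runif(10 * 6), 10, 6,
                  dimnames = list(sprintf("cg%02d", 1:10), paste0("s", 1:6)))
  expect_warning(differentialMethylation(groupedMethylExperiment(beta2, 3, 3)),
                 "fewer than 4 normal")
})

test_that("context summary cross-tabulates with fractional multi-labels", {
  res <- data.frame(probe_id = paste0("cg", 1:3),
                    p_value = 0.01, delta = 0.3,
                    status = c("hyper", "hyper", "ns"))
  ann <- data.frame(probe_id = paste0("cg", 1:3), chr = "chr1", pos = 1:3,
                    genes = c("A", "A;B", "C"),
                    regions = c("TSS200", "TSS200;Body", "Body"),
                    island_relation = c("Island", "Island", "OpenSea"),
                    snp_flag = FALSE)
  cs <- contextSummary(res, ann)
  reg <- cs$region
  expect_equal(reg$count[reg$status == "hyper" & reg$region == "TSS200"], 1.5)
  expect_equal(reg$count[reg$status == "hyper" & reg$region == "Body"], 0.5)
  expect_equal(sum(reg$count[reg$status == "hyper"]), 2)  # totals preserved
  isl <- cs$island
  expect_equal(isl$pct[isl$status == "hyper" &
                       isl$island_relation == "Island"], 100)

  empty <- contextSummary(res[0, ], ann)
  expect_true(all(empty$region$count == 0))
  expect_true(all(empty$island$count == 0))
})

test_that("planted island composition is recovered by the summary", {
  s <- simulateMethylation(3000, 20, 20, fracHyper = 0, fracHypo = 0.1,
                           deltaMean = 0.3, seed = 8)
  me <- filterImputeMissing(filterProbes(s$experiment))
  dm <- differentialMethylation(me)
  cs <- contextSummary(dm, probeAnnotation(me))
  ann <- probeAnnotation(me)
  planted <- ann[ann$probe_id %in% s$truth$differential_probes$probe_id, ]
  trueFrac <- mean(planted$island_relation == "OpenSea")
  got <- cs$island
  gotFrac <- got$pct[got$status == "hypo" &
                     got$island_relation == "OpenSea"] / 100
  expect_lt(abs(gotFrac - trueFrac), 0.07)
})

test_that("gene-level aggregation averages deltas and counts calls", {
  res <- data.frame(probe_id = paste0("cg", 1:10), p_value = 0.01,
                    delta = c(0.2, 0.4, rep(-0.3, 2), rep(0, 6)),
                    status = c("hyper", "hyper", "hypo", "hypo",
                               rep("ns", 6)))
  pm <- list(GENEA = c("cg1", "cg2"),
             GENEB = paste0("cg", 1:10),
             GENEC = "cg99")
  expect_message(gl <- geneLevelDifferential(res, pm), "no promoter probes")
  a <- gl[gl$gene == "GENEA", ]
  expect_equal(a$mean_delta, 0.3)
  expect_equal(a$fraction_diff, 1)
  b <- gl[gl$gene == "GENEB", ]
  expect_equal(b$n_hyper, 2)
  expect_equal(b$n_hypo, 2)
  expect_equal(b$fraction_diff, 0.4)
  expect_false("GENEC" %in% gl$gene)
  expect_error(geneLevelDifferential(res, list()), "empty")
})
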