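test_that("externally supplied coefficients give a pure linear predictor", {
  b <- matrix(0.5, 5, 3,
              dimnames = list(paste0("cg", 1:5), paste0("s", 1:3)))
  cf <- c(cg1 = -1.68, cg2 = 1.94, cg3 = -0.93, cg4 = -1.52, cg5 = -0.09)
  rs <- coxRiskScore(b, coefficients = cf)
  expect_equal(unname(rs$scores), rep(-1.14, 3), tolerance = 1e-12)
  # zero betas give zero score regardless of coefficients
  expect_equal(unname(coxRiskScore(b * 0, coefficients = cf)$scores),
               rep(0, 3))
  # linearity in the methylation profile
  b2 <- matrix(runif(15), 5, 3, dimnames = dimnames(b))
  s1 <- coxRiskScore(b, coefficients = cf)$scores
  s2 <- coxRiskScore(b2, coefficients = cf)$scores
  s12 <- coxRiskScore(b + b2, coefficients = cf)$scores
  expect_equal(s12, s1 + s2, tolerance = 1e-12)
  expect_error(coxRiskScore(b, coefficients = c(bad = 1)),
               "match probe ids")
})

test_that("Cox fitting recovers a planted log-hazard", {
  set.seed(1)
  n <- 500
  x <- runif(n)
  surv <- simulateSurvival(2 * x, baselineHazard = 0.01,
                           censorRate = 0.2, seed = 2)
  b <- matrix(x, 1, n, dimnames = list("cg1", sprintf("s%03d", 1:n)))
  fit <- coxRiskScore(b, time = surv$time, event = surv$event)
  expect_lt(abs(unname(fit$coefficients["cg1"]) - 2), 0.3)
  expect_error(coxRiskScore(b, time = surv$time,
                            event = rep(0, n)), "2 events")
})

test_that("Kaplan-Meier product-limit matches hand computation", {
  km <- kmCurve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2/3, 1/3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))
  # all censored: no steps, S stays 1
  expect_equal(nrow(kmCurve(c(1, 2, 3), c(0, 0, 0))), 0)
  expect_error(kmCurve(c(-1, 2), c(1, 1)), "negative")
  # censoring reduces risk sets without steps
  km2 <- kmCurve(c(1, 1.5, 2), c(1, 0, 1))
  expect_equal(km2$survival, c(2/3, 2/3 * 0), tolerance = 1e-12)
})

test_that("KM equals the empirical survival without censoring and the closed form at scale", {
  set.seed(3)
  t <- rexp(1000, 0.02)
  km <- kmCurve(t, rep(1, 1000))
  # no censoring: S(t_i) is the empirical survival fraction
  i <- 500
  expect_equal(km$survival[i], mean(t > km$time[i]), tolerance = 1e-12)
  # S at the theoretical median is ~0.5
  sMed <- km$survival[which.min(abs(km$time - log(2) / 0.02))]
  expect_lt(abs(sMed - 0.5), 0.03)
})

test_that("log-rank matches survival::survdiff on random data", {
  set.seed(4)
  for (i in 1:50) {
    n <- sample(30:80, 1)
    g <- factor(sample(c("a", "b"), n, replace = TRUE))
    time <- round(rexp(n, ifelse(g == "a", 0.02, 0.04)), 2)
    event <- rbinom(n, 1, 0.8)
    if (length(unique(g)) < 2 || sum(event) < 2) next
    ours <- logrankTest(g, time = time, event = event)
    ref <- survival::survdiff(survival::Surv(time, event) ~ g)
    expect_equal(ours$chi_square, ref$chisq, tolerance = 1e-8)
  }
})

test_that("identical groups give chi-square 0 and p = 1", {
  time <- c(1, 2, 3, 4, 1, 2, 3, 4)
  event <- rep(1, 8)
  g <- rep(c("a", "b"), each = 4)
  lr <- logrankTest(g, time = time, event = event)
  expect_equal(lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  expect_error(logrankTest(rep("a", 8), time = time, event = event),
               "two groups")
})

test_that("maxstat finds the separating region and honours minProp", {
  scores <- rep(c(0, 10), each = 50)
  surv <- simulateSurvival(rep(c(0, log(4)), each = 50),
                           baselineHazard = 0.02, censorRate = 0,
                           seed = 5)
  ms <- maxstatCutoff(scores, surv$time, surv$event)
  expect_gt(ms$cutoff, 0)
  expect_lt(ms$cutoff, 10)
  expect_lt(ms$p_naive, 0.001)
  expect_error(maxstatCutoff(rep(1, 20), 1:20, rep(1, 20)),
               "no candidate")
})

test_that("a planted change-point is recovered within tolerance", {
  set.seed(6)
  sc <- runif(300, 0, 3)
  surv <- simulateSurvival(log(3) * (sc > 1.5), baselineHazard = 0.01,
                           censorRate = 0.2, seed = 7)
  ms <- maxstatCutoff(sc, surv$time, surv$event)
  expect_lt(abs(ms$cutoff - 1.5), 0.25)
})

test_that("naive maxstat p is anti-conservative under the null and flagged", {
  set.seed(8)
  reject <- mean(replicate(60, {
    sc <- runif(40)
    surv <- simulateSurvival(rep(0, 40), baselineHazard = 0.02,
                             censorRate = 0.1,
                             seed = sample.int(1e6, 1))
    maxstatCutoff(sc, surv$time, surv$event)$p_naive <= 0.05
  }))
  expect_gt(reject, 0.05)  # selection inflates the naive rejection rate
  # the permutation-corrected p exists and is larger on a null draw
  sc <- runif(40)
  surv <- simulateSurvival(rep(0, 40), baselineHazard = 0.02,
                           censorRate = 0.1, seed = 9)
  ms <- maxstatCutoff(sc, surv$time, surv$event, nPermutations = 100,
                      seed = 10)
  expect_gte(ms$p_corrected, ms$p_naive)
})

test_that("log-rank is invariant to monotone transforms of the scores", {
  set.seed(11)
  sc <- runif(80)
  surv <- simulateSurvival(2 * sc, baselineHazard = 0.02,
                           censorRate = 0.1, seed = 12)
  g1 <- survivalGrouping(sc, surv$time, surv$event)
  lr1 <- logrankTest(g1)
  g2 <- survivalGrouping(exp(3 * sc), surv$time, surv$event)
  lr2 <- logrankTest(g2)
  expect_equal(lr1$chi_square, lr2$chi_square, tolerance = 1e-10)
  expect_identical(as.character(riskGroups(g1)),
                   as.character(riskGroups(g2)))
})

test_that("SurvivalGrouping enforces its invariants", {
  set.seed(13)
  sc <- runif(60)
  surv <- simulateSurvival(2 * sc, baselineHazard = 0.02,
                           censorRate = 0.1, seed = 14)
  g <- survivalGrouping(sc, surv$time, surv$event)
  expect_true(validObject(g))
  expect_identical(unname(riskGroups(g) == "high"),
                   unname(riskScores(g) > riskCutoff(g)))
  expect_true(all(table(riskGroups(g)) > 0))
})
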