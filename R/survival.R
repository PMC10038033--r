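## CpG risk scoring, maximally selected log-rank cutoff, Kaplan-Meier and
## log-rank testing.

#' CpG-based Cox risk score
#'
#' Fits a multivariate Cox proportional-hazards model (Efron tie handling)
#' of survival on the beta values of the selected CpG sites and returns the
#' per-CpG coefficients with the per-sample linear predictor
#' \code{sum(coef * beta)}. Externally supplied coefficients (e.g. a
#' published risk model) bypass fitting entirely and are applied as given.
#'
#' @param betaSubset numeric matrix, selected CpG probes x samples.
#' @param time,event numeric survival times and 0/1 event indicators,
#'   parallel to the columns of \code{betaSubset}.
#' @param coefficients optional named numeric vector (names = probe ids);
#'   when given, no model is fitted.
#' @return list with \code{coefficients} (named numeric) and \code{scores}
#'   (named per-sample risk scores).
#' @examples
#' b <- matrix(0.5, 5, 3, dimnames = list(paste0("cg", 1:5), paste0("s", 1:3)))
#' cf <- c(cg1 = -1.68, cg2 = 1.94, cg3 = -0.93, cg4 = -1.52, cg5 = -0.09)
#' coxRiskScore(b, coefficients = cf)$scores  # all -1.14
#' @export
coxRiskScore <- function(betaSubset, time = NULL, event = NULL,
                         coefficients = NULL) {
  betaSubset <- as.matrix(betaSubset)
  if (is.null(coefficients)) {
    if (is.null(time) || is.null(event))
      stop("time and event are required to fit coefficients")
    if (sum(event) < 2) stop("need at least 2 events to fit")
    if (nrow(betaSubset) > ncol(betaSubset) / 5)
      warning("more than n/5 CpGs in the Cox model; risk of overfitting")
    df <- as.data.frame(t(betaSubset))
    colnames(df) <- rownames(betaSubset)
    fit <- survival::coxph(
      survival::Surv(time, event) ~ .,
      data = cbind(df, time = time, event = event)[,
        c(rownames(betaSubset), "time", "event")],
      ties = "efron")
    if (any(is.na(stats::coef(fit))))
      stop("Cox fit failed to estimate all coefficients for CpG set: ",
           paste(rownames(betaSubset), collapse = ", "))
    coefficients <- stats::coef(fit)
    names(coefficients) <- rownames(betaSubset)
  } else {
    if (is.null(names(coefficients)) ||
        !all(names(coefficients) %in% rownames(betaSubset)))
      stop("coefficient names must match probe ids in betaSubset")
    betaSubset <- betaSubset[names(coefficients), , drop = FALSE]
  }
  scores <- as.numeric(crossprod(coefficients, betaSubset))
  names(scores) <- colnames(betaSubset)
  list(coefficients = coefficients, scores = scores)
}

## two-group log-rank internals: observed/expected/variance in group 1
.logrankOEV <- function(time, event, in1) {
  dt <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in dt) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & in1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & in1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  c(O = O, E = E, V = V)
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square comparing the high- and low-risk
#' groups of a \linkS4class{SurvivalGrouping}, or any two-level grouping
#' supplied as vectors.
#'
#' @param grouping a \linkS4class{SurvivalGrouping}, or a factor/vector of
#'   two group labels when \code{time}/\code{event} are given.
#' @param time,event used when \code{grouping} is a plain vector.
#' @return list with \code{chi_square}, \code{p_value} and the per-group
#'   observed/expected event counts.
#' @export
logrankTest <- function(grouping, time = NULL, event = NULL) {
  if (is(grouping, "SurvivalGrouping")) {
    time <- grouping@time; event <- grouping@event
    g <- grouping@group
  } else g <- grouping
  g <- factor(g)
  if (nlevels(g) != 2) stop("log-rank test requires exactly two groups")
  oev <- .logrankOEV(time, event, g == levels(g)[1])
  chi <- if (oev["V"] > 0) (oev["O"] - oev["E"])^2 / oev["V"] else 0
  p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  list(chi_square = unname(chi), p_value = unname(p),
       observed = unname(oev["O"]), expected = unname(oev["E"]))
}

#' Maximally selected log-rank cutoff
#'
#' Evaluates the standardized log-rank statistic
#' \eqn{(O-E)/\sqrt{V}} at every candidate split of the risk scores whose
#' two induced groups each contain at least \code{minProp} of the samples,
#' and returns the cutoff with the largest absolute statistic; ties go to
#' the more balanced split. Candidate cutoffs are midpoints between
#' adjacent distinct score values. The naive log-rank p-value at the
#' selected cutoff is anti-conservative because the cutoff was chosen to
#' maximise the statistic; it is reported as \code{p_naive}, and
#' \code{nPermutations > 0} adds a permutation-corrected p-value
#' (maximum-statistic null under label permutation).
#'
#' @param scores numeric per-sample risk scores.
#' @param time,event survival columns parallel to \code{scores}.
#' @param minProp minimum group proportion per side (default 0.1).
#' @param nPermutations permutations for the corrected p (default 0 = off).
#' @param seed seed for the permutation null.
#' @return list with \code{cutoff}, \code{statistic} (signed standardized
#'   log-rank), \code{p_naive} and optionally \code{p_corrected}.
#' @export
maxstatCutoff <- function(scores, time, event, minProp = 0.1,
                          nPermutations = 0L, seed = 1L) {
  n <- length(scores)
  if (n < ceiling(1 / minProp)) stop("too few samples for minProp")
  maxStatOver <- function(sc) {
    u <- sort(unique(sc))
    if (length(u) < 2) return(NULL)
    cand <- (u[-1] + u[-length(u)]) / 2
    lowN <- vapply(cand, function(cc) sum(sc <= cc), numeric(1))
    ok <- lowN >= minProp * n & (n - lowN) >= minProp * n
    cand <- cand[ok]
    if (!length(cand)) return(NULL)
    stat <- vapply(cand, function(cc) {
      oev <- .logrankOEV(time, event, sc > cc)
      if (oev["V"] <= 0) 0 else
        unname((oev["O"] - oev["E"]) / sqrt(oev["V"]))
    }, numeric(1))
    list(cand = cand, stat = stat,
         balance = abs(n - 2 * vapply(cand, function(cc)
           sum(sc <= cc), numeric(1))))
  }
  obs <- maxStatOver(scores)
  if (is.null(obs)) stop("no candidate split satisfies minProp")
  best <- which(abs(obs$stat) == max(abs(obs$stat)))
  if (length(best) > 1) best <- best[which.min(obs$balance[best])]
  cutoff <- obs$cand[best]
  stat <- obs$stat[best]
  lr <- logrankTest(factor(scores > cutoff), time = time, event = event)
  out <- list(cutoff = cutoff, statistic = stat, p_naive = lr$p_value)
  if (nPermutations > 0) {
    set.seed(as.integer(seed))
    nullMax <- vapply(seq_len(nPermutations), function(i) {
      perm <- maxStatOver(scores[sample.int(n)])
      if (is.null(perm)) 0 else max(abs(perm$stat))
    }, numeric(1))
    out$p_corrected <- (1 + sum(nullMax >= abs(stat))) /
      (1 + nPermutations)
  }
  out
}

#' Kaplan-Meier product-limit curve
#'
#' Stepwise survival estimate at the distinct event times; censored times
#' reduce the at-risk counts without producing steps.
#'
#' @param time non-negative survival times.
#' @param event 0/1 event indicators.
#' @return data.frame (time, n_risk, n_event, survival), one row per
#'   distinct event time; survival starts below 1 at the first event and is
#'   non-increasing. All-censored input yields zero rows (S identically 1).
#' @export
kmCurve <- function(time, event) {
  if (any(time < 0)) stop("negative survival times")
  dt <- sort(unique(time[event == 1]))
  s <- 1
  rows <- lapply(dt, function(t) {
    n <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <<- s * (1 - d / n)
    data.frame(time = t, n_risk = n, n_event = d, survival = s)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(time = numeric(), n_risk = numeric(),
                      n_event = numeric(), survival = numeric())
  rownames(out) <- NULL
  out
}

#' Dichotomise risk scores at a maxstat cutoff into a SurvivalGrouping
#'
#' Convenience wrapper: selects the cutoff with \code{\link{maxstatCutoff}}
#' and packages scores, groups and survival columns into a
#' \linkS4class{SurvivalGrouping} ("high" = score strictly above cutoff).
#'
#' @inheritParams maxstatCutoff
#' @param sampleId optional sample ids (defaults to names of scores).
#' @return a \linkS4class{SurvivalGrouping}.
#' @export
survivalGrouping <- function(scores, time, event, minProp = 0.1,
                             sampleId = names(scores)) {
  ms <- maxstatCutoff(scores, time, event, minProp = minProp)
  if (is.null(sampleId)) sampleId <- paste0("S", seq_along(scores))
  grp <- factor(ifelse(scores > ms$cutoff, "high", "low"),
                levels = c("low", "high"))
  new("SurvivalGrouping", sampleId = as.character(sampleId),
      riskScore = as.numeric(scores), group = grp, cutoff = ms$cutoff,
      time = as.numeric(time), event = as.numeric(event),
      maxstat = ms$statistic)
}
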