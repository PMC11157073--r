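#' Cochran's Q heterogeneity test
#'
#' Q = sum_j w_j (theta_j - theta_IVW)^2 over per-SNP Wald ratios theta_j
#' with ratio-scale inverse-variance weights w_j = gamma_j^2/sigma_Yj^2
#' and the fixed-effect IVW estimate as the centre. Under homogeneity Q is
#' chi-squared with J-1 degrees of freedom. I-squared =
#' max(0, (Q - (J-1))/Q) * 100 is the percentage of variability across
#' instruments attributable to heterogeneity.
#'
#' @param set a [HarmonizedSet-class] with at least 2 instruments.
#' @return list with \code{Q}, \code{df}, \code{pvalue}, \code{I2} and the
#'   per-SNP \code{contributions} (named; they sum to Q).
#' @export
cochranQ <- function(set) {
  e <- .effects(set)
  .needSnps(e$J, 2L, "Cochran's Q")
  w <- (e$g / e$sy)^2
  ratios <- e$G / e$g
  thetaF <- sum(w * ratios) / sum(w)
  contrib <- w * (ratios - thetaF)^2
  Q <- sum(contrib)
  df <- e$J - 1
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  list(Q = Q, df = df,
       pvalue = stats::pchisq(Q, df, lower.tail = FALSE), I2 = I2,
       contributions = stats::setNames(contrib, e$id))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Re-exposes the intercept record of the [mrEgger()] fit: a non-zero
#' intercept indicates an average directional pleiotropic effect across
#' instruments. Two-sided p from t(J-2).
#'
#' @param set a [HarmonizedSet-class] with at least 3 instruments.
#' @return list with \code{intercept}, \code{se}, \code{pvalue}.
#' @export
eggerInterceptTest <- function(set) {
  fit <- mrEgger(set)
  x <- fit@extra
  list(intercept = x$intercept, se = x$intercept_se,
       pvalue = x$intercept_pvalue)
}

#' MR-PRESSO global and outlier tests
#'
#' Residual-sum-of-squares test for horizontal pleiotropy. The observed
#' statistic is RSSobs = sum_j w_j (Gamma_j - gamma_j theta_(-j))^2 with
#' w_j = 1/sigma_Yj^2 and theta_(-j) the fixed-effect IVW estimate
#' excluding SNP j. The null distribution is built from \code{nSim}
#' parametric simulations drawing gamma*_j ~ N(gamma_j, sigma_Xj) and
#' Gamma*_j ~ N(gamma_j theta_(-j), sigma_Yj) and recomputing the
#' statistic; the global p-value uses the add-one estimator
#' (1 + #\{RSS* >= RSSobs\})/(nSim + 1), so it is never exactly zero and
#' never below 1/(nSim + 1). Each SNP's observed residual contribution is
#' compared with its own simulated distribution, Bonferroni-adjusted
#' across the J instruments; ids with adjusted p below
#' \code{outlierSignificance} are reported as outliers. Fewer than 4
#' instruments yields \code{NA} fields with an insufficient-instruments
#' status instead of an error.
#'
#' @param set a [HarmonizedSet-class].
#' @param nSim parametric simulations (default 1000).
#' @param seed integer seed (required when the test runs).
#' @param outlierSignificance Bonferroni-adjusted cutoff (default 0.05).
#' @return list with \code{status}, \code{rss_obs}, \code{global_pvalue},
#'   \code{n_sim}, \code{outlier_pvalues} (Bonferroni-adjusted, named) and
#'   \code{outliers}.
#' @export
mrPresso <- function(set, nSim = 1000, seed = NULL,
                     outlierSignificance = 0.05) {
  e <- .effects(set)
  if (e$J < 4L)
    return(list(status = "insufficient_instruments", rss_obs = NA_real_,
                global_pvalue = NA_real_, n_sim = nSim,
                outlier_pvalues = stats::setNames(rep(NA_real_, e$J), e$id),
                outliers = character()))
  seed <- .needSeed(seed)
  w <- 1 / e$sy^2
  num <- w * e$g * e$G
  den <- w * e$g^2
  thetaLoo <- (sum(num) - num) / (sum(den) - den)
  resObs <- w * (e$G - e$g * thetaLoo)^2
  rssObs <- sum(resObs)

  set.seed(seed)
  gs <- matrix(stats::rnorm(e$J * nSim, mean = e$g, sd = e$sx), e$J)
  Gs <- matrix(stats::rnorm(e$J * nSim, mean = e$g * thetaLoo, sd = e$sy),
               e$J)
  numS <- w * gs * Gs
  denS <- w * gs^2
  sn <- rep(colSums(numS), each = e$J)
  sd_ <- rep(colSums(denS), each = e$J)
  thetaLooS <- (sn - numS) / (sd_ - denS)
  resSim <- w * (Gs - gs * thetaLooS)^2
  rssSim <- colSums(resSim)

  globalP <- (1 + sum(rssSim >= rssObs)) / (nSim + 1)
  pj <- (1 + rowSums(resSim >= resObs)) / (nSim + 1)
  padj <- pmin(1, pj * e$J)
  names(padj) <- e$id
  list(status = "ok", rss_obs = rssObs, global_pvalue = globalP,
       n_sim = nSim, outlier_pvalues = padj,
       outliers = e$id[padj < outlierSignificance])
}

#' Leave-one-out IVW analysis
#'
#' Refits the IVW estimator J times, excluding one instrument each time,
#' to reveal whether a single SNP drives the pooled finding.
#'
#' @param set a [HarmonizedSet-class] with at least 2 instruments.
#' @param effectsModel IVW effects model, see [mrIVW()].
#' @return data.frame with one row per excluded SNP: \code{excluded},
#'   \code{n_snps}, \code{beta}, \code{se}, \code{ci_low}, \code{ci_high},
#'   \code{pvalue}.
#' @export
leaveOneOut <- function(set,
                        effectsModel = c("multiplicative_random", "fixed")) {
  effectsModel <- match.arg(effectsModel)
  e <- .effects(set)
  .needSnps(e$J, 2L, "leave-one-out")
  rows <- lapply(seq_len(e$J), function(j) {
    est <- suppressWarnings(
      mrIVW(.subsetHarmonized(set, setdiff(seq_len(e$J), j)), effectsModel))
    data.frame(excluded = e$id[j], n_snps = est@nSnps, beta = est@thetaHat,
               se = est@se, ci_low = est@ciLow, ci_high = est@ciHigh,
               pvalue = est@pvalue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full sensitivity suite for one instrument set
#'
#' Bundles [cochranQ()], [eggerInterceptTest()], [mrPresso()] and
#' [leaveOneOut()] into a [SensitivityReport-class]. Diagnostics whose
#' minimum instrument count is not met are reported as \code{NA} fields
#' (and an empty leave-one-out table) rather than errors, so degenerate
#' sets still yield a complete row in screening output.
#'
#' @param set a [HarmonizedSet-class].
#' @param nSim,seed,outlierSignificance passed to [mrPresso()].
#' @param effectsModel passed to [leaveOneOut()].
#' @return a [SensitivityReport-class].
#' @export
sensitivityReport <- function(set, nSim = 1000, seed = NULL,
                              outlierSignificance = 0.05,
                              effectsModel = c("multiplicative_random",
                                               "fixed")) {
  effectsModel <- match.arg(effectsModel)
  J <- nrow(set@snps)
  q <- if (J >= 2L) cochranQ(set) else
    list(Q = NA_real_, df = NA_real_, pvalue = NA_real_, I2 = NA_real_)
  eg <- if (J >= 3L) eggerInterceptTest(set) else
    list(intercept = NA_real_, se = NA_real_, pvalue = NA_real_)
  pr <- mrPresso(set, nSim = nSim, seed = seed,
                 outlierSignificance = outlierSignificance)
  loo <- if (J >= 2L) leaveOneOut(set, effectsModel) else
    data.frame(excluded = character(), n_snps = integer(), beta = numeric(),
               se = numeric(), ci_low = numeric(), ci_high = numeric(),
               pvalue = numeric(), stringsAsFactors = FALSE)
  new("SensitivityReport", exposureName = set@exposureName,
      outcomeName = set@outcomeName, Q = q$Q, QDf = as.numeric(q$df),
      QPvalue = q$pvalue, I2 = q$I2, eggerIntercept = eg$intercept,
      eggerInterceptSe = eg$se, eggerInterceptPvalue = eg$pvalue,
      pressoRssObs = pr$rss_obs, pressoGlobalPvalue = pr$global_pvalue,
      pressoNSim = as.numeric(pr$n_sim), pressoOutliers = pr$outliers,
      loo = loo)
}
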