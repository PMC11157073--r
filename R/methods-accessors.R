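#' @rdname mrscreen-accessors
setMethod("traitName", "SummaryStats", function(x) x@traitName)
#' @rdname mrscreen-accessors
setMethod("traitType", "SummaryStats", function(x) x@traitType)
#' @rdname mrscreen-accessors
setMethod("variants", "SummaryStats", function(x) x@variants)
#' @rdname mrscreen-accessors
setMethod("nVariants", "SummaryStats", function(x) nrow(x@variants))

#' @rdname mrscreen-accessors
setMethod("exposureName", "HarmonizedSet", function(x) x@exposureName)
#' @rdname mrscreen-accessors
setMethod("outcomeName", "HarmonizedSet", function(x) x@outcomeName)
#' @rdname mrscreen-accessors
setMethod("instruments", "HarmonizedSet", function(x) x@snps)
#' @rdname mrscreen-accessors
setMethod("nInstruments", "HarmonizedSet", function(x) nrow(x@snps))

#' @rdname mrscreen-accessors
setMethod("mrMethod", "MREstimate", function(x) x@method)
#' @rdname mrscreen-accessors
setMethod("thetaHat", "MREstimate", function(x) x@thetaHat)
#' @rdname mrscreen-accessors
setMethod("stdError", "MREstimate", function(x) x@se)
#' @rdname mrscreen-accessors
setMethod("pValue", "MREstimate", function(x) x@pvalue)
#' @rdname mrscreen-accessors
setMethod("confInt", "MREstimate",
          function(x) c(low = x@ciLow, high = x@ciHigh))
#' @rdname mrscreen-accessors
setMethod("oddsRatio", "MREstimate",
          function(x) c(or = x@orValue, low = x@orLow, high = x@orHigh))
#' @rdname mrscreen-accessors
setMethod("nSnps", "MREstimate", function(x) x@nSnps)
#' @rdname mrscreen-accessors
setMethod("mrExtra", "MREstimate", function(x) x@extra)

#' @rdname mrscreen-accessors
setMethod("pValue", "MediationResult", function(x) x@step1Pvalue)
#' @rdname mrscreen-accessors
setMethod("indirectEffect", "MediationResult", function(x) x@indirect)
#' @rdname mrscreen-accessors
setMethod("proportionMediated", "MediationResult", function(x) x@proportion)
#' @rdname mrscreen-accessors
setMethod("gatePassed", "MediationResult", function(x) x@gatePassed)

#' @rdname mrscreen-accessors
setMethod("exposureName", "SensitivityReport", function(x) x@exposureName)
#' @rdname mrscreen-accessors
setMethod("outcomeName", "SensitivityReport", function(x) x@outcomeName)
#' @rdname mrscreen-accessors
setMethod("sensitivityTable", "SensitivityReport", function(x) {
  data.frame(exposure = x@exposureName, outcome = x@outcomeName,
             Q = x@Q, Q_df = x@QDf, Q_p = x@QPvalue, I2 = x@I2,
             egger_intercept = x@eggerIntercept,
             egger_intercept_se = x@eggerInterceptSe,
             egger_intercept_p = x@eggerInterceptPvalue,
             rss_obs = x@pressoRssObs,
             presso_global_p = x@pressoGlobalPvalue,
             presso_outliers = paste(x@pressoOutliers, collapse = ","),
             stringsAsFactors = FALSE)
})
#' @rdname mrscreen-accessors
setMethod("looTable", "SensitivityReport", function(x) x@loo)

setMethod("show", "SummaryStats", function(object) {
  cat(sprintf("SummaryStats: %s (%s), %d variants\n", object@traitName,
              object@traitType, nrow(object@variants)))
  if (nrow(object@variants))
    print(utils::head(object@variants, 3L))
})

setMethod("show", "HarmonizedSet", function(object) {
  cat(sprintf("HarmonizedSet: %s -> %s, %d instruments (%d dropped)\n",
              object@exposureName, object@outcomeName, nrow(object@snps),
              nrow(object@log)))
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf(
    "MREstimate [%s] n_snps=%d\n  beta %.4g (se %.4g), OR %.4g [%.4g, %.4g], p=%.3g\n",
    object@method, object@nSnps, object@thetaHat, object@se,
    object@orValue, object@orLow, object@orHigh, object@pvalue))
})

setMethod("show", "SensitivityReport", function(object) {
  cat(sprintf("SensitivityReport: %s -> %s\n", object@exposureName,
              object@outcomeName))
  cat(sprintf("  Q=%.4g (df=%s, p=%.3g), I2=%.1f%%\n", object@Q,
              format(object@QDf), object@QPvalue, object@I2))
  cat(sprintf("  Egger intercept %.4g (se %.4g, p=%.3g)\n",
              object@eggerIntercept, object@eggerInterceptSe,
              object@eggerInterceptPvalue))
  cat(sprintf("  MR-PRESSO RSSobs=%.4g, global p=%.3g, outliers: %s\n",
              object@pressoRssObs, object@pressoGlobalPvalue,
              if (length(object@pressoOutliers))
                paste(object@pressoOutliers, collapse = ",") else "none"))
})

setMethod("show", "MediationResult", function(object) {
  cat(sprintf("MediationResult: indirect=%.4g (se %.4g), proportion=%.4g\n",
              object@indirect, object@indirectSe, object@proportion))
  cat(sprintf("  beta1=%.4g beta2=%.4g beta3=%.4g; step-1 gate %s (p=%.3g)\n",
              object@beta1, object@beta2, object@beta3,
              if (object@gatePassed) "passed" else "failed",
              object@step1Pvalue))
})

setMethod("show", "LDMatrix", function(object) {
  cat(sprintf("LDMatrix: %d ids, %d stored pairs\n", length(object@ids),
              length(object@r2)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: J=%d, n_exp=%d, n_out=%d, theta=%g, pleiotropy=%s, seed=%d\n",
    object@nSnps, object@nExposure, object@nOutcome, object@theta,
    object@pleiotropyMode, object@seed))
})
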