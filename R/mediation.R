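#' Two-step mediation Mendelian randomization
#'
#' Combines three MR estimates into a mediation decomposition:
#' beta1 (exposure to mediator), beta2 (mediator to outcome) and beta3
#' (the total exposure-to-outcome effect, from the direct MR, not a
#' re-composition). The indirect effect is the product beta1*beta2 with
#' Sobel delta-method standard error
#' sqrt(beta1^2 se2^2 + beta2^2 se1^2); the proportion mediated is
#' beta1*beta2/beta3. The step-1 significance gate mirrors the usual
#' screening logic: mediation is only claimed when the exposure has a
#' nominally significant causal effect on the mediator; when the gate
#' fails the result is still computed but flagged unsupported.
#'
#' @param step1 [MREstimate-class] for exposure -> mediator (beta1).
#' @param step2 [MREstimate-class] for mediator -> outcome (beta2).
#' @param step3 [MREstimate-class] for exposure -> outcome (beta3, total).
#' @param gateAlpha significance level for the step-1 gate (default 0.05).
#' @return a [MediationResult-class]. The proportion is \code{NA} with a
#'   warning when beta3 = 0.
#' @examples
#' est <- function(b, s) mrscreen:::.mkEstimate("ivw", b, s,
#'   2 * pnorm(-abs(b / s)), 5L)
#' twoStepMediation(est(0.5, 0.1), est(0.4, 0.1), est(1.0, 0.1))
#' @export
twoStepMediation <- function(step1, step2, step3, gateAlpha = 0.05) {
  stopifnot(is(step1, "MREstimate"), is(step2, "MREstimate"),
            is(step3, "MREstimate"))
  b1 <- step1@thetaHat; s1 <- step1@se
  b2 <- step2@thetaHat; s2 <- step2@se
  b3 <- step3@thetaHat; s3 <- step3@se
  indirect <- b1 * b2
  indirectSe <- sqrt(b1^2 * s2^2 + b2^2 * s1^2)
  if (b3 == 0) {
    warning("total effect beta3 is zero; proportion mediated undefined",
            call. = FALSE)
    proportion <- NA_real_
  } else {
    proportion <- indirect / b3
  }
  new("MediationResult", beta1 = b1, se1 = s1, beta2 = b2, se2 = s2,
      beta3 = b3, se3 = s3, indirect = indirect, indirectSe = indirectSe,
      proportion = proportion,
      gatePassed = is.finite(step1@pvalue) && step1@pvalue < gateAlpha,
      gateAlpha = gateAlpha, step1Pvalue = step1@pvalue)
}

#' Monte-Carlo standard error for a product of two estimates
#'
#' Product-of-normals alternative to the Sobel formula: samples beta1 and
#' beta2 from normal distributions with their standard errors and returns
#' the standard deviation of the sampled products.
#'
#' @param beta1,se1,beta2,se2 the two estimates and standard errors.
#' @param nDraws Monte-Carlo draws (default 10000).
#' @param seed integer seed.
#' @return numeric standard error.
#' @export
productSeMonteCarlo <- function(beta1, se1, beta2, se2, nDraws = 10000,
                                seed = 1L) {
  set.seed(.needSeed(seed))
  stats::sd(stats::rnorm(nDraws, beta1, se1) * stats::rnorm(nDraws, beta2, se2))
}

#' Run a full two-step mediation MR from summary statistics
#'
#' Convenience wrapper: selects instruments for the exposure and for the
#' mediator, harmonizes the three trait pairs, fits IVW for each step and
#' combines them with [twoStepMediation()].
#'
#' @param exposure,mediator,outcome [SummaryStats-class] objects.
#' @param ld an [LDMatrix-class] or \code{NULL}.
#' @param exposureConfig,mediatorConfig [SelectionConfig-class] for the
#'   two instrument selections (defaults: exposure p < 1e-5, mediator
#'   p < 5e-6, matching microbiome and cytokine screening thresholds).
#' @param gateAlpha step-1 gate level.
#' @param effectsModel IVW effects model.
#' @return a [MediationResult-class].
#' @export
estimateMediation <- function(exposure, mediator, outcome, ld = NULL,
                              exposureConfig = selectionConfig(pThreshold = 1e-5),
                              mediatorConfig = selectionConfig(pThreshold = 5e-6),
                              gateAlpha = 0.05,
                              effectsModel = c("multiplicative_random",
                                               "fixed")) {
  effectsModel <- match.arg(effectsModel)
  selE <- selectInstruments(exposure, ld, exposureConfig)
  selM <- selectInstruments(mediator, ld, mediatorConfig)
  est1 <- suppressWarnings(
    mrIVW(harmonize(exposure, mediator, selE$variant_id), effectsModel))
  est2 <- suppressWarnings(
    mrIVW(harmonize(mediator, outcome, selM$variant_id), effectsModel))
  est3 <- suppressWarnings(
    mrIVW(harmonize(exposure, outcome, selE$variant_id), effectsModel))
  twoStepMediation(est1, est2, est3, gateAlpha)
}
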