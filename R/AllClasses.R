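#' @import methods
NULL

.SUMMARY_COLS <- c("variant_id", "chrom", "pos", "effect_allele",
                   "other_allele", "eaf", "beta", "se", "pvalue", "n")

#' Per-trait GWAS summary statistics
#'
#' A table of per-variant associations with one trait. Each row holds one
#' SNP's effect estimate on the trait: variant identifier, chromosome,
#' 1-based position, effect and other allele (A/C/G/T), effect-allele
#' frequency (may be \code{NA}), per-allele effect \code{beta} (log odds
#' ratio for binary traits), its standard error, p-value and sample size.
#'
#' @slot traitName single character, name of the trait.
#' @slot traitType \code{"binary"} or \code{"continuous"}.
#' @slot variants data.frame with columns \code{variant_id}, \code{chrom},
#'   \code{pos}, \code{effect_allele}, \code{other_allele}, \code{eaf},
#'   \code{beta}, \code{se}, \code{pvalue}, \code{n}.
#' @slot log list of per-stage drop counts recorded while reading.
#'
#' @seealso [readSummaryStats()], [harmonize()]
#' @export
setClass("SummaryStats",
         slots = c(traitName = "character", traitType = "character",
                   variants = "data.frame", log = "list"))

setValidity("SummaryStats", function(object) {
  msgs <- character()
  miss <- setdiff(.SUMMARY_COLS, names(object@variants))
  if (length(miss)) {
    msgs <- c(msgs, paste0("missing variant columns: ",
                           paste(miss, collapse = ", ")))
  } else {
    v <- object@variants
    if (anyDuplicated(v$variant_id))
      msgs <- c(msgs, "variant_id must be unique within a table")
    if (any(!is.na(v$se) & v$se <= 0))
      msgs <- c(msgs, "all standard errors must be > 0")
    if (any(v$effect_allele == v$other_allele))
      msgs <- c(msgs, "effect and other allele must differ")
    if (any(!is.na(v$eaf) & (v$eaf < 0 | v$eaf > 1)))
      msgs <- c(msgs, "eaf must lie in [0, 1]")
    if (any(!is.na(v$pvalue) & (v$pvalue <= 0 | v$pvalue > 1)))
      msgs <- c(msgs, "p-values must lie in (0, 1]")
  }
  if (length(object@traitType) != 1L ||
      !object@traitType %in% c("binary", "continuous"))
    msgs <- c(msgs, "traitType must be 'binary' or 'continuous'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SummaryStats object
#'
#' @param variants data.frame of per-variant associations; missing optional
#'   columns (\code{chrom}, \code{pos}, \code{eaf}, \code{n}) are filled
#'   with \code{NA}.
#' @param traitName trait label.
#' @param traitType \code{"continuous"} (default) or \code{"binary"}.
#' @param log optional list of bookkeeping counts.
#' @return a [SummaryStats-class] object.
#' @export
SummaryStats <- function(variants, traitName,
                         traitType = c("continuous", "binary"),
                         log = list()) {
  traitType <- match.arg(traitType)
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  for (col in c("chrom", "pos", "eaf", "n")) {
    if (!col %in% names(v))
      v[[col]] <- if (col == "chrom") NA_character_ else NA_real_
  }
  v$variant_id <- as.character(v$variant_id)
  v$chrom <- as.character(v$chrom)
  v$effect_allele <- toupper(as.character(v$effect_allele))
  v$other_allele <- toupper(as.character(v$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n"))
    v[[col]] <- as.numeric(v[[col]])
  v <- v[, .SUMMARY_COLS]
  rownames(v) <- NULL
  new("SummaryStats", traitName = as.character(traitName),
      traitType = traitType, variants = v, log = log)
}

.HARMONIZED_COLS <- c("variant_id", "chrom", "pos", "effect_allele",
                      "other_allele", "eaf_exposure", "eaf_outcome",
                      "beta_exposure", "se_exposure", "pval_exposure",
                      "beta_outcome", "se_outcome", "pval_outcome", "f_stat")

#' Harmonized exposure/outcome instrument set
#'
#' Per-SNP exposure and outcome associations expressed on a shared
#' effect-allele frame, ready for MR estimation. For SNP j the exposure
#' effect and standard error are the instrument-exposure association
#' (gamma_j, sigma_Xj) and the outcome columns hold (Gamma_j, sigma_Yj).
#' Palindromic SNPs and SNPs absent from the outcome never appear here.
#'
#' @slot exposureName,outcomeName trait labels.
#' @slot snps data.frame with paired effect columns (see
#'   \code{mrscreen:::.HARMONIZED_COLS}).
#' @slot log data.frame of dropped SNPs with a \code{reason} per SNP.
#' @export
setClass("HarmonizedSet",
         slots = c(exposureName = "character", outcomeName = "character",
                   snps = "data.frame", log = "data.frame"))

setValidity("HarmonizedSet", function(object) {
  msgs <- character()
  miss <- setdiff(.HARMONIZED_COLS, names(object@snps))
  if (length(miss)) {
    msgs <- c(msgs, paste0("missing columns: ", paste(miss, collapse = ", ")))
  } else {
    s <- object@snps
    if (anyDuplicated(s$variant_id)) msgs <- c(msgs, "duplicate variant_id")
    if (any(s$se_exposure <= 0) || any(s$se_outcome <= 0))
      msgs <- c(msgs, "all standard errors must be > 0")
    pal <- .COMPLEMENT[s$effect_allele] == s$other_allele
    if (any(pal %in% TRUE))
      msgs <- c(msgs, "palindromic SNPs must not remain after harmonization")
  }
  if (length(msgs)) msgs else TRUE
})

#' One method's causal estimate
#'
#' @slot method one of \code{wald_ratio}, \code{ivw}, \code{egger},
#'   \code{weighted_median}, \code{simple_mode}, \code{weighted_mode}.
#' @slot thetaHat causal effect on the beta (log-odds) scale.
#' @slot se standard error of \code{thetaHat}.
#' @slot ciLow,ciHigh 95\% confidence bounds, beta scale.
#' @slot orValue,orLow,orHigh exponentiated equivalents.
#' @slot pvalue two-sided p-value.
#' @slot nSnps number of instruments used.
#' @slot extra method-specific fields (e.g. Egger intercept record).
#' @export
setClass("MREstimate",
         slots = c(method = "character", thetaHat = "numeric", se = "numeric",
                   ciLow = "numeric", ciHigh = "numeric", orValue = "numeric",
                   orLow = "numeric", orHigh = "numeric", pvalue = "numeric",
                   nSnps = "integer", extra = "list"))

setValidity("MREstimate", function(object) {
  msgs <- character()
  ok <- c("wald_ratio", "ivw", "egger", "weighted_median", "simple_mode",
          "weighted_mode")
  if (!object@method %in% ok)
    msgs <- c(msgs, paste0("unknown method '", object@method, "'"))
  if (is.finite(object@ciLow) && is.finite(object@ciHigh) &&
      (object@ciLow > object@thetaHat || object@thetaHat > object@ciHigh))
    msgs <- c(msgs, "confidence bounds must bracket thetaHat")
  if (object@nSnps < 1L) msgs <- c(msgs, "nSnps must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Heterogeneity and pleiotropy diagnostics for one instrument set
#'
#' Bundles Cochran's Q (with df, p and I-squared), the MR-Egger intercept
#' test, the MR-PRESSO global test with outlier ids, and leave-one-out IVW
#' estimates. Diagnostics whose minimum instrument count is not met are
#' reported as \code{NA} fields rather than omitted.
#' @export
setClass("SensitivityReport",
         slots = c(exposureName = "character", outcomeName = "character",
                   Q = "numeric", QDf = "numeric", QPvalue = "numeric",
                   I2 = "numeric", eggerIntercept = "numeric",
                   eggerInterceptSe = "numeric",
                   eggerInterceptPvalue = "numeric",
                   pressoRssObs = "numeric", pressoGlobalPvalue = "numeric",
                   pressoNSim = "numeric", pressoOutliers = "character",
                   loo = "data.frame"))

#' Two-step mediation MR result
#'
#' Holds the three component estimates (exposure to mediator beta1,
#' mediator to outcome beta2, exposure to outcome beta3), the product
#' indirect effect beta1*beta2 with its Sobel standard error, and the
#' proportion mediated beta1*beta2/beta3.
#' @export
setClass("MediationResult",
         slots = c(beta1 = "numeric", se1 = "numeric", beta2 = "numeric",
                   se2 = "numeric", beta3 = "numeric", se3 = "numeric",
                   indirect = "numeric", indirectSe = "numeric",
                   proportion = "numeric", gatePassed = "logical",
                   gateAlpha = "numeric", step1Pvalue = "numeric"))

#' Instrument selection configuration
#'
#' @slot pThreshold exposure-association significance cutoff (instruments
#'   must satisfy p < pThreshold).
#' @slot clumpR2 LD r-squared above which a SNP is claimed by a clump index.
#' @slot clumpWindowKb clumping window half-width in kilobases (inclusive).
#' @slot fMin weak-instrument cutoff; SNPs with F <= fMin are dropped or
#'   flagged per \code{fAction}.
#' @slot fAction \code{"drop"} or \code{"flag"}.
#' @export
setClass("SelectionConfig",
         slots = c(pThreshold = "numeric", clumpR2 = "numeric",
                   clumpWindowKb = "numeric", fMin = "numeric",
                   fAction = "character"))

setValidity("SelectionConfig", function(object) {
  msgs <- character()
  if (!(object@pThreshold > 0 && object@pThreshold <= 1))
    msgs <- c(msgs, "pThreshold must lie in (0, 1]")
  if (object@clumpR2 < 0 || object@clumpR2 > 1)
    msgs <- c(msgs, "clumpR2 must lie in [0, 1]")
  if (object@clumpWindowKb <= 0) msgs <- c(msgs, "clumpWindowKb must be > 0")
  if (!object@fAction %in% c("drop", "flag"))
    msgs <- c(msgs, "fAction must be 'drop' or 'flag'")
  if (length(msgs)) msgs else TRUE
})

#' @param pThreshold,clumpR2,clumpWindowKb,fMin,fAction see slots.
#' @return a \code{SelectionConfig}.
#' @rdname SelectionConfig-class
#' @export
selectionConfig <- function(pThreshold = 5e-8, clumpR2 = 0.01,
                            clumpWindowKb = 10000, fMin = 10,
                            fAction = c("drop", "flag")) {
  new("SelectionConfig", pThreshold = pThreshold, clumpR2 = clumpR2,
      clumpWindowKb = clumpWindowKb, fMin = fMin,
      fAction = match.arg(fAction))
}

#' Pairwise LD (r-squared) lookup table
#'
#' Sparse symmetric store of pairwise r-squared values; pairs not present
#' are treated as r2 = 0 and the diagonal as 1. Cross-chromosome pairs are
#' always treated as unlinked by the clumping routine regardless of the
#' stored values.
#' @slot ids variant ids mentioned by the table.
#' @slot r2 named numeric; names are canonical "a\\tb" keys with a < b.
#' @export
setClass("LDMatrix", slots = c(ids = "character", r2 = "numeric"))

setValidity("LDMatrix", function(object) {
  if (length(object@r2) &&
      (any(object@r2 < 0) || any(object@r2 > 1)))
    "r2 values must lie in [0, 1]" else TRUE
})

#' Synthetic GWAS generating configuration
#'
#' Parameters of the linear structural model used by [simulatePair()] and
#' [simulateMediationChain()]; see those functions for the model.
#' @export
setClass("SimConfig",
         slots = c(nSnps = "integer", nExposure = "integer",
                   nOutcome = "integer", theta = "numeric",
                   pleiotropyMode = "character", pleiotropyMean = "numeric",
                   pleiotropySd = "numeric", pleiotropyFrac = "numeric",
                   mafRange = "numeric", nNullSnps = "integer",
                   ldBlocks = "list", mediation = "list",
                   nOutcomeSnps = "integer", reverseTheta = "numeric",
                   noiseScale = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msgs <- character()
  if (object@nSnps < 1L) msgs <- c(msgs, "nSnps must be >= 1")
  if (object@nExposure < 1L || object@nOutcome < 1L)
    msgs <- c(msgs, "sample sizes must be positive")
  if (object@pleiotropySd < 0) msgs <- c(msgs, "pleiotropySd must be >= 0")
  if (length(object@mafRange) != 2L || any(object@mafRange <= 0) ||
      any(object@mafRange > 0.5) ||
      object@mafRange[1] > object@mafRange[2])
    msgs <- c(msgs, "mafRange must be increasing within (0, 0.5]")
  if (object@pleiotropyFrac < 0 || object@pleiotropyFrac > 1)
    msgs <- c(msgs, "pleiotropyFrac must lie in [0, 1]")
  if (!object@pleiotropyMode %in%
      c("none", "balanced", "directional", "inside_violating"))
    msgs <- c(msgs, "unknown pleiotropyMode")
  if (object@noiseScale < 0) msgs <- c(msgs, "noiseScale must be >= 0")
  if (length(msgs)) msgs else TRUE
})
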