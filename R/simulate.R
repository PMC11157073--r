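#' Synthetic GWAS generating configuration
#'
#' Builds a [SimConfig-class] describing the linear structural model used
#' by [simulatePair()] and [simulateMediationChain()]. Defaults emulate a
#' desk-scale two-sample MR study: 50 instruments, 20,000 samples per
#' trait (the scale of consortium microbiome/cytokine GWAS), minor allele
#' frequencies uniform on (0.05, 0.5), and no pleiotropy.
#'
#' @param nSnps number of instrument SNPs J.
#' @param nExposure,nOutcome GWAS sample sizes for the two traits.
#' @param theta true causal effect of exposure on outcome (beta scale).
#' @param pleiotropyMode \code{"none"}, \code{"balanced"} (mean-zero
#'   direct effects), \code{"directional"} (mean \code{pleiotropyMean}),
#'   or \code{"inside_violating"} (direct effects correlated with
#'   instrument strength, violating the InSiDE assumption).
#' @param pleiotropyMean mean direct effect under the directional and
#'   InSiDE-violating modes.
#' @param pleiotropySd spread of the direct effects.
#' @param pleiotropyFrac fraction of instruments carrying a pleiotropic
#'   effect (the rest are valid); default 1.
#' @param mafRange range of simulated minor allele frequencies.
#' @param nNullSnps decoy SNPs with no exposure effect whose p-values are
#'   constructed to sit above any instrument threshold in use.
#' @param ldBlocks \code{NULL} for fully unlinked SNPs, or
#'   \code{list(size =, r2 =)} giving the LD block size and the
#'   compound-symmetric within-block r-squared (blocks are mutually
#'   unlinked).
#' @param mediation \code{NULL}, or \code{list(beta1 =, beta2 =,
#'   direct =, nMediator =, nSnpsMediator =)} describing an
#'   exposure -> mediator -> outcome chain (see
#'   [simulateMediationChain()]).
#' @param nOutcomeSnps SNPs with direct effects on the outcome trait
#'   (instruments *for* the outcome), used to exercise reverse MR.
#' @param reverseTheta causal effect of outcome on exposure carried by the
#'   outcome instruments (0 = unidirectional X -> Y).
#' @param noiseScale multiplier on all sampling noise; 0 gives the
#'   deterministic regime in which observed effects equal their means and
#'   IVW recovers theta exactly.
#' @param seed master integer seed; sub-streams are derived from it by
#'   fixed offsets, one per SNP category, so e.g. adding decoys does not
#'   perturb the instrument draws.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(nSnps = 50, nExposure = 20000, nOutcome = 20000,
                      theta = 0,
                      pleiotropyMode = c("none", "balanced", "directional",
                                         "inside_violating"),
                      pleiotropyMean = 0.05, pleiotropySd = 0.01,
                      pleiotropyFrac = 1, mafRange = c(0.05, 0.5),
                      nNullSnps = 0, ldBlocks = NULL, mediation = NULL,
                      nOutcomeSnps = 0, reverseTheta = 0, noiseScale = 1,
                      seed = 1L) {
  pleiotropyMode <- match.arg(pleiotropyMode)
  if (!is.null(mediation)) {
    need <- c("beta1", "beta2", "direct")
    miss <- setdiff(need, names(mediation))
    if (length(miss))
      .mrError(paste0("mediation block missing: ",
                      paste(miss, collapse = ", ")),
               "mrscreen_config_error")
    if (is.null(mediation$nMediator)) mediation$nMediator <- nOutcome
    if (is.null(mediation$nSnpsMediator)) mediation$nSnpsMediator <- nSnps
  }
  new("SimConfig", nSnps = as.integer(nSnps),
      nExposure = as.integer(nExposure), nOutcome = as.integer(nOutcome),
      theta = theta, pleiotropyMode = pleiotropyMode,
      pleiotropyMean = pleiotropyMean, pleiotropySd = pleiotropySd,
      pleiotropyFrac = pleiotropyFrac, mafRange = as.numeric(mafRange),
      nNullSnps = as.integer(nNullSnps),
      ldBlocks = if (is.null(ldBlocks)) list() else ldBlocks,
      mediation = if (is.null(mediation)) list() else mediation,
      nOutcomeSnps = as.integer(nOutcomeSnps), reverseTheta = reverseTheta,
      noiseScale = as.numeric(noiseScale), seed = as.integer(seed))
}

# GWAS standard error of a per-allele effect for a standardized trait
.gwasSe <- function(maf, n) 1 / sqrt(2 * maf * (1 - maf) * n)

# non-palindromic ordered allele pairs
.NONPAL_PAIRS <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                          "G", "A", "G", "T", "T", "C", "T", "G"),
                        ncol = 2, byrow = TRUE)

# chromosome/position layout: each LD block sits on its own stretch,
# blocks >= 30 Mb apart (outside any 10 Mb clumping window)
.layout <- function(nSnps, blockSizes) {
  blockOf <- rep(seq_along(blockSizes), blockSizes)[seq_len(nSnps)]
  within <- sequence(blockSizes)[seq_len(nSnps)]
  chrom <- as.character(((blockOf - 1L) %% 22L) + 1L)
  ordinal <- ((blockOf - 1L) %/% 22L)
  pos <- 1e6 + ordinal * 3e7 + (within - 1L) * 5e4
  list(chrom = chrom, pos = pos, block = blockOf)
}

# draw maf, alleles and clamped true effects for one SNP category
.drawCategory <- function(n, cfg, nSample, idOffset, seedOffset,
                          clampSd = 0.05, clamp = 6) {
  set.seed(.subSeed(cfg@seed, seedOffset))
  maf <- stats::runif(n, cfg@mafRange[1], cfg@mafRange[2])
  pair <- .NONPAL_PAIRS[sample.int(nrow(.NONPAL_PAIRS), n, replace = TRUE), ,
                        drop = FALSE]
  se <- .gwasSe(maf, nSample)
  # effects are reported for the trait-raising allele (all positive), the
  # usual orientation in MR simulation studies; magnitudes are clamped so
  # instruments are not weak
  raw <- clampSd * stats::rnorm(n)
  bTrue <- pmax(abs(raw), clamp * se)
  bHat <- if (cfg@noiseScale == 0) bTrue else
    stats::rnorm(n, bTrue, se * cfg@noiseScale)
  list(id = sprintf("rs%06d", idOffset + seq_len(n)), maf = maf,
       effect = pair[, 1], other = pair[, 2], se = se, bTrue = bTrue,
       bHat = bHat)
}

.pFromZ <- function(beta, se) 2 * stats::pnorm(-abs(beta) / se)

# per-SNP pleiotropic direct effects
.drawAlpha <- function(cfg, gammaTrue) {
  J <- length(gammaTrue)
  alpha <- numeric(J)
  if (cfg@pleiotropyMode == "none") return(alpha)
  tau <- cfg@pleiotropySd
  alpha <- switch(cfg@pleiotropyMode,
    balanced = stats::rnorm(J, 0, tau),
    directional = stats::rnorm(J, cfg@pleiotropyMean, tau),
    inside_violating = {
      # direct effects correlated (r = 0.7) with instrument strength
      z <- (gammaTrue - mean(gammaTrue)) / stats::sd(gammaTrue)
      cfg@pleiotropyMean + tau * (0.7 * z + sqrt(1 - 0.49) * stats::rnorm(J))
    })
  if (cfg@pleiotropyFrac < 1) {
    nOn <- round(cfg@pleiotropyFrac * J)
    on <- sample.int(J, nOn)
    mask <- rep(FALSE, J); mask[on] <- TRUE
    alpha[!mask] <- 0
  }
  alpha
}

# decoy null SNPs: |z| truncated below 3.5 so p >= ~4.7e-4, above any
# instrument threshold in use
.truncZ <- function(n) {
  stats::qnorm(stats::runif(n, stats::pnorm(-3.5), stats::pnorm(3.5)))
}

#' Simulate a two-sample GWAS summary-statistics pair
#'
#' Generates exposure and outcome summary statistics under a linear
#' structural model with known truth. For instrument SNP j with minor
#' allele frequency f_j, the reported standard errors follow the
#' standardized-trait GWAS form sigma = 1/sqrt(2 f_j (1-f_j) n); true
#' exposure effect magnitudes gamma_j are |N(0, 0.05^2)| draws, expressed
#' for the exposure-raising allele (the usual orientation in MR
#' simulation work, and the frame in which a directional pleiotropy mean
#' is meaningful) and clamped to at least 6 sigma_Xj so that instrument F
#' statistics typically exceed 10; observed effects add
#' N(0, sigma_Xj^2) noise.
#' Outcome associations are drawn with mean theta * gamma_hat_j + alpha_j
#' conditional on the realized exposure associations (so estimator
#' recovery is not confounded by weak-instrument dilution) and standard
#' deviation sigma_Yj * noiseScale; alpha_j follows the configured
#' pleiotropy regime. Decoy null SNPs (exposure p-values above any
#' instrument threshold by construction), LD blocks and
#' outcome-instrument SNPs for reverse MR are appended per the
#' configuration. All draws are reproducible from the master seed.
#'
#' @param config a [SimConfig-class].
#' @return list with elements \code{exposure} and \code{outcome}
#'   ([SummaryStats-class]), \code{ld} ([LDMatrix-class]) and
#'   \code{truth} (list echoing the generating parameters plus per-SNP
#'   true gamma_j and alpha_j and the instrument ids).
#' @export
simulatePair <- function(config) {
  stopifnot(is(config, "SimConfig"))
  cfg <- config
  J <- cfg@nSnps
  ns <- cfg@noiseScale

  inst <- .drawCategory(J, cfg, cfg@nExposure, 0L, 1L)
  seY <- .gwasSe(inst$maf, cfg@nOutcome)

  set.seed(.subSeed(cfg@seed, 2L))
  alpha <- .drawAlpha(cfg, inst$bTrue)
  muY <- cfg@theta * inst$bHat + alpha
  GammaHat <- if (ns == 0) muY else stats::rnorm(J, muY, seY * ns)

  blockSizes <- if (length(cfg@ldBlocks)) {
    size <- cfg@ldBlocks$size
    rep(size, ceiling(J / size))
  } else rep(1L, J)
  lay <- .layout(J, blockSizes)
  ldPairs <- NULL
  if (length(cfg@ldBlocks) && cfg@ldBlocks$size > 1L) {
    pairRows <- lapply(unique(lay$block), function(b) {
      ids <- inst$id[lay$block == b]
      if (length(ids) < 2L) return(NULL)
      cmb <- utils::combn(ids, 2L)
      data.frame(id_a = cmb[1, ], id_b = cmb[2, ], r2 = cfg@ldBlocks$r2,
                 stringsAsFactors = FALSE)
    })
    ldPairs <- do.call(rbind, pairRows)
  }

  expRows <- data.frame(
    variant_id = inst$id, chrom = lay$chrom, pos = lay$pos,
    effect_allele = inst$effect, other_allele = inst$other, eaf = inst$maf,
    beta = inst$bHat, se = inst$se, pvalue = .pFromZ(inst$bHat, inst$se),
    n = cfg@nExposure, stringsAsFactors = FALSE)
  outRows <- data.frame(
    variant_id = inst$id, chrom = lay$chrom, pos = lay$pos,
    effect_allele = inst$effect, other_allele = inst$other, eaf = inst$maf,
    beta = GammaHat, se = seY, pvalue = .pFromZ(GammaHat, seY),
    n = cfg@nOutcome, stringsAsFactors = FALSE)

  nextChrom <- max(lay$block)
  if (cfg@nNullSnps > 0L) {
    nd <- cfg@nNullSnps
    set.seed(.subSeed(cfg@seed, 3L))
    maf <- stats::runif(nd, cfg@mafRange[1], cfg@mafRange[2])
    pair <- .NONPAL_PAIRS[sample.int(nrow(.NONPAL_PAIRS), nd,
                                     replace = TRUE), , drop = FALSE]
    seX <- .gwasSe(maf, cfg@nExposure)
    bX <- .truncZ(nd) * seX
    seYd <- .gwasSe(maf, cfg@nOutcome)
    bY <- stats::rnorm(nd, 0, seYd)
    layD <- .layout(nd, rep(1L, nd))
    ids <- sprintf("rs%06d", J + seq_len(nd))
    posD <- layD$pos + (nextChrom %/% 22L + 1L) * 3e8
    expRows <- rbind(expRows, data.frame(
      variant_id = ids, chrom = layD$chrom, pos = posD,
      effect_allele = pair[, 1], other_allele = pair[, 2], eaf = maf,
      beta = bX, se = seX, pvalue = .pFromZ(bX, seX), n = cfg@nExposure,
      stringsAsFactors = FALSE))
    outRows <- rbind(outRows, data.frame(
      variant_id = ids, chrom = layD$chrom, pos = posD,
      effect_allele = pair[, 1], other_allele = pair[, 2], eaf = maf,
      beta = bY, se = seYd, pvalue = .pFromZ(bY, seYd), n = cfg@nOutcome,
      stringsAsFactors = FALSE))
  }

  outSnpIds <- character()
  if (cfg@nOutcomeSnps > 0L) {
    no <- cfg@nOutcomeSnps
    # outcome-trait instruments: clamp against the outcome-side se
    ocat <- .drawCategory(no, cfg, cfg@nOutcome,
                          J + cfg@nNullSnps, 5L)
    outSnpIds <- ocat$id
    seXo <- .gwasSe(ocat$maf, cfg@nExposure)
    muX <- cfg@reverseTheta * ocat$bHat
    bXo <- if (ns == 0) muX else stats::rnorm(no, muX, seXo * ns)
    layO <- .layout(no, rep(1L, no))
    posO <- layO$pos + 6e8
    expRows <- rbind(expRows, data.frame(
      variant_id = ocat$id, chrom = layO$chrom, pos = posO,
      effect_allele = ocat$effect, other_allele = ocat$other,
      eaf = ocat$maf, beta = bXo, se = seXo, pvalue = .pFromZ(bXo, seXo),
      n = cfg@nExposure, stringsAsFactors = FALSE))
    outRows <- rbind(outRows, data.frame(
      variant_id = ocat$id, chrom = layO$chrom, pos = posO,
      effect_allele = ocat$effect, other_allele = ocat$other,
      eaf = ocat$maf, beta = ocat$bHat, se = ocat$se,
      pvalue = .pFromZ(ocat$bHat, ocat$se), n = cfg@nOutcome,
      stringsAsFactors = FALSE))
  }

  truth <- list(theta = cfg@theta, pleiotropy_mode = cfg@pleiotropyMode,
                pleiotropy_mean = cfg@pleiotropyMean,
                pleiotropy_sd = cfg@pleiotropySd,
                pleiotropy_frac = cfg@pleiotropyFrac,
                reverse_theta = cfg@reverseTheta,
                noise_scale = cfg@noiseScale, seed = cfg@seed,
                instrument_ids = inst$id, gamma_true = inst$bTrue,
                alpha = alpha, outcome_snp_ids = outSnpIds)

  list(exposure = SummaryStats(expRows, "sim_exposure"),
       outcome = SummaryStats(outRows, "sim_outcome"),
       ld = ldMatrix(ldPairs, ids = expRows$variant_id),
       truth = truth)
}

#' Simulate an exposure -> mediator -> outcome chain
#'
#' Extends [simulatePair()] with a mediator trait. Exposure instruments
#' affect the mediator with slope beta1 and the outcome with total slope
#' direct + beta1*beta2; a second, independent set of SNPs instruments
#' the mediator directly (effects delta_k) and reaches the outcome with
#' slope beta2. The true proportion mediated is
#' beta1*beta2/(direct + beta1*beta2). In the noiseless regime
#' (noiseScale = 0) the pipeline recovers it exactly.
#'
#' @param config a [SimConfig-class] whose \code{mediation} block holds
#'   \code{beta1}, \code{beta2}, \code{direct} (and optionally
#'   \code{nMediator}, \code{nSnpsMediator}).
#' @return list with \code{exposure}, \code{mediator}, \code{outcome}
#'   ([SummaryStats-class]), \code{ld} and \code{truth} (including
#'   \code{proportion_true}).
#' @export
simulateMediationChain <- function(config) {
  stopifnot(is(config, "SimConfig"))
  cfg <- config
  if (!length(cfg@mediation))
    .mrError("config has no mediation block", "mrscreen_config_error")
  med <- cfg@mediation
  J <- cfg@nSnps
  K <- as.integer(med$nSnpsMediator)
  nM <- as.integer(med$nMediator)
  ns <- cfg@noiseScale
  totalSlope <- med$direct + med$beta1 * med$beta2

  inst <- .drawCategory(J, cfg, cfg@nExposure, 0L, 1L)
  layI <- .layout(J, rep(1L, J))
  # mediator's own instruments
  mcat <- .drawCategory(K, cfg, nM, J, 4L)
  layM <- .layout(K, rep(1L, K))
  posM <- layM$pos + 6e8

  seM_inst <- .gwasSe(inst$maf, nM)
  seY_inst <- .gwasSe(inst$maf, cfg@nOutcome)
  seX_m <- .gwasSe(mcat$maf, cfg@nExposure)
  seY_m <- .gwasSe(mcat$maf, cfg@nOutcome)

  set.seed(.subSeed(cfg@seed, 2L))
  alpha <- .drawAlpha(cfg, inst$bTrue)
  draw <- function(mu, s) if (ns == 0) mu else stats::rnorm(length(mu), mu,
                                                            s * ns)
  medB_inst <- draw(med$beta1 * inst$bHat, seM_inst)
  outB_inst <- draw(totalSlope * inst$bHat + alpha, seY_inst)
  expB_m <- draw(rep(0, K), seX_m)
  outB_m <- draw(med$beta2 * mcat$bHat, seY_m)

  mk <- function(id, chrom, pos, eff, oth, maf, beta, se, n) {
    data.frame(variant_id = id, chrom = chrom, pos = pos,
               effect_allele = eff, other_allele = oth, eaf = maf,
               beta = beta, se = se, pvalue = .pFromZ(beta, se), n = n,
               stringsAsFactors = FALSE)
  }
  expTab <- rbind(
    mk(inst$id, layI$chrom, layI$pos, inst$effect, inst$other, inst$maf,
       inst$bHat, inst$se, cfg@nExposure),
    mk(mcat$id, layM$chrom, posM, mcat$effect, mcat$other, mcat$maf,
       expB_m, seX_m, cfg@nExposure))
  medTab <- rbind(
    mk(inst$id, layI$chrom, layI$pos, inst$effect, inst$other, inst$maf,
       medB_inst, seM_inst, nM),
    mk(mcat$id, layM$chrom, posM, mcat$effect, mcat$other, mcat$maf,
       mcat$bHat, mcat$se, nM))
  outTab <- rbind(
    mk(inst$id, layI$chrom, layI$pos, inst$effect, inst$other, inst$maf,
       outB_inst, seY_inst, cfg@nOutcome),
    mk(mcat$id, layM$chrom, posM, mcat$effect, mcat$other, mcat$maf,
       outB_m, seY_m, cfg@nOutcome))

  truth <- list(beta1 = med$beta1, beta2 = med$beta2, direct = med$direct,
                total = totalSlope,
                proportion_true = med$beta1 * med$beta2 / totalSlope,
                theta = cfg@theta, noise_scale = ns, seed = cfg@seed,
                instrument_ids = inst$id, mediator_snp_ids = mcat$id,
                gamma_true = inst$bTrue, delta_true = mcat$bTrue,
                alpha = alpha)

  list(exposure = SummaryStats(expTab, "sim_exposure"),
       mediator = SummaryStats(medTab, "sim_mediator"),
       outcome = SummaryStats(outTab, "sim_outcome"),
       ld = ldMatrix(NULL, ids = expTab$variant_id), truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Writes exposure.tsv, outcome.tsv (and mediator.tsv for chains), ld.tsv
#' and truth.json (plain-text JSON written without external dependencies)
#' into a directory.
#'
#' @param sim result of [simulatePair()] or [simulateMediationChain()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSimulatedData <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeSummaryStats(sim$exposure, file.path(dir, "exposure.tsv"))
  writeSummaryStats(sim$outcome, file.path(dir, "outcome.tsv"))
  if (!is.null(sim$mediator))
    writeSummaryStats(sim$mediator, file.path(dir, "mediator.tsv"))
  writeLDFile(sim$ld, file.path(dir, "ld.tsv"))
  writeLines(.toJSON(sim$truth), file.path(dir, "truth.json"))
  invisible(dir)
}

# minimal JSON serializer for the truth record (scalars, vectors, lists)
.toJSON <- function(x) {
  esc <- function(s) gsub('"', '\\\\"', s)
  one <- function(v) {
    if (is.null(v)) return("null")
    if (is.list(v))
      return(paste0("{", paste0('"', esc(names(v)), '": ',
                                vapply(v, one, ""), collapse = ", "), "}"))
    vals <- if (is.character(v)) paste0('"', esc(v), '"')
      else ifelse(is.na(v), "null", format(v, digits = 17, trim = TRUE,
                                           scientific = FALSE))
    if (length(v) == 1L && is.null(names(v))) vals
    else paste0("[", paste(vals, collapse = ", "), "]")
  }
  one(x)
}
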