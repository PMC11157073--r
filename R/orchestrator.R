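#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false discovery rate control: p-values are validated to lie in
#' (0, 1] and adjusted with the Benjamini-Hochberg procedure
#' (q_i = p_i * m / rank_i, made monotone non-increasing from the largest
#' rank down, capped at 1, returned in the original order).
#'
#' @param pvalues numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values in the input order.
#' @examples
#' bhFDR(c(0.001, 0.01, 0.03))  # 0.003 0.015 0.030
#' @export
bhFDR <- function(pvalues) {
  if (!is.numeric(pvalues) || any(!is.finite(pvalues)) ||
      any(pvalues <= 0 | pvalues > 1))
    .mrError("p-values must be finite and lie in (0, 1]",
             "mrscreen_input_error")
  stats::p.adjust(pvalues, method = "BH")
}

# class-appropriate selection defaults: relaxed thresholds for microbiome
# taxa (1e-5) and cytokines (5e-6) where genome-wide hits are scarce;
# r2 = 0.1 in eQTL mode so cis signals are not pruned away
.defaultSelectionConfig <- function(class) {
  switch(class,
         microbiome = selectionConfig(pThreshold = 1e-5),
         cytokine = selectionConfig(pThreshold = 5e-6),
         eqtl = selectionConfig(pThreshold = 5e-8, clumpR2 = 0.1),
         selectionConfig(pThreshold = 5e-8))
}

.emptyResults <- function() {
  data.frame(exposure = character(), outcome = character(),
             direction = character(), method = character(),
             n_snps = integer(), beta = numeric(), se = numeric(),
             or = numeric(), or_low = numeric(), or_high = numeric(),
             pvalue = numeric(), p_fdr = numeric(),
             egger_intercept = numeric(), egger_intercept_p = numeric(),
             stringsAsFactors = FALSE)
}

.estimateRow <- function(exposure, outcome, direction, est) {
  ex <- est@extra
  data.frame(exposure = exposure, outcome = outcome, direction = direction,
             method = est@method, n_snps = est@nSnps, beta = est@thetaHat,
             se = est@se, or = est@orValue, or_low = est@orLow,
             or_high = est@orHigh, pvalue = est@pvalue, p_fdr = NA_real_,
             egger_intercept = if (est@method == "egger") ex$intercept
               else NA_real_,
             egger_intercept_p = if (est@method == "egger")
               ex$intercept_pvalue else NA_real_,
             stringsAsFactors = FALSE)
}

# run one exposure-outcome pair end to end, labelled with configured names
.runPair <- function(exposure, outcome, expLabel, outLabel, ld, config,
                     direction, seed, nBoot, nSim, effectsModel,
                     outlierSignificance) {
  sel <- selectInstruments(exposure, ld, config)
  set <- harmonize(exposure, outcome, sel$variant_id)
  ests <- mrAllMethods(set, nBoot = nBoot, seed = seed,
                       effectsModel = effectsModel)
  rows <- do.call(rbind, lapply(ests, function(est)
    .estimateRow(expLabel, outLabel, direction, est)))
  sens <- sensitivityReport(set, nSim = nSim, seed = seed + 7L,
                            outlierSignificance = outlierSignificance,
                            effectsModel = effectsModel)
  st <- sensitivityTable(sens)
  st$exposure <- expLabel
  st$outcome <- outLabel
  list(rows = rows, sens = st)
}

#' Forward MR screen across exposures and outcomes
#'
#' Runs the full two-sample MR battery for every exposure x outcome pair:
#' class-appropriate instrument selection (microbiome p < 1e-5, cytokine
#' p < 5e-6, otherwise genome-wide 5e-8; LD clumping at r2 = 0.01 within
#' 10,000 kb; F > 10 screen), harmonization, the five estimators and the
#' sensitivity suite. Benjamini-Hochberg FDR is applied to the IVW
#' p-values within each outcome across all exposures of the same class.
#' Pairs for which selection or harmonization fails are logged and
#' skipped, never fatal, so one degenerate exposure cannot abort a
#' many-taxon screen.
#'
#' @param exposures named list of [SummaryStats-class] objects.
#' @param outcomes named list of [SummaryStats-class] objects.
#' @param ld an [LDMatrix-class] or \code{NULL}.
#' @param classes character vector (recycled) of exposure classes:
#'   \code{"microbiome"}, \code{"cytokine"}, \code{"eqtl"},
#'   \code{"disease"} or \code{"other"}.
#' @param configs optional named list of [SelectionConfig-class] objects
#'   keyed by class, overriding the defaults.
#' @param seed master integer seed for bootstrap and MR-PRESSO draws.
#' @param nBoot bootstrap replicates for median/mode standard errors.
#' @param nSim MR-PRESSO simulations.
#' @param effectsModel IVW effects model.
#' @param outlierSignificance MR-PRESSO outlier cutoff.
#' @return list with \code{results} (one row per method per pair, with
#'   \code{p_fdr} filled on IVW rows), \code{sensitivity} (one row per
#'   pair) and \code{skipped} (pair, stage, reason).
#' @export
runForward <- function(exposures, outcomes, ld = NULL, classes = "other",
                       configs = NULL, seed = 1L, nBoot = 1000,
                       nSim = 1000,
                       effectsModel = c("multiplicative_random", "fixed"),
                       outlierSignificance = 0.05) {
  effectsModel <- match.arg(effectsModel)
  if (is.null(names(exposures)))
    names(exposures) <- vapply(exposures, traitName, "")
  if (is.null(names(outcomes)))
    names(outcomes) <- vapply(outcomes, traitName, "")
  classes <- rep_len(classes, length(exposures))
  seed <- .needSeed(seed)

  allRows <- list(); allSens <- list(); skipped <- list()
  k <- 0L
  for (oi in seq_along(outcomes)) {
    for (ei in seq_along(exposures)) {
      k <- k + 1L
      cls <- classes[ei]
      cfg <- if (!is.null(configs) && cls %in% names(configs))
        configs[[cls]] else .defaultSelectionConfig(cls)
      res <- tryCatch(
        .runPair(exposures[[ei]], outcomes[[oi]], names(exposures)[ei],
                 names(outcomes)[oi], ld, cfg, "forward", seed + 13L * k,
                 nBoot, nSim, effectsModel, outlierSignificance),
        mrscreen_error = function(e) e)
      if (is(res, "condition")) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          exposure = names(exposures)[ei], outcome = names(outcomes)[oi],
          reason = conditionMessage(res), stringsAsFactors = FALSE)
      } else {
        res$rows$class <- cls
        allRows[[length(allRows) + 1L]] <- res$rows
        allSens[[length(allSens) + 1L]] <- res$sens
      }
    }
  }
  results <- if (length(allRows)) do.call(rbind, allRows) else
    cbind(.emptyResults(), class = character())
  sens <- if (length(allSens)) do.call(rbind, allSens) else NULL
  rownames(results) <- NULL

  # FDR family: per outcome, across exposures of one class, on IVW rows
  ivw <- results$method == "ivw"
  for (oc in unique(results$outcome[ivw])) {
    for (cl in unique(results$class[ivw & results$outcome == oc])) {
      idx <- which(ivw & results$outcome == oc & results$class == cl)
      results$p_fdr[idx] <- bhFDR(results$pvalue[idx])
    }
  }
  list(results = results, sensitivity = sens,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(exposure = character(), outcome = character(),
                    reason = character(), stringsAsFactors = FALSE))
}

#' Reverse MR for significant forward pairs
#'
#' Swaps exposure and outcome roles for each significant forward pair:
#' instruments are selected from the disease (former outcome) trait at a
#' genome-wide threshold (default 5e-8) with the same clumping, all
#' methods are run, and a reverse IVW p-value below 0.05 is flagged as
#' potential reverse causality. Outcomes without instruments are logged
#' skips, not errors.
#'
#' @param significantPairs data.frame with columns \code{exposure},
#'   \code{outcome} naming the forward pairs to re-test.
#' @param exposures,outcomes the same named lists passed to
#'   [runForward()].
#' @param ld an [LDMatrix-class] or \code{NULL}.
#' @param reversePThreshold instrument p threshold for the disease trait.
#' @param seed,nBoot,effectsModel as in [runForward()].
#' @return list with \code{results} (rows flagged by
#'   \code{reverse_significant} on IVW rows) and \code{skipped}.
#' @export
runReverse <- function(significantPairs, exposures, outcomes, ld = NULL,
                       reversePThreshold = 5e-8, seed = 1L, nBoot = 1000,
                       effectsModel = c("multiplicative_random", "fixed")) {
  effectsModel <- match.arg(effectsModel)
  seed <- .needSeed(seed)
  if (is.null(names(exposures)))
    names(exposures) <- vapply(exposures, traitName, "")
  if (is.null(names(outcomes)))
    names(outcomes) <- vapply(outcomes, traitName, "")
  rows <- list(); skipped <- list()
  if (NROW(significantPairs) == 0L)
    return(list(results = cbind(.emptyResults(),
                                reverse_significant = logical()),
                skipped = data.frame()))
  cfg <- selectionConfig(pThreshold = reversePThreshold)
  for (i in seq_len(nrow(significantPairs))) {
    dis <- outcomes[[significantPairs$outcome[i]]]
    gm <- exposures[[significantPairs$exposure[i]]]
    res <- tryCatch({
      sel <- selectInstruments(dis, ld, cfg)
      set <- harmonize(dis, gm, sel$variant_id)
      ests <- mrAllMethods(set, nBoot = nBoot, seed = seed + 13L * i,
                           effectsModel = effectsModel)
      r <- do.call(rbind, lapply(ests, function(est)
        .estimateRow(significantPairs$outcome[i],
                     significantPairs$exposure[i], "reverse", est)))
      r$reverse_significant <- ifelse(
        r$method == "ivw", r$pvalue < 0.05, NA)
      r
    }, mrscreen_error = function(e) e)
    if (is(res, "condition")) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        exposure = significantPairs$outcome[i],
        outcome = significantPairs$exposure[i],
        reason = conditionMessage(res), stringsAsFactors = FALSE)
    } else rows[[length(rows) + 1L]] <- res
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    cbind(.emptyResults(), reverse_significant = logical())
  rownames(results) <- NULL
  list(results = results,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(exposure = character(), outcome = character(),
                    reason = character(), stringsAsFactors = FALSE))
}

#' Transcriptomic (cis-eQTL instrument) MR mode
#'
#' Identical to [runForward()] but tuned for gene-expression exposures:
#' cis-eQTL instruments are clumped at the looser r2 < 0.1 threshold (a
#' stringent cutoff would discard causal cis variants), FDR is applied
#' across genes within each outcome, and a per-pair directionality
#' consistency flag records whether all estimated methods agree in sign.
#'
#' @param genes named list of [SummaryStats-class], one gene's cis-eQTL
#'   associations per element.
#' @param outcomes named list of [SummaryStats-class].
#' @param ld an [LDMatrix-class] or \code{NULL}.
#' @param config [SelectionConfig-class] for the eQTL class; default
#'   p < 5e-8, r2 = 0.1, 10,000 kb window, F > 10.
#' @param ... passed to [runForward()] (seed, nBoot, nSim, ...).
#' @return as [runForward()], with a \code{directions_consistent} column.
#' @export
runEqtlMode <- function(genes, outcomes, ld = NULL,
                        config = .defaultSelectionConfig("eqtl"), ...) {
  out <- runForward(genes, outcomes, ld = ld, classes = "eqtl",
                    configs = list(eqtl = config), ...)
  res <- out$results
  if (nrow(res)) {
    key <- paste(res$exposure, res$outcome)
    cons <- vapply(unique(key), function(k) {
      b <- res$beta[key == k]
      all(b > 0) || all(b < 0)
    }, TRUE)
    res$directions_consistent <- cons[key]
  } else res$directions_consistent <- logical()
  out$results <- res
  out
}

#' Run the full screening pipeline and write result tables
#'
#' Drives the complete study design from a configuration: forward MR for
#' every exposure x outcome pair with class-appropriate thresholds and
#' FDR, reverse MR for the nominally significant forward pairs
#' (IVW p < 0.05), and optional two-step mediation chains. Writes
#' \code{results.tsv}, \code{sensitivity.tsv}, \code{mediation.tsv} and
#' \code{run.log} into \code{outDir}; identical configuration and seed
#' give byte-identical tables.
#'
#' The configuration is an R list (or a YAML file path, read with the
#' \pkg{yaml} package) with entries:
#' \describe{
#'   \item{exposures}{list of \code{list(name =, path =, class =)}.}
#'   \item{outcomes}{list of \code{list(name =, path =)}.}
#'   \item{ld}{optional LD file path.}
#'   \item{mediation}{optional list of chains
#'     \code{list(exposure =, mediator =, outcome =)} referring to
#'     configured names (the mediator must be a configured exposure).}
#'   \item{options}{optional overrides: \code{fdr_alpha},
#'     \code{reverse_p_threshold}, \code{n_boot}, \code{n_sim},
#'     \code{run_reverse}, \code{gate_alpha}.}
#' }
#'
#' @param config configuration list or YAML file path.
#' @param outDir output directory (created if needed).
#' @param seed master integer seed.
#' @return invisibly, a list with the forward, reverse and mediation
#'   results plus the paths written.
#' @export
runPipeline <- function(config, outDir, seed = 1L) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      .mrError("reading YAML configs requires the yaml package",
               "mrscreen_config_error")
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$exposures) || is.null(config$outcomes))
    .mrError("config must define exposures and outcomes",
             "mrscreen_config_error")
  seed <- .needSeed(seed)
  opts <- config$options
  getOpt <- function(key, default) if (!is.null(opts[[key]])) opts[[key]]
    else default
  nBoot <- getOpt("n_boot", 1000)
  nSim <- getOpt("n_sim", 1000)
  reverseP <- getOpt("reverse_p_threshold", 5e-8)
  doReverse <- getOpt("run_reverse", TRUE)
  gateAlpha <- getOpt("gate_alpha", 0.05)

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logLines <- character()
  note <- function(...) logLines <<- c(logLines, sprintf(...))

  loadTables <- function(specs) {
    tabs <- lapply(specs, function(s)
      readSummaryStats(s$path, columnMap = s$column_map,
                       traitName = s$name))
    names(tabs) <- vapply(specs, `[[`, "", "name")
    tabs
  }
  exposures <- loadTables(config$exposures)
  classes <- vapply(config$exposures, function(s)
    if (is.null(s$class)) "other" else s$class, "")
  outcomes <- loadTables(config$outcomes)
  ld <- if (!is.null(config$ld)) readLDFile(config$ld) else NULL
  note("loaded %d exposures, %d outcomes%s", length(exposures),
       length(outcomes), if (is.null(ld)) "" else ", LD table")

  fwd <- runForward(exposures, outcomes, ld = ld, classes = classes,
                    seed = seed, nBoot = nBoot, nSim = nSim)
  note("forward MR: %d result rows, %d pairs skipped",
       nrow(fwd$results), nrow(fwd$skipped))
  for (i in seq_len(nrow(fwd$skipped)))
    note("skipped %s -> %s: %s", fwd$skipped$exposure[i],
         fwd$skipped$outcome[i], fwd$skipped$reason[i])

  ivw <- fwd$results[fwd$results$method == "ivw", , drop = FALSE]
  sig <- ivw[ivw$pvalue < 0.05, c("exposure", "outcome"), drop = FALSE]
  rev <- NULL
  if (doReverse && nrow(sig)) {
    rev <- runReverse(sig, exposures, outcomes, ld = ld,
                      reversePThreshold = reverseP, seed = seed + 101L,
                      nBoot = nBoot)
    note("reverse MR: %d rows, %d skips", nrow(rev$results),
         nrow(rev$skipped))
    for (i in seq_len(nrow(rev$skipped)))
      note("reverse skipped %s -> %s: %s", rev$skipped$exposure[i],
           rev$skipped$outcome[i], rev$skipped$reason[i])
  }

  medRows <- list()
  for (chain in config$mediation) {
    res <- tryCatch({
      expTab <- exposures[[chain$exposure]]
      medTab <- exposures[[chain$mediator]]
      outTab <- outcomes[[chain$outcome]]
      cls <- classes[match(chain$exposure, names(exposures))]
      mcls <- classes[match(chain$mediator, names(exposures))]
      m <- estimateMediation(
        expTab, medTab, outTab, ld = ld,
        exposureConfig = .defaultSelectionConfig(cls),
        mediatorConfig = .defaultSelectionConfig(mcls),
        gateAlpha = gateAlpha)
      data.frame(exposure = chain$exposure, mediator = chain$mediator,
                 outcome = chain$outcome, beta1 = m@beta1, se1 = m@se1,
                 beta2 = m@beta2, se2 = m@se2, beta3 = m@beta3,
                 se3 = m@se3, indirect = m@indirect,
                 indirect_se = m@indirectSe, proportion = m@proportion,
                 gate_passed = m@gatePassed, stringsAsFactors = FALSE)
    }, mrscreen_error = function(e) e)
    if (is(res, "condition")) {
      note("mediation chain %s -> %s -> %s skipped: %s", chain$exposure,
           chain$mediator, chain$outcome, conditionMessage(res))
    } else medRows[[length(medRows) + 1L]] <- res
  }
  mediation <- if (length(medRows)) do.call(rbind, medRows) else
    data.frame(exposure = character(), mediator = character(),
               outcome = character(), beta1 = numeric(), se1 = numeric(),
               beta2 = numeric(), se2 = numeric(), beta3 = numeric(),
               se3 = numeric(), indirect = numeric(),
               indirect_se = numeric(), proportion = numeric(),
               gate_passed = logical(), stringsAsFactors = FALSE)

  results <- fwd$results
  if (!is.null(rev) && nrow(rev$results)) {
    rr <- rev$results
    rr$class <- NA_character_
    results$reverse_significant <- NA
    results <- rbind(results, rr[, names(results)])
  }
  paths <- list(results = file.path(outDir, "results.tsv"),
                sensitivity = file.path(outDir, "sensitivity.tsv"),
                mediation = file.path(outDir, "mediation.tsv"),
                log = file.path(outDir, "run.log"))
  .writeTable(results, paths$results)
  sensOut <- if (is.null(fwd$sensitivity))
    data.frame(exposure = character(), outcome = character()) else
    fwd$sensitivity
  .writeTable(sensOut, paths$sensitivity)
  .writeTable(mediation, paths$mediation)
  note("wrote %s", paths$results)
  writeLines(logLines, paths$log)
  invisible(list(forward = fwd, reverse = rev, mediation = mediation,
                 paths = paths))
}
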