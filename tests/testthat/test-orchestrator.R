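test_that("BH adjustment matches the worked example and the step-up oracle", {
  expect_equal(bhFDR(c(0.001, 0.01, 0.03)), c(0.003, 0.015, 0.03))
  expect_equal(bhFDR(0.5), 0.5)
  expect_error(bhFDR(c(0.1, 0)), class = "mrscreen_input_error")
  expect_error(bhFDR(c(0.1, 1.2)), class = "mrscreen_input_error")

  set.seed(123)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    adj <- bhFDR(p)
    expect_equal(adj, bhOracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    # monotonicity: adjusted order never inverts the raw order
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("a single synthetic pair yields five method rows and one sensitivity row", {
  sim <- simulatePair(simConfig(nSnps = 15, theta = 0.2, seed = 201))
  fwd <- runForward(list(gm = sim$exposure), list(ep = sim$outcome),
                    ld = sim$ld, classes = "microbiome", seed = 11,
                    nBoot = 100, nSim = 100)
  expect_equal(nrow(fwd$results), 5)
  expect_setequal(fwd$results$method,
                  c("ivw", "egger", "weighted_median", "simple_mode",
                    "weighted_mode"))
  expect_equal(nrow(fwd$sensitivity), 1)
  expect_equal(nrow(fwd$skipped), 0)
  ivw <- fwd$results[fwd$results$method == "ivw", ]
  expect_false(is.na(ivw$p_fdr))
  expect_gte(ivw$p_fdr, ivw$pvalue)
  # OR columns are the exponentiated beta-scale columns
  expect_equal(ivw$or, exp(ivw$beta))
})

test_that("pairs that fail selection are skipped, not fatal, and accounted for", {
  good <- simulatePair(simConfig(nSnps = 12, theta = 0.2, seed = 202))
  # a null exposure with no signal below any threshold
  bad <- simulatePair(simConfig(nSnps = 5, theta = 0, seed = 203,
                                nNullSnps = 20))
  nullExpo <- SummaryStats(
    variants(bad$exposure)[-(1:5), ], "null_taxon")
  fwd <- runForward(list(gm = good$exposure, null_taxon = nullExpo),
                    list(ep = good$outcome), ld = good$ld,
                    classes = "microbiome", seed = 12, nBoot = 50,
                    nSim = 50)
  expect_equal(nrow(fwd$skipped), 1)
  expect_equal(fwd$skipped$exposure, "null_taxon")
  expect_false("null_taxon" %in% fwd$results$exposure)
  # every configured pair appears exactly once in results or skips
  expect_equal(length(unique(fwd$results$exposure)) + nrow(fwd$skipped), 2)
})

test_that("FDR families are outcome-by-class on IVW rows only", {
  sims <- lapply(1:4, function(i)
    simulatePair(simConfig(nSnps = 10, theta = 0.1, seed = 210 + i)))
  exposures <- c(lapply(sims[1:2], `[[`, "exposure"),
                 lapply(sims[3:4], `[[`, "exposure"))
  names(exposures) <- c("m1", "m2", "c1", "c2")
  fwd <- runForward(exposures, list(ep = sims[[1]]$outcome),
                    classes = c("microbiome", "microbiome", "cytokine",
                                "cytokine"),
                    seed = 13, nBoot = 0, nSim = 50)
  res <- fwd$results
  expect_true(all(is.na(res$p_fdr[res$method != "ivw"])))
  for (cl in c("microbiome", "cytokine")) {
    idx <- res$method == "ivw" & res$class == cl
    expect_equal(res$p_fdr[idx], bhFDR(res$pvalue[idx]))
  }
})

test_that("a null many-exposure screen yields almost no FDR discoveries", {
  # each taxon gets its own instruments; one outcome table covers them all
  exposures <- list()
  outRows <- list()
  for (i in 1:60) {
    sim <- simulatePair(simConfig(nSnps = 8, theta = 0, seed = 7000 + i))
    pfx <- function(tab) {
      v <- variants(tab)
      v$variant_id <- paste0(sprintf("t%02d_", i), v$variant_id)
      v
    }
    exposures[[sprintf("taxon%02d", i)]] <-
      SummaryStats(pfx(sim$exposure), sprintf("taxon%02d", i))
    outRows[[i]] <- pfx(sim$outcome)
  }
  outcome <- SummaryStats(do.call(rbind, outRows), "ep")
  fwd <- runForward(exposures, list(ep = outcome),
                    classes = "microbiome", seed = 14, nBoot = 0,
                    nSim = 0)
  ivw <- fwd$results[fwd$results$method == "ivw", ]
  expect_equal(nrow(ivw), 60)
  expect_lte(sum(ivw$p_fdr < 0.05), 2)
})

test_that("reverse MR flags bidirectional effects and clears X->Y-only data", {
  # X -> Y only
  uni <- simulatePair(simConfig(nSnps = 20, theta = 0.2, seed = 301,
                                nOutcomeSnps = 15, reverseTheta = 0))
  pairs <- data.frame(exposure = "gm", outcome = "ep",
                      stringsAsFactors = FALSE)
  rev <- runReverse(pairs, list(gm = uni$exposure), list(ep = uni$outcome),
                    seed = 15, nBoot = 0)
  rivw <- rev$results[rev$results$method == "ivw", ]
  expect_equal(rivw$direction, "reverse")
  expect_equal(rivw$exposure, "ep")  # roles swapped
  # only the outcome's own instruments are used
  expect_lte(rivw$n_snps, 15)

  # bidirectional: outcome feeds back on the exposure
  bi <- simulatePair(simConfig(nSnps = 20, theta = 0.2, seed = 302,
                               nOutcomeSnps = 15, reverseTheta = 0.3))
  rev2 <- runReverse(pairs, list(gm = bi$exposure), list(ep = bi$outcome),
                     seed = 15, nBoot = 0)
  r2 <- rev2$results[rev2$results$method == "ivw", ]
  expect_true(r2$reverse_significant)

  # empty significant set -> empty table
  rev0 <- runReverse(pairs[0, ], list(gm = uni$exposure),
                     list(ep = uni$outcome), seed = 15, nBoot = 0)
  expect_equal(nrow(rev0$results), 0)

  # no disease instruments -> logged skip, not an error
  weak <- SummaryStats(within(variants(uni$outcome), pvalue <- pmax(
    pvalue, 0.5)), "ep")
  rev3 <- runReverse(pairs, list(gm = uni$exposure), list(ep = weak),
                     seed = 15, nBoot = 0)
  expect_equal(nrow(rev3$results), 0)
  expect_equal(nrow(rev3$skipped), 1)
})

test_that("eQTL mode keeps r2 < 0.1 pairs that 0.01 would prune", {
  sim <- simulatePair(simConfig(nSnps = 10, theta = 0.2, seed = 401,
                                ldBlocks = list(size = 2, r2 = 0.05)))
  selTight <- selectInstruments(sim$exposure, sim$ld,
                                selectionConfig(pThreshold = 1,
                                                clumpR2 = 0.01))
  selLoose <- selectInstruments(sim$exposure, sim$ld,
                                selectionConfig(pThreshold = 1,
                                                clumpR2 = 0.1))
  expect_lt(nrow(selTight), nrow(selLoose))
  expect_equal(nrow(selLoose), 10)

  res <- runEqtlMode(list(GENE1 = sim$exposure), list(ep = sim$outcome),
                     ld = sim$ld, seed = 16, nBoot = 0, nSim = 0)
  expect_equal(sum(res$results$method == "ivw"), 1)
  expect_true("directions_consistent" %in% names(res$results))
})

test_that("genes with true effects rank ahead of null genes by FDR", {
  genes <- list(); hot <- sprintf("gene%02d", 1:3)
  for (i in 1:12) {
    th <- if (i <= 3) 0.3 else 0
    genes[[sprintf("gene%02d", i)]] <- simulatePair(
      simConfig(nSnps = 10, theta = th, seed = 8000 + i))$exposure
  }
  out <- simulatePair(simConfig(nSnps = 10, theta = 0.3,
                                seed = 8001))$outcome
  # a shared outcome table covering every gene's instruments
  allOut <- do.call(rbind, lapply(1:12, function(i) {
    th <- if (i <= 3) 0.3 else 0
    sim <- simulatePair(simConfig(nSnps = 10, theta = th, seed = 8000 + i))
    v <- variants(sim$outcome)
    v$variant_id <- paste0(sprintf("g%02d_", i), v$variant_id)
    v
  }))
  for (i in 1:12) {
    v <- variants(genes[[i]])
    v$variant_id <- paste0(sprintf("g%02d_", i), v$variant_id)
    genes[[i]] <- SummaryStats(v, sprintf("gene%02d", i))
  }
  res <- runEqtlMode(genes, list(ep = SummaryStats(allOut, "ep")),
                     seed = 17, nBoot = 0, nSim = 0)
  ivw <- res$results[res$results$method == "ivw", ]
  ranked <- ivw$exposure[order(ivw$p_fdr)]
  expect_setequal(ranked[1:3], hot)
})

test_that("the pipeline writes byte-identical outputs for identical seeds", {
  dir0 <- tempfile("simdat")
  sim <- simulatePair(simConfig(nSnps = 12, theta = 0.25, seed = 501,
                                nOutcomeSnps = 10))
  med <- simulateMediationChain(
    simConfig(nSnps = 12, seed = 502,
              mediation = list(beta1 = 0.3, beta2 = 0.5, direct = 0.1)))
  dir.create(dir0)
  writeSummaryStats(sim$exposure, file.path(dir0, "gm.tsv"))
  writeSummaryStats(sim$outcome, file.path(dir0, "ep.tsv"))
  writeSummaryStats(med$exposure, file.path(dir0, "mexp.tsv"))
  writeSummaryStats(med$mediator, file.path(dir0, "cyto.tsv"))
  writeSummaryStats(med$outcome, file.path(dir0, "mout.tsv"))
  writeLDFile(sim$ld, file.path(dir0, "ld.tsv"))
  config <- list(
    exposures = list(
      list(name = "gm", path = file.path(dir0, "gm.tsv"),
           class = "microbiome"),
      list(name = "mexp", path = file.path(dir0, "mexp.tsv"),
           class = "microbiome"),
      list(name = "cyto", path = file.path(dir0, "cyto.tsv"),
           class = "cytokine")),
    outcomes = list(list(name = "ep", path = file.path(dir0, "ep.tsv")),
                    list(name = "mout", path = file.path(dir0, "mout.tsv"))),
    ld = file.path(dir0, "ld.tsv"),
    mediation = list(list(exposure = "mexp", mediator = "cyto",
                          outcome = "mout")),
    options = list(n_boot = 100, n_sim = 100))
  outA <- tempfile("runA"); outB <- tempfile("runB")
  runPipeline(config, outA, seed = 99)
  runPipeline(config, outB, seed = 99)
  for (f in c("results.tsv", "sensitivity.tsv", "mediation.tsv")) {
    a <- readBin(file.path(outA, f), "raw",
                 file.size(file.path(outA, f)))
    b <- readBin(file.path(outB, f), "raw",
                 file.size(file.path(outB, f)))
    expect_identical(a, b)
  }
  res <- read.delim(file.path(outA, "results.tsv"))
  expect_true(all(c("forward", "reverse") %in% res$direction) ||
                all(res$direction == "forward"))
  medTab <- read.delim(file.path(outA, "mediation.tsv"))
  expect_equal(nrow(medTab), 1)
  expect_true(is.finite(medTab$proportion))
  expect_true(file.exists(file.path(outA, "run.log")))
})

test_that("a YAML pipeline config is accepted", {
  dir0 <- tempfile("ydat"); dir.create(dir0)
  sim <- simulatePair(simConfig(nSnps = 10, theta = 0.2, seed = 601))
  writeSummaryStats(sim$exposure, file.path(dir0, "gm.tsv"))
  writeSummaryStats(sim$outcome, file.path(dir0, "ep.tsv"))
  cfg <- file.path(dir0, "config.yaml")
  writeLines(c(
    "exposures:",
    sprintf("  - name: gm"),
    sprintf("    path: %s", file.path(dir0, "gm.tsv")),
    "    class: microbiome",
    "outcomes:",
    sprintf("  - name: ep"),
    sprintf("    path: %s", file.path(dir0, "ep.tsv")),
    "options:",
    "  n_boot: 50",
    "  n_sim: 50",
    "  run_reverse: false"), cfg)
  out <- tempfile("yrun")
  res <- runPipeline(cfg, out, seed = 7)
  expect_true(file.exists(file.path(out, "results.tsv")))
  expect_equal(nrow(res$forward$results), 5)
})
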