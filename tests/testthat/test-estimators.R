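test_that("Wald ratio arithmetic, null case and delta-method se", {
  est <- mrWaldRatio(0.2, 0.02, 0.1, 0.02)
  expect_equal(thetaHat(est), 0.5)
  expect_equal(stdError(est), 0.1)
  expect_equal(confInt(est), c(low = 0.5 - 1.96 * 0.1,
                               high = 0.5 + 1.96 * 0.1))
  expect_equal(unname(oddsRatio(est)["or"]), exp(0.5))

  null <- mrWaldRatio(1.0, 0.1, 0.0, 0.1)
  expect_equal(thetaHat(null), 0)
  expect_equal(pValue(null), 1)

  expect_error(mrWaldRatio(0, 0.1, 0.2, 0.1), class = "mrscreen_input_error")

  # first-order se agrees with finite-difference error propagation in
  # Gamma (the first-order formula ignores the gamma term by design)
  set.seed(4)
  for (i in 1:20) {
    g <- runif(1, 0.1, 1) * sample(c(-1, 1), 1)
    sy <- runif(1, 0.01, 0.2)
    G <- rnorm(1)
    eps <- 1e-6
    dG <- ((G + eps) / g - G / g) / eps
    expect_equal(stdError(mrWaldRatio(g, 0.05, G, sy)), abs(dG) * sy,
                 tolerance = 1e-6)
  }
})

test_that("IVW matches hand arithmetic and collapses to the Wald ratio", {
  set <- makeSet(c(1, 1), c(0.1, 0.1), c(0.4, 0.6), c(0.1, 0.1))
  est <- mrIVW(set, effectsModel = "fixed")
  expect_equal(thetaHat(est), 0.5)
  expect_equal(stdError(est), sqrt(1 / 200))

  one <- makeSet(0.21, 0.03, 0.12, 0.05)
  wald <- mrWaldRatio(0.21, 0.03, 0.12, 0.05)
  expect_warning(mrIVW(one), "single instrument")
  ivw1 <- suppressWarnings(mrIVW(one))
  expect_identical(thetaHat(ivw1), thetaHat(wald))
  expect_identical(stdError(ivw1), stdError(wald))
  expect_identical(pValue(ivw1), pValue(wald))
})

test_that("IVW and Egger coefficients match the weighted-least-squares oracle", {
  for (seed in 1:25) {
    set <- randomSet(sample(4:25, 1), seed)
    expect_equal(thetaHat(mrIVW(set, "fixed")), wlsOracle(set)$slope,
                 tolerance = 1e-12)
    o <- wlsOracle(set, intercept = TRUE)
    eg <- mrEgger(set)
    expect_equal(thetaHat(eg), o$slope, tolerance = 1e-12)
    expect_equal(mrExtra(eg)$intercept, o$intercept, tolerance = 1e-12)
    expect_equal(stdError(eg), unname(o$slope_se), tolerance = 1e-10)
    expect_equal(mrExtra(eg)$intercept_se, unname(o$intercept_se),
                 tolerance = 1e-10)
  }
})

test_that("random-effects IVW inflates but never deflates the fixed se", {
  for (seed in 26:35) {
    set <- randomSet(10, seed)
    fe <- mrIVW(set, "fixed")
    re <- mrIVW(set, "multiplicative_random")
    expect_identical(thetaHat(re), thetaHat(fe))
    expect_gte(stdError(re), stdError(fe))
    Q <- mrExtra(fe)$Q
    expect_equal(stdError(re), stdError(fe) * max(1, sqrt(Q / 9)))
  }
})

test_that("Egger recovers slope and intercept from collinear points", {
  set <- makeSet(c(1, 2, 3), rep(0.01, 3), c(1.5, 2.5, 3.5), rep(0.1, 3))
  eg <- mrEgger(set)
  expect_equal(thetaHat(eg), 1.0, tolerance = 1e-12)
  expect_equal(mrExtra(eg)$intercept, 0.5, tolerance = 1e-12)
  expect_error(mrEgger(makeSet(c(1, 2), c(0.1, 0.1), c(1, 2), c(0.1, 0.1))),
               class = "mrscreen_insufficient_instruments")
})

test_that("Egger slope/intercept estimates recover simulation truth", {
  # directional pleiotropy with InSiDE satisfied: intercept = mean alpha
  reps <- 300
  slopes <- numeric(reps); inters <- numeric(reps)
  for (i in seq_len(reps)) {
    sim <- simulatePair(simConfig(nSnps = 40, theta = 0.2,
                                  pleiotropyMode = "directional",
                                  pleiotropyMean = 0.05,
                                  pleiotropySd = 0.02, seed = 5000 + i))
    set <- harmonize(sim$exposure, sim$outcome)
    eg <- mrEgger(set)
    slopes[i] <- thetaHat(eg)
    inters[i] <- mrExtra(eg)$intercept
  }
  expect_lt(abs(mean(slopes) - 0.2), 3 * sd(slopes) / sqrt(reps))
  expect_lt(abs(mean(inters) - 0.05), 3 * sd(inters) / sqrt(reps))
})

test_that("weighted median interpolates the ratio distribution at weight 0.5", {
  # equal weights, odd count: the middle ratio
  set <- makeSet(c(1, 1, 1), rep(0.01, 3), c(0.1, 0.2, 0.9), rep(0.1, 3))
  expect_equal(thetaHat(mrWeightedMedian(set, nBoot = 0)), 0.2)

  # unequal weights: hand-computed interpolation (midpoints .1/.35/.75)
  expect_equal(mrscreen:::.weightedMedian(c(1, 2, 3), c(0.2, 0.3, 0.5)),
               2.375)

  # brute-force weighted-quantile oracle on random sets
  for (seed in 36:55) {
    set <- randomSet(sample(3:20, 1), seed)
    s <- instruments(set)
    ratios <- s$beta_outcome / s$beta_exposure
    w <- (s$beta_exposure / s$se_outcome)^2
    expect_equal(thetaHat(mrWeightedMedian(set, nBoot = 0)),
                 weightedMedianOracle(ratios, w), tolerance = 1e-12)
    # equal weights reduce to the unweighted interpolated median
    expect_equal(mrscreen:::.weightedMedian(ratios, rep(1, length(ratios))),
                 weightedMedianOracle(ratios, rep(1, length(ratios))),
                 tolerance = 1e-12)
  }
})

test_that("mode estimators find the dominant ratio cluster", {
  # tight bimodal mixture: 60% of the mass at 0.2, 40% at 0.9
  g <- rep(1, 10); sy <- rep(0.05, 10)
  ratios <- c(rep(0.2, 6), rep(0.9, 4)) + seq(-0.005, 0.005,
                                              length.out = 10)
  set <- makeSet(g, rep(0.01, 10), ratios, sy)
  m <- mrMode(set, nBoot = 0)
  expect_lt(abs(thetaHat(m) - 0.2), 0.05)

  # dense-grid density oracle: same kernel, much finer grid
  s <- instruments(set)
  r <- s$beta_outcome / s$beta_exposure
  w <- rep(1 / 10, 10)
  sp <- min(sd(r), mad(r))
  h <- 0.9 * sp * 10^(-1 / 5)
  fine <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 20001)
  dens <- vapply(fine, function(x) sum(w * dnorm((x - r) / h)), 0)
  expect_equal(thetaHat(m), fine[which.max(dens)], tolerance = 1e-3)

  # all ratios identical: the common ratio is returned
  flat <- makeSet(c(1, 2, 4), rep(0.01, 3), c(0.4, 0.8, 1.6),
                  rep(0.05, 3))
  expect_equal(thetaHat(mrMode(flat, nBoot = 0)), 0.4, tolerance = 1e-9)

  # simple and weighted mode coincide under equal weights
  eq <- makeSet(c(1, 1, 1, 1), rep(0.01, 4), c(0.3, 0.32, 0.5, 0.31),
                rep(0.05, 4))
  expect_equal(thetaHat(mrMode(eq, weighted = FALSE, nBoot = 0)),
               thetaHat(mrMode(eq, weighted = TRUE, nBoot = 0)),
               tolerance = 1e-10)
})

test_that("bootstrap standard errors are deterministic given a seed", {
  set <- randomSet(8, 77)
  a <- mrWeightedMedian(set, nBoot = 300, seed = 42)
  b <- mrWeightedMedian(set, nBoot = 300, seed = 42)
  expect_identical(stdError(a), stdError(b))
  c_ <- mrWeightedMedian(set, nBoot = 300, seed = 43)
  expect_false(identical(stdError(a), stdError(c_)))
  m1 <- mrMode(set, nBoot = 200, seed = 42)
  m2 <- mrMode(set, nBoot = 200, seed = 42)
  expect_identical(stdError(m1), stdError(m2))
  expect_error(mrWeightedMedian(set, nBoot = 100),
               class = "mrscreen_config_error")
})

test_that("estimators are sign- and scale-equivariant", {
  for (seed in 56:65) {
    set <- randomSet(9, seed)
    s <- instruments(set)
    neg <- makeSet(s$beta_exposure, s$se_exposure, -s$beta_outcome,
                   s$se_outcome)
    for (fit in list(mrIVW, mrEgger,
                     function(x) mrWeightedMedian(x, nBoot = 0))) {
      e1 <- suppressWarnings(fit(set))
      e2 <- suppressWarnings(fit(neg))
      expect_equal(thetaHat(e2), -thetaHat(e1), tolerance = 1e-12)
      expect_equal(stdError(e2), stdError(e1), tolerance = 1e-12)
    }
    cc <- 3.7
    scaled <- makeSet(cc * s$beta_exposure, cc * s$se_exposure,
                      s$beta_outcome, s$se_outcome)
    expect_equal(thetaHat(mrIVW(scaled, "fixed")),
                 thetaHat(mrIVW(set, "fixed")) / cc, tolerance = 1e-12)
    expect_equal(thetaHat(mrEgger(scaled)), thetaHat(mrEgger(set)) / cc,
                 tolerance = 1e-12)
  }
})

test_that("the method battery runs everything applicable and logs skips", {
  big <- randomSet(10, 91)
  all5 <- mrAllMethods(big, nBoot = 50, seed = 3)
  expect_named(all5, c("ivw", "egger", "weighted_median", "simple_mode",
                       "weighted_mode"))
  expect_length(attr(all5, "skipped"), 0)

  two <- randomSet(2, 92)
  just1 <- mrAllMethods(two, nBoot = 50, seed = 3)
  expect_named(just1, "ivw")
  expect_length(attr(just1, "skipped"), 4)

  # degenerate homogeneity: identical ratios -> every method agrees
  s <- makeSet(c(1, 2, 3, 4), rep(0.01, 4), 0.25 * c(1, 2, 3, 4),
               rep(0.05, 4))
  ests <- mrAllMethods(s, nBoot = 50, seed = 3)
  for (est in ests)
    expect_equal(thetaHat(est), 0.25, tolerance = 1e-6)
})

test_that("all five estimators are unbiased under the sharp null", {
  reps <- 300
  est <- matrix(NA_real_, reps, 5)
  for (i in seq_len(reps)) {
    sim <- simulatePair(simConfig(nSnps = 30, theta = 0, seed = 20000 + i))
    set <- harmonize(sim$exposure, sim$outcome)
    ests <- mrAllMethods(set, nBoot = 0)
    est[i, ] <- vapply(ests, thetaHat, 0)
  }
  for (k in 1:5) {
    mc <- sd(est[, k]) / sqrt(reps)
    expect_lt(abs(mean(est[, k])), 3 * mc)
  }
})
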