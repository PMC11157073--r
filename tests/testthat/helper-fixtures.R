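# fixtures and independent oracles used across the suite

# build a HarmonizedSet directly from effect vectors (non-palindromic
# alleles, dummy coordinates)
makeSet <- function(g, sx, G, sy, ids = sprintf("rs%d", seq_along(g))) {
  J <- length(g)
  snps <- data.frame(
    variant_id = ids, chrom = "1", pos = 1e6 + seq_len(J) * 1e5,
    effect_allele = "A", other_allele = "G",
    eaf_exposure = 0.3, eaf_outcome = 0.3,
    beta_exposure = g, se_exposure = sx,
    pval_exposure = 2 * pnorm(-abs(g / sx)),
    beta_outcome = G, se_outcome = sy,
    pval_outcome = 2 * pnorm(-abs(G / sy)),
    f_stat = (g / sx)^2, stringsAsFactors = FALSE)
  new("HarmonizedSet", exposureName = "X", outcomeName = "Y", snps = snps,
      log = data.frame(variant_id = character(), reason = character()))
}

# random instrument set for oracle-equivalence checks
randomSet <- function(J, seed) {
  set.seed(seed)
  g <- runif(J, 0.05, 0.3) * sample(c(-1, 1), J, replace = TRUE)
  sx <- runif(J, 0.005, 0.05)
  sy <- runif(J, 0.01, 0.1)
  G <- 0.3 * g + rnorm(J, 0, sy)
  makeSet(g, sx, G, sy)
}

# SummaryStats from a compact spec data.frame
makeStats <- function(df, name = "trait") {
  SummaryStats(df, traitName = name)
}

# ---- independent oracles -------------------------------------------------

# weighted least squares through lm(): the reference for IVW and Egger
wlsOracle <- function(set, intercept = FALSE) {
  s <- instruments(set)
  g <- s$beta_exposure; G <- s$beta_outcome; w <- 1 / s$se_outcome^2
  if (intercept) {
    flip <- g < 0
    g[flip] <- -g[flip]; G[flip] <- -G[flip]
    fit <- lm(G ~ g, weights = w)
    s2 <- max(1, sum(w * residuals(fit)^2) / (length(g) - 2))
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         slope_se = sqrt(diag(vcov(fit) / summary(fit)$sigma^2 * s2))[2],
         intercept_se = sqrt(diag(vcov(fit) / summary(fit)$sigma^2 * s2))[1])
  } else {
    fit <- lm(G ~ 0 + g, weights = w)
    list(slope = unname(coef(fit)))
  }
}

# brute-force weighted median via the cumulative-midpoint definition
weightedMedianOracle <- function(ratios, w) {
  o <- order(ratios)
  r <- ratios[o]; w <- w[o] / sum(w)
  p <- numeric(length(w))
  run <- 0
  for (i in seq_along(w)) {
    p[i] <- run + w[i] / 2
    run <- run + w[i]
  }
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(p)])
  i <- findInterval(0.5, p)
  r[i] + (0.5 - p[i]) * (r[i + 1] - r[i]) / (p[i + 1] - p[i])
}

# exhaustive greedy clumping oracle: literal restatement of the rule with
# repeated which.min over a shrinking data.frame
clumpOracle <- function(cand, ld, r2max, windowKb) {
  cand <- cand[order(cand$pvalue, cand$chrom, cand$pos, cand$variant_id), ]
  kept <- character()
  while (nrow(cand) > 0) {
    idx <- cand[1, ]
    kept <- c(kept, idx$variant_id)
    cand <- cand[-1, , drop = FALSE]
    if (nrow(cand) == 0) break
    drop <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (cand$chrom[i] != idx$chrom) next
      if (abs(cand$pos[i] - idx$pos) > windowKb * 1000) next
      if (ldR2(ld, cand$variant_id[i], idx$variant_id) > r2max)
        drop[i] <- TRUE
    }
    cand <- cand[!drop, , drop = FALSE]
  }
  kept
}

# step-up BH oracle, coded from the definition
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# random candidate table + LD for clumping equivalence tests
randomClumpInstance <- function(n, seed) {
  set.seed(seed)
  cand <- data.frame(
    variant_id = sprintf("s%02d", seq_len(n)),
    chrom = as.character(sample(1:2, n, replace = TRUE)),
    pos = sample(1e6:5e6, n),
    pvalue = 10^runif(n, -12, -2), stringsAsFactors = FALSE)
  pairs <- t(combn(cand$variant_id, 2))
  keep <- runif(nrow(pairs)) < 0.3
  ld <- ldMatrix(data.frame(id_a = pairs[keep, 1], id_b = pairs[keep, 2],
                            r2 = runif(sum(keep)),
                            stringsAsFactors = FALSE))
  list(cand = cand, ld = ld)
}
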