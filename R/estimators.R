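# extract per-SNP effect vectors from a HarmonizedSet
.effects <- function(set) {
  s <- set@snps
  list(id = s$variant_id, g = s$beta_exposure, sx = s$se_exposure,
       G = s$beta_outcome, sy = s$se_outcome, J = nrow(s))
}

.Z95 <- 1.96

.mkEstimate <- function(method, theta, se, pvalue, nSnps, extra = list()) {
  lo <- theta - .Z95 * se
  hi <- theta + .Z95 * se
  new("MREstimate", method = method, thetaHat = theta, se = se,
      ciLow = lo, ciHigh = hi, orValue = exp(theta), orLow = exp(lo),
      orHigh = exp(hi), pvalue = pvalue, nSnps = as.integer(nSnps),
      extra = extra)
}

.needSnps <- function(J, minJ, method) {
  if (J < minJ)
    .mrError(sprintf("%s requires at least %d instruments (got %d)",
                     method, minJ, J), "mrscreen_insufficient_instruments")
}

.needSeed <- function(seed) {
  if (is.null(seed) || !is.finite(seed))
    .mrError("an explicit integer seed is required for bootstrap methods",
             "mrscreen_config_error")
  as.integer(seed)
}

#' Wald ratio for a single instrument
#'
#' The per-SNP causal estimate theta = Gamma/gamma with first-order
#' standard error sigma_Y/|gamma|; the 95\% CI is theta +/- 1.96 se and
#' the p-value is two-sided normal.
#'
#' @param gamma,sigmaX SNP-exposure effect and its standard error.
#' @param Gamma,sigmaY SNP-outcome effect and its standard error.
#' @return an [MREstimate-class] with method \code{"wald_ratio"}.
#' @examples
#' thetaHat(mrWaldRatio(0.2, 0.02, 0.1, 0.02))  # 0.5
#' @export
mrWaldRatio <- function(gamma, sigmaX, Gamma, sigmaY) {
  if (!is.finite(gamma) || gamma == 0)
    .mrError("Wald ratio undefined for gamma = 0", "mrscreen_input_error")
  if (sigmaY <= 0) .mrError("sigmaY must be > 0", "mrscreen_input_error")
  theta <- Gamma / gamma
  se <- sigmaY / abs(gamma)
  p <- 2 * stats::pnorm(-abs(theta) / se)
  .mkEstimate("wald_ratio", theta, se, p, 1L)
}

#' Inverse-variance-weighted estimator
#'
#' Combines per-SNP Wald ratios with weights 1/sigma_Yj^2; equivalently a
#' weighted regression of outcome on exposure effects through the origin.
#' The default multiplicative random-effects model scales the fixed-effect
#' standard error by max(1, sqrt(Q/(J-1))), where Q is Cochran's
#' heterogeneity statistic, so mild heterogeneity widens the interval but
#' homogeneous sets are never narrowed. With a single SNP the estimate
#' collapses to the Wald ratio exactly (random-effects requests fall back
#' to fixed with a warning).
#'
#' @param set a [HarmonizedSet-class].
#' @param effectsModel \code{"multiplicative_random"} (default) or
#'   \code{"fixed"}.
#' @return an [MREstimate-class] with method \code{"ivw"}; \code{mrExtra}
#'   carries the effects model and Q.
#' @export
mrIVW <- function(set, effectsModel = c("multiplicative_random", "fixed")) {
  effectsModel <- match.arg(effectsModel)
  e <- .effects(set)
  .needSnps(e$J, 1L, "IVW")
  if (e$J == 1L) {
    if (effectsModel == "multiplicative_random") {
      warning("single instrument: falling back to fixed-effect IVW",
              call. = FALSE)
      effectsModel <- "fixed"
    }
    w <- mrWaldRatio(e$g, e$sx, e$G, e$sy)
    return(.mkEstimate("ivw", w@thetaHat, w@se, w@pvalue, 1L,
                       extra = list(effects_model = effectsModel, Q = 0)))
  }
  w <- 1 / e$sy^2
  theta <- sum(w * e$g * e$G) / sum(w * e$g^2)
  seFixed <- 1 / sqrt(sum(w * e$g^2))
  Q <- sum(w * (e$G - theta * e$g)^2)
  se <- if (effectsModel == "multiplicative_random")
    seFixed * max(1, sqrt(Q / (e$J - 1))) else seFixed
  p <- 2 * stats::pnorm(-abs(theta) / se)
  .mkEstimate("ivw", theta, se, p, e$J,
              extra = list(effects_model = effectsModel, Q = Q))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome on exposure effects with a free
#' intercept (weights 1/sigma_Yj^2), after orienting every SNP so that its
#' exposure effect is non-negative (joint sign flip of gamma_j and
#' Gamma_j), which makes the intercept interpretable as the average
#' directional pleiotropic effect. Both coefficient variances are inflated
#' multiplicatively by max(1, RSS/(J-2)) and p-values use the t
#' distribution with J-2 degrees of freedom. The slope is the
#' pleiotropy-adjusted causal effect; the intercept record (estimate, se,
#' p) is stored in \code{mrExtra}.
#'
#' @param set a [HarmonizedSet-class] with at least 3 instruments.
#' @return an [MREstimate-class] with method \code{"egger"}.
#' @export
mrEgger <- function(set) {
  e <- .effects(set)
  .needSnps(e$J, 3L, "MR-Egger")
  flip <- e$g < 0
  g <- ifelse(flip, -e$g, e$g)
  G <- ifelse(flip, -e$G, e$G)
  w <- 1 / e$sy^2
  sw <- sum(w); swg <- sum(w * g); swgg <- sum(w * g^2)
  swG <- sum(w * G); swgG <- sum(w * g * G)
  denom <- sw * swgg - swg^2
  slope <- (sw * swgG - swg * swG) / denom
  inter <- (swG - slope * swg) / sw
  rss <- sum(w * (G - inter - slope * g)^2)
  phi <- max(1, rss / (e$J - 2))
  seSlope <- sqrt(phi * sw / denom)
  seInter <- sqrt(phi * swgg / denom)
  pSlope <- 2 * stats::pt(-abs(slope / seSlope), df = e$J - 2)
  pInter <- 2 * stats::pt(-abs(inter / seInter), df = e$J - 2)
  .mkEstimate("egger", slope, seSlope, pSlope, e$J,
              extra = list(intercept = inter, intercept_se = seInter,
                           intercept_pvalue = pInter, rss = rss,
                           df = e$J - 2))
}

# interpolated weighted median of ratios (weights need not be normalized)
.weightedMedian <- function(ratios, w) {
  o <- order(ratios)
  r <- ratios[o]
  w <- w[o] / sum(w)
  mid <- cumsum(w) - w / 2
  if (0.5 <= mid[1]) return(r[1])
  J <- length(r)
  if (0.5 >= mid[J]) return(r[J])
  k <- max(which(mid <= 0.5))
  if (mid[k + 1] == mid[k]) return(r[k + 1])
  r[k] + (0.5 - mid[k]) / (mid[k + 1] - mid[k]) * (r[k + 1] - r[k])
}

# parametric bootstrap draws of (gamma, Gamma); returns J x nBoot matrices
.bootDraws <- function(e, nBoot, seed) {
  set.seed(seed)
  list(g = matrix(stats::rnorm(e$J * nBoot, mean = e$g, sd = e$sx), e$J),
       G = matrix(stats::rnorm(e$J * nBoot, mean = e$G, sd = e$sy), e$J))
}

#' Weighted median estimator
#'
#' Consistent when instruments carrying at least half the weight are
#' valid. Per-SNP Wald ratios are ordered and the estimate is the linear
#' interpolation of the ordered ratios at cumulative weight-midpoint 0.5,
#' with weights proportional to the inverse variance of each ratio
#' (gamma_j^2/sigma_Yj^2). The standard error comes from a parametric
#' bootstrap that redraws gamma_j and Gamma_j from normal distributions
#' with their reported standard errors; identical seeds give identical
#' standard errors.
#'
#' @param set a [HarmonizedSet-class] with at least 3 instruments.
#' @param nBoot bootstrap replicates (default 1000); 0 skips the bootstrap
#'   and reports \code{NA} se/p.
#' @param seed integer seed, required when \code{nBoot > 0}.
#' @return an [MREstimate-class] with method \code{"weighted_median"}.
#' @export
mrWeightedMedian <- function(set, nBoot = 1000, seed = NULL) {
  e <- .effects(set)
  .needSnps(e$J, 3L, "weighted median")
  ratios <- e$G / e$g
  w <- (e$g / e$sy)^2
  theta <- .weightedMedian(ratios, w)
  se <- NA_real_; p <- NA_real_
  if (nBoot > 0) {
    seed <- .needSeed(seed)
    d <- .bootDraws(e, nBoot, seed)
    est <- vapply(seq_len(nBoot), function(b) {
      gb <- d$g[, b]
      .weightedMedian(d$G[, b] / gb, (gb / e$sy)^2)
    }, 0)
    se <- stats::sd(est)
    p <- 2 * stats::pnorm(-abs(theta) / se)
  }
  .mkEstimate("weighted_median", theta, se, p, e$J,
              extra = list(n_boot = nBoot, seed = seed))
}

# kernel-density mode of ratio estimates; grid argmax with optional
# golden-section/parabolic refinement between the neighbouring grid points
.modePoint <- function(ratios, w, phi, refine = TRUE) {
  s <- min(stats::sd(ratios), stats::mad(ratios))
  if (!is.finite(s) || s == 0) s <- stats::sd(ratios)
  if (!is.finite(s) || s == 0) return(ratios[1])
  h <- phi * 0.9 * s * length(ratios)^(-1 / 5)
  grid <- seq(min(ratios) - 3 * h, max(ratios) + 3 * h, length.out = 512L)
  f <- as.vector(stats::dnorm(outer(grid, ratios, "-") / h) %*% w)
  i <- which.max(f)
  if (!refine) return(grid[i])
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(512L, i + 1L)]
  stats::optimize(function(x) sum(w * stats::dnorm((x - ratios) / h)),
                  c(lo, hi), maximum = TRUE, tol = 1e-10)$maximum
}

#' Mode-based estimators
#'
#' Locates the mode of a normal-kernel density over the per-SNP Wald
#' ratios: the largest cluster of agreeing instruments drives the
#' estimate, so a minority of invalid instruments is ignored. Weights are
#' uniform for the simple mode and proportional to gamma_j^2/sigma_Yj^2
#' for the weighted mode. The bandwidth is
#' phi * 0.9 * min(sd, mad) * J^(-1/5) (mad with the consistency constant
#' 1.4826); the argmax is located on a fixed 512-point grid spanning the
#' ratios +/- 3 bandwidths and then refined by derivative-free
#' optimisation, so results are deterministic. If all ratios coincide the
#' common ratio is returned. Standard errors use the same parametric
#' bootstrap as [mrWeightedMedian()].
#'
#' @param set a [HarmonizedSet-class] with at least 3 instruments.
#' @param weighted use inverse-variance weights (\code{TRUE}) or uniform
#'   weights (\code{FALSE}, default).
#' @param phi bandwidth multiplier (default 1).
#' @param nBoot,seed bootstrap control as in [mrWeightedMedian()].
#' @return an [MREstimate-class] with method \code{"simple_mode"} or
#'   \code{"weighted_mode"}.
#' @export
mrMode <- function(set, weighted = FALSE, phi = 1, nBoot = 1000,
                   seed = NULL) {
  e <- .effects(set)
  .needSnps(e$J, 3L, "mode estimator")
  ratios <- e$G / e$g
  w <- if (weighted) (e$g / e$sy)^2 else rep(1, e$J)
  w <- w / sum(w)
  theta <- .modePoint(ratios, w, phi, refine = TRUE)
  se <- NA_real_; p <- NA_real_
  if (nBoot > 0) {
    seed <- .needSeed(seed)
    d <- .bootDraws(e, nBoot, seed)
    est <- vapply(seq_len(nBoot), function(b) {
      gb <- d$g[, b]
      wb <- if (weighted) (gb / e$sy)^2 else rep(1, e$J)
      .modePoint(d$G[, b] / gb, wb / sum(wb), phi, refine = FALSE)
    }, 0)
    se <- stats::sd(est)
    p <- 2 * stats::pnorm(-abs(theta) / se)
  }
  .mkEstimate(if (weighted) "weighted_mode" else "simple_mode",
              theta, se, p, e$J,
              extra = list(phi = phi, n_boot = nBoot, seed = seed))
}

#' Run every applicable MR estimator
#'
#' Runs, in fixed order, IVW, MR-Egger, weighted median, simple mode and
#' weighted mode on one harmonized set. Methods whose minimum instrument
#' count is not met (3 for all but IVW) are recorded in the
#' \code{"skipped"} attribute rather than raising errors. Bootstrap
#' methods derive distinct sub-seeds from \code{seed} so each method is
#' reproducible in isolation.
#'
#' @param set a [HarmonizedSet-class].
#' @param nBoot bootstrap replicates for median/mode standard errors.
#' @param seed integer seed, required when \code{nBoot > 0} and J >= 3.
#' @param effectsModel IVW effects model, see [mrIVW()].
#' @param phi mode bandwidth multiplier, see [mrMode()].
#' @return named list of [MREstimate-class] objects with a
#'   \code{"skipped"} attribute naming methods not run and why.
#' @export
mrAllMethods <- function(set, nBoot = 1000, seed = NULL,
                         effectsModel = c("multiplicative_random", "fixed"),
                         phi = 1) {
  effectsModel <- match.arg(effectsModel)
  e <- .effects(set)
  out <- list()
  skipped <- character()
  out$ivw <- suppressWarnings(mrIVW(set, effectsModel))
  if (e$J >= 3L) {
    sd1 <- if (nBoot > 0) .needSeed(seed) else NULL
    out$egger <- mrEgger(set)
    out$weighted_median <- mrWeightedMedian(set, nBoot,
                                            if (nBoot > 0) sd1 + 1L else NULL)
    out$simple_mode <- mrMode(set, weighted = FALSE, phi, nBoot,
                              if (nBoot > 0) sd1 + 2L else NULL)
    out$weighted_mode <- mrMode(set, weighted = TRUE, phi, nBoot,
                                if (nBoot > 0) sd1 + 3L else NULL)
  } else {
    msg <- sprintf("insufficient instruments (%d < 3)", e$J)
    skipped <- c(egger = msg, weighted_median = msg, simple_mode = msg,
                 weighted_mode = msg)
  }
  attr(out, "skipped") <- skipped
  out
}
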