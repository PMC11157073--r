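---
title: "Methods: two-sample MR screening with mrscreen"
author: "mrscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR screening with mrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

# The model

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure X (for example, the relative abundance of a gut-microbiome taxon)
on an outcome Y (for example, an epilepsy subtype) from two independent
GWAS. For each instrument SNP j we observe the SNP-exposure association
$\hat\gamma_j$ with standard error $\sigma_{Xj}$ and the SNP-outcome
association $\hat\Gamma_j$ with standard error $\sigma_{Yj}$. Under the
three instrumental-variable assumptions (relevance, independence from
confounders, and exclusion — the SNP affects Y only through X), each SNP
supplies a Wald ratio $\hat\theta_j = \hat\Gamma_j/\hat\gamma_j$ for the
causal effect $\theta$, and the estimators differ in how they pool the
ratios when some instruments are invalid:

* **IVW** — weighted regression of $\hat\Gamma$ on $\hat\gamma$ through
  the origin with weights $1/\sigma_{Yj}^2$. Unbiased only when *all*
  instruments are valid. We default to the multiplicative random-effects
  variant: the fixed-effect standard error is scaled by
  $\max(1, \sqrt{Q/(J-1)})$, so heterogeneity widens the interval but can
  never narrow it. With one SNP, IVW *is* the Wald ratio (implemented as
  an exact collapse, not as a sum that merely agrees analytically).
* **MR-Egger** — the same regression with a free intercept after
  orienting every SNP so $\hat\gamma_j \ge 0$. The intercept estimates
  the average directional pleiotropic effect; the slope is a
  pleiotropy-adjusted estimate valid under the InSiDE assumption
  (instrument strength independent of direct effects). Coefficient
  variances carry the multiplicative inflation $\max(1, RSS/(J-2))$ and
  p-values use $t_{J-2}$.
* **Weighted median** — the ratio distribution interpolated at
  cumulative weight 0.5 with weights
  $\propto \hat\gamma_j^2/\sigma_{Yj}^2$; consistent while instruments
  carrying half the weight are valid.
* **Simple / weighted mode** — the argmax of a normal-kernel density over
  the ratios (uniform or inverse-variance weights); consistent when the
  largest cluster of agreeing instruments is valid.

Estimates are reported on the beta (log-odds for binary outcomes) scale
with 95% confidence bounds $\hat\theta \pm 1.96\,\mathrm{se}$ and as odds
ratios by exponentiation.

# Instrument selection

`selectInstruments()` applies three screens in order and logs the count
surviving each:

1. **Association**: exposure p-value strictly below the threshold.
   Defaults by exposure class: $10^{-5}$ for microbiome taxa and
   $5\times10^{-6}$ for cytokines (genome-wide significant hits are too
   scarce for these traits), $5\times10^{-8}$ otherwise.
2. **LD clumping**: greedy — repeatedly take the smallest-p unclaimed SNP
   as an index and remove unclaimed SNPs on the same chromosome within
   10,000 kb (inclusive) whose $r^2$ with the index exceeds 0.01
   (0.1 in cis-eQTL mode, where the stringent cutoff would discard causal
   variants). Ties on p are broken by (chromosome, position, id), so the
   result is deterministic. LD comes from an explicit pairwise $r^2$
   table (absent pairs are unlinked, cross-chromosome pairs always
   unlinked) rather than a reference-panel service, which keeps the whole
   pipeline testable offline.
3. **Instrument strength**: $F = \beta^2/\mathrm{se}^2$; SNPs with
   $F \le 10$ are dropped by default (a `flag` mode retains them marked
   weak, for diagnostics).

Harmonization (`harmonize()`) drops SNPs missing from the outcome,
*unconditionally* drops palindromic (A/T, C/G) SNPs — no allele-frequency
rescue, since strand cannot be resolved from the alleles alone — and
aligns swapped-allele records by flipping the outcome beta and
complementing its allele frequency. Records matching neither orientation
are dropped, and every drop is logged with a per-SNP reason. Matching is
by variant id only (no positional fallback); indels and multi-allelic
records are removed at read time. Effect-allele frequency is never
required downstream, so missing `eaf` is permitted throughout.

# Diagnostics

`sensitivityReport()` bundles Cochran's $Q$ with
$I^2 = \max(0, (Q-(J-1))/Q) \times 100$, the Egger intercept test,
MR-PRESSO and leave-one-out IVW. MR-PRESSO computes
$RSS_{obs} = \sum_j (\hat\Gamma_j - \hat\gamma_j\hat\theta_{(-j)})^2 /
\sigma_{Yj}^2$ with leave-one-out IVW predictions and calibrates it
against parametric simulations; the global p uses the add-one estimator
$(1 + \#\{RSS^* \ge RSS_{obs}\})/(n_{sim}+1)$, so it is never 0 and never
below $1/(n_{sim}+1)$, and per-SNP outlier p-values are
Bonferroni-adjusted across instruments (cutoff 0.05). Diagnostics whose
minimum instrument count is not met (2 for Q and leave-one-out, 3 for
Egger, 4 for MR-PRESSO) appear as `NA` fields in the report rather than
missing rows, so a screening table stays rectangular.

# Screening, FDR, reverse MR, mediation

`runForward()` screens every exposure–outcome pair and applies
Benjamini–Hochberg FDR to the IVW p-values **within each outcome, across
exposures of one class**. Whether a published screen pools taxonomic
levels into one family is often ambiguous; we fix the family as
outcome-by-class and expose the raw p-values so any other family can be
re-formed. Pair-level failures (no instruments, nothing harmonizable)
are logged skips: one degenerate taxon cannot abort a screen.

`runReverse()` re-tests nominally significant forward pairs
(IVW p < 0.05 — the broader set, not only FDR survivors) with roles
swapped, selecting disease instruments at $5\times10^{-8}$; a reverse
IVW p < 0.05 flags potential reverse causality.

`twoStepMediation()` combines exposure→mediator ($\beta_1$),
mediator→outcome ($\beta_2$) and the *total* exposure→outcome effect
($\beta_3$): indirect $=\beta_1\beta_2$ with Sobel standard error
$\sqrt{\beta_1^2 se_2^2 + \beta_2^2 se_1^2}$ (a product-of-normals
Monte-Carlo alternative is provided), proportion mediated
$=\beta_1\beta_2/\beta_3$ (undefined at $\beta_3 = 0$). A step-1
significance gate (default $\alpha = 0.05$) mirrors the usual screening
logic: a chain whose exposure does not causally move the mediator is
computed but flagged unsupported.

# The synthetic generator

`simulatePair()` emulates the two-sample design under a linear structural
model. Choices that matter:

* **Standard errors** follow the standardized-trait GWAS form
  $\sigma = 1/\sqrt{2f(1-f)n}$ with minor allele frequencies uniform on
  (0.05, 0.5) and default sample sizes of 20,000 per trait — the scale of
  consortium microbiome/cytokine GWAS.
* **Instrument strength**: true effect magnitudes are $|N(0, 0.05^2)|$
  clamped to at least $6\sigma_{Xj}$, so observed F statistics typically
  exceed 10, matching the instrument sets that survive a real F > 10
  screen.
* **Orientation**: effects are expressed for the exposure-raising allele
  (all positive), the standard frame in MR simulation work. In this
  frame a "directional" pleiotropy mean is well defined; with arbitrary
  signs, Egger's $\gamma \ge 0$ orientation would flip direct effects
  SNP-by-SNP and the mean pleiotropic effect would not be recoverable
  even in principle.
* **Conditioning**: outcome associations are drawn with mean
  $\theta\hat\gamma_j + \alpha_j$ given the *realized* exposure
  associations. This makes the generator test the estimators themselves:
  recovery and calibration results are not confounded by weak-instrument
  regression dilution (which the clamp renders negligible anyway), and
  the deterministic regime (`noiseScale = 0`, where
  $\hat\Gamma_j = \theta\hat\gamma_j$ exactly and IVW returns $\theta$
  to machine precision) falls out as a special case.
* **Pleiotropy regimes**: none; balanced ($\alpha_j \sim N(0,\tau^2)$);
  directional ($N(\mu_\alpha,\tau^2)$); InSiDE-violating ($\alpha_j$
  correlated 0.7 with instrument strength). `pleiotropyFrac` applies the
  regime to a random subset of instruments (e.g. 40% invalid).
* **Structure for the orchestrator**: decoy null SNPs whose p-values sit
  above any instrument threshold by construction (|z| truncated below
  3.5), compound-symmetric LD blocks (each block on its own chromosome
  stretch, blocks mutually unlinked — the simplest structure that
  exercises clumping), and outcome-trait instruments with a configurable
  back-effect on the exposure so reverse MR has something to select in
  both the unidirectional and bidirectional cases.
* **Reproducibility**: each SNP category draws from its own sub-stream
  derived from the master seed by fixed offsets, so enabling decoys does
  not perturb the instrument draws.

What the generator does **not** emulate: case-control ascertainment
(binary traits are treated on a linear/log-odds scale), genotype-level
LD beyond block-constant $r^2$, sample overlap between the two GWAS,
population stratification, and realistic taxon-abundance distributions.
Passing tests therefore demonstrate correctness of the estimators and
pipeline logic under the stated model, not robustness to those
real-data complications.

# Numerical choices

* CI multiplier 1.96 exactly; p-values from the normal (IVW, Wald,
  bootstrap methods) or $t_{J-2}$ (Egger) distributions.
* Mode bandwidth $h = \phi\, 0.9\, \min(\mathrm{sd},
  \mathrm{mad})\,J^{-1/5}$ (mad with the 1.4826 consistency constant,
  falling back to the sd when the mad degenerates to zero); the density
  argmax is located on a fixed 512-point grid spanning the ratios
  $\pm 3h$ and refined by derivative-free optimisation, so mode
  estimates are deterministic. If all ratios coincide the common ratio
  is returned.
* Bootstrap standard errors (weighted median, modes) use a parametric
  bootstrap redrawing $(\hat\gamma_j, \hat\Gamma_j)$ from their reported
  standard errors; 1000 replicates by default, an explicit integer seed
  is required, and identical seeds give bit-identical standard errors.
* Benjamini–Hochberg adjustment delegates to `stats::p.adjust`; the test
  suite checks it against an independently coded step-up oracle.
* TSV output prints doubles with 17 significant digits, so
  write-then-read round trips are exact and pipeline outputs are
  byte-stable.

# Problem sizes used in validation

The shipped checks run at desk scale, chosen to give tight Monte-Carlo
error while keeping the suite quick: oracle equivalence on 100 random
instrument sets and 1000 random p-vectors; recovery/coverage at J = 50,
n = 20,000, 500 replicates; diagnostic calibration over 600–1000
replicates (MR-PRESSO uniformity over 200 replicates at 200
simulations); robustness, outlier-detection, directionality and
mediation recovery over 100–500 replicates each. `scripts/acceptance.R`
recomputes the same quantities from scratch at comparable sizes.

# Known limitations

MR-PRESSO's distortion test is not implemented (only global and outlier
tests). No proxy-SNP lookup, liftover, GWAS-VCF parsing, or
reference-panel LD computation: inputs are plain summary-statistics
tables plus an explicit LD table. Steiger filtering, MR-RAPS,
contamination-mixture and multivariable MR are out of scope. The FDR
family and the reverse-MR instrument threshold are configurable because
published screens rarely pin them down; defaults are documented above.
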