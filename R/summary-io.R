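#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated table with a header row into a
#' [SummaryStats-class] object. Default column names are \code{snp},
#' \code{chr}, \code{pos}, \code{effect_allele}, \code{other_allele},
#' \code{eaf}, \code{beta}, \code{se}, \code{pval}, \code{n}; supply
#' \code{columnMap} to map these standard keys onto the file's actual
#' column names. Rows with unparseable \code{beta}/\code{se}/\code{pval},
#' non-positive \code{se}, p-values outside (0, 1], identical alleles, or
#' alleles outside A/C/G/T (indels, multi-allelic records) are dropped with
#' a summary warning; drop counts are kept in the object's log. Allele
#' letters are upper-cased.
#'
#' @param path file path to a delimited text table with a header.
#' @param columnMap named character vector mapping standard keys (e.g.
#'   \code{c(snp = "rsid", pval = "p")}) to file column names.
#' @param traitName trait label; defaults to the file name.
#' @param traitType \code{"continuous"} or \code{"binary"}.
#' @return a [SummaryStats-class] object.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("snp\tchr\tpos\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
#'              "rs1\t1\t1000\tA\tG\t0.2\t0.1\t0.02\t1e-6\t10000"), tf)
#' readSummaryStats(tf, traitName = "toy")
#' @export
readSummaryStats <- function(path, columnMap = NULL, traitName = NULL,
                             traitType = c("continuous", "binary")) {
  traitType <- match.arg(traitType)
  if (is.null(traitName))
    traitName <- sub("\\.[^.]*$", "", basename(path))
  # colClasses = "character": an all-T allele column must not become logical
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "", comment.char = "",
                           colClasses = "character")
  std <- c("snp", "chr", "pos", "effect_allele", "other_allele", "eaf",
           "beta", "se", "pval", "n")
  cols <- stats::setNames(std, std)
  if (!is.null(columnMap)) {
    bad <- setdiff(names(columnMap), std)
    if (length(bad))
      .mrError(paste0("unknown columnMap keys: ", paste(bad, collapse = ", ")),
               "mrscreen_config_error")
    cols[names(columnMap)] <- columnMap
  }
  for (k in c("snp", "effect_allele", "other_allele", "beta", "se", "pval"))
    if (!cols[[k]] %in% names(raw))
      .mrError(sprintf("mandatory column '%s' ('%s') not found in %s",
                       k, cols[[k]], path), "mrscreen_config_error")
  chr <- function(k) {
    if (cols[[k]] %in% names(raw)) as.character(raw[[cols[[k]]]])
    else rep(NA_character_, nrow(raw))
  }
  num <- function(k) {
    if (cols[[k]] %in% names(raw))
      suppressWarnings(as.numeric(raw[[cols[[k]]]]))
    else rep(NA_real_, nrow(raw))
  }
  v <- data.frame(variant_id = chr("snp"), chrom = chr("chr"),
                  pos = num("pos"), effect_allele = toupper(chr("effect_allele")),
                  other_allele = toupper(chr("other_allele")), eaf = num("eaf"),
                  beta = num("beta"), se = num("se"), pvalue = num("pval"),
                  n = num("n"), stringsAsFactors = FALSE)

  dropLog <- list()
  alphabet <- c("A", "C", "G", "T")
  keep <- rep(TRUE, nrow(v))
  mark <- function(bad, reason) {
    bad <- bad & keep
    dropLog[[reason]] <<- sum(bad)
    keep <<- keep & !bad
  }
  mark(!v$effect_allele %in% alphabet | !v$other_allele %in% alphabet,
       "non_snp_alleles")
  mark(v$effect_allele == v$other_allele, "identical_alleles")
  mark(is.na(v$beta) | is.na(v$se) | is.na(v$pvalue), "unparseable_numeric")
  mark(v$se <= 0, "nonpositive_se")
  mark(v$pvalue <= 0 | v$pvalue > 1, "pvalue_out_of_range")
  mark(!is.na(v$eaf) & (v$eaf < 0 | v$eaf > 1), "eaf_out_of_range")
  mark(duplicated(v$variant_id), "duplicate_id")
  nDropped <- sum(!keep)
  if (nDropped > 0) {
    parts <- vapply(names(dropLog)[unlist(dropLog) > 0],
                    function(r) sprintf("%s=%d", r, dropLog[[r]]), "")
    warning(sprintf("%s: dropped %d of %d rows (%s)", traitName, nDropped,
                    nrow(v), paste(parts, collapse = ", ")), call. = FALSE)
  }
  v <- v[keep, , drop = FALSE]
  if (nrow(v) == 0L)
    .mrError(sprintf("no usable rows remain in %s after filtering", path),
             "mrscreen_input_error")
  SummaryStats(v, traitName = traitName, traitType = traitType,
               log = c(list(n_read = length(keep), n_kept = nrow(v)), dropLog))
}

#' Write a summary-statistics table to TSV
#'
#' Writes the standard ten-column dialect read by [readSummaryStats()].
#' Doubles are printed with 17 significant digits so a write-then-read
#' round trip reproduces every finite value exactly.
#'
#' @param x a [SummaryStats-class] object.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeSummaryStats <- function(x, path) {
  stopifnot(is(x, "SummaryStats"))
  out <- x@variants
  names(out) <- c("snp", "chr", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pval", "n")
  .writeTable(out, path)
}

#' Is an allele pair palindromic?
#'
#' A SNP is palindromic when its two alleles are complementary ({A,T} or
#' {C,G}), so the strand cannot be resolved from the alleles alone.
#' Vectorized over both arguments.
#'
#' @param effectAllele,otherAllele allele letters in A/C/G/T.
#' @return logical vector.
#' @examples
#' isPalindromic("A", "T")  # TRUE
#' isPalindromic("A", "G")  # FALSE
#' @export
isPalindromic <- function(effectAllele, otherAllele) {
  effectAllele <- toupper(effectAllele)
  otherAllele <- toupper(otherAllele)
  ok <- c("A", "C", "G", "T")
  if (any(!effectAllele %in% ok) || any(!otherAllele %in% ok))
    .mrError("alleles must be one of A, C, G, T", "mrscreen_input_error")
  unname(.COMPLEMENT[effectAllele] == otherAllele)
}

#' Harmonize exposure and outcome associations
#'
#' Aligns outcome associations onto the exposure's effect-allele frame for
#' the requested SNPs. SNPs absent from the outcome table are dropped;
#' palindromic SNPs are dropped unconditionally (no frequency-based
#' rescue); if the outcome's alleles are swapped relative to the exposure,
#' the outcome beta sign is flipped and its effect-allele frequency
#' replaced by 1 - eaf; allele pairs matching neither orientation are
#' dropped. Per-SNP instrument-strength F statistics (beta^2/se^2 on the
#' exposure association) are attached. Drop reasons are recorded per SNP
#' in the returned object's log.
#'
#' @param exposure,outcome [SummaryStats-class] objects.
#' @param snpIds instrument ids drawn from the exposure table; default all.
#' @return a [HarmonizedSet-class].
#' @export
harmonize <- function(exposure, outcome, snpIds = NULL) {
  stopifnot(is(exposure, "SummaryStats"), is(outcome, "SummaryStats"))
  ev <- exposure@variants
  if (is.null(snpIds)) snpIds <- ev$variant_id
  snpIds <- as.character(snpIds)
  unknown <- setdiff(snpIds, ev$variant_id)
  if (length(unknown))
    .mrError(sprintf("snpIds not present in exposure '%s': %s",
                     exposure@traitName,
                     paste(utils::head(unknown, 5L), collapse = ", ")),
             "mrscreen_input_error")
  ie <- match(snpIds, ev$variant_id)
  ov <- outcome@variants
  io <- match(snpIds, ov$variant_id)

  reason <- rep(NA_character_, length(snpIds))
  reason[is.na(io)] <- "missing_outcome"
  pal <- .COMPLEMENT[ev$effect_allele[ie]] == ev$other_allele[ie]
  reason[is.na(reason) & pal] <- "palindromic"

  same <- !is.na(io) &
    ov$effect_allele[io] == ev$effect_allele[ie] &
    ov$other_allele[io] == ev$other_allele[ie]
  swapped <- !is.na(io) &
    ov$effect_allele[io] == ev$other_allele[ie] &
    ov$other_allele[io] == ev$effect_allele[ie]
  reason[is.na(reason) & !(same | swapped)] <- "allele_mismatch"

  keep <- is.na(reason)
  log <- data.frame(variant_id = snpIds[!keep], reason = reason[!keep],
                    stringsAsFactors = FALSE)
  if (!any(keep))
    .mrError(sprintf("no SNPs survive harmonization for %s -> %s",
                     exposure@traitName, outcome@traitName),
             "mrscreen_harmonization_error")

  ie <- ie[keep]; io <- io[keep]
  flip <- swapped[keep]
  betaOut <- ifelse(flip, -ov$beta[io], ov$beta[io])
  eafOut <- ifelse(flip, 1 - ov$eaf[io], ov$eaf[io])
  snps <- data.frame(
    variant_id = ev$variant_id[ie], chrom = ev$chrom[ie], pos = ev$pos[ie],
    effect_allele = ev$effect_allele[ie], other_allele = ev$other_allele[ie],
    eaf_exposure = ev$eaf[ie], eaf_outcome = eafOut,
    beta_exposure = ev$beta[ie], se_exposure = ev$se[ie],
    pval_exposure = ev$pvalue[ie],
    beta_outcome = betaOut, se_outcome = ov$se[io],
    pval_outcome = ov$pvalue[io],
    f_stat = (ev$beta[ie] / ev$se[ie])^2,
    stringsAsFactors = FALSE)
  rownames(snps) <- NULL
  new("HarmonizedSet", exposureName = exposure@traitName,
      outcomeName = outcome@traitName, snps = snps, log = log)
}

#' Write a harmonized instrument set to TSV
#'
#' Serializes the paired-column dialect (beta_exposure, se_exposure,
#' beta_outcome, se_outcome, ...) with round-trippable numeric formatting.
#'
#' @param x a [HarmonizedSet-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeHarmonized <- function(x, path) {
  stopifnot(is(x, "HarmonizedSet"))
  out <- cbind(exposure = x@exposureName, outcome = x@outcomeName, x@snps)
  .writeTable(out, path)
}

# rebuild a HarmonizedSet from a subset of rows (validity already holds)
.subsetHarmonized <- function(set, idx) {
  new("HarmonizedSet", exposureName = set@exposureName,
      outcomeName = set@outcomeName,
      snps = set@snps[idx, , drop = FALSE], log = set@log)
}
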