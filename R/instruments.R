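.ldKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\t")

#' Build an LD lookup table from pairwise r-squared values
#'
#' @param pairs data.frame with columns \code{id_a}, \code{id_b},
#'   \code{r2} (undirected); may be \code{NULL} for a fully unlinked set.
#' @param ids optional character vector of ids covered by the table.
#' @return an [LDMatrix-class].
#' @export
ldMatrix <- function(pairs = NULL, ids = character()) {
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(new("LDMatrix", ids = as.character(ids), r2 = numeric()))
  a <- as.character(pairs$id_a); b <- as.character(pairs$id_b)
  r2 <- as.numeric(pairs$r2)
  keep <- a != b
  keys <- .ldKey(a[keep], b[keep])
  r2 <- r2[keep]
  # first value wins for duplicate pairs
  first <- !duplicated(keys)
  new("LDMatrix", ids = unique(c(ids, a, b)),
      r2 = stats::setNames(r2[first], keys[first]))
}

#' Pairwise r-squared lookup
#'
#' Vectorized lookup; absent pairs return 0, identical ids return 1.
#'
#' @param ld an [LDMatrix-class] or \code{NULL} (all pairs unlinked).
#' @param a,b variant id vectors (recycled to a common length).
#' @return numeric vector of r-squared values.
#' @export
ldR2 <- function(ld, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n); b <- rep_len(as.character(b), n)
  out <- numeric(n)
  if (!is.null(ld) && length(ld@r2)) {
    hit <- ld@r2[.ldKey(a, b)]
    out[!is.na(hit)] <- hit[!is.na(hit)]
  }
  out[a == b] <- 1
  out
}

#' Read an LD file
#'
#' Two dialects are auto-detected: whitespace-delimited triplets
#' \code{id_a id_b r2} (undirected, with or without a header row), or a
#' square matrix with an id header row and id first column.
#'
#' @param path file path.
#' @return an [LDMatrix-class].
#' @export
readLDFile <- function(path) {
  first <- strsplit(trimws(readLines(path, n = 1L)), "\\s+")[[1]]
  if (length(first) == 3L) {
    hasHeader <- is.na(suppressWarnings(as.numeric(first[3])))
    tab <- utils::read.table(path, header = hasHeader,
                             stringsAsFactors = FALSE)
    names(tab) <- c("id_a", "id_b", "r2")
    if (any(is.na(tab$r2)))
      .mrError(sprintf("unparseable r2 values in %s", path),
               "mrscreen_input_error")
    return(ldMatrix(tab))
  }
  m <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!is.numeric(m[[1]])) {
    rownames(m) <- m[[1]]
    m <- m[, -1, drop = FALSE]
  } else {
    rownames(m) <- colnames(m)
  }
  m <- as.matrix(m)
  if (nrow(m) != ncol(m))
    .mrError(sprintf("LD matrix in %s is not square", path),
             "mrscreen_input_error")
  if (max(abs(m - t(m))) > 1e-8)
    .mrError(sprintf("LD matrix in %s is not symmetric", path),
             "mrscreen_input_error")
  ut <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  ldMatrix(data.frame(id_a = rownames(m)[ut[, 1]],
                      id_b = colnames(m)[ut[, 2]],
                      r2 = m[ut], stringsAsFactors = FALSE),
           ids = rownames(m))
}

#' Write an LDMatrix as an id_a/id_b/r2 triplet file
#'
#' @param ld an [LDMatrix-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeLDFile <- function(ld, path) {
  stopifnot(is(ld, "LDMatrix"))
  if (length(ld@r2)) {
    parts <- do.call(rbind, strsplit(names(ld@r2), "\t", fixed = TRUE))
    df <- data.frame(id_a = parts[, 1], id_b = parts[, 2], r2 = ld@r2,
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(id_a = character(), id_b = character(), r2 = numeric())
  }
  .writeTable(df, path)
}

#' Instrument-strength F statistic
#'
#' Computes F = beta^2/se^2, the squared z score used as the conventional
#' weak-instrument screen (values above 10 indicate negligible
#' weak-instrument bias).
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), all > 0.
#' @return numeric vector of F values.
#' @examples
#' fStatistic(0.1, 0.02)  # 25
#' @export
fStatistic <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0))
    .mrError("se must be finite and > 0", "mrscreen_input_error")
  beta^2 / se^2
}

#' Greedy LD clumping
#'
#' Repeatedly takes the smallest-p unclaimed SNP as an index, then removes
#' every unclaimed SNP on the same chromosome within
#' \code{clumpWindowKb} kilobases (inclusive) whose r-squared with the
#' index exceeds \code{clumpR2}. Ties on p-value are broken by
#' (chrom, pos, variant_id) order, making the result deterministic.
#' Cross-chromosome pairs are always treated as unlinked.
#'
#' @param candidates data.frame with columns \code{variant_id},
#'   \code{chrom}, \code{pos}, \code{pvalue} (a [SummaryStats-class] is
#'   also accepted).
#' @param ld an [LDMatrix-class] or \code{NULL}.
#' @param config a [SelectionConfig-class].
#' @return character vector of retained index SNP ids, in selection order.
#' @export
clumpVariants <- function(candidates, ld = NULL, config = selectionConfig()) {
  if (is(candidates, "SummaryStats")) candidates <- candidates@variants
  if (NROW(candidates) == 0L) return(character())
  o <- order(candidates$pvalue, candidates$chrom, candidates$pos,
             candidates$variant_id)
  id <- as.character(candidates$variant_id)[o]
  chrom <- as.character(candidates$chrom)[o]
  pos <- as.numeric(candidates$pos)[o]
  win <- config@clumpWindowKb * 1000
  alive <- rep(TRUE, length(id))
  kept <- character()
  for (i in seq_along(id)) {
    if (!alive[i]) next
    alive[i] <- FALSE
    kept <- c(kept, id[i])
    near <- which(alive & chrom == chrom[i] & !is.na(pos) &
                    abs(pos - pos[i]) <= win)
    if (length(near)) {
      r2 <- ldR2(ld, id[near], id[i])
      alive[near[r2 > config@clumpR2]] <- FALSE
    }
  }
  kept
}

#' Select instrumental variables for an exposure
#'
#' Applies the three-stage screen: (1) exposure-association p-value
#' threshold (p < \code{pThreshold}), (2) greedy LD clumping
#' ([clumpVariants()]), (3) weak-instrument F screen: SNPs with
#' F = beta^2/se^2 <= \code{fMin} are dropped (\code{fAction = "drop"}) or
#' kept with a \code{weak} flag (\code{fAction = "flag"}). Counts at every
#' stage are recorded in the \code{"log"} attribute of the result.
#'
#' @param exposure a [SummaryStats-class].
#' @param ld an [LDMatrix-class] or \code{NULL}.
#' @param config a [SelectionConfig-class].
#' @return data.frame with columns \code{variant_id}, \code{pvalue},
#'   \code{f_stat}, \code{weak}, in clump selection order, with a
#'   \code{"log"} attribute of stage counts.
#' @export
selectInstruments <- function(exposure, ld = NULL,
                              config = selectionConfig()) {
  stopifnot(is(exposure, "SummaryStats"))
  v <- exposure@variants
  sig <- v[!is.na(v$pvalue) & v$pvalue < config@pThreshold, , drop = FALSE]
  if (nrow(sig) == 0L)
    .mrError(sprintf("no variants pass p < %g for exposure '%s'",
                     config@pThreshold, exposure@traitName),
             "mrscreen_selection_error")
  keptIds <- clumpVariants(sig, ld, config)
  sel <- sig[match(keptIds, sig$variant_id), , drop = FALSE]
  f <- fStatistic(sel$beta, sel$se)
  weak <- f <= config@fMin
  nWeak <- sum(weak)
  if (config@fAction == "drop" && nWeak > 0) {
    sel <- sel[!weak, , drop = FALSE]
    f <- f[!weak]
    weak <- weak[!weak]
  }
  if (nrow(sel) == 0L)
    .mrError(sprintf(
      "all clumped instruments for exposure '%s' are weak (F <= %g)",
      exposure@traitName, config@fMin), "mrscreen_selection_error")
  out <- data.frame(variant_id = sel$variant_id, pvalue = sel$pvalue,
                    f_stat = f, weak = weak, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "log") <- list(n_input = nrow(v), n_significant = nrow(sig),
                           n_clumped = length(keptIds), n_weak = nWeak,
                           f_action = config@fAction, n_selected = nrow(out))
  out
}
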