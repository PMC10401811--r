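# Reproducibility and enrichment utilities for peak sets: RPKM over merged
# peaks, irreproducible-peak selection, shuffled control regions with an
# exclusion constraint, Fisher enrichment with a star-threshold ladder, and
# a Poisson-scan SNP hotspot test with Benjamini-Hochberg correction.

#' Construct a count matrix over intervals
#'
#' @param intervals interval table (0-based half-open), one row per region.
#' @param counts integer matrix, intervals x replicates.
#' @param librarySizes per-replicate total mapped reads (> 0).
#' @return list of class `count_matrix`.
#' @export
countMatrix <- function(intervals, counts, librarySizes) {
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(intervals))
    stop("counts rows must match intervals")
  if (length(librarySizes) != ncol(counts))
    stop("one library size per replicate required")
  if (any(librarySizes <= 0)) stop("library sizes must be > 0")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(intervals = intervals, counts = counts,
                 librarySizes = as.numeric(librarySizes)),
            class = "count_matrix")
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm[i, j] = counts[i, j] / (length_kb(i) * librarySizes[j] / 1e6)`.
#'
#' @param cm a [countMatrix()].
#' @return numeric matrix of RPKM values.
#' @export
rpkm <- function(cm) {
  len_kb <- (cm$intervals$end - cm$intervals$start) / 1000
  if (any(len_kb <= 0)) stop("zero-length interval in count matrix")
  sweep(cm$counts / len_kb, 2L, cm$librarySizes / 1e6, `/`)
}

#' Select irreproducible regions
#'
#' Regions whose signal is strong in one replicate and near background in
#' another: minimum RPKM across replicates strictly below `low` AND maximum
#' strictly above `high`.
#'
#' @param rpkmMatrix RPKM matrix (regions x replicates, >= 2 replicates).
#' @param intervals matching interval table.
#' @param low,high RPKM thresholds (0.5 and 2 for the ChIP defaults; 1 and
#'   2 for the ATAC defaults).
#' @return the selected rows of `intervals`.
#' @export
irreproducibleRegions <- function(rpkmMatrix, intervals, low = 0.5,
                                  high = 2) {
  if (ncol(rpkmMatrix) < 2L) stop("need >= 2 replicates")
  if (low >= high) stop("low threshold must be below high threshold")
  mins <- apply(rpkmMatrix, 1L, min)
  maxs <- apply(rpkmMatrix, 1L, max)
  intervals[mins < low & maxs > high, , drop = FALSE]
}

#' Randomly shuffle regions with an exclusion constraint
#'
#' Places each input interval uniformly at random on the genome (length
#' preserved), rejecting placements that overlap the excluded set by more
#' than `maxOverlap` of the interval's own length. Deterministic given
#' `seed`.
#'
#' @param intervals interval table to shuffle.
#' @param contigSizes named vector of contig lengths.
#' @param excluded interval table of excluded regions (e.g. repeats).
#' @param maxOverlap maximum allowed overlap fraction (0.5 by default).
#' @param seed integer seed.
#' @param maxTries rejection-sampling retries per interval.
#' @return interval table of shuffled regions (same count and lengths).
#' @export
shuffleControls <- function(intervals, contigSizes,
                            excluded = intervalTable(character(), integer(),
                                                     integer()),
                            maxOverlap = 0.5, seed = 1L, maxTries = 1000L) {
  set.seed(as.integer(seed))
  n <- nrow(intervals)
  out_contig <- character(n)
  out_start <- integer(n)
  widths <- intervals$end - intervals$start
  for (i in seq_len(n)) {
    w <- widths[i]
    eligible <- names(contigSizes)[contigSizes >= w]
    if (length(eligible) == 0L)
      stop("interval ", i, " (", w, " bp) longer than every contig")
    placeable <- contigSizes[eligible] - w + 1L
    placed <- FALSE
    for (try in seq_len(maxTries)) {
      ctg <- sample(eligible, 1L, prob = placeable / sum(placeable))
      s <- sample.int(placeable[[ctg]], 1L) - 1L
      ov <- excluded[excluded$contig == ctg, , drop = FALSE]
      ov_bp <- if (nrow(ov)) sum(pmax(0L, pmin(ov$end, s + w) -
                                        pmax(ov$start, s))) else 0L
      if (ov_bp <= maxOverlap * w) {
        out_contig[i] <- ctg
        out_start[i] <- s
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place interval ", i, " (", w, " bp) after ",
           maxTries, " tries")
  }
  intervalTable(out_contig, out_start, out_start + widths,
                name = intervals$name, score = intervals$score,
                strand = intervals$strand)
}

#' Star annotation for a p-value ladder
#'
#' Strict thresholds, most significant level wins:
#' `p < .01` = \*, `< .001` = \*\*, `< 1e-5` = \*\*\*, `< 1e-10` = \*\*\*\*.
#'
#' @param p p-value(s).
#' @return character vector of stars ("" when not significant).
#' @export
starsForP <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x < 1e-10) "****"
    else if (x < 1e-5) "***"
    else if (x < 1e-3) "**"
    else if (x < 1e-2) "*"
    else ""
  }, character(1L))
}

#' Overlap enrichment between a test set and a control set
#'
#' Fisher's exact test on the 2x2 table
#' `[[hitsTest, nTest - hitsTest], [hitsControl, nControl - hitsControl]]`.
#'
#' @param hitsTest,nTest hits and total in the test set.
#' @param hitsControl,nControl hits and total in the control set.
#' @param alternative passed to [stats::fisher.test()] (two-sided default).
#' @return list with `oddsRatio`, `pValue` and `stars`.
#' @export
overlapEnrichment <- function(hitsTest, nTest, hitsControl, nControl,
                              alternative = "two.sided") {
  stopifnot(hitsTest <= nTest, hitsControl <= nControl)
  tab <- matrix(c(hitsTest, nTest - hitsTest,
                  hitsControl, nControl - hitsControl),
                nrow = 2L, byrow = TRUE)
  ft <- stats::fisher.test(tab, alternative = alternative)
  list(oddsRatio = unname(ft$estimate), pValue = ft$p.value,
       stars = starsForP(ft$p.value))
}

#' SNP hotspot scan
#'
#' Tests each pre-merged region for an excess of SNPs over the genome-wide
#' background rate with an upper-tail Poisson test
#' (`lambda = nSnps / genomeSize` per base), corrects across regions by
#' Benjamini-Hochberg, and keeps regions with at least `minSnps` SNPs and
#' `q < fdr`.
#'
#' @param regions non-overlapping interval table.
#' @param snpPositions data.frame with columns `contig`, `pos` (0-based) —
#'   or a variant table, whose 1-based `pos` is converted.
#' @param genomeSize total genome size in bp (> 0).
#' @param minSnps minimum SNP count per significant hotspot (50 default).
#' @param fdr BH threshold (0.05 default).
#' @return list with `table` (all regions with count, expected, p, q) and
#'   `hotspots` (the significant subset).
#' @export
snpHotspots <- function(regions, snpPositions, genomeSize, minSnps = 50L,
                        fdr = 0.05) {
  if (genomeSize <= 0) stop("genomeSize must be > 0")
  pos0 <- if (inherits(snpPositions, "variant_table"))
    data.frame(contig = snpPositions$contig, pos = snpPositions$pos - 1L)
  else snpPositions
  lambda <- nrow(pos0) / genomeSize
  counts <- vapply(seq_len(nrow(regions)), function(i) {
    sum(pos0$contig == regions$contig[i] &
          pos0$pos >= regions$start[i] & pos0$pos < regions$end[i])
  }, integer(1L))
  expect <- lambda * (regions$end - regions$start)
  p <- stats::ppois(counts - 1L, expect, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  tab <- cbind(regions, count = counts, expected = expect, p = p, q = q)
  list(table = tab,
       hotspots = tab[counts >= minSnps & q < fdr, , drop = FALSE])
}
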