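# Cohort variant classification: GATK-style hard filters, then selection of
# "uniform" sites (the whole cohort carries the same non-reference allele)
# and "non-uniform" sites (segregating within the cohort), plus the
# indel-spacing and SNP-over-indel exclusions and the cohort-downsampling
# variant of the thresholds.

#' Hard-filter thresholds for SNPs and indels
#'
#' The classic GATK germline short-variant hard filters. A record fails when
#' any inequality triggers: `QD < qd_min`, `QUAL < qual_min`,
#' `SOR > sor_max`, `FS > fs_max`, `MQ < mq_min`,
#' `MQRankSum < mqranksum_min`, `ReadPosRankSum < readposranksum_min`
#' (SNPs), or the four-term indel set. All inequalities are strict, so a
#' value exactly at a threshold passes.
#'
#' @return list with elements `snp` and `indel`, each a named numeric vector.
#' @export
hardFilterThresholds <- function() {
  list(snp = c(qd_min = 2.0, qual_min = 30.0, sor_max = 3.0, fs_max = 60.0,
               mq_min = 40.0, mqranksum_min = -12.5, readposranksum_min = -8.0),
       indel = c(qd_min = 2.0, qual_min = 30.0, fs_max = 200.0,
                 readposranksum_min = -20.0))
}

#' Uniform/non-uniform classification thresholds
#'
#' For a cohort of `nMice` diploid individuals: uniform sites are biallelic
#' with `AF > uniform_af_min` and `AC > uniform_ac_min`; non-uniform sites
#' are biallelic with `nonuniform_af_lo < AF <= nonuniform_af_hi` and
#' `AC > nonuniform_ac_min`, or multiallelic with `AN > multiallelic_an_min`
#' and top alternate-allele fraction `> multiallelic_topfreq_min`. The
#' integer thresholds scale with cohort size (for 5 mice: AC > 5 uniform,
#' AC > 2 non-uniform, AN > 5 multiallelic; for down-sampled cohorts of
#' 2/3/4 mice: AC > 2/3/4 uniform, AC > 0/1/1 non-uniform, AN > 2/3/4).
#'
#' @param nMice cohort size (2 to 5 supported for the integer scalings).
#' @return named list of thresholds.
#' @export
classificationThresholds <- function(nMice = 5L) {
  nMice <- as.integer(nMice)
  scaled <- list(`2` = c(u = 2L, nu = 0L, an = 2L),
                 `3` = c(u = 3L, nu = 1L, an = 3L),
                 `4` = c(u = 4L, nu = 1L, an = 4L),
                 `5` = c(u = 5L, nu = 2L, an = 5L))
  key <- as.character(nMice)
  if (!key %in% names(scaled))
    stop("unsupported cohort size for classification thresholds: ", nMice)
  s <- scaled[[key]]
  list(uniform_af_min = 0.8, uniform_ac_min = s[["u"]],
       nonuniform_af_lo = 0.2, nonuniform_af_hi = 0.8,
       nonuniform_ac_min = s[["nu"]],
       multiallelic_an_min = s[["an"]], multiallelic_topfreq_min = 0.2,
       min_indel_spacing = 1L)
}

#' Apply hard filters to a variant table
#'
#' A missing site annotation (NA) skips the corresponding sub-filter rather
#' than failing it, mirroring how GATK VariantFiltration treats annotations
#' it cannot compute (e.g. MQRankSum at sites with no heterozygote).
#'
#' @param records a variant table (see [variantTable()]).
#' @param thresholds as from [hardFilterThresholds()].
#' @param variantClass `"snp"` or `"indel"`.
#' @return list with `pass` and `fail` variant tables; the `fail` table's
#'   `filter` column names the first rule that fired.
#' @export
hardFilter <- function(records, thresholds = hardFilterThresholds(),
                       variantClass = c("snp", "indel")) {
  variantClass <- match.arg(variantClass)
  th <- thresholds[[variantClass]]
  rules <- list(
    QD = function(r) r$QD < th[["qd_min"]],
    QUAL = function(r) r$qual < th[["qual_min"]],
    SOR = function(r) if ("sor_max" %in% names(th)) r$SOR > th[["sor_max"]] else FALSE,
    FS = function(r) r$FS > th[["fs_max"]],
    MQ = function(r) if ("mq_min" %in% names(th)) r$MQ < th[["mq_min"]] else FALSE,
    MQRankSum = function(r) if ("mqranksum_min" %in% names(th))
      r$MQRankSum < th[["mqranksum_min"]] else FALSE,
    ReadPosRankSum = function(r) r$ReadPosRankSum < th[["readposranksum_min"]])
  fired <- matrix(FALSE, nrow(records), length(rules),
                  dimnames = list(NULL, names(rules)))
  for (k in names(rules)) {
    v <- rules[[k]](records)
    fired[, k] <- !is.na(v) & v   # NA annotation: sub-filter skipped
  }
  fails <- rowSums(fired) > 0L
  fail <- records[fails, , drop = FALSE]
  if (nrow(fail))
    fail$filter <- apply(fired[fails, , drop = FALSE], 1L,
                         function(x) names(rules)[which(x)[1L]])
  pass <- records[!fails, , drop = FALSE]
  if (nrow(pass)) pass$filter <- "PASS"
  list(pass = .restore_vt(pass, records), fail = .restore_vt(fail, records))
}

.restore_vt <- function(x, template) {
  attr(x, "samples") <- attr(template, "samples")
  class(x) <- c("variant_table", "data.frame")
  x
}

.sort_vt <- function(records) {
  .restore_vt(records[order(records$contig, records$pos), , drop = FALSE],
              records)
}

#' Select uniform variants
#'
#' Biallelic sites where the cohort is (near-)fixed for the alternate
#' allele: `AF > uniform_af_min` (strict) and `AC > uniform_ac_min`
#' (strict). Output is sorted by (contig, pos).
#'
#' @param records a hard-filtered variant table.
#' @param thresholds as from [classificationThresholds()].
#' @return a variant table of uniform sites.
#' @export
classifyUniform <- function(records, thresholds = classificationThresholds()) {
  biallelic <- lengths(records$alt) == 1L
  af <- topAltFrequency(records)
  ac <- vapply(records$ac, function(x) if (length(x)) max(x) else 0L, integer(1L))
  keep <- biallelic & !is.na(af) & af > thresholds$uniform_af_min &
    ac > thresholds$uniform_ac_min
  .sort_vt(records[keep, , drop = FALSE])
}

#' Select non-uniform variants
#'
#' The union of (i) biallelic sites with
#' `nonuniform_af_lo < AF <= nonuniform_af_hi` and `AC > nonuniform_ac_min`,
#' and (ii) multiallelic sites with `AN > multiallelic_an_min` whose most
#' frequent alternate allele exceeds `multiallelic_topfreq_min` of called
#' alleles. Disjoint from [classifyUniform()] on the same input.
#'
#' @inheritParams classifyUniform
#' @return a variant table of non-uniform sites.
#' @export
classifyNonuniform <- function(records,
                               thresholds = classificationThresholds()) {
  nalt <- lengths(records$alt)
  af <- topAltFrequency(records)
  ac_top <- vapply(records$ac, function(x) if (length(x)) max(x) else 0L,
                   integer(1L))
  bi <- nalt == 1L & !is.na(af) &
    af > thresholds$nonuniform_af_lo & af <= thresholds$nonuniform_af_hi &
    ac_top > thresholds$nonuniform_ac_min
  multi <- nalt > 1L & records$an > thresholds$multiallelic_an_min &
    !is.na(af) & af > thresholds$multiallelic_topfreq_min
  .sort_vt(records[bi | multi, , drop = FALSE])
}

# reference footprint of a variant, 0-based half-open, anchor base stripped;
# for pure insertions the empty interval at the insertion point
.indel_footprint <- function(records) {
  ref_len <- nchar(records$ref)
  start <- records$pos            # pos is 1-based; anchor at pos-1 0-based
  end <- records$pos - 1L + ref_len
  data.frame(start = as.integer(start), end = as.integer(end))
}

#' Drop indels that are closer together than a minimum spacing
#'
#' Every member of a pair of indels on the same contig whose
#' reference-interval gap (half-open; start of the later minus end of the
#' earlier) is below `minSpacing` is removed, so the surviving set has all
#' pairwise gaps `>= minSpacing`.
#'
#' @param indels a variant table of indels, sorted by (contig, pos).
#' @param minSpacing minimum allowed gap in bp (default 1: only touching or
#'   overlapping pairs are removed).
#' @return the filtered variant table.
#' @export
removeNearbyIndels <- function(indels, minSpacing = 1L) {
  if (nrow(indels) < 2L) return(indels)
  indels <- .sort_vt(indels)
  fp <- .indel_footprint(indels)
  drop <- logical(nrow(indels))
  for (i in seq_len(nrow(indels) - 1L)) {
    j <- i + 1L
    # sorted by start, so the gap to i is non-decreasing in j
    while (j <= nrow(indels) && indels$contig[j] == indels$contig[i]) {
      gap <- fp$start[j] - fp$end[i]
      if (gap >= minSpacing) break
      drop[i] <- drop[j] <- TRUE
      j <- j + 1L
    }
  }
  .restore_vt(indels[!drop, , drop = FALSE], indels)
}

#' Exclude SNPs whose base lies within an indel's reference interval
#'
#' A SNP is removed when its reference base falls inside any indel's
#' reference footprint (the deleted span for deletions; the single anchor
#' base for pure insertions).
#'
#' @param snps,indels variant tables.
#' @return the filtered SNP table.
#' @export
excludeSnpsOverlappingIndels <- function(snps, indels) {
  if (nrow(indels) == 0L || nrow(snps) == 0L) return(snps)
  fp <- .indel_footprint(indels)
  # pure insertion (empty footprint): use the anchor base
  ins <- fp$start == fp$end
  fp$start[ins] <- fp$start[ins] - 1L
  drop <- vapply(seq_len(nrow(snps)), function(i) {
    p0 <- snps$pos[i] - 1L  # 0-based base position
    any(indels$contig == snps$contig[i] & fp$start <= p0 & p0 < fp$end)
  }, logical(1L))
  .restore_vt(snps[!drop, , drop = FALSE], snps)
}

#' Reclassify variants on a cohort subset
#'
#' Recomputes AF/AC/AN from the subset's genotypes, drops sites that are
#' non-variant in the subset, removes unused alternate alleles, re-applies
#' the hard filters and classifies with the integer thresholds scaled to the
#' subset size.
#'
#' @param records the full-cohort variant table (with genotypes).
#' @param sampleSubset character or integer vector naming the retained
#'   samples (must have `nMice` members).
#' @param nMice subset size, 2 to 4.
#' @param variantClass `"snp"` or `"indel"` (controls the hard-filter set).
#' @param restrictTo optional variant table; when supplied, only sites also
#'   present there (by contig and pos) are considered, mirroring restriction
#'   to the full-cohort uniform and non-uniform site sets.
#' @return list with `uniform` and `nonuniform` variant tables.
#' @export
downsampleClassify <- function(records, sampleSubset, nMice,
                               variantClass = c("snp", "indel"),
                               restrictTo = NULL) {
  variantClass <- match.arg(variantClass)
  samples <- attr(records, "samples")
  nMice <- as.integer(nMice)
  if (nMice < 2L || nMice >= length(samples))
    stop("nMice must satisfy 2 <= nMice < cohort size")
  idx <- if (is.character(sampleSubset)) match(sampleSubset, samples)
         else as.integer(sampleSubset)
  if (length(idx) != nMice || anyNA(idx))
    stop("sampleSubset must name ", nMice, " cohort members")
  sub <- records
  sub$gt <- lapply(sub$gt, `[`, idx)
  attr(sub, "samples") <- samples[idx]
  sub <- recomputeAlleleStats(sub)
  if (!is.null(restrictTo)) {
    keep <- paste(sub$contig, sub$pos) %in%
      paste(restrictTo$contig, restrictTo$pos)
    sub <- .restore_vt(sub[keep, , drop = FALSE], sub)
  }
  # --exclude-non-variants: drop sites with no alternate allele called
  variant <- vapply(sub$ac, function(x) any(x > 0L), logical(1L)) & sub$an > 0L
  sub <- .restore_vt(sub[variant, , drop = FALSE], sub)
  # --remove-unused-alternates: drop alts with AC == 0 and reindex genotypes
  for (i in seq_len(nrow(sub))) {
    used <- sub$ac[[i]] > 0L
    if (all(used)) next
    old_idx <- which(used)
    remap <- stats::setNames(seq_along(old_idx), old_idx)
    sub$alt[[i]] <- sub$alt[[i]][used]
    sub$ac[[i]] <- sub$ac[[i]][used]
    sub$af[[i]] <- sub$ac[[i]] / sub$an[i]
    sub$gt[[i]] <- vapply(sub$gt[[i]], function(g) {
      parts <- strsplit(g, "/", fixed = TRUE)[[1L]]
      paste(vapply(parts, function(a) {
        if (a %in% c(".", "0")) a else as.character(remap[[a]])
      }, character(1L)), collapse = "/")
    }, character(1L), USE.NAMES = FALSE)
  }
  filt <- hardFilter(sub, variantClass = variantClass)$pass
  th <- classificationThresholds(nMice)
  list(uniform = classifyUniform(filt, th),
       nonuniform = classifyNonuniform(filt, th))
}
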