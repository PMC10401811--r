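# Seeded synthetic-data generators: desk-scale genomes, cohort variant
# calls with known per-site population frequencies, TE call tables with
# planted pass/fail labels, and peak count matrices with planted
# irreproducible regions. Every generator is a pure function of its
# parameters and seed, and emits truth labels so downstream filters can be
# scored exactly without external data.

#' Simulate a genome of i.i.d. bases
#'
#' @param contigLengths named integer vector of contig lengths (>= 1).
#' @param gc target GC content in `[0, 1]`.
#' @param seed integer seed.
#' @return A [Genome-class].
#' @export
simulateGenome <- function(contigLengths, gc = 0.42, seed = 1L) {
  stopifnot(all(contigLengths >= 1L), gc >= 0, gc <= 1)
  set.seed(as.integer(seed))
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(contigLengths, function(len) {
    paste(sample(names(probs), len, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1L))
  Genome(seqs)
}

#' Simulate cohort variant calls with known population frequencies
#'
#' Places non-overlapping sites on the genome; at each site, `2 * nMice`
#' alleles are drawn independently at the site's population frequency
#' (matching the bias model's independent-allele assumption) and genotypes,
#' AF/AC/AN and passing-range site annotations are derived from the draws.
#' A configurable fraction of sites gets a failing QD injected.
#'
#' @param genome a [Genome-class].
#' @param nMice cohort size.
#' @param siteSpecs data.frame with columns `kind` ("snp" or "indel"),
#'   `popFreq` (alternate-allele population frequency; 1.0 plants a fixed
#'   difference), `length` (deleted bases for indels; 0 for SNPs) and `n`
#'   (number of sites of that spec).
#' @param seed integer seed.
#' @param failFraction fraction of sites given QD below the hard-filter
#'   threshold.
#' @return a variant table with extra truth columns `truth_kind` and
#'   `truth_popfreq`.
#' @export
simulateCohortVariants <- function(genome, nMice = 5L, siteSpecs,
                                   seed = 1L, failFraction = 0) {
  set.seed(as.integer(seed))
  specs <- siteSpecs[rep(seq_len(nrow(siteSpecs)), siteSpecs$n), , drop = FALSE]
  n_sites <- nrow(specs)
  slot_w <- max(specs$length) + 12L
  lens <- contigLengths(genome)
  n_slots <- pmax((lens - 2L) %/% slot_w, 0L)
  if (sum(n_slots) < n_sites)
    stop("cannot place ", n_sites, " non-overlapping sites on this genome")
  slot_ctg <- rep(names(lens), n_slots)
  slot_off <- unlist(lapply(n_slots, function(k) (seq_len(k) - 1L) * slot_w),
                     use.names = FALSE)
  pick <- sample(length(slot_ctg), n_sites)
  ctg <- slot_ctg[pick]
  pos1 <- slot_off[pick] + 2L   # 1-based, leaves room for an anchor base
  ord <- order(ctg, pos1)
  specs <- specs[ord, , drop = FALSE]
  ctg <- ctg[ord]; pos1 <- pos1[ord]
  bases <- c("A", "C", "G", "T")
  ref <- alt <- character(n_sites)
  gt <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    if (specs$kind[i] == "snp") {
      ref[i] <- toupper(substr(genome[[ctg[i]]], pos1[i], pos1[i]))
      alt[i] <- sample(setdiff(bases, ref[i]), 1L)
    } else {
      ref[i] <- toupper(substr(genome[[ctg[i]]], pos1[i],
                               pos1[i] + specs$length[i]))
      alt[i] <- substr(ref[i], 1L, 1L)
    }
    draws <- stats::rbinom(2L * nMice, 1L, specs$popFreq[i])
    gt[[i]] <- vapply(seq_len(nMice), function(m) {
      paste(sort(draws[c(2L * m - 1L, 2L * m)]), collapse = "/")
    }, character(1L))
  }
  ann <- data.frame(
    QD = stats::runif(n_sites, 5, 30),
    SOR = stats::runif(n_sites, 0.5, 2.5),
    FS = stats::runif(n_sites, 0, 30),
    MQ = stats::runif(n_sites, 50, 60),
    MQRankSum = stats::runif(n_sites, -3, 3),
    ReadPosRankSum = stats::runif(n_sites, -3, 3))
  if (failFraction > 0) {
    bad <- sample(n_sites, round(failFraction * n_sites))
    ann$QD[bad] <- stats::runif(length(bad), 0, 1.9)
  }
  tab <- variantTable(ctg, pos1, ref, as.list(alt),
                      qual = stats::runif(n_sites, 100, 1000), gt = gt,
                      annotations = ann,
                      samples = paste0("mouse", seq_len(nMice)))
  tab$truth_kind <- specs$kind
  tab$truth_popfreq <- specs$popFreq
  .restore_vt(tab, tab)
}

#' Simulate TE call tables with planted pass/fail labels
#'
#' Generates per-sample and pooled insertion calls plus pooled absence
#' calls, with a controllable mix of calls planted inside and outside the
#' filter thresholds, and a consensus-sequence store keyed by family.
#'
#' @param genome a [Genome-class].
#' @param nInsertions,nAbsences planted germline counts.
#' @param nFailInsertions,nFailAbsences planted sub-threshold counts.
#' @param nSamples number of per-sample callsets.
#' @param seed integer seed.
#' @param params filter thresholds the planting respects
#'   (see [teFilterParams()]).
#' @return list with `perSample`, `pooled`, `absences` (TE call tables with
#'   a logical `truth_pass` column), and `consensus` (a [Genome-class]).
#' @export
simulateTeCalls <- function(genome, nInsertions = 20L, nAbsences = 10L,
                            nFailInsertions = 0L, nFailAbsences = 0L,
                            nSamples = 5L, seed = 1L,
                            params = teFilterParams()) {
  set.seed(as.integer(seed))
  families <- c("L1Md", "B1_Mm", "IAPEz", "ETnERV")
  consensus <- Genome(stats::setNames(vapply(families, function(f) {
    paste(sample(c("A", "C", "G", "T"), sample(60:150, 1L), replace = TRUE),
          collapse = "")
  }, character(1L)), families))
  lens <- contigLengths(genome)
  rand_pos <- function(n, w = 0L) {
    ctg <- sample(names(lens), n, replace = TRUE, prob = lens / sum(lens))
    start <- vapply(ctg, function(cc)
      sample.int(max(lens[[cc]] - w - 1L, 1L), 1L), integer(1L))
    data.frame(contig = ctg, start = start, stringsAsFactors = FALSE)
  }
  n_ins <- nInsertions + nFailInsertions
  ins_pos <- rand_pos(n_ins)
  ins_fam <- sample(families, n_ins, replace = TRUE)
  ins_pass <- rep(c(TRUE, FALSE), c(nInsertions, nFailInsertions))
  per_sample <- list()
  pooled_af <- numeric(n_ins)
  for (i in seq_len(n_ins)) {
    carriers <- sample(nSamples, sample(1:3, 1L))
    af <- if (ins_pass[i]) stats::runif(length(carriers),
                                        params$candidate_af_min, 1)
          else stats::runif(length(carriers), 0.05,
                            params$candidate_af_min - 0.01)
    reads <- if (ins_pass[i]) sample(params$candidate_reads_min:20,
                                     length(carriers), replace = TRUE)
             else sample(0:(params$candidate_reads_min - 1L),
                         length(carriers), replace = TRUE)
    jitter <- sample(-10:10, length(carriers), replace = TRUE)
    per_sample[[i]] <- teCallTable(
      ins_pos$contig[i], ins_pos$start[i] + jitter,
      ins_pos$start[i] + jitter, ins_fam[i], af, reads,
      paste0("mouse", carriers))
    pooled_af[i] <- if (ins_pass[i])
      stats::runif(1L, params$pooled_af_min, 1)
    else stats::runif(1L, 0.01, params$pooled_af_min - 0.005)
  }
  per_sample_tab <- do.call(rbind, per_sample)
  per_sample_tab$truth_pass <- rep(ins_pass, vapply(per_sample, nrow,
                                                    integer(1L)))
  pooled <- teCallTable(ins_pos$contig, ins_pos$start, ins_pos$start,
                        ins_fam, pooled_af,
                        sample(2:40, n_ins, replace = TRUE), "pooled")
  pooled$truth_pass <- ins_pass
  n_abs <- nAbsences + nFailAbsences
  abs_w <- sample(80:200, max(n_abs, 1L), replace = TRUE)
  abs_pos <- rand_pos(n_abs, w = max(abs_w))
  abs_pass <- rep(c(TRUE, FALSE), c(nAbsences, nFailAbsences))
  abs_reads <- ifelse(abs_pass,
                      sample(params$absence_reads_min:60, n_abs,
                             replace = TRUE),
                      sample(0:(params$absence_reads_min - 1L), n_abs,
                             replace = TRUE))
  abs_af <- ifelse(abs_pass, params$absence_popfreq,
                   stats::runif(n_abs, 0.2, 0.95))
  absences <- teCallTable(abs_pos$contig, abs_pos$start,
                          abs_pos$start + abs_w[seq_len(n_abs)],
                          sample(families, n_abs, replace = TRUE),
                          abs_af, abs_reads, "pooled")
  absences$truth_pass <- abs_pass
  list(perSample = per_sample_tab, pooled = pooled, absences = absences,
       consensus = consensus)
}

#' Simulate a peak count matrix with planted irreproducible regions
#'
#' Reproducible intervals get correlated negative-binomial counts at a
#' mid-range RPKM across replicates; the rest are planted to span the
#' irreproducibility thresholds, with one replicate near background and
#' one strongly enriched.
#'
#' @param intervals interval table of merged peaks.
#' @param nReplicates number of replicates (>= 2).
#' @param reproducibleFraction fraction of intervals planted reproducible.
#' @param seed integer seed.
#' @param librarySize per-replicate mapped reads.
#' @param low,high RPKM thresholds the planting spans.
#' @return list with `cm` (a [countMatrix()]) and `truth` (logical vector,
#'   TRUE = planted reproducible).
#' @export
simulateCountMatrix <- function(intervals, nReplicates = 2L,
                                reproducibleFraction = 0.8, seed = 1L,
                                librarySize = 1e7, low = 0.5, high = 2) {
  stopifnot(nReplicates >= 2L, reproducibleFraction >= 0,
            reproducibleFraction <= 1)
  set.seed(as.integer(seed))
  n <- nrow(intervals)
  len_kb <- (intervals$end - intervals$start) / 1000
  per_rpkm <- len_kb * librarySize / 1e6   # counts per RPKM unit
  n_rep <- round(reproducibleFraction * n)
  truth <- rep(FALSE, n)
  if (n_rep > 0L) truth[sample(n, n_rep)] <- TRUE
  counts <- matrix(0L, n, nReplicates)
  mid <- stats::runif(n, 4, 10)   # reproducible target RPKM
  for (j in seq_len(nReplicates)) {
    counts[truth, j] <- stats::rnbinom(sum(truth),
                                       mu = mid[truth] * per_rpkm[truth],
                                       size = 50)
  }
  if (any(!truth)) {
    hi_rep <- sample(nReplicates, sum(!truth), replace = TRUE)
    hi_rpkm <- stats::runif(sum(!truth), 3 * high, 6 * high)
    lo_rpkm <- stats::runif(sum(!truth), 0, low / 5)
    idx <- which(!truth)
    for (k in seq_along(idx)) {
      i <- idx[k]
      counts[i, ] <- stats::rpois(nReplicates,
                                  lo_rpkm[k] * per_rpkm[i])
      counts[i, hi_rep[k]] <- stats::rpois(1L, hi_rpkm[k] * per_rpkm[i])
    }
  }
  list(cm = countMatrix(intervals, counts, rep(librarySize, nReplicates)),
       truth = truth)
}
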