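# Germline transposable-element filtering. Raw per-sample insertion calls
# are reduced to candidate germline insertions (a germline TE must be fully
# present on at least one allele, so its within-sample allele frequency is
# ~0.5 or more), pooled calls are kept when they are frequent enough in the
# population AND backed by a candidate, and reference-TE absence calls are
# kept when fully absent from the cohort with enough supporting reads.

#' TE filter parameters
#'
#' @param candidate_af_min minimum within-sample allele frequency for a
#'   candidate germline insertion (0.495: one of two alleles, minus a small
#'   sequencing-error slack).
#' @param candidate_reads_min minimum insertion-supporting reads per sample.
#' @param pooled_af_min minimum population allele frequency for pooled calls
#'   (0.0995, "just under 10%": one germline allele in ten, minus slack).
#' @param absence_reads_min minimum reads supporting a reference-TE absence.
#' @param absence_popfreq required estimated population frequency of the
#'   absence (1.0; equality tested with `popfreq_tol`).
#' @param match_tolerance_bp window for matching pooled calls to candidates
#'   (TE breakpoint estimates jitter between runs).
#' @param popfreq_tol numeric tolerance on the absence population frequency.
#' @return named list of parameters.
#' @export
teFilterParams <- function(candidate_af_min = 0.495, candidate_reads_min = 2L,
                           pooled_af_min = 0.0995, absence_reads_min = 10L,
                           absence_popfreq = 1.0, match_tolerance_bp = 50L,
                           popfreq_tol = 1e-9) {
  list(candidate_af_min = candidate_af_min,
       candidate_reads_min = as.integer(candidate_reads_min),
       pooled_af_min = pooled_af_min,
       absence_reads_min = as.integer(absence_reads_min),
       absence_popfreq = absence_popfreq,
       match_tolerance_bp = as.integer(match_tolerance_bp),
       popfreq_tol = popfreq_tol)
}

#' Construct a TE call table
#'
#' @param contig,start,end call coordinates (0-based half-open; for
#'   insertion points `end = start`).
#' @param family TE family name (keys into a consensus FASTA).
#' @param af allele frequency in `[0, 1]`.
#' @param reads supporting read count.
#' @param sample sample label, or `"pooled"` for population-pooled calls.
#' @return data.frame with those columns.
#' @export
teCallTable <- function(contig, start, end, family, af, reads, sample) {
  if (any(af < 0 | af > 1)) stop("allele frequency must lie in [0, 1]")
  if (any(reads < 0)) stop("supporting read counts must be >= 0")
  data.frame(contig = as.character(contig), start = as.integer(start),
             end = as.integer(end), family = as.character(family),
             af = as.numeric(af), reads = as.integer(reads),
             sample = as.character(sample), stringsAsFactors = FALSE)
}

#' Read / write TE call tables (BED-like TSV)
#'
#' Columns: contig, start, end, family, af, reads, sample.
#' @param path file path.
#' @return [readTeCalls()]: a TE call table.
#' @export
readTeCalls <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  teCallTable(tab$contig, tab$start, tab$end, tab$family, tab$af, tab$reads,
              tab$sample)
}

#' @rdname readTeCalls
#' @param calls a TE call table.
#' @export
writeTeCalls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Candidate germline TE insertions from per-sample calls
#'
#' Keeps calls with `af >= candidate_af_min` and
#' `reads >= candidate_reads_min`, deduplicated across samples by
#' (contig, position within `match_tolerance_bp`, family).
#'
#' @param perSampleCalls TE call table with `sample != "pooled"`.
#' @param params as from [teFilterParams()].
#' @return deduplicated TE call table of candidates.
#' @export
candidateGermlineInsertions <- function(perSampleCalls,
                                        params = teFilterParams()) {
  stopifnot(all(perSampleCalls$sample != "pooled"))
  keep <- perSampleCalls$af >= params$candidate_af_min &
    perSampleCalls$reads >= params$candidate_reads_min
  kept <- perSampleCalls[keep, , drop = FALSE]
  if (nrow(kept) < 2L) return(kept)
  kept <- kept[order(kept$contig, kept$family, kept$start), , drop = FALSE]
  dup <- logical(nrow(kept))
  for (i in 2:nrow(kept)) {
    j <- i - 1L
    while (j >= 1L && kept$contig[j] == kept$contig[i] &&
           kept$family[j] == kept$family[i]) {
      if (!dup[j] &&
          abs(kept$start[i] - kept$start[j]) <= params$match_tolerance_bp) {
        dup[i] <- TRUE
        break
      }
      j <- j - 1L
    }
  }
  kept[!dup, , drop = FALSE]
}

#' Germline TE insertions from pooled calls
#'
#' Keeps pooled calls with `af >= pooled_af_min` that match a candidate
#' (same family, position within `match_tolerance_bp`), ensuring each
#' retained insertion is present on at least one allele of at least one
#' sample.
#'
#' @param pooledCalls TE call table with `sample == "pooled"`.
#' @param candidates output of [candidateGermlineInsertions()].
#' @param params as from [teFilterParams()].
#' @return TE call table of germline insertions (subset of `pooledCalls`).
#' @export
germlineInsertions <- function(pooledCalls, candidates,
                               params = teFilterParams()) {
  stopifnot(all(pooledCalls$sample == "pooled"))
  keep <- vapply(seq_len(nrow(pooledCalls)), function(i) {
    if (pooledCalls$af[i] < params$pooled_af_min) return(FALSE)
    any(candidates$contig == pooledCalls$contig[i] &
        candidates$family == pooledCalls$family[i] &
        abs(candidates$start - pooledCalls$start[i]) <=
          params$match_tolerance_bp)
  }, logical(1L))
  pooledCalls[keep, , drop = FALSE]
}

#' Germline absences of reference TE copies
#'
#' Keeps absence calls (reference intervals of base-genome TE copies) with
#' `reads >= absence_reads_min` and an estimated population frequency equal
#' to `absence_popfreq` (within `popfreq_tol`).
#'
#' @param pooledAbsenceCalls TE call table of absence calls with reference
#'   intervals.
#' @param params as from [teFilterParams()].
#' @return filtered TE call table.
#' @export
germlineAbsences <- function(pooledAbsenceCalls, params = teFilterParams()) {
  keep <- pooledAbsenceCalls$reads >= params$absence_reads_min &
    abs(pooledAbsenceCalls$af - params$absence_popfreq) <= params$popfreq_tol
  pooledAbsenceCalls[keep, , drop = FALSE]
}
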