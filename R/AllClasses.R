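#' @import methods
NULL

IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

.nucleotide_regex <- function() {
  chars <- paste0(c(IUPAC_CHARS, tolower(IUPAC_CHARS)), collapse = "")
  paste0("[^", chars, "]")
}

#' Genome: an ordered set of named nucleotide sequences
#'
#' A `Genome` is a named character vector of contig sequences over the IUPAC
#' nucleotide alphabet. Case is preserved (soft-masked lowercase bases keep
#' their case) but all arithmetic treats a base as its uppercase nucleotide.
#'
#' @slot .Data named character vector, one element per contig.
#' @export
setClass("Genome", contains = "character")

setValidity("Genome", function(object) {
  nm <- names(object)
  if (is.null(nm) || any(is.na(nm)) || any(nm == ""))
    return("all contigs must be named")
  if (anyDuplicated(nm))
    return(sprintf("duplicate contig name: %s", nm[duplicated(nm)][1L]))
  if (any(nchar(object) == 0L))
    return(sprintf("empty sequence for contig %s", nm[nchar(object) == 0L][1L]))
  bad <- regexpr(.nucleotide_regex(), object)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    return(sprintf("non-nucleotide character in contig %s at offset %d",
                   nm[i], bad[i] - 1L))
  }
  TRUE
})

#' Construct a Genome
#'
#' @param sequences named character vector of contig sequences (A/C/G/T/N and
#'   IUPAC ambiguity codes, either case).
#' @return A [Genome-class] object.
#' @examples
#' Genome(c(chr1 = "ACGTACGT"))
#' @export
Genome <- function(sequences) {
  new("Genome", sequences)
}

#' @describeIn Genome contig lengths, named by contig.
#' @param genome a [Genome-class].
#' @export
contigLengths <- function(genome) {
  stats::setNames(nchar(genome), names(genome))
}

setMethod("show", "Genome", function(object) {
  cat(sprintf("Genome with %d contig(s), %d bases total\n",
              length(object), sum(nchar(object))))
  for (i in seq_len(min(length(object), 6L))) {
    s <- object[[i]]
    cat(sprintf("  %s (%d bp): %s%s\n", names(object)[i], nchar(s),
                substr(s, 1L, 40L), if (nchar(s) > 40L) "..." else ""))
  }
  if (length(object) > 6L) cat(sprintf("  ... and %d more\n", length(object) - 6L))
})

#' ChainAlignment: a UCSC chain between two coordinate systems
#'
#' Ordered ungapped alignment blocks relating a target (base genome) interval
#' to a query (edited genome) interval. Blocks are rows of an integer matrix
#' with columns `size`, `dt`, `dq`; the final row carries `dt = dq = 0`
#' (omitted on disk, per the UCSC dialect). All coordinates are 0-based
#' half-open. For `-` strand, coordinates on that side count from the
#' opposite end of the sequence, as in the UCSC specification.
#'
#' @slot score numeric alignment score (sum of block sizes for built chains).
#' @slot tName,tSize,tStart,tEnd,tStrand target side.
#' @slot qName,qSize,qStart,qEnd,qStrand query side.
#' @slot blocks integer matrix with columns size, dt, dq.
#' @slot id integer chain id.
#' @export
setClass("ChainAlignment",
  representation(score = "numeric",
                 tName = "character", tSize = "integer", tStrand = "character",
                 tStart = "integer", tEnd = "integer",
                 qName = "character", qSize = "integer", qStrand = "character",
                 qStart = "integer", qEnd = "integer",
                 blocks = "matrix", id = "integer"))

setValidity("ChainAlignment", function(object) {
  b <- object@blocks
  if (!is.numeric(b) || ncol(b) != 3L)
    return("blocks must be a numeric matrix with columns size, dt, dq")
  if (nrow(b) == 0L) return("chain must have at least one block")
  if (any(b[, 1L] <= 0L)) return("all block sizes must be > 0")
  if (any(b[, 2:3] < 0L)) return("dt and dq must be >= 0")
  if (b[nrow(b), 2L] != 0L || b[nrow(b), 3L] != 0L)
    return("final block must carry size only (dt = dq = 0)")
  tspan <- sum(b[, 1L]) + sum(b[, 2L])
  qspan <- sum(b[, 1L]) + sum(b[, 3L])
  if (tspan != object@tEnd - object@tStart)
    return(sprintf("chain %d: block sums (%d) != target span (%d)",
                   object@id, tspan, object@tEnd - object@tStart))
  if (qspan != object@qEnd - object@qStart)
    return(sprintf("chain %d: block sums (%d) != query span (%d)",
                   object@id, qspan, object@qEnd - object@qStart))
  if (object@tEnd > object@tSize || object@qEnd > object@qSize)
    return("chain spans exceed sequence sizes")
  TRUE
})

#' Construct a ChainAlignment
#'
#' @param tName,tSize,tStart,tEnd target (base) contig name, length and span.
#' @param qName,qSize,qStart,qEnd query (edited) contig name, length and span.
#' @param blocks matrix-like with columns size, dt, dq; the last row must have
#'   dt = dq = 0.
#' @param score numeric score; defaults to the sum of block sizes.
#' @param tStrand,qStrand strands ("+" or "-"); built chains are always "+".
#' @param id integer chain id.
#' @return A [ChainAlignment-class].
#' @export
ChainAlignment <- function(tName, tSize, tStart, tEnd,
                           qName, qSize, qStart, qEnd,
                           blocks, score = NULL, tStrand = "+", qStrand = "+",
                           id = 1L) {
  blocks <- matrix(as.integer(as.matrix(blocks)), ncol = 3L,
                   dimnames = list(NULL, c("size", "dt", "dq")))
  if (is.null(score)) score <- sum(blocks[, 1L])
  new("ChainAlignment", score = as.numeric(score),
      tName = tName, tSize = as.integer(tSize), tStrand = tStrand,
      tStart = as.integer(tStart), tEnd = as.integer(tEnd),
      qName = qName, qSize = as.integer(qSize), qStrand = qStrand,
      qStart = as.integer(qStart), qEnd = as.integer(qEnd),
      blocks = blocks, id = as.integer(id))
}

setMethod("show", "ChainAlignment", function(object) {
  cat(sprintf("ChainAlignment %d: %s:%d-%d (%s) -> %s:%d-%d (%s), %d block(s), score %g\n",
              object@id, object@tName, object@tStart, object@tEnd,
              object@tStrand, object@qName, object@qStart, object@qEnd,
              object@qStrand, nrow(object@blocks), object@score))
})

#' @describeIn ChainAlignment block matrix accessor.
#' @param chain a [ChainAlignment-class].
#' @export
chainBlocks <- function(chain) chain@blocks

#' EditPlan: a resolved, conflict-free set of genome edits
#'
#' Edits are rows of a data.frame with columns `contig`, `start`, `end`
#' (0-based half-open on the base genome; `start == end` for pure
#' insertions), `alt` (replacement sequence, possibly empty), `kind`
#' (one of snp_sub, indel, te_insert, te_remove, n_mask) and `priority`.
#' A resolved plan has no two overlapping edits on a contig.
#'
#' @slot edits data.frame of retained edits, sorted by (contig, start, end).
#' @slot conflicts data.frame of dropped edits with a `reason` column.
#' @export
setClass("EditPlan",
  representation(edits = "data.frame", conflicts = "data.frame"))

setValidity("EditPlan", function(object) {
  e <- object@edits
  need <- c("contig", "start", "end", "alt", "kind", "priority")
  if (!all(need %in% names(e)))
    return(paste("edits must have columns", paste(need, collapse = ", ")))
  if (nrow(e) > 0L) {
    if (any(e$start > e$end)) return("edit with start > end")
    if (any(!e$kind %in% names(EDIT_PRIORITY))) return("unknown edit kind")
    len_ok <- e$kind %in% c("snp_sub", "n_mask")
    if (any(len_ok & (e$end - e$start != 1L | nchar(e$alt) != 1L)))
      return("snp_sub and n_mask edits must be single-base")
    sp <- split(e, e$contig)
    for (cc in sp) {
      o <- order(cc$start, cc$end)
      cc <- cc[o, ]
      if (nrow(cc) > 1L) {
        prev_end <- cc$end[-nrow(cc)]
        nxt_start <- cc$start[-1L]
        if (any(nxt_start < prev_end))
          return(sprintf("overlapping edits remain on contig %s", cc$contig[1L]))
      }
    }
  }
  TRUE
})

#' Edit kind priorities used in conflict resolution
#'
#' TE edits outrank indels, which outrank substitutions, which outrank
#' N-masks; of two overlapping edits the lower-priority one is dropped.
#' @export
EDIT_PRIORITY <- c(te_remove = 4L, te_insert = 4L, indel = 3L,
                   snp_sub = 2L, n_mask = 1L)

#' @describeIn EditPlan retained edits.
#' @param plan an [EditPlan-class].
#' @export
planEdits <- function(plan) plan@edits

#' @describeIn EditPlan dropped edits with reasons.
#' @export
planConflicts <- function(plan) plan@conflicts

setMethod("show", "EditPlan", function(object) {
  cat(sprintf("EditPlan: %d edit(s), %d conflict(s) dropped\n",
              nrow(object@edits), nrow(object@conflicts)))
  if (nrow(object@edits) > 0L)
    print(table(object@edits$kind))
})

#' SaturationModel: asymptotic variant-discovery curve
#'
#' N(x) = a - (a - c) * exp(-b * (x - x0)): the number of variants
#' discovered from a cohort of x individuals, approaching asymptote `a`,
#' anchored at N(x0) = c, with rate `b` per individual.
#'
#' @slot a asymptote (variant count as cohort size grows).
#' @slot b rate per added individual; must be > 0.
#' @slot c value of the curve at `x = x0`.
#' @slot x0 anchor cohort size.
#' @export
setClass("SaturationModel",
  representation(a = "numeric", b = "numeric", c = "numeric", x0 = "numeric"))

setValidity("SaturationModel", function(object) {
  if (!is.finite(object@a) || !is.finite(object@b) || !is.finite(object@c))
    return("parameters must be finite")
  if (object@b <= 0) return("rate b must be > 0")
  TRUE
})

#' Construct a SaturationModel
#' @param a,b,c,x0 model parameters (see [SaturationModel-class]).
#' @return A [SaturationModel-class].
#' @export
SaturationModel <- function(a, b, c, x0 = 3) {
  new("SaturationModel", a = a, b = b, c = c, x0 = x0)
}

setMethod("show", "SaturationModel", function(object) {
  cat(sprintf("SaturationModel: N(x) = %.6g - (%.6g) * exp(-%.6g * (x - %g))\n",
              object@a, object@a - object@c, object@b, object@x0))
})

#' @describeIn SaturationModel named parameter vector (a, b, c, x0).
#' @param model a [SaturationModel-class].
#' @export
saturationParams <- function(model) {
  c(a = model@a, b = model@b, c = model@c, x0 = model@x0)
}
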