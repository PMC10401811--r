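# Coordinate liftover through chain alignments: positions, intervals, VCF
# records and GTF annotations, plus chain composition/inversion for the
# two-stage genome build and an exon-sequence validation report.

# vectorized core: map 0-based target positions through one chain.
# Returns q positions (forward strand) or NA; attr "reason" per element.
.lift_core <- function(chain, pos) {
  b <- chain@blocks
  size <- b[, 1L]; dt <- b[, 2L]; dq <- b[, 3L]
  t_block <- chain@tStart + c(0L, cumsum(size + dt))[seq_along(size)]
  q_block <- chain@qStart + c(0L, cumsum(size + dq))[seq_along(size)]
  idx <- findInterval(pos, t_block)
  out <- rep(NA_integer_, length(pos))
  reason <- rep("deleted", length(pos))
  inblock <- idx >= 1L & idx <= length(size)
  inblock[inblock] <- pos[inblock] < t_block[idx[inblock]] + size[idx[inblock]]
  q <- q_block[idx[inblock]] + (pos[inblock] - t_block[idx[inblock]])
  if (chain@qStrand == "-") q <- chain@qSize - 1L - q
  out[inblock] <- q
  reason[inblock] <- NA_character_
  attr(out, "reason") <- reason
  out
}

.chain_for <- function(chains, contig) {
  if (is(chains, "ChainAlignment")) chains <- list(chains)
  hit <- Filter(function(ch) ch@tName == contig, chains)
  if (length(hit) == 0L) return(NULL)
  hit[[1L]]
}

#' Lift a single position through chains
#'
#' @param chains a [ChainAlignment-class] or list of them (target side =
#'   source coordinate system).
#' @param contig contig name in the source system.
#' @param pos 0-based position.
#' @param direction `"base_to_edited"` lifts through the chains as given;
#'   `"edited_to_base"` lifts through their inversion.
#' @return list with `pos` (0-based mapped position or NA) and `reason`
#'   (NA when mapped; `"deleted"` for positions in target gaps or outside
#'   the aligned span; `"no_chain"` for an unknown contig).
#' @export
liftPosition <- function(chains, contig, pos,
                         direction = c("base_to_edited", "edited_to_base")) {
  direction <- match.arg(direction)
  if (direction == "edited_to_base") {
    if (is(chains, "ChainAlignment")) chains <- list(chains)
    chains <- lapply(chains, invertChain)
  }
  ch <- .chain_for(chains, contig)
  if (is.null(ch)) return(list(pos = NA_integer_, reason = "no_chain"))
  mapped <- .lift_core(ch, pos)
  list(pos = mapped[1L], reason = attr(mapped, "reason")[1L])
}

#' Lift many positions through chains at once
#'
#' Vectorized companion to [liftPosition()].
#'
#' @inheritParams liftPosition
#' @param pos integer vector of 0-based positions.
#' @return integer vector of mapped positions (NA where unmapped), with a
#'   `"reason"` attribute parallel to the input.
#' @export
liftPositions <- function(chains, contig, pos,
                          direction = c("base_to_edited",
                                        "edited_to_base")) {
  direction <- match.arg(direction)
  if (direction == "edited_to_base") {
    if (is(chains, "ChainAlignment")) chains <- list(chains)
    chains <- lapply(chains, invertChain)
  }
  ch <- .chain_for(chains, contig)
  if (is.null(ch)) {
    out <- rep(NA_integer_, length(pos))
    attr(out, "reason") <- rep("no_chain", length(pos))
    return(out)
  }
  .lift_core(ch, pos)
}

#' Lift an interval through chains
#'
#' In `strict` mode both endpoints must map and at least `minMatch` of the
#' interval's bases must be mappable (0.95 by default, the classic liftOver
#' default); in `partial` mode the interval is trimmed to its mappable
#' core.
#'
#' @param chains chains as in [liftPosition()].
#' @param interval one-row interval table (0-based half-open).
#' @param minMatch minimum mappable-base fraction for strict mode.
#' @param mode `"strict"` or `"partial"`.
#' @return list with `interval` (one-row interval table or NULL) and
#'   `reason` (NA when mapped).
#' @export
liftInterval <- function(chains, interval, minMatch = 0.95,
                         mode = c("strict", "partial")) {
  mode <- match.arg(mode)
  ch <- .chain_for(chains, interval$contig[1L])
  if (is.null(ch)) return(list(interval = NULL, reason = "no_chain"))
  s <- interval$start[1L]; e <- interval$end[1L]
  mapped <- .lift_core(ch, s:(e - 1L))
  n_ok <- sum(!is.na(mapped))
  if (n_ok == 0L) return(list(interval = NULL, reason = "deleted"))
  if (mode == "strict") {
    if (is.na(mapped[1L]) || is.na(mapped[length(mapped)]))
      return(list(interval = NULL, reason = "end_unmapped"))
    if (n_ok / (e - s) < minMatch)
      return(list(interval = NULL, reason = "below_min_match"))
  }
  qs <- range(mapped, na.rm = TRUE)
  out <- interval[1L, , drop = FALSE]
  out$contig <- ch@qName
  out$start <- qs[1L]
  out$end <- qs[2L] + 1L
  if (ch@qStrand == "-" && out$strand %in% c("+", "-"))
    out$strand <- if (out$strand == "+") "-" else "+"
  list(interval = out, reason = NA_character_)
}

#' Lift VCF records through chains
#'
#' Records whose reference span falls in a deleted region (or is broken by
#' a length-changing edit) are rejected with reason `deleted`; records
#' whose REF no longer matches the target genome are rejected with reason
#' `ref_mismatch`. Mapped and rejected tables partition the input.
#'
#' @param chains chains as in [liftPosition()].
#' @param records a variant table valid against the source genome.
#' @param targetGenome a [Genome-class] in the chains' query coordinates.
#' @return list with `mapped` and `rejected` variant tables; `rejected`
#'   carries a `reason` column.
#' @export
liftVcf <- function(chains, records, targetGenome) {
  n <- nrow(records)
  new_pos <- rep(NA_integer_, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    p0 <- records$pos[i] - 1L
    w <- nchar(records$ref[i])
    ch <- .chain_for(chains, records$contig[i])
    if (is.null(ch)) { reason[i] <- "no_chain"; next }
    mapped <- .lift_core(ch, p0:(p0 + w - 1L))
    if (anyNA(mapped) || (w > 1L && any(diff(mapped) != 1L))) {
      reason[i] <- "deleted"
      next
    }
    q0 <- mapped[1L]
    got <- toupper(substr(targetGenome[[ch@qName]], q0 + 1L, q0 + w))
    if (got != toupper(records$ref[i])) {
      reason[i] <- "ref_mismatch"
      next
    }
    new_pos[i] <- q0 + 1L
  }
  ok <- is.na(reason)
  mapped_tab <- records[ok, , drop = FALSE]
  mapped_tab$pos <- new_pos[ok]
  rejected <- records[!ok, , drop = FALSE]
  rejected$reason <- reason[!ok]
  list(mapped = .restore_vt(mapped_tab, records),
       rejected = .restore_vt(rejected, records))
}

#' Lift a GTF annotation through chains
#'
#' Exons are lifted in strict mode; a transcript is retained only when all
#' its exons convert (exclude-partial semantics), and a gene only when it
#' retains at least one transcript. Gene and transcript spans are
#' recomputed from their converted exons.
#'
#' @param chains chains as in [liftPosition()].
#' @param gtfRecords a data.frame as from [readGtf()].
#' @param minMatch strict-mode mappable fraction per exon.
#' @return list with `converted` (data.frame in target coordinates),
#'   `failedExons` (exon ids that did not convert) and `summary`
#'   (exon/transcript conversion fractions).
#' @export
liftGtf <- function(chains, gtfRecords, minMatch = 0.95) {
  ex <- gtfRecords[gtfRecords$feature == "exon", , drop = FALSE]
  lifted <- vector("list", nrow(ex))
  ok <- logical(nrow(ex))
  for (i in seq_len(nrow(ex))) {
    r <- liftInterval(chains, intervalTable(ex$contig[i], ex$start[i],
                                            ex$end[i], strand = ex$strand[i]),
                      minMatch = minMatch, mode = "strict")
    ok[i] <- !is.null(r$interval)
    if (ok[i]) lifted[[i]] <- r$interval
  }
  failed_exons <- ex$exon_id[!ok]
  tx_all <- unique(ex$transcript_id)
  tx_ok <- vapply(tx_all, function(tx) all(ok[ex$transcript_id == tx]),
                  logical(1L))
  keep_tx <- tx_all[tx_ok]
  conv_ex <- ex[ok & ex$transcript_id %in% keep_tx, , drop = FALSE]
  li <- do.call(rbind, lifted[ok & ex$transcript_id %in% keep_tx])
  if (!is.null(li)) {
    conv_ex$contig <- li$contig
    conv_ex$start <- li$start
    conv_ex$end <- li$end
  }
  parents <- lapply(keep_tx, function(tx) {
    rows <- conv_ex[conv_ex$transcript_id == tx, , drop = FALSE]
    src <- gtfRecords[gtfRecords$feature == "transcript" &
                        gtfRecords$transcript_id == tx, , drop = FALSE]
    if (nrow(src) == 0L) return(NULL)
    src$start <- min(rows$start)
    src$end <- max(rows$end)
    src$contig <- rows$contig[1L]
    src
  })
  genes <- unique(conv_ex$gene_id)
  gene_rows <- lapply(genes, function(g) {
    rows <- conv_ex[conv_ex$gene_id == g, , drop = FALSE]
    src <- gtfRecords[gtfRecords$feature == "gene" &
                        gtfRecords$gene_id == g, , drop = FALSE]
    if (nrow(src) == 0L) return(NULL)
    src$start <- min(rows$start)
    src$end <- max(rows$end)
    src$contig <- rows$contig[1L]
    src
  })
  converted <- rbind(do.call(rbind, gene_rows), do.call(rbind, parents),
                     conv_ex)
  if (!is.null(converted))
    converted <- converted[order(converted$contig, converted$start), ,
                           drop = FALSE]
  list(converted = converted,
       failedExons = failed_exons,
       summary = c(exon_fraction = if (nrow(ex)) mean(ok) else NA_real_,
                   transcript_fraction = if (length(tx_all)) mean(tx_ok)
                                         else NA_real_))
}

#' Validate exon sequences across a genome edit
#'
#' For every exon that converts through the chains, extracts the base and
#' edited sequences and checks that they agree outside edited positions,
#' and that at edited positions the edited base is the documented
#' substitution (or N for masks). Length-changing edits break mappability,
#' so mapped exon bases align one-to-one.
#'
#' @param baseGenome,editedGenome [Genome-class] objects.
#' @param chains base-to-edited chains.
#' @param gtfRecords annotation in base coordinates.
#' @param edits edit table in base coordinates (used to explain mismatches).
#' @return list with `checked` (number of exons compared), `mismatches`
#'   (data.frame of unexplained per-base mismatches; expected empty) and
#'   `explained` (count of mismatching bases accounted for by edits).
#' @export
validateExonSequences <- function(baseGenome, editedGenome, chains,
                                  gtfRecords, edits) {
  ex <- gtfRecords[gtfRecords$feature == "exon", , drop = FALSE]
  sub_edits <- edits[(edits$end - edits$start) == nchar(edits$alt) &
                       nchar(edits$alt) > 0L, , drop = FALSE]
  mism <- list()
  explained <- 0L
  checked <- 0L
  for (i in seq_len(nrow(ex))) {
    ch <- .chain_for(chains, ex$contig[i])
    if (is.null(ch)) next
    pos <- ex$start[i]:(ex$end[i] - 1L)
    mapped <- .lift_core(ch, pos)
    keep <- !is.na(mapped)
    if (!any(keep)) next
    checked <- checked + 1L
    base_chars <- strsplit(substr(baseGenome[[ex$contig[i]]],
                                  ex$start[i] + 1L, ex$end[i]), "")[[1L]]
    for (k in which(keep)) {
      b <- toupper(base_chars[k])
      q <- mapped[k]
      e <- toupper(substr(editedGenome[[ch@qName]], q + 1L, q + 1L))
      if (b == e) next
      p0 <- pos[k]
      cover <- sub_edits[sub_edits$contig == ex$contig[i] &
                           sub_edits$start <= p0 & p0 < sub_edits$end, ,
                         drop = FALSE]
      expl <- FALSE
      for (j in seq_len(nrow(cover))) {
        want <- toupper(substr(cover$alt[j], p0 - cover$start[j] + 1L,
                               p0 - cover$start[j] + 1L))
        if (want == e) { expl <- TRUE; break }
      }
      if (expl) explained <- explained + 1L
      else mism[[length(mism) + 1L]] <-
          data.frame(contig = ex$contig[i], pos = p0, base = b, edited = e,
                     exon_id = ex$exon_id[i], stringsAsFactors = FALSE)
    }
  }
  list(checked = checked,
       mismatches = if (length(mism)) do.call(rbind, mism)
                    else data.frame(contig = character(), pos = integer(),
                                    base = character(), edited = character(),
                                    exon_id = character()),
       explained = explained)
}

#' Invert a chain
#'
#' Swaps target and query sides (and dt with dq), so lifting through the
#' inverse maps edited coordinates back to base coordinates.
#'
#' @param chain a [ChainAlignment-class].
#' @return the inverted [ChainAlignment-class].
#' @export
invertChain <- function(chain) {
  b <- chain@blocks
  ChainAlignment(tName = chain@qName, tSize = chain@qSize,
                 tStart = chain@qStart, tEnd = chain@qEnd,
                 qName = chain@tName, qSize = chain@tSize,
                 qStart = chain@tStart, qEnd = chain@tEnd,
                 blocks = cbind(size = b[, 1L], dt = b[, 3L], dq = b[, 2L]),
                 score = chain@score, tStrand = chain@qStrand,
                 qStrand = chain@tStrand, id = chain@id)
}

#' Compose two chains
#'
#' `composeChains(ab, bc)` returns a chain mapping any position identically
#' to lifting through `ab` and then `bc`. The query side of `ab` must be
#' the target side of `bc` (same contig name and size). Only `+` strand
#' chains (as produced by the builder) are supported.
#'
#' @param chainAB,chainBC [ChainAlignment-class] objects.
#' @return the composed [ChainAlignment-class].
#' @export
composeChains <- function(chainAB, chainBC) {
  if (chainAB@qName != chainBC@tName || chainAB@qSize != chainBC@tSize)
    stop(sprintf("mismatched intermediate contig: %s (%d) vs %s (%d)",
                 chainAB@qName, chainAB@qSize, chainBC@tName, chainBC@tSize))
  if (chainAB@qStrand != "+" || chainBC@tStrand != "+" ||
      chainAB@tStrand != "+" || chainBC@qStrand != "+")
    stop("composeChains supports + strand chains only")
  blk <- function(ch) {
    b <- ch@blocks
    size <- b[, 1L]
    t0 <- ch@tStart + c(0L, cumsum(size + b[, 2L]))[seq_along(size)]
    q0 <- ch@qStart + c(0L, cumsum(size + b[, 3L]))[seq_along(size)]
    data.frame(t0 = t0, q0 = q0, size = size)
  }
  A <- blk(chainAB)  # maps A-space (t) -> B-space (q)
  B <- blk(chainBC)  # maps B-space (t) -> C-space (q)
  rows <- list()
  i <- 1L; j <- 1L
  while (i <= nrow(A) && j <= nrow(B)) {
    a_lo <- A$q0[i]; a_hi <- A$q0[i] + A$size[i]
    b_lo <- B$t0[j]; b_hi <- B$t0[j] + B$size[j]
    lo <- max(a_lo, b_lo); hi <- min(a_hi, b_hi)
    if (hi > lo) {
      rows[[length(rows) + 1L]] <- c(
        t = A$t0[i] + (lo - a_lo),
        q = B$q0[j] + (lo - b_lo),
        size = hi - lo)
    }
    if (a_hi <= b_hi) i <- i + 1L else j <- j + 1L
  }
  if (length(rows) == 0L)
    stop("composed chain is empty: no aligned bases survive both stages")
  m <- do.call(rbind, rows)
  # merge blocks contiguous in both coordinate systems
  keep <- list(m[1L, ])
  for (k in seq_len(nrow(m))[-1L]) {
    last <- keep[[length(keep)]]
    if (m[k, "t"] == last["t"] + last["size"] &&
        m[k, "q"] == last["q"] + last["size"]) {
      last["size"] <- last["size"] + m[k, "size"]
      keep[[length(keep)]] <- last
    } else keep[[length(keep) + 1L]] <- m[k, ]
  }
  m <- do.call(rbind, keep)
  n <- nrow(m)
  dt <- c(m[-1L, "t"] - (m[-n, "t"] + m[-n, "size"]), 0L)
  dq <- c(m[-1L, "q"] - (m[-n, "q"] + m[-n, "size"]), 0L)
  ChainAlignment(tName = chainAB@tName, tSize = chainAB@tSize,
                 tStart = m[1L, "t"], tEnd = m[n, "t"] + m[n, "size"],
                 qName = chainBC@qName, qSize = chainBC@qSize,
                 qStart = m[1L, "q"], qEnd = m[n, "q"] + m[n, "size"],
                 blocks = cbind(size = m[, "size"], dt = dt, dq = dq),
                 id = chainAB@id)
}
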