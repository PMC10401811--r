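# Applies a resolved edit plan (TE insertions/removals, fixed-difference
# SNP/indel substitutions, N-masks of segregating SNPs) to a base genome,
# producing the edited genome together with the exact chain alignment
# between the two coordinate systems. The two-stage build mirrors the
# hybrid-genome construction order: structural TE edits first, then
# nucleotide-level edits on the hybrid, with segregating-SNP positions
# lifted through the stage-1 chain.

#' Build an edit table
#'
#' @param contig contig names.
#' @param start,end 0-based half-open interval on the base genome
#'   (`start == end` for pure insertions, which place `alt` before base
#'   position `start`).
#' @param alt replacement sequence ("" for deletions, "N" for masks).
#' @param kind one of snp_sub, indel, te_insert, te_remove, n_mask.
#' @param ref optional expected reference sequence, verified at apply time.
#' @return data.frame of edits with a `priority` column derived from kind.
#' @export
editTable <- function(contig, start, end, alt, kind, ref = NA_character_) {
  kind <- as.character(kind)
  if (!all(kind %in% names(EDIT_PRIORITY)))
    stop("unknown edit kind: ", paste(setdiff(kind, names(EDIT_PRIORITY)),
                                      collapse = ", "))
  n <- length(start)
  kind <- rep_len(kind, n)
  data.frame(contig = as.character(contig), start = as.integer(start),
             end = as.integer(end), alt = rep_len(as.character(alt), n),
             kind = kind, priority = unname(EDIT_PRIORITY[kind]),
             ref = rep_len(as.character(ref), n), stringsAsFactors = FALSE)
}

.edits_overlap <- function(s1, e1, s2, e2) {
  if (s1 == e1 && s2 == e2) return(s1 == s2)
  if (s1 == e1) return(s2 < s1 && s1 < e2)   # insertion strictly inside
  if (s2 == e2) return(s1 < s2 && s2 < e1)
  s1 < e2 && s2 < e1
}

#' Resolve conflicts among raw edits
#'
#' Overlapping edits are resolved by kind priority
#' (te_remove = te_insert > indel > snp_sub > n_mask); among equal
#' priorities the earlier (contig, start, end) wins. Losers are dropped and
#' logged. The result is deterministic for any input ordering.
#'
#' @param rawEdits an edit table (see [editTable()]).
#' @return An [EditPlan-class].
#' @export
resolveConflicts <- function(rawEdits) {
  if (nrow(rawEdits) == 0L)
    return(new("EditPlan", edits = rawEdits,
               conflicts = cbind(rawEdits, reason = character(0))))
  rawEdits <- unique(rawEdits)
  key <- paste(rawEdits$contig, rawEdits$start, rawEdits$end,
               rawEdits$priority)
  contradictory <- names(which(tapply(rawEdits$alt, key,
                                      function(a) length(unique(a)) > 1L)))
  if (length(contradictory))
    stop("contradictory call set: same-priority edits with identical ",
         "intervals but different replacement at ", contradictory[1L])
  o <- order(-rawEdits$priority, rawEdits$contig, rawEdits$start,
             rawEdits$end, rawEdits$alt)
  rawEdits <- rawEdits[o, , drop = FALSE]
  kept <- logical(nrow(rawEdits))
  reason <- character(nrow(rawEdits))
  by_contig <- split(seq_len(nrow(rawEdits)), rawEdits$contig)
  for (idx in by_contig) {
    kept_idx <- integer()
    for (i in idx) {
      clash <- NA_integer_
      for (j in kept_idx) {
        if (.edits_overlap(rawEdits$start[i], rawEdits$end[i],
                           rawEdits$start[j], rawEdits$end[j])) {
          clash <- j
          break
        }
      }
      if (is.na(clash)) {
        kept[i] <- TRUE
        kept_idx <- c(kept_idx, i)
      } else {
        reason[i] <- sprintf("overlaps retained %s edit at %s:%d-%d",
                             rawEdits$kind[clash], rawEdits$contig[clash],
                             rawEdits$start[clash], rawEdits$end[clash])
      }
    }
  }
  edits <- rawEdits[kept, , drop = FALSE]
  edits <- edits[order(edits$contig, edits$start, edits$end), , drop = FALSE]
  rownames(edits) <- NULL
  conflicts <- cbind(rawEdits[!kept, , drop = FALSE],
                     reason = reason[!kept])
  rownames(conflicts) <- NULL
  new("EditPlan", edits = edits, conflicts = conflicts)
}

#' Apply a resolved edit plan to a genome
#'
#' The edited contig is the in-order concatenation of unedited segments and
#' replacement sequences. One chain per contig relates the two coordinate
#' systems: length-preserving edits (substitutions, masks) stay inside
#' ungapped blocks — chain blocks are alignments, not identity runs — while
#' length-changing edits break blocks with `dt = |ref interval|`,
#' `dq = |alt|`.
#'
#' @param genome a [Genome-class].
#' @param plan an [EditPlan-class].
#' @return list with `genome` (edited [Genome-class]) and `chains` (named
#'   list of [ChainAlignment-class], one per contig, base genome as target).
#' @export
applyEdits <- function(genome, plan) {
  stopifnot(is(plan, "EditPlan"))
  edits <- planEdits(plan)
  unknown <- setdiff(unique(edits$contig), names(genome))
  if (length(unknown)) stop("edit on unknown contig: ", unknown[1L])
  out_seq <- character(length(genome))
  names(out_seq) <- names(genome)
  chains <- vector("list", length(genome))
  names(chains) <- names(genome)
  chain_id <- 0L
  for (ctg in names(genome)) {
    base <- genome[[ctg]]
    len <- nchar(base)
    e <- edits[edits$contig == ctg, , drop = FALSE]
    e <- e[order(e$start, e$end), , drop = FALSE]
    if (nrow(e) > 0L && any(e$end > len))
      stop("edit beyond contig end on ", ctg)
    # verify expected reference sequence where provided
    if (nrow(e) > 0L) {
      has_ref <- !is.na(e$ref) & nchar(e$ref) > 0L
      for (i in which(has_ref)) {
        got <- toupper(substr(base, e$start[i] + 1L, e$end[i]))
        if (got != toupper(e$ref[i]))
          stop(sprintf("reference mismatch at %s:%d (expected %s, found %s)",
                       ctg, e$start[i], e$ref[i], got))
      }
    }
    # edited sequence
    pieces <- character(2L * nrow(e) + 1L)
    prev <- 0L
    k <- 1L
    for (i in seq_len(nrow(e))) {
      pieces[k] <- substr(base, prev + 1L, e$start[i])
      pieces[k + 1L] <- e$alt[i]
      prev <- e$end[i]
      k <- k + 2L
    }
    pieces[k] <- substr(base, prev + 1L, len)
    edited <- paste(pieces, collapse = "")
    out_seq[[ctg]] <- edited
    # chain: break only at length-changing edits
    lc <- e[(e$end - e$start) != nchar(e$alt), , drop = FALSE]
    m <- nrow(lc)
    sizes <- integer(m + 1L)
    dts <- lc$end - lc$start
    dqs <- nchar(lc$alt)
    prev <- 0L
    for (i in seq_len(m)) {
      sizes[i] <- lc$start[i] - prev
      prev <- lc$end[i]
    }
    sizes[m + 1L] <- len - prev
    # normalize away zero-size blocks
    t_start <- 0L; q_start <- 0L
    while (m > 0L && sizes[1L] == 0L) {
      t_start <- t_start + dts[1L]; q_start <- q_start + dqs[1L]
      sizes <- sizes[-1L]; dts <- dts[-1L]; dqs <- dqs[-1L]
      m <- m - 1L
    }
    t_end <- len; q_end <- nchar(edited)
    while (m > 0L && sizes[m + 1L] == 0L) {
      t_end <- t_end - dts[m]; q_end <- q_end - dqs[m]
      sizes <- sizes[-(m + 1L)]; dts <- dts[-m]; dqs <- dqs[-m]
      m <- m - 1L
    }
    i <- 2L
    while (i <= m) {
      if (sizes[i] == 0L) {
        dts[i - 1L] <- dts[i - 1L] + dts[i]
        dqs[i - 1L] <- dqs[i - 1L] + dqs[i]
        sizes <- sizes[-i]; dts <- dts[-i]; dqs <- dqs[-i]
        m <- m - 1L
      } else i <- i + 1L
    }
    if (length(sizes) == 0L || all(sizes == 0L))
      stop("contig ", ctg, " entirely replaced; no alignable block remains")
    chain_id <- chain_id + 1L
    chains[[ctg]] <- ChainAlignment(
      tName = ctg, tSize = len, tStart = t_start, tEnd = t_end,
      qName = ctg, qSize = nchar(edited), qStart = q_start, qEnd = q_end,
      blocks = cbind(size = sizes, dt = c(dts, 0L), dq = c(dqs, 0L)),
      id = chain_id)
  }
  list(genome = Genome(out_seq), chains = chains)
}

## ---- converting calls to edits -------------------------------------------

#' Convert uniform variants to substitution/indel edits
#'
#' SNPs become single-base substitutions; indels are normalized to minimal
#' representation (the shared leading anchor bases of REF and ALT are
#' stripped) before becoming edits.
#'
#' @param records a variant table of uniform (biallelic) variants.
#' @return an edit table.
#' @export
editsFromUniform <- function(records) {
  if (nrow(records) == 0L)
    return(editTable(character(), integer(), integer(), character(),
                     character()))
  alt <- vapply(records$alt, `[[`, character(1L), 1L)
  ref <- records$ref
  is_snp <- nchar(ref) == 1L & nchar(alt) == 1L
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    p0 <- records$pos[i] - 1L
    if (is_snp[i]) {
      out[[i]] <- editTable(records$contig[i], p0, p0 + 1L, alt[i],
                            "snp_sub", ref = ref[i])
    } else {
      k <- .common_prefix_len(ref[i], alt[i])
      out[[i]] <- editTable(records$contig[i], p0 + k,
                            p0 + nchar(ref[i]),
                            substr(alt[i], k + 1L, nchar(alt[i])), "indel",
                            ref = substr(ref[i], k + 1L, nchar(ref[i])))
    }
  }
  do.call(rbind, out)
}

.common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  k <- 0L
  while (k < n && substr(a, k + 1L, k + 1L) == substr(b, k + 1L, k + 1L))
    k <- k + 1L
  k
}

#' Convert segregating SNPs to N-mask edits
#'
#' @param records a variant table of non-uniform SNPs (single-base REF).
#' @return an edit table of `n_mask` edits.
#' @export
maskEditsFromSnps <- function(records) {
  snp <- nchar(records$ref) == 1L
  records <- records[snp, , drop = FALSE]
  editTable(records$contig, records$pos - 1L, records$pos, "N", "n_mask",
            ref = records$ref)
}

#' Convert germline TE calls to structural edits
#'
#' Insertions place the family's consensus sequence at the call position;
#' absences delete the reference TE interval.
#'
#' @param insertions,absences TE call tables (see [teCallTable()]).
#' @param consensus a [Genome-class] of TE consensus sequences keyed by
#'   family name.
#' @return an edit table of `te_insert` and `te_remove` edits.
#' @export
editsFromTeCalls <- function(insertions, absences, consensus) {
  missing_fam <- setdiff(unique(insertions$family), names(consensus))
  if (length(missing_fam))
    stop("no consensus sequence for TE family: ", missing_fam[1L])
  ins <- editTable(insertions$contig, insertions$start, insertions$start,
                   unname(unclass(consensus)[insertions$family]), "te_insert")
  rem <- editTable(absences$contig, absences$start, absences$end, "",
                   "te_remove")
  rbind(ins, rem)
}

## ---- two-stage reference build -------------------------------------------

#' Build a strain-specific reference genome
#'
#' Stage 1 applies TE insertions/removals to the base genome, producing a
#' hybrid genome and its chain. Stage 2 lifts the nucleotide-level edits
#' (uniform SNP/indel substitutions plus N-masks at segregating SNP
#' positions) through the stage-1 chain, drops any that fall in removed
#' regions (logged, not fatal), and applies them to the hybrid. The
#' returned chain is the composition of the two stages, mapping base
#' coordinates directly to the final genome.
#'
#' @param baseGenome a [Genome-class].
#' @param teInsertions,teAbsences germline TE call tables (may be empty).
#' @param uniformVariants variant table of fixed-difference SNPs/indels.
#' @param nonuniformSnps variant table of segregating SNPs to N-mask.
#' @param consensus TE consensus [Genome-class] keyed by family.
#' @return list with `genome` (final [Genome-class]), `chains` (named list
#'   of composed base-to-final [ChainAlignment-class]), `hybrid` (stage-1
#'   genome), and `report` (edit counts per kind, dropped edits,
#'   N bases introduced).
#' @export
buildReference <- function(baseGenome, teInsertions = NULL, teAbsences = NULL,
                           uniformVariants = NULL, nonuniformSnps = NULL,
                           consensus = Genome(c(none = "N"))) {
  empty_te <- teCallTable(character(), integer(), integer(), character(),
                          numeric(), integer(), character())
  if (is.null(teInsertions)) teInsertions <- empty_te
  if (is.null(teAbsences)) teAbsences <- empty_te
  te_edits <- editsFromTeCalls(teInsertions, teAbsences, consensus)
  plan1 <- resolveConflicts(te_edits)
  stage1 <- applyEdits(baseGenome, plan1)
  nuc_edits <- rbind(
    if (!is.null(uniformVariants) && nrow(uniformVariants))
      editsFromUniform(uniformVariants),
    if (!is.null(nonuniformSnps) && nrow(nonuniformSnps))
      maskEditsFromSnps(nonuniformSnps))
  if (is.null(nuc_edits))
    nuc_edits <- editTable(character(), integer(), integer(), character(),
                           character())
  lifted <- .lift_edits(nuc_edits, stage1$chains)
  plan2 <- resolveConflicts(lifted$edits)
  stage2 <- applyEdits(stage1$genome, plan2)
  composed <- lapply(names(stage1$chains), function(ctg) {
    composeChains(stage1$chains[[ctg]], stage2$chains[[ctg]])
  })
  names(composed) <- names(stage1$chains)
  applied <- rbind(planEdits(plan1), planEdits(plan2))
  dropped <- rbind(
    cbind(planConflicts(plan1)[, names(te_edits), drop = FALSE],
          reason = planConflicts(plan1)$reason),
    if (nrow(lifted$dropped))
      cbind(lifted$dropped, reason = "unmappable through stage-1 chain"),
    cbind(planConflicts(plan2)[, names(te_edits), drop = FALSE],
          reason = planConflicts(plan2)$reason))
  report <- list(
    applied_by_kind = table(factor(applied$kind,
                                   levels = names(EDIT_PRIORITY))),
    dropped = dropped,
    n_masked = sum(planEdits(plan2)$kind == "n_mask"))
  list(genome = stage2$genome, chains = composed, hybrid = stage1$genome,
       report = report)
}

# lift base-coordinate edits into hybrid coordinates through stage-1 chains;
# edits touching removed/inserted regions are dropped
.lift_edits <- function(edits, chains) {
  if (nrow(edits) == 0L) return(list(edits = edits, dropped = edits[0L, ]))
  ok <- logical(nrow(edits))
  new_start <- integer(nrow(edits))
  for (i in seq_len(nrow(edits))) {
    s <- liftPosition(chains, edits$contig[i], edits$start[i])
    if (is.na(s$pos)) next
    width <- edits$end[i] - edits$start[i]
    if (width > 0L) {
      e_last <- liftPosition(chains, edits$contig[i], edits$end[i] - 1L)
      if (is.na(e_last$pos) || e_last$pos - s$pos != width - 1L) next
    }
    ok[i] <- TRUE
    new_start[i] <- s$pos
  }
  lifted <- edits[ok, , drop = FALSE]
  width <- lifted$end - lifted$start
  lifted$start <- new_start[ok]
  lifted$end <- lifted$start + width
  list(edits = lifted, dropped = edits[!ok, , drop = FALSE])
}
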