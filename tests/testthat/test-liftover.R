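make_del_chain <- function() {
  # "ACGTACGT" with [2,4) deleted -> "ACACGT"
  g <- Genome(c(c1 = "ACGTACGT"))
  applyEdits(g, resolveConflicts(editTable("c1", 2L, 4L, "", "indel")))$chains
}

test_that("positions map affinely through blocks and die in deleted gaps", {
  chains <- make_del_chain()
  expect_equal(liftPosition(chains, "c1", 5L)$pos, 3L)
  r <- liftPosition(chains, "c1", 2L)
  expect_true(is.na(r$pos))
  expect_equal(r$reason, "deleted")
  expect_equal(liftPosition(chains, "zzz", 5L)$reason, "no_chain")
  # edited -> base -> edited identity for every mappable position
  for (p in 0:5) {
    b <- liftPosition(chains, "c1", p, direction = "edited_to_base")
    expect_false(is.na(b$pos))
    expect_equal(liftPosition(chains, "c1", b$pos)$pos, p)
  }
})

test_that("interval lifting honors strict and partial modes", {
  chains <- make_del_chain()
  r <- liftInterval(chains, intervalTable("c1", 4L, 7L))
  expect_equal(c(r$interval$start, r$interval$end), c(2L, 5L))
  # spanning the gap with min_match 1 fails strict mode
  r2 <- liftInterval(chains, intervalTable("c1", 0L, 8L), minMatch = 1.0)
  expect_null(r2$interval)
  # partial mode trims to the mappable core
  r3 <- liftInterval(chains, intervalTable("c1", 2L, 5L), mode = "partial")
  expect_equal(c(r3$interval$start, r3$interval$end), c(2L, 3L))
})

test_that("randomized strict interval lifting equals the per-base oracle", {
  g <- simulateGenome(c(c1 = 40000L), seed = 61L)
  for (seed in 62:64) {
    plan <- resolveConflicts(random_edits(g, n_per_kind = 10L, seed = seed))
    r <- applyEdits(g, plan)
    e <- planEdits(plan)
    omap <- oracle_base_map(40000L, e[e$contig == "c1", ])
    set.seed(seed + 100L)
    starts <- sample.int(39000L, 150L)
    widths <- sample(10:600, 150L, replace = TRUE)
    for (k in seq_len(150L)) {
      iv <- intervalTable("c1", starts[k], min(starts[k] + widths[k], 40000L))
      got <- liftInterval(r$chains, iv, minMatch = 0.95, mode = "strict")
      span <- omap[(iv$start + 1L):iv$end]
      ok <- !is.na(span[1L]) && !is.na(span[length(span)]) &&
        mean(!is.na(span)) >= 0.95
      expect_equal(!is.null(got$interval), ok, label = paste("interval", k))
      if (ok) {
        expect_equal(got$interval$start, span[1L])
        expect_equal(got$interval$end, span[length(span)] + 1L)
      }
    }
    # full-vector agreement of position lifting with the oracle
    expect_identical(as.integer(liftPositions(r$chains, "c1", 0:39999)),
                     omap)
  }
})

test_that("VCF liftover shifts, rejects deletions and detects ref mismatches", {
  g <- Genome(c(c1 = "ACGTACGTAC"))
  r <- applyEdits(g, resolveConflicts(editTable("c1", 2L, 4L, "", "indel")))
  recs <- bind_vt(
    vt1(pos = 7L, ref = "G", alt = "T"),   # base 6 0-based -> shifts -2
    vt1(pos = 3L, ref = "G", alt = "A"))   # inside the deletion
  out <- liftVcf(r$chains, recs, r$genome)
  expect_equal(nrow(out$mapped), 1L)
  expect_equal(out$mapped$pos, 5L)
  expect_equal(out$rejected$reason, "deleted")
  expect_equal(nrow(out$mapped) + nrow(out$rejected), nrow(recs))
  # a record whose REF disagrees with the target genome is rejected
  bad <- vt1(pos = 7L, ref = "C", alt = "T")
  expect_equal(liftVcf(r$chains, bad, r$genome)$rejected$reason,
               "ref_mismatch")
})

test_that("round-tripped variant sets keep their positions", {
  g <- simulateGenome(c(c1 = 30000L), seed = 65L)
  plan <- resolveConflicts(random_edits(g, n_per_kind = 8L, seed = 66L))
  r <- applyEdits(g, plan)
  specs <- data.frame(kind = "snp", popFreq = 1, length = 0L, n = 100L)
  recs <- simulateCohortVariants(g, 5L, specs, seed = 67L)
  fwd <- liftVcf(r$chains, recs, r$genome)
  back <- liftVcf(lapply(r$chains, invertChain), fwd$mapped, g)
  expect_equal(nrow(back$rejected), 0L)
  orig_ok <- !(paste(recs$contig, recs$pos) %in%
                 paste(fwd$rejected$contig, fwd$rejected$pos))
  expect_equal(back$mapped$pos, recs$pos[orig_ok])
})

test_that("GTF liftover drops transcripts with unmappable exons and keeps structure", {
  g <- simulateGenome(c(c1 = 10000L), seed = 68L)
  r <- applyEdits(g, resolveConflicts(
    editTable("c1", 5000L, 5200L, "", "te_remove")))
  gtf <- data.frame(
    contig = "c1", strand = "+",
    feature = c("transcript", "exon", "exon",
                "transcript", "exon", "exon"),
    start = c(1000L, 1000L, 2000L, 4000L, 4000L, 5100L),
    end = c(2500L, 1500L, 2500L, 5300L, 4500L, 5300L),
    gene_id = c("g1", "g1", "g1", "g2", "g2", "g2"),
    transcript_id = c("t1", "t1", "t1", "t2", "t2", "t2"),
    exon_id = c(NA, "e1", "e2", NA, "e3", "e4"),
    stringsAsFactors = FALSE)
  out <- liftGtf(r$chains, gtf)
  conv <- out$converted
  expect_true(all(conv$transcript_id %in% "t1"))
  expect_equal(out$failedExons, "e4")
  expect_equal(out$summary[["transcript_fraction"]], 0.5)
  ex <- conv[conv$feature == "exon", ]
  expect_equal(ex$start, c(1000L, 2000L))   # upstream of the removal: unshifted
  expect_equal(ex$strand, c("+", "+"))
})

test_that("exon sequence validation explains every mismatch by its edit", {
  g <- simulateGenome(c(c1 = 8000L), seed = 69L)
  base <- toupper(substr(g[["c1"]], 1001L, 1001L))
  edits <- rbind(
    editTable("c1", 1000L, 1001L,
              setdiff(c("A", "C", "G", "T"), base)[1L], "snp_sub"),
    editTable("c1", 1200L, 1201L, "N", "n_mask"),
    editTable("c1", 3000L, 3010L, "", "te_remove"))
  plan <- resolveConflicts(edits)
  r <- applyEdits(g, plan)
  gtf <- data.frame(contig = "c1", strand = "+", feature = "exon",
                    start = c(500L, 900L, 1150L), end = c(700L, 1100L, 1300L),
                    gene_id = "g", transcript_id = "t",
                    exon_id = c("clean", "snp", "mask"),
                    stringsAsFactors = FALSE)
  rep <- validateExonSequences(g, r$genome, r$chains, gtf, planEdits(plan))
  expect_equal(rep$checked, 3L)
  expect_equal(nrow(rep$mismatches), 0L)
  expect_equal(rep$explained, 2L)   # one substitution, one N
})

test_that("compose and invert obey their algebraic identities", {
  g <- simulateGenome(c(c1 = 20000L), seed = 70L)
  plan1 <- resolveConflicts(random_edits(g, n_per_kind = 6L, seed = 71L))
  r1 <- applyEdits(g, plan1)
  plan2 <- resolveConflicts(random_edits(r1$genome, n_per_kind = 6L,
                                         seed = 72L))
  r2 <- applyEdits(r1$genome, plan2)
  comp <- composeChains(r1$chains$c1, r2$chains$c1)
  expect_true(validObject(comp))
  pos <- seq(0L, 19999L, by = 7L)
  step1 <- liftPositions(r1$chains, "c1", pos)
  step2 <- rep(NA_integer_, length(pos))
  ok <- !is.na(step1)
  step2[ok] <- as.integer(liftPositions(r2$chains, "c1", step1[ok]))
  direct <- as.integer(liftPositions(list(comp), "c1", pos))
  expect_identical(direct, step2)
  # compose with identity leaves the mapping unchanged
  ident <- applyEdits(g, resolveConflicts(
    editTable(character(), integer(), integer(), character(),
              character())))$chains$c1
  expect_identical(as.integer(liftPositions(list(composeChains(ident,
                                                               r1$chains$c1)),
                                            "c1", pos)),
                   as.integer(step1))
  # invert twice is the identity on the chain itself
  inv2 <- invertChain(invertChain(r1$chains$c1))
  expect_identical(chainBlocks(inv2), chainBlocks(r1$chains$c1))
  # monotonicity of mapped positions
  expect_true(all(diff(stats::na.omit(step1)) > 0))
  # partition: mappable + in-gap counts reconcile with block sums
  b <- chainBlocks(r1$chains$c1)
  ch <- r1$chains$c1
  all_pos <- liftPositions(r1$chains, "c1", 0:19999)
  expect_equal(sum(!is.na(all_pos)), sum(b[, 1L]))
  expect_equal(sum(is.na(all_pos)),
               sum(b[, 2L]) + ch@tStart + (ch@tSize - ch@tEnd))
})

test_that("minus-strand chains lift to the opposite end of the query", {
  # target 0..7 aligned to an 8-base query written on the minus strand
  ch <- ChainAlignment("c1", 8L, 0L, 8L, "q1", 10L, 0L, 8L,
                       blocks = cbind(8L, 0L, 0L), qStrand = "-")
  # reversed-frame position p maps to forward position qSize - 1 - p
  expect_equal(liftPosition(list(ch), "c1", 0L)$pos, 9L)
  expect_equal(liftPosition(list(ch), "c1", 7L)$pos, 2L)
  iv <- liftInterval(list(ch), intervalTable("c1", 0L, 3L, strand = "+"))
  expect_equal(c(iv$interval$start, iv$interval$end), c(7L, 10L))
  expect_equal(iv$interval$strand, "-")
})
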