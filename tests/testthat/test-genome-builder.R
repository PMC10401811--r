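test_that("conflict resolution follows the kind-priority ladder", {
  # SNP substitution inside an indel: the indel wins
  raw <- rbind(editTable("c1", 101L, 102L, "G", "snp_sub"),
               editTable("c1", 100L, 103L, "", "indel"))
  plan <- resolveConflicts(raw)
  expect_equal(planEdits(plan)$kind, "indel")
  expect_equal(planConflicts(plan)$kind, "snp_sub")
  # N-mask inside a TE removal: the mask is dropped and logged
  raw2 <- rbind(editTable("c1", 50L, 51L, "N", "n_mask"),
                editTable("c1", 40L, 60L, "", "te_remove"))
  plan2 <- resolveConflicts(raw2)
  expect_equal(planEdits(plan2)$kind, "te_remove")
  expect_match(planConflicts(plan2)$reason, "te_remove")
  # disjoint edits pass through untouched
  raw3 <- rbind(editTable("c1", 10L, 11L, "A", "snp_sub"),
                editTable("c1", 20L, 23L, "", "indel"))
  plan3 <- resolveConflicts(raw3)
  expect_equal(nrow(planEdits(plan3)), 2L)
  expect_equal(nrow(planConflicts(plan3)), 0L)
})

test_that("contradictory same-priority calls are an error; resolution is order-invariant", {
  raw <- rbind(editTable("c1", 10L, 11L, "A", "snp_sub"),
               editTable("c1", 10L, 11L, "T", "snp_sub"))
  expect_error(resolveConflicts(raw), "contradictory")
  g <- simulateGenome(c(c1 = 20000L, c2 = 10000L), seed = 41L)
  raw2 <- random_edits(g, n_per_kind = 10L, seed = 42L)
  p1 <- planEdits(resolveConflicts(raw2))
  p2 <- planEdits(resolveConflicts(raw2[sample(nrow(raw2)), ]))
  rownames(p1) <- rownames(p2) <- NULL
  expect_identical(p1, p2)
})

test_that("applyEdits reproduces the hand-checkable sequences and chains", {
  g <- Genome(c(c1 = "ACGTACGT"))
  del <- applyEdits(g, resolveConflicts(editTable("c1", 2L, 4L, "", "indel")))
  expect_equal(del$genome[["c1"]], "ACACGT")
  expect_equal(unname(chainBlocks(del$chains$c1)),
               unname(rbind(c(2L, 2L, 0L), c(4L, 0L, 0L))))
  ins <- applyEdits(g, resolveConflicts(editTable("c1", 4L, 4L, "TT", "indel")))
  expect_equal(ins$genome[["c1"]], "ACGTTTACGT")
  expect_equal(unname(chainBlocks(ins$chains$c1)),
               unname(rbind(c(4L, 0L, 2L), c(4L, 0L, 0L))))
  subs <- applyEdits(g, resolveConflicts(rbind(
    editTable("c1", 2L, 3L, "A", "snp_sub"),
    editTable("c1", 6L, 7L, "N", "n_mask"))))
  expect_equal(subs$genome[["c1"]], "ACATACNT")
  expect_equal(unname(chainBlocks(subs$chains$c1)),
               unname(cbind(8L, 0L, 0L)))   # length-preserving: one block
})

test_that("an expected-reference mismatch aborts the build", {
  g <- Genome(c(c1 = "ACGTACGT"))
  bad <- resolveConflicts(editTable("c1", 2L, 3L, "A", "snp_sub", ref = "T"))
  expect_error(applyEdits(g, bad), "reference mismatch")
})

test_that("empty plans are identity with a single-block chain", {
  g <- Genome(c(c1 = "ACGTACGT", c2 = "GGGG"))
  r <- applyEdits(g, resolveConflicts(
    editTable(character(), integer(), integer(), character(), character())))
  expect_identical(unclass(r$genome)[], unclass(g)[])
  for (ctg in names(g)) {
    b <- chainBlocks(r$chains[[ctg]])
    expect_equal(nrow(b), 1L)
    expect_equal(unname(b[1L, 1L]), nchar(g[[ctg]]))
  }
})

test_that("random edit plans conserve length, N-count and match the naive replay oracle", {
  g <- simulateGenome(c(c1 = 50000L, c2 = 30000L), seed = 43L)
  for (seed in 44:48) {
    plan <- resolveConflicts(random_edits(g, n_per_kind = 12L, seed = seed))
    r <- applyEdits(g, plan)
    e <- planEdits(plan)
    for (ctg in names(g)) {
      ec <- e[e$contig == ctg, ]
      delta <- sum(nchar(ec$alt)) - sum(ec$end - ec$start)
      expect_equal(nchar(r$genome[[ctg]]) - nchar(g[[ctg]]), delta)
      # independent oracle: rightmost-first string surgery
      expect_identical(r$genome[[ctg]], oracle_apply_seq(g[[ctg]], ec))
      expect_true(validObject(r$chains[[ctg]]))
    }
    n_masks <- sum(e$kind == "n_mask")
    n_introduced <- sum(vapply(names(g), function(ctg) {
      lengths(regmatches(r$genome[[ctg]],
                         gregexpr("N", r$genome[[ctg]], fixed = TRUE)))
    }, integer(1L)))
    expect_equal(n_introduced, n_masks)   # simulated base genome has no N
  }
})

test_that("the two-stage build lifts nucleotide edits through the TE chain", {
  set.seed(51)
  g <- simulateGenome(c(c1 = 20000L), seed = 51L)
  cons <- Genome(c(L1Md = "ACGTACGTACGTACGTACGTACGT"))
  te_ins <- teCallTable("c1", 5000L, 5000L, "L1Md", 0.5, 10L, "pooled")
  te_abs <- teCallTable("c1", 10000L, 10200L, "L1Md", 1.0, 20L, "pooled")
  # uniform SNP downstream of the insertion; mask inside the removed TE
  uni <- vt1(pos = 7001L,
             ref = toupper(substr(g[["c1"]], 7001L, 7001L)),
             alt = setdiff(c("A", "C", "G", "T"),
                           toupper(substr(g[["c1"]], 7001L, 7001L)))[1L])
  non <- bind_vt(vt1(pos = 9001L, ref = toupper(substr(g[["c1"]], 9001L, 9001L))),
                 vt1(pos = 10050L, ref = toupper(substr(g[["c1"]], 10050L, 10050L))))
  built <- buildReference(g, te_ins, te_abs, uni, non, cons)
  # length: +24 TE, -200 removal
  expect_equal(nchar(built$genome[["c1"]]), 20000L + 24L - 200L)
  # the mask inside the removed TE is dropped, the other applied
  expect_equal(built$report$n_masked, 1L)
  expect_true(any(built$report$dropped$reason == "unmappable through stage-1 chain"))
  # uniform SNP landed where the composed chain says it should
  p <- liftPosition(built$chains, "c1", 7000L)
  expect_equal(toupper(substr(built$genome[["c1"]], p$pos + 1L, p$pos + 1L)),
               uni$alt[[1L]][1L])
  # mask landed at the lifted position of base 9000
  pm <- liftPosition(built$chains, "c1", 9000L)
  expect_equal(substr(built$genome[["c1"]], pm$pos + 1L, pm$pos + 1L), "N")
  # composed chain: positions inside the removed TE are unmappable, the
  # rest recover the identical base (TE insertion and removal aside)
  pos <- seq(0L, 19999L, by = 37L)
  mapped <- liftPositions(built$chains, "c1", pos)
  in_removed <- pos >= 10000L & pos < 10200L
  expect_true(all(is.na(mapped[in_removed])))
  base_chars <- strsplit(g[["c1"]], "")[[1L]]
  final_chars <- strsplit(built$genome[["c1"]], "")[[1L]]
  ok <- !is.na(mapped)
  agree <- base_chars[pos[ok] + 1L] == final_chars[mapped[ok] + 1L]
  edited_pos <- c(7000L, 9000L)   # the SNP substitution and the mask
  expect_true(all(agree | pos[ok] %in% edited_pos))
})
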