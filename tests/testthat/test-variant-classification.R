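test_that("hard filters fire on the stated inequalities, strictly", {
  base <- vt1(QD = 20)
  cases <- list(
    list(mod = list(QD = 1.9), class = "snp", fails = TRUE),
    list(mod = list(QD = 2.0), class = "snp", fails = FALSE),  # strict "<"
    list(mod = list(SOR = 3.5), class = "snp", fails = TRUE),
    list(mod = list(SOR = 3.0), class = "snp", fails = FALSE),
    list(mod = list(MQ = 39.9), class = "snp", fails = TRUE),
    list(mod = list(MQRankSum = -13), class = "snp", fails = TRUE),
    list(mod = list(FS = 150, ReadPosRankSum = -25), class = "indel",
         fails = TRUE),
    list(mod = list(FS = 150), class = "indel", fails = FALSE),  # indel FS cap is 200
    list(mod = list(SOR = 10), class = "indel", fails = FALSE))  # no SOR rule for indels
  for (cs in cases) {
    rec <- base
    for (k in names(cs$mod)) rec[[k]] <- cs$mod[[k]]
    out <- hardFilter(rec, variantClass = cs$class)
    expect_equal(nrow(out$fail) == 1L, cs$fails,
                 label = paste(names(cs$mod), unlist(cs$mod), cs$class))
    expect_equal(nrow(out$pass) + nrow(out$fail), 1L)
  }
})

test_that("a missing annotation skips its sub-filter instead of failing it", {
  rec <- vt1(MQRankSum = NA)
  expect_equal(nrow(hardFilter(rec, variantClass = "snp")$pass), 1L)
  rec2 <- vt1(MQRankSum = NA, QD = 1)
  expect_equal(hardFilter(rec2, variantClass = "snp")$fail$filter, "QD")
})

test_that("uniform selection applies AF > 0.8 and AC > 5, biallelic only", {
  th <- classificationThresholds(5L)
  recs <- bind_vt(
    vt1(pos = 10L, ac = list(10L), an = 10L),                  # af 1.0: in
    vt1(pos = 20L, ac = list(5L), an = 6L),                    # ac not > 5
    vt1(pos = 30L, af = list(0.8), ac = list(8L), an = 10L),   # af not > 0.8
    vt1(pos = 40L, ac = list(9L), an = 10L),                   # af 0.9: in
    variantTable("c1", 50L, "A", list(c("G", "T")), ac = list(c(8L, 1L)),
                 an = 10L))                                    # triallelic: out
  uni <- classifyUniform(recs, th)
  expect_equal(uni$pos, c(10L, 40L))
})

test_that("non-uniform selection covers both biallelic and multiallelic arms", {
  th <- classificationThresholds(5L)
  recs <- bind_vt(
    vt1(pos = 10L, ac = list(5L), an = 10L),                  # af 0.5: in
    vt1(pos = 20L, af = list(0.2), ac = list(2L), an = 10L),  # af not > 0.2
    vt1(pos = 30L, af = list(0.8), ac = list(8L), an = 10L),  # af <= 0.8: in
    vt1(pos = 35L, ac = list(2L), an = 8L),                   # ac not > 2
    variantTable("c1", 40L, "A", list(c("G", "T")), ac = list(c(3L, 2L)),
                 an = 8L),                                    # 3/8 > 0.2, an 8 > 5: in
    variantTable("c1", 50L, "A", list(c("G", "T")), ac = list(c(1L, 1L)),
                 an = 10L))                                   # top 0.1: out
  non <- classifyNonuniform(recs, th)
  expect_equal(non$pos, c(10L, 30L, 40L))
})

test_that("uniform and non-uniform outputs are disjoint and permutation-invariant", {
  g <- simulateGenome(c(c1 = 50000L), seed = 11L)
  specs <- data.frame(kind = "snp", popFreq = c(1, 0.8, 0.5, 0.3, 0.1),
                      length = 0L, n = 40L)
  recs <- simulateCohortVariants(g, 5L, specs, seed = 12L)
  filt <- hardFilter(recs, variantClass = "snp")$pass
  uni <- classifyUniform(filt)
  non <- classifyNonuniform(filt)
  expect_length(intersect(paste(uni$contig, uni$pos),
                          paste(non$contig, non$pos)), 0L)
  # permuting samples never changes classification
  perm <- filt
  perm$gt <- lapply(perm$gt, function(g) g[c(3L, 5L, 1L, 2L, 4L)])
  perm <- recomputeAlleleStats(perm)
  expect_equal(classifyUniform(perm)$pos, uni$pos)
  expect_equal(classifyNonuniform(perm)$pos, non$pos)
})

test_that("nearby indels are removed pairwise by half-open gap", {
  del <- vt1(pos = 100L, ref = "ACGT", alt = "A")   # footprint [100,103)
  ins_touch <- vt1(pos = 103L, ref = "A", alt = "ATT")  # insertion at [103,103)
  far <- vt1(pos = 104L, ref = "AC", alt = "A")     # footprint [104,105)
  both_dropped <- removeNearbyIndels(bind_vt(del, ins_touch), 1L)
  expect_equal(nrow(both_dropped), 0L)
  kept <- removeNearbyIndels(bind_vt(del, far), 1L)  # gap 1 >= 1
  expect_equal(nrow(kept), 2L)
  expect_equal(nrow(removeNearbyIndels(del, 1L)), 1L)  # singleton kept
})

test_that("SNPs inside indel footprints are excluded; insertions count their anchor", {
  del <- vt1(pos = 100L, ref = "ACGT", alt = "A")
  expect_equal(nrow(excludeSnpsOverlappingIndels(
    vt1(pos = 101L), del)), 0L)       # base 100 0-based in [100,103)
  expect_equal(nrow(excludeSnpsOverlappingIndels(
    vt1(pos = 104L), del)), 1L)       # base 103 outside
  ins <- vt1(pos = 50L, ref = "A", alt = "ATT")
  expect_equal(nrow(excludeSnpsOverlappingIndels(vt1(pos = 50L), ins)), 0L)
  snps <- vt1(pos = 7L)
  expect_equal(nrow(excludeSnpsOverlappingIndels(snps, del[0L, ])), 1L)
})

test_that("downsampling recomputes allele stats and applies scaled thresholds", {
  gt <- list(c("0/1", "0/1", "1/1", "1/1", "1/1"))
  rec <- variantTable("c1", 100L, "A", list("G"), qual = 500, gt = gt,
                      annotations = data.frame(QD = 20, SOR = 1, FS = 5,
                                               MQ = 55, MQRankSum = 0,
                                               ReadPosRankSum = 0),
                      samples = paste0("m", 1:5))
  # subset {3,4,5}: all 1/1 -> af 1.0, ac 6 > 3 -> uniform
  r <- downsampleClassify(rec, c("m3", "m4", "m5"), 3L)
  expect_equal(nrow(r$uniform), 1L)
  expect_equal(r$uniform$ac[[1L]], 6L)
  expect_equal(nrow(r$nonuniform), 0L)
  # subset {1,2,3}: ac 4 of 6, af 0.667 -> non-uniform at n=3 (ac > 1)
  r2 <- downsampleClassify(rec, 1:3, 3L)
  expect_equal(nrow(r2$uniform), 0L)
  expect_equal(nrow(r2$nonuniform), 1L)
  expect_equal(r2$nonuniform$af[[1L]], 4 / 6)
  # hand-computed planted case: uniform in 5 mice, af drops to 0.75 in a
  # 2-mouse subset -> non-uniform there (ac 3 > 0)
  gt3 <- list(c("1/1", "0/1", "1/1", "1/1", "1/1"))
  rec3 <- variantTable("c1", 100L, "A", list("G"), qual = 500, gt = gt3,
                       annotations = attr(rec, "ann"),
                       samples = paste0("m", 1:5))
  rec3$QD <- 20; rec3$ReadPosRankSum <- 0; rec3$FS <- 5
  expect_equal(nrow(classifyUniform(rec3)), 1L)
  r3 <- downsampleClassify(rec3, c("m1", "m2"), 2L)
  expect_equal(r3$nonuniform$af[[1L]], 0.75)
  expect_equal(nrow(r3$uniform), 0L)
  # homozygous-reference subset: site dropped entirely
  gt4 <- list(c("0/0", "0/0", "1/1", "1/1", "1/1"))
  rec4 <- variantTable("c1", 100L, "A", list("G"), qual = 500, gt = gt4,
                       samples = paste0("m", 1:5))
  r4 <- downsampleClassify(rec4, 1:2, 2L)
  expect_equal(nrow(r4$uniform) + nrow(r4$nonuniform), 0L)
  expect_error(downsampleClassify(rec, 1:5, 5L), "cohort size")
})

test_that("unused alternate alleles are removed and genotypes reindexed", {
  gt <- list(c("0/1", "0/1", "2/2", "0/2", "0/0"))
  rec <- variantTable("c1", 10L, "A", list(c("G", "T")), qual = 500,
                      gt = gt, samples = paste0("m", 1:5))
  r <- downsampleClassify(rec, 3:5, 3L)
  all_sites <- rbind(r$uniform, r$nonuniform)
  expect_equal(nrow(all_sites), 1L)
  expect_identical(all_sites$alt[[1L]], "T")     # G unused in subset
  expect_identical(all_sites$gt[[1L]], c("1/1", "0/1", "0/0"))
})

test_that("planted fixed differences are always uniform; 50/50 sites follow the AC rule", {
  g <- simulateGenome(c(c1 = 200000L), seed = 21L)
  specs <- data.frame(kind = "snp", popFreq = c(1.0, 0.5), length = 0L,
                      n = c(200L, 200L))
  recs <- simulateCohortVariants(g, 5L, specs, seed = 22L)
  filt <- hardFilter(recs, variantClass = "snp")$pass
  uni <- classifyUniform(filt)
  non <- classifyNonuniform(filt)
  fixed_keys <- paste(recs$contig, recs$pos)[recs$truth_popfreq == 1.0]
  expect_true(all(fixed_keys %in% paste(uni$contig, uni$pos)))
  expect_false(any(paste(non$contig, non$pos) %in% fixed_keys))
  # per-site agreement with the rule applied directly to drawn counts
  bal <- recs[recs$truth_popfreq == 0.5, ]
  k <- vapply(bal$ac, max, integer(1L))
  rule_says <- k >= 3L & k <= 8L    # 0.2 < k/10 <= 0.8 and k > 2
  classified <- paste(bal$contig, bal$pos) %in% paste(non$contig, non$pos)
  expect_identical(classified, rule_says)
})
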