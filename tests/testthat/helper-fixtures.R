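# Shared fixture builders and independent oracles. The oracles replay edit
# semantics directly on positions/strings and never touch the chain code
# they are used to check.

# one-row variant table shortcut
vt1 <- function(contig = "c1", pos = 100L, ref = "A", alt = "G",
                qual = 500, gt = NULL, ac = NULL, an = NULL, af = NULL,
                QD = 20, SOR = 1, FS = 5, MQ = 55, MQRankSum = 0,
                ReadPosRankSum = 0, samples = character()) {
  variantTable(contig, pos, ref, list(alt), qual = qual,
               gt = if (is.null(gt)) NULL else list(gt),
               annotations = data.frame(QD = QD, SOR = SOR, FS = FS,
                                        MQ = MQ, MQRankSum = MQRankSum,
                                        ReadPosRankSum = ReadPosRankSum),
               ac = ac, an = an, af = af, samples = samples)
}

bind_vt <- function(...) {
  tabs <- list(...)
  out <- do.call(rbind, tabs)
  attr(out, "samples") <- attr(tabs[[1L]], "samples")
  class(out) <- c("variant_table", "data.frame")
  out
}

# independent per-base mapping oracle: replays the edit plan on positions.
# Returns, for one contig, an integer vector of length len: 0-based edited
# position of each base, NA where the base is replaced by a
# length-changing edit.
oracle_base_map <- function(len, edits) {
  edits <- edits[order(edits$start, edits$end), , drop = FALSE]
  lc <- edits[(edits$end - edits$start) != nchar(edits$alt), , drop = FALSE]
  map <- rep(NA_integer_, len)
  delta <- 0L
  prev <- 0L
  for (i in seq_len(nrow(lc))) {
    s <- lc$start[i]; e <- lc$end[i]
    if (s > prev) map[(prev + 1L):s] <- (prev:(s - 1L)) + delta
    delta <- delta + nchar(lc$alt[i]) - (e - s)
    prev <- e
  }
  if (prev < len) map[(prev + 1L):len] <- (prev:(len - 1L)) + delta
  map
}

# independent sequence oracle: applies edits one at a time, rightmost
# first, by plain string surgery.
oracle_apply_seq <- function(seq, edits) {
  edits <- edits[order(-edits$start, -edits$end), , drop = FALSE]
  for (i in seq_len(nrow(edits))) {
    seq <- paste0(substr(seq, 1L, edits$start[i]), edits$alt[i],
                  substr(seq, edits$end[i] + 1L, nchar(seq)))
  }
  seq
}

# random raw edit set over a genome (conflicts left for resolveConflicts)
random_edits <- function(genome, n_per_kind = 8L, seed = 1L) {
  set.seed(seed)
  lens <- contigLengths(genome)
  rnd_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
  one <- function(kind) {
    ctg <- sample(names(lens), n_per_kind, replace = TRUE)
    out <- lapply(seq_len(n_per_kind), function(i) {
      len <- lens[[ctg[i]]]
      switch(kind,
        te_insert = {
          p <- sample.int(len - 1L, 1L)
          editTable(ctg[i], p, p, rnd_seq(sample(5:30, 1L)), "te_insert")
        },
        te_remove = {
          w <- sample(10:50, 1L)
          s <- sample.int(len - w - 1L, 1L)
          editTable(ctg[i], s, s + w, "", "te_remove")
        },
        indel = {
          if (stats::runif(1) < 0.5) {
            w <- sample(1:5, 1L)
            s <- sample.int(len - w - 1L, 1L)
            editTable(ctg[i], s, s + w, "", "indel")
          } else {
            p <- sample.int(len - 1L, 1L)
            editTable(ctg[i], p, p, rnd_seq(sample(1:5, 1L)), "indel")
          }
        },
        snp_sub = {
          p <- sample.int(len - 1L, 1L) - 1L
          cur <- toupper(substr(genome[[ctg[i]]], p + 1L, p + 1L))
          editTable(ctg[i], p, p + 1L,
                    sample(setdiff(c("A", "C", "G", "T"), cur), 1L),
                    "snp_sub")
        },
        n_mask = {
          p <- sample.int(len - 1L, 1L) - 1L
          editTable(ctg[i], p, p + 1L, "N", "n_mask")
        })
    })
    do.call(rbind, out)
  }
  do.call(rbind, lapply(names(strainref::EDIT_PRIORITY), one))
}

# cohort variant fixture used across classification tests
cohort_specs <- function(n_fixed = 50L, n_balanced = 50L,
                         n_indel = 0L) {
  data.frame(kind = c("snp", "snp", rep("indel", n_indel > 0L)),
             popFreq = c(1.0, 0.5, rep(1.0, n_indel > 0L)),
             length = c(0L, 0L, rep(3L, n_indel > 0L)),
             n = c(n_fixed, n_balanced, rep(n_indel, n_indel > 0L)))
}
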