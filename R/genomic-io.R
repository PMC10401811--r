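# Readers and writers for FASTA, VCF 4.x, BED, GTF and UCSC chain files.
# One internal convention everywhere: 0-based half-open intervals. VCF
# (1-based) and GTF (1-based, inclusive both ends) are converted at the
# boundary and nowhere else.

#' Read a FASTA file into a Genome
#'
#' Case is preserved exactly (soft-masked lowercase stays lowercase).
#'
#' @param path path to a FASTA file.
#' @return A [Genome-class].
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             whole.header = FALSE)
  Genome(stats::setNames(vapply(seqs, `[[`, character(1L), 1L), names(seqs)))
}

#' Write a Genome to FASTA
#'
#' @param genome a [Genome-class].
#' @param path output path.
#' @param lineWidth bases per sequence line (default 60).
#' @return `path`, invisibly.
#' @export
writeFasta <- function(genome, path, lineWidth = 60L) {
  seqinr::write.fasta(as.list(unclass(genome)), names = names(genome),
                      file.out = path, nbchar = lineWidth, as.string = TRUE)
  invisible(path)
}

## ---- variant tables -------------------------------------------------------

VCF_ANNOTATIONS <- c("QD", "SOR", "FS", "MQ", "MQRankSum", "ReadPosRankSum")

#' Construct a variant table
#'
#' The in-memory representation of VCF sites: a data.frame with one row per
#' site, list-columns for the per-alt fields, and per-sample genotypes as
#' allele-index strings ("0/1", "./."). Multi-allelic sites stay single rows.
#'
#' @param contig,pos,ref site coordinates (pos is 1-based, VCF convention)
#'   and reference allele.
#' @param alt list of character vectors of alternate alleles (or a character
#'   vector for all-biallelic input).
#' @param qual numeric site quality.
#' @param gt optional list of per-sample genotype strings; element names are
#'   ignored, use `samples` for the sample names.
#' @param annotations optional data.frame holding any of
#'   QD, SOR, FS, MQ, MQRankSum, ReadPosRankSum (NA = absent).
#' @param af,ac,an optional INFO-derived values; when NULL and genotypes are
#'   present they are computed from the genotypes and flagged `afDerived`.
#' @param samples character vector of sample names.
#' @param id,filter optional ID / FILTER columns.
#' @return A data.frame of class `c("variant_table", "data.frame")` with
#'   attribute `samples`.
#' @export
variantTable <- function(contig, pos, ref, alt, qual = NA_real_, gt = NULL,
                         annotations = NULL, af = NULL, ac = NULL, an = NULL,
                         samples = character(), id = ".", filter = ".") {
  n <- length(pos)
  if (!is.list(alt)) alt <- as.list(alt)
  tab <- data.frame(contig = as.character(contig), pos = as.integer(pos),
                    id = rep_len(as.character(id), n),
                    ref = as.character(ref), qual = rep_len(as.numeric(qual), n),
                    filter = rep_len(as.character(filter), n),
                    stringsAsFactors = FALSE)
  tab$alt <- alt
  for (k in VCF_ANNOTATIONS) {
    tab[[k]] <- if (!is.null(annotations) && k %in% names(annotations))
      as.numeric(annotations[[k]]) else rep(NA_real_, n)
  }
  tab$gt <- if (is.null(gt)) rep(list(character()), n) else gt
  derived <- FALSE
  if (is.null(ac) || is.null(an)) {
    counted <- lapply(tab$gt, .count_alleles, n_alt = lengths(alt))
    if (is.null(ac)) ac <- lapply(seq_len(n), function(i) counted[[i]]$ac)
    if (is.null(an)) an <- vapply(counted, function(x) x$an, integer(1L))
    derived <- TRUE
  }
  if (!is.list(ac)) ac <- as.list(ac)
  tab$ac <- lapply(ac, as.integer)
  tab$an <- as.integer(an)
  if (is.null(af)) {
    tab$af <- lapply(seq_len(n), function(i)
      if (tab$an[i] > 0L) tab$ac[[i]] / tab$an[i] else rep(NA_real_, length(tab$ac[[i]])))
  } else {
    if (!is.list(af)) af <- as.list(af)
    tab$af <- lapply(af, as.numeric)
  }
  tab$afDerived <- rep(derived, n)
  bad <- which(vapply(seq_len(n), function(i) any(tab$ac[[i]] > tab$an[i]), logical(1L)))
  if (length(bad))
    stop(sprintf("AC > AN at %s:%d", tab$contig[bad[1L]], tab$pos[bad[1L]]))
  attr(tab, "samples") <- samples
  class(tab) <- c("variant_table", "data.frame")
  tab
}

.count_alleles <- function(gt, n_alt) {
  alleles <- unlist(strsplit(gt, "[/|]"))
  alleles <- suppressWarnings(as.integer(alleles[alleles != "."]))
  alleles <- alleles[!is.na(alleles)]
  nalt <- if (length(n_alt) > 1L) max(n_alt) else n_alt
  ac <- vapply(seq_len(max(nalt, 1L)), function(i) sum(alleles == i), integer(1L))
  list(ac = ac, an = length(alleles))
}

#' Recompute AF/AC/AN of a variant table from its genotypes
#'
#' @param records a variant table.
#' @return the table with `ac`, `an`, `af` recomputed and `afDerived = TRUE`.
#' @export
recomputeAlleleStats <- function(records) {
  counted <- lapply(records$gt, .count_alleles, n_alt = lengths(records$alt))
  records$ac <- lapply(counted, function(x) as.integer(x$ac))
  records$an <- vapply(counted, function(x) x$an, integer(1L))
  records$af <- lapply(seq_len(nrow(records)), function(i)
    if (records$an[i] > 0L) records$ac[[i]] / records$an[i]
    else rep(NA_real_, length(records$ac[[i]])))
  records$afDerived <- rep(TRUE, nrow(records))
  records
}

#' Top alternate-allele frequency of each site
#'
#' For biallelic sites this is the single alt frequency; for multiallelic
#' sites, the most frequent alternate allele's fraction of called alleles.
#'
#' @param records a variant table.
#' @return numeric vector.
#' @export
topAltFrequency <- function(records) {
  vapply(seq_len(nrow(records)), function(i) {
    af <- records$af[[i]]
    if (length(af) == 0L || all(is.na(af))) NA_real_ else max(af, na.rm = TRUE)
  }, numeric(1L))
}

#' Read a VCF file
#'
#' Multi-allelic records are kept as single rows. When INFO lacks AF/AC/AN
#' they are recomputed from the genotypes and flagged `afDerived`.
#'
#' @param path path to an uncompressed VCF.
#' @param genome optional [Genome-class]; when supplied, each record's REF is
#'   checked against the genome and a mismatch is an error.
#' @return a variant table (see [variantTable()]).
#' @export
readVcf <- function(path, genome = NULL) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  chrom_line <- hdr[startsWith(hdr, "#CHROM")]
  if (length(chrom_line) != 1L) stop("VCF missing #CHROM header line")
  cols <- strsplit(chrom_line, "\t")[[1L]]
  samples <- if (length(cols) > 9L) cols[10:length(cols)] else character()
  if (length(body) == 0L) {
    return(variantTable(character(), integer(), character(), list(),
                        samples = samples))
  }
  f <- strsplit(body, "\t")
  getf <- function(i) vapply(f, `[[`, character(1L), i)
  info <- lapply(strsplit(getf(8L), ";"), function(kvs) {
    kvs <- kvs[kvs != "."]
    kv <- strsplit(kvs, "=", fixed = TRUE)
    stats::setNames(vapply(kv, function(x) if (length(x) > 1L) x[2L] else "TRUE",
                           character(1L)),
                    vapply(kv, `[[`, character(1L), 1L))
  })
  info_num <- function(key) {
    vapply(info, function(x) {
      if (key %in% names(x)) suppressWarnings(as.numeric(x[[key]])) else NA_real_
    }, numeric(1L))
  }
  info_numlist <- function(key) {
    lapply(info, function(x) {
      if (key %in% names(x))
        suppressWarnings(as.numeric(strsplit(x[[key]], ",")[[1L]]))
      else NULL
    })
  }
  alt <- strsplit(getf(5L), ",", fixed = TRUE)
  gt <- NULL
  if (length(samples)) {
    gt <- lapply(f, function(x) {
      fmt <- strsplit(x[[9L]], ":")[[1L]]
      gti <- match("GT", fmt)
      vapply(x[10:length(x)], function(s) strsplit(s, ":")[[1L]][gti],
             character(1L), USE.NAMES = FALSE)
    })
  }
  have_counts <- vapply(info, function(x) all(c("AC", "AN") %in% names(x)),
                        logical(1L))
  af <- ac <- an <- NULL
  if (all(have_counts)) {
    ac <- lapply(info_numlist("AC"), as.integer)
    an <- as.integer(info_num("AN"))
    af_raw <- info_numlist("AF")
    af <- lapply(seq_along(ac), function(i) {
      if (!is.null(af_raw[[i]])) af_raw[[i]]
      else if (an[i] > 0L) ac[[i]] / an[i] else rep(NA_real_, length(ac[[i]]))
    })
  } else if (is.null(gt)) {
    # sites without genotypes: fall back to whatever INFO carries
    af <- info_numlist("AF")
    ac <- lapply(info, function(x)
      if ("AC" %in% names(x)) as.integer(strsplit(x[["AC"]], ",")[[1L]]) else NA_integer_)
    an <- as.integer(info_num("AN"))
    tab <- variantTable(getf(1L), as.integer(getf(2L)), getf(4L), alt,
                        qual = suppressWarnings(as.numeric(getf(6L))), gt = NULL,
                        annotations = as.data.frame(
                          stats::setNames(lapply(VCF_ANNOTATIONS, info_num),
                                          VCF_ANNOTATIONS)),
                        af = af, ac = ac, an = an,
                        samples = samples, id = getf(3L), filter = getf(7L))
    tab$afDerived <- rep(FALSE, nrow(tab))
    if (!is.null(genome)) .check_ref(tab, genome)
    return(tab)
  }
  tab <- variantTable(getf(1L), as.integer(getf(2L)), getf(4L), alt,
                      qual = suppressWarnings(as.numeric(getf(6L))), gt = gt,
                      annotations = as.data.frame(
                        stats::setNames(lapply(VCF_ANNOTATIONS, info_num),
                                        VCF_ANNOTATIONS)),
                      af = af, ac = ac, an = an,
                      samples = samples, id = getf(3L), filter = getf(7L))
  if (all(have_counts)) tab$afDerived <- rep(FALSE, nrow(tab))
  if (!is.null(genome)) .check_ref(tab, genome)
  tab
}

.check_ref <- function(records, genome) {
  for (i in seq_len(nrow(records))) {
    ctg <- records$contig[i]
    if (!ctg %in% names(genome)) stop("unknown contig in VCF: ", ctg)
    want <- toupper(records$ref[i])
    got <- toupper(substr(genome[[ctg]], records$pos[i],
                          records$pos[i] + nchar(want) - 1L))
    if (got != want)
      stop(sprintf("REF mismatch at %s:%d (VCF %s, genome %s)",
                   ctg, records$pos[i], want, got))
  }
  invisible(TRUE)
}

#' Write a variant table to VCF
#'
#' @param records a variant table.
#' @param path output path.
#' @param extraHeader optional character vector of extra `##` header lines.
#' @return `path`, invisibly.
#' @export
writeVcf <- function(records, path, extraHeader = character()) {
  samples <- attr(records, "samples")
  hdr <- c("##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Allele Count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Total Alleles\">",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
            VCF_ANNOTATIONS, VCF_ANNOTATIONS),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    extraHeader,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t"))
  fmtnum <- function(x) ifelse(is.na(x), NA_character_,
                               formatC(x, format = "g", digits = 10))
  body <- vapply(seq_len(nrow(records)), function(i) {
    info <- c(
      sprintf("AF=%s", paste(fmtnum(records$af[[i]]), collapse = ",")),
      sprintf("AC=%s", paste(records$ac[[i]], collapse = ",")),
      sprintf("AN=%d", records$an[i]),
      unlist(lapply(VCF_ANNOTATIONS, function(k) {
        v <- records[[k]][i]
        if (is.na(v)) character() else sprintf("%s=%s", k, fmtnum(v))
      })))
    fields <- c(records$contig[i], records$pos[i], records$id[i],
                records$ref[i], paste(records$alt[[i]], collapse = ","),
                if (is.na(records$qual[i])) "." else fmtnum(records$qual[i]),
                records$filter[i], paste(info, collapse = ";"))
    if (length(samples))
      fields <- c(fields, "GT", records$gt[[i]])
    paste(fields, collapse = "\t")
  }, character(1L))
  writeLines(c(hdr, body), path)
  invisible(path)
}

## ---- BED ------------------------------------------------------------------

#' Construct an interval table (0-based half-open)
#'
#' @param contig,start,end coordinates; start inclusive, end exclusive.
#' @param name,score,strand optional BED columns.
#' @return data.frame with columns contig, start, end, name, score, strand.
#' @export
intervalTable <- function(contig, start, end, name = ".", score = 0,
                          strand = ".") {
  n <- length(start)
  if (any(start < 0L) || any(start >= end))
    stop("intervals require 0 <= start < end")
  data.frame(contig = as.character(contig), start = as.integer(start),
             end = as.integer(end), name = rep_len(as.character(name), n),
             score = rep_len(as.numeric(score), n),
             strand = rep_len(as.character(strand), n),
             stringsAsFactors = FALSE)
}

#' Read a BED3+ file into an interval table
#' @param path BED file path.
#' @return an interval table (see [intervalTable()]).
#' @export
readBed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("contig", "start", "end", "name",
                                         "score", "strand")[1:max(
                             utils::count.fields(path, sep = "\t"))])
  intervalTable(tab$contig, tab$start, tab$end,
                name = if ("name" %in% names(tab)) tab$name else ".",
                score = if ("score" %in% names(tab)) tab$score else 0,
                strand = if ("strand" %in% names(tab)) tab$strand else ".")
}

#' Write an interval table to BED
#' @param intervals an interval table.
#' @param path output path.
#' @param ncol number of BED columns to emit (3..6).
#' @return `path`, invisibly.
#' @export
writeBed <- function(intervals, path, ncol = 6L) {
  cols <- c("contig", "start", "end", "name", "score", "strand")[seq_len(ncol)]
  utils::write.table(intervals[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- GTF ------------------------------------------------------------------

#' Read a GTF annotation
#'
#' Parsed with rtracklayer and converted to the internal 0-based half-open
#' convention.
#'
#' @param path GTF file path.
#' @return data.frame with columns contig, start, end (0-based half-open),
#'   strand, feature, gene_id, transcript_id, exon_id.
#' @export
readGtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  pick <- function(key) {
    if (key %in% names(mc)) as.character(mc[[key]]) else rep(NA_character_, length(gr))
  }
  exon_id <- pick("exon_id")
  if (all(is.na(exon_id)) && "exon_number" %in% names(mc))
    exon_id <- ifelse(pick("type") == "exon",
                      paste0(pick("transcript_id"), ".exon", pick("exon_number")),
                      NA_character_)
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             feature = pick("type"),
             gene_id = pick("gene_id"),
             transcript_id = pick("transcript_id"),
             exon_id = exon_id,
             stringsAsFactors = FALSE)
}

#' Write a GTF annotation
#'
#' @param gtf a data.frame as returned by [readGtf()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGtf <- function(gtf, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = gtf$contig,
    ranges = IRanges::IRanges(start = gtf$start + 1L, end = gtf$end),
    strand = ifelse(gtf$strand %in% c("+", "-"), gtf$strand, "*"))
  S4Vectors::mcols(gr)$type <- gtf$feature
  S4Vectors::mcols(gr)$gene_id <- gtf$gene_id
  S4Vectors::mcols(gr)$transcript_id <- gtf$transcript_id
  if ("exon_id" %in% names(gtf)) S4Vectors::mcols(gr)$exon_id <- gtf$exon_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

## ---- chain ----------------------------------------------------------------

#' Read a UCSC chain file
#'
#' @param path chain file path.
#' @return list of [ChainAlignment-class]; block-sum invariants are verified
#'   on read and an inconsistency is an error naming the chain id.
#' @export
readChain <- function(path) {
  lines <- trimws(readLines(path))
  starts <- which(startsWith(lines, "chain"))
  if (length(starts) == 0L) stop("no chain records in ", path)
  lapply(starts, function(s) {
    hd <- strsplit(lines[s], "[ \t]+")[[1L]]
    if (length(hd) != 13L) stop("malformed chain header: ", lines[s])
    i <- s + 1L
    rows <- list()
    repeat {
      if (i > length(lines) || !nzchar(lines[i])) break
      v <- as.integer(strsplit(lines[i], "[ \t]+")[[1L]])
      rows[[length(rows) + 1L]] <- if (length(v) == 1L) c(v, 0L, 0L) else v
      i <- i + 1L
      if (length(v) == 1L) break
    }
    ChainAlignment(tName = hd[3L], tSize = as.integer(hd[4L]),
                   tStart = as.integer(hd[6L]), tEnd = as.integer(hd[7L]),
                   qName = hd[8L], qSize = as.integer(hd[9L]),
                   qStart = as.integer(hd[11L]), qEnd = as.integer(hd[12L]),
                   blocks = do.call(rbind, rows), score = as.numeric(hd[2L]),
                   tStrand = hd[5L], qStrand = hd[10L],
                   id = as.integer(hd[13L]))
  })
}

#' Write chains to a UCSC chain file
#'
#' @param chains a [ChainAlignment-class] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeChain <- function(chains, path) {
  if (is(chains, "ChainAlignment")) chains <- list(chains)
  out <- unlist(lapply(chains, function(ch) {
    b <- ch@blocks
    body <- if (nrow(b) > 1L) {
      c(paste(b[-nrow(b), 1L], b[-nrow(b), 2L], b[-nrow(b), 3L]),
        as.character(b[nrow(b), 1L]))
    } else as.character(b[1L, 1L])
    c(sprintf("chain %s %s %d %s %d %d %s %d %s %d %d %d",
              format(ch@score, scientific = FALSE, trim = TRUE),
              ch@tName, ch@tSize, ch@tStrand, ch@tStart, ch@tEnd,
              ch@qName, ch@qSize, ch@qStrand, ch@qStart, ch@qEnd, ch@id),
      body, "")
  }))
  writeLines(out, path)
  invisible(path)
}
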