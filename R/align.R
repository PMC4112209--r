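#' Align paired reads to a combined reference by exact matching
#'
#' Minimal exact matcher for synthetic fixtures: each read is searched
#' full-length, on both strands, against the combined reference (masked
#' genome plus TE library) with [Biostrings::matchPDict()].  A read is mapped
#' (MAPQ 60) only if it has exactly one match location in the whole combined
#' reference; reads with several matches are written at their first location
#' with MAPQ 0 and an `NH` tag (multi-mapped), and reads with no exact match
#' are unmapped.  Real datasets would use an external aligner and feed SAM to
#' [classify_pairs()] directly.
#'
#' @param fastq1,fastq2 paths to the two mate files.
#' @param ref a `ReferenceBundle`; its `masked_genome` and `te_library` form
#'   the combined reference.
#' @param sam_path output SAM path.
#' @param sample_id read-group style sample label recorded in a `@CO` line.
#' @return (invisibly) a data.table of alignment records (one row per mate),
#'   the same information serialized to `sam_path`; columns qname, mate (1/2),
#'   rname (NA if unmapped), strand, pos, mapq, nhits, seq, qual.
#' @export
align_reads <- function(fastq1, fastq2, ref, sam_path, sample_id = "sample") {
  reads1 <- Biostrings::readDNAStringSet(fastq1, format = "fastq")
  reads2 <- Biostrings::readDNAStringSet(fastq2, format = "fastq")
  if (length(reads1) != length(reads2))
    stop("malformed FASTQ pair: ", length(reads1), " vs ", length(reads2),
         " records")
  if (!identical(names(reads1), names(reads2)))
    stop("malformed FASTQ pair: mate ids differ or are out of order")
  subjects <- c(ref$masked_genome, ref$te_library)
  rl <- unique(c(Biostrings::width(reads1), Biostrings::width(reads2)))
  if (length(rl) != 1L)
    stop("the built-in matcher requires constant read length")
  if (rl >= min(Biostrings::width(subjects)))
    stop("reads must be shorter than every reference sequence")

  hits1 <- exact_hits(reads1, subjects)
  hits2 <- exact_hits(reads2, subjects)
  n <- length(reads1)
  aln <- rbind(
    mate_records(hits1, reads1, 1L),
    mate_records(hits2, reads2, 2L))
  data.table::setorder(aln, idx, mate)
  aln[, qname := rep(names(reads1), each = 2L)]
  write_sam(aln, subjects, sam_path, sample_id)
  invisible(aln[])
}

# exact full-length matches of all reads against all subjects, both strands;
# returns data.table(idx, rname, strand, pos, nhits-per-read computed later)
exact_hits <- function(reads, subjects) {
  pd_f <- Biostrings::PDict(reads)
  pd_r <- Biostrings::PDict(Biostrings::reverseComplement(reads))
  res <- list()
  for (j in seq_along(subjects)) {
    for (st in c("+", "-")) {
      pd <- if (st == "+") pd_f else pd_r
      m <- Biostrings::matchPDict(pd, subjects[[j]])
      cnt <- S4Vectors::elementNROWS(m)
      if (sum(cnt) == 0L) next
      res[[length(res) + 1L]] <- data.table::data.table(
        idx = rep(seq_along(cnt), cnt),
        rname = names(subjects)[j],
        strand = st,
        pos = unlist(Biostrings::startIndex(m), use.names = FALSE))
    }
  }
  if (!length(res))
    return(data.table::data.table(idx = integer(), rname = character(),
                                  strand = character(), pos = integer()))
  data.table::rbindlist(res)
}

# one alignment record per mate: unique hit, first-of-multiple (MAPQ 0),
# or unmapped
mate_records <- function(hits, reads, mate) {
  n <- length(reads)
  nh <- integer(n)
  if (nrow(hits)) {
    tab <- hits[, .N, by = idx]
    nh[tab$idx] <- tab$N
    data.table::setorder(hits, idx, rname, strand, pos)
    first <- hits[!duplicated(idx)]
  } else {
    first <- hits
  }
  out <- data.table::data.table(
    idx = seq_len(n), mate = mate,
    rname = NA_character_, strand = "+", pos = 0L,
    mapq = 0L, nhits = nh)
  if (nrow(first)) {
    out[first$idx, `:=`(rname = first$rname, strand = first$strand,
                        pos = first$pos)]
    out[nhits == 1L, mapq := 60L]
  }
  out[, seq := as.character(reads)]
  # SAM stores the read on the reference strand
  rc <- which(out$strand == "-" & !is.na(out$rname))
  if (length(rc))
    out$seq[rc] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(out$seq[rc])))
  out[]
}

# serialize paired alignment records as SAM 1.6
write_sam <- function(aln, subjects, sam_path, sample_id) {
  rl <- nchar(aln$seq[1])
  a1 <- aln[mate == 1L][order(idx)]
  a2 <- aln[mate == 2L][order(idx)]
  rec <- function(a, b, first) {
    mapped <- !is.na(a$rname)
    mate_mapped <- !is.na(b$rname)
    proper <- mapped & mate_mapped & a$rname == b$rname &
      a$strand != b$strand & a$mapq >= 1L & b$mapq >= 1L
    flag <- 1L +
      ifelse(proper, 2L, 0L) +
      ifelse(mapped, 0L, 4L) +
      ifelse(mate_mapped, 0L, 8L) +
      ifelse(mapped & a$strand == "-", 16L, 0L) +
      ifelse(mate_mapped & b$strand == "-", 32L, 0L) +
      if (first) 64L else 128L
    same <- mapped & mate_mapped & a$rname == b$rname
    tlen <- integer(nrow(a))
    if (any(same)) {
      lo <- pmin(a$pos[same], b$pos[same])
      hi <- pmax(a$pos[same] + rl - 1L, b$pos[same] + rl - 1L)
      tlen[same] <- ifelse(a$pos[same] <= b$pos[same], hi - lo + 1L,
                           -(hi - lo + 1L))
    }
    data.table::data.table(
      qname = a$qname,
      flag = flag,
      rname = ifelse(mapped, a$rname, "*"),
      pos = ifelse(mapped, a$pos, 0L),
      mapq = a$mapq,
      cigar = ifelse(mapped, paste0(rl, "M"), "*"),
      rnext_ = ifelse(mate_mapped, ifelse(same, "=", b$rname), "*"),
      pnext_ = ifelse(mate_mapped, b$pos, 0L),
      tlen = tlen,
      seq_ = a$seq,
      qual_ = strrep("I", rl),
      nh = paste0("NH:i:", pmax(a$nhits, 1L)))
  }
  recs <- rbind(rec(a1, a2, TRUE), rec(a2, a1, FALSE))
  ord <- order(rep(seq_len(nrow(a1)), 2L), rep(1:2, each = nrow(a1)))
  recs <- recs[ord]
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(subjects),
                   Biostrings::width(subjects)),
           "@PG\tID:tepop\tPN:tepop",
           sprintf("@CO\tsample:%s", sample_id))
  writeLines(hdr, sam_path)
  data.table::fwrite(recs, sam_path, sep = "\t", append = TRUE,
                     col.names = FALSE, quote = FALSE)
  invisible(sam_path)
}
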