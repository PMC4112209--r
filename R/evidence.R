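#' Classify read pairs as TE-supporting or spanning evidence
#'
#' The discordant-pair principle: a pair with one mate uniquely mapped to a
#' genomic location and the other mate mapped to a TE library sequence
#' supports a TE insertion near the genomic mate; a concordant genomic pair
#' whose insert lies in the expected size range is spanning evidence against
#' an insertion between its mates.  All other pairs (both mates on TEs, any
#' multi-mapped or unmapped mate, discordant orientation or insert size) are
#' dropped.
#'
#' For supporting pairs the genomic mate's strand gives the side: a
#' forward-strand genomic mate points at a junction downstream
#' (`side = "forward"`, position = the mate's 3' end); a reverse-strand mate
#' points upstream (`side = "reverse"`, position = the mate's 5' start).
#'
#' Uniqueness: records with MAPQ below `min_mapq`, or flagged secondary or
#' supplementary, are treated as non-unique.  The built-in matcher writes
#' MAPQ 60 for unique and 0 for multi-mapped reads, so one rule covers both
#' built-in and external SAM.
#'
#' @param alignments a SAM file path, or the alignment data.table returned by
#'   [align_reads()].
#' @param te_family named character vector mapping TE library sequence names
#'   to family labels (e.g. a `ReferenceBundle$te_family`).
#' @param insert_mean,insert_sd expected fragment-length distribution; pairs
#'   are concordant when their outer span is within `insert_mean +/- 3 *
#'   insert_sd`.
#' @param min_mapq minimum mapping quality treated as unique.
#' @return a `PairEvidence` data.table: read_id, chrom, genomic_pos, side,
#'   te_id, te_family, kind (`"supporting"`/`"spanning"`), inner_start,
#'   inner_end (the open interval strictly between the two reads of a
#'   spanning pair; NA for supporting pairs).
#' @export
classify_pairs <- function(alignments, te_family, insert_mean = 300,
                           insert_sd = 30, min_mapq = 20L) {
  aln <- if (is.character(alignments)) {
    read_sam_alignments(alignments)
  } else {
    dt <- data.table::as.data.table(alignments)
    dt[, `:=`(end = pos + nchar(seq) - 1L,
              unmapped = is.na(rname), secondary = FALSE)]
    dt[, .(qname, mate, rname, strand, pos, end, mapq, unmapped, secondary)]
  }
  te_names <- names(te_family)
  a <- aln[mate == 1L]
  b <- aln[mate == 2L]
  data.table::setkey(a, qname)
  data.table::setkey(b, qname)
  stopifnot(identical(a$qname, b$qname))

  uniq <- function(d) !d$unmapped & !d$secondary & d$mapq >= min_mapq
  ua <- uniq(a); ub <- uniq(b)
  ta <- a$rname %in% te_names
  tb <- b$rname %in% te_names

  support_rows <- function(g, t, sel) {
    if (!any(sel)) return(NULL)
    data.table::data.table(
      read_id = g$qname[sel],
      chrom = g$rname[sel],
      genomic_pos = ifelse(g$strand[sel] == "+", g$end[sel], g$pos[sel]),
      side = ifelse(g$strand[sel] == "+", "forward", "reverse"),
      te_id = t$rname[sel],
      te_family = unname(te_family[t$rname[sel]]),
      kind = "supporting",
      inner_start = NA_integer_, inner_end = NA_integer_)
  }
  supp <- data.table::rbindlist(list(
    support_rows(a, b, ua & !ta & ub & tb),
    support_rows(b, a, ub & !tb & ua & ta)))

  both_gen <- ua & ub & !ta & !tb & a$rname == b$rname
  span <- NULL
  if (any(both_gen)) {
    ga <- a[both_gen]; gb <- b[both_gen]
    left_is_a <- ga$pos <= gb$pos
    lpos <- ifelse(left_is_a, ga$pos, gb$pos)
    lend <- ifelse(left_is_a, ga$end, gb$end)
    rpos <- ifelse(left_is_a, gb$pos, ga$pos)
    rend <- ifelse(left_is_a, gb$end, ga$end)
    lstr <- ifelse(left_is_a, ga$strand, gb$strand)
    rstr <- ifelse(left_is_a, gb$strand, ga$strand)
    outer <- rend - lpos + 1L
    ok <- lstr == "+" & rstr == "-" &
      outer >= insert_mean - 3 * insert_sd &
      outer <= insert_mean + 3 * insert_sd
    if (any(ok))
      span <- data.table::data.table(
        read_id = ga$qname[ok],
        chrom = ga$rname[ok],
        genomic_pos = lpos[ok],
        side = NA_character_,
        te_id = NA_character_, te_family = NA_character_,
        kind = "spanning",
        inner_start = lend[ok] + 1L,
        inner_end = rpos[ok] - 1L)
  }
  ev <- data.table::rbindlist(list(supp, span))
  if (nrow(ev) == 0L)
    ev <- data.table::data.table(
      read_id = character(), chrom = character(), genomic_pos = integer(),
      side = character(), te_id = character(), te_family = character(),
      kind = character(), inner_start = integer(), inner_end = integer())
  data.table::setorder(ev, chrom, genomic_pos, kind, read_id)
  ev[]
}

# load a SAM file through Rsamtools (SAM -> BAM -> records)
read_sam_alignments <- function(sam_path) {
  con <- file(sam_path, "rt")
  hdr <- character()
  while (length(l <- readLines(con, n = 1L)) && startsWith(l, "@"))
    hdr <- c(hdr, l)
  close(con)
  if (!any(startsWith(hdr, "@SQ")))
    stop("SAM file has no @SQ header lines: ", sam_path)
  bam <- Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam))
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "strand",
                                        "pos", "qwidth", "mapq"))
  r <- Rsamtools::scanBam(bam, param = p)[[1]]
  dt <- data.table::data.table(
    qname = r$qname,
    flag = r$flag,
    rname = as.character(r$rname),
    strand = as.character(r$strand),
    pos = r$pos,
    qwidth = r$qwidth,
    mapq = r$mapq)
  dt[, `:=`(
    mate = ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L),
    unmapped = bitwAnd(flag, 4L) > 0L,
    secondary = bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L,
    end = pos + qwidth - 1L)]
  dt[is.na(mapq), mapq := 0L]
  dt[(unmapped), `:=`(rname = NA_character_, strand = "+",
                      pos = 0L, end = 0L)]
  dt[, .(qname, mate, rname, strand, pos, end, mapq, unmapped, secondary)]
}

#' Estimate the within-sample insertion frequency at a locus
#'
#' The fraction of informative pairs that support the insertion:
#' `n_support / (n_support + n_spanning)`.  Acts as a proxy for allele
#' dosage within one individual (about 1 for homozygous, about 0.5 for
#' heterozygous insertions).
#'
#' @param n_support number of TE-supporting pairs.
#' @param n_spanning number of spanning pairs.
#' @return proportion(s) in `[0, 1]`; vectorized.
#' @export
estimate_frequency <- function(n_support, n_spanning) {
  stopifnot(length(n_support) == length(n_spanning),
            all(n_support + n_spanning > 0))
  n_support / (n_support + n_spanning)
}

#' Detect TE insertions in one sample from pair evidence
#'
#' Same-family, same-side supporting evidence is clustered by greedy
#' left-to-right chaining after a position sort: a pair extends the open
#' cluster when it is within `cluster_window` of the previous position
#' (equivalent to single-linkage transitive closure in one dimension).  A
#' forward and a reverse cluster of the same family whose innermost
#' positions (forward cluster: maximum mate end; reverse cluster: minimum
#' mate start) lie within `cluster_window` are joined into one both-sided
#' observation with `pos_estimate` at the floor of their midpoint; unjoined
#' single-sided clusters that meet `min_support` are also emitted, at their
#' innermost position.  Spanning pairs whose inner span strictly contains
#' `pos_estimate` form the frequency denominator.
#'
#' The frequency of a both-sided observation is the mean of the two per-side
#' estimates `side_support / (side_support + n_spanning)`; a single-sided
#' observation uses the plain ratio.  Averaging the sides keeps heterozygous
#' insertions near 0.5: an insertion longer than the insert size presents two
#' junctions, so pooling both sides against one spanning region would push
#' heterozygotes toward 2/3.
#'
#' @param evidence a `PairEvidence` table from [classify_pairs()] (one
#'   sample).
#' @param cluster_window clustering window (bp); default mirrors
#'   `insert_mean + 3 * insert_sd` of the default read simulator geometry.
#' @param min_support minimum supporting pairs per emitted observation.
#' @param sample_id sample label for the output rows.
#' @return an `InsertionObservation` data.table: sample_id, chrom,
#'   pos_estimate, family, n_support_fwd, n_support_rev, n_spanning,
#'   freq_estimate, both_sided.
#' @export
detect_insertions <- function(evidence, cluster_window = 390L,
                              min_support = 2L, sample_id = "sample") {
  ev <- data.table::as.data.table(evidence)
  empty <- data.table::data.table(
    sample_id = character(), chrom = character(), pos_estimate = integer(),
    family = character(), n_support_fwd = integer(),
    n_support_rev = integer(), n_spanning = integer(),
    freq_estimate = numeric(), both_sided = logical())
  if (nrow(ev) == 0L) return(empty)
  supp <- ev[kind == "supporting"]
  if (nrow(supp) == 0L) return(empty)
  span <- ev[kind == "spanning"]

  # per-side clusters: chrom, family, side, innermost position, support n
  supp <- supp[order(chrom, te_family, side, genomic_pos)]
  supp[, cluster := cumsum(
    c(TRUE, diff(genomic_pos) > cluster_window)),
    by = .(chrom, te_family, side)]
  cl <- supp[, .(
    innermost = if (side[1] == "forward") max(genomic_pos)
                else min(genomic_pos),
    n = .N), by = .(chrom, te_family, side, cluster)]

  obs <- list()
  for (grp in split(cl, by = c("chrom", "te_family"))) {
    fwd <- grp[side == "forward"][order(innermost)]
    rev <- grp[side == "reverse"][order(innermost)]
    pairs <- NULL
    if (nrow(fwd) && nrow(rev)) {
      cand <- data.table::CJ(fi = seq_len(nrow(fwd)), ri = seq_len(nrow(rev)))
      cand[, dist := abs(rev$innermost[ri] - fwd$innermost[fi])]
      cand <- cand[dist <= cluster_window][order(dist, fi, ri)]
      used_f <- logical(nrow(fwd)); used_r <- logical(nrow(rev))
      keep <- integer()
      for (i in seq_len(nrow(cand))) {
        if (used_f[cand$fi[i]] || used_r[cand$ri[i]]) next
        used_f[cand$fi[i]] <- TRUE; used_r[cand$ri[i]] <- TRUE
        keep <- c(keep, i)
      }
      pairs <- cand[keep]
    } else {
      used_f <- logical(nrow(fwd)); used_r <- logical(nrow(rev))
    }
    rows <- list()
    if (!is.null(pairs) && nrow(pairs)) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        chrom = grp$chrom[1], family = grp$te_family[1],
        pos_estimate = as.integer(floor(
          (fwd$innermost[pairs$fi] + rev$innermost[pairs$ri]) / 2)),
        n_support_fwd = fwd$n[pairs$fi],
        n_support_rev = rev$n[pairs$ri],
        both_sided = TRUE)
    }
    if (any(!used_f))
      rows[[length(rows) + 1L]] <- data.table::data.table(
        chrom = grp$chrom[1], family = grp$te_family[1],
        pos_estimate = fwd$innermost[!used_f],
        n_support_fwd = fwd$n[!used_f], n_support_rev = 0L,
        both_sided = FALSE)
    if (any(!used_r))
      rows[[length(rows) + 1L]] <- data.table::data.table(
        chrom = grp$chrom[1], family = grp$te_family[1],
        pos_estimate = rev$innermost[!used_r],
        n_support_fwd = 0L, n_support_rev = rev$n[!used_r],
        both_sided = FALSE)
    obs[[length(obs) + 1L]] <- data.table::rbindlist(rows)
  }
  obs <- data.table::rbindlist(obs)
  if (nrow(obs) == 0L) return(empty)
  obs <- obs[n_support_fwd + n_support_rev >= min_support]
  if (nrow(obs) == 0L) return(empty)

  obs[, n_spanning := 0L]
  if (nrow(span)) {
    for (i in seq_len(nrow(obs))) {
      obs$n_spanning[i] <- span[chrom == obs$chrom[i] &
                                inner_start <= obs$pos_estimate[i] &
                                inner_end >= obs$pos_estimate[i], .N]
    }
  }
  # same ratio as estimate_frequency(); computed per side and averaged for
  # both-sided observations (see Details)
  obs[, freq_estimate := ifelse(
    both_sided,
    (n_support_fwd / (n_support_fwd + n_spanning) +
       n_support_rev / (n_support_rev + n_spanning)) / 2,
    (n_support_fwd + n_support_rev) /
      (n_support_fwd + n_support_rev + n_spanning))]
  sid <- sample_id
  obs[, sample_id := sid]
  data.table::setcolorder(obs, c("sample_id", "chrom", "pos_estimate",
                                 "family", "n_support_fwd", "n_support_rev",
                                 "n_spanning", "freq_estimate", "both_sided"))
  data.table::setorder(obs, chrom, pos_estimate, family)
  obs[]
}

#' Run alignment, classification and detection for one sample
#'
#' Convenience wrapper: [align_reads()] then [classify_pairs()] then
#' [detect_insertions()].
#'
#' @param fastq1,fastq2 mate FASTQ paths.
#' @param ref a `ReferenceBundle`.
#' @param sample_id sample label.
#' @param read_length,insert_mean,insert_sd read geometry (used for the
#'   concordance range and the default cluster window).
#' @param cluster_window,min_support,min_mapq detection parameters; the
#'   cluster window defaults to `insert_mean + 3 * insert_sd`.
#' @param sam_path where to write the SAM file; a tempfile (removed
#'   afterwards) when `NULL`.
#' @return an `InsertionObservation` data.table.
#' @export
sample_observations <- function(fastq1, fastq2, ref, sample_id,
                                read_length = 108L, insert_mean = 300,
                                insert_sd = 30, cluster_window = NULL,
                                min_support = 2L, min_mapq = 20L,
                                sam_path = NULL) {
  cluster_window <- cluster_window %||% (insert_mean + 3 * insert_sd)
  tmp <- is.null(sam_path)
  if (tmp) sam_path <- tempfile(fileext = ".sam")
  aln <- align_reads(fastq1, fastq2, ref, sam_path, sample_id)
  if (tmp) on.exit(unlink(sam_path))
  ev <- classify_pairs(aln, ref$te_family, insert_mean, insert_sd, min_mapq)
  detect_insertions(ev, cluster_window, min_support, sample_id)
}

#' Write per-sample insertion observations as TSV
#' @param obs an `InsertionObservation` data.table.
#' @param path output path.
#' @param header optional provenance header lines.
#' @return `path`, invisibly.
#' @export
write_observations_tsv <- function(obs, path, header = character()) {
  out <- data.table::as.data.table(obs)[, .(
    sample_id, chrom, pos0 = pos_estimate - 1L, family,
    n_support_fwd, n_support_rev, n_spanning,
    freq = round(freq_estimate, 6))]
  write_tsv_header(out, path, header)
}
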