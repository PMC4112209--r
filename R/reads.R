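#' Simulate paired-end reads for one individual
#'
#' Builds the individual's two haplotype sequences by inserting the full TE
#' sequence after each carried site position (homozygous sites on both
#' haplotypes, heterozygous sites on the recorded carrier haplotype), then
#' draws read pairs: fragment lengths are normal
#' (`insert_mean`, `insert_sd`), fragments are placed uniformly on a random
#' haplotype, and the two mates are the fragment's ends in forward-reverse
#' inward orientation.  The expected pair count is
#' `coverage * genome_length / (2 * read_length)` (Poisson-distributed).
#' Base qualities are constant.
#'
#' @param ref a `ReferenceBundle`.
#' @param truth one individual's truth table (an element of
#'   `PopulationTruth$individuals`); may have zero rows.
#' @param coverage target fold coverage (> 0).
#' @param out_prefix path prefix; writes `<prefix>_1.fastq`, `<prefix>_2.fastq`.
#' @param read_length read length (bp).
#' @param insert_mean,insert_sd fragment-length distribution (bp);
#'   `insert_mean` must exceed `2 * read_length`.
#' @param error_rate per-base substitution error probability.
#' @param te_mutation_rate per-base substitution rate applied to each
#'   inserted TE copy (within-family divergence of individual copies);
#'   default 0 keeps copies identical to the library sequence.
#' @param seed integer seed.
#' @param sample_id sample name used in read ids; default taken from `truth`.
#' @return (invisibly) list with `fastq1`, `fastq2`, `n_pairs`.
#' @export
simulate_reads <- function(ref, truth, coverage, out_prefix,
                           read_length = 108L, insert_mean = 300L,
                           insert_sd = 30L, error_rate = 0,
                           te_mutation_rate = 0, seed = 1L,
                           sample_id = NULL) {
  stopifnot(coverage > 0, insert_mean > 2L * read_length)
  truth <- data.table::as.data.table(truth)
  if (is.null(sample_id)) {
    if (nrow(truth) == 0L)
      stop("sample_id is required when the truth table is empty")
    sample_id <- truth$sample_id[1]
  }
  set.seed(substream_seed(seed, paste0("reads:", sample_id)))

  haps <- build_haplotypes(ref, truth, te_mutation_rate)
  glen <- sum(Biostrings::width(ref$chromosomes))
  n_pairs <- stats::rpois(1L, coverage * glen / (2 * read_length))

  # sample (haplotype, chromosome) jointly, weight = sequence length
  combo <- data.table::data.table(
    hap = rep(1:2, each = length(haps[[1]])),
    chrom = rep(names(haps[[1]]), 2L),
    len = c(nchar(haps[[1]]), nchar(haps[[2]])))
  pick <- sample.int(nrow(combo), n_pairs, replace = TRUE, prob = combo$len)
  frag <- pmax(2L * read_length,
               as.integer(round(stats::rnorm(n_pairs, insert_mean, insert_sd))))
  frag <- pmin(frag, combo$len[pick])
  start <- floor(stats::runif(n_pairs) * (combo$len[pick] - frag + 1)) + 1L

  r1 <- character(n_pairs); r2 <- character(n_pairs)
  for (k in unique(pick)) {
    idx <- which(pick == k)
    s <- haps[[combo$hap[k]]][[combo$chrom[k]]]
    r1[idx] <- substring(s, start[idx], start[idx] + read_length - 1L)
    r2[idx] <- substring(s, start[idx] + frag[idx] - read_length,
                         start[idx] + frag[idx] - 1L)
  }
  if (error_rate > 0) {
    r1 <- add_read_errors(r1, error_rate)
    r2 <- add_read_errors(r2, error_rate)
  }
  reads1 <- Biostrings::DNAStringSet(r1)
  reads2 <- Biostrings::reverseComplement(Biostrings::DNAStringSet(r2))
  nm <- sprintf("%s:%06d", sample_id, seq_len(n_pairs))
  names(reads1) <- nm
  names(reads2) <- nm

  qual <- Biostrings::BStringSet(rep(strrep("I", read_length), n_pairs))
  f1 <- paste0(out_prefix, "_1.fastq")
  f2 <- paste0(out_prefix, "_2.fastq")
  Biostrings::writeXStringSet(reads1, f1, format = "fastq", qualities = qual)
  Biostrings::writeXStringSet(reads2, f2, format = "fastq", qualities = qual)
  invisible(list(fastq1 = f1, fastq2 = f2, n_pairs = n_pairs))
}

# insert TE sequences into reference chromosomes; returns
# list(hap1 = named character, hap2 = named character).  With a non-zero
# te_mutation_rate each carried copy diverges from the library sequence
# (one allele per site: a homozygote's two copies are identical).
build_haplotypes <- function(ref, truth, te_mutation_rate = 0) {
  chroms <- stats::setNames(as.character(ref$chromosomes),
                            names(ref$chromosomes))
  copy_seq <- vapply(seq_len(nrow(truth)), function(i)
    as.character(ref$te_library[[truth$te_id[i]]]), "")
  if (te_mutation_rate > 0 && nrow(truth))
    copy_seq <- add_read_errors(copy_seq, te_mutation_rate)
  truth <- data.table::copy(truth)[, copy_seq := copy_seq]
  lapply(1:2, function(h) {
    out <- chroms
    if (nrow(truth) == 0L) return(out)
    carried <- truth[copy_count == 2L | (copy_count == 1L & hap == h)]
    for (cn in unique(carried$chrom)) {
      rows <- carried[chrom == cn][order(pos)]
      pieces <- character(2L * nrow(rows) + 1L)
      prev <- 0L
      for (i in seq_len(nrow(rows))) {
        pieces[2L * i - 1L] <- substring(chroms[[cn]], prev + 1L, rows$pos[i])
        pieces[2L * i] <- rows$copy_seq[i]
        prev <- rows$pos[i]
      }
      pieces[2L * nrow(rows) + 1L] <-
        substring(chroms[[cn]], prev + 1L, nchar(chroms[[cn]]))
      out[[cn]] <- paste(pieces, collapse = "")
    }
    out
  })
}

add_read_errors <- function(reads, rate) {
  lens <- nchar(reads)
  n_err <- stats::rbinom(length(reads), lens, rate)
  for (i in which(n_err > 0L)) {
    s <- strsplit(reads[i], "")[[1]]
    at <- sample.int(lens[i], n_err[i])
    s[at] <- vapply(s[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    reads[i] <- paste(s, collapse = "")
  }
  reads
}

#' Merge paired FASTQ sets into one paired sample
#'
#' Concatenates mate-1 files and mate-2 files in the given order, preserving
#' within-file pairing.  This constructs the merged "hybrid" of two
#' individuals, or the pooled sample of a whole species, used by the
#' validation experiments.  Read ids must be unique across inputs (the
#' simulator prefixes ids with the sample name).
#'
#' @param fastq_sets list of length-2 character vectors `c(fastq1, fastq2)`.
#' @param out_prefix path prefix for `<prefix>_1.fastq` / `<prefix>_2.fastq`.
#' @return (invisibly) list with `fastq1`, `fastq2`, `n_pairs`.
#' @export
merge_samples <- function(fastq_sets, out_prefix) {
  stopifnot(length(fastq_sets) >= 1L)
  read_fq <- function(p)
    Biostrings::readDNAStringSet(p, format = "fastq", with.qualities = TRUE)
  all1 <- list(); all2 <- list()
  for (fs in fastq_sets) {
    a <- read_fq(fs[[1]]); b <- read_fq(fs[[2]])
    if (length(a) != length(b))
      stop("mate count mismatch between ", fs[[1]], " and ", fs[[2]])
    all1[[length(all1) + 1L]] <- a
    all2[[length(all2) + 1L]] <- b
  }
  m1 <- do.call(c, all1); m2 <- do.call(c, all2)
  if (anyDuplicated(names(m1)))
    stop("duplicate read ids across merged inputs")
  f1 <- paste0(out_prefix, "_1.fastq")
  f2 <- paste0(out_prefix, "_2.fastq")
  Biostrings::writeXStringSet(m1, f1, format = "fastq",
                              qualities = S4Vectors::mcols(m1)$qualities)
  Biostrings::writeXStringSet(m2, f2, format = "fastq",
                              qualities = S4Vectors::mcols(m2)$qualities)
  invisible(list(fastq1 = f1, fastq2 = f2, n_pairs = length(m1)))
}
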