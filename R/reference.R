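#' Build a synthetic reference bundle
#'
#' Generates a toy reference for end-to-end testing of the insertion-detection
#' pipeline: random-background chromosomes, a central pericentromere per
#' chromosome, non-overlapping genes restricted to the chromosome arms, and a
#' TE library with members of the four families (LTR, non-LTR, DNA, Helitron).
#' Optionally a number of reference-resident TE copies are carved into the
#' pericentromeres; the masked genome replaces those spans with `N`, mirroring
#' the repeat-masked reference used for read mapping.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of each chromosome (bp), at least 10 kb.
#' @param n_genes total number of genes to place (across all chromosomes).
#' @param n_te_per_family TE library members generated per family.
#' @param pericentromere_fraction fraction of each chromosome, centered,
#'   treated as pericentromere; in `[0, 0.5]`.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param gene_length_range min/max gene length (bp).
#' @param te_length_range min/max TE length (bp); minimum must be >= 400.
#' @param n_reference_tes reference-resident TE copies carved into
#'   pericentromeres (masked to `N` in the masked genome). Default 0.
#' @return a `ReferenceBundle`: list with `chromosomes` and `masked_genome`
#'   ([Biostrings::DNAStringSet]), `genes` and `pericentromeres`
#'   ([GenomicRanges::GRanges]), `te_library` (DNAStringSet), `te_family`
#'   (named character vector, TE id -> family), `reference_tes` (GRanges).
#' @export
build_reference <- function(n_chromosomes = 1L,
                            chrom_length = 100000L,
                            n_genes = 20L,
                            n_te_per_family = 2L,
                            pericentromere_fraction = 0.2,
                            seed = 1L,
                            gene_length_range = c(500L, 1500L),
                            te_length_range = c(600L, 1500L),
                            n_reference_tes = 0L) {
  stopifnot(chrom_length >= 10000L,
            pericentromere_fraction >= 0, pericentromere_fraction <= 0.5,
            n_chromosomes >= 1L, n_genes >= 0L, n_te_per_family >= 1L,
            te_length_range[1] >= 400L)
  set.seed(substream_seed(seed, "reference"))

  chrom_names <- sprintf("chr%d", seq_len(n_chromosomes))
  chroms <- vapply(chrom_names, function(x) random_dna(chrom_length), "")

  # central pericentromere per chromosome
  peri_len <- round(pericentromere_fraction * chrom_length)
  if (peri_len > 0) {
    peri_start <- floor((chrom_length - peri_len) / 2) + 1L
    peri <- GenomicRanges::GRanges(
      chrom_names,
      IRanges::IRanges(start = peri_start, width = peri_len))
  } else {
    peri <- GenomicRanges::GRanges()
  }

  genes <- place_genes(chrom_names, chrom_length, peri, n_genes,
                       gene_length_range)

  te_lib <- make_te_library(n_te_per_family, te_length_range)

  # reference-resident TE copies: carve (replace in place, no coordinate
  # shift) into pericentromeric background, then N-mask those spans
  ref_tes <- GenomicRanges::GRanges()
  masked <- chroms
  if (n_reference_tes > 0L) {
    if (peri_len == 0) stop("reference TEs require a pericentromere")
    picks <- sample(names(te_lib$seqs), n_reference_tes, replace = TRUE)
    spans <- vector("list", n_reference_tes)
    occupied <- IRanges::IRanges()
    ps <- GenomicRanges::start(peri)[1]; pe <- GenomicRanges::end(peri)[1]
    for (i in seq_len(n_reference_tes)) {
      cn <- sample(chrom_names, 1L)
      w <- Biostrings::width(te_lib$seqs[picks[i]])
      for (try in 1:200) {
        s <- sample(ps:(pe - w + 1L), 1L)
        cand <- IRanges::IRanges(s, width = w)
        hit <- GenomicRanges::GRanges(cn, cand)
        if (length(ref_tes) == 0 ||
            !any(GenomicRanges::countOverlaps(hit, ref_tes))) break
        s <- NA_integer_
      }
      if (is.na(s)) stop("could not place reference TE copies without overlap")
      substr(chroms[cn], s, s + w - 1L) <-
        as.character(te_lib$seqs[[picks[i]]])
      substr(masked[cn], s, s + w - 1L) <- strrep("N", w)
      g <- GenomicRanges::GRanges(cn, IRanges::IRanges(s, width = w))
      S4Vectors::mcols(g)$te_id <- picks[i]
      ref_tes <- c(ref_tes, g)
    }
    # masked must track the carved chromosomes
    masked <- chroms
    for (i in seq_along(ref_tes)) {
      cn <- as.character(GenomicRanges::seqnames(ref_tes))[i]
      s <- GenomicRanges::start(ref_tes)[i]
      e <- GenomicRanges::end(ref_tes)[i]
      substr(masked[cn], s, e) <- strrep("N", e - s + 1L)
    }
  }

  bundle <- structure(list(
    chromosomes = Biostrings::DNAStringSet(chroms),
    masked_genome = Biostrings::DNAStringSet(masked),
    genes = genes,
    pericentromeres = peri,
    te_library = te_lib$seqs,
    te_family = te_lib$family,
    reference_tes = ref_tes
  ), class = "ReferenceBundle")
  validate_reference(bundle)
  bundle
}

# distribute genes over chromosome arms (outside pericentromeres),
# non-overlapping, via multinomial gap allocation (exact, deterministic)
place_genes <- function(chrom_names, chrom_length, peri, n_genes,
                        gene_length_range) {
  if (n_genes == 0L)
    return(GenomicRanges::GRanges(seqnames = character(),
                                  IRanges::IRanges()))
  # arms: per chromosome, the complement of the pericentromere
  arms <- list()
  for (cn in chrom_names) {
    p <- peri[GenomicRanges::seqnames(peri) == cn]
    if (length(p) == 0) {
      arms[[length(arms) + 1L]] <- list(chrom = cn, start = 1L,
                                        end = chrom_length)
    } else {
      s <- GenomicRanges::start(p)[1]; e <- GenomicRanges::end(p)[1]
      if (s > 1)
        arms[[length(arms) + 1L]] <- list(chrom = cn, start = 1L,
                                          end = s - 1L)
      if (e < chrom_length)
        arms[[length(arms) + 1L]] <- list(chrom = cn, start = e + 1L,
                                          end = chrom_length)
    }
  }
  arm_len <- vapply(arms, function(a) as.integer(a$end - a$start + 1L), 1L)
  # largest-remainder apportionment of genes to arms
  quota <- n_genes * arm_len / sum(arm_len)
  n_arm <- floor(quota)
  rem <- n_genes - sum(n_arm)
  if (rem > 0) {
    ord <- order(quota - n_arm, decreasing = TRUE)
    n_arm[ord[seq_len(rem)]] <- n_arm[ord[seq_len(rem)]] + 1L
  }
  out <- list()
  gid <- 0L
  for (i in seq_along(arms)) {
    k <- n_arm[i]
    if (k == 0) next
    lens <- sample(seq(gene_length_range[1], gene_length_range[2]), k,
                   replace = TRUE)
    free <- arm_len[i] - sum(lens)
    if (free < 0)
      stop("cannot place ", k, " genes in a ", arm_len[i], "-bp arm")
    gaps <- as.integer(stats::rmultinom(1, free, rep(1, k + 1L)))
    starts <- arms[[i]]$start + cumsum(gaps[seq_len(k)]) +
      c(0L, cumsum(lens[-k]))
    g <- GenomicRanges::GRanges(factor(arms[[i]]$chrom,
                                       levels = chrom_names),
                                IRanges::IRanges(starts, width = lens))
    S4Vectors::mcols(g)$gene_id <- sprintf("gene_%03d", gid + seq_len(k))
    gid <- gid + k
    out[[length(out) + 1L]] <- g
  }
  g <- sort(do.call(c, out))
  S4Vectors::mcols(g)$gene_id <- sprintf("gene_%03d", seq_along(g))
  g
}

make_te_library <- function(n_per_family, te_length_range) {
  ids <- character(); fams <- character(); seqs <- character()
  for (fam in TE_FAMILIES) {
    for (i in seq_len(n_per_family)) {
      ids <- c(ids, sprintf("%s_%d", gsub("[^A-Za-z0-9]", "", fam), i))
      fams <- c(fams, fam)
      seqs <- c(seqs, random_dna(sample(
        seq(te_length_range[1], te_length_range[2]), 1L)))
    }
  }
  if (anyDuplicated(seqs)) stop("TE library sequences are not distinct")
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- ids
  list(seqs = ss, family = stats::setNames(fams, ids))
}

validate_reference <- function(bundle) {
  stopifnot(inherits(bundle, "ReferenceBundle"))
  lens <- Biostrings::width(bundle$chromosomes)
  stopifnot(identical(lens, Biostrings::width(bundle$masked_genome)))
  assert_families(bundle$te_family)
  cl <- stats::setNames(lens, names(bundle$chromosomes))
  for (gr in list(bundle$genes, bundle$pericentromeres)) {
    if (length(gr) == 0) next
    cn <- as.character(GenomicRanges::seqnames(gr))
    stopifnot(all(cn %in% names(cl)),
              all(GenomicRanges::start(gr) >= 1),
              all(GenomicRanges::end(gr) <= cl[cn]))
  }
  stopifnot(all(Biostrings::width(bundle$te_library) >= 400L))
  invisible(bundle)
}

#' @export
print.ReferenceBundle <- function(x, ...) {
  cat("ReferenceBundle\n")
  cat(sprintf("  chromosomes: %d (%s bp total)\n",
              length(x$chromosomes),
              format(sum(Biostrings::width(x$chromosomes)), big.mark = ",")))
  cat(sprintf("  genes: %d; pericentromeres: %d\n",
              length(x$genes), length(x$pericentromeres)))
  cat(sprintf("  TE library: %d sequences (%s)\n", length(x$te_library),
              paste(sprintf("%s:%d", names(table(x$te_family)),
                            as.integer(table(x$te_family))), collapse = ", ")))
  invisible(x)
}

#' Write a reference bundle to standard file formats
#'
#' Writes `genome.fasta`, `masked_genome.fasta`, `te_library.fasta` (headers
#' `id#family`, RepeatMasker-style), `genes.gff3` (1-based) and
#' `pericentromeres.bed` (0-based half-open) under `dir`.
#'
#' @param bundle a `ReferenceBundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(bundle$chromosomes,
                              file.path(dir, "genome.fasta"))
  Biostrings::writeXStringSet(bundle$masked_genome,
                              file.path(dir, "masked_genome.fasta"))
  te <- bundle$te_library
  names(te) <- paste0(names(te), "#", bundle$te_family[names(te)])
  Biostrings::writeXStringSet(te, file.path(dir, "te_library.fasta"))
  genes <- bundle$genes
  if (length(genes)) {
    S4Vectors::mcols(genes)$type <- "gene"
    S4Vectors::mcols(genes)$source <- "tepop"
    S4Vectors::mcols(genes)$ID <- S4Vectors::mcols(genes)$gene_id
  }
  rtracklayer::export(genes, file.path(dir, "genes.gff3"), format = "gff3")
  rtracklayer::export(bundle$pericentromeres,
                      file.path(dir, "pericentromeres.bed"), format = "bed")
  invisible(dir)
}

#' Read a reference bundle written by [write_reference_bundle()]
#' @param dir directory containing the bundle files.
#' @return a `ReferenceBundle`.
#' @export
read_reference_bundle <- function(dir) {
  te <- Biostrings::readDNAStringSet(file.path(dir, "te_library.fasta"))
  parts <- strsplit(names(te), "#", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1L)
  fams <- vapply(parts, `[`, "", 2L)
  names(te) <- ids
  genes <- rtracklayer::import(file.path(dir, "genes.gff3"), format = "gff3")
  bundle <- structure(list(
    chromosomes = Biostrings::readDNAStringSet(file.path(dir, "genome.fasta")),
    masked_genome = Biostrings::readDNAStringSet(
      file.path(dir, "masked_genome.fasta")),
    genes = genes,
    pericentromeres = rtracklayer::import(
      file.path(dir, "pericentromeres.bed"), format = "bed"),
    te_library = te,
    te_family = stats::setNames(fams, ids),
    reference_tes = GenomicRanges::GRanges()
  ), class = "ReferenceBundle")
  validate_reference(bundle)
  bundle
}

#' Create a diverged copy of a reference (reference-swap control)
#'
#' Substitutes bases at a fixed per-site rate to emulate mapping against the
#' assembly of a related species, as in reference-bias control experiments.
#' Masked spans stay masked; the TE library is left untouched unless
#' `diverge_te = TRUE`.
#'
#' @param bundle a `ReferenceBundle`.
#' @param rate per-base substitution probability.
#' @param seed integer seed.
#' @param diverge_te also diverge the TE library sequences.
#' @return a new `ReferenceBundle`.
#' @export
diverge_reference <- function(bundle, rate = 0.01, seed = 1L,
                              diverge_te = FALSE) {
  stopifnot(rate >= 0, rate < 1)
  set.seed(substream_seed(seed, "diverge"))
  mutate_set <- function(ss) {
    out <- as.character(ss)
    for (i in seq_along(out)) {
      s <- strsplit(out[i], "")[[1]]
      idx <- which(stats::runif(length(s)) < rate & s != "N")
      if (length(idx)) {
        repl <- vapply(s[idx], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
        s[idx] <- repl
      }
      out[i] <- paste(s, collapse = "")
    }
    res <- Biostrings::DNAStringSet(out)
    names(res) <- names(ss)
    res
  }
  new <- bundle
  new$chromosomes <- mutate_set(bundle$chromosomes)
  # re-mask the same spans on the diverged sequence
  masked <- as.character(new$chromosomes)
  if (length(bundle$reference_tes)) {
    for (i in seq_along(bundle$reference_tes)) {
      cn <- as.character(GenomicRanges::seqnames(bundle$reference_tes))[i]
      s <- GenomicRanges::start(bundle$reference_tes)[i]
      e <- GenomicRanges::end(bundle$reference_tes)[i]
      substr(masked[cn], s, e) <- strrep("N", e - s + 1L)
    }
  }
  new$masked_genome <- Biostrings::DNAStringSet(masked)
  names(new$masked_genome) <- names(bundle$chromosomes)
  if (diverge_te) new$te_library <- mutate_set(bundle$te_library)
  new
}

#' Restrict the TE library of a bundle to a subset of families
#' @param bundle a `ReferenceBundle`.
#' @param families character vector of family labels to keep.
#' @return a new `ReferenceBundle` with the restricted library.
#' @export
subset_te_library <- function(bundle, families) {
  assert_families(families)
  keep <- names(bundle$te_family)[bundle$te_family %in% families]
  if (!length(keep)) stop("no TE library members left after subsetting")
  new <- bundle
  new$te_library <- bundle$te_library[keep]
  new$te_family <- bundle$te_family[keep]
  new
}
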