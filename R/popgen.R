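site_compartment <- function(sites, pericentromeres) {
  if (is.null(pericentromeres) || length(pericentromeres) == 0L)
    return(rep("arms", nrow(sites)))
  gr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos_consensus,
                                                width = 1L))
  inside <- GenomicRanges::countOverlaps(gr, pericentromeres) > 0L
  ifelse(inside, "centromeric", "arms")
}

#' Per-individual TE copy numbers
#'
#' Counts, for each sample, the insertion sites with a non-absent call,
#' restricted to a genomic compartment (genome-wide, chromosome arms, or
#' pericentromeric/centromeric regions) and broken down by TE family.
#' Counting is presence-based by default (a heterozygous and a homozygous
#' call each contribute one site); `dosage = TRUE` counts homozygous calls
#' twice.
#'
#' @param x an `InsertionSites` object.
#' @param grouping one of `"genome_wide"`, `"arms"`, `"centromeric"`.
#' @param pericentromeres GRanges of pericentromere intervals; required
#'   unless `grouping = "genome_wide"`.
#' @param dosage count homozygous sites as 2 copies.
#' @return data.table: sample_id, family, n (every sample x family
#'   combination present, zero-filled), plus rows with `family = "all"`
#'   giving the per-sample totals.
#' @export
copy_number_per_individual <- function(x, grouping = c("genome_wide", "arms",
                                                       "centromeric"),
                                       pericentromeres = NULL,
                                       dosage = FALSE) {
  grouping <- match.arg(grouping)
  stopifnot(inherits(x, "InsertionSites"))
  if (grouping != "genome_wide" && is.null(pericentromeres))
    stop("pericentromere intervals are required for grouping = ", grouping)
  sites <- data.table::copy(x$sites)
  sites[, compartment := site_compartment(sites, pericentromeres)]
  keep_sites <- switch(grouping,
                       genome_wide = sites$site_id,
                       arms = sites[compartment == "arms", site_id],
                       centromeric = sites[compartment == "centromeric",
                                           site_id])
  calls <- x$calls[site_id %in% keep_sites]
  calls <- merge(calls, sites[, .(site_id, family)], by = "site_id")
  calls[, value := if (dosage) genotype_to_int(call) else 1L]
  grid <- data.table::CJ(sample_id = x$samples,
                         family = TE_FAMILIES, unique = TRUE)
  counts <- calls[, .(n = sum(value)), by = .(sample_id, family)]
  out <- merge(grid, counts, by = c("sample_id", "family"), all.x = TRUE)
  out[is.na(n), n := 0L]
  totals <- out[, .(family = "all", n = sum(n)), by = sample_id]
  out <- rbind(out, totals)
  data.table::setorder(out, sample_id, family)
  out[]
}

#' Copy-number table over all three compartments
#'
#' Convenience wrapper running [copy_number_per_individual()] for the
#' genome-wide, arms and centromeric groupings.
#'
#' @inheritParams copy_number_per_individual
#' @return data.table: sample_id, compartment, family, n.
#' @export
copy_number_table <- function(x, pericentromeres, dosage = FALSE) {
  out <- data.table::rbindlist(lapply(
    c("genome_wide", "arms", "centromeric"), function(g) {
      cn <- copy_number_per_individual(x, g, pericentromeres, dosage)
      cn[, compartment := g]
    }))
  data.table::setcolorder(out, c("sample_id", "compartment", "family", "n"))
  out[]
}

#' Population frequency of one insertion site
#'
#' For a selfing species every carrier is taken as homozygous, so the
#' frequency is the fraction of individuals in which the insertion was
#' detected.  For an outcrossing species each haplotype is an independent
#' sample: frequency = (2 x homozygous + heterozygous) / (2 x individuals).
#'
#' @param calls character vector of genotype calls (one per sampled
#'   individual, `"absent"`/`"heterozygous"`/`"homozygous"`).
#' @param mating_system `"selfing"` or `"outcrossing"`.
#' @return a proportion in `[0, 1]`.
#' @export
population_frequency <- function(calls, mating_system = c("selfing",
                                                          "outcrossing")) {
  mating_system <- match.arg(mating_system)
  if (length(calls) == 0L) stop("empty sample list")
  stopifnot(all(calls %in% c("absent", "heterozygous", "homozygous")))
  if (mating_system == "selfing") {
    mean(calls != "absent")
  } else {
    sum(genotype_to_int(calls)) / (2 * length(calls))
  }
}

#' Population frequencies of all sites, per species, with subsampling
#'
#' Applies [population_frequency()] site-wise after drawing a fixed random
#' subsample of individuals per species: by default 8 individuals for a
#' selfing species and half of that (4) for an outcrossing species, whose 8
#' haplotypes make the two mating systems comparable.
#'
#' @param x an `InsertionSites` object.
#' @param sample_sheet data.frame with columns sample_id, species,
#'   mating_system.
#' @param subsample named vector `c(selfing = 8, outcrossing = 4)`; species
#'   with fewer individuals use all of them.
#' @param seed integer seed for the subsample draw.
#' @return data.table: site_id, species, freq (sites at frequency 0 in the
#'   species subsample are retained with freq 0; spectra drop them).
#' @export
population_frequencies <- function(x, sample_sheet,
                                   subsample = c(selfing = 8L,
                                                 outcrossing = 4L),
                                   seed = 1L) {
  stopifnot(inherits(x, "InsertionSites"))
  sheet <- data.table::as.data.table(sample_sheet)
  stopifnot(all(c("sample_id", "species", "mating_system") %in% names(sheet)))
  m <- genotype_matrix(x)
  int_to_call <- c("absent", "heterozygous", "homozygous")
  out <- list()
  for (sp in unique(sheet$species)) {
    rows <- sheet[species == sp]
    ms <- rows$mating_system[1]
    k <- min(nrow(rows), subsample[[ms]])
    set.seed(substream_seed(seed, paste0("subsample:", sp)))
    chosen <- sort(sample(rows$sample_id, k))
    sub <- m[, chosen, drop = FALSE]
    freq <- if (ms == "selfing") {
      rowMeans(sub > 0L)
    } else {
      rowSums(sub) / (2 * ncol(sub))
    }
    out[[sp]] <- data.table::data.table(site_id = rownames(m), species = sp,
                                        freq = unname(freq))
  }
  data.table::rbindlist(out)
}

#' Site frequency spectrum with bootstrap confidence intervals
#'
#' Bins population frequencies over `(0, 1]` (right-closed bins) and
#' attaches percentile-bootstrap confidence intervals obtained by resampling
#' sites with replacement.
#'
#' @param frequencies numeric vector of population frequencies in `(0, 1]`
#'   (zeros are rejected: a site must segregate to enter the spectrum).
#' @param bin_edges increasing numeric vector from 0 to 1; default 8 bins of
#'   width 1/8, matching 8 sampled individuals (or haplotypes).
#' @param n_boot bootstrap replicates (default 200).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @param include_fixed keep sites at frequency 1; `FALSE` drops them before
#'   binning (spectra ignoring fixed insertions).
#' @param species,compartment labels stored on the result.
#' @return a `FrequencySpectrum`: list with bin_edges, proportions, ci_low,
#'   ci_high, n_sites, species, compartment.  With `n_sites = 0` the
#'   proportions are `NA` and `degenerate = TRUE`.
#' @export
frequency_spectrum <- function(frequencies, bin_edges = seq(0, 1, by = 0.125),
                               n_boot = 200L, conf = 0.95, seed = 1L,
                               include_fixed = TRUE, species = NA_character_,
                               compartment = "genome_wide") {
  stopifnot(all(frequencies > 0 & frequencies <= 1),
            isTRUE(all.equal(range(bin_edges), c(0, 1))),
            !is.unsorted(bin_edges, strictly = TRUE))
  f <- frequencies
  if (!include_fixed) f <- f[f < 1]
  nb <- length(bin_edges) - 1L
  bin_of <- function(v) pmin(pmax(findInterval(v, bin_edges,
                                               left.open = TRUE,
                                               rightmost.closed = TRUE),
                                  1L), nb)
  if (length(f) == 0L) {
    return(structure(list(bin_edges = bin_edges,
                          proportions = rep(NA_real_, nb),
                          ci_low = rep(NA_real_, nb),
                          ci_high = rep(NA_real_, nb),
                          n_sites = 0L, degenerate = TRUE,
                          species = species, compartment = compartment),
                     class = "FrequencySpectrum"))
  }
  bins <- bin_of(f)
  prop <- tabulate(bins, nbins = nb) / length(f)
  set.seed(substream_seed(seed, "bootstrap"))
  boot <- matrix(0, n_boot, nb)
  for (b in seq_len(n_boot)) {
    res <- bins[sample.int(length(bins), replace = TRUE)]
    boot[b, ] <- tabulate(res, nbins = nb) / length(bins)
  }
  alpha <- (1 - conf) / 2
  ci <- apply(boot, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  structure(list(bin_edges = bin_edges, proportions = prop,
                 ci_low = ci[1L, ], ci_high = ci[2L, ],
                 n_sites = length(f), degenerate = FALSE,
                 species = species, compartment = compartment),
            class = "FrequencySpectrum")
}

#' @export
print.FrequencySpectrum <- function(x, ...) {
  cat(sprintf("FrequencySpectrum: %s / %s, %d sites\n",
              x$species, x$compartment, x$n_sites))
  if (!x$degenerate) {
    nb <- length(x$proportions)
    lab <- sprintf("(%.3g,%.3g]", x$bin_edges[-(nb + 1L)], x$bin_edges[-1L])
    print(data.frame(bin = lab, proportion = round(x$proportions, 4),
                     ci_low = round(x$ci_low, 4),
                     ci_high = round(x$ci_high, 4)))
  }
  invisible(x)
}

#' Bin membership helper used by the spectrum (exposed for tests)
#' @noRd
spectrum_as_table <- function(spec) {
  nb <- length(spec$proportions)
  data.table::data.table(
    species = spec$species, compartment = spec$compartment,
    bin_low = spec$bin_edges[-(nb + 1L)], bin_high = spec$bin_edges[-1L],
    proportion = spec$proportions, ci_low = spec$ci_low,
    ci_high = spec$ci_high, n_sites = spec$n_sites)
}

#' Distance from insertion sites to the nearest gene
#'
#' Distance from the site's consensus position to the nearer edge of the
#' closest gene: 0 inside a gene, otherwise the number of base pairs from
#' the position to the gene boundary; `NA` when the site's chromosome has no
#' gene.
#'
#' @param x an `InsertionSites` object, or a data.frame with columns chrom
#'   and pos_consensus.
#' @param genes GRanges of gene intervals (e.g. `ReferenceBundle$genes`).
#' @return integer vector of distances, one per site.
#' @export
distance_to_nearest_gene <- function(x, genes) {
  sites <- if (inherits(x, "InsertionSites")) x$sites else
    data.table::as.data.table(x)
  if (nrow(sites) == 0L) return(integer())
  gr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos_consensus,
                                                width = 1L))
  d <- rep(NA_integer_, length(gr))
  if (length(genes) == 0L) return(d)
  lvls <- union(GenomeInfoDb::seqlevels(gr), GenomeInfoDb::seqlevels(genes))
  GenomeInfoDb::seqlevels(gr) <- lvls
  GenomeInfoDb::seqlevels(genes) <- lvls
  # half-open coordinate arithmetic: distance to an upstream gene is
  # pos0 - gene_end0 (exclusive end), to a downstream gene gene_start0 -
  # pos0, which makes the two flanks symmetric around the inter-gene gap
  pre <- GenomicRanges::precede(gr, genes, ignore.strand = TRUE)
  fol <- GenomicRanges::follow(gr, genes, ignore.strand = TRUE)
  d_down <- ifelse(is.na(pre), NA_integer_,
                   GenomicRanges::start(genes)[pre] -
                     GenomicRanges::start(gr))
  d_up <- ifelse(is.na(fol), NA_integer_,
                 GenomicRanges::start(gr) - 1L -
                   GenomicRanges::end(genes)[fol])
  d <- pmin(d_down, d_up, na.rm = TRUE)
  d[GenomicRanges::countOverlaps(gr, genes) > 0L] <- 0L
  as.integer(d)
}

#' Mean per-individual insertion counts in distance-to-gene bins
#'
#' Assigns each site to a bin `[k * bin_width, (k + 1) * bin_width)` of its
#' distance to the nearest gene, counts per-individual non-absent calls per
#' bin, and summarizes per species as mean and standard error across
#' individuals.
#'
#' @param x an `InsertionSites` object.
#' @param genes GRanges of gene intervals.
#' @param sample_sheet data.frame with sample_id and species columns.
#' @param bin_width bin width in bp (default 100).
#' @param max_distance largest distance kept (sites farther away are
#'   dropped); default 2000.
#' @return data.table: species, bin (index), bin_low, mean_count, se,
#'   n_individuals.
#' @export
bin_by_distance <- function(x, genes, sample_sheet, bin_width = 100L,
                            max_distance = 2000L) {
  stopifnot(inherits(x, "InsertionSites"))
  sheet <- data.table::as.data.table(sample_sheet)
  d <- distance_to_nearest_gene(x, genes)
  sites <- data.table::copy(x$sites)[, distance := d]
  sites <- sites[!is.na(distance) & distance <= max_distance]
  sites[, bin := distance %/% bin_width]
  calls <- merge(x$calls, sites[, .(site_id, bin)], by = "site_id")
  grid <- data.table::CJ(sample_id = x$samples,
                         bin = seq(0L, max_distance %/% bin_width))
  per_ind <- merge(grid, calls[, .(n = .N), by = .(sample_id, bin)],
                   by = c("sample_id", "bin"), all.x = TRUE)
  per_ind[is.na(n), n := 0L]
  per_ind <- merge(per_ind, sheet[, .(sample_id, species)], by = "sample_id")
  out <- per_ind[, .(
    mean_count = mean(n),
    se = stats::sd(n) / sqrt(.N),
    n_individuals = .N
  ), by = .(species, bin)]
  out[, bin_low := bin * bin_width]
  data.table::setcolorder(out, c("species", "bin", "bin_low", "mean_count",
                                 "se", "n_individuals"))
  data.table::setorder(out, species, bin)
  out[]
}
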