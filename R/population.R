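#' Describe a species population for simulation
#'
#' A species profile captures what downstream comparisons need: mating system
#' (selfers are fully homozygous; outcrossers draw two haplotypes per
#' individual under Hardy-Weinberg), sample size, the fraction of the shared
#' site pool segregating in the species, the site-frequency architecture of
#' segregating sites, and how strongly insertions are enriched in
#' pericentromeres.
#'
#' @param name species name.
#' @param mating_system `"selfing"` or `"outcrossing"`.
#' @param n_individuals number of sampled individuals (>= 1).
#' @param p_present probability that a site from the shared pool segregates
#'   in this species at all.
#' @param freq_sampler function(n) returning n true population frequencies in
#'   (0, 1] for segregating sites; e.g. `function(n) rbeta(n, 1.2, 1.2)`.
#' @param pericentromere_enrichment multiplier (>= 1) for the sampling weight
#'   of pericentromeric positions when this profile draws its own sites.
#' @return a `SpeciesProfile` (list).
#' @export
species_profile <- function(name, mating_system, n_individuals,
                            p_present = 1,
                            freq_sampler = function(n) stats::rbeta(n, 1.2, 1.2),
                            pericentromere_enrichment = 3) {
  mating_system <- match.arg(mating_system, c("selfing", "outcrossing"))
  stopifnot(n_individuals >= 1L, p_present >= 0, p_present <= 1,
            pericentromere_enrichment >= 1)
  structure(list(name = name, mating_system = mating_system,
                 n_individuals = as.integer(n_individuals),
                 p_present = p_present, freq_sampler = freq_sampler,
                 pericentromere_enrichment = pericentromere_enrichment),
            class = "SpeciesProfile")
}

#' Default three-species study design
#'
#' One outcrosser with 8 individuals and a rare-skewed frequency spectrum;
#' one recently selfing species with 24 individuals, a large TE complement
#' and intermediate frequencies; one older selfing species with 10
#' individuals, a reduced TE complement and an excess of high-frequency and
#' fixed insertions.  Sample sizes follow the 8/10/24 design of the study
#' this package emulates; frequency architectures are free simulation
#' parameters chosen to produce those qualitative contrasts.
#'
#' @param n_individuals optional named integer vector overriding the sample
#'   sizes, names `c("outcrosser", "selfer_recent", "selfer_old")`.
#' @return named list of three `SpeciesProfile`s.
#' @export
default_species_profiles <- function(n_individuals = c(outcrosser = 8L,
                                                       selfer_recent = 24L,
                                                       selfer_old = 10L)) {
  list(
    outcrosser = species_profile(
      "outcrosser", "outcrossing", n_individuals[["outcrosser"]],
      p_present = 0.9,
      freq_sampler = function(n) stats::rbeta(n, 0.6, 1.2)),
    selfer_recent = species_profile(
      "selfer_recent", "selfing", n_individuals[["selfer_recent"]],
      p_present = 0.95,
      freq_sampler = function(n) stats::rbeta(n, 1.3, 1.1)),
    selfer_old = species_profile(
      "selfer_old", "selfing", n_individuals[["selfer_old"]],
      p_present = 0.45,
      freq_sampler = function(n) stats::rbeta(n, 4, 1))
  )
}

#' Draw true TE insertion sites on a reference
#'
#' Sites are at least `edge_margin` bp from chromosome ends and pairwise at
#' least `min_spacing` bp apart; positions inside pericentromeres are
#' oversampled by `peri_enrichment`.  Each site is assigned a family (by
#' `family_weights`) and a concrete TE library member of that family.
#'
#' @param ref a `ReferenceBundle`.
#' @param n_sites number of sites to draw.
#' @param seed integer seed.
#' @param min_spacing minimum pairwise distance between sites (bp).
#' @param edge_margin minimum distance from chromosome ends (bp).
#' @param peri_enrichment sampling-weight multiplier inside pericentromeres.
#' @param family_weights named numeric vector of family sampling weights.
#' @return data.table: site_id, chrom, pos (1-based), family, te_id.
#' @export
draw_true_sites <- function(ref, n_sites, seed = 1L, min_spacing = 500L,
                            edge_margin = 500L, peri_enrichment = 3,
                            family_weights = c("LTR" = 0.59, "non-LTR" = 0.19,
                                               "DNA" = 0.11, "Helitron" = 0.11)) {
  assert_families(names(family_weights))
  set.seed(substream_seed(seed, "sites"))
  lens <- stats::setNames(Biostrings::width(ref$chromosomes),
                          names(ref$chromosomes))
  capacity <- sum(pmax(0, (lens - 2 * edge_margin) %/% min_spacing + 1L))
  if (n_sites > 0.5 * capacity)
    stop("cannot place ", n_sites, " sites ", min_spacing,
         " bp apart on this reference (capacity about ", capacity, ")")
  pc_start <- stats::setNames(rep(NA_integer_, length(lens)), names(lens))
  pc_end <- pc_start
  if (length(ref$pericentromeres)) {
    cn <- as.character(GenomicRanges::seqnames(ref$pericentromeres))
    pc_start[cn] <- GenomicRanges::start(ref$pericentromeres)
    pc_end[cn] <- GenomicRanges::end(ref$pericentromeres)
  }
  got_chrom <- character(); got_pos <- integer()
  n_try <- 0L
  while (length(got_pos) < n_sites) {
    n_try <- n_try + 1L
    if (n_try > 500L * max(1L, n_sites))
      stop("cannot place ", n_sites, " sites ", min_spacing,
           " bp apart on this reference")
    cn <- sample(names(lens), 1L, prob = lens)
    p <- sample(seq(edge_margin, lens[[cn]] - edge_margin), 1L)
    in_peri <- !is.na(pc_start[cn]) && p >= pc_start[cn] && p <= pc_end[cn]
    # rejection sampling implements the enrichment weight
    if (!in_peri && stats::runif(1) > 1 / peri_enrichment) next
    same <- got_chrom == cn
    if (any(same) && min(abs(got_pos[same] - p)) < min_spacing) next
    got_chrom <- c(got_chrom, cn); got_pos <- c(got_pos, p)
  }
  placed <- data.table::data.table(chrom = got_chrom, pos = got_pos)
  fams <- sample(names(family_weights), n_sites, replace = TRUE,
                 prob = family_weights)
  te_ids <- vapply(fams, function(f) {
    sample(names(ref$te_family)[ref$te_family == f], 1L)
  }, "")
  out <- data.table::data.table(chrom = placed$chrom, pos = placed$pos,
                                family = fams, te_id = te_ids)
  data.table::setorder(out, chrom, pos)
  out[, site_id := sprintf("true_%03d", .I)]
  data.table::setcolorder(out, c("site_id", "chrom", "pos", "family", "te_id"))
  out[]
}

#' Simulate true genotypes for one species population
#'
#' For selfing profiles every individual is fully homozygous: it carries a
#' site (copy count 2) with probability equal to the site's true population
#' frequency.  For outcrossing profiles two haplotypes are drawn
#' independently per individual (Hardy-Weinberg), so copy counts 0/1/2 occur
#' with probabilities \eqn{(1-f)^2, 2f(1-f), f^2}.
#'
#' @param ref a `ReferenceBundle`.
#' @param profile a `SpeciesProfile`.
#' @param n_true_sites number of candidate sites to draw when `sites` is not
#'   supplied.
#' @param seed integer seed.
#' @param sites optional site table from [draw_true_sites()]; supplying the
#'   same table to several species creates a shared site pool (the basis of
#'   cross-species sharing).
#' @return a `PopulationTruth`: list with `profile`, `sites` (site table plus
#'   per-site `true_freq`, 0 for sites not segregating in this species) and
#'   `individuals` (list of per-individual truth data.tables with columns
#'   sample_id, chrom, pos, family, te_id, copy_count, hap; hap in 1:2 marks
#'   the carrier haplotype of heterozygotes, NA for homozygotes).
#' @export
simulate_population <- function(ref, profile, n_true_sites = 50L, seed = 1L,
                                sites = NULL) {
  stopifnot(inherits(profile, "SpeciesProfile"))
  if (is.null(sites))
    sites <- draw_true_sites(ref, n_true_sites, seed = seed,
                             peri_enrichment = profile$pericentromere_enrichment)
  sites <- data.table::copy(data.table::as.data.table(sites))
  set.seed(substream_seed(seed, paste0("pop:", profile$name)))
  n_s <- nrow(sites)
  seg <- stats::runif(n_s) < profile$p_present
  freq <- numeric(n_s)
  freq[seg] <- profile$freq_sampler(sum(seg))
  freq <- pmin(pmax(freq, 0), 1)
  sites[, true_freq := freq]

  ids <- sprintf("%s_%02d", profile$name, seq_len(profile$n_individuals))
  individuals <- lapply(ids, function(sid) {
    if (profile$mating_system == "selfing") {
      carried <- stats::runif(n_s) < freq
      cc <- ifelse(carried, 2L, 0L)
      hp <- rep(NA_integer_, n_s)
    } else {
      h1 <- stats::runif(n_s) < freq
      h2 <- stats::runif(n_s) < freq
      cc <- as.integer(h1) + as.integer(h2)
      hp <- ifelse(cc == 1L, ifelse(h1, 1L, 2L), NA_integer_)
    }
    keep <- cc > 0L
    data.table::data.table(sample_id = sid, chrom = sites$chrom[keep],
                           pos = sites$pos[keep], family = sites$family[keep],
                           te_id = sites$te_id[keep],
                           copy_count = cc[keep], hap = hp[keep])
  })
  names(individuals) <- ids
  structure(list(profile = profile, sites = sites[],
                 individuals = individuals),
            class = "PopulationTruth")
}

#' @export
print.PopulationTruth <- function(x, ...) {
  cc <- vapply(x$individuals, nrow, 1L)
  cat(sprintf("PopulationTruth: %s (%s), %d individuals, %d/%d sites segregating\n",
              x$profile$name, x$profile$mating_system, length(x$individuals),
              sum(x$sites$true_freq > 0), nrow(x$sites)))
  cat(sprintf("  sites carried per individual: mean %.1f (range %d-%d)\n",
              mean(cc), min(cc), max(cc)))
  invisible(x)
}

#' Write a population truth table as TSV
#'
#' Columns: sample_id, chrom, pos0 (0-based), family, copy_count.
#'
#' @param pop a `PopulationTruth`.
#' @param path output TSV path.
#' @param header optional character vector of provenance header lines.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(pop, path, header = character()) {
  dt <- data.table::rbindlist(pop$individuals)
  out <- dt[, .(sample_id, chrom, pos0 = pos - 1L, family, copy_count)]
  write_tsv_header(out, path, header)
}

#' Simulate one study: shared site pool across several species
#'
#' Draws one pool of true TE sites on the reference and simulates each
#' species' genotypes over that pool, so that sites can be private to one
#' species or shared, as in multi-species comparisons.
#'
#' @param ref a `ReferenceBundle`.
#' @param profiles list of `SpeciesProfile`s.
#' @param n_sites size of the shared site pool.
#' @param seed integer seed.
#' @return list with `sites` (the pool) and `populations` (named list of
#'   `PopulationTruth`).
#' @export
simulate_study <- function(ref, profiles, n_sites = 50L, seed = 1L) {
  sites <- draw_true_sites(ref, n_sites, seed = seed)
  pops <- lapply(profiles, function(pr)
    simulate_population(ref, pr, seed = seed, sites = sites))
  names(pops) <- vapply(profiles, function(p) p$name, "")
  list(sites = sites, populations = pops)
}
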