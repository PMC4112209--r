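#' Call a genotype from an insertion frequency estimate
#'
#' Frequency above the high threshold is called homozygous; below the low
#' threshold the observation is treated as an error (absent); anything in
#' between, including exactly the two thresholds, is heterozygous (the
#' thresholds are stated as strict inequalities: "higher than 0.8",
#' "less than 0.2").
#'
#' @param freq_estimate frequency estimate(s) in `[0, 1]`; vectorized.
#' @param low,high the two thresholds, `0 <= low < high <= 1`.
#' @return character vector in `c("absent", "heterozygous", "homozygous")`.
#' @export
call_genotype <- function(freq_estimate, low = 0.2, high = 0.8) {
  stopifnot(low >= 0, high <= 1, low < high)
  if (any(is.na(freq_estimate)) ||
      any(freq_estimate < 0 | freq_estimate > 1))
    stop("freq_estimate must lie in [0, 1]")
  ifelse(freq_estimate > high, "homozygous",
         ifelse(freq_estimate < low, "absent", "heterozygous"))
}

genotype_to_int <- function(call) {
  c(absent = 0L, heterozygous = 1L, homozygous = 2L)[call]
}

#' Merge per-sample insertion observations into cross-sample sites
#'
#' Observations on the same chromosome (and, by default, of the same TE
#' family) are merged into one insertion site when their estimated positions
#' chain within `identity_window` bp of each other.  Two merge rules are
#' available: `"chain"` (default) links observations transitively whenever
#' consecutive sorted positions are within the window; `"anchor"` opens a
#' site at the first unassigned observation and admits only observations
#' within the window of that anchor.  Observations whose frequency falls in
#' the error band (below `low`) are dropped before merging; a sample can
#' still be recorded absent at a site seeded by other samples.
#'
#' Each site receives `pos_consensus` (floor of the mean member position) and
#' one genotype call per sample; a sample with several member observations at
#' one site contributes its best-supported one.
#'
#' @param observations `InsertionObservation` rows from any number of
#'   samples (rbind of [detect_insertions()] outputs).
#' @param identity_window merge window in bp (default 200).
#' @param low,high genotype thresholds passed to [call_genotype()].
#' @param samples optional character vector of all sample ids (samples that
#'   contributed no observation still get absent calls and matrix columns).
#' @param require_same_family merge only observations of one family
#'   (default TRUE; prevents chimeric sites).
#' @param method `"chain"` or `"anchor"`.
#' @return an `InsertionSites` object: list with `sites` (data.table:
#'   site_id, chrom, pos_consensus, family, n_members, pos_min, pos_max),
#'   `calls` (data.table: site_id, sample_id, call, freq, n_support; only
#'   non-absent calls stored) and `samples` (character vector).
#' @export
merge_across_samples <- function(observations, identity_window = 200L,
                                 low = 0.2, high = 0.8, samples = NULL,
                                 require_same_family = TRUE,
                                 method = c("chain", "anchor")) {
  method <- match.arg(method)
  obs <- data.table::copy(data.table::as.data.table(observations))
  samples <- sort(unique(c(samples, obs$sample_id)))
  obs <- obs[, call := call_genotype(freq_estimate, low, high)][
    call != "absent"]
  if (nrow(obs) == 0L) {
    return(structure(list(
      sites = data.table::data.table(
        site_id = character(), chrom = character(), pos_consensus = integer(),
        family = character(), n_members = integer(), pos_min = integer(),
        pos_max = integer()),
      calls = data.table::data.table(
        site_id = character(), sample_id = character(), call = character(),
        freq = numeric(), n_support = integer()),
      samples = samples), class = "InsertionSites"))
  }
  grp_cols <- if (require_same_family) c("chrom", "family") else "chrom"
  data.table::setorderv(obs, c(grp_cols, "pos_estimate", "sample_id"))
  if (method == "chain") {
    obs[, cluster := cumsum(c(TRUE, diff(pos_estimate) > identity_window)),
        by = grp_cols]
  } else {
    obs[, cluster := {
      cl <- integer(.N); anchor <- pos_estimate[1]; id <- 1L; cl[1] <- 1L
      for (i in seq_len(.N)[-1]) {
        if (pos_estimate[i] - anchor > identity_window) {
          id <- id + 1L; anchor <- pos_estimate[i]
        }
        cl[i] <- id
      }
      cl
    }, by = grp_cols]
  }
  if (!require_same_family) {
    # family of a mixed site = family of its best-supported member
    obs[, family := family[which.max(n_support_fwd + n_support_rev)],
        by = c(grp_cols, "cluster")]
  }
  sites <- obs[, .(
    pos_consensus = as.integer(floor(mean(pos_estimate))),
    n_members = .N,
    pos_min = min(pos_estimate),
    pos_max = max(pos_estimate)
  ), by = c(grp_cols, if (require_same_family) NULL else "family", "cluster")]
  if (!"family" %in% names(sites)) sites[, family := NA_character_]
  data.table::setorder(sites, chrom, pos_consensus, family)
  sites[, site_id := sprintf("site_%05d", .I)]
  # best member per (cluster, sample): max support, then max freq, then pos
  obs[, n_support := n_support_fwd + n_support_rev]
  best <- obs[order(-n_support, -freq_estimate, pos_estimate),
              .SD[1L],
              by = c(grp_cols, "cluster", "sample_id")]
  key_cols <- c(grp_cols, if (require_same_family) NULL else "family",
                "cluster")
  calls <- merge(best, sites[, c(key_cols, "site_id"), with = FALSE],
                 by = key_cols)[, .(
    site_id, sample_id, call, freq = freq_estimate, n_support)]
  data.table::setorder(calls, site_id, sample_id)
  sites[, cluster := NULL]
  data.table::setcolorder(sites, c("site_id", "chrom", "pos_consensus",
                                   "family", "n_members", "pos_min",
                                   "pos_max"))
  structure(list(sites = sites[], calls = calls[], samples = samples),
            class = "InsertionSites")
}

#' @export
print.InsertionSites <- function(x, ...) {
  cat(sprintf("InsertionSites: %d sites x %d samples (%d non-absent calls)\n",
              nrow(x$sites), length(x$samples), nrow(x$calls)))
  invisible(x)
}

#' Site-by-sample genotype matrix
#'
#' @param x an `InsertionSites` object.
#' @return integer matrix, rows = sites (rownames = site ids), columns =
#'   samples; 0 absent, 1 heterozygous, 2 homozygous.
#' @export
genotype_matrix <- function(x) {
  stopifnot(inherits(x, "InsertionSites"))
  m <- matrix(0L, nrow = nrow(x$sites), ncol = length(x$samples),
              dimnames = list(x$sites$site_id, x$samples))
  if (nrow(x$calls))
    m[cbind(match(x$calls$site_id, x$sites$site_id),
            match(x$calls$sample_id, x$samples))] <-
      genotype_to_int(x$calls$call)
  m
}

#' Species sharing of insertion sites
#'
#' A species is counted as carrying a site when at least one of its samples
#' has a non-absent call there; the per-subset counts over all sites
#' partition the site list (the Venn-diagram counts of cross-species
#' comparisons).
#'
#' @param x an `InsertionSites` object.
#' @param species_of named character vector mapping sample id to species.
#' @return data.table: site_id, species_subset (comma-joined sorted species
#'   names); the subset counts are `table(result$species_subset)`.
#' @export
classify_sharing <- function(x, species_of) {
  stopifnot(inherits(x, "InsertionSites"))
  missing_sp <- setdiff(x$samples, names(species_of))
  if (length(missing_sp))
    stop("no species assigned for sample(s): ",
         paste(missing_sp, collapse = ", "))
  calls <- data.table::copy(x$calls)
  calls[, species := unname(species_of[sample_id])]
  subsets <- calls[, .(species_subset = paste(sort(unique(species)),
                                              collapse = ",")),
                   by = site_id]
  out <- merge(x$sites[, .(site_id)], subsets, by = "site_id", all.x = TRUE)
  data.table::setorder(out, site_id)
  out[]
}

#' Write the site-by-sample genotype matrix as TSV
#'
#' Rows carry site_id, chrom, pos0 (0-based), family, then one integer
#' column per sample (0 absent, 1 heterozygous, 2 homozygous).
#'
#' @param x an `InsertionSites` object.
#' @param path output path.
#' @param header optional provenance header lines.
#' @return `path`, invisibly.
#' @export
write_site_matrix <- function(x, path, header = character()) {
  m <- genotype_matrix(x)
  out <- cbind(
    x$sites[, .(site_id, chrom, pos0 = pos_consensus - 1L, family)],
    data.table::as.data.table(m))
  write_tsv_header(out, path, header)
}

#' Write merged insertion sites as BED (0-based half-open)
#' @param x an `InsertionSites` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(x, path) {
  bed <- x$sites[, .(chrom, start = pos_consensus - 1L, end = pos_consensus,
                     name = site_id, score = n_members,
                     strand = ".")]
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
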