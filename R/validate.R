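#' Hybrid mixing check of genotype calling
#'
#' Runs detection on two fully homozygous ("selfed") parents and on the
#' hybrid sample obtained by merging their reads.  If frequency-based
#' genotype calling works, each pure parent's insertions concentrate at
#' inferred frequency near 1, while in the hybrid the sites carried by only
#' one parent drop toward 0.5 and are called heterozygous.
#'
#' @param parent1,parent2 lists with elements `fastq` (length-2 vector of
#'   mate files) and `truth` (the individual's truth table).
#' @param ref a `ReferenceBundle`.
#' @param params detection parameters, a [run_config()] or a plain list with
#'   read_length, insert_mean, insert_sd, cluster_window, min_support,
#'   freq_low, freq_high.
#' @param identity_window window (bp) for matching observations to true
#'   sites and across runs.
#' @param work_dir directory for the merged FASTQ (a tempdir by default).
#' @return list with `summary` (data.table: run, n_insertions, frac_high
#'   = fraction at frequency >= freq_high, frac_intermediate = fraction in
#'   [freq_low, freq_high]), `het_rate_discordant` (fraction of sites
#'   homozygous in exactly one parent that the hybrid calls heterozygous),
#'   `n_discordant_true`, and `pattern_holds` (hybrid frac_high below both
#'   parents' frac_high).
#' @export
hybrid_check <- function(parent1, parent2, ref, params = run_config(),
                         identity_window = 200L, work_dir = NULL) {
  work_dir <- work_dir %||% tempfile("hybrid_")
  dir.create(work_dir, recursive = TRUE, showWarnings = FALSE)
  p <- params
  det <- function(fq, sid) sample_observations(
    fq[[1]], fq[[2]], ref, sid,
    read_length = p$read_length, insert_mean = p$insert_mean,
    insert_sd = p$insert_sd, cluster_window = p$cluster_window,
    min_support = p$min_support)

  t1 <- data.table::as.data.table(parent1$truth)
  t2 <- data.table::as.data.table(parent2$truth)
  key1 <- paste(t1$chrom, t1$pos); key2 <- paste(t2$chrom, t2$pos)
  if (setequal(key1, key2))
    warning("parents carry identical insertion sets; hybrid check is ",
            "uninformative")

  merged <- merge_samples(list(parent1$fastq, parent2$fastq),
                          file.path(work_dir, "hybrid"))
  obs1 <- det(parent1$fastq, "parent1")
  obs2 <- det(parent2$fastq, "parent2")
  obsh <- det(c(merged$fastq1, merged$fastq2), "hybrid")

  frac <- function(obs) {
    keep <- obs[freq_estimate >= p$freq_low]
    data.table::data.table(
      n_insertions = nrow(keep),
      frac_high = mean(keep$freq_estimate >= p$freq_high),
      frac_intermediate = mean(keep$freq_estimate >= p$freq_low &
                               keep$freq_estimate <= p$freq_high))
  }
  summary <- cbind(run = c("parent1", "parent2", "hybrid"),
                   data.table::rbindlist(list(frac(obs1), frac(obs2),
                                              frac(obsh))))

  # sites homozygous in exactly one parent -> expect heterozygous in hybrid
  disc <- data.table::rbindlist(list(t1, t2))[, .N, by = .(chrom, pos)][
    N == 1L]
  het_rate <- NA_real_
  if (nrow(disc)) {
    calls <- vapply(seq_len(nrow(disc)), function(i) {
      hit <- obsh[chrom == disc$chrom[i] &
                  abs(pos_estimate - disc$pos[i]) <= identity_window]
      if (nrow(hit) == 0L) return(NA_character_)
      call_genotype(hit$freq_estimate[which.max(
        hit$n_support_fwd + hit$n_support_rev)],
        p$freq_low, p$freq_high)
    }, "")
    het_rate <- mean(calls == "heterozygous", na.rm = TRUE)
  }
  pattern <- summary$frac_high[3L] < summary$frac_high[1L] &&
    summary$frac_high[3L] < summary$frac_high[2L]
  list(summary = summary, het_rate_discordant = het_rate,
       n_discordant_true = nrow(disc), pattern_holds = pattern,
       observations = list(parent1 = obs1, parent2 = obs2, hybrid = obsh))
}

#' Pooled versus individual calling comparison
#'
#' Runs the pipeline once per individual (copy numbers from merged genotype
#' calls) and once on per-species pooled read sets (all individuals of a
#' species merged into one sample), then compares the species abundance
#' ranking between the two modes and whether the Kruskal-Wallis test agrees.
#' In pooled mode the per-site frequency estimates play the role of the
#' per-individual presence calls.
#'
#' @param species_sets named list (one element per species, >= 2) of lists
#'   with `fastqs` (list of per-individual length-2 FASTQ vectors) and
#'   `sample_ids` (character).
#' @param ref a `ReferenceBundle`.
#' @param params detection parameters ([run_config()] or compatible list).
#' @param work_dir directory for pooled FASTQ files.
#' @return list with `individual` (copy numbers, ranking, `te_test`),
#'   `pooled` (per-species site counts and frequency-based `te_test`,
#'   ranking), and `agreement` (rankings identical; both reject at 0.05 or
#'   both fail to).
#' @export
pooled_vs_individual <- function(species_sets, ref, params = run_config(),
                                 work_dir = NULL) {
  stopifnot(length(species_sets) >= 2L)
  work_dir <- work_dir %||% tempfile("pooled_")
  dir.create(work_dir, recursive = TRUE, showWarnings = FALSE)
  p <- params
  det <- function(fq, sid) sample_observations(
    fq[[1]], fq[[2]], ref, sid,
    read_length = p$read_length, insert_mean = p$insert_mean,
    insert_sd = p$insert_sd, cluster_window = p$cluster_window,
    min_support = p$min_support)

  # individual mode
  all_obs <- list(); sample_species <- character()
  for (sp in names(species_sets)) {
    ss <- species_sets[[sp]]
    for (i in seq_along(ss$fastqs)) {
      all_obs[[length(all_obs) + 1L]] <- det(ss$fastqs[[i]],
                                             ss$sample_ids[[i]])
      sample_species[ss$sample_ids[[i]]] <- sp
    }
  }
  sites <- merge_across_samples(data.table::rbindlist(all_obs),
                                identity_window = p$identity_window,
                                low = p$freq_low, high = p$freq_high,
                                samples = names(sample_species))
  cn <- copy_number_per_individual(sites, "genome_wide")[family == "all"]
  cn[, species := unname(sample_species[sample_id])]
  groups <- split(cn$n, cn$species)
  kw_ind <- if (min(lengths(groups)) >= 2L) kruskal_wallis(groups) else NULL
  means_ind <- vapply(groups, mean, 1)
  rank_ind <- names(sort(means_ind))

  # pooled mode: one merged sample per species
  pooled_counts <- numeric(); pooled_freqs <- list()
  for (sp in names(species_sets)) {
    ss <- species_sets[[sp]]
    if (length(ss$fastqs) == 1L) {
      fq <- ss$fastqs[[1L]]
    } else {
      m <- merge_samples(ss$fastqs, file.path(work_dir, paste0("pool_", sp)))
      fq <- c(m$fastq1, m$fastq2)
    }
    obs <- det(fq, paste0("pool_", sp))
    obs <- obs[freq_estimate >= p$freq_low]
    pooled_counts[sp] <- nrow(obs)
    pooled_freqs[[sp]] <- obs$freq_estimate
  }
  rank_pool <- names(sort(pooled_counts))
  kw_pool <- kruskal_wallis(pooled_freqs)

  agree_rank <- identical(rank_ind, rank_pool)
  agree_test <- if (is.null(kw_ind)) NA else
    (kw_ind$p_value < 0.05) == (kw_pool$p_value < 0.05)
  list(individual = list(copy_numbers = cn, ranking = rank_ind,
                         test = kw_ind, means = means_ind),
       pooled = list(site_counts = pooled_counts, ranking = rank_pool,
                     test = kw_pool),
       agreement = list(ranking = agree_rank, test = agree_test))
}

#' Reference and TE-database swap (reference-bias control)
#'
#' Re-runs detection for every sample against an alternative reference
#' bundle (for example a diverged copy of the genome produced by
#' [diverge_reference()], or a bundle with a restricted TE library from
#' [subset_te_library()]) and reports whether the between-species abundance
#' ordering observed under the original reference is preserved.
#'
#' @param samples data.frame/list with columns or elements `sample_id`,
#'   `species`, `fastq1`, `fastq2`.
#' @param ref the original `ReferenceBundle`.
#' @param alt_ref the alternative `ReferenceBundle`.
#' @param params detection parameters ([run_config()] or compatible list).
#' @return list with `per_species` (data.table: species, mean copy number
#'   under original and alternative reference), `ranking_original`,
#'   `ranking_alternative`, `ordering_preserved`.
#' @export
reference_swap <- function(samples, ref, alt_ref, params = run_config()) {
  s <- data.table::as.data.table(samples)
  p <- params
  count_mode <- function(bundle) {
    vapply(seq_len(nrow(s)), function(i) {
      obs <- sample_observations(
        s$fastq1[i], s$fastq2[i], bundle, s$sample_id[i],
        read_length = p$read_length, insert_mean = p$insert_mean,
        insert_sd = p$insert_sd, cluster_window = p$cluster_window,
        min_support = p$min_support)
      nrow(obs[freq_estimate >= p$freq_low])
    }, 1L)
  }
  s[, n_orig := count_mode(ref)]
  s[, n_alt := count_mode(alt_ref)]
  per_species <- s[, .(mean_original = mean(n_orig),
                       mean_alternative = mean(n_alt)), by = species]
  rank_orig <- per_species$species[order(per_species$mean_original)]
  rank_alt <- per_species$species[order(per_species$mean_alternative)]
  list(per_species = per_species[],
       ranking_original = rank_orig,
       ranking_alternative = rank_alt,
       ordering_preserved = identical(rank_orig, rank_alt))
}
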