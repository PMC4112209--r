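#' Build a validated pipeline configuration
#'
#' Collects every tunable constant of the pipeline with the standard
#' defaults: 200-bp cross-sample identity window, 0.2/0.8 genotype frequency
#' thresholds, cluster window of `insert_mean + 3 * insert_sd`, minimum
#' support of 2 pairs, 200 bootstrap replicates, 100-bp distance bins, and
#' subsampling of 8 individuals per selfing species and 4 per outcrossing
#' species for population frequencies.  All randomness in a run flows from
#' the single `seed` through named substreams ([substream_seed()]).
#'
#' @param seed root seed of the run.
#' @param coverage fold coverage simulated per individual.
#' @param read_length,insert_mean,insert_sd read geometry (bp).
#' @param error_rate per-base read error probability.
#' @param cluster_window within-sample clustering window; default
#'   `insert_mean + 3 * insert_sd`.
#' @param min_support minimum supporting pairs per observation.
#' @param min_mapq minimum MAPQ treated as uniquely mapped.
#' @param identity_window cross-sample site merge window (bp).
#' @param freq_low,freq_high genotype-call thresholds.
#' @param n_boot bootstrap replicates for spectrum confidence intervals.
#' @param bin_width distance-to-gene bin width (bp).
#' @param subsample named vector, individuals drawn per mating system for
#'   population frequencies.
#' @param n_chromosomes,chrom_length,n_genes,n_te_per_family,
#'   pericentromere_fraction synthetic reference geometry.
#' @param n_sites size of the simulated true-site pool.
#' @param n_individuals named integer vector of per-species sample sizes
#'   passed to [default_species_profiles()].
#' @param reference_dir optional directory with an existing reference bundle
#'   (skips reference simulation).
#' @param keep_sam write per-sample SAM files under the output directory.
#' @return a `RunConfig` (list).
#' @export
run_config <- function(seed = 1L,
                       coverage = 20,
                       read_length = 108L,
                       insert_mean = 300L,
                       insert_sd = 30L,
                       error_rate = 0,
                       cluster_window = NULL,
                       min_support = 2L,
                       min_mapq = 20L,
                       identity_window = 200L,
                       freq_low = 0.2,
                       freq_high = 0.8,
                       n_boot = 200L,
                       bin_width = 100L,
                       subsample = c(selfing = 8L, outcrossing = 4L),
                       n_chromosomes = 1L,
                       chrom_length = 500000L,
                       n_genes = 60L,
                       n_te_per_family = 2L,
                       pericentromere_fraction = 0.2,
                       n_sites = 50L,
                       n_individuals = c(outcrosser = 8L,
                                         selfer_recent = 24L,
                                         selfer_old = 10L),
                       reference_dir = NULL,
                       keep_sam = FALSE) {
  cluster_window <- cluster_window %||%
    as.integer(insert_mean + 3 * insert_sd)
  cfg <- list(seed = as.integer(seed), coverage = coverage,
              read_length = as.integer(read_length),
              insert_mean = insert_mean, insert_sd = insert_sd,
              error_rate = error_rate, cluster_window = cluster_window,
              min_support = as.integer(min_support),
              min_mapq = as.integer(min_mapq),
              identity_window = as.integer(identity_window),
              freq_low = freq_low, freq_high = freq_high,
              n_boot = as.integer(n_boot), bin_width = as.integer(bin_width),
              subsample = subsample, n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              n_te_per_family = as.integer(n_te_per_family),
              pericentromere_fraction = pericentromere_fraction,
              n_sites = as.integer(n_sites), n_individuals = n_individuals,
              reference_dir = reference_dir, keep_sam = keep_sam)
  validate_config(cfg)
  structure(cfg, class = "RunConfig")
}

validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(freq_low >= 0, freq_low < freq_high, freq_high <= 1,
              cluster_window > 0, identity_window > 0, bin_width > 0,
              min_support >= 1, coverage > 0,
              insert_mean > 2 * read_length,
              n_boot >= 1, all(subsample >= 1))
  })
  invisible(cfg)
}

config_header <- function(cfg) {
  sprintf("tepop config=%s seed=%d", object_hash(unclass(cfg)), cfg$seed)
}

PIPELINE_STAGES <- c("simulate", "detect", "genotype", "popgen", "compare",
                     "validate")

#' Run the pipeline stages on one output directory
#'
#' Stages communicate through files under `out_dir`, so any stage can be
#' rerun from an existing directory: `simulate` writes the reference bundle,
#' per-individual truth, the sample sheet and paired FASTQ files; `detect`
#' writes per-sample insertion observations (and SAM when configured);
#' `genotype` writes the merged site-by-sample matrix, a site BED and
#' sharing table; `popgen` writes copy-number, population-frequency,
#' spectrum and distance-bin tables; `compare` writes the statistical test
#' table; `validate` runs the hybrid, pooled-versus-individual and
#' reference-swap checks.  Every TSV carries a header line with the config
#' hash and seed; a rerun with the same config and seed is byte-identical.
#' On a stage failure that stage's outputs are removed before the error
#' propagates.
#'
#' @param config a `RunConfig` from [run_config()].
#' @param stages subset of
#'   `c("simulate", "detect", "genotype", "popgen", "compare", "validate")`.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) named list of per-stage output file paths.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "detect", "genotype",
                                    "popgen", "compare"),
                         out_dir) {
  stopifnot(inherits(config, "RunConfig"))
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown))
    stop("unknown stage(s): ", paste(unknown, collapse = ", "),
         " (valid: ", paste(PIPELINE_STAGES, collapse = ", "), ")")
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  for (st in stages) {
    fn <- switch(st, simulate = stage_simulate, detect = stage_detect,
                 genotype = stage_genotype, popgen = stage_popgen,
                 compare = stage_compare, validate = stage_validate)
    produced <- character()
    res <- tryCatch(fn(config, out_dir),
                    error = function(e) {
                      unlink(stage_outputs(st, out_dir), recursive = TRUE)
                      stop("stage '", st, "' failed: ", conditionMessage(e),
                           call. = FALSE)
                    })
    message(sprintf("[tepop] stage %-9s done (%s)", st,
                    paste(basename(unlist(res)), collapse = ", ")))
    outputs[[st]] <- res
  }
  invisible(outputs)
}

stage_outputs <- function(stage, out_dir) {
  switch(stage,
    simulate = file.path(out_dir, c("reference", "fastq", "truth.tsv",
                                    "sample_sheet.tsv", "true_sites.tsv")),
    detect = file.path(out_dir, c("observations", "sam")),
    genotype = file.path(out_dir, c("site_matrix.tsv", "sites.bed",
                                    "sharing.tsv")),
    popgen = file.path(out_dir, c("copy_numbers.tsv",
                                  "population_frequencies.tsv",
                                  "spectra.tsv", "distance_bins.tsv")),
    compare = file.path(out_dir, "tests.tsv"),
    validate = file.path(out_dir, "validation"))
}

require_inputs <- function(paths, stage, needed_from) {
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("stage '", stage, "' is missing input(s): ",
         paste(missing, collapse = ", "),
         "; run the '", needed_from, "' stage first")
  invisible(TRUE)
}

stage_simulate <- function(cfg, out_dir) {
  hdr <- config_header(cfg)
  if (!is.null(cfg$reference_dir)) {
    ref <- read_reference_bundle(cfg$reference_dir)
    write_reference_bundle(ref, file.path(out_dir, "reference"))
  } else {
    ref <- build_reference(cfg$n_chromosomes, cfg$chrom_length, cfg$n_genes,
                           cfg$n_te_per_family, cfg$pericentromere_fraction,
                           seed = cfg$seed)
    write_reference_bundle(ref, file.path(out_dir, "reference"))
  }
  profiles <- default_species_profiles(cfg$n_individuals)
  study <- simulate_study(ref, profiles, cfg$n_sites, cfg$seed)
  write_tsv_header(study$sites[, .(site_id, chrom, pos0 = pos - 1L, family,
                                   te_id)],
                   file.path(out_dir, "true_sites.tsv"), hdr)
  sheet <- data.table::rbindlist(lapply(study$populations, function(pop)
    data.table::data.table(sample_id = names(pop$individuals),
                           species = pop$profile$name,
                           mating_system = pop$profile$mating_system)))
  write_tsv_header(sheet, file.path(out_dir, "sample_sheet.tsv"), hdr)
  truth <- data.table::rbindlist(lapply(study$populations, function(pop)
    data.table::rbindlist(pop$individuals)))
  write_tsv_header(truth[, .(sample_id, chrom, pos0 = pos - 1L, family,
                             copy_count)],
                   file.path(out_dir, "truth.tsv"), hdr)
  fq_dir <- file.path(out_dir, "fastq")
  dir.create(fq_dir, showWarnings = FALSE)
  for (pop in study$populations) {
    for (sid in names(pop$individuals)) {
      simulate_reads(ref, pop$individuals[[sid]], cfg$coverage,
                     file.path(fq_dir, sid), cfg$read_length,
                     cfg$insert_mean, cfg$insert_sd, cfg$error_rate,
                     seed = cfg$seed, sample_id = sid)
    }
  }
  stage_outputs("simulate", out_dir)
}

stage_detect <- function(cfg, out_dir) {
  hdr <- config_header(cfg)
  sheet_path <- file.path(out_dir, "sample_sheet.tsv")
  ref_dir <- file.path(out_dir, "reference")
  require_inputs(c(sheet_path, ref_dir), "detect", "simulate")
  sheet <- read_tsv_header(sheet_path)
  ref <- read_reference_bundle(ref_dir)
  obs_dir <- file.path(out_dir, "observations")
  dir.create(obs_dir, showWarnings = FALSE)
  sam_dir <- file.path(out_dir, "sam")
  if (cfg$keep_sam) dir.create(sam_dir, showWarnings = FALSE)
  for (sid in sheet$sample_id) {
    fq1 <- file.path(out_dir, "fastq", paste0(sid, "_1.fastq"))
    fq2 <- file.path(out_dir, "fastq", paste0(sid, "_2.fastq"))
    require_inputs(c(fq1, fq2), "detect", "simulate")
    obs <- sample_observations(
      fq1, fq2, ref, sid, cfg$read_length, cfg$insert_mean, cfg$insert_sd,
      cfg$cluster_window, cfg$min_support, cfg$min_mapq,
      sam_path = if (cfg$keep_sam) file.path(sam_dir, paste0(sid, ".sam"))
                 else NULL)
    write_observations_tsv(obs, file.path(obs_dir, paste0(sid, ".tsv")), hdr)
  }
  if (cfg$keep_sam) stage_outputs("detect", out_dir) else
    file.path(out_dir, "observations")
}

read_all_observations <- function(out_dir, sheet) {
  files <- file.path(out_dir, "observations", paste0(sheet$sample_id, ".tsv"))
  require_inputs(files, "genotype", "detect")
  obs <- data.table::rbindlist(lapply(files, read_tsv_header))
  obs[, `:=`(pos_estimate = pos0 + 1L, freq_estimate = freq)]
  obs
}

stage_genotype <- function(cfg, out_dir) {
  hdr <- config_header(cfg)
  sheet <- read_tsv_header(file.path(out_dir, "sample_sheet.tsv"))
  obs <- read_all_observations(out_dir, sheet)
  sites <- merge_across_samples(obs, cfg$identity_window, cfg$freq_low,
                                cfg$freq_high, samples = sheet$sample_id)
  write_site_matrix(sites, file.path(out_dir, "site_matrix.tsv"), hdr)
  write_sites_bed(sites, file.path(out_dir, "sites.bed"))
  species_of <- stats::setNames(sheet$species, sheet$sample_id)
  sharing <- classify_sharing(sites, species_of)
  write_tsv_header(sharing, file.path(out_dir, "sharing.tsv"), hdr)
  stage_outputs("genotype", out_dir)
}

#' Rebuild an `InsertionSites` object from a written site matrix
#' @param path path to a `site_matrix.tsv` written by the genotype stage.
#' @return an `InsertionSites` object (member positions and per-call
#'   frequencies are not recoverable from the matrix; downstream summaries
#'   do not need them).
#' @export
read_site_matrix <- function(path) {
  dt <- read_tsv_header(path)
  meta <- c("site_id", "chrom", "pos0", "family")
  samples <- setdiff(names(dt), meta)
  sites <- dt[, .(site_id, chrom, pos_consensus = pos0 + 1L, family,
                  n_members = NA_integer_, pos_min = NA_integer_,
                  pos_max = NA_integer_)]
  m <- as.matrix(dt[, samples, with = FALSE])
  idx <- which(m > 0L, arr.ind = TRUE)
  calls <- data.table::data.table(
    site_id = sites$site_id[idx[, 1L]],
    sample_id = samples[idx[, 2L]],
    call = c("heterozygous", "homozygous")[m[idx]],
    freq = NA_real_, n_support = NA_integer_)
  data.table::setorder(calls, site_id, sample_id)
  structure(list(sites = sites, calls = calls, samples = samples),
            class = "InsertionSites")
}

stage_popgen <- function(cfg, out_dir) {
  hdr <- config_header(cfg)
  matrix_path <- file.path(out_dir, "site_matrix.tsv")
  require_inputs(matrix_path, "popgen", "genotype")
  sheet <- read_tsv_header(file.path(out_dir, "sample_sheet.tsv"))
  sites <- read_site_matrix(matrix_path)
  ref_dir <- file.path(out_dir, "reference")
  peri <- rtracklayer::import(file.path(ref_dir, "pericentromeres.bed"))
  genes <- rtracklayer::import(file.path(ref_dir, "genes.gff3"))

  cn <- copy_number_table(sites, peri)
  write_tsv_header(cn, file.path(out_dir, "copy_numbers.tsv"), hdr)

  pf <- population_frequencies(sites, sheet, cfg$subsample, cfg$seed)
  write_tsv_header(pf, file.path(out_dir, "population_frequencies.tsv"), hdr)

  comp_of <- site_compartment(sites$sites, peri)
  spectra <- list()
  for (sp in unique(sheet$species)) {
    freqs <- pf[species == sp & freq > 0]
    for (comp in c("genome_wide", "arms", "centromeric")) {
      keep <- if (comp == "genome_wide") freqs else
        freqs[site_id %in% sites$sites$site_id[comp_of ==
          if (comp == "arms") "arms" else "centromeric"]]
      sp_spec <- frequency_spectrum(keep$freq, n_boot = cfg$n_boot,
                                    seed = cfg$seed, species = sp,
                                    compartment = comp)
      spectra[[length(spectra) + 1L]] <- spectrum_as_table(sp_spec)
    }
  }
  write_tsv_header(data.table::rbindlist(spectra),
                   file.path(out_dir, "spectra.tsv"), hdr)

  bins <- bin_by_distance(sites, genes, sheet, cfg$bin_width)
  write_tsv_header(bins, file.path(out_dir, "distance_bins.tsv"), hdr)
  stage_outputs("popgen", out_dir)
}

stage_compare <- function(cfg, out_dir) {
  hdr <- config_header(cfg)
  cn_path <- file.path(out_dir, "copy_numbers.tsv")
  require_inputs(cn_path, "compare", "popgen")
  sheet <- read_tsv_header(file.path(out_dir, "sample_sheet.tsv"))
  cn <- read_tsv_header(cn_path)
  cn <- merge(cn, sheet[, .(sample_id, species)], by = "sample_id")
  rows <- list()
  add <- function(unit, tt) {
    rows[[length(rows) + 1L]] <<- data.table::data.table(
      test = tt$method, unit = unit, statistic_name = tt$statistic_name,
      statistic = signif(tt$statistic, 6), df = tt$df,
      p_value = signif(tt$p_value, 6))
  }
  gw <- cn[compartment == "genome_wide" & family == "all"]
  add("per-individual genome-wide copy number across species",
      kruskal_wallis(split(gw$n, gw$species)))
  arms <- cn[compartment == "arms" & family == "all"]
  add("per-individual arms copy number across species",
      kruskal_wallis(split(arms$n, arms$species)))
  for (sp in unique(cn$species)) {
    a <- cn[species == sp & compartment == "arms" & family == "all", n]
    c_ <- cn[species == sp & compartment == "centromeric" & family == "all",
             n]
    add(paste0("arms vs centromeric copy number, ", sp), rank_sum(a, c_))
  }
  out <- data.table::rbindlist(rows)
  write_tsv_header(out, file.path(out_dir, "tests.tsv"), hdr)
  stage_outputs("compare", out_dir)
}

stage_validate <- function(cfg, out_dir) {
  hdr <- config_header(cfg)
  sheet <- read_tsv_header(file.path(out_dir, "sample_sheet.tsv"))
  ref <- read_reference_bundle(file.path(out_dir, "reference"))
  truth <- read_tsv_header(file.path(out_dir, "truth.tsv"))
  truth[, pos := pos0 + 1L]
  val_dir <- file.path(out_dir, "validation")
  dir.create(val_dir, showWarnings = FALSE)
  fq_of <- function(sid) c(file.path(out_dir, "fastq",
                                     paste0(sid, "_1.fastq")),
                           file.path(out_dir, "fastq",
                                     paste0(sid, "_2.fastq")))
  log <- character()

  # hybrid check on the first two individuals of the first selfing species
  selfers <- sheet[mating_system == "selfing"]
  hc <- NULL
  if (nrow(selfers) >= 2L) {
    sp <- selfers$species[1]
    ids <- selfers[species == sp, sample_id][1:2]
    hc <- hybrid_check(
      list(fastq = fq_of(ids[1]), truth = truth[sample_id == ids[1]]),
      list(fastq = fq_of(ids[2]), truth = truth[sample_id == ids[2]]),
      ref, cfg, work_dir = val_dir)
    write_tsv_header(hc$summary, file.path(val_dir, "hybrid.tsv"), hdr)
    log <- c(log, sprintf(
      "hybrid check (%s, %s): pattern_holds=%s het_rate_discordant=%.3f",
      ids[1], ids[2], hc$pattern_holds, hc$het_rate_discordant))
  }

  # pooled vs individual over all species (2 individuals each, for speed)
  sets <- lapply(split(sheet, by = "species"), function(sh) {
    ids <- utils::head(sh$sample_id, 2L)
    list(fastqs = lapply(ids, fq_of), sample_ids = ids)
  })
  pv <- pooled_vs_individual(sets, ref, cfg, work_dir = val_dir)
  log <- c(log, sprintf(
    "pooled vs individual: ranking agreement=%s",
    pv$agreement$ranking))

  # reference swap against a 1%-diverged genome, 2 individuals per species
  sub <- sheet[, utils::head(.SD, 2L), by = species]
  alt <- diverge_reference(ref, 0.01, cfg$seed)
  rs <- reference_swap(
    data.table::data.table(sample_id = sub$sample_id, species = sub$species,
                           fastq1 = vapply(sub$sample_id,
                                           function(s) fq_of(s)[1], ""),
                           fastq2 = vapply(sub$sample_id,
                                           function(s) fq_of(s)[2], "")),
    ref, alt, cfg)
  write_tsv_header(rs$per_species, file.path(val_dir, "reference_swap.tsv"),
                   hdr)
  log <- c(log, sprintf("reference swap: ordering_preserved=%s",
                        rs$ordering_preserved))
  writeLines(log, file.path(val_dir, "validation.log"))
  stage_outputs("validate", out_dir)
}
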