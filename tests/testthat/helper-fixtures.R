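library(data.table)

# ---- session-level fixture cache (built once, reused across test files) ----
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

tiny_ref <- function() fixture("tiny_ref", function() {
  build_reference(n_chromosomes = 1L, chrom_length = 60000L, n_genes = 10L,
                  n_te_per_family = 2L, pericentromere_fraction = 0.2,
                  seed = 42L)
})

# a small simulated three-species study plus detected observations,
# shared by the genotyping/popgen/pipeline tests
tiny_study <- function() fixture("tiny_study", function() {
  ref <- tiny_ref()
  profs <- default_species_profiles(c(outcrosser = 3L, selfer_recent = 3L,
                                      selfer_old = 3L))
  study <- simulate_study(ref, profs, n_sites = 12L, seed = 11L)
  fq_dir <- file.path(tempdir(), "tiny_study_fq")
  dir.create(fq_dir, showWarnings = FALSE)
  obs <- list(); sheet <- list()
  for (pop in study$populations) {
    for (sid in names(pop$individuals)) {
      rr <- simulate_reads(ref, pop$individuals[[sid]], coverage = 20,
                           out_prefix = file.path(fq_dir, sid), seed = 11L,
                           sample_id = sid)
      obs[[sid]] <- sample_observations(rr$fastq1, rr$fastq2, ref, sid)
      sheet[[sid]] <- data.table(sample_id = sid, species = pop$profile$name,
                                 mating_system = pop$profile$mating_system)
    }
  }
  list(ref = ref, study = study, observations = rbindlist(obs),
       sample_sheet = rbindlist(sheet), fq_dir = fq_dir)
})

# minimal hand-built reference bundle for alignment edge cases
make_bundle <- function(chroms, masked = chroms, te_seqs = NULL,
                        te_family = NULL) {
  if (is.null(te_seqs)) {
    set.seed(99)
    te_seqs <- c(LTR_1 = paste(sample(c("A", "C", "G", "T"), 500,
                                      replace = TRUE), collapse = ""))
    te_family <- c(LTR_1 = "LTR")
  }
  structure(list(
    chromosomes = Biostrings::DNAStringSet(chroms),
    masked_genome = Biostrings::DNAStringSet(masked),
    genes = GenomicRanges::GRanges(),
    pericentromeres = GenomicRanges::GRanges(),
    te_library = Biostrings::DNAStringSet(te_seqs),
    te_family = te_family,
    reference_tes = GenomicRanges::GRanges()
  ), class = "ReferenceBundle")
}

write_fastq_pair <- function(r1, r2, prefix, names = NULL) {
  names <- names %||% sprintf("r%04d", seq_along(r1))
  s1 <- Biostrings::DNAStringSet(r1); names(s1) <- names
  s2 <- Biostrings::DNAStringSet(r2); names(s2) <- names
  q <- function(s) Biostrings::BStringSet(strrep("I", Biostrings::width(s)))
  Biostrings::writeXStringSet(s1, paste0(prefix, "_1.fastq"),
                              format = "fastq", qualities = q(s1))
  Biostrings::writeXStringSet(s2, paste0(prefix, "_2.fastq"),
                              format = "fastq", qualities = q(s2))
  c(paste0(prefix, "_1.fastq"), paste0(prefix, "_2.fastq"))
}

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

# build a PairEvidence table directly (positions are the proximal ends of
# supporting mates; spanning rows carry their inner interval)
make_evidence <- function(fwd = integer(), rev = integer(),
                          span = list(), chrom = "chr1", family = "LTR") {
  rows <- list()
  if (length(fwd))
    rows$f <- data.table(read_id = sprintf("f%03d", seq_along(fwd)),
                         chrom = chrom, genomic_pos = as.integer(fwd),
                         side = "forward", te_id = paste0(family, "_1"),
                         te_family = family, kind = "supporting",
                         inner_start = NA_integer_, inner_end = NA_integer_)
  if (length(rev))
    rows$r <- data.table(read_id = sprintf("r%03d", seq_along(rev)),
                         chrom = chrom, genomic_pos = as.integer(rev),
                         side = "reverse", te_id = paste0(family, "_1"),
                         te_family = family, kind = "supporting",
                         inner_start = NA_integer_, inner_end = NA_integer_)
  if (length(span))
    rows$s <- data.table(read_id = sprintf("s%03d", seq_along(span)),
                         chrom = chrom,
                         genomic_pos = vapply(span, `[`, 1L, 1),
                         side = NA_character_, te_id = NA_character_,
                         te_family = NA_character_, kind = "spanning",
                         inner_start = vapply(span, `[`, 1L, 1),
                         inner_end = vapply(span, `[`, 1L, 2))
  rbindlist(rows)
}

# ---- independent oracles -------------------------------------------------

# transitive closure of the |p_i - p_j| <= window relation, by fixed-point
# label propagation over the full pairwise adjacency matrix
closure_clusters <- function(pos, window) {
  n <- length(pos)
  if (n == 0L) return(integer())
  adj <- abs(outer(pos, pos, "-")) <= window
  lab <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) min(lab[adj[i, ]]), 1L)
    if (identical(new, lab)) break
    lab <- new
  }
  match(lab, unique(lab))
}

# Kruskal-Wallis H by the rank formula (no ties assumed)
kw_h_oracle <- function(groups) {
  x <- unlist(groups)
  r <- rank(x)
  n <- length(x)
  idx <- rep(seq_along(groups), lengths(groups))
  rs <- tapply(r, idx, sum)
  12 / (n * (n + 1)) * sum(rs^2 / lengths(groups)) - 3 * (n + 1)
}

# exact signed-rank null distribution by enumeration of all sign vectors
signed_rank_enumeration <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  n <- length(d)
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_two <- min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
  list(V = v_obs, p = p_two)
}

# match observations/sites to true site positions within a tolerance;
# returns per-true-site index of the nearest detected position (or NA)
match_to_truth <- function(det_chrom, det_pos, true_chrom, true_pos,
                           tol = 200L) {
  vapply(seq_along(true_pos), function(i) {
    j <- which(det_chrom == true_chrom[i] &
               abs(det_pos - true_pos[i]) <= tol)
    if (!length(j)) NA_integer_ else
      j[which.min(abs(det_pos[j] - true_pos[i]))]
  }, 1L)
}
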