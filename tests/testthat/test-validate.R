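# small simulated parents used by the hybrid tests
hybrid_fixture <- function() fixture("hybrid_fixture", function() {
  ref <- tiny_ref()
  sites <- draw_true_sites(ref, 10L, seed = 21L)
  mk_parent <- function(rows, sid, seed) {
    truth <- data.table(sample_id = sid, chrom = sites$chrom[rows],
                        pos = sites$pos[rows], family = sites$family[rows],
                        te_id = sites$te_id[rows], copy_count = 2L,
                        hap = NA_integer_)
    rr <- simulate_reads(ref, truth, coverage = 30,
                         out_prefix = file.path(tempdir(), sid), seed = seed,
                         sample_id = sid)
    list(fastq = c(rr$fastq1, rr$fastq2), truth = truth)
  }
  list(ref = ref, sites = sites,
       p1 = mk_parent(1:5, "par1", 21L),
       p2 = mk_parent(6:10, "par2", 22L),
       p1b = mk_parent(1:5, "par1b", 23L))
})

test_that("hybrid of disjoint homozygous parents shifts to heterozygous", {
  hf <- hybrid_fixture()
  res <- hybrid_check(hf$p1, hf$p2, hf$ref)
  expect_true(res$pattern_holds)
  # pure parents: nearly all insertions at high inferred frequency
  expect_gte(res$summary[run == "parent1", frac_high], 0.9)
  expect_gte(res$summary[run == "parent2", frac_high], 0.9)
  # all 10 true sites are discordant; most become heterozygous in the hybrid
  expect_equal(res$n_discordant_true, 10L)
  expect_gte(res$het_rate_discordant, 0.8)
})

test_that("hybrid of identical parents warns and changes nothing", {
  hf <- hybrid_fixture()
  expect_warning(res <- hybrid_check(hf$p1, hf$p1b, hf$ref),
                 "identical insertion sets")
  expect_gte(res$summary[run == "hybrid", frac_high], 0.9)
})

test_that("merged detection equals union of evidence regardless of order", {
  hf <- hybrid_fixture()
  m12 <- merge_samples(list(hf$p1$fastq, hf$p2$fastq),
                       file.path(tempdir(), "m12"))
  m21 <- merge_samples(list(hf$p2$fastq, hf$p1$fastq),
                       file.path(tempdir(), "m21"))
  o12 <- sample_observations(m12$fastq1, m12$fastq2, hf$ref, "m")
  o21 <- sample_observations(m21$fastq1, m21$fastq2, hf$ref, "m")
  expect_identical(o12, o21)
})

test_that("pooled and individual modes rank species identically", {
  st <- tiny_study()
  sets <- lapply(split(st$sample_sheet, by = "species"), function(sh) {
    list(fastqs = lapply(sh$sample_id, function(s)
      c(file.path(st$fq_dir, paste0(s, "_1.fastq")),
        file.path(st$fq_dir, paste0(s, "_2.fastq")))),
      sample_ids = sh$sample_id)
  })
  res <- pooled_vs_individual(sets, st$ref, work_dir = tempdir())
  expect_true(res$agreement$ranking)
  expect_equal(sort(names(res$pooled$site_counts)),
               sort(unique(st$sample_sheet$species)))
})

test_that("single-individual species make pooled mode an identity", {
  st <- tiny_study()
  one <- st$sample_sheet[, .SD[1], by = species]
  sets <- lapply(split(one, by = "species"), function(sh) {
    list(fastqs = list(c(file.path(st$fq_dir, paste0(sh$sample_id, "_1.fastq")),
                         file.path(st$fq_dir, paste0(sh$sample_id, "_2.fastq")))),
      sample_ids = sh$sample_id)
  })
  res <- pooled_vs_individual(sets, st$ref, work_dir = tempdir())
  # per-species pooled site counts equal the single individual's counts
  ind <- res$individual$copy_numbers
  for (sp in names(res$pooled$site_counts))
    expect_equal(unname(res$pooled$site_counts[sp]), ind[species == sp, n])
})

test_that("reference swap with the original reference is an identity", {
  hf <- hybrid_fixture()
  samples <- data.table(sample_id = c("par1", "par2"),
                        species = c("A", "B"),
                        fastq1 = c(hf$p1$fastq[1], hf$p2$fastq[1]),
                        fastq2 = c(hf$p1$fastq[2], hf$p2$fastq[2]))
  res <- reference_swap(samples, hf$ref, hf$ref)
  expect_equal(res$per_species$mean_original, res$per_species$mean_alternative)
  expect_true(res$ordering_preserved)
})

test_that("restricting the TE database drops only the excluded families", {
  hf <- hybrid_fixture()
  keep <- c("LTR", "non-LTR")
  sub <- subset_te_library(hf$ref, keep)
  obs_full <- sample_observations(hf$p1$fastq[1], hf$p1$fastq[2], hf$ref,
                                  "par1")
  obs_sub <- sample_observations(hf$p1$fastq[1], hf$p1$fastq[2], sub, "par1")
  expect_equal(obs_sub[family %in% keep],
               obs_full[family %in% keep])
  expect_equal(nrow(obs_sub[!family %in% keep]), 0L)
})
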