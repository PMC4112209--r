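make_sites <- function(pos, family, calls_by_sample, chrom = "chr1") {
  # calls_by_sample: named list sample -> character vector (one per site)
  sites <- data.table(site_id = sprintf("site_%05d", seq_along(pos)),
                      chrom = chrom, pos_consensus = as.integer(pos),
                      family = family, n_members = 1L,
                      pos_min = as.integer(pos), pos_max = as.integer(pos))
  calls <- rbindlist(lapply(names(calls_by_sample), function(s) {
    cc <- calls_by_sample[[s]]
    keep <- cc != "absent"
    data.table(site_id = sites$site_id[keep], sample_id = s,
               call = cc[keep], freq = NA_real_, n_support = NA_integer_)
  }))
  setorder(calls, site_id, sample_id)
  structure(list(sites = sites, calls = calls,
                 samples = sort(names(calls_by_sample))),
            class = "InsertionSites")
}

peri_gr <- function(start, end, chrom = "chr1")
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))

test_that("copy numbers count present sites, with optional dosage", {
  x <- make_sites(pos = c(100, 200, 300, 400, 500) * 10L,
                  family = c("LTR", "LTR", "DNA", "Helitron", "non-LTR"),
                  calls_by_sample = list(
                    s1 = c("homozygous", "homozygous", "homozygous",
                           "heterozygous", "heterozygous"),
                    s2 = c("absent", "absent", "absent", "absent", "absent")))
  cn <- copy_number_per_individual(x, "genome_wide")
  expect_equal(cn[sample_id == "s1" & family == "all", n], 5L)
  expect_equal(cn[sample_id == "s2" & family == "all", n], 0L)
  expect_equal(cn[sample_id == "s1" & family == "LTR", n], 2L)
  dos <- copy_number_per_individual(x, "genome_wide", dosage = TRUE)
  expect_equal(dos[sample_id == "s1" & family == "all", n], 8L)  # 3*2 + 2*1
})

test_that("compartment counts partition the genome-wide counts", {
  x <- make_sites(pos = c(1000L, 2500L, 3000L, 9000L),
                  family = rep("LTR", 4),
                  calls_by_sample = list(
                    s1 = rep("homozygous", 4),
                    s2 = c("heterozygous", "absent", "heterozygous",
                           "absent")))
  peri <- peri_gr(2000L, 4000L)
  gw <- copy_number_per_individual(x, "genome_wide", peri)
  arms <- copy_number_per_individual(x, "arms", peri)
  cen <- copy_number_per_individual(x, "centromeric", peri)
  merged <- merge(arms, cen, by = c("sample_id", "family"))
  merged <- merge(merged, gw, by = c("sample_id", "family"))
  expect_equal(merged$n.x + merged$n.y, merged$n)
  expect_equal(cen[sample_id == "s1" & family == "all", n], 2L)
  expect_error(copy_number_per_individual(x, "arms"), "pericentromere")
})

test_that("population frequency follows the selfer and outcrosser formulas", {
  expect_equal(population_frequency(
    c(rep("homozygous", 4), rep("absent", 4)), "selfing"), 0.5)
  # outcrossing: haplotype counting; verify against explicit enumeration
  calls <- c("homozygous", "homozygous", "heterozygous", "absent")
  hap_oracle <- sum(c(homozygous = 2, heterozygous = 1, absent = 0)[calls]) /
    (2 * length(calls))
  expect_equal(population_frequency(calls, "outcrossing"), hap_oracle)
  expect_equal(hap_oracle, 0.625)
  expect_equal(population_frequency(rep("homozygous", 8), "selfing"), 1.0)
  # selfers treat stray heterozygous calls as carriers
  expect_equal(population_frequency(
    c("heterozygous", "absent"), "selfing"), 0.5)
  expect_error(population_frequency(character(), "selfing"), "empty")
})

test_that("species subsampling is seeded and sized per mating system", {
  x <- make_sites(pos = c(1000L, 2000L),
                  family = c("LTR", "DNA"),
                  calls_by_sample = setNames(
                    rep(list(c("homozygous", "absent")), 12),
                    sprintf("s%02d", 1:12)))
  sheet <- data.table(sample_id = sprintf("s%02d", 1:12), species = "sp",
                      mating_system = "selfing")
  f1 <- population_frequencies(x, sheet, seed = 5L)
  f2 <- population_frequencies(x, sheet, seed = 5L)
  expect_identical(f1, f2)
  expect_equal(f1$freq, c(1, 0))  # all carriers / no carriers
})

test_that("frequency spectra bin correctly and honour include_fixed", {
  spec <- frequency_spectrum(rep(1, 10), n_boot = 50L, seed = 1L)
  expect_equal(spec$n_sites, 10L)
  expect_equal(spec$proportions[8], 1)
  expect_equal(spec$ci_low[8], 1)
  expect_equal(spec$ci_high[8], 1)
  expect_equal(sum(spec$proportions), 1)
  nofix <- frequency_spectrum(rep(1, 10), include_fixed = FALSE,
                              n_boot = 50L, seed = 1L)
  expect_equal(nofix$n_sites, 0L)
  expect_true(nofix$degenerate)
  expect_error(frequency_spectrum(c(0, 0.5)), "frequencies > 0")
  # right-closed bins: 1/8 falls in the first bin
  spec2 <- frequency_spectrum(c(1 / 8, 2 / 8, 1), n_boot = 10L, seed = 1L)
  expect_equal(which(spec2$proportions > 0), c(1L, 2L, 8L))
})

test_that("spectrum confidence intervals bracket the point estimate", {
  set.seed(9)
  f <- sample(seq(0.125, 1, by = 0.125), 200, replace = TRUE,
              prob = c(4, 3, 2, 1, 1, 1, 1, 2))
  spec <- frequency_spectrum(f, n_boot = 200L, seed = 2L)
  expect_true(all(spec$ci_low <= spec$proportions + 1e-12))
  expect_true(all(spec$ci_high >= spec$proportions - 1e-12))
  expect_equal(sum(spec$proportions), 1, tolerance = 1e-12)
})

test_that("distance to the nearest gene handles all placements", {
  genes <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(1301L, 2501L),
                                                   c(2000L, 3500L)))
  sites <- data.table(chrom = "chr1",
                      pos_consensus = c(1201L, 1500L, 2251L, 5000L))
  d <- distance_to_nearest_gene(sites, genes)
  expect_equal(d[1], 100L)  # 100 bp upstream of the first gene
  expect_equal(d[2], 0L)    # inside a gene
  expect_equal(d[3], 250L)  # equidistant between the two genes
  expect_equal(d[4], 1499L) # past the exclusive end of the last gene
  # chromosome without genes -> NA
  s2 <- data.table(chrom = "chr9", pos_consensus = 100L)
  expect_true(is.na(distance_to_nearest_gene(s2, genes)))
})

test_that("distance bins are half-open multiples of the bin width", {
  genes <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(10001L, 12000L))
  # three sites at distances 50, 60, 150 -> bin0 = 2, bin1 = 1
  x <- make_sites(pos = 10001L - c(50L, 60L, 150L),
                  family = rep("LTR", 3),
                  calls_by_sample = list(s1 = rep("homozygous", 3)))
  sheet <- data.table(sample_id = "s1", species = "sp",
                      mating_system = "selfing")
  bins <- bin_by_distance(x, genes, sheet, bin_width = 100L,
                          max_distance = 500L)
  expect_equal(bins[bin == 0L, mean_count], 2)
  expect_equal(bins[bin == 1L, mean_count], 1)
  expect_equal(bins[bin == 2L, mean_count], 0)
  # distance exactly 100 belongs to bin 1, distance 0 to bin 0
  x2 <- make_sites(pos = c(10001L - 100L, 10500L),
                   family = c("LTR", "LTR"),
                   calls_by_sample = list(s1 = rep("homozygous", 2)))
  b2 <- bin_by_distance(x2, genes, sheet, bin_width = 100L,
                        max_distance = 500L)
  expect_equal(b2[bin == 1L, mean_count], 1)
  expect_equal(b2[bin == 0L, mean_count], 1)
})
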