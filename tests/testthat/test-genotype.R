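make_obs <- function(sample_id, pos, family = "LTR", freq = 1,
                     chrom = "chr1", nf = 3L, nr = 3L) {
  data.table(sample_id = sample_id, chrom = chrom,
             pos_estimate = as.integer(pos), family = family,
             n_support_fwd = nf, n_support_rev = nr,
             n_spanning = as.integer(round(
               (nf + nr) * (1 - freq) / max(freq, 1e-9))),
             freq_estimate = freq, both_sided = TRUE)
}

test_that("genotype thresholds follow the strict 0.2/0.8 rule", {
  expect_equal(call_genotype(0.9), "homozygous")
  expect_equal(call_genotype(0.1), "absent")
  expect_equal(call_genotype(0.5), "heterozygous")
  # the thresholds themselves fall in the heterozygous band
  expect_equal(call_genotype(0.8), "heterozygous")
  expect_equal(call_genotype(0.2), "heterozygous")
  expect_equal(call_genotype(c(1, 0, 0.79999, 0.80001)),
               c("homozygous", "absent", "heterozygous", "homozygous"))
  expect_error(call_genotype(1.2), "\\[0, 1\\]")
  expect_error(call_genotype(-0.1), "\\[0, 1\\]")
})

test_that("cross-sample merging chains within 200 bp", {
  obs <- rbind(make_obs("A", 100L), make_obs("B", 250L))
  x <- merge_across_samples(obs)
  expect_equal(nrow(x$sites), 1L)
  expect_equal(x$sites$pos_consensus, 175L)  # floor(mean(100, 250))
  expect_equal(nrow(x$calls), 2L)

  obs <- rbind(make_obs("A", 100L), make_obs("B", 250L), make_obs("C", 460L))
  x <- merge_across_samples(obs)
  # 250 -> 460 gap is 210 > 200: two sites
  expect_equal(x$sites$pos_consensus, c(175L, 460L))
  expect_equal(x$sites$n_members, c(2L, 1L))

  # same position, different family: never merged
  obs <- rbind(make_obs("A", 100L, family = "LTR"),
               make_obs("B", 100L, family = "Helitron"))
  x <- merge_across_samples(obs)
  expect_equal(nrow(x$sites), 2L)
})

test_that("chained merging equals the transitive-closure oracle", {
  set.seed(23)
  for (rep in 1:30) {
    n <- sample(2:60, 1)
    pos <- sample.int(5000L, n, replace = TRUE)
    obs <- make_obs(sprintf("s%02d", seq_len(n)), pos)
    x <- merge_across_samples(obs, identity_window = 200L)
    oracle <- closure_clusters(pos, 200L)
    expect_equal(nrow(x$sites), length(unique(oracle)))
    got <- x$calls[, .N, by = site_id][order(-N), N]
    want <- sort(as.integer(table(oracle)), decreasing = TRUE)
    expect_equal(got, want)
  }
})

test_that("error-band observations are dropped but samples stay in the matrix", {
  obs <- rbind(make_obs("A", 1000L, freq = 1),
               make_obs("B", 1010L, freq = 0.1),   # error band: dropped
               make_obs("B", 5000L, freq = 0.5))
  x <- merge_across_samples(obs, samples = c("A", "B", "C"))
  m <- genotype_matrix(x)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(colnames(m), c("A", "B", "C"))
  s1 <- x$sites[pos_consensus == 1000L, site_id]
  s2 <- x$sites[pos_consensus == 5000L, site_id]
  expect_equal(unname(m[s1, ]), c(2L, 0L, 0L))  # B absent despite its obs
  expect_equal(unname(m[s2, ]), c(0L, 1L, 0L))
})

test_that("a sample's best-supported member provides its call", {
  obs <- rbind(make_obs("A", 1000L, freq = 0.5, nf = 2L, nr = 2L),
               make_obs("A", 1100L, freq = 1, nf = 10L, nr = 10L))
  x <- merge_across_samples(obs)
  expect_equal(nrow(x$sites), 1L)
  expect_equal(x$calls$call, "homozygous")
})

test_that("anchor-based merging respects the window from the anchor", {
  obs <- rbind(make_obs("A", 100L), make_obs("B", 250L), make_obs("C", 390L))
  chain <- merge_across_samples(obs, method = "chain")
  anchor <- merge_across_samples(obs, method = "anchor")
  expect_equal(nrow(chain$sites), 1L)   # 100-250-390 chains
  expect_equal(nrow(anchor$sites), 2L)  # 390 is > 200 from anchor 100
})

test_that("species sharing subsets partition the site list", {
  st <- tiny_study()
  x <- merge_across_samples(st$observations,
                            samples = st$sample_sheet$sample_id)
  species_of <- setNames(st$sample_sheet$species, st$sample_sheet$sample_id)
  sh <- classify_sharing(x, species_of)
  expect_equal(nrow(sh), nrow(x$sites))
  expect_equal(sum(table(sh$species_subset)), nrow(x$sites))
  expect_false(anyNA(sh$species_subset))
  expect_error(classify_sharing(x, species_of[-1]), "no species assigned")
})

test_that("merging is invariant to observation order", {
  st <- tiny_study()
  obs <- st$observations
  x1 <- merge_across_samples(obs)
  x2 <- merge_across_samples(obs[sample.int(nrow(obs))])
  expect_identical(x1$sites, x2$sites)
  expect_identical(x1$calls, x2$calls)
})
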