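test_that("pair count follows coverage * G / (2 * read_length)", {
  ref <- tiny_ref()
  truth <- data.table(sample_id = character(), chrom = character(),
                      pos = integer(), family = character(),
                      te_id = character(), copy_count = integer(),
                      hap = integer())
  rr <- simulate_reads(ref, truth, coverage = 20,
                       out_prefix = tempfile(), seed = 1L, sample_id = "x")
  expected <- 20 * 60000 / (2 * 108)
  expect_lt(abs(rr$n_pairs - expected), 5 * sqrt(expected))
})

test_that("error-free reads from an insertion-free genome are reference substrings", {
  ref <- tiny_ref()
  truth <- data.table(sample_id = character(), chrom = character(),
                      pos = integer(), family = character(),
                      te_id = character(), copy_count = integer(),
                      hap = integer())
  rr <- simulate_reads(ref, truth, coverage = 2,
                       out_prefix = tempfile(), seed = 2L, sample_id = "x")
  r1 <- Biostrings::readDNAStringSet(rr$fastq1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(rr$fastq2, format = "fastq")
  genome <- ref$chromosomes[[1]]
  hits1 <- Biostrings::countPDict(Biostrings::PDict(r1), genome)
  # mate 2 is written reverse-complemented, so it matches on the minus strand
  hits2 <- Biostrings::countPDict(
    Biostrings::PDict(Biostrings::reverseComplement(r2)), genome)
  expect_true(all(hits1 >= 1L))
  expect_true(all(hits2 >= 1L))
})

test_that("junction-spanning pair yield matches the coverage expectation", {
  ref <- tiny_ref()
  te <- names(ref$te_family)[1]
  truth <- data.table(sample_id = "x", chrom = "chr1", pos = 30000L,
                      family = unname(ref$te_family[te]), te_id = te,
                      copy_count = 2L, hap = NA_integer_)
  cov <- 40; rl <- 108L; f <- 300L
  rr <- simulate_reads(ref, truth, coverage = cov, out_prefix = tempfile(),
                       seed = 3L)
  obs <- sample_observations(rr$fastq1, rr$fastq2, ref, "x",
                             insert_mean = f, insert_sd = 30)
  expect_equal(nrow(obs), 1L)
  support <- obs$n_support_fwd + obs$n_support_rev
  # two junctions x two haplotypes x (F - 2L + 1) start positions, at
  # per-haplotype fragment-start density coverage / (4L)
  expected <- (f - 2 * rl + 1) * cov / rl
  expect_lt(abs(support - expected), 4.5 * sqrt(expected))
})

test_that("read simulation rejects bad geometry and is byte-deterministic", {
  ref <- tiny_ref()
  truth <- data.table(sample_id = character(), chrom = character(),
                      pos = integer(), family = character(),
                      te_id = character(), copy_count = integer(),
                      hap = integer())
  expect_error(simulate_reads(ref, truth, coverage = 5,
                              out_prefix = tempfile(), insert_mean = 200L,
                              sample_id = "x"),
               "insert_mean")
  p1 <- tempfile(); p2 <- tempfile()
  simulate_reads(ref, truth, coverage = 1, out_prefix = p1, seed = 7L,
                 sample_id = "x")
  simulate_reads(ref, truth, coverage = 1, out_prefix = p2, seed = 7L,
                 sample_id = "x")
  expect_identical(unname(tools::md5sum(paste0(p1, "_1.fastq"))),
                   unname(tools::md5sum(paste0(p2, "_1.fastq"))))
  expect_identical(unname(tools::md5sum(paste0(p1, "_2.fastq"))),
                   unname(tools::md5sum(paste0(p2, "_2.fastq"))))
})

test_that("per-copy TE mutation diverges carried copies from the library", {
  ref <- tiny_ref()
  te <- names(ref$te_family)[1]
  truth <- data.table(sample_id = "x", chrom = "chr1", pos = 30000L,
                      family = unname(ref$te_family[te]), te_id = te,
                      copy_count = 2L, hap = NA_integer_)
  lib_seq <- as.character(ref$te_library[[te]])
  set.seed(1)
  h0 <- tepop:::build_haplotypes(ref, truth, te_mutation_rate = 0)
  h1 <- tepop:::build_haplotypes(ref, truth, te_mutation_rate = 0.05)
  expect_true(grepl(lib_seq, h0[[1]][["chr1"]], fixed = TRUE))
  expect_false(grepl(lib_seq, h1[[1]][["chr1"]], fixed = TRUE))
  # homozygous: both haplotypes carry the same mutated allele
  expect_identical(h1[[1]][["chr1"]], h1[[2]][["chr1"]])
})

test_that("merge_samples concatenates pairs and validates mate counts", {
  r1 <- c(strrep("A", 50), strrep("C", 50))
  r2 <- c(strrep("G", 50), strrep("T", 50))
  fa <- write_fastq_pair(r1, r2, tempfile(), names = c("a:1", "a:2"))
  fb <- write_fastq_pair(r1[1], r2[1], tempfile(), names = "b:1")
  m <- merge_samples(list(fa, fb), tempfile())
  expect_equal(m$n_pairs, 3L)
  # merging a single set is an identity on content
  one <- merge_samples(list(fa), tempfile())
  expect_identical(readLines(one$fastq1), readLines(fa[1]))
  # mate-count mismatch is fatal
  bad <- c(fa[1], fb[2])
  expect_error(merge_samples(list(bad), tempfile()), "mate count mismatch")
  # duplicate ids across inputs are fatal
  expect_error(merge_samples(list(fa, fa), tempfile()), "duplicate read ids")
})
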