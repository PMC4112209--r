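# build an alignment table row pair in the align_reads output format
aln_pair <- function(qname, r1, r2) {
  rbindlist(list(
    data.table(idx = 1L, mate = 1L, rname = r1$rname, strand = r1$strand,
               pos = r1$pos, mapq = r1$mapq, nhits = 1L,
               seq = strrep("A", 50), qname = qname),
    data.table(idx = 1L, mate = 2L, rname = r2$rname, strand = r2$strand,
               pos = r2$pos, mapq = r2$mapq, nhits = 1L,
               seq = strrep("A", 50), qname = qname)))
}
rec <- function(rname, strand, pos, mapq = 60L)
  list(rname = rname, strand = strand, pos = pos, mapq = mapq)

test_that("pair classification implements the discordant-pair rules", {
  tf <- c(LTR_1 = "LTR")
  # genomic mate forward + TE mate -> supporting, side forward, at mate end
  ev <- classify_pairs(aln_pair("p1", rec("chr1", "+", 10000L),
                                rec("LTR_1", "-", 37L)), tf)
  expect_equal(ev$kind, "supporting")
  expect_equal(ev$side, "forward")
  expect_equal(ev$genomic_pos, 10049L)  # proximal end of a 50-bp mate
  expect_equal(ev$te_family, "LTR")
  expect_equal(ev$te_id, "LTR_1")
  # genomic mate reverse -> side reverse, at mate start
  ev <- classify_pairs(aln_pair("p2", rec("LTR_1", "+", 5L),
                                rec("chr1", "-", 10000L)), tf)
  expect_equal(ev$side, "reverse")
  expect_equal(ev$genomic_pos, 10000L)
  # concordant genomic pair within the insert range -> spanning
  ev <- classify_pairs(aln_pair("p3", rec("chr1", "+", 10000L),
                                rec("chr1", "-", 10231L)), tf,
                       insert_mean = 300, insert_sd = 30)
  expect_equal(ev$kind, "spanning")
  expect_equal(ev$inner_start, 10050L)
  expect_equal(ev$inner_end, 10230L)
  # multi-mapped mate (MAPQ < 20) -> dropped
  ev <- classify_pairs(aln_pair("p4", rec("chr1", "+", 10000L, mapq = 0L),
                                rec("LTR_1", "-", 37L)), tf)
  expect_equal(nrow(ev), 0L)
  # both mates on TEs -> dropped
  ev <- classify_pairs(aln_pair("p5", rec("LTR_1", "+", 5L),
                                rec("LTR_1", "-", 200L)), tf)
  expect_equal(nrow(ev), 0L)
  # discordant insert size -> dropped
  ev <- classify_pairs(aln_pair("p6", rec("chr1", "+", 10000L),
                                rec("chr1", "-", 12000L)), tf,
                       insert_mean = 300, insert_sd = 30)
  expect_equal(nrow(ev), 0L)
})

test_that("frequency estimate is support over support plus spanning", {
  expect_equal(estimate_frequency(6, 4), 0.6)
  expect_equal(estimate_frequency(5, 0), 1.0)
  expect_equal(estimate_frequency(1, 9), 0.1)
  expect_equal(estimate_frequency(c(6, 5), c(4, 0)), c(0.6, 1.0))
  expect_error(estimate_frequency(0, 0))
})

test_that("two-sided clusters join at the midpoint with the right frequency", {
  ev <- make_evidence(fwd = c(9900L, 9950L, 9980L),
                      rev = c(10020L, 10060L, 10100L))
  obs <- detect_insertions(ev, cluster_window = 390L, min_support = 2L)
  expect_equal(nrow(obs), 1L)
  expect_equal(obs$pos_estimate, 10000L)  # floor((9980 + 10020) / 2)
  expect_equal(obs$n_support_fwd, 3L)
  expect_equal(obs$n_support_rev, 3L)
  expect_equal(obs$freq_estimate, 1.0)
  expect_true(obs$both_sided)
})

test_that("support threshold and spanning denominator behave as specified", {
  # a single one-sided pair does not reach min_support = 2
  expect_equal(nrow(detect_insertions(make_evidence(fwd = 10000L),
                                      390L, 2L)), 0L)
  # 4 supporting + 4 spanning pairs straddling the position -> 0.5
  ev <- make_evidence(fwd = c(9940L, 9960L, 9980L, 10000L),
                      span = replicate(4, c(9900L, 10100L), simplify = FALSE))
  obs <- detect_insertions(ev, 390L, 2L)
  expect_equal(obs$freq_estimate, 0.5)
  expect_equal(obs$n_spanning, 4L)
  # spanning counts only strict containment of the position estimate
  ev2 <- make_evidence(fwd = c(9990L, 10000L),
                       span = list(c(9900L, 9999L),   # ends before
                                   c(10000L, 10100L), # contains at edge
                                   c(9900L, 10000L))) # contains at edge
  obs2 <- detect_insertions(ev2, 390L, 2L)
  expect_equal(obs2$pos_estimate, 10000L)
  expect_equal(obs2$n_spanning, 2L)
})

test_that("same-family same-side clustering matches the closure oracle", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(2:40, 1)
    pos <- sort(sample.int(20000L, n))
    w <- sample(c(50L, 200L, 390L), 1)
    ev <- make_evidence(fwd = pos)
    obs <- detect_insertions(ev, cluster_window = w, min_support = 1L)
    oracle <- closure_clusters(pos, w)
    expect_equal(nrow(obs), length(unique(oracle)))
    # innermost (max) positions per oracle cluster = emitted positions
    expect_setequal(obs$pos_estimate,
                    as.integer(tapply(pos, oracle, max)))
  }
})

test_that("families and sides never mix in one cluster", {
  ev <- rbindlist(list(
    make_evidence(fwd = c(10000L, 10010L), family = "LTR"),
    make_evidence(fwd = c(10000L, 10010L), family = "Helitron")))
  obs <- detect_insertions(ev, 390L, 2L)
  expect_equal(nrow(obs), 2L)
  expect_setequal(obs$family, c("LTR", "Helitron"))
})

test_that("detection output is invariant to evidence order", {
  set.seed(17)
  ev <- rbindlist(list(
    make_evidence(fwd = sample.int(50000L, 30), rev = sample.int(50000L, 30),
                  span = replicate(20, {
                    s <- sample.int(50000L, 1)
                    c(s, s + 180L)
                  }, simplify = FALSE)),
    make_evidence(fwd = sample.int(50000L, 10), family = "DNA")))
  obs1 <- detect_insertions(ev, 390L, 2L)
  obs2 <- detect_insertions(ev[sample.int(nrow(ev))], 390L, 2L)
  expect_identical(obs1, obs2)
})

test_that("empty evidence yields an empty observation table", {
  obs <- detect_insertions(make_evidence(), 390L, 2L)
  expect_equal(nrow(obs), 0L)
  expect_true(all(c("sample_id", "chrom", "pos_estimate", "family",
                    "freq_estimate") %in% names(obs)))
})
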