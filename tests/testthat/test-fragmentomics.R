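test_that("fragment length spans the outermost aligned bases of a pair", {
  # mates [1000,1101) and [1066,1167) in 0-based half-open coordinates
  path <- sam_fixture(c(
    sam_rec("f1", 99, "chr1", 1001, "101M", mpos = 1067, tlen = 167),
    sam_rec("f1", 147, "chr1", 1067, "101M", mpos = 1001, tlen = -167)
  ))
  fs <- pair_fragments(path)
  expect_identical(fs$fragments$length, 167L)
  expect_identical(fs$fragments$start, 1000L)
  expect_identical(fs$fragments$end, 1167L)
})

test_that("fully overlapping mates are a single 120 bp observation", {
  path <- sam_fixture(c(
    sam_rec("f1", 99, "chr1", 501, "120M", tlen = 120),
    sam_rec("f1", 147, "chr1", 501, "120M", tlen = -120)
  ))
  fs <- pair_fragments(path)
  expect_identical(nrow(fs$fragments), 1L)
  expect_identical(fs$fragments$length, 120L)
})

test_that("non-qualifying pairs are excluded with tallied reasons", {
  path <- sam_fixture(c(
    sam_pair("ok", 1000, 160),
    # mates on different chromosomes
    sam_rec("xchrom", 97, "chr1", 100, "50M", mrnm = "chr2", mpos = 200),
    sam_rec("xchrom", 145, "chr2", 200, "50M", mrnm = "chr1", mpos = 100),
    # both mates forward
    sam_rec("sstrand", 65, "chr1", 300, "50M", mpos = 400, tlen = 150),
    sam_rec("sstrand", 129, "chr1", 400, "50M", mpos = 300, tlen = -150),
    # RF orientation: leftmost mate on the reverse strand
    sam_rec("rf", 83, "chr1", 600, "50M", mpos = 700, tlen = 150),
    sam_rec("rf", 163, "chr1", 700, "50M", mpos = 600, tlen = -150),
    # orphan single record
    sam_rec("orphan", 99, "chr1", 900, "50M")
  ), sq = c(chr1 = 10000L, chr2 = 10000L))
  fs <- pair_fragments(path)
  expect_identical(fs$fragments$qname, "ok")
  expect_identical(unname(fs$excluded["different_chrom"]), 1L)
  expect_identical(unname(fs$excluded["same_strand"]), 1L)
  expect_identical(unname(fs$excluded["not_fr"]), 1L)
  expect_identical(unname(fs$excluded["not_two_primary"]), 1L)
  # conservation: fragments + exclusions account for every pair seen
  expect_identical(nrow(fs$fragments) + sum(fs$excluded), fs$n_pairs)
})

test_that("length histogram bins per bp and tallies out-of-range lengths", {
  h <- length_histogram(c(167, 167, 134))
  expect_identical(unname(h$counts[c("134", "167")]), c(1L, 2L))
  expect_identical(h$total, 3L)
  expect_identical(sum(h$counts), h$total)
  expect_equal(sum(length_density(h)), 1)

  low <- length_histogram(rep(30, 10), min_bp = 50)
  expect_identical(low$total, 0L)
  expect_identical(low$underflow, 10L)
  empty <- length_histogram(numeric(0))
  expect_identical(empty$total, 0L)
})

test_that("modal length takes the argmax with ties broken downward", {
  h <- length_histogram(rep(c(166, 167, 168), c(5, 10, 5)))
  expect_identical(as.integer(modal_length(h)), 167L)

  tied <- modal_length(rep(c(134, 144), c(10, 10)))
  expect_identical(as.integer(tied), 134L)
  expect_identical(attr(tied, "ties"), c(134L, 144L))
  expect_error(modal_length(length_histogram(numeric(0))), "empty")
})

# Deterministic comb profile: teeth every `period` bp over [105, 160],
# heights from a discretized Gaussian of width sd around each tooth.
comb_lengths <- function(period = 10, sd = 1, per_tooth = 1000) {
  teeth <- seq(105, 160, by = period)
  grid <- 100:165
  counts <- rowSums(vapply(teeth, function(t)
    round(per_tooth * (pnorm(grid + 0.5, t, sd) - pnorm(grid - 0.5, t, sd))),
    numeric(length(grid))))
  rep(grid, counts)
}

test_that("periodicity estimator recovers planted comb periods exactly", {
  h10 <- length_histogram(comb_lengths(period = 10))
  p10 <- estimate_periodicity(h10)
  expect_identical(p10$period_bp, 10L)
  expect_gt(p10$amplitude, 0.5)

  h12 <- length_histogram(comb_lengths(period = 12))
  p12 <- estimate_periodicity(h12, search = c(8, 14))
  expect_identical(p12$period_bp, 12L)
})

test_that("flat profiles have near-zero amplitude", {
  flat <- length_histogram(rep(100:165, each = 100))
  p <- estimate_periodicity(flat)
  expect_lt(p$amplitude, 0.05)
})

test_that("amplitude decreases monotonically with comb contrast", {
  amp_at <- function(lambda) {
    comb <- comb_lengths(period = 10, per_tooth = 2000)
    flat <- rep(100:165, each = round(lambda * 0 + 300))
    lengths <- c(rep(comb, round(lambda * 10)), rep(flat, round((1 - lambda) * 10)))
    estimate_periodicity(length_histogram(lengths))$amplitude
  }
  amps <- vapply(c(0.9, 0.5, 0.2), amp_at, numeric(1))
  expect_true(all(diff(amps) < 0))
})

test_that("periodicity estimation validates its band and sample size", {
  h <- length_histogram(comb_lengths())
  expect_error(estimate_periodicity(h, band = c(10, 160)), "band")
  expect_error(estimate_periodicity(length_histogram(rep(130, 10))),
               "fewer than")
})

test_that("allele stratification recovers the simulated truth exactly", {
  coh <- simulate_cohort(2000, mixture_spec(tumor_fraction = 0.1), seed = 11)
  paths <- write_cohort(coh, tempfile())
  st <- stratify_by_allele(paths[["alignments"]], coh$variant)
  truth <- coh$observations
  expect_identical(sort(st$mut), sort(truth$length[truth$allele == "mut"]))
  expect_identical(sort(st$wt), sort(truth$length[truth$allele == "wt"]))
  expect_identical(sum(st$excluded), 0L)
})

test_that("low-quality and discordant variant bases are excluded", {
  # fragment of 60 bp fully covered by both 60 bp mates; variant at pos 130
  # (offset 11 into each read)
  seq_ref <- strrep("A", 60)
  seq_alt <- paste0(strrep("A", 10), "T", strrep("A", 49))
  qual_hi <- strrep("I", 60)
  qual_lo <- paste0(strrep("I", 10), "#", strrep("I", 49))
  v <- variant_site("chr1", 130, "A", "T")
  # mutf: both mates alt;  lowq: alt base below Q20 on both mates;
  # disc: mates disagree at the position
  path <- sam_fixture(c(
    sam_pair("mutf", 119, 60, seq1 = seq_alt, seq2 = seq_alt),
    sam_pair("wtf", 119, 60, seq1 = seq_ref, seq2 = seq_ref),
    sam_pair("lowq", 119, 60, seq1 = seq_alt, seq2 = seq_alt,
             qual1 = qual_lo, qual2 = qual_lo),
    sam_pair("disc", 119, 60, seq1 = seq_alt, seq2 = seq_ref)
  ))
  st <- stratify_by_allele(path, v)
  expect_identical(st$mut, 60L)
  expect_identical(st$wt, 60L)
  expect_identical(unname(st$excluded["discordant_mates"]), 1L)
  expect_gte(unname(st$excluded["low_base_quality"]), 1L)
})

test_that("a variant covered by no fragment warns and returns empty strata", {
  path <- sam_fixture(sam_pair("f1", 1000, 150))
  v <- variant_site("chr1", 5000, "A", "T")
  expect_warning(st <- stratify_by_allele(path, v), "no fragment")
  expect_identical(st$mut, integer(0))
  expect_identical(st$wt, integer(0))
})

test_that("binned MAF follows the lower-edge bin rule", {
  tab <- binned_allele_frequency(mut_lengths = c(57, 57, 57, 134),
                                 wt_lengths = c(51, 134, 134, 134))
  r50 <- tab[tab$bin_lower == 50, ]
  expect_identical(r50$mut_count, 3L)   # 57 bp fragments land in bin 50
  expect_identical(r50$wt_count, 1L)
  expect_equal(r50$frequency, 0.75)
  r130 <- tab[tab$bin_lower == 130, ]
  expect_equal(r130$frequency, 0.25)

  # sparse bins are reported undefined, not dropped
  sparse <- binned_allele_frequency(c(57), c(134, 134), min_count = 2)
  expect_true(is.na(sparse$frequency[sparse$bin_lower == 50]))
  expect_false(is.na(sparse$frequency[sparse$bin_lower == 130]))
  expect_identical(nrow(binned_allele_frequency(numeric(0), numeric(0))), 0L)
})

test_that("pooled MAF equals the count-weighted mean of per-bin frequencies", {
  set.seed(41)
  mut <- sample(60:250, 300, replace = TRUE)
  wt <- sample(60:250, 900, replace = TRUE)
  tab <- binned_allele_frequency(mut, wt)
  pooled <- sum(tab$frequency * tab$total) / sum(tab$total)
  expect_equal(pooled, maf(length(mut), length(wt)))
})

test_that("maf handles its boundary cases", {
  expect_equal(maf(1, 99), 0.01)
  expect_equal(maf(0, 10), 0)
  expect_equal(maf(5, 5), 0.5)
  expect_true(is.na(maf(0, 0)))
  expect_equal(maf(c(1, 0), c(99, 0)), c(0.01, NA))
  expect_error(maf(-1, 5), "non-negative")
})
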