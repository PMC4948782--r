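test_that("tumor fraction controls mutant alleles in the cohort", {
  coh0 <- simulate_cohort(2000, mixture_spec(tumor_fraction = 0), seed = 21)
  expect_identical(sum(coh0$observations$allele == "mut"), 0L)
  expect_identical(nrow(coh0$observations), 2000L)

  coh1 <- simulate_cohort(1e4, mixture_spec(tumor_fraction = 1),
                          covering_fraction = 1, seed = 22)
  obs <- coh1$observations
  n <- sum(obs$allele %in% c("mut", "wt"))
  expect_identical(n, 1e4L)  # covering share 1: every fragment informative
  m <- maf(sum(obs$allele == "mut"), sum(obs$allele == "wt"))
  expect_lt(abs(m - 0.5), 3 * sqrt(0.25 / n))
})

test_that("fragments land inside the reference and carry valid coordinates", {
  coh <- demo_cohort(n = 3000, seed = 23)
  obs <- coh$observations
  expect_true(all(obs$start >= 0))
  expect_true(all(obs$end <= Biostrings::width(coh$reference)[1]))
  expect_identical(obs$length, obs$end - obs$start)
  # allele labels only on fragments covering the variant
  pos0 <- coh$variant$pos0
  covers <- obs$start <= pos0 & pos0 < obs$end
  expect_true(all(obs$allele[!covers] == "none"))
  expect_true(all(obs$allele[covers] %in% c("mut", "wt")))
  # mut only on tumor-origin fragments
  expect_true(all(obs$origin[obs$allele == "mut"] == "tumor"))
})

test_that("library-prep retention matches its quadrature oracle", {
  spec <- mixture_spec(recovery_midpoint_bp = 100, recovery_scale_bp = 5)
  set.seed(24)
  lengths <- sample(50:200, 1e5, replace = TRUE)
  kept <- apply_library_prep(lengths, spec)
  # oracle: average of the closed-form retention curve over the uniform grid
  expected <- mean(stats::plogis((50:200 - 100) / 5))
  expect_lt(abs(mean(kept) - expected), 0.01)

  # with peaks near the recovery midpoint a visible share must drop
  short_spec <- mixture_spec(normal_peaks = list(c(100, 1)), peak_sd_bp = 15)
  coh <- simulate_cohort(500, short_spec, seed = 25, apply_prep = TRUE)
  expect_true(is.logical(coh$observations$retained))
  expect_lt(sum(coh$observations$retained), 500)
})

test_that("identical seeds give byte-identical truth tables and SAM output", {
  run <- function() {
    coh <- simulate_cohort(500, mixture_spec(tumor_fraction = 0.2),
                           seed = 77, apply_prep = TRUE)
    d <- tempfile()
    write_cohort(coh, d)
  }
  p1 <- run(); p2 <- run()
  for (f in c("alignments", "truth", "reference", "config")) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
})

test_that("emitted SAM round-trips through alignment pairing exactly", {
  coh <- demo_cohort(n = 1500, seed = 26)
  paths <- write_cohort(coh, tempfile())
  fs <- pair_fragments(paths[["alignments"]])
  expect_identical(sum(fs$excluded), 0L)
  expect_identical(sort(fs$fragments$length),
                   sort(coh$observations$length))
  # fragment coordinates survive, not just lengths
  frag <- fs$fragments[order(fs$fragments$qname), ]
  obs <- coh$observations[order(coh$observations$fragment_id), ]
  expect_identical(frag$start, obs$start)
  expect_identical(frag$end, obs$end)
})

test_that("mutant fragments carry the alt base in the emitted reads", {
  coh <- simulate_cohort(800, mixture_spec(tumor_fraction = 0.5),
                         covering_fraction = 1, seed = 27)
  sam <- cohort_sam(coh)
  body <- sam[!startsWith(sam, "@")]
  fields <- strsplit(body, "\t")
  qname <- vapply(fields, `[`, character(1), 1)
  pos <- as.integer(vapply(fields, `[`, character(1), 4))
  seqs <- vapply(fields, `[`, character(1), 10)
  pos1 <- coh$variant$pos
  covers <- pos <= pos1 & pos1 < pos + nchar(seqs)
  base <- substr(seqs, pos1 - pos + 1L, pos1 - pos + 1L)
  allele <- coh$observations$allele[match(qname, coh$observations$fragment_id)]
  expect_true(all(base[covers & allele == "mut"] == coh$variant$alt))
  expect_true(all(base[covers & allele == "wt"] == coh$variant$ref))
})

test_that("dual-species MQ emitter reproduces its configured class shares", {
  set.seed(28)
  q <- emit_dual_species_qualities(1e4, theta = 0.6, p_ambiguous = 0.1,
                                   p_low = 0.05)
  expect_identical(nrow(q), 1e4L)
  calls <- classify_read_pair(q$mq_a, q$mq_b)
  # clean pairs are recovered as their true origin
  clean <- q$class == "clean"
  expect_true(all(as.character(calls[clean]) == q$true_origin[clean]))
  expect_true(all(calls[q$class == "low"] == "discard_low"))
  expect_true(all(calls[q$class == "ambiguous"] == "discard_ambiguous"))
  share <- mean(calls == "discard_ambiguous")
  expect_lt(abs(share - 0.1), 3 * sqrt(0.1 * 0.9 / 1e4))
})

test_that("simulator rejects inconsistent variant/reference input", {
  ref <- random_reference(1000)
  v <- variant_site("chrS", 5000, "A", "T")
  expect_error(simulate_cohort(10, mixture_spec(), variant = v,
                               reference = ref), "outside")
  expect_error(simulate_cohort(10, mixture_spec(),
                               reference = random_reference(400)),
               "shorter than the maximum fragment length")
})
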