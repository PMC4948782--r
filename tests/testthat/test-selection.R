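# observation table with given allele counts and lengths
obs_table <- function(mut_lengths, wt_lengths, none_lengths = integer(0)) {
  data.frame(
    length = c(mut_lengths, wt_lengths, none_lengths),
    allele = rep(c("mut", "wt", "none"),
                 c(length(mut_lengths), length(wt_lengths),
                   length(none_lengths))),
    stringsAsFactors = FALSE)
}

test_that("window selection keeps [lo, hi) and preserves order", {
  x <- c(134L, 144L, 167L, 134L)
  expect_identical(select_window(x, 50, 501), x)
  expect_identical(select_window(x, 130, 150), c(134L, 144L, 134L))
  expect_identical(select_window(x, 300, 400), integer(0))
  # hi is exclusive, lo inclusive
  expect_identical(select_window(x, 134, 167), c(134L, 144L, 134L))
  expect_error(select_window(x, 150, 130), "lo must be < hi")

  df <- obs_table(134, c(144, 167))
  expect_identical(select_window(df, 130, 150)$length, c(134, 144))
})

test_that("enrichment fold reproduces the printed 9.1-fold worked example", {
  # library MAF 0.017, fraction MAF 0.155 (fraction peak 320, library 348)
  library_obs <- obs_table(rep(320, 17), rep(348, 983))
  fraction_obs <- obs_table(rep(320, 155), rep(320, 845))
  e <- enrichment(library_obs, fraction_obs)
  expect_equal(e$maf_library, 0.017, tolerance = 1e-6)
  expect_equal(e$maf_fraction, 0.155)
  expect_equal(e$fold, 9.1, tolerance = 0.02)
  expect_identical(e$peak_offset, -28L)
  expect_identical(e$n_fraction, 1000L)
})

test_that("a fraction equal to the whole library has fold exactly 1", {
  coh <- demo_cohort(n = 1000, seed = 51)
  obs <- coh$observations
  e <- enrichment(obs, obs)
  expect_identical(e$fold, 1)
  expect_identical(e$peak_offset, 0L)
})

test_that("zero library MAF gives a flagged undefined fold", {
  library_obs <- obs_table(integer(0), rep(167, 100))
  fraction_obs <- obs_table(integer(0), rep(140, 20))
  e <- enrichment(library_obs, fraction_obs)
  expect_false(e$fold_defined)
  expect_true(is.na(e$fold))
})

test_that("peak offset is fraction minus library, negative means shorter", {
  expect_identical(peak_offset(320, 348), -28L)
  expect_identical(peak_offset(361, 348), 13L)
  expect_identical(peak_offset(250, 250), 0L)
})

test_that("gel fractions tile the span with adjacent disjoint windows", {
  b <- c(100, 150, 200, 250, 300, 350, 400)
  fr <- gel_fractions(NULL, n_fractions = 6, boundaries = b)
  expect_identical(nrow(fr), 6L)
  expect_equal(fr$lo, b[-7])
  expect_equal(fr$hi, b[-1])
  expect_true(all(fr$hi[-6] == fr$lo[-1]))  # adjacency
  expect_error(gel_fractions(NULL, 6, boundaries = c(100, 90, 200, 250, 300,
                                                     350, 400)),
               "strictly increasing")
  expect_error(gel_fractions(NULL, 6, boundaries = c(100, 200)), "boundaries")
})

test_that("per-fraction counts conserve the library count within the span", {
  set.seed(52)
  lengths <- sample_fragment_length(5000, "normal",
                                    mixture_spec(peak_sd_bp = 30))
  fr <- gel_fractions(lengths, n_fractions = 6)
  per <- vapply(seq_len(nrow(fr)), function(i)
    length(select_window(lengths, fr$lo[i], fr$hi[i])), integer(1))
  in_span <- sum(lengths >= fr$lo[1] & lengths < fr$hi[6])
  expect_identical(sum(per), in_span)
  expect_identical(sum(per), length(lengths))  # quantile cuts cover everything
  # roughly equal-count fractions
  expect_true(all(per > 0))
})

test_that("quantile fractions reject degenerate distributions", {
  expect_error(gel_fractions(rep(167, 100), n_fractions = 6), "concentrated")
  expect_error(gel_fractions(numeric(0)), "empty")
})

test_that("pure mixtures give flat scan profiles", {
  # theta = 1: MAF ~ 0.5 everywhere, fold ~ 1 at every defined offset
  coh1 <- simulate_cohort(3e4, mixture_spec(tumor_fraction = 1),
                          covering_fraction = 1, seed = 53)
  sc1 <- scan_windows(coh1$observations)
  ok <- !is.na(sc1$profile$fold)
  expect_true(any(ok))
  se <- 3 * sqrt(0.25 / sc1$profile$n_alleles[ok])
  expect_true(all(abs(sc1$profile$maf[ok] - 0.5) < pmax(se, 1e-12)))
  expect_true(all(abs(sc1$profile$fold[ok] - 1) < 4 * se))

  # theta = 0: no tumor signal anywhere; window MAF 0, fold undefined
  coh0 <- simulate_cohort(3e4, mixture_spec(tumor_fraction = 0),
                          covering_fraction = 1, seed = 54)
  sc0 <- scan_windows(coh0$observations)
  expect_true(all(sc0$profile$maf[!is.na(sc0$profile$maf)] == 0))
  expect_true(all(is.na(sc0$profile$fold)))
})

test_that("dilute short-fragment tumor signal is enriched at negative offsets", {
  spec <- mixture_spec(tumor_fraction = 0.05,
                       tumor_peaks = list(c(145, 1)))
  coh <- simulate_cohort(1e5, spec, covering_fraction = 1, seed = 55)
  sc <- scan_windows(coh$observations)
  expect_lt(sc$best_offset, 0)
  # Monte-Carlo window MAF at the best offset matches the quadrature oracle
  i <- match(sc$best_offset, sc$profile$offset)
  w <- c(sc$profile$window_lo[i], sc$profile$window_hi[i])
  p <- mixture_window_maf(spec, w)
  se <- sqrt(p * (1 - p) / sc$profile$n_alleles[i])
  expect_lt(abs(sc$profile$maf[i] - p), 3 * pmax(se, 1e-12))
  expect_error(scan_windows(coh$observations[0, ]))
})

test_that("closed-form folds are >= 1 below and <= 1 above the library peak", {
  spec <- mixture_spec(tumor_fraction = 0.05, tumor_peaks = list(c(145, 1)))
  maf_lib <- mixture_window_maf(spec, c(50, 501))
  # crossover of the two densities lies between the tumor and normal peaks
  ft <- mixture_density(spec, "tumor"); fn <- mixture_density(spec, "normal")
  cross <- stats::uniroot(function(l) ft(l) - fn(l), c(146, 166))$root
  # only windows where either component carries mass have a defined MAF
  below <- lapply(seq(110, floor(cross) - 30, by = 5),
                  function(lo) c(lo, lo + 30))
  checked <- 0L
  for (w in below) {
    p <- mixture_window_maf(spec, w)
    if (is.nan(p)) next
    expect_gte(p / maf_lib, 1)
    checked <- checked + 1L
  }
  expect_gte(checked, 2L)
  # cap at 180 so the normal tail mass stays numerically non-zero
  above <- lapply(seq(168, 180, by = 4), function(lo) c(lo, lo + 30))
  for (w in above) {
    p <- mixture_window_maf(spec, w)
    expect_false(is.nan(p))  # normal mass keeps these defined
    expect_lte(p / maf_lib, 1)
  }
})
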