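#' Restrict observations to a fragment-length window
#'
#' In-silico analogue of excising a gel slice: keeps fragments with
#' `lo <= length < hi`, preserving order.
#'
#' @param x Numeric vector of lengths, or a data.frame with a `length`
#'   column (e.g. cohort observations).
#' @param lo,hi Window bounds in bp, `lo < hi`; `lo` inclusive, `hi`
#'   exclusive.
#' @return The subset of `x` (possibly empty).
#' @export
select_window <- function(x, lo, hi) {
  if (lo >= hi) stop("invalid window: lo must be < hi")
  if (is.data.frame(x)) {
    stopifnot("length" %in% names(x))
    return(x[x$length >= lo & x$length < hi, , drop = FALSE])
  }
  x[x >= lo & x < hi]
}

allele_counts <- function(obs) {
  if (is.data.frame(obs)) {
    stopifnot(all(c("length", "allele") %in% names(obs)))
    c(mut = sum(obs$allele == "mut"), wt = sum(obs$allele == "wt"))
  } else stop("observations must be a data.frame with length and allele")
}

#' Mutant-allele enrichment of a size-selected fraction
#'
#' Compares a fraction (size-selected subset) to its library: fold change of
#' the mutant allele frequency (`MAF(fraction) / MAF(library)`) and the
#' fraction-vs-library peak offset (modal length of the fraction minus modal
#' length of the library; negative offsets mean shorter fragments). A
#' fraction equal to the whole library has fold exactly 1. With zero or
#' undefined library MAF the fold is undefined and flagged, never silently
#' dropped.
#'
#' @param library_obs,fraction_obs data.frames with `length` and `allele`
#'   (`"mut"`/`"wt"`/`"none"`) columns, e.g. cohort observations or the
#'   output of [strata_observations()].
#' @return An `enrichment_result`: list with `maf_library`, `maf_fraction`,
#'   `fold` (`NA` when undefined), `fold_defined`, `peak_offset`,
#'   `n_fraction`.
#' @export
enrichment <- function(library_obs, fraction_obs) {
  cl <- allele_counts(library_obs)
  cf <- allele_counts(fraction_obs)
  maf_l <- maf(cl["mut"], cl["wt"])
  maf_f <- maf(cf["mut"], cf["wt"])
  defined <- !is.na(maf_l) && maf_l > 0 && !is.na(maf_f)
  fold <- if (defined) unname(maf_f / maf_l) else NA_real_
  offset <- peak_offset(modal_length(fraction_obs$length),
                        modal_length(library_obs$length))
  structure(list(maf_library = unname(maf_l), maf_fraction = unname(maf_f),
                 fold = fold, fold_defined = defined,
                 peak_offset = offset, n_fraction = nrow(fraction_obs)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("size-selection enrichment\n")
  cat(sprintf("  library MAF %.4g, fraction MAF %.4g (n = %d)\n",
              x$maf_library, x$maf_fraction, x$n_fraction))
  if (x$fold_defined)
    cat(sprintf("  fold change %.3g; peak offset %+d bp\n",
                x$fold, x$peak_offset))
  else cat("  fold undefined (library MAF zero or undefined)\n")
  invisible(x)
}

#' Fraction-vs-library peak offset
#'
#' `fraction_peak - library_peak` in bp; negative values correspond to
#' fractions of shorter fragments.
#'
#' @param fraction_peak,library_peak Peak (modal) fragment lengths in bp.
#' @return Signed offset in bp.
#' @export
#' @examples
#' peak_offset(320, 348)
peak_offset <- function(fraction_peak, library_peak) {
  stopifnot(is.numeric(fraction_peak), is.numeric(library_peak))
  as.integer(fraction_peak) - as.integer(library_peak)
}

#' Scan fixed-width windows around the library peak for enrichment
#'
#' Slides a window of `window_width` bp centered at
#' `library peak + offset` across the given offsets and computes the
#' mutant-allele enrichment fold for each window, emulating a systematic
#' version of serial gel-fraction collection. Windows with fewer than
#' `min_count` allele-informative fragments get an undefined (`NA`) fold —
#' sparse windows give erratic frequencies — and are excluded from the
#' reported argmax.
#'
#' @param obs data.frame with `length` and `allele` columns (the library).
#' @param window_width Window width in bp (default 30).
#' @param offsets Signed offsets in bp to scan
#'   (default `seq(-60, 60, by = 5)`).
#' @param min_count Minimum allele-informative fragments per window
#'   (default 20).
#' @return An `enrichment_scan`: list with `profile` (data.frame
#'   `offset, window_lo, window_hi, n, n_alleles, maf, fold`), `best_offset`
#'   (offset with the largest defined fold; `NA` if none), `library_peak`,
#'   `maf_library`. Errors if every window is empty.
#' @export
scan_windows <- function(obs, window_width = 30L, offsets = seq(-60, 60, 5),
                         min_count = 20L) {
  stopifnot(is.data.frame(obs), nrow(obs) > 0, window_width >= 1)
  peak <- as.integer(modal_length(obs$length))
  cl <- allele_counts(obs)
  maf_l <- maf(cl["mut"], cl["wt"])
  half <- window_width / 2
  rows <- lapply(offsets, function(off) {
    lo <- peak + off - half
    hi <- lo + window_width
    w <- select_window(obs, lo, hi)
    cw <- allele_counts(w)
    n_all <- unname(cw["mut"] + cw["wt"])
    m <- if (n_all >= min_count) unname(maf(cw["mut"], cw["wt"])) else NA_real_
    fold <- if (!is.na(m) && !is.na(maf_l) && maf_l > 0) m / maf_l else NA_real_
    data.frame(offset = off, window_lo = lo, window_hi = hi, n = nrow(w),
               n_alleles = n_all, maf = m, fold = fold)
  })
  profile <- do.call(rbind, rows)
  if (all(profile$n == 0)) stop("all windows are empty")
  best <- if (any(!is.na(profile$fold)))
    profile$offset[which.max(profile$fold)] else NA_real_
  structure(list(profile = profile, best_offset = best,
                 library_peak = peak, maf_library = unname(maf_l)),
            class = "enrichment_scan")
}

#' @export
print.enrichment_scan <- function(x, ...) {
  cat(sprintf("enrichment scan: library peak %d bp, library MAF %.4g\n",
              x$library_peak, x$maf_library))
  if (!is.na(x$best_offset)) {
    i <- match(x$best_offset, x$profile$offset)
    cat(sprintf("  best offset %+d bp (fold %.3g, n = %d)\n",
                x$best_offset, x$profile$fold[i], x$profile$n[i]))
  }
  invisible(x)
}

#' Partition a length distribution into adjacent gel-like fractions
#'
#' Produces adjacent, non-overlapping selection windows tiling a span of the
#' length axis, emulating serial collection of consecutive gel slices.
#' With explicit `boundaries` (strictly increasing, length
#' `n_fractions + 1`), windows are `[b[i], b[i+1])`; otherwise equal-count
#' quantile cuts over the distribution are used (the top window's upper
#' bound is extended by 1 bp so the maximum observed length is included).
#'
#' @param dist A [length_histogram()] result, or a numeric length vector.
#' @param n_fractions Number of fractions (default 6, >= 2).
#' @param boundaries Optional numeric boundaries.
#' @return data.frame `fraction, lo, hi` of adjacent windows.
#' @export
gel_fractions <- function(dist, n_fractions = 6L, boundaries = NULL) {
  stopifnot(n_fractions >= 2)
  if (!is.null(boundaries)) {
    if (any(diff(boundaries) <= 0)) stop("boundaries must be strictly increasing")
    if (length(boundaries) != n_fractions + 1L)
      stop("need n_fractions + 1 boundaries")
    b <- boundaries
  } else {
    if (inherits(dist, "length_distribution")) {
      lengths <- rep(as.integer(names(dist$counts)), dist$counts)
    } else lengths <- dist
    if (length(lengths) == 0) stop("empty distribution")
    b <- unname(stats::quantile(lengths, probs = seq(0, 1, length.out =
                                                       n_fractions + 1L),
                                type = 1))
    b[length(b)] <- b[length(b)] + 1  # include the maximum (hi is exclusive)
    if (any(diff(b) <= 0))
      stop("distribution too concentrated for ", n_fractions,
           " distinct quantile fractions")
  }
  data.frame(fraction = seq_len(n_fractions),
             lo = b[-length(b)], hi = b[-1])
}

#' Allele strata as a flat observation table
#'
#' Converts the output of [stratify_by_allele()] into the
#' `length`/`allele` data.frame consumed by [enrichment()] and
#' [scan_windows()].
#'
#' @param strata An `allele_strata` object.
#' @return data.frame with `length` and `allele` columns.
#' @export
strata_observations <- function(strata) {
  stopifnot(inherits(strata, "allele_strata"))
  data.frame(length = c(strata$mut, strata$wt),
             allele = rep(c("mut", "wt"),
                          c(length(strata$mut), length(strata$wt))),
             stringsAsFactors = FALSE)
}
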