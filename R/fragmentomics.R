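#' Fragment lengths from paired-end alignment records
#'
#' Pairs primary alignment records by read name and computes the fragment
#' (insert) length as the absolute distance between the outermost aligned
#' bases of the two mates: in 0-based half-open coordinates,
#' `max(mate ends) - min(mate starts)`. A pair qualifies when both mates are
#' mapped, on the same chromosome, on opposite strands in FR orientation
#' (leftmost mate forward). Overlapping and fully overlapping mates yield a
#' single observation per pair. Everything else is excluded with a tallied
#' reason rather than an error.
#'
#' @param aln Alignment data.frame from [read_alignments()], or a SAM/BAM
#'   path.
#' @return A list of class `fragment_set`: `fragments` (data.frame
#'   `qname, chrom, start, end, length`, 0-based half-open), `excluded`
#'   (named integer tally: `not_two_primary`, `unmapped_mate`,
#'   `different_chrom`, `same_strand`, `not_fr`), and `n_pairs` (distinct
#'   read names seen).
#' @export
pair_fragments <- function(aln) {
  if (is.character(aln)) aln <- read_alignments(aln)
  excl <- c(not_two_primary = 0L, unmapped_mate = 0L, different_chrom = 0L,
            same_strand = 0L, not_fr = 0L)
  empty <- data.frame(qname = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), stringsAsFactors = FALSE)
  n_pairs <- length(unique(aln$qname))
  if (nrow(aln) == 0)
    return(structure(list(fragments = empty, excluded = excl,
                          n_pairs = 0L), class = "fragment_set"))
  ord <- order(aln$qname)
  x <- aln[ord, , drop = FALSE]
  r <- rle(x$qname)
  first <- cumsum(r$lengths) - r$lengths + 1L
  two <- r$lengths == 2L
  excl["not_two_primary"] <- sum(!two)
  i1 <- first[two]; i2 <- i1 + 1L
  m1 <- x[i1, , drop = FALSE]; m2 <- x[i2, , drop = FALSE]

  unmapped <- bitwAnd(m1$flag, 0x4L) > 0L | bitwAnd(m2$flag, 0x4L) > 0L |
    is.na(m1$pos) | is.na(m2$pos)
  diff_chrom <- !unmapped & m1$rname != m2$rname
  same_strand <- !unmapped & !diff_chrom & m1$strand == m2$strand
  # FR: the leftmost mate must be on the forward strand
  left_fwd <- ifelse(m1$pos <= m2$pos, m1$strand == "+", m2$strand == "+")
  not_fr <- !unmapped & !diff_chrom & !same_strand & !left_fwd
  ok <- !unmapped & !diff_chrom & !same_strand & !not_fr
  excl["unmapped_mate"] <- sum(unmapped)
  excl["different_chrom"] <- sum(diff_chrom)
  excl["same_strand"] <- sum(same_strand)
  excl["not_fr"] <- sum(not_fr)

  start0 <- pmin(m1$pos[ok], m2$pos[ok]) - 1L
  end0 <- pmax(m1$end[ok], m2$end[ok])
  frag <- data.frame(qname = m1$qname[ok], chrom = m1$rname[ok],
                     start = start0, end = end0,
                     length = end0 - start0, stringsAsFactors = FALSE)
  structure(list(fragments = frag, excluded = excl, n_pairs = n_pairs),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("%d fragments from %d read pairs (%d excluded)\n",
              nrow(x$fragments), x$n_pairs, sum(x$excluded)))
  if (sum(x$excluded) > 0) {
    e <- x$excluded[x$excluded > 0]
    cat("  excluded:", paste(names(e), e, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fragment lengths from a SAM/BAM file
#'
#' Convenience wrapper: [pair_fragments()] and return the length vector.
#' @inheritParams pair_fragments
#' @return Integer vector of fragment lengths in bp.
#' @export
fragment_lengths <- function(aln) pair_fragments(aln)$fragments$length

#' Integer-binned fragment-length histogram
#'
#' Counts per 1-bp length bin over `[min_bp, max_bp]`; lengths outside the
#' range are tallied as underflow/overflow, not dropped silently.
#'
#' @param lengths Positive fragment lengths in bp.
#' @param min_bp,max_bp Histogram range (defaults 50 and 500).
#' @return A `length_distribution`: list with `min_bp`, `max_bp`, `counts`
#'   (named integer vector, one bin per bp), `total` (in-range count),
#'   `underflow`, `overflow`.
#' @export
length_histogram <- function(lengths, min_bp = 50L, max_bp = 500L) {
  stopifnot(min_bp < max_bp)
  lengths <- lengths[!is.na(lengths)]
  if (any(lengths <= 0)) stop("fragment lengths must be positive")
  grid <- min_bp:max_bp
  inr <- lengths >= min_bp & lengths <= max_bp
  counts <- tabulate(lengths[inr] - min_bp + 1L, nbins = length(grid))
  names(counts) <- grid
  structure(list(min_bp = as.integer(min_bp), max_bp = as.integer(max_bp),
                 counts = counts, total = sum(counts),
                 underflow = sum(lengths < min_bp),
                 overflow = sum(lengths > max_bp)),
            class = "length_distribution")
}

#' @export
print.length_distribution <- function(x, ...) {
  cat(sprintf("fragment-length histogram [%d, %d] bp: %d fragments",
              x$min_bp, x$max_bp, x$total))
  if (x$underflow + x$overflow > 0)
    cat(sprintf(" (+%d under, +%d over range)", x$underflow, x$overflow))
  cat("\n")
  if (x$total > 0)
    cat(sprintf("  modal length %d bp\n", modal_length(x)))
  invisible(x)
}

#' Density view of a length distribution
#'
#' @param dist A [length_histogram()] result.
#' @return Named numeric vector summing to 1 (all zeros when empty).
#' @export
length_density <- function(dist) {
  stopifnot(inherits(dist, "length_distribution"))
  if (dist$total == 0) return(dist$counts * 0)
  dist$counts / dist$total
}

#' Modal fragment length
#'
#' The most common fragment length. Ties are broken toward the smallest
#' length; all tied modes are reported in the `"ties"` attribute.
#'
#' @param x A `length_distribution` or a numeric vector of lengths.
#' @return Integer modal length with attribute `ties` (all tied modes).
#' @export
#' @examples
#' modal_length(c(134, 144, 144, 167, 167))
modal_length <- function(x) {
  if (inherits(x, "length_distribution")) {
    if (x$total == 0) stop("modal length undefined for an empty distribution")
    counts <- x$counts
    grid <- as.integer(names(counts))
  } else {
    x <- x[!is.na(x)]
    if (length(x) == 0) stop("modal length undefined for an empty distribution")
    tab <- table(x)
    counts <- as.integer(tab)
    grid <- as.integer(names(tab))
  }
  ties <- grid[counts == max(counts) & counts > 0]
  structure(min(ties), ties = ties)
}

#' Estimate fragment-length periodicity by detrended autocorrelation
#'
#' Detects the ~10 bp nucleosome-ladder periodicity of ctDNA length profiles.
#' The count profile inside `band` is detrended with a centered moving
#' average; the period is the lag (within `search`) maximizing the
#' autocorrelation of the residual. The amplitude is the autocorrelation at
#' that lag multiplied by the residual's coefficient of variation relative to
#' the mean profile level, clipped to \[0, 1\]: it is 0 for a flat profile and
#' decreases with comb contrast, unlike the scale-invariant autocorrelation
#' alone.
#'
#' @param dist A [length_histogram()] result.
#' @param band `c(lo, hi)` length band analysed (default `c(100, 160)`);
#'   must lie within the distribution range.
#' @param search `c(min_lag, max_lag)` period search range in bp
#'   (default `c(8, 12)`).
#' @param detrend_window Moving-average window in bp (odd; default 11,
#'   chosen to span one full period).
#' @param min_total Minimum in-band fragment count required (default 50).
#' @return A `periodicity_estimate`: list with `period_bp`, `amplitude`,
#'   `band`.
#' @export
estimate_periodicity <- function(dist, band = c(100, 160), search = c(8, 12),
                                 detrend_window = 11L, min_total = 50L) {
  stopifnot(inherits(dist, "length_distribution"))
  if (band[1] < dist$min_bp || band[2] > dist$max_bp)
    stop("band wider than the distribution range")
  grid <- as.integer(names(dist$counts))
  y <- as.numeric(dist$counts[grid >= band[1] & grid <= band[2]])
  if (sum(y) < min_total)
    stop("fewer than ", min_total, " fragments in the band")
  w <- as.integer(detrend_window)
  if (w %% 2L == 0L) w <- w + 1L
  trend <- stats::filter(y, rep(1 / w, w), sides = 2)
  keep <- !is.na(trend)
  resid <- y[keep] - trend[keep]
  n <- length(resid)
  lags <- search[1]:search[2]
  if (max(lags) >= n) stop("band too narrow for the period search range")
  denom <- sum(resid^2)
  if (denom < .Machine$double.eps) {
    ac <- rep(0, length(lags))
  } else {
    ac <- vapply(lags, function(k)
      sum(resid[1:(n - k)] * resid[(k + 1):n]) / denom, numeric(1))
  }
  best <- which.max(ac)
  cv <- if (mean(y) > 0) stats::sd(resid) / mean(y) else 0
  amplitude <- min(1, max(0, ac[best]) * cv)
  structure(list(period_bp = lags[best], amplitude = amplitude,
                 band = band), class = "periodicity_estimate")
}

#' @export
print.periodicity_estimate <- function(x, ...) {
  cat(sprintf("periodicity: %d bp (amplitude %.3f) in band [%d, %d] bp\n",
              x$period_bp, x$amplitude, x$band[1], x$band[2]))
  invisible(x)
}

#' Stratify fragment lengths by allele at a variant site
#'
#' Splits fragment lengths into mutant- and wild-type-carrying sets using the
#' sequenced base at the variant position. Bases below `min_base_quality` and
#' bases matching neither allele are excluded; each fragment gets one vote
#' (overlapping mates are not double-counted), and fragments whose mates
#' disagree at the position are excluded with a tallied reason.
#'
#' @param path SAM or BAM file of paired-end alignments.
#' @param variant A [variant_site()].
#' @param min_base_quality Minimum Phred base quality (default 20).
#' @param region_margin Margin in bp around the variant used to fetch both
#'   mates of covering pairs (default 1000; must be at least the longest
#'   fragment).
#' @return A list of class `allele_strata`: `mut` and `wt` (integer length
#'   vectors), `excluded` (named tally: `low_base_quality`, `other_base`,
#'   `discordant_mates`, `no_length`), `n_covering` fragments considered.
#'   Warns when no fragment covers the variant.
#' @export
stratify_by_allele <- function(path, variant, min_base_quality = 20L,
                               region_margin = 1000L) {
  stopifnot(inherits(variant, "variant_site"))
  bam <- as_indexed_bam(path)
  gr <- GenomicRanges::GRanges(variant$chrom,
                               IRanges::IRanges(variant$pos, variant$pos))
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE),
    which = gr)
  bases <- GenomicAlignments::stackStringsFromBam(
    bam, param = param, what = "seq", use.names = TRUE,
    D.letter = "-", N.letter = "-")
  quals <- GenomicAlignments::stackStringsFromBam(
    bam, param = param, what = "qual", use.names = TRUE,
    D.letter = "!", N.letter = "!")
  excl <- c(low_base_quality = 0L, other_base = 0L, discordant_mates = 0L,
            no_length = 0L)
  if (length(bases) == 0) {
    warning("no fragment covers the variant position")
    return(structure(list(mut = integer(0), wt = integer(0), excluded = excl,
                          n_covering = 0L), class = "allele_strata"))
  }
  base <- as.character(bases)
  q <- vapply(as.character(quals), function(s) utf8ToInt(s) - 33L, integer(1))
  ok_q <- q >= min_base_quality & base %in% c("A", "C", "G", "T")
  excl["low_base_quality"] <- length(unique(names(bases)[!ok_q]))
  votes <- split(base[ok_q], names(bases)[ok_q])
  call_one <- function(v) {
    u <- unique(v)
    if (length(u) > 1L) return("discordant")
    if (u == variant$alt) return("mut")
    if (u == variant$ref) return("wt")
    "other"
  }
  calls <- vapply(votes, call_one, character(1))
  excl["discordant_mates"] <- sum(calls == "discordant")
  excl["other_base"] <- sum(calls == "other")

  # fetch a window wide enough to contain both mates of every covering pair
  wide <- GenomicRanges::GRanges(
    variant$chrom,
    IRanges::IRanges(max(1L, variant$pos - region_margin),
                     variant$pos + region_margin))
  frag <- pair_fragments(read_alignments(bam, region = wide))$fragments
  len <- stats::setNames(frag$length, frag$qname)
  pick <- function(lbl) {
    ids <- names(calls)[calls == lbl]
    l <- len[ids]
    unname(l[!is.na(l)])
  }
  mut <- pick("mut"); wt <- pick("wt")
  excl["no_length"] <- sum(calls %in% c("mut", "wt")) - length(mut) - length(wt)
  structure(list(mut = as.integer(mut), wt = as.integer(wt), excluded = excl,
                 n_covering = length(calls)),
            class = "allele_strata")
}

#' @export
print.allele_strata <- function(x, ...) {
  cat(sprintf("allele-stratified fragment lengths: %d mut, %d wt (%d excluded)\n",
              length(x$mut), length(x$wt), sum(x$excluded)))
  invisible(x)
}

#' Mutant allele frequency
#'
#' `mut / (mut + wt)`; undefined (`NA`) when both counts are zero.
#'
#' @param mut_count,wt_count Non-negative allele counts (vectorized).
#' @return Proportion(s) in \[0, 1\], `NA` where undefined.
#' @export
#' @examples
#' maf(1, 99)
maf <- function(mut_count, wt_count) {
  if (any(c(mut_count, wt_count) < 0, na.rm = TRUE))
    stop("allele counts must be non-negative")
  total <- mut_count + wt_count
  ifelse(total > 0, mut_count / total, NA_real_)
}

#' Mutant-allele frequency by fragment-length bin
#'
#' Bins fragment lengths into `bin_width`-bp bins labelled by their lower
#' edge (`floor(length / bin_width) * bin_width`, so bin 50 covers 50-59 bp
#' at the default width) and reports the mutant allele frequency per bin.
#' Bins with fewer than `min_count` total observations are reported with an
#' undefined (`NA`) frequency, since sparse bins are erratic.
#'
#' @param mut_lengths,wt_lengths Fragment lengths carrying the mutant and
#'   wild-type alleles.
#' @param bin_width Bin width in bp (default 10, >= 1).
#' @param min_count Minimum bin total for a defined frequency (default 1).
#' @return data.frame `bin_lower, mut_count, wt_count, total, frequency`,
#'   one row per occupied bin, sorted by `bin_lower`. Empty inputs yield an
#'   empty table.
#' @export
binned_allele_frequency <- function(mut_lengths, wt_lengths, bin_width = 10L,
                                    min_count = 1L) {
  stopifnot(bin_width >= 1)
  bin_of <- function(l) as.integer(floor(l / bin_width) * bin_width)
  bins <- sort(unique(c(bin_of(mut_lengths), bin_of(wt_lengths))))
  if (length(bins) == 0)
    return(data.frame(bin_lower = integer(0), mut_count = integer(0),
                      wt_count = integer(0), total = integer(0),
                      frequency = numeric(0)))
  mut <- as.integer(table(factor(bin_of(mut_lengths), levels = bins)))
  wt <- as.integer(table(factor(bin_of(wt_lengths), levels = bins)))
  total <- mut + wt
  freq <- ifelse(total >= min_count, maf(mut, wt), NA_real_)
  data.frame(bin_lower = bins, mut_count = mut, wt_count = wt,
             total = total, frequency = freq)
}
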