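#' Two-component nucleosome-ladder fragment-length mixture
#'
#' Generative model for cell-free DNA (cfDNA) fragment lengths as a mixture of
#' two components: background cfDNA from normal (mostly hematopoietic) cells
#' with a modal length around 167 bp (mononucleosome plus linker), and
#' tumor-derived cfDNA (ctDNA) with shorter modal lengths (134/144 bp in the
#' xenograft setting, 145 bp in melanoma) on an approximately 10 bp ladder.
#' Each component is a weighted mixture of discretized truncated Gaussian
#' "teeth"; the tooth spacing of a comb built with [ladder_peaks()] carries the
#' 10 bp periodicity.
#'
#' @param tumor_fraction Proportion of fragments of tumor origin (theta),
#'   in \[0, 1\].
#' @param normal_peaks Peaks of the normal component: a list of
#'   `c(center_bp, weight)` pairs (or a two-column matrix). Default a single
#'   167 bp peak.
#' @param tumor_peaks Peaks of the tumor component, same format. Default two
#'   equal-weight peaks at 134 and 144 bp. For the melanoma-like preset use
#'   `list(c(145, 1))`.
#' @param period_bp Ladder tooth spacing in bp (default 10). Used by
#'   [ladder_peaks()] when building combs; the default peak lists put all mass
#'   on the listed peaks.
#' @param peak_sd_bp Standard deviation of each Gaussian tooth in bp
#'   (default 3). `0` gives point masses at the peak centers.
#' @param length_support Inclusive `c(min_bp, max_bp)` truncation range
#'   (default `c(50, 500)`).
#' @param het_mutant_fraction Probability that a tumor-origin fragment covering
#'   the variant carries the mutant allele (default 0.5, heterozygous;
#'   raise it to model amplification).
#' @param recovery_midpoint_bp Fragment length at which library-prep recovery
#'   is 50% (default 100 bp; short fragments are poorly recovered).
#' @param recovery_scale_bp Logistic scale of the recovery curve in bp
#'   (default 5). Must be positive (a value of 0 is accepted as the step-limit
#'   only through [retention_probability()]).
#'
#' @return An object of class `mixture_spec`.
#' @seealso [sample_fragment_length()], [length_pmf()], [mixture_window_maf()]
#' @export
#' @examples
#' spec <- mixture_spec(tumor_fraction = 0.05)
#' spec
mixture_spec <- function(tumor_fraction = 0,
                         normal_peaks = list(c(167, 1)),
                         tumor_peaks = list(c(134, 0.5), c(144, 0.5)),
                         period_bp = 10L,
                         peak_sd_bp = 3,
                         length_support = c(50L, 500L),
                         het_mutant_fraction = 0.5,
                         recovery_midpoint_bp = 100L,
                         recovery_scale_bp = 5) {
  stopifnot(is.numeric(tumor_fraction), length(tumor_fraction) == 1L,
            tumor_fraction >= 0, tumor_fraction <= 1)
  stopifnot(is.numeric(het_mutant_fraction), het_mutant_fraction >= 0,
            het_mutant_fraction <= 1)
  stopifnot(length(length_support) == 2L, length_support[1] < length_support[2])
  if (!is.numeric(peak_sd_bp) || peak_sd_bp < 0)
    stop("'peak_sd_bp' must be a non-negative number")
  if (!is.numeric(recovery_scale_bp) || recovery_scale_bp <= 0)
    stop("'recovery_scale_bp' must be positive")
  if (!is.numeric(period_bp) || period_bp <= 0)
    stop("'period_bp' must be positive")

  normal_peaks <- normalize_peaks(normal_peaks, length_support, "normal_peaks")
  tumor_peaks <- normalize_peaks(tumor_peaks, length_support, "tumor_peaks")

  structure(list(
    tumor_fraction = tumor_fraction,
    normal_peaks = normal_peaks,
    tumor_peaks = tumor_peaks,
    period_bp = as.integer(period_bp),
    peak_sd_bp = peak_sd_bp,
    length_support = as.integer(length_support),
    het_mutant_fraction = het_mutant_fraction,
    recovery_midpoint_bp = as.integer(recovery_midpoint_bp),
    recovery_scale_bp = recovery_scale_bp
  ), class = "mixture_spec")
}

# peaks: list of c(center, weight) or 2-col matrix -> matrix with normalized
# weights, centers checked against the support
normalize_peaks <- function(peaks, support, what) {
  if (length(peaks) == 0L)
    stop("'", what, "' must contain at least one peak")
  if (is.list(peaks)) peaks <- do.call(rbind, peaks)
  peaks <- as.matrix(peaks)
  if (ncol(peaks) != 2L) stop("'", what, "' must be (center, weight) pairs")
  colnames(peaks) <- c("center", "weight")
  if (any(peaks[, "weight"] < 0) || sum(peaks[, "weight"]) <= 0)
    stop("'", what, "' weights must be non-negative with positive sum")
  if (any(peaks[, "center"] < support[1] | peaks[, "center"] > support[2]))
    stop("'", what, "' centers must lie within the length support")
  peaks[, "weight"] <- peaks[, "weight"] / sum(peaks[, "weight"])
  peaks
}

#' @export
print.mixture_spec <- function(x, ...) {
  fmt <- function(p) paste(sprintf("%g bp (w=%.3g)", p[, "center"], p[, "weight"]),
                           collapse = ", ")
  cat("cfDNA fragment-length mixture\n")
  cat(sprintf("  tumor fraction (theta): %g\n", x$tumor_fraction))
  cat(sprintf("  normal peaks: %s\n", fmt(x$normal_peaks)))
  cat(sprintf("  tumor peaks:  %s\n", fmt(x$tumor_peaks)))
  cat(sprintf("  tooth sd %g bp, period %d bp, support [%d, %d] bp\n",
              x$peak_sd_bp, x$period_bp, x$length_support[1], x$length_support[2]))
  cat(sprintf("  het mutant fraction %g; recovery midpoint %d bp, scale %g bp\n",
              x$het_mutant_fraction, x$recovery_midpoint_bp, x$recovery_scale_bp))
  invisible(x)
}

#' Build a decaying comb of ladder teeth
#'
#' Convenience constructor for a peak list with teeth at
#' `center - k * period` for `k = 0, ..., n_teeth - 1`, with geometrically
#' decaying weights. Used to emulate the sawtooth sub-peaks spaced ~10 bp
#' that nuclease cutting leaves in cfDNA length profiles.
#'
#' @param center Dominant tooth position in bp.
#' @param period Tooth spacing in bp (default 10).
#' @param n_teeth Number of teeth (default 1).
#' @param decay Weight ratio between consecutive teeth, in (0, 1\] (default 0.5).
#' @return A list of `c(center, weight)` pairs suitable for [mixture_spec()].
#' @export
#' @examples
#' ladder_peaks(167, n_teeth = 3)
ladder_peaks <- function(center, period = 10, n_teeth = 1, decay = 0.5) {
  stopifnot(n_teeth >= 1, decay > 0, decay <= 1)
  k <- seq_len(n_teeth) - 1L
  lapply(k, function(i) c(center - i * period, decay^i))
}

component_peaks <- function(spec, component = c("tumor", "normal")) {
  component <- match.arg(component)
  if (component == "tumor") spec$tumor_peaks else spec$normal_peaks
}

#' Library-preparation retention probability
#'
#' Logistic retention curve modelling the dropout of short fragments during
#' library preparation: fragments below ~100 bp are poorly recovered.
#'
#' @param length_bp Fragment length(s) in bp.
#' @param midpoint_bp Length with 50% retention.
#' @param scale_bp Logistic scale in bp; `0` is treated as the step limit
#'   (retain iff `length_bp >= midpoint_bp`, with 0.5 exactly at the midpoint).
#' @return Retention probabilities in \[0, 1\].
#' @export
retention_probability <- function(length_bp, midpoint_bp = 100, scale_bp = 5) {
  if (scale_bp < 0) stop("'scale_bp' must be non-negative")
  if (scale_bp == 0) {
    p <- as.numeric(length_bp > midpoint_bp)
    p[length_bp == midpoint_bp] <- 0.5
    return(p)
  }
  stats::plogis((length_bp - midpoint_bp) / scale_bp)
}

#' Per-base-pair length probabilities of a mixture component
#'
#' Discretized truncated-Gaussian mass for every integer length in the
#' support: each tooth contributes `pnorm(l + 0.5) - pnorm(l - 0.5)` around its
#' center (a point mass when `peak_sd_bp` is 0), weighted and renormalized over
#' the support. Optionally multiplies in the library-prep retention curve
#' (renormalized), giving the length law of *sequenced* fragments.
#'
#' @param spec A [mixture_spec()].
#' @param component `"tumor"` or `"normal"`.
#' @param retention Apply the logistic library-prep retention curve
#'   (default `FALSE`).
#' @return Named numeric vector over `length_support[1]:length_support[2]`
#'   summing to 1.
#' @export
length_pmf <- function(spec, component = c("tumor", "normal"),
                       retention = FALSE) {
  peaks <- component_peaks(spec, component)
  lo <- spec$length_support[1]; hi <- spec$length_support[2]
  grid <- lo:hi
  pmf <- numeric(length(grid))
  for (i in seq_len(nrow(peaks))) {
    ctr <- peaks[i, "center"]; w <- peaks[i, "weight"]
    if (spec$peak_sd_bp == 0) {
      j <- match(round(ctr), grid)
      if (!is.na(j)) pmf[j] <- pmf[j] + w
    } else {
      pmf <- pmf + w * (stats::pnorm(grid + 0.5, ctr, spec$peak_sd_bp) -
                          stats::pnorm(grid - 0.5, ctr, spec$peak_sd_bp))
    }
  }
  if (retention)
    pmf <- pmf * retention_probability(grid, spec$recovery_midpoint_bp,
                                       spec$recovery_scale_bp)
  if (sum(pmf) <= 0) stop("component has no mass on the length support")
  pmf <- pmf / sum(pmf)
  names(pmf) <- grid
  pmf
}

#' Continuous mixture density of a component
#'
#' The continuous analogue of [length_pmf()]: a function of length (bp)
#' proportional to the weighted sum of Gaussian teeth, normalized so it
#' integrates to 1 over the length support. Requires `peak_sd_bp > 0`.
#'
#' @inheritParams length_pmf
#' @return A vectorized density function of length in bp.
#' @export
mixture_density <- function(spec, component = c("tumor", "normal")) {
  peaks <- component_peaks(spec, component)
  if (spec$peak_sd_bp == 0)
    stop("continuous density undefined for peak_sd_bp = 0")
  lo <- spec$length_support[1]; hi <- spec$length_support[2]
  z <- sum(peaks[, "weight"] *
             (stats::pnorm(hi, peaks[, "center"], spec$peak_sd_bp) -
                stats::pnorm(lo, peaks[, "center"], spec$peak_sd_bp)))
  function(l) {
    f <- vapply(l, function(li)
      sum(peaks[, "weight"] * stats::dnorm(li, peaks[, "center"], spec$peak_sd_bp)),
      numeric(1))
    ifelse(l < lo | l > hi, 0, f / z)
  }
}

#' Probability mass of a component inside a length window
#'
#' @inheritParams length_pmf
#' @param window `c(lo, hi)`: lengths with `lo <= L < hi` are inside.
#' @return Window mass in \[0, 1\].
#' @export
window_mass <- function(spec, component, window, retention = FALSE) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  pmf <- length_pmf(spec, component, retention = retention)
  grid <- as.integer(names(pmf))
  sum(pmf[grid >= window[1] & grid < window[2]])
}

#' Closed-form mutant-allele frequency inside a length window
#'
#' For a mixture with tumor fraction `theta` and heterozygous mutant fraction
#' `h`, the expected mutant-allele frequency among fragments restricted to a
#' length window W is
#' `h * theta * F_t(W) / (theta * F_t(W) + (1 - theta) * F_n(W))`,
#' where `F_t`, `F_n` are the tumor and normal window masses. This is the
#' quadrature oracle used to check Monte-Carlo size-selection results.
#'
#' @inheritParams window_mass
#' @return Expected MAF in the window, or `NaN` when neither component has
#'   mass there.
#' @export
mixture_window_maf <- function(spec, window, retention = FALSE) {
  ft <- window_mass(spec, "tumor", window, retention = retention)
  fn <- window_mass(spec, "normal", window, retention = retention)
  th <- spec$tumor_fraction
  num <- spec$het_mutant_fraction * th * ft
  den <- th * ft + (1 - th) * fn
  if (den == 0) return(NaN)
  num / den
}

#' Draw fragment lengths from one mixture component
#'
#' Integer lengths from the component's discretized truncated-Gaussian tooth
#' mixture: a tooth is chosen by weight, a Gaussian draw is rounded, and draws
#' outside the length support are rejected and redrawn. With `peak_sd_bp = 0`
#' the draw is the tooth center itself.
#'
#' @param n Number of draws.
#' @param component `"tumor"` or `"normal"`.
#' @param spec A [mixture_spec()].
#' @return Integer vector of `n` lengths, all within the support.
#' @export
#' @examples
#' spec <- mixture_spec()
#' set.seed(1)
#' table(sample_fragment_length(5, "normal", spec))
sample_fragment_length <- function(n, component = c("tumor", "normal"), spec) {
  component <- match.arg(component)
  stopifnot(inherits(spec, "mixture_spec"), n >= 0)
  if (n == 0) return(integer(0))
  peaks <- component_peaks(spec, component)
  idx <- sample.int(nrow(peaks), n, replace = TRUE, prob = peaks[, "weight"])
  centers <- peaks[idx, "center"]
  if (spec$peak_sd_bp == 0) return(as.integer(round(centers)))
  lo <- spec$length_support[1]; hi <- spec$length_support[2]
  out <- as.integer(round(stats::rnorm(n, centers, spec$peak_sd_bp)))
  bad <- which(out < lo | out > hi)
  while (length(bad) > 0) {
    out[bad] <- as.integer(round(stats::rnorm(length(bad), centers[bad],
                                              spec$peak_sd_bp)))
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}
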