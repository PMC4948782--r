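#' Generate a random reference sequence
#'
#' Uniform-base synthetic reference used when no real reference is supplied.
#'
#' @param length_bp Reference length in bp.
#' @param name Sequence name (default `"chrS"`).
#' @return A named length-1 [Biostrings::DNAStringSet].
#' @export
random_reference <- function(length_bp = 10000L, name = "chrS") {
  stopifnot(length_bp > 0)
  seq <- paste(sample(c("A", "C", "G", "T"), length_bp, replace = TRUE),
               collapse = "")
  ref <- Biostrings::DNAStringSet(seq)
  names(ref) <- name
  ref
}

#' Simulate a synthetic cfDNA cohort
#'
#' Draws `n_fragments` cfDNA fragments from the two-component length mixture:
#' each fragment is tumor-origin with probability `spec$tumor_fraction`, gets a
#' length from its component's nucleosome-ladder mixture, and is placed on the
#' reference. A configurable share of fragments is placed so that it covers
#' the variant position; covering tumor-origin fragments carry the mutant
#' allele with probability `spec$het_mutant_fraction`, all other covering
#' fragments carry the reference allele. Every fragment receives a random
#' duplex barcode. Optionally the logistic library-prep dropout of short
#' fragments is applied (see [apply_library_prep()]).
#'
#' @param n_fragments Number of fragments to draw (> 0).
#' @param spec A [mixture_spec()].
#' @param variant A [variant_site()] on the reference, or `NULL` to place one
#'   at the middle of the reference (alt allele chosen as the complement of
#'   the reference base).
#' @param reference A [Biostrings::DNAStringSet] (first sequence used), a
#'   character string, or `NULL` to generate a random 10 kb reference.
#' @param covering_fraction Share of fragments placed to overlap the variant
#'   (default 0.5).
#' @param apply_prep Apply library-prep retention and record the `retained`
#'   flag (default `FALSE`; all fragments retained).
#' @param seed Optional integer seed; when given, the R RNG is seeded so that
#'   the cohort (and any files written from it) is reproducible. Recorded in
#'   the returned object.
#' @return A `cfdna_cohort`: list with `observations` (the per-fragment
#'   truth table: data.frame `fragment_id, chrom, start, end, length,
#'   origin, allele, barcode, retained`; coordinates 0-based half-open),
#'   `variant`, `spec`, `reference`, `seed`.
#' @export
#' @examples
#' spec <- mixture_spec(tumor_fraction = 0.1)
#' coh <- simulate_cohort(500, spec, seed = 1)
#' coh
simulate_cohort <- function(n_fragments, spec, variant = NULL, reference = NULL,
                            covering_fraction = 0.5, apply_prep = FALSE,
                            seed = NULL) {
  stopifnot(inherits(spec, "mixture_spec"), n_fragments > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(reference)) reference <- random_reference()
  if (is.character(reference)) {
    reference <- Biostrings::DNAStringSet(reference)
    if (is.null(names(reference))) names(reference) <- "chrS"
  }
  ref_len <- Biostrings::width(reference)[1]
  ref_name <- names(reference)[1]
  if (ref_len == 0) stop("zero-length reference")
  ref_chars <- strsplit(as.character(reference[[1]]), "")[[1]]
  if (is.null(variant)) {
    pos <- as.integer(ceiling(ref_len / 2))
    ref_base <- ref_chars[pos]
    alt_base <- c(A = "T", C = "G", G = "C", T = "A")[[ref_base]]
    variant <- variant_site(ref_name, pos, ref_base, alt_base)
  }
  if (variant$pos < 1 || variant$pos > ref_len)
    stop("variant position outside the reference")
  if (ref_chars[variant$pos] != variant$ref)
    stop("reference base at the variant position is '", ref_chars[variant$pos],
         "', not the stated ref allele '", variant$ref, "'")
  if (spec$length_support[2] > ref_len)
    stop("reference shorter than the maximum fragment length")

  origin <- ifelse(stats::runif(n_fragments) < spec$tumor_fraction,
                   "tumor", "normal")
  len <- integer(n_fragments)
  is_t <- origin == "tumor"
  len[is_t] <- sample_fragment_length(sum(is_t), "tumor", spec)
  len[!is_t] <- sample_fragment_length(sum(!is_t), "normal", spec)

  # placement (0-based half-open [start, end)); variant at 0-based pos0
  pos0 <- variant$pos - 1L
  covers <- stats::runif(n_fragments) < covering_fraction
  start <- integer(n_fragments)
  # covering: start uniform in [pos0 - L + 1, pos0], clipped into the reference
  if (any(covers)) {
    lo <- pmax(0L, pos0 - len[covers] + 1L)
    hi <- pmin(pos0, ref_len - len[covers])
    if (any(hi < lo)) stop("variant too close to a reference edge to be covered")
    start[covers] <- lo + floor(stats::runif(sum(covers)) * (hi - lo + 1))
  }
  # non-covering: uniform placement, redrawn while overlapping the variant
  if (any(!covers)) {
    idx <- which(!covers)
    start[idx] <- floor(stats::runif(length(idx)) * (ref_len - len[idx] + 1))
    bad <- idx[start[idx] <= pos0 & pos0 < start[idx] + len[idx]]
    while (length(bad) > 0) {
      start[bad] <- floor(stats::runif(length(bad)) * (ref_len - len[bad] + 1))
      bad <- bad[start[bad] <= pos0 & pos0 < start[bad] + len[bad]]
    }
  }
  start <- as.integer(start)
  end <- start + len

  allele <- rep("none", n_fragments)
  cov_now <- start <= pos0 & pos0 < end
  allele[cov_now] <- "wt"
  mut <- cov_now & is_t &
    stats::runif(n_fragments) < spec$het_mutant_fraction
  allele[mut] <- "mut"

  barcode <- paste(random_barcodes(n_fragments), random_barcodes(n_fragments),
                   sep = "-")
  obs <- data.frame(
    fragment_id = sprintf("frag%06d", seq_len(n_fragments)),
    chrom = ref_name, start = start, end = end, length = len,
    origin = origin, allele = allele, barcode = barcode,
    retained = TRUE, stringsAsFactors = FALSE
  )
  coh <- structure(list(observations = obs, variant = variant, spec = spec,
                        reference = reference, seed = seed),
                   class = "cfdna_cohort")
  if (apply_prep) coh <- apply_library_prep(coh, spec)
  coh
}

#' @export
print.cfdna_cohort <- function(x, ...) {
  o <- x$observations
  cat(sprintf("cfDNA cohort: %d fragments (%d retained) on %s\n",
              nrow(o), sum(o$retained), o$chrom[1]))
  cat(sprintf("  tumor origin: %d; alleles mut/wt/none: %d/%d/%d\n",
              sum(o$origin == "tumor"), sum(o$allele == "mut"),
              sum(o$allele == "wt"), sum(o$allele == "none")))
  cat(sprintf("  variant %s:%d %s>%s; seed %s\n", x$variant$chrom,
              x$variant$pos, x$variant$ref, x$variant$alt,
              ifelse(is.null(x$seed), "<none>", x$seed)))
  invisible(x)
}

random_barcodes <- function(n, width = 6L) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
              nrow = n)
  apply(m, 1, paste, collapse = "")
}

#' Apply library-preparation dropout to a cohort
#'
#' Each fragment is retained independently with the logistic probability
#' `plogis((L - midpoint) / scale)` (see [retention_probability()]), modelling
#' the poor recovery of fragments shorter than ~100 bp during library
#' preparation. The truth table keeps all fragments, with `retained` updated.
#'
#' @param x A `cfdna_cohort` or a numeric vector of fragment lengths.
#' @param spec A [mixture_spec()] carrying the recovery parameters (defaults
#'   to the cohort's own spec).
#' @return For a cohort: the cohort with `retained` flags updated. For a
#'   numeric vector: a logical vector of retention indicators.
#' @export
apply_library_prep <- function(x, spec = NULL) {
  if (is.numeric(x)) {
    stopifnot(inherits(spec, "mixture_spec"))
    p <- retention_probability(x, spec$recovery_midpoint_bp,
                               spec$recovery_scale_bp)
    return(stats::runif(length(x)) < p)
  }
  stopifnot(inherits(x, "cfdna_cohort"))
  if (is.null(spec)) spec <- x$spec
  x$observations$retained <- apply_library_prep(x$observations$length, spec)
  x
}

#' Simulate dual-reference mapping qualities for read pairs
#'
#' Emits per-pair mapping qualities against two references (species A and B)
#' with a known true origin, for testing the xenograft species-of-origin
#' classifier. Each pair is drawn as one of three classes: `clean`
#' (high MQ against its own species, low against the other), `low` (low MQ
#' against both, discarded by the classifier), or `ambiguous` (comparable MQ
#' against both, also discarded).
#'
#' @param n_pairs Number of read pairs.
#' @param theta Probability that a pair's true origin is species A.
#' @param mq_clean `c(own, other)` mapping qualities of a clean pair
#'   (default `c(60, 0)`), oriented by the true origin.
#' @param p_low,p_ambiguous Probabilities of the `low` and `ambiguous`
#'   classes (defaults 0).
#' @param mq_low MQ pair emitted for the `low` class (default `c(10, 5)`,
#'   both below the 30 threshold).
#' @param mq_ambiguous MQ pair for the `ambiguous` class (default `c(45, 40)`:
#'   not both low, difference below 20).
#' @return data.frame `pair_id, true_origin, class, mq_a, mq_b`.
#' @export
emit_dual_species_qualities <- function(n_pairs, theta = 0.5,
                                        mq_clean = c(60, 0),
                                        p_low = 0, p_ambiguous = 0,
                                        mq_low = c(10, 5),
                                        mq_ambiguous = c(45, 40)) {
  stopifnot(n_pairs > 0, p_low >= 0, p_ambiguous >= 0, p_low + p_ambiguous <= 1)
  for (m in list(mq_clean, mq_low, mq_ambiguous))
    if (any(m < 0 | m > 60)) stop("mapping qualities must be in [0, 60]")
  cls <- sample(c("clean", "low", "ambiguous"), n_pairs, replace = TRUE,
                prob = c(1 - p_low - p_ambiguous, p_low, p_ambiguous))
  origin <- ifelse(stats::runif(n_pairs) < theta, "A", "B")
  mq_a <- numeric(n_pairs); mq_b <- numeric(n_pairs)
  ca <- cls == "clean" & origin == "A"
  cb <- cls == "clean" & origin == "B"
  mq_a[ca] <- mq_clean[1]; mq_b[ca] <- mq_clean[2]
  mq_a[cb] <- mq_clean[2]; mq_b[cb] <- mq_clean[1]
  mq_a[cls == "low"] <- mq_low[1]; mq_b[cls == "low"] <- mq_low[2]
  mq_a[cls == "ambiguous"] <- mq_ambiguous[1]
  mq_b[cls == "ambiguous"] <- mq_ambiguous[2]
  data.frame(pair_id = sprintf("pair%06d", seq_len(n_pairs)),
             true_origin = origin, class = cls,
             mq_a = mq_a, mq_b = mq_b, stringsAsFactors = FALSE)
}

#' Simulate duplex-barcoded read pairs with PCR duplicates
#'
#' Draws `n_molecules` source molecules (each with a distinct barcode and
#' fragment coordinates) and emits each one `duplicates` times (scalar, vector,
#' or sampled from a distribution function), for testing barcode-family
#' collapsing: unique-molecule recovery, singleton omission, and consensus
#' calling.
#'
#' @param n_molecules Number of distinct source molecules.
#' @param duplicates Integer scalar or vector (recycled) of copies per
#'   molecule, each >= 1.
#' @param p_mut Probability that a molecule carries the mutant allele.
#' @param chrom Chromosome name for the synthetic coordinates.
#' @return data.frame of read pairs: `read_id, barcode, chrom, start, end,
#'   orientation, allele, molecule_id` (the truth column).
#' @export
simulate_barcoded_pairs <- function(n_molecules, duplicates = 2L, p_mut = 0.5,
                                    chrom = "chrS") {
  stopifnot(n_molecules > 0, all(duplicates >= 1))
  d <- rep_len(as.integer(duplicates), n_molecules)
  start <- sample.int(1e6L, n_molecules, replace = TRUE)
  len <- sample(120:200, n_molecules, replace = TRUE)
  mol <- data.frame(
    molecule_id = sprintf("mol%05d", seq_len(n_molecules)),
    barcode = paste(random_barcodes(n_molecules), random_barcodes(n_molecules),
                    sep = "-"),
    chrom = chrom, start = start, end = start + len,
    orientation = sample(c("+", "-"), n_molecules, replace = TRUE),
    allele = ifelse(stats::runif(n_molecules) < p_mut, "mut", "wt"),
    stringsAsFactors = FALSE
  )
  idx <- rep(seq_len(n_molecules), d)
  out <- mol[idx, ]
  out$read_id <- sprintf("read%06d", seq_along(idx))
  rownames(out) <- NULL
  out[, c("read_id", "barcode", "chrom", "start", "end", "orientation",
          "allele", "molecule_id")]
}
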