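#' Collapse duplex-barcoded read pairs into molecule families
#'
#' Groups read pairs by `(barcode, chrom, start, end, orientation)` — the
#' duplex molecular barcode plus alignment information — into families, one
#' unique source-molecule observation per family. Families observed only once
#' (singletons) are flagged as omitted from downstream unique counts because
#' of their relatively higher error rates. The consensus allele at a variant
#' site is called by strict majority over the members' `mut`/`wt` votes;
#' ties are `ambiguous`, members without a vote contribute nothing, and a
#' family with no votes has consensus `none`.
#'
#' @param pairs data.frame with columns `read_id, barcode, chrom, start,
#'   end, orientation` and optionally `allele` (`"mut"`/`"wt"`; other values
#'   ignored as non-votes). Missing barcodes are record-level errors.
#' @return A list of class `barcode_families`: `families` (data.frame
#'   `barcode, chrom, start, end, orientation, size, consensus_allele,
#'   singleton`), `n_pairs` (input records), `n_unique` (non-singleton
#'   families).
#' @export
collapse_families <- function(pairs) {
  need <- c("read_id", "barcode", "chrom", "start", "end", "orientation")
  stopifnot(is.data.frame(pairs), all(need %in% names(pairs)))
  bad <- is.na(pairs$barcode) | pairs$barcode == ""
  if (any(bad))
    stop("missing barcode on read '", pairs$read_id[which(bad)[1]], "'")
  if (!"allele" %in% names(pairs)) pairs$allele <- "none"
  key <- paste(pairs$barcode, pairs$chrom, pairs$start, pairs$end,
               pairs$orientation, sep = "\r")
  idx <- split(seq_len(nrow(pairs)), key)
  fam <- lapply(idx, function(i) {
    v <- pairs$allele[i]
    nm <- sum(v == "mut"); nw <- sum(v == "wt")
    consensus <- if (nm + nw == 0) "none"
      else if (nm > nw) "mut" else if (nw > nm) "wt" else "ambiguous"
    data.frame(barcode = pairs$barcode[i[1]], chrom = pairs$chrom[i[1]],
               start = pairs$start[i[1]], end = pairs$end[i[1]],
               orientation = pairs$orientation[i[1]],
               size = length(i), consensus_allele = consensus,
               stringsAsFactors = FALSE)
  })
  families <- do.call(rbind, fam)
  families <- families[order(families$chrom, families$start, families$end,
                             families$barcode), , drop = FALSE]
  rownames(families) <- NULL
  families$singleton <- families$size == 1L
  structure(list(families = families, n_pairs = nrow(pairs),
                 n_unique = sum(!families$singleton)),
            class = "barcode_families")
}

#' @export
print.barcode_families <- function(x, ...) {
  cat(sprintf("barcode collapsing: %d read pairs -> %d families (%d singletons omitted)\n",
              x$n_pairs, nrow(x$families), sum(x$families$singleton)))
  invisible(x)
}

#' Unique observations from collapsed families
#'
#' One row per non-singleton family, suitable as input for
#' [copy_number_by_gene()] or re-collapsing (idempotence).
#'
#' @param x A `barcode_families` object.
#' @param drop_singletons Omit singleton families (default `TRUE`).
#' @return data.frame of unique molecule observations with a `read_id`
#'   column (the family key) so the table round-trips through
#'   [collapse_families()].
#' @export
unique_observations <- function(x, drop_singletons = TRUE) {
  stopifnot(inherits(x, "barcode_families"))
  f <- x$families
  if (drop_singletons) f <- f[!f$singleton, , drop = FALSE]
  data.frame(read_id = sprintf("uniq%06d", seq_len(nrow(f))),
             barcode = f$barcode, chrom = f$chrom, start = f$start,
             end = f$end, orientation = f$orientation,
             allele = ifelse(f$consensus_allele %in% c("mut", "wt"),
                             f$consensus_allele, "none"),
             stringsAsFactors = FALSE)
}

#' Gene-level copy number from mean unique depth
#'
#' Per-gene mean read depth of unique (family-collapsed) observations and
#' its ratio to a baseline; amplification is flagged when the ratio exceeds
#' a threshold. The baseline defaults to the panel median of the per-gene
#' mean depths, the usual normalisation for a targeted panel without
#' matched controls.
#'
#' @param obs data.frame of unique observations with `chrom, start, end`
#'   (0-based half-open).
#' @param genes data.frame with `gene, chrom, start, end` intervals
#'   (0-based half-open, non-overlapping per gene).
#' @param baseline Baseline depth; `NULL` (default) for the panel median.
#' @param amp_threshold Ratio above which a gene is flagged amplified
#'   (default 2).
#' @return data.frame `gene, mean_unique_depth, depth_ratio, amplified`.
#'   With no observations all depths are `NA`.
#' @export
copy_number_by_gene <- function(obs, genes, baseline = NULL,
                                amp_threshold = 2) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(genes)))
  if (nrow(obs) == 0) {
    return(data.frame(gene = genes$gene, mean_unique_depth = NA_real_,
                      depth_ratio = NA_real_, amplified = NA))
  }
  cov <- GenomicRanges::coverage(GenomicRanges::GRanges(
    obs$chrom, IRanges::IRanges(obs$start + 1L, obs$end)))
  mean_depth <- vapply(seq_len(nrow(genes)), function(i) {
    chrom <- genes$chrom[i]
    width <- genes$end[i] - genes$start[i]
    if (width <= 0) return(NA_real_)
    if (!chrom %in% names(cov)) return(0)
    v <- cov[[chrom]]
    lo <- genes$start[i] + 1L; hi <- genes$end[i]
    if (lo > length(v)) return(0)
    # coverage() run-length vectors end at the last covered base; bases
    # beyond that are depth 0 but must still enter the mean
    covered_hi <- min(hi, length(v))
    s <- sum(IRanges::Views(v, start = lo, end = covered_hi))
    s / width
  }, numeric(1))
  if (is.null(baseline)) baseline <- stats::median(mean_depth, na.rm = TRUE)
  ratio <- if (!is.na(baseline) && baseline > 0) mean_depth / baseline
    else rep(NA_real_, length(mean_depth))
  data.frame(gene = genes$gene, mean_unique_depth = mean_depth,
             depth_ratio = ratio,
             amplified = !is.na(ratio) & ratio > amp_threshold)
}
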