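#' Classify read pairs by species of origin from dual mapping qualities
#'
#' Xenograft read disambiguation: each read pair, aligned against both the
#' graft (A, e.g. human) and host (B, e.g. rat) references, is assigned to the
#' species it maps to unambiguously. The rules, applied in order:
#' \enumerate{
#'   \item both mapping qualities below `low_mq` (default 30): discarded as
#'     low quality;
#'   \item absolute MQ difference below `ambiguity_diff` (default 20):
#'     discarded as ambiguous (comparable quality against both references);
#'   \item otherwise assigned to the reference with the greater MQ.
#' }
#' Thresholds are strict as stated: a difference of exactly 20 is kept, an MQ
#' of exactly 30 is not low. `NA` mapping qualities (unmapped) are treated
#' as 0, so a pair unmapped against both references is discarded as low.
#'
#' @param mq_a,mq_b Mapping qualities (0-60) against references A and B;
#'   vectors are classified elementwise.
#' @param low_mq Both-low discard threshold (default 30).
#' @param ambiguity_diff Ambiguity discard threshold on `|mq_a - mq_b|`
#'   (default 20).
#' @return Factor with levels `A`, `B`, `discard_low`, `discard_ambiguous`.
#' @export
#' @examples
#' classify_read_pair(c(60, 25, 60, 50), c(0, 25, 45, 10))
classify_read_pair <- function(mq_a, mq_b, low_mq = 30, ambiguity_diff = 20) {
  stopifnot(length(mq_a) == length(mq_b))
  mq_a[is.na(mq_a)] <- 0
  mq_b[is.na(mq_b)] <- 0
  if (any(mq_a < 0 | mq_a > 60 | mq_b < 0 | mq_b > 60))
    stop("mapping qualities must be in [0, 60]")
  call <- ifelse(mq_a < low_mq & mq_b < low_mq, "discard_low",
                 ifelse(abs(mq_a - mq_b) < ambiguity_diff, "discard_ambiguous",
                        ifelse(mq_a > mq_b, "A", "B")))
  factor(call, levels = c("A", "B", "discard_low", "discard_ambiguous"))
}

#' Tumor-DNA abundance from species calls
#'
#' Abundance of graft (tumor) DNA among unambiguously assigned read pairs:
#' `n_A / (n_A + n_B)`. Discarded pairs are excluded from the denominator.
#' With no assigned pairs the abundance is undefined (`NA`), not zero.
#'
#' @param calls Factor or character vector of species calls as produced by
#'   [classify_read_pair()].
#' @return An `abundance_result`: list with counts `n_a`, `n_b`,
#'   `n_discard_low`, `n_discard_ambiguous`, the `abundance` proportion
#'   (`NA` when undefined) and the logical `defined`.
#' @export
tumor_abundance <- function(calls) {
  calls <- factor(as.character(calls),
                  levels = c("A", "B", "discard_low", "discard_ambiguous"))
  if (anyNA(calls)) stop("unknown species call value")
  n <- table(calls)
  n_a <- as.integer(n[["A"]]); n_b <- as.integer(n[["B"]])
  defined <- (n_a + n_b) > 0
  structure(list(
    n_a = n_a, n_b = n_b,
    n_discard_low = as.integer(n[["discard_low"]]),
    n_discard_ambiguous = as.integer(n[["discard_ambiguous"]]),
    abundance = if (defined) n_a / (n_a + n_b) else NA_real_,
    defined = defined
  ), class = "abundance_result")
}

#' @export
print.abundance_result <- function(x, ...) {
  cat("Species-of-origin abundance\n")
  cat(sprintf("  assigned A: %d, B: %d; discarded low: %d, ambiguous: %d\n",
              x$n_a, x$n_b, x$n_discard_low, x$n_discard_ambiguous))
  if (x$defined)
    cat(sprintf("  tumor (A) abundance: %.6g\n", x$abundance))
  else cat("  abundance undefined (no assigned pairs)\n")
  invisible(x)
}

#' Join per-reference alignments into per-pair dual mapping qualities
#'
#' Reads primary alignments of the same library against two references and
#' produces one record per read-pair name found in either file. The pair's MQ
#' against a reference is the minimum of its two mates' primary MQs there
#' (conservative); a pair missing from one file, or with unmapped mates,
#' contributes MQ 0 for that reference.
#'
#' @param path_a,path_b SAM or BAM files of the same read set aligned against
#'   references A and B.
#' @return data.frame `pair_id, mq_a, mq_b`.
#' @export
join_dual_alignments <- function(path_a, path_b) {
  pair_mq <- function(path, label) {
    aln <- read_alignments(path)
    if (nrow(aln) == 0)
      return(stats::setNames(numeric(0), character(0)))
    mate <- ifelse(bitwAnd(aln$flag, 0x40L) > 0L, 1L, 2L)
    key <- paste(aln$qname, mate)
    if (anyDuplicated(key)) {
      dup <- aln$qname[duplicated(key)][1]
      stop("duplicate primary alignment for read '", dup, "' in ", label)
    }
    mq <- aln$mapq
    mq[is.na(mq) | bitwAnd(aln$flag, 0x4L) > 0L] <- 0
    tapply(mq, aln$qname, min)
  }
  a <- pair_mq(path_a, "file A")
  b <- pair_mq(path_b, "file B")
  ids <- sort(union(names(a), names(b)))
  out <- data.frame(pair_id = ids,
                    mq_a = ifelse(ids %in% names(a), a[ids], 0),
                    mq_b = ifelse(ids %in% names(b), b[ids], 0),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
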