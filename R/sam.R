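#' Render a cohort as paired-end SAM alignment records
#'
#' Emits one proper FR read pair per retained fragment: 101 bp mates (the
#' sequencing configuration emulated throughout), with the forward mate at the
#' fragment start and the reverse mate ending at the fragment end. Fragments
#' shorter than the read length produce fully overlapping mates of the
#' fragment's own length. Mutant fragments carry the alt base in any mate that
#' covers the variant position; base qualities are uniform Q40. The duplex
#' barcode is written in the `RX` tag, the fragment id in `MI`.
#'
#' @param cohort A `cfdna_cohort` from [simulate_cohort()].
#' @param read_length Mate length in bp (default 101).
#' @return Character vector of SAM lines (header included).
#' @export
cohort_sam <- function(cohort, read_length = 101L) {
  stopifnot(inherits(cohort, "cfdna_cohort"))
  obs <- cohort$observations[cohort$observations$retained, , drop = FALSE]
  ref <- cohort$reference
  ref_name <- names(ref)[1]
  ref_len <- Biostrings::width(ref)[1]
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", ref_name, ref_len))
  if (nrow(obs) == 0) return(header)
  pos0 <- cohort$variant$pos - 1L
  alt <- cohort$variant$alt
  rl <- pmin(as.integer(read_length), obs$length)
  r1_start <- obs$start                 # 0-based
  r2_start <- obs$end - rl
  seq_at <- function(s0, w, mutated) {
    out <- as.character(Biostrings::extractAt(
      ref[[1]], IRanges::IRanges(start = s0 + 1L, width = w)))
    hit <- mutated & s0 <= pos0 & pos0 < s0 + w
    if (any(hit))
      substr(out[hit], pos0 - s0[hit] + 1L, pos0 - s0[hit] + 1L) <- alt
    out
  }
  mutated <- obs$allele == "mut"
  seq1 <- seq_at(r1_start, rl, mutated)
  seq2 <- seq_at(r2_start, rl, mutated)
  qual <- strrep("I", rl)
  tags <- sprintf("RX:Z:%s\tMI:Z:%s", obs$barcode, obs$fragment_id)
  rec <- function(flag, s0, mate_s0, seq, tlen) {
    sprintf("%s\t%d\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s\t%s",
            obs$fragment_id, flag, ref_name, s0 + 1L, rl, mate_s0 + 1L,
            tlen, seq, qual, tags)
  }
  lines <- c(rbind(rec(99L, r1_start, r2_start, seq1, obs$length),
                   rec(147L, r2_start, r1_start, seq2, -obs$length)))
  c(header, lines)
}

#' Write a cohort to disk (FASTA, SAM, truth table, config echo)
#'
#' Writes `reference.fa`, `alignments.sam` (retained fragments only),
#' `truth.tsv` (all fragments: `fragment_id, origin, length, allele, barcode,
#' retained`) and `config.json` (mixture parameters, variant, seed) into a
#' directory. Outputs are deterministic for a fixed seed, so identical runs
#' are byte-identical.
#'
#' @param cohort A `cfdna_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cfdna_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(reference = file.path(dir, "reference.fa"),
             alignments = file.path(dir, "alignments.sam"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "config.json"))
  Biostrings::writeXStringSet(cohort$reference, paths["reference"])
  writeLines(cohort_sam(cohort), paths["alignments"])
  truth <- cohort$observations[, c("fragment_id", "origin", "length",
                                   "allele", "barcode", "retained")]
  utils::write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  spec <- cohort$spec
  cfg <- list(
    tumor_fraction = spec$tumor_fraction,
    normal_peaks = unname(apply(spec$normal_peaks, 1, as.list)),
    tumor_peaks = unname(apply(spec$tumor_peaks, 1, as.list)),
    period_bp = spec$period_bp, peak_sd_bp = spec$peak_sd_bp,
    length_support = spec$length_support,
    het_mutant_fraction = spec$het_mutant_fraction,
    recovery_midpoint_bp = spec$recovery_midpoint_bp,
    recovery_scale_bp = spec$recovery_scale_bp,
    variant = cohort$variant[c("chrom", "pos", "ref", "alt")],
    seed = cohort$seed
  )
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null"), paths["config"])
  invisible(paths)
}
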