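# Shared fixtures: all test inputs are generated in code.

# Write a SAM file with the given alignment body lines and @SQ entries.
# sq: named integer vector of contig lengths.
sam_fixture <- function(lines, sq = c(chr1 = 10000L)) {
  path <- tempfile(fileext = ".sam")
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq))
  writeLines(c(header, lines), path)
  path
}

# One SAM record; seq/qual default to CIGAR-matched runs.
sam_rec <- function(qname, flag, rname, pos, cigar, mrnm = "=", mpos = pos,
                    tlen = 0, mapq = 60, seq = NULL, qual = NULL) {
  w <- GenomicAlignments::cigarWidthAlongQuerySpace(cigar)
  if (is.null(seq)) seq <- strrep("A", w)
  if (is.null(qual)) qual <- strrep("I", w)
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
          qname, flag, rname, pos, mapq, cigar, mrnm, mpos, tlen, seq, qual)
}

# A proper FR pair covering [start0, start0 + len) in 0-based half-open
# coordinates, with fully spanning mates when len <= 2 * read_len.
sam_pair <- function(qname, start0, len, rname = "chr1", read_len = NULL,
                     seq1 = NULL, seq2 = NULL, qual1 = NULL, qual2 = NULL) {
  if (is.null(read_len)) read_len <- min(101L, len)
  r1_pos <- start0 + 1L
  r2_pos <- start0 + len - read_len + 1L
  cig <- sprintf("%dM", read_len)
  c(sam_rec(qname, 99L, rname, r1_pos, cig, mpos = r2_pos, tlen = len,
            seq = seq1, qual = qual1),
    sam_rec(qname, 147L, rname, r2_pos, cig, mpos = r1_pos, tlen = -len,
            seq = seq2, qual = qual2))
}

# Cohort used by several suites: moderate tumor fraction, fixed seed.
demo_cohort <- function(n = 2000L, theta = 0.1, seed = 11L, ...) {
  simulate_cohort(n, mixture_spec(tumor_fraction = theta, ...), seed = seed)
}
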