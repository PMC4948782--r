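#' A single-nucleotide variant site
#'
#' @param chrom Sequence name.
#' @param pos 1-based position.
#' @param ref,alt Single reference / alternate bases (A/C/G/T), distinct.
#' @return A `variant_site`: list with `chrom`, `pos` (1-based), `pos0`
#'   (0-based), `ref`, `alt`.
#' @export
#' @examples
#' variant_site("chr7", 55249071, "C", "T")
variant_site <- function(chrom, pos, ref, alt) {
  pos <- as.integer(pos)
  stopifnot(length(chrom) == 1L, length(pos) == 1L, !is.na(pos), pos >= 1L)
  for (b in c(ref, alt))
    if (!is.character(b) || nchar(b) != 1L || !b %in% c("A", "C", "G", "T"))
      stop("alleles must be single A/C/G/T bases (SNVs only)")
  if (ref == alt) stop("ref and alt alleles must differ")
  structure(list(chrom = as.character(chrom), pos = pos, pos0 = pos - 1L,
                 ref = ref, alt = alt),
            class = "variant_site")
}

#' @export
print.variant_site <- function(x, ...) {
  cat(sprintf("variant %s:%d %s>%s\n", x$chrom, x$pos, x$ref, x$alt))
  invisible(x)
}

#' Read a variant site from a minimal VCF or TSV
#'
#' Accepts a VCF (`.vcf`) or a tab-separated file with columns
#' `chrom, pos, ref, alt` (header optional). Only single-SNV specifications
#' are supported: indels and multi-allelic records are errors, and files with
#' several records require `which` to select one.
#'
#' @param path File path.
#' @param which 1-based record index for multi-record files.
#' @return A [variant_site()].
#' @export
read_variant <- function(path, which = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- t(fix)  # single record: bare named vector
    fix <- as.data.frame(fix, stringsAsFactors = FALSE)
    if (nrow(fix) == 0) stop("no variant records in ", path)
    df <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  } else {
    first <- readLines(path, n = 1L)
    has_header <- grepl("chrom", first, ignore.case = TRUE)
    df <- utils::read.delim(path, header = has_header, comment.char = "#",
                            colClasses = "character")  # keep "T" a base
    if (!has_header) names(df)[1:4] <- c("chrom", "pos", "ref", "alt")
  }
  if (nrow(df) > 1L) {
    if (is.null(which))
      stop(nrow(df), " records in ", path,
           "; use 'which' to select one")
    df <- df[which, , drop = FALSE]
  }
  if (grepl(",", df$alt)) stop("multi-allelic record unsupported")
  if (nchar(df$ref) != 1L || nchar(df$alt) != 1L)
    stop("indel record unsupported (SNVs only)")
  variant_site(df$chrom, df$pos, toupper(df$ref), toupper(df$alt))
}

# Ensure a coordinate-sorted, indexed BAM exists for `path`; converts SAM
# in a session-local temp directory. Returns the BAM path.
as_indexed_bam <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = TRUE)
    # htslib drops unparseable records with only a console warning; surface
    # any loss as an explicit error
    n_body <- sum(!startsWith(readLines(path), "@"))
    n_bam <- Rsamtools::countBam(bam)$records
    if (n_bam != n_body)
      stop("parse error: ", n_body - n_bam, " of ", n_body,
           " alignment lines in '", path, "' could not be converted")
    return(bam)
  }
  if (!file.exists(paste0(path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", path)))
    Rsamtools::indexBam(path)
  path
}

#' Read primary alignment records from a SAM or BAM file
#'
#' Thin wrapper over [Rsamtools::scanBam()]: SAM input is converted to a
#' temporary coordinate-sorted BAM; secondary and supplementary alignments are
#' dropped. The reference-space `end` coordinate is derived from the CIGAR.
#'
#' @param path SAM or BAM file.
#' @param region Optional region as a [GenomicRanges::GRanges] or a
#'   `"chrom:start-end"` string; requires (and creates) an index.
#' @return data.frame with columns `qname, flag, rname, strand, pos, end,
#'   mapq, cigar, mrnm, mpos, isize, seq, qual`. Coordinates are 1-based
#'   inclusive as in SAM; `pos`/`end` are `NA` for unmapped records.
#' @export
read_alignments <- function(path, region = NULL) {
  bam <- as_indexed_bam(path)
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  what <- c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar",
            "mrnm", "mpos", "isize", "seq", "qual")
  if (is.null(region)) {
    param <- Rsamtools::ScanBamParam(flag = flag, what = what)
  } else {
    if (is.character(region)) region <- methods::as(region, "GRanges")
    param <- Rsamtools::ScanBamParam(flag = flag, what = what, which = region)
  }
  res <- Rsamtools::scanBam(bam, param = param)
  one <- function(r) data.frame(
    qname = r$qname, flag = r$flag, rname = as.character(r$rname),
    strand = as.character(r$strand), pos = r$pos,
    end = r$pos + ifelse(is.na(r$cigar), NA_integer_,
                         GenomicAlignments::cigarWidthAlongReferenceSpace(
                           ifelse(is.na(r$cigar), "1M", r$cigar))) - 1L,
    mapq = r$mapq, cigar = r$cigar, mrnm = as.character(r$mrnm),
    mpos = r$mpos, isize = r$isize,
    seq = as.character(r$seq), qual = as.character(r$qual),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(res, one))
  if (is.null(out))
    out <- one(list(qname = character(0), flag = integer(0),
                    rname = character(0), strand = character(0),
                    pos = integer(0), mapq = integer(0), cigar = character(0),
                    mrnm = character(0), mpos = integer(0), isize = integer(0),
                    seq = character(0), qual = character(0)))
  rownames(out) <- NULL
  out
}

#' Build a reconciled run report
#'
#' Structured record of one pipeline stage: record counts in/out with
#' per-reason exclusions, a parameter echo, input checksums, and the seed.
#' Construction fails unless the counts reconcile
#' (`n_in = n_out + sum(excluded)`).
#'
#' @param stage Stage name.
#' @param n_in,n_out Records in and out.
#' @param excluded Named integer vector of per-reason exclusion counts
#'   (may be empty).
#' @param params Named list of parameters to echo.
#' @param inputs Character vector of input paths; md5 checksums are recorded
#'   for those that exist.
#' @param seed Seed used by the stage, if any.
#' @param timestamp Optional timestamp string. Omitted by default so that
#'   identical runs produce byte-identical reports.
#' @return A `run_report` list.
#' @export
run_report <- function(stage, n_in, n_out, excluded = integer(0),
                       params = list(), inputs = character(0), seed = NULL,
                       timestamp = NULL) {
  nm <- names(excluded)
  if (length(excluded) > 0 && is.null(nm))
    stop("'excluded' must be named by reason")
  excluded <- stats::setNames(as.integer(excluded), nm)
  if (n_in != n_out + sum(excluded))
    stop("counts do not reconcile: in = ", n_in, ", out = ", n_out,
         ", excluded = ", sum(excluded))
  checksums <- NULL
  existing <- inputs[file.exists(inputs)]
  if (length(existing) > 0)
    checksums <- as.list(tools::md5sum(existing))
  structure(list(stage = stage, n_in = n_in, n_out = n_out,
                 excluded = as.list(excluded), params = params,
                 input_checksums = checksums, seed = seed,
                 timestamp = timestamp),
            class = "run_report")
}

#' Write a run report as deterministic JSON
#'
#' Keys are sorted and no timestamp is included unless one was set, so a
#' rerun with the same inputs, seed and parameters is byte-identical.
#'
#' @param report A [run_report()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  if (report$n_in != report$n_out + sum(unlist(report$excluded)))
    stop("refusing to write an unreconciled report")
  x <- unclass(report)
  x <- x[!vapply(x, is.null, logical(1))]
  sort_rec <- function(v) {
    if (is.list(v) && !is.null(names(v)) && length(v) > 0)
      v <- lapply(v[order(names(v))], sort_rec)
    v
  }
  writeLines(jsonlite::toJSON(sort_rec(x), auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}
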