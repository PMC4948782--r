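#' A PCR primer pair
#'
#' The reverse primer is kept as printed in protocol notation, which is
#' commonly written 3'->5'. That notation is ambiguous (it may denote the
#' antiparallel complement of the plus strand, or be a mislabelled 5'->3'
#' oligo), so [find_amplicon()] can resolve it empirically.
#'
#' @param forward Forward primer, 5'->3', A/C/G/T only.
#' @param reverse_printed Reverse primer exactly as printed.
#' @param expected_length Optional expected product length in bp
#'   (primer-inclusive), used by `auto` orientation resolution.
#' @return A `primer_pair` list.
#' @export
primer_pair <- function(forward, reverse_printed, expected_length = NULL) {
  for (p in c(forward, reverse_printed))
    if (!grepl("^[ACGT]+$", p))
      stop("primers must be non-empty A/C/G/T strings")
  structure(list(forward = forward, reverse_printed = reverse_printed,
                 expected_length = expected_length), class = "primer_pair")
}

#' Ladder primer pairs on phage lambda
#'
#' The three primer pairs used to build a gel ladder of 262, 240 and 229 bp
#' double-stranded DNA fragments from the phage lambda genome, reverse
#' primers as printed (3'->5' notation).
#'
#' @return List of three [primer_pair()]s with expected lengths 262, 240
#'   and 229 bp.
#' @export
lambda_ladder_primers <- function() {
  list(
    primer_pair("CATCTGCTTCTGCTTTCGCC", "CTGGGTATTTCCCGGCCTTT", 262L),
    primer_pair("GGAACCCACCGAGTGAAAGT", "ACTCTTTCCATGCCGCTTCA", 240L),
    primer_pair("GATGGCTCGCCAGTTCCATA", "ACCAATATCCAGCACCGCAT", 229L)
  )
}

dna_complement <- function(x) chartr("ACGT", "TGCA", x)
dna_revcomp <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(dna_complement(s), "")[[1]]),
                              collapse = ""), character(1), USE.NAMES = FALSE)
}

# Plus-strand binding site of the printed reverse primer under one
# interpretation of its notation.
reverse_site <- function(printed, orientation = c("as_printed", "reversed")) {
  orientation <- match.arg(orientation)
  if (orientation == "as_printed") dna_complement(printed)  # 3'->5' antiparallel
  else dna_revcomp(printed)                                 # printed is 5'->3'
}

match_starts <- function(pattern, template) {
  Biostrings::start(Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                             template))
}

find_amplicon_one_strand <- function(template, pair, orientation) {
  fwd_starts <- match_starts(pair$forward, template)
  if (length(fwd_starts) == 0) return(NULL)
  site <- reverse_site(pair$reverse_printed, orientation)
  site_starts <- match_starts(site, template)
  if (length(site_starts) == 0)
    return(list(products = data.frame(start = integer(0), end = integer(0),
                                      length = integer(0))))
  combos <- expand.grid(f = fwd_starts, s = site_starts)
  combos <- combos[combos$s >= combos$f + nchar(pair$forward), , drop = FALSE]
  end <- combos$s + nchar(site) - 1L
  list(products = data.frame(start = as.integer(combos$f) - 1L,  # 0-based
                             end = as.integer(end),              # exclusive
                             length = as.integer(end) - as.integer(combos$f) + 1L))
}

#' Locate a primer pair's amplicon on a template by exact matching
#'
#' Finds the forward primer on the template, locates the reverse primer's
#' binding site downstream under the chosen interpretation of its printed
#' notation, and returns the primer-inclusive amplicon. Both strands of the
#' template are considered (product length is invariant under
#' reverse-complementing the template). `auto` mode tries both
#' interpretations of the printed reverse primer and keeps the one that
#' yields a unique product (preferring a product matching
#' `expected_length` when both do), reporting which was used.
#'
#' @param template Template sequence: a character string,
#'   [Biostrings::DNAString] or length-1 [Biostrings::DNAStringSet].
#' @param pair A [primer_pair()].
#' @param orientation_mode `"auto"` (default), `"as_printed"` (the printed
#'   reverse primer is a 3'->5' antiparallel annotation; its plus-strand
#'   site is its base complement) or `"reversed"` (the printed string is
#'   already the 5'->3' oligo; its site is its reverse complement).
#' @return An `amplicon`: list with `start` (0-based), `end` (exclusive)
#'   on the strand where the forward primer matched, `length` in bp,
#'   `strand` (`"+"`/`"-"` of the template), and `orientation` used.
#'   Errors name the missing primer, or list all sites when the product is
#'   not unique.
#' @export
find_amplicon <- function(template, pair,
                          orientation_mode = c("auto", "as_printed",
                                               "reversed")) {
  orientation_mode <- match.arg(orientation_mode)
  stopifnot(inherits(pair, "primer_pair"))
  if (is.character(template)) template <- Biostrings::DNAString(template)
  if (inherits(template, "DNAStringSet")) template <- template[[1]]
  if (length(template) == 0) stop("empty template")

  try_orientation <- function(orientation) {
    found_fwd <- FALSE
    products <- NULL
    for (strand in c("+", "-")) {
      tmpl <- if (strand == "+") template
        else Biostrings::reverseComplement(template)
      res <- find_amplicon_one_strand(tmpl, pair, orientation)
      if (is.null(res)) next  # forward primer absent on this strand
      found_fwd <- TRUE
      p <- res$products
      if (nrow(p) > 0) {
        p$strand <- strand
        products <- rbind(products, p)
      }
    }
    if (!found_fwd) return(NULL)
    if (is.null(products))
      products <- data.frame(start = integer(0), end = integer(0),
                             length = integer(0), strand = character(0))
    list(products = products, orientation = orientation)
  }

  modes <- if (orientation_mode == "auto") c("as_printed", "reversed")
    else orientation_mode
  hits <- list()
  fwd_seen <- FALSE
  for (m in modes) {
    h <- try_orientation(m)
    if (is.null(h)) next
    fwd_seen <- TRUE
    if (nrow(h$products) > 0) hits[[m]] <- h
  }
  if (!fwd_seen)
    stop("forward primer '", pair$forward, "' not found on either strand")
  if (length(hits) == 0)
    stop("reverse primer '", pair$reverse_printed,
         "' has no downstream binding site under ",
         paste(modes, collapse = " or "), " interpretation")
  pick <- function(h) {
    p <- h$products
    if (nrow(p) > 1L) {
      if (!is.null(pair$expected_length) &&
          sum(p$length == pair$expected_length) == 1L)
        p <- p[p$length == pair$expected_length, , drop = FALSE]
      else
        stop("multiple products (", paste(p$length, collapse = ", "),
             " bp) at starts ", paste(p$start, collapse = ", "))
    }
    structure(list(start = p$start, end = p$end, length = p$length,
                   strand = p$strand, orientation = h$orientation),
              class = "amplicon")
  }
  if (length(hits) == 1L) return(pick(hits[[1]]))
  # both interpretations produce products: disambiguate by expected length
  amps <- lapply(hits, pick)
  if (!is.null(pair$expected_length)) {
    ok <- vapply(amps, function(a) a$length == pair$expected_length,
                 logical(1))
    if (sum(ok) == 1L) return(amps[[which(ok)]])
  }
  stop("ambiguous reverse-primer orientation: both interpretations yield ",
       "products (", paste(vapply(amps, `[[`, numeric(1), "length"),
                           collapse = ", "), " bp)")
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("amplicon %d bp at [%d, %d) on '%s' strand (reverse primer read %s)\n",
              x$length, x$start, x$end, x$strand, x$orientation))
  invisible(x)
}

#' Product lengths of a list of primer pairs on one template
#'
#' @inheritParams find_amplicon
#' @param pairs List of [primer_pair()]s.
#' @return Integer vector of primer-inclusive product lengths, in input
#'   order; errors from [find_amplicon()] propagate per pair.
#' @export
ladder_lengths <- function(template, pairs,
                           orientation_mode = "auto") {
  vapply(pairs, function(p)
    find_amplicon(template, p, orientation_mode)$length, integer(1))
}

#' Synthetic ladder template with the lambda ladder primer sites
#'
#' The real phage lambda genome is not distributed with this package; this
#' function builds a small *synthetic* stand-in template in which the three
#' printed ladder primer pairs are planted so that their primer-inclusive
#' products are exactly 262, 240 and 229 bp. It exercises the printed-primer
#' orientation resolution and length arithmetic of [find_amplicon()], but
#' its coordinates are synthetic and do not correspond to the lambda genome.
#'
#' @param spacer_bp Random spacer length between planted amplicons
#'   (default 60).
#' @return A named [Biostrings::DNAStringSet] of one synthetic template.
#' @export
synthetic_ladder_template <- function(spacer_bp = 60L) {
  pairs <- lambda_ladder_primers()
  # deterministic background; keep the caller's RNG state untouched
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(state)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", state, envir = globalenv())
  })
  set.seed(20160718L)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")
  repeat {
    parts <- rand(spacer_bp)
    for (p in pairs) {
      site <- reverse_site(p$reverse_printed, "as_printed")
      filler <- p$expected_length - nchar(p$forward) - nchar(site)
      parts <- c(parts, p$forward, rand(filler), site, rand(spacer_bp))
    }
    template <- Biostrings::DNAString(paste(parts, collapse = ""))
    # reject templates with spurious primer/site matches on either strand
    probes <- unlist(lapply(pairs, function(p)
      c(p$forward, reverse_site(p$reverse_printed, "as_printed"),
        reverse_site(p$reverse_printed, "reversed"))))
    n_hits <- vapply(probes, function(q)
      length(match_starts(q, template)) +
        length(match_starts(q, Biostrings::reverseComplement(template))),
      integer(1))
    expected_hits <- rep(c(1L, 1L, 0L), length(pairs))
    if (all(n_hits == expected_hits)) break
  }
  out <- Biostrings::DNAStringSet(template)
  names(out) <- "synthetic_ladder_template"
  out
}
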