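#' IUPAC code expansion
#'
#' @param code single IUPAC nucleotide letter.
#' @return Character vector of the concrete bases the code allows.
#' @export
iupac_bases <- function(code) {
  tab <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  code <- toupper(code)
  if (!code %in% names(tab)) stop("invalid IUPAC letter: '", code, "'")
  tab[[code]]
}

#' Scan a reference for a degenerate (IUPAC) motif
#'
#' Reports the 0-based start positions of every exact degenerate match on
#' the top strand, overlapping matches included; circular references are
#' scanned across the origin. Matching is delegated to
#' [Biostrings::matchPattern()] with `fixed = FALSE`. For patterns that are
#' their own reverse complement (such as the dyad-symmetric hexamers GNATNC
#' and its inverse control CNTANG) single-strand scanning already finds
#' every dyad placement; for general patterns set `both_strands = TRUE` to
#' additionally report top-strand start positions of reverse-complement
#' matches.
#'
#' @param ref a `ref_seq`.
#' @param pattern IUPAC string.
#' @param regions optional data.frame of 0-based half-open `start`/`end`
#'   intervals; matches are kept only if fully inside a region.
#' @param both_strands also scan the reverse complement of the pattern.
#' @return Sorted integer vector of 0-based match start positions.
#' @export
motif_scan <- function(ref, pattern, regions = NULL, both_strands = FALSE) {
  pattern <- toupper(pattern)
  for (ch in strsplit(pattern, "", fixed = TRUE)[[1L]]) iupac_bases(ch)
  k <- nchar(pattern)
  subject <- ref$seq
  if (ref$topology == "circular" && k > 1L)
    subject <- paste0(subject, substr(ref$seq, 1L, k - 1L))
  pats <- pattern
  if (both_strands) pats <- unique(c(pattern, revcomp(pattern)))
  hits <- integer(0)
  for (p in pats) {
    m <- Biostrings::matchPattern(p, Biostrings::DNAString(subject),
                                  fixed = FALSE)
    hits <- c(hits, BiocGenerics::start(m) - 1L)
  }
  hits <- sort(unique(hits[hits < ref_length(ref)]))
  if (!is.null(regions) && nrow(regions) > 0L) {
    inside <- vapply(hits, function(h) {
      any(h >= regions$start & (h + k) <= regions$end)
    }, logical(1L))
    hits <- hits[inside]
  }
  hits
}
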