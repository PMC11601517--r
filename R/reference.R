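#' Reference sequences
#'
#' A reference sequence is a named DNA sequence over the strict alphabet
#' {A, C, G, T} with linear or circular topology. All coordinates in this
#' package are 0-based (BED-style): the first base of the reference is
#' position 0. Circular references wrap coordinates modulo their length.
#'
#' @param name character scalar identifier.
#' @param seq character scalar over A/C/G/T (lowercase accepted, uppercased).
#' @param topology `"circular"` or `"linear"`.
#' @return An object of class `ref_seq` with fields `name`, `seq`, `topology`.
#' @export
reference_sequence <- function(name, seq, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) < 1L) stop("reference sequence must have length >= 1")
  if (grepl("[^ACGT]", seq)) {
    bad <- regmatches(seq, regexpr("[^ACGT]", seq))
    stop("reference sequence contains non-ACGT character: '", bad, "'")
  }
  structure(list(name = name, seq = seq, topology = topology),
            class = "ref_seq")
}

#' @export
print.ref_seq <- function(x, ...) {
  cat(sprintf("<ref_seq> %s: %d bp, %s\n", x$name, ref_length(x), x$topology))
  invisible(x)
}

#' Length of a reference sequence in base pairs
#' @param ref a `ref_seq`.
#' @export
ref_length <- function(ref) nchar(ref$seq)

#' Generate a random reference sequence
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = `gc`/2 and
#' P(A) = P(T) = (1 - `gc`)/2. The same `length`, `gc` and `seed` always
#' yield the same sequence.
#'
#' @param length number of bases (>= 1).
#' @param gc target G+C fraction in `[0, 1]`.
#' @param topology `"circular"` or `"linear"`.
#' @param seed integer RNG seed.
#' @param name identifier for the generated sequence.
#' @return A `ref_seq`.
#' @export
generate_reference <- function(length, gc = 0.5,
                               topology = c("circular", "linear"),
                               seed = 1L, name = "synthetic") {
  topology <- match.arg(topology)
  if (!is.numeric(length) || length < 1) stop("length must be >= 1")
  if (!is.numeric(gc) || gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  s <- paste(sample(names(p), size = length, replace = TRUE, prob = p),
             collapse = "")
  reference_sequence(name, s, topology)
}

# Base complement / reverse complement on plain character vectors.
complement_base <- function(b) chartr("ACGT", "TGCA", b)

revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# Extract bases at 0-based positions (wrapping if circular). Returns a
# character vector of single bases; errors if a linear reference cannot
# cover the request.
ref_bases_at <- function(ref, pos0) {
  L <- ref_length(ref)
  if (ref$topology == "circular") {
    pos0 <- pos0 %% L
  } else if (any(pos0 < 0L | pos0 >= L)) {
    stop("window out of range for linear reference '", ref$name, "'")
  }
  substring(ref$seq, pos0 + 1L, pos0 + 1L)
}

# Contiguous 0-based [start, start + width) slice with circular wrapping.
ref_slice <- function(ref, start0, width) {
  paste(ref_bases_at(ref, start0 + seq_len(width) - 1L), collapse = "")
}

#' Reverse-complement a reference sequence
#'
#' Used by symmetry checks: a rotationally symmetric cleavage-preference
#' model must score a reverse-complemented circular reference identically
#' (up to coordinate relabelling).
#'
#' @param ref a `ref_seq`.
#' @return A `ref_seq` on the opposite strand.
#' @export
ref_revcomp <- function(ref) {
  reference_sequence(ref$name, revcomp(ref$seq), ref$topology)
}
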