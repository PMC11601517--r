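#' Extract the dyad-oriented sequence window of a peak
#'
#' Reorients every called position into a common dyad frame, so that base
#' composition can be averaged across peaks from both strands. The read
#' position (the nucleotide next to the sequencing adaptor) always lands at
#' relative position -1, one base 5' of the dyad axis on the read's strand:
#'
#' * top-strand peak at `x`: relative -k maps to `x - k + 1`, +k to `x + k`
#'   (window `x - N + 1 .. x + N` read off the top strand);
#' * bottom-strand peak at `x`: the window is taken on the bottom strand —
#'   top-strand slice `x - N .. x + N - 1`, reverse-complemented — so `x`
#'   again occupies relative -1 of the oriented sequence.
#'
#' For a DSB at `dyad_left = p` (top read at `p`, bottom read at `p + 1`)
#' the two oriented windows are exact reverse complements of one another.
#'
#' @param ref a `ref_seq`.
#' @param pos 0-based peak position.
#' @param strand `"top"` or `"bottom"`.
#' @param halfwidth N: window covers relative positions -N..-1, +1..+N.
#' @return Character vector of 2N single bases named by relative position.
#' @export
extract_dyad_window <- function(ref, pos, strand, halfwidth = 10L) {
  N <- as.integer(halfwidth)
  if (N < 1L) stop("halfwidth must be >= 1")
  if (strand == "top") {
    bases <- ref_bases_at(ref, pos - N + seq_len(2L * N))
  } else if (strand == "bottom") {
    fwd <- ref_bases_at(ref, pos - N - 1L + seq_len(2L * N))
    bases <- rev(complement_base(fwd))
  } else stop("strand must be 'top' or 'bottom'")
  names(bases) <- relpos_labels(N)
  bases
}

#' Dyad windows for a set of peaks
#'
#' @param ref a `ref_seq`.
#' @param peaks data.frame with `pos` and `strand`.
#' @param halfwidth window half-width N.
#' @return Character matrix, one row per peak, columns -N..-1, +1..+N.
#' @export
dyad_windows <- function(ref, peaks, halfwidth = 10L) {
  m <- t(vapply(seq_len(nrow(peaks)), function(i) {
    extract_dyad_window(ref, peaks$pos[i], as.character(peaks$strand[i]),
                        halfwidth)
  }, character(2L * halfwidth)))
  colnames(m) <- relpos_labels(halfwidth)
  m
}

#' Base-composition matrix over dyad-oriented windows
#'
#' Column-wise base frequencies across equal-width oriented windows: the
#' fractional composition of each base at each position relative to the
#' dyad axis.
#'
#' @param windows character matrix from [dyad_windows()], or a list of
#'   equal-length base vectors.
#' @return An object of class `composition_matrix`: list with `fractions`
#'   (positions x ACGT, rows sum to 1), `n_sites`, `halfwidth`.
#' @export
composition_matrix <- function(windows) {
  if (is.list(windows) && !is.matrix(windows)) {
    wid <- unique(lengths(windows))
    if (length(wid) != 1L) stop("windows differ in width")
    windows <- do.call(rbind, windows)
    colnames(windows) <- relpos_labels(wid / 2L)
  }
  if (nrow(windows) < 1L) stop("need at least one window")
  bases <- c("A", "C", "G", "T")
  frac <- t(apply(windows, 2L, function(col) {
    tab <- table(factor(col, levels = bases))
    as.numeric(tab) / length(col)
  }))
  colnames(frac) <- bases
  structure(list(fractions = frac, n_sites = nrow(windows),
                 halfwidth = ncol(windows) / 2L),
            class = "composition_matrix")
}

#' @export
print.composition_matrix <- function(x, ...) {
  cat(sprintf("<composition_matrix> %d sites, positions -%d..+%d\n",
              x$n_sites, x$halfwidth, x$halfwidth))
  print(round(x$fractions, 3))
  invisible(x)
}

#' GC-corrected sequence logo matrix
#'
#' Letter heights in bits against a background set by the substrate's G+C
#' content: background b = {A, T: (1-gc)/2; G, C: gc/2}; per-position
#' information is the relative entropy R = sum_b f_b log2(f_b / b_b) (with
#' 0 log 0 = 0) and each letter's height is f_b * R. A composition equal to
#' the background scores 0 everywhere; a one-hot column at gc = 0.5 scores
#' log2(4) = 2 bits. The background GC is overridable per substrate, e.g.
#' local GC around mapped sites instead of the genome average when the two
#' differ substantially.
#'
#' @param comp a `composition_matrix`.
#' @param background_gc background G+C fraction, strictly inside (0, 1).
#' @return An object of class `logo_matrix`: `heights` (positions x ACGT,
#'   bits), `information` (per-position R), `background` (ACGT probs).
#' @export
gc_corrected_logo <- function(comp, background_gc = 0.5) {
  if (background_gc <= 0 || background_gc >= 1)
    stop("background_gc must be strictly between 0 and 1")
  b <- c(A = (1 - background_gc) / 2, C = background_gc / 2,
         G = background_gc / 2, T = (1 - background_gc) / 2)
  f <- comp$fractions
  kl_term <- f * log2(sweep(f, 2L, b[colnames(f)], "/"))
  kl_term[f == 0] <- 0
  R <- rowSums(kl_term)
  structure(list(heights = f * R, information = R, background = b),
            class = "logo_matrix")
}

#' Rotational-symmetry score of a composition matrix
#'
#' Mean absolute deviation from the dyad-symmetry identity
#' `f(p, b) == f(-p, complement(b))` over all positions p > 0 and bases b.
#' 0 means perfectly rotationally symmetric (the signature expected of a
#' symmetric dimer); sampling noise keeps empirical values slightly above 0.
#'
#' @param comp a `composition_matrix`.
#' @return Scalar in `[0, 1]`.
#' @export
symmetry_score <- function(comp) {
  f <- comp$fractions
  N <- comp$halfwidth
  compl <- c(A = "T", C = "G", G = "C", T = "A")
  devs <- unlist(lapply(seq_len(N), function(p) {
    vapply(colnames(f), function(b) {
      abs(f[as.character(p), b] - f[as.character(-p), compl[[b]]])
    }, numeric(1L))
  }))
  mean(devs)
}

#' Average strand-specific profile around anchor positions
#'
#' Position-wise mean of top- and bottom-strand values across windows
#' centred on each anchor, plus the per-anchor matrices for heat-map style
#' display. Used e.g. to ask whether motif matches carry cleavage signal at
#' the geometrically expected strand offsets while control anchors are flat.
#'
#' @param map a `strand_map`.
#' @param anchors 0-based anchor positions (window centres).
#' @param halfwidth half window width h (window spans offsets -h..+h).
#' @return List with `offset` (-h..h), `top`/`bottom` (mean profiles) and
#'   `top_matrix`/`bottom_matrix` (anchors x offsets).
#' @export
average_profile_around <- function(map, anchors, halfwidth = 10L) {
  if (length(anchors) == 0L) stop("empty anchor list")
  h <- as.integer(halfwidth)
  L <- map$length
  offs <- seq.int(-h, h)
  idx_of <- function(a) {
    i <- a + offs
    if (map$topology == "circular") i <- i %% L
    else if (any(i < 0L | i >= L)) stop("window out of range at anchor ", a)
    i + 1L
  }
  tm <- t(vapply(anchors, function(a) map$top[idx_of(a)], numeric(length(offs))))
  bm <- t(vapply(anchors, function(a) map$bottom[idx_of(a)], numeric(length(offs))))
  colnames(tm) <- colnames(bm) <- offs
  list(offset = offs, top = colMeans(tm), bottom = colMeans(bm),
       top_matrix = tm, bottom_matrix = bm)
}
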