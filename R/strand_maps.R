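#' Strand-specific cleavage maps
#'
#' A strand map holds per-position read counts (or RPM values) for the top
#' and bottom strands of one reference, together with a mask of excluded
#' positions. Internally the vectors are dense and 1-indexed; all coordinate
#' arguments and outputs are 0-based.
#'
#' @name strand_map
NULL

new_strand_map <- function(ref_name, length, topology, top, bottom,
                           units = "raw", total_mapped = sum(top) + sum(bottom),
                           mask = rep(FALSE, length)) {
  stopifnot(length(top) == length, length(bottom) == length,
            length(mask) == length)
  if (any(top[!mask] < 0, na.rm = TRUE) || any(bottom[!mask] < 0, na.rm = TRUE))
    stop("strand-map values must be nonnegative outside the mask")
  structure(list(ref_name = ref_name, length = as.integer(length),
                 topology = topology, top = as.numeric(top),
                 bottom = as.numeric(bottom), units = units,
                 total_mapped = total_mapped, mask = mask),
            class = "strand_map")
}

#' @export
print.strand_map <- function(x, ...) {
  cat(sprintf("<strand_map> %s: %d bp (%s), units=%s, total_mapped=%s, %d masked\n",
              x$ref_name, x$length, x$topology, x$units,
              format(x$total_mapped), sum(x$mask)))
  invisible(x)
}

#' Build a raw strand map from reads
#'
#' `top[i]` is the number of top-strand reads assigned to position `i`,
#' likewise `bottom[i]`; `total_mapped` is the total read count over both
#' strands (the later RPM denominator).
#'
#' @param reads data.frame with 0-based `pos` and `strand` (top/bottom).
#' @param ref a `ref_seq`.
#' @return A `strand_map` in raw counts.
#' @export
build_strand_map <- function(reads, ref) {
  L <- ref_length(ref)
  if (nrow(reads) > 0 && (any(reads$pos < 0) || any(reads$pos >= L)))
    stop("read position outside reference [0, ", L, ")")
  count <- function(strand) {
    p <- reads$pos[reads$strand == strand]
    tabulate(p + 1L, nbins = L)
  }
  new_strand_map(ref$name, L, ref$topology,
                 top = count("top"), bottom = count("bottom"),
                 units = "raw", total_mapped = nrow(reads))
}

#' Normalise a strand map to reads per million mapped (RPM)
#'
#' Each value becomes `raw * 1e6 / total_mapped`, the denominator being the
#' library total over both strands before masking. Normalising an already
#' normalised map is an error, not a no-op.
#'
#' @param map a raw-unit `strand_map` with `total_mapped > 0`.
#' @export
normalize_rpm <- function(map) {
  if (map$units != "raw") stop("map is already in RPM units")
  if (map$total_mapped <= 0) stop("cannot normalise: total_mapped is zero")
  f <- 1e6 / map$total_mapped
  map$top <- map$top * f
  map$bottom <- map$bottom * f
  map$units <- "rpm"
  map
}

#' Mask regions of a strand map
#'
#' Positions inside the regions are excluded from all downstream statistics
#' (peak calling, correlation, composition). `total_mapped` is unchanged, so
#' masking and RPM normalisation commute. Typical use: telomeric ends and
#' repetitive loci.
#'
#' @param map a `strand_map`.
#' @param regions data.frame of 0-based half-open intervals with columns
#'   `ref_name` (optional), `start`, `end`.
#' @export
mask_regions <- function(map, regions) {
  if (is.null(regions) || nrow(regions) == 0L) return(map)
  if (!is.null(regions$ref_name))
    regions <- regions[regions$ref_name == map$ref_name, , drop = FALSE]
  for (i in seq_len(nrow(regions))) {
    s <- regions$start[i]; e <- regions$end[i]
    if (s < 0 || e > map$length || s >= e)
      stop("region [", s, ", ", e, ") invalid for reference of length ",
           map$length)
    map$mask[(s + 1L):e] <- TRUE
  }
  map
}

#' Hann-window smoothing of a signal track
#'
#' Convolves a track with a unit-sum Hann window
#' `w(n) = 0.5 * (1 - cos(2*pi*n / (M - 1)))`, `n = 0..M-1` (default
#' M = 21 bp, the setting used for overview cleavage profiles). Circular
#' topology wraps; linear topology truncates the kernel at the edges and
#' renormalises, so a constant track is always left unchanged. Smoothing is
#' for display: peak calling, composition and correlation run on unsmoothed
#' values.
#'
#' @param track numeric vector.
#' @param window odd integer >= 3.
#' @param topology `"circular"` or `"linear"`.
#' @return Numeric vector of the same length.
#' @export
smooth_hann <- function(track, window = 21L,
                        topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (window %% 2L != 1L || window < 3L) stop("window must be an odd integer >= 3")
  n <- 0:(window - 1L)
  w <- 0.5 * (1 - cos(2 * pi * n / (window - 1L)))
  w <- w / sum(w)
  L <- length(track)
  half <- (window - 1L) %/% 2L
  if (topology == "circular") {
    idx <- outer(seq_len(L), seq(-half, half), function(i, k) ((i - 1L + k) %% L) + 1L)
    as.numeric(matrix(track[idx], nrow = L) %*% w)
  } else {
    out <- numeric(L)
    for (i in seq_len(L)) {
      k <- seq(max(1L, i - half), min(L, i + half))
      wk <- w[k - i + half + 1L]
      out[i] <- sum(track[k] * wk) / sum(wk)
    }
    out
  }
}

#' Smooth both strands of a map (display helper)
#' @param map a `strand_map`.
#' @param window odd Hann width, default 21 bp.
#' @export
smooth_strand_map <- function(map, window = 21L) {
  map$top <- smooth_hann(map$top, window, map$topology)
  map$bottom <- smooth_hann(map$bottom, window, map$topology)
  map
}
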