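#' Threshold peak calling on an RPM strand map
#'
#' A peak is any unmasked position whose strand-specific RPM value strictly
#' exceeds the threshold; the two strands are called independently. Peaks
#' are threshold exceedances, not local maxima. Preset thresholds: 3000 RPM
#' for a small plasmid map, 10 or 15 RPM for genome-scale maps.
#'
#' @param map a `strand_map` in RPM units.
#' @param threshold calling threshold in RPM (default `"plasmid"` preset,
#'   3000; also accepts a number or preset names `"plasmid"`,
#'   `"bacterial"` (10), `"yeast"` (15)).
#' @return data.frame with 0-based `pos`, `strand`, `score` (RPM).
#' @export
call_peaks <- function(map, threshold = "plasmid") {
  if (map$units != "rpm")
    stop("peak calling requires an RPM-normalised map; see normalize_rpm()")
  presets <- c(plasmid = 3000, bacterial = 10, yeast = 15)
  if (is.character(threshold)) {
    if (!threshold %in% names(presets)) stop("unknown threshold preset: ", threshold)
    threshold <- presets[[threshold]]
  }
  one_strand <- function(strand) {
    v <- map[[strand]]
    hit <- which(v > threshold & !map$mask)
    data.frame(pos = hit - 1L, strand = rep(strand, length(hit)),
               score = v[hit])
  }
  out <- rbind(one_strand("top"), one_strand("bottom"))
  out$strand <- factor(out$strand, levels = c("top", "bottom"))
  rownames(out) <- NULL
  out
}

#' Filter incomplete fill-in artifact peaks
#'
#' Incomplete fill-in of the 2-nt 5' overhang shifts reads one nucleotide
#' inward from the true end, producing a satellite position immediately
#' inward of a strong cleavage site. Such positions carry fewer reads than
#' the true position they flank, so: a top-strand peak at `x` is removed
#' when `top[x] < top[x - 1]`, and a bottom-strand peak at `x` is removed
#' when `bottom[x] < bottom[x + 1]` (neighbours wrap on circular
#' references). The neighbour comparison is isolated in a single predicate
#' so the direction convention can be swapped if a different artifact
#' geometry applies.
#'
#' @param peaks data.frame from [call_peaks()].
#' @param map the `strand_map` the peaks were called from.
#' @return Filtered peak data.frame.
#' @export
filter_fillin_artifacts <- function(peaks, map) {
  if (nrow(peaks) == 0L) return(peaks)
  keep <- vapply(seq_len(nrow(peaks)), function(i) {
    !.is_fillin_artifact(peaks$pos[i], as.character(peaks$strand[i]), map)
  }, logical(1L))
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Predicate: does position x on this strand look like an inward-shifted
# fill-in satellite (fewer reads than the site it flanks)?
.is_fillin_artifact <- function(x, strand, map) {
  L <- map$length
  neighbour <- if (strand == "top") x - 1L else x + 1L
  if (map$topology == "circular") {
    neighbour <- neighbour %% L
  } else if (neighbour < 0L || neighbour >= L) {
    return(FALSE)  # no outward neighbour to be shifted from
  }
  map[[strand]][x + 1L] < map[[strand]][neighbour + 1L]
}

#' Top-n peaks by score
#'
#' Both strands pooled, ordered by descending score; ties broken by
#' ascending position, then top strand first. Returns fewer than `n` if
#' fewer exist. The default of 50 matches averaging base composition around
#' the ~50 strongest called sites.
#'
#' @param peaks data.frame of peaks.
#' @param n number to keep (>= 1).
#' @export
top_n_peaks <- function(peaks, n = 50L) {
  if (n < 1L) stop("n must be >= 1")
  ord <- order(-peaks$score, peaks$pos, peaks$strand)
  out <- peaks[ord, , drop = FALSE][seq_len(min(n, nrow(peaks))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
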