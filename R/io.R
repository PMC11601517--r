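#' Read references from a FASTA file
#'
#' Sequences are uppercased; topology is not encoded in FASTA and is
#' supplied by the caller (default linear).
#'
#' @param path FASTA file.
#' @param topology topology to assign to every record.
#' @return List of `ref_seq` objects.
#' @export
read_fasta <- function(path, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no sequences in FASTA file: ", path)
  lapply(seq_along(ss), function(i) {
    reference_sequence(names(ss)[i], as.character(ss[[i]]), topology)
  })
}

#' Write references to a FASTA file
#' @param refs a `ref_seq` or list of them.
#' @param path output file.
#' @export
write_fasta <- function(refs, path) {
  if (inherits(refs, "ref_seq")) refs <- list(refs)
  ss <- Biostrings::DNAStringSet(vapply(refs, function(r) r$seq, character(1L)))
  names(ss) <- vapply(refs, function(r) r$name, character(1L))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

.split_bed_line <- function(line, lineno, path, min_fields) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(f) < min_fields)
    stop(path, " line ", lineno, ": expected >= ", min_fields,
         " tab-separated fields, got ", length(f))
  f
}

#' Read strand-assigned read positions from BED6
#'
#' Each line is one read 5'-end: `chrom start end name score strand`, with
#' `+` = top strand and `-` = bottom strand. Malformed lines are rejected
#' with line-numbered messages.
#'
#' @param path BED6 file.
#' @return data.frame with 0-based `pos` and `strand` (top/bottom).
#' @export
read_reads_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(pos = integer(0),
                      strand = factor(character(0), levels = c("top", "bottom"))))
  pos <- integer(length(lines)); strand <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- .split_bed_line(lines[i], i, path, 6L)
    s <- suppressWarnings(as.integer(f[2L]))
    if (is.na(s) || s < 0L)
      stop(path, " line ", i, ": invalid start '", f[2L], "'")
    if (!f[6L] %in% c("+", "-"))
      stop(path, " line ", i, ": invalid strand '", f[6L], "'")
    pos[i] <- s
    strand[i] <- if (f[6L] == "+") "top" else "bottom"
  }
  data.frame(pos = pos, strand = factor(strand, levels = c("top", "bottom")))
}

#' Write strand-assigned reads as BED6
#' @param reads data.frame with `pos`, `strand`.
#' @param ref_name chromosome name for column 1.
#' @param path output file.
#' @export
write_reads_bed <- function(reads, ref_name, path) {
  strand_sym <- ifelse(reads$strand == "top", "+", "-")
  lines <- sprintf("%s\t%d\t%d\tread%d\t0\t%s",
                   ref_name, reads$pos, reads$pos + 1L,
                   seq_len(nrow(reads)), strand_sym)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of regions (hotspots, masks)
#'
#' @param path BED3+ file.
#' @return data.frame with `ref_name`, 0-based half-open `start`/`end`,
#'   optional `label`.
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(ref_name = character(0), start = integer(0),
                      end = integer(0), label = character(0)))
  out <- lapply(seq_along(lines), function(i) {
    f <- .split_bed_line(lines[i], i, path, 3L)
    s <- suppressWarnings(as.integer(f[2L]))
    e <- suppressWarnings(as.integer(f[3L]))
    if (is.na(s) || is.na(e) || s < 0L || s >= e)
      stop(path, " line ", i, ": invalid interval [", f[2L], ", ", f[3L], ")")
    data.frame(ref_name = f[1L], start = s, end = e,
               label = if (length(f) >= 4L) f[4L] else NA_character_)
  })
  do.call(rbind, out)
}

#' Write peaks as BED6 with RPM score
#' @param peaks data.frame with `pos`, `strand`, `score`.
#' @param ref_name chromosome name.
#' @param path output file.
#' @export
write_peaks_bed <- function(peaks, ref_name, path) {
  strand_sym <- ifelse(peaks$strand == "top", "+", "-")
  lines <- sprintf("%s\t%d\t%d\tpeak%d\t%.6g\t%s",
                   ref_name, peaks$pos, peaks$pos + 1L,
                   seq_len(nrow(peaks)), peaks$score, strand_sym)
  writeLines(lines, path)
  invisible(path)
}

# Run-length encode one strand track into bedGraph data lines; masked
# positions are emitted as absent intervals (not zeros), and zero runs are
# compressed away.
.track_to_bedgraph <- function(ref_name, values, mask) {
  v <- values
  v[mask] <- NA_real_
  r <- rle(sprintf("%.17g", v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- !is.na(r$values) & r$values != "NA" & r$values != "0"
  if (!any(keep)) return(character(0))
  sprintf("%s\t%d\t%d\t%s", ref_name, starts[keep], ends[keep], r$values[keep])
}

#' Write a strand map as a pair of bedGraph tracks
#'
#' Produces `<prefix>_top.bedgraph` and `<prefix>_bottom.bedgraph`. Header
#' comment lines carry the reference name, length, topology, units and
#' total mapped reads so the pair round-trips losslessly; masked positions
#' are written as absent intervals.
#'
#' @param map a `strand_map`.
#' @param prefix output path prefix.
#' @return Character vector of the two paths written.
#' @export
write_bedgraph_pair <- function(map, prefix) {
  if (any(!is.finite(map$top[!map$mask])) || any(!is.finite(map$bottom[!map$mask])))
    stop("non-finite values outside masked regions")
  paths <- paste0(prefix, "_", c("top", "bottom"), ".bedgraph")
  for (i in 1:2) {
    strand <- c("top", "bottom")[i]
    hdr <- sprintf("# ref=%s length=%d topology=%s units=%s total_mapped=%s strand=%s",
                   map$ref_name, map$length, map$topology, map$units,
                   format(map$total_mapped, scientific = FALSE), strand)
    if (any(map$mask)) {
      r <- rle(map$mask)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths
      iv <- sprintf("%d-%d", starts[r$values], ends[r$values])
      hdr <- c(hdr, paste0("# mask=", paste(iv, collapse = ",")))
    }
    writeLines(c(hdr, .track_to_bedgraph(map$ref_name, map[[strand]], map$mask)),
               paths[i])
  }
  invisible(paths)
}

#' Read a strand map back from a bedGraph pair
#'
#' Inverse of [write_bedgraph_pair()]: value-exact round-trip, with masked
#' positions recovered from shared absent intervals. Positions absent from
#' one strand but valued on the other are zeros, not mask.
#'
#' @param prefix path prefix used at write time.
#' @return A `strand_map`.
#' @export
read_bedgraph_pair <- function(prefix) {
  paths <- paste0(prefix, "_", c("top", "bottom"), ".bedgraph")
  parse_one <- function(path) {
    lines <- readLines(path)
    hdr <- lines[grepl("^# ref=", lines)]
    if (length(hdr) != 1L) stop(path, ": missing strand-map header line")
    kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1L]]
    meta <- stats::setNames(sub("^[a-z_]+=", "", kv), sub("=.*$", "", kv))
    L <- as.integer(meta[["length"]])
    vals <- rep(0, L); seen <- rep(FALSE, L)
    data_lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    for (i in seq_along(data_lines)) {
      f <- .split_bed_line(data_lines[i], i, path, 4L)
      s <- as.integer(f[2L]); e <- as.integer(f[3L])
      v <- suppressWarnings(as.numeric(f[4L]))
      if (is.na(s) || is.na(e) || s < 0L || e > L || s >= e || is.na(v))
        stop(path, " line ", i, ": malformed bedGraph interval")
      vals[(s + 1L):e] <- v
      seen[(s + 1L):e] <- TRUE
    }
    list(meta = meta, vals = vals, seen = seen)
  }
  top <- parse_one(paths[1L]); bot <- parse_one(paths[2L])
  L <- as.integer(top$meta[["length"]])
  # mask intervals travel in the header; data lines leave them absent
  mask <- rep(FALSE, L)
  mask_hdr <- grep("^# mask=", readLines(paths[1L]), value = TRUE)
  if (length(mask_hdr) == 1L) {
    for (iv in strsplit(sub("^# mask=", "", mask_hdr), ",", fixed = TRUE)[[1L]]) {
      se <- as.integer(strsplit(iv, "-", fixed = TRUE)[[1L]])
      mask[(se[1L] + 1L):se[2L]] <- TRUE
    }
  }
  new_strand_map(top$meta[["ref"]], L, top$meta[["topology"]],
                 top = top$vals, bottom = bot$vals,
                 units = top$meta[["units"]],
                 total_mapped = as.numeric(top$meta[["total_mapped"]]),
                 mask = mask)
}

#' Write a matrix as TSV with row names in the first column
#' @param m matrix (e.g. composition fractions or logo heights).
#' @param path output file.
#' @param rowname_col header for the row-name column.
#' @export
write_matrix_tsv <- function(m, path, rowname_col = "position") {
  df <- data.frame(rn = rownames(m), as.data.frame(m), check.names = FALSE)
  names(df)[1L] <- rowname_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
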