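#' Default pipeline configuration
#'
#' Settings for a self-contained simulate -> map -> polarity -> peaks ->
#' composition run on synthetic data. Every key can be overridden via the
#' `config` argument of [run_pipeline()] or a YAML file with the same keys.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    reference = list(length = 10000L, gc = 0.5, topology = "circular",
                     name = "synthetic"),
    bias = list(consensus = "GNATNC", fold = 10, strength = 1),
    n_events = 2000L,
    prep = list(p_nick = 0, f_partial = 0, background_rate = 0,
                reads_per_event = 5),
    polarity_max_lag = 10L,
    peak_threshold = 3000,
    top_n = 50L,
    composition_halfwidth = 10L
  )
}

.merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(override[[k]]) && is.list(base[[k]]))
      base[[k]] <- .merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Load a pipeline configuration from YAML
#' @param path YAML file whose keys mirror [default_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  .merge_config(default_config(), yaml::read_yaml(path))
}

#' Run the full synthetic-analysis pipeline
#'
#' Generates a reference and a sequence-biased cleavage library, builds and
#' normalises the strand map, tests overhang polarity, calls and filters
#' peaks, and computes the dyad composition matrix and GC-corrected logo.
#' All stage outputs are written under `outdir` (FASTA reference, BED6
#' reads and peaks, bedGraph map pair, TSV lag profile / composition /
#' logo) together with a YAML manifest of the effective parameters, and
#' returned invisibly as a list. Reruns with the same config are
#' deterministic.
#'
#' @param config list of overrides to [default_config()], or a YAML path.
#' @param outdir output directory (created if needed); `NULL` skips writing.
#' @return (Invisibly) list with `ref`, `events`, `reads`, `map_rpm`,
#'   `lags`, `offset`, `peaks`, `composition`, `logo`, `config`.
#' @export
run_pipeline <- function(config = list(), outdir = NULL) {
  cfg <- if (is.character(config)) read_config(config)
         else .merge_config(default_config(), config)

  ref <- generate_reference(cfg$reference$length, cfg$reference$gc,
                            cfg$reference$topology, seed = cfg$seed,
                            name = cfg$reference$name)
  model <- if (is.null(cfg$bias$consensus)) uniform_bias_model()
           else consensus_bias_model(cfg$bias$consensus, cfg$bias$fold,
                                     cfg$bias$strength)
  prep <- library_prep_params(p_nick = cfg$prep$p_nick,
                              f_partial = cfg$prep$f_partial,
                              background_rate = cfg$prep$background_rate,
                              reads_per_event = cfg$prep$reads_per_event)
  events <- sample_cleavage_events(ref, model, cfg$n_events, prep,
                                   seed = cfg$seed + 1L)
  reads <- simulate_library(events, prep, ref_length(ref), ref$topology,
                            seed = cfg$seed + 2L)
  map <- build_strand_map(reads, ref)
  map_rpm <- normalize_rpm(map)
  lags <- cross_correlation(map_rpm, cfg$polarity_max_lag)
  offset <- polarity_offset(map_rpm, cfg$polarity_max_lag)
  peaks <- call_peaks(map_rpm, cfg$peak_threshold)
  peaks <- filter_fillin_artifacts(peaks, map_rpm)
  peaks <- top_n_peaks(peaks, cfg$top_n)
  comp <- NULL; logo <- NULL
  if (nrow(peaks) > 0L) {
    comp <- composition_matrix(dyad_windows(ref, peaks,
                                            cfg$composition_halfwidth))
    logo <- gc_corrected_logo(comp, background_gc = cfg$reference$gc)
  }

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(outdir, ...)
    write_fasta(ref, p("reference.fa"))
    write_reads_bed(reads, ref$name, p("reads.bed"))
    write_bedgraph_pair(map_rpm, p("map_rpm"))
    utils::write.table(lags, p("polarity_lags.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_peaks_bed(peaks, ref$name, p("peaks.bed"))
    if (!is.null(comp)) {
      write_matrix_tsv(comp$fractions, p("composition.tsv"))
      write_matrix_tsv(logo$heights, p("logo_bits.tsv"))
    }
    manifest <- c(cfg, list(
      package_version = as.character(utils::packageVersion("cleavemap")),
      polarity_offset = offset,
      n_peaks = nrow(peaks)))
    yaml::write_yaml(manifest, p("manifest.yaml"))
  }

  invisible(list(ref = ref, events = events, reads = reads, map_rpm = map_rpm,
                 lags = lags, offset = offset, peaks = peaks,
                 composition = comp, logo = logo, config = cfg))
}
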