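# Shared fixture builders for the suite. Everything is generated in code;
# no files on disk.

# A strand map straight from explicit count vectors.
map_from_vectors <- function(top, bottom, topology = "circular",
                             units = "raw", name = "fix",
                             total_mapped = sum(top) + sum(bottom)) {
  m <- cleavemap:::new_strand_map(name, length(top), topology,
                                  top = top, bottom = bottom,
                                  units = units, total_mapped = total_mapped)
  m
}

# A complete simulated library on a circular reference; returns all
# intermediates so tests can compare against generator ground truth.
simulated_library <- function(seed = 101L, length = 10000L, n_events = 1000L,
                              model = uniform_bias_model(),
                              p_nick = 0, f_partial = 0, background_rate = 0,
                              reads_per_event = 5) {
  ref <- generate_reference(length, 0.5, "circular", seed = seed)
  prep <- library_prep_params(p_nick = p_nick, f_partial = f_partial,
                              background_rate = background_rate,
                              reads_per_event = reads_per_event)
  events <- sample_cleavage_events(ref, model, n_events, prep, seed = seed + 1L)
  reads <- simulate_library(events, prep, length, "circular", seed = seed + 2L)
  map <- build_strand_map(reads, ref)
  list(ref = ref, prep = prep, events = events, reads = reads, map = map)
}

# Independent letter-by-letter IUPAC matcher used as the dual-route oracle
# for motif_scan (deliberately naive; linear scan, no wrap).
naive_iupac_scan <- function(seq, pattern) {
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  p <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
  hits <- integer(0)
  for (start in seq_len(length(s) - length(p) + 1L)) {
    ok <- all(vapply(seq_along(p), function(j) {
      s[start + j - 1L] %in% iupac_bases(p[j])
    }, logical(1L)))
    if (ok) hits <- c(hits, start - 1L)
  }
  hits
}

# Flattened cosine similarity between two matrices of identical shape.
cosine_sim <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
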