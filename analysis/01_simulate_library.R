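#!/usr/bin/env Rscript
# Simulate a sequence-biased cleavage library on a synthetic plasmid-sized
# circular reference. Events favour the dyad-symmetric hexamer GNATNC; the
# library carries a nick fraction, 20% incomplete fill-in and a uniform
# nonspecific background, mimicking the artifacts the downstream stages
# must cope with. Writes reference + reads under results/library/.

suppressMessages(library(cleavemap))
outdir <- "results/library"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260L

ref <- generate_reference(10000L, gc = 0.5, topology = "circular",
                          seed = seed, name = "synthetic_plasmid")
model <- consensus_bias_model("GNATNC", fold = 10, strength = 2)
prep <- library_prep_params(p_nick = 0.2, f_partial = 0.2,
                            background_rate = 0.005, reads_per_event = 5)
events <- sample_cleavage_events(ref, model, n_events = 2000L, prep,
                                 seed = seed + 1L)
reads <- simulate_library(events, prep, ref_length(ref), ref$topology,
                          seed = seed + 2L)

write_fasta(ref, file.path(outdir, "reference.fa"))
write_reads_bed(reads, ref$name, file.path(outdir, "reads.bed"))
# generator ground truth, kept for later comparison with called peaks
utils::write.table(events, file.path(outdir, "events_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
yaml::write_yaml(list(seed = seed, n_events = nrow(events),
                      p_nick = prep$p_nick, f_partial = prep$f_partial,
                      background_rate = prep$background_rate,
                      reads_per_event = prep$reads_per_event,
                      consensus = "GNATNC", fold = 10, strength = 2),
                 file.path(outdir, "params.yaml"))

cat(sprintf("reference: %d bp circular, GC %.3f\n", ref_length(ref),
            mean(strsplit(ref$seq, "")[[1]] %in% c("G", "C"))))
cat(sprintf("events: %d (%.1f%% nicks), reads: %d\n", nrow(events),
            100 * mean(events$kind != "dsb"), nrow(reads)))
cat(sprintf("motif placements available: %d\n",
            length(motif_scan(ref, "GNATNC"))))
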