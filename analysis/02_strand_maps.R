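#!/usr/bin/env Rscript
# Build the strand-specific cleavage map from the simulated reads, normalise
# to RPM, and write the map as a bedGraph pair plus a Hann-smoothed overview
# track (smoothing is display-only; later stages use raw values).

suppressMessages(library(cleavemap))
lib <- "results/library"
outdir <- "results/maps"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

ref <- read_fasta(file.path(lib, "reference.fa"), topology = "circular")[[1]]
reads <- read_reads_bed(file.path(lib, "reads.bed"))
map <- build_strand_map(reads, ref)
rpm <- normalize_rpm(map)

write_bedgraph_pair(rpm, file.path(outdir, "map_rpm"))
smoothed <- smooth_strand_map(rpm, window = 21L)
write_bedgraph_pair(smoothed, file.path(outdir, "map_rpm_hann21"))

cat(sprintf("total mapped reads: %d\n", map$total_mapped))
cat(sprintf("top/bottom read split: %d / %d\n",
            sum(map$top), sum(map$bottom)))
cat(sprintf("max strand-specific signal: %.0f RPM (%.1f kRPM)\n",
            max(rpm$top, rpm$bottom), max(rpm$top, rpm$bottom) / 1000))
cat(sprintf("smoothed total conserved: %s\n",
            isTRUE(all.equal(sum(smoothed$top), sum(rpm$top)))))
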