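# cleavemap

Simulation and analysis of strand-specific, nucleotide-resolution DNA
cleavage maps of the kind produced by end-capture sequencing of
topoisomerase-like double-strand breaks (DSBs) with 2-nt 5' overhangs —
the chemistry of SPO11-family nucleases that initiate meiotic
recombination — together with equilibrium and kinetic models of the
dimeric assemblies that make those breaks.

The package is organised as an analysis workflow: all computation lives in
the package functions (`R/`), and the numbered scripts under `analysis/`
are thin narrative drivers that run the stages in order and write their
tables under `results/`.

## What it computes

A DSB with a 2-nt 5' overhang is centred on a dyad axis between positions
`p` and `p + 1`; after fill-in and adaptor ligation, its top-strand read
maps to `p` and its bottom-strand read to `p + 1`. On this geometry the
package builds:

* **a synthetic library generator** — sequence-biased cleavage events
  (position-specific weights `w(p, b)` with the rotational symmetry
  `w(p, b) = w(−p, complement(b))`), nick/DSB mixtures, incomplete
  fill-in read shifts, uniform background;
* **strand maps** — per-position top/bottom counts, RPM normalisation
  (`value × 10⁶ / total mapped`), region masking, 21-bp Hann smoothing
  for display;
* **overhang-polarity testing** — Pearson cross-correlation
  `r(k) = cor(top[i], bottom[i+k])` over lags −10..+10; genuine 5'-overhang
  DSB libraries peak at k = +1;
* **peak calling** — strand-specific threshold exceedances (presets
  >3000 / >10 / >15 RPM) with a filter that removes the one-base-inward
  satellites created by incomplete fill-in;
* **dyad composition and logos** — reorientation of bottom-strand peaks
  into the dyad frame, base-composition matrices, GC-corrected
  relative-entropy logos (`R = Σ f log₂(f/b)`, letter height `f·R`),
  rotational-symmetry scoring, IUPAC motif scanning (e.g. the favoured
  hexamer `GNATNC`), motif-anchored strand profiles;
* **binding and kinetics** — two-independent-site occupancy
  `θ² = (P/(Kd+P))²`, hyperbola Kd fits, two-phase association fits, and a
  mass-action kinetic-trap model (sequential dimer assembly on cleavable
  sites competing with excess decoy sites) that reproduces biphasic
  cleavage and order-of-addition asymmetry.

## Worked example

```r
library(cleavemap)

res <- run_pipeline(list(n_events = 500, reference = list(length = 4000)))
res$offset
#> [1] 1
nrow(res$peaks)
#> [1] 50
round(res$composition$fractions[c("-3", "-1", "1", "3"), ], 2)
#>       A    C    G    T
#> -3 0.06 0.02 0.92 0.00
#> -1 0.92 0.02 0.04 0.02
#> 1  0.02 0.04 0.00 0.94
#> 3  0.02 0.90 0.06 0.02
```

The simulated library's strand maps cross-correlate with an argmax at
lag +1 (the 5'-overhang signature); the 50 strongest peaks, reoriented
into the dyad frame, recover the embedded preference — G at −3, A at −1,
T at +1, C at +3, a rotationally symmetric `GNATNC` signature.

The full demo analysis is the script sequence:

```sh
Rscript analysis/01_simulate_library.R   # biased library + artifacts
Rscript analysis/02_strand_maps.R        # counts -> RPM -> bedGraph
Rscript analysis/03_polarity.R           # lag profile, argmax +1
Rscript analysis/04_peaks_composition.R  # peaks, filter, logo, profiles
Rscript analysis/05_binding_kinetics.R   # occupancy, Kd, trap model
```

Among the numbers the kinetics driver prints: two-site dimer occupancy at
P = 10 nM and Kd = 1.8 nM is 71.8% (rounds to 72%), and 300 fmol of strand
breaks in a 70 µl reaction at 100 nM protein engages 4.3% (~4%) of the
protein molecules.

## Layout

```
R/                  package code (generator, maps, polarity, peaks,
                    composition, motif, kinetics, pipeline, I/O)
analysis/           numbered narrative drivers (see above)
scripts/acceptance.R  headline-quantity recomputation
tests/testthat/     unit + property + end-to-end acceptance tests
vignettes/          methods vignette: models, assumptions, choices
```
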