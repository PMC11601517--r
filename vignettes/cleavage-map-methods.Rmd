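---
title: "Methods: simulated strand-specific cleavage maps and dimeric binding kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated strand-specific cleavage maps and dimeric binding kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleavemap)
```

## Scope and model

`cleavemap` analyses nucleotide-resolution, strand-specific maps of DNA
cleavage by topoisomerase-like enzymes that cut with 2-nt 5' overhangs —
the geometry of meiotic DSB-forming SPO11-family nucleases. In an
end-capture sequencing library (TDP2-seq / S1-seq style), the covalently
bound protein is removed, the overhang is filled in, an adaptor is ligated,
and each read is assigned to the nucleotide immediately next to the
adaptor. Two structural facts follow and drive every analysis in the
package:

1. **Overhang polarity.** For a DSB whose 2-nt overhang is centred on a
   dyad axis between positions `p` and `p + 1` (0-based), the filled-in
   top-strand read lands at `p` and the bottom-strand read at `p + 1`.
   The maps of the two strands therefore co-vary with a displacement of
   exactly +1, which the Pearson cross-correlation over lags −10..+10
   detects as an argmax at +1. Nicks, random fragmentation or a different
   overhang chemistry do not produce this signature.
2. **Rotational symmetry.** A cleavage-competent dimer engages two
   half-sites related by twofold rotation about the dyad axis, so any
   position-specific base preference must satisfy
   `f(p, b) = f(−p, complement(b))`. Dyad-relative positions are numbered
   −k/+k with no position 0; the axis lies between −1 and +1.

Coordinates are 0-based throughout (matching BED); dyad-relative labels
are the only user-facing 1-free indexing.

## Synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream claim is verified.

* **Reference**: i.i.d. bases at a target GC (default 0.5), 10 kb circular
  by default — a plasmid-sized substrate without edge effects. Circular
  topology wraps all windows; linear references exclude dyads whose
  window does not fit.
* **Bias model**: per-position multiplicative weights over dyad positions
  −W..+W, raised to a `strength` exponent. The stock model favours the
  dyad-symmetric hexamer `GNATNC` (G at −3, A at −1, T at +1, C at +3)
  by 10-fold per matching base. `GNATNC` and its reversed control
  `CNTANG` are each their own reverse complement, so a single-strand
  motif scan finds every dyad placement. `strength` stands in for
  substrate complexity and protein:DNA ratio: larger exponents
  concentrate events on fewer, better-matching sites, which is how the
  stringency-vs-complexity behaviour of real substrates is emulated.
* **Library prep**: an event is a nick with probability `p_nick`
  (default 0 in tests that need clean DSB geometry; 0.2 in the demo
  analysis, a realistic early-time-point mixture); each read is shifted
  one nucleotide inward with probability `f_partial` (incomplete fill-in
  of the overhang before ligation — top `p → p+1`, bottom `p+1 → p`);
  uniform background reads arrive Poisson per position per strand
  (`background_rate`), emulating a catalytically dead control; read
  multiplicity is Poisson per event with mean `reads_per_event`, shared
  by the two ends of a DSB so that the strand totals balance exactly.

What the generator deliberately does **not** model: sequencing errors,
fragment-length effects, mappability, adaptor sequence, or any coupling
between nearby events (each event is independent). Passing tests
therefore demonstrate that the analysis recovers what this generative
model embeds — polarity, composition bias, artifact geometry — not that
real libraries are free of other failure modes.

## Map construction, masking, smoothing

Raw maps count read 5' ends per position per strand. RPM normalisation
multiplies by `1e6 / total_mapped`, where the denominator is the library
total over both strands **before masking**; this is the standard reading
of "per million mapped reads", and masking never alters it (so masking
and normalisation commute — a tested invariant). Masked positions
(telomere-like ends, repetitive loci) are excluded from every downstream
statistic and are written to bedGraph as absent intervals rather than
zeros, keeping "no signal" distinct from "excluded".

The 21-bp Hann window (`w(n) = 0.5 (1 − cos(2πn/20))`, unit-normalised)
is provided for overview profiles only; peaks, correlation and
composition always use unsmoothed values. On circular references the
convolution wraps and conserves the track total to 1e−9 relative; on
linear references the kernel is truncated and renormalised at the edges,
so constant tracks are fixed points there too.

## Peak calling and the fill-in artifact filter

Peaks are strict threshold exceedances per strand — not local maxima —
with presets 3000 RPM (plasmid-sized maps) and 10/15 RPM (genome-scale
maps). The incomplete fill-in artifact places a satellite one nucleotide
inward of a true site with (at realistic `f_partial`) fewer reads, so a
top-strand peak at `x` is dropped when `top[x] < top[x−1]` and a
bottom-strand peak when `bottom[x] < bottom[x+1]`. The published wording
of this rule is ambiguous about which neighbour is compared; the
implemented direction is the one that removes the inward-shifted
satellite this protocol geometry actually produces, and it lives in a
single predicate (`cleavemap:::.is_fillin_artifact`) so the opposite
convention is a one-line swap. Under the generator's conditions
(`f_partial = 0.3`, background ≤ 1% of signal) the filter leaves ≥ 95% of
surviving peaks on true dyad read positions — a tested property.
"Top-n" selection is by descending score with deterministic tie-breaks
(position, then strand); whether a curated peak list would coincide with
a pure top-n cut on real data is not something the package can decide.

## Composition, logos, symmetry

Bottom-strand peaks are reoriented before averaging: the window is read
off the bottom strand so that the adaptor-adjacent nucleotide sits at −1,
making the top- and bottom-strand windows of one DSB exact reverse
complements (tested). The composition matrix is the column-wise base
fraction over oriented windows. The logo statistic is background-relative
entropy: with background `b` set by a GC fraction
(`{A,T: (1−gc)/2; G,C: gc/2}`), per-position information is
`R = Σ_b f_b log2(f_b/b_b)` (0·log 0 = 0) and letter height is `f_b·R`.
Only the GC correction is prescribed by the field's practice; the exact
statistic (KL against a GC-matched background) is this package's choice,
made because it is the standard information-content logo with the
background generalised away from uniform. The background GC is a plain
argument, so a local-GC override (e.g. 47.8% around mapped sites versus a
38.5% genome average) is a call-site decision, not a code path.
The symmetry score is the mean absolute deviation from the rotational
identity over p > 0; it is 0 for any exactly symmetric matrix (including
the uniform one) and stays below 0.02 for libraries of ≥ 2000 events
drawn from a symmetric model — a sampling-noise bound established by the
test suite's simulations.

## Binding and kinetics

Closed forms: single-site occupancy `θ = P/(Kd+P)`; two independent
monomer sites give a doubly bound (cleavage-competent) fraction `θ²` —
at P = 10 nM and Kd = 1.8 nM, 0.72. Protein-utilization arithmetic
converts strand breaks to a percentage of protein molecules via
moles = concentration × volume (1 nM·µl = 1 fmol). Kd fitting uses the
simple hyperbola (the "apparent Kd" convention); a ligand-depletion
quadratic is available when the probe concentration is not far below the
Kd. Two-phase association fits
(`Y = A1(1−e^{−k1 t}) + A2(1−e^{−k2 t})`, k1 ≥ k2 by relabelling) use
8 multi-start initialisations of a Levenberg–Marquardt optimiser and flag
near-degenerate solutions (k1/k2 < 3 or a vanishing amplitude); they are
descriptive summaries of biphasic shape, not estimates of mechanistic
rates.

The kinetic-trap model is the minimal mass-action scheme that yields
biphasic cleavage and order-of-addition asymmetry: cleavable sites load
protomers sequentially (S ↔ SP ↔ SP2, SP2 → cleaved) while an excess of
decoy monomer sites (D ↔ DP) soaks up protein; time t < 0 is assembly on
ice with cleavage off, and staged additions inject new substrate pools at
scheduled times. Two deliberate choices:

* **Statistical factors.** The first binding carries on-rate `2·k_on`
  and the doubly bound state off-rate `2·k_off`, the binomial factors for
  two equivalent independent sites. Without them the k_cut = 0
  equilibrium would *not* equal `θ²`; with them the simulated equilibrium
  matches the closed form to 1e−6 (tested), which makes the ODE model and
  the occupancy arithmetic mutually consistent rather than two unrelated
  descriptions.
* **No recycling.** Cleavage sequesters the two bound protomers
  (covalent protein–DNA adducts), so conservation reads
  `P + Σ(SP + 2·SP2 + DP + 2·C)`; it holds to 1e−8 relative in every
  simulation (tested). `dimer_on_boost` multiplies the second-binding
  on-rate to represent pre-paired protomers (an artificial dimerization
  module); the package asserts only the direction of its effect — a
  larger initial burst — never a specific fold-change.

Default rates (`k_on = 0.1 /nM/min`, `k_off = 0.06 /min`, i.e.
Kd = 0.6 nM; `k_cut = 1 /min`) encode fast, high-affinity binding with
slow exchange and cleavage much faster than dissociation. The scheme is
agnostic about whether dimers assemble by capture from solution or by
one-dimensional sliding; nothing in the rate structure commits to either.

## Numerical and procedural choices

* Cross-correlation uses Pearson's r per lag (raw cross-covariance is an
  option); ties in the argmax break towards the smallest |lag|, then the
  positive sign. Masking is respected — a lag only uses position pairs
  where both entries are unmasked — and whether to mask this test at all
  is left to the caller, since the statistic is robust to small masks.
* Degenerate inputs fail loudly: zero-variance strands, raw-unit maps
  passed to peak calling, re-normalising an RPM map, all-zero titrations,
  empty anchor lists.
* The ODE integrator is `lsoda` at `rtol = atol = 1e−10`, integrating
  piecewise between schedule breakpoints with pool injections at the
  boundaries; negative concentrations abort the run rather than being
  clipped silently.
* Problem sizes in the tests and demo analysis — 10-kb references,
  1000–2000 events, ~40 motif placements, 50-site composition averages —
  were chosen as the smallest sizes at which the binomial/multinomial
  error bounds in the tests are comfortably informative; the whole suite
  and the analysis scripts run in well under a minute.

## Known limitations

* Analyses are per-reference; there is no genome-wide indexing, binning,
  or multi-chromosome aggregation beyond running per reference.
* No FDR control, peak merging or width estimation — peaks are defined
  exactly as threshold exceedances, which is only sensible at the
  sequencing depths the thresholds were designed for.
* The bedGraph round-trip cannot distinguish a masked position from an
  all-zero one from the data lines alone; the mask therefore travels in a
  header comment, which generic browsers ignore but other tools will not
  re-emit.
* Quantities that depend on raw gel or particle data (absolute Kd values,
  nick fractions at specific time points, fold-speedups of engineered
  dimers) are outside what simulation can validate; the package uses such
  values only as ground truths in recovery tests, never as assertions
  about its own outputs.
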