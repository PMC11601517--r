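#!/usr/bin/env Rscript
# Equilibrium occupancy arithmetic, Kd recovery, and the kinetic-trap model
# of biphasic cleavage: pre-assembly on ice, fast consumption of doubly
# bound (cleavage-competent) substrate, then slow exchange-limited cutting;
# staged substrate addition reproduces the order-of-addition asymmetry.

suppressMessages(library(cleavemap))
outdir <- "results/kinetics"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

# --- occupancy benchmarks ----------------------------------------------------
occ <- fraction_dimer_bound(P = 10, Kd = 1.8)
cat(sprintf("two-site dimer occupancy at P=10 nM, Kd=1.8 nM: %.1f%% (rounds to %d%%)\n",
            100 * occ, round(100 * occ)))
pct <- breaks_to_protein_fraction(300, 100, 70)
cat(sprintf("300 fmol breaks / (100 nM x 70 ul): %.1f%% of protein molecules (~%g%%)\n",
            pct, signif(pct, 1)))

# --- Kd recovery from a noisy titration --------------------------------------
set.seed(5)
P <- c(0.1, 0.2, 0.5, 1, 2, 5, 10)
f <- fraction_single_bound(P, 0.6)
fit <- fit_kd(P, pmin(pmax(f + rnorm(length(P), 0, 0.03), 0), 1))
cat(sprintf("Kd recovered from 3%%-noise titration (truth 0.6 nM): %.3f +/- %.3f nM\n",
            fit$Kd, fit$se))

# --- kinetic trap: biphasic kinetics and order of addition -------------------
sc <- kinetic_scheme(k_on = 0.5, k_off = 0.005, k_cut = 2, P0 = 100,
                     batches = data.frame(name = c("first", "second"),
                                          S0 = c(2, 2), D0 = c(200, 200),
                                          t_add = c(-30, 0)))
tg <- c(0, 0.5, 1, 2, 3, 5, 8, 12, 20, 30, 45, 60)
tr <- simulate_cleavage_kinetics(sc, tg)
u <- substrate_utilization(tr, sc)
utils::write.table(round(u, 4), file.path(outdir, "utilization.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
fit2 <- two_phase_fit(u$time, u$first)
cat(sprintf("first-added substrate: two-phase fit A1=%.1f%% k1=%.2f/min, A2=%.1f%% k2=%.4f/min%s\n",
            fit2$A1, fit2$k1, fit2$A2, fit2$k2,
            if (fit2$degenerate) " [degenerate]" else ""))
cat(sprintf("utilization at 60 min: first %.1f%%, second %.1f%% — first-added is cut faster\n",
            u$first[u$time == 60], u$second[u$time == 60]))

# --- pre-paired protomers (artificial dimerization analogue) -----------------
early <- function(boost) {
  s <- kinetic_scheme(k_on = 0.5, k_off = 0.005, k_cut = 2, P0 = 100,
                      batches = data.frame(name = "s", S0 = 2, D0 = 200,
                                           t_add = -30),
                      dimer_on_boost = boost)
  substrate_utilization(simulate_cleavage_kinetics(s, c(0, 3)), s)$s[2]
}
cat(sprintf("early (3 min) utilization: boost x1 %.1f%%, boost x5 %.1f%% — pre-pairing speeds the initial burst\n",
            early(1), early(5)))
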