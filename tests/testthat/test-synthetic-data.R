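test_that("generate_reference respects GC content, seed and alphabet", {
  # gc = 0 forces a pure A/T sequence
  at_only <- generate_reference(200, gc = 0, seed = 1)
  expect_false(grepl("[GC]", at_only$seq))

  # observed GC within 3 binomial s.d. of the target
  r <- generate_reference(10000, gc = 0.5, seed = 7)
  gc_obs <- mean(strsplit(r$seq, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.5), 3 * sqrt(0.25 / 10000))

  # determinism
  expect_identical(generate_reference(500, 0.4, "linear", seed = 3)$seq,
                   generate_reference(500, 0.4, "linear", seed = 3)$seq)

  expect_error(generate_reference(0, 0.5), "length")
  expect_error(generate_reference(10, 1.5), "gc")
  expect_error(reference_sequence("x", "ACGN"), "non-ACGT")
})

test_that("site_weight multiplies per-position preferences in the dyad frame", {
  ref <- generate_reference(100, 0.5, "circular", seed = 2)
  expect_equal(site_weight(uniform_bias_model(), ref, 0:99), rep(1, 100))

  gb <- consensus_bias_model("GNATNC", fold = 10, strength = 1)
  off <- bias_model(gb$weights, strength = 0)
  expect_equal(site_weight(off, ref, 0:99), rep(1, 100))

  # 4 determinate positions x fold 10 = 10^4 at an exact placement,
  # 1 at the reverse (CNTANG) placement: hand product over positions
  r2 <- reference_sequence("x", "GGATACAAAAACCTATGG", "circular")
  expect_equal(site_weight(gb, r2, 2), 10^4)   # GGATAC at 0 -> dyad_left 2
  expect_equal(site_weight(gb, r2, 13), 1)     # CCTATG at 11 -> dyad_left 13

  # strength acts as an exponent on the product
  gb2 <- consensus_bias_model("GNATNC", fold = 10, strength = 2)
  expect_equal(site_weight(gb2, r2, 2), 10^8)
})

test_that("symmetric bias models give reverse-complement-invariant landscapes", {
  gb <- consensus_bias_model("GNATNC", fold = 10, strength = 1)
  expect_true(gb$symmetric)
  for (seed in 1:3) {
    ref <- generate_reference(60, 0.5, "circular", seed = seed)
    w <- site_weight_landscape(gb, ref)
    w_rc <- site_weight_landscape(gb, ref_revcomp(ref))
    L <- ref_length(ref)
    # dyad between p and p+1 maps to dyad_left L-2-p on the other strand
    expect_equal(w_rc[((L - 2L - (0:(L - 1L))) %% L) + 1L], w)
  }
  # the symmetry identity is enforced at construction
  w <- matrix(1, 6, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  w[1, "G"] <- 5  # -3 G favoured but +3 C not: asymmetric
  expect_error(bias_model(w, symmetric = TRUE), "complement")
})

test_that("sample_cleavage_events draws sites proportional to weight", {
  ref <- generate_reference(400, 0.5, "circular", seed = 11)
  prep <- library_prep_params()
  expect_equal(nrow(sample_cleavage_events(ref, uniform_bias_model(), 0, prep)), 0)

  # uniform model: multinomial goodness-of-fit over sites
  ev <- sample_cleavage_events(ref, uniform_bias_model(), 20000, prep, seed = 5)
  counts <- tabulate(ev$dyad_left + 1L, nbins = 400)
  gof <- suppressWarnings(chisq.test(counts, p = rep(1 / 400, 400)))
  expect_gt(gof$p.value, 1e-4)

  # strongly biased model: nearly all events at exact motif placements
  gb <- consensus_bias_model("GNATNC", fold = 10, strength = 3)
  ref2 <- generate_reference(10000, 0.5, "circular", seed = 12)
  motif_dyads <- motif_scan(ref2, "GNATNC") + 2L  # window start -> dyad_left
  ev2 <- sample_cleavage_events(ref2, gb, 2000, prep, seed = 13)
  expect_gte(mean(ev2$dyad_left %in% (motif_dyads %% 10000)), 0.9)

  # nick fraction tracks p_nick
  prep_n <- library_prep_params(p_nick = 0.4)
  ev3 <- sample_cleavage_events(ref, uniform_bias_model(), 5000, prep_n, seed = 6)
  p_hat <- mean(ev3$kind != "dsb")
  expect_lt(abs(p_hat - 0.4), 3 * sqrt(0.4 * 0.6 / 5000))
})

test_that("simulate_library places reads at the filled-in ends", {
  prep <- library_prep_params(reads_per_event = 1)
  one_dsb <- data.frame(dyad_left = 100L,
                        kind = factor("dsb", c("dsb", "nick_top", "nick_bottom")))
  # Poisson multiplicity: fix seed where one read per end is emitted
  set.seed(1)
  rd <- NULL
  for (s in 1:50) {
    cand <- simulate_library(one_dsb, prep, 1000L, "circular", seed = s)
    if (nrow(cand) == 2L && length(unique(cand$strand)) == 2L) { rd <- cand; break }
  }
  expect_equal(sort(rd$pos), c(100L, 101L))
  expect_setequal(as.character(rd$strand[order(rd$pos)]), c("top", "bottom"))

  nick <- data.frame(dyad_left = 50L,
                     kind = factor("nick_top", c("dsb", "nick_top", "nick_bottom")))
  rdn <- simulate_library(nick, library_prep_params(reads_per_event = 3),
                          1000L, "circular", seed = 2)
  expect_true(all(rdn$strand == "top"))
  expect_true(all(rdn$pos == 50L))
})

test_that("strand balance and +1 offset hold without nicks or background", {
  sim <- simulated_library(seed = 21, length = 2000, n_events = 300)
  expect_equal(sum(sim$map$top), sum(sim$map$bottom))
  # per-event geometry: bottom - top = +1 (mod L) for every DSB
  expect_true(all(sim$events$kind == "dsb"))
  top_pos <- sort(unique(sim$reads$pos[sim$reads$strand == "top"]))
  bot_pos <- sort(unique(sim$reads$pos[sim$reads$strand == "bottom"]))
  expect_setequal((top_pos + 1L) %% 2000L, bot_pos)
})

test_that("incomplete fill-in shifts the expected fraction of reads inward", {
  one_site <- data.frame(dyad_left = rep(500L, 10000L),
                         kind = factor(rep("dsb", 10000L),
                                       c("dsb", "nick_top", "nick_bottom")))
  prep <- library_prep_params(f_partial = 0.2, reads_per_event = 1)
  rd <- simulate_library(one_site, prep, 2000L, "circular", seed = 31)
  top <- rd[rd$strand == "top", ]
  shifted <- mean(top$pos == 501L)
  expect_lt(abs(shifted - 0.2), 3 * sqrt(0.2 * 0.8 / nrow(top)))
  bot <- rd[rd$strand == "bottom", ]
  expect_lt(abs(mean(bot$pos == 500L) - 0.2), 3 * sqrt(0.2 * 0.8 / nrow(bot)))
})
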