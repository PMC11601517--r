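test_that("dyad windows are extracted and reoriented correctly", {
  # hand-indexed: circular AAGCATTA, top peak at index 3 ('C'), N = 2
  ref <- reference_sequence("x", "AAGCATTA", "circular")
  w <- extract_dyad_window(ref, 3L, "top", 2L)
  expect_equal(unname(w), c("G", "C", "A", "T"))
  expect_equal(names(w), c("-2", "-1", "1", "2"))

  # bottom peak of the same DSB (dyad_left = 3, bottom read at 4) gives
  # the exact reverse complement of the top window
  wb <- extract_dyad_window(ref, 4L, "bottom", 2L)
  expect_equal(unname(wb), c("A", "T", "G", "C"))  # revcomp of G,C,A,T

  # property over random dyads
  r <- generate_reference(300, 0.5, "circular", seed = 7)
  for (p in c(0L, 50L, 150L, 299L)) {
    top_w <- extract_dyad_window(r, p, "top", 5L)
    bot_w <- extract_dyad_window(r, (p + 1L) %% 300L, "bottom", 5L)
    expect_equal(paste(bot_w, collapse = ""),
                 cleavemap:::revcomp(paste(top_w, collapse = "")))
  }

  lin <- reference_sequence("y", "ACGTACGT", "linear")
  expect_error(extract_dyad_window(lin, 0L, "top", 3L), "out of range")
})

test_that("composition matrices hold column-wise base fractions", {
  same <- matrix(rep(c("G", "A", "T", "C"), each = 3), nrow = 3)
  colnames(same) <- c("-2", "-1", "1", "2")
  cm <- composition_matrix(same)
  expect_equal(cm$fractions["-2", "G"], 1)
  expect_equal(cm$fractions["2", "C"], 1)
  expect_true(all(abs(rowSums(cm$fractions) - 1) < 1e-9))

  # windows off a uniform sequence: all fractions near 0.25
  r <- generate_reference(5000, 0.5, "circular", seed = 17)
  anchors <- data.frame(pos = seq(0L, 4999L, by = 7L),
                        strand = factor("top", c("top", "bottom")))
  cmu <- composition_matrix(dyad_windows(r, anchors, 4L))
  expect_true(all(abs(cmu$fractions - 0.25) < 3 * sqrt(0.25 * 0.75 / nrow(anchors))))
})

test_that("a biased generator leaves its signature in recovered composition", {
  gb <- consensus_bias_model("GNATNC", fold = 10, strength = 2)
  sim <- simulated_library(seed = 23, length = 10000, n_events = 2000,
                           model = gb)
  anchors <- data.frame(pos = sim$events$dyad_left,
                        strand = factor("top", c("top", "bottom")))
  cm <- composition_matrix(dyad_windows(sim$ref, anchors, 3L))
  # G favoured at -3 and, rotationally symmetric, C at +3; A/T at -1/+1
  expect_equal(names(which.max(cm$fractions["-3", ])), "G")
  expect_equal(names(which.max(cm$fractions["3", ])), "C")
  expect_equal(names(which.max(cm$fractions["-1", ])), "A")
  expect_equal(names(which.max(cm$fractions["1", ])), "T")
})

test_that("GC-corrected logo is relative entropy against the background", {
  # observed == background -> all heights zero
  f <- matrix(0.25, nrow = 4, ncol = 4,
              dimnames = list(c("-2", "-1", "1", "2"), c("A", "C", "G", "T")))
  cm <- structure(list(fractions = f, n_sites = 10, halfwidth = 2),
                  class = "composition_matrix")
  lg <- gc_corrected_logo(cm, 0.5)
  expect_true(all(abs(lg$heights) < 1e-12))

  # one-hot column at gc = 0.5 carries log2(4) = 2 bits
  f2 <- f; f2["-1", ] <- c(1, 0, 0, 0)
  cm2 <- structure(list(fractions = f2, n_sites = 10, halfwidth = 2),
                   class = "composition_matrix")
  lg2 <- gc_corrected_logo(cm2, 0.5)
  expect_equal(lg2$information[["-1"]], 2)
  expect_equal(lg2$heights["-1", "A"], 2)

  # AT-rich background raises the information of a GC-biased column
  f3 <- f; f3["1", ] <- c(0.1, 0.4, 0.4, 0.1)
  cm3 <- structure(list(fractions = f3, n_sites = 10, halfwidth = 2),
                   class = "composition_matrix")
  expect_gt(gc_corrected_logo(cm3, 0.38)$information[["1"]],
            gc_corrected_logo(cm3, 0.50)$information[["1"]])

  expect_error(gc_corrected_logo(cm, 0), "strictly between")
  expect_error(gc_corrected_logo(cm, 1), "strictly between")
})

test_that("symmetry score is zero iff the dyad identity holds", {
  f <- matrix(0.25, nrow = 4, ncol = 4,
              dimnames = list(c("-2", "-1", "1", "2"), c("A", "C", "G", "T")))
  cm <- structure(list(fractions = f, n_sites = 5, halfwidth = 2),
                  class = "composition_matrix")
  expect_equal(symmetry_score(cm), 0)

  # construct an exactly symmetric non-uniform matrix:
  # f(p, b) = f(-p, complement(b))
  f2 <- f
  f2["-1", ] <- c(A = 0.7, C = 0.1, G = 0.1, T = 0.1)
  f2["1", ]  <- c(A = 0.1, C = 0.1, G = 0.1, T = 0.7)  # complement mirror
  cm2 <- structure(list(fractions = f2, n_sites = 5, halfwidth = 2),
                   class = "composition_matrix")
  expect_equal(symmetry_score(cm2), 0)

  f3 <- f2; f3["1", ] <- c(A = 0.7, C = 0.1, G = 0.1, T = 0.1)
  cm3 <- structure(list(fractions = f3, n_sites = 5, halfwidth = 2),
                   class = "composition_matrix")
  expect_gt(symmetry_score(cm3), 0.1)
})

test_that("average profiles around motif anchors show the dyad geometry", {
  gb <- consensus_bias_model("GNATNC", fold = 10, strength = 3)
  sim <- simulated_library(seed = 33, length = 8000, n_events = 1500,
                           background_rate = 0.002, model = gb)
  motif_starts <- motif_scan(sim$ref, "GNATNC")
  prof <- average_profile_around(sim$map, motif_starts, 5L)
  # motif start s corresponds to dyad_left = s + 2: mean top profile peaks
  # at center offset +2 and bottom at +3
  expect_equal(prof$offset[which.max(prof$top)], 2)
  expect_equal(prof$offset[which.max(prof$bottom)], 3)

  # single anchor returns the raw slice
  one <- average_profile_around(sim$map, motif_starts[1], 3L)
  idx <- ((motif_starts[1] + (-3:3)) %% 8000) + 1
  expect_equal(unname(one$top), sim$map$top[idx])

  # control anchors away from motifs are flat at background level
  set.seed(9)
  non <- setdiff(0:7999, as.vector(outer(motif_starts, -8:8, "+")) %% 8000)
  ctrl <- average_profile_around(sim$map, sample(non, 300), 5L)
  expect_lt(max(ctrl$top), max(prof$top) / 10)

  expect_error(average_profile_around(sim$map, integer(0), 5L), "empty")
})
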