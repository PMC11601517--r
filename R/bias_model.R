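#' Position-specific cleavage-bias models
#'
#' A bias model assigns each candidate cleavage dyad a multiplicative weight
#' built from position-specific base preferences. Positions are indexed
#' relative to the dyad axis as -W..-1, +1..+W (no position 0): the dyad axis
#' lies between relative positions -1 and +1. In absolute 0-based reference
#' coordinates, a dyad with `dyad_left = p` maps relative -1 to `p`,
#' relative -k to `p - k + 1`, and relative +k to `p + k`, so the window
#' covers `p - W + 1 .. p + W` (2W bases).
#'
#' A model declared `symmetric` must satisfy the rotational-symmetry identity
#' `weights[p, b] == weights[-p, complement(b)]`, the signature expected of a
#' twofold-symmetric protein dimer engaging two half-sites.
#'
#' @param weights numeric matrix with `2 * W` rows (relative positions
#'   -W..-1, +1..+W in that order) and 4 columns named A, C, G, T; all
#'   entries strictly positive.
#' @param strength nonnegative exponent applied to the product of
#'   per-position factors; `strength = 0` gives a uniform landscape.
#' @param symmetric if `TRUE`, the rotational-symmetry identity is enforced
#'   at construction.
#' @return An object of class `bias_model`.
#' @export
bias_model <- function(weights, strength = 1, symmetric = FALSE) {
  stopifnot(is.matrix(weights), ncol(weights) == 4L)
  if (nrow(weights) %% 2L != 0L || nrow(weights) < 2L)
    stop("weights must have an even number of rows >= 2 (positions -W..-1, +1..+W)")
  if (is.null(colnames(weights)) || !identical(colnames(weights), c("A", "C", "G", "T")))
    stop("weights columns must be named A, C, G, T in that order")
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("all bias weights must be finite and > 0")
  if (!is.numeric(strength) || length(strength) != 1L || strength < 0)
    stop("strength must be a nonnegative scalar")
  W <- nrow(weights) / 2L
  rownames(weights) <- relpos_labels(W)
  if (symmetric && !.is_symmetric_weights(weights))
    stop("weights do not satisfy weights[p, b] == weights[-p, complement(b)]")
  structure(list(W = W, weights = weights, strength = strength,
                 symmetric = symmetric),
            class = "bias_model")
}

# Dyad-relative position labels -W..-1, +1..+W (no 0).
relpos_labels <- function(W) {
  as.character(c(seq(-W, -1L), seq(1L, W)))
}

.is_symmetric_weights <- function(weights, tol = 1e-9) {
  W <- nrow(weights) / 2L
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (p in seq_len(W)) {
    for (b in colnames(weights)) {
      if (abs(weights[as.character(p), b] -
              weights[as.character(-p), comp[[b]]]) > tol) return(FALSE)
    }
  }
  TRUE
}

#' Uniform (no-preference) bias model
#'
#' All weights 1: every dyad placement is equally likely. Stands in for a
#' nonspecific background such as a catalytically dead control library.
#'
#' @param W half-width of the (inert) window.
#' @export
uniform_bias_model <- function(W = 3L) {
  w <- matrix(1, nrow = 2L * W, ncol = 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  bias_model(w, strength = 1, symmetric = TRUE)
}

#' Bias model from a degenerate consensus
#'
#' Builds a model whose determinate positions favour the given IUPAC-coded
#' consensus by `fold` per matching base; `N` positions are indifferent.
#' The consensus is laid across relative positions -W..-1, +1..+W. The
#' default `GNATNC` encodes the favoured hexamer at dimeric cleavage dyads
#' (G at -3, A at -1, T at +1, C at +3); it is its own reverse complement,
#' so the resulting model is rotationally symmetric.
#'
#' @param consensus IUPAC string of even length (2W).
#' @param fold preference factor for a matching base (> 0).
#' @param strength exponent passed to [bias_model()].
#' @export
consensus_bias_model <- function(consensus = "GNATNC", fold = 10, strength = 1) {
  letters_ <- strsplit(toupper(consensus), "", fixed = TRUE)[[1L]]
  if (length(letters_) %% 2L != 0L)
    stop("consensus length must be even (positions -W..-1, +1..+W)")
  w <- matrix(1, nrow = length(letters_), ncol = 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(letters_)) {
    allowed <- iupac_bases(letters_[i])
    if (length(allowed) < 4L) w[i, allowed] <- fold
  }
  sym <- .is_symmetric_weights(`rownames<-`(w, relpos_labels(length(letters_) / 2L)))
  bias_model(w, strength = strength, symmetric = sym)
}

#' Site weight of a dyad placement
#'
#' The weight of placing a cleavage dyad at `dyad_left` is the product of the
#' per-position preference factors over the window, raised to the model's
#' `strength`. A uniform model or `strength = 0` gives 1 everywhere.
#'
#' @param model a `bias_model`.
#' @param ref a `ref_seq`.
#' @param dyad_left 0-based coordinate of the base at relative position -1
#'   (vectorised).
#' @return Nonnegative numeric vector of weights.
#' @export
site_weight <- function(model, ref, dyad_left) {
  if (model$strength == 0) return(rep(1, length(dyad_left)))
  W <- model$W
  out <- rep(1, length(dyad_left))
  labs <- relpos_labels(W)
  offsets <- c(seq(-W, -1L) + 1L, seq(1L, W))  # rel -k -> p-k+1, +k -> p+k
  for (j in seq_along(labs)) {
    b <- ref_bases_at(ref, dyad_left + offsets[j])
    out <- out * model$weights[labs[j], ][b]
  }
  unname(out^model$strength)
}

#' Site-weight landscape over a whole reference
#'
#' @param model a `bias_model`.
#' @param ref a `ref_seq`.
#' @return Numeric vector of length `ref_length(ref)`; for a linear
#'   reference, dyads whose window does not fit are assigned weight 0
#'   (they cannot be sampled).
#' @export
site_weight_landscape <- function(model, ref) {
  L <- ref_length(ref)
  if (ref$topology == "circular") {
    site_weight(model, ref, 0:(L - 1L))
  } else {
    W <- model$W
    valid <- seq.int(W - 1L, L - W - 1L)  # window p-W+1..p+W in [0, L)
    out <- numeric(L)
    if (length(valid) > 0L && valid[1L] <= valid[length(valid)])
      out[valid + 1L] <- site_weight(model, ref, valid)
    out
  }
}

#' Normalised base preferences of a bias model
#'
#' Each row of the weight matrix rescaled to sum to 1 — the base
#' distribution the model induces at that position on an otherwise uniform
#' substrate. Comparable to a recovered composition matrix.
#'
#' @param model a `bias_model`.
#' @return Matrix of per-position base probabilities (rows sum to 1).
#' @export
bias_model_fractions <- function(model) {
  w <- model$weights^model$strength
  sweep(w, 1L, rowSums(w), "/")
}
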