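#' Equilibrium occupancy of monomer and dimer binding
#'
#' Under the simple hyperbola, the fraction of sites occupied by a monomer
#' at free protein concentration P is `theta = P / (Kd + P)`. For a DNA
#' substrate carrying two independent monomer binding sites, the fraction
#' of molecules with both sites occupied (the cleavage-competent,
#' dimer-bound pool) is `theta^2`. At P = 10 nM and Kd = 1.8 nM this is
#' 0.72 — the benchmark occupancy against which cleavage endpoints are
#' compared.
#'
#' @param P free protein concentration, nM (>= 0).
#' @param Kd apparent dissociation constant, nM (> 0).
#' @return Fraction in `[0, 1]`.
#' @export
fraction_single_bound <- function(P, Kd) {
  if (any(Kd <= 0)) stop("Kd must be > 0")
  if (any(P < 0)) stop("P must be >= 0")
  P / (Kd + P)
}

#' @rdname fraction_single_bound
#' @export
fraction_dimer_bound <- function(P, Kd) {
  fraction_single_bound(P, Kd)^2
}

#' Fit an apparent Kd to a binding titration
#'
#' Least-squares fit of the simple hyperbola `f = P / (Kd + P)` to observed
#' bound fractions, the standard reduction of an EMSA titration to an
#' apparent Kd. Optionally fits the ligand-depletion quadratic
#' (`quadratic = TRUE`, requiring the probe concentration `L0`), relevant
#' when the probe is not far below the Kd.
#'
#' @param concentrations protein concentrations, nM (>= 3 distinct values).
#' @param fraction_bound observed bound fractions in `[0, 1]`.
#' @param quadratic use the ligand-depletion (tight-binding) form.
#' @param L0 labelled-probe concentration, nM (quadratic form only).
#' @return List with `Kd`, `se` (standard error), `fitted`, `model`.
#' @export
fit_kd <- function(concentrations, fraction_bound,
                   quadratic = FALSE, L0 = NULL) {
  if (length(concentrations) < 3L || length(unique(concentrations)) < 3L)
    stop("need at least 3 distinct concentrations")
  if (length(fraction_bound) != length(concentrations))
    stop("concentrations and fraction_bound differ in length")
  if (all(fraction_bound == 0))
    stop("all bound fractions are zero: Kd is unidentifiable")
  d <- data.frame(P = concentrations, f = fraction_bound)
  start_kd <- max(stats::median(d$P), 1e-6)
  fit <- if (quadratic) {
    if (is.null(L0)) stop("quadratic fit requires the probe concentration L0")
    # fraction bound of probe with depletion: roots of L0*f^2 - (L0+P+Kd)*f + P = 0
    minpack.lm::nlsLM(
      f ~ ((L0 + P + Kd) - sqrt((L0 + P + Kd)^2 - 4 * L0 * P)) / (2 * L0),
      data = d, start = list(Kd = start_kd),
      lower = 1e-9, control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    minpack.lm::nlsLM(f ~ P / (Kd + P), data = d,
                      start = list(Kd = start_kd), lower = 1e-9,
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  if (!fit$convInfo$isConv) stop("Kd fit did not converge")
  est <- summary(fit)$coefficients
  list(Kd = unname(est["Kd", "Estimate"]), se = unname(est["Kd", "Std. Error"]),
       fitted = stats::fitted(fit), model = fit)
}

#' Strand breaks as a fraction of protein molecules
#'
#' Converts a measured quantity of strand breaks into the percentage of
#' protein molecules that can have performed (at most one) cleavage, using
#' protein moles = concentration x volume (1 nM x 1 ul = 1 fmol). 300 fmol
#' of breaks in a 70 ul reaction at 100 nM protein is 4.3% — i.e. only ~4%
#' of molecules cut, the arithmetic behind the low per-protein efficiency
#' of plasmid reactions.
#'
#' @param breaks_fmol strand breaks, fmol.
#' @param protein_conc_nM protein concentration, nM (> 0).
#' @param volume_ul reaction volume, ul (> 0).
#' @return Percent of protein molecules (can exceed 100 if breaks exceed
#'   protein; capped nowhere — the caller interprets saturation).
#' @export
breaks_to_protein_fraction <- function(breaks_fmol, protein_conc_nM, volume_ul) {
  if (protein_conc_nM <= 0) stop("protein concentration must be > 0")
  if (volume_ul <= 0) stop("volume must be > 0")
  if (breaks_fmol < 0) stop("breaks must be >= 0")
  100 * breaks_fmol / (protein_conc_nM * volume_ul)
}

#' Two-phase association fit of a substrate-utilization time course
#'
#' Least-squares fit of `Y(t) = A1 (1 - exp(-k1 t)) + A2 (1 - exp(-k2 t))`
#' with the convention `k1 >= k2`. Multi-start initialisation guards
#' against local optima; fits where the two rates nearly coincide (or one
#' amplitude vanishes) are flagged `degenerate`, since a single exponential
#' then describes the data equally well. These fits are descriptive
#' summaries of biphasic shape, not estimates of mechanistic rate
#' constants.
#'
#' @param times time points, minutes (>= 5).
#' @param utilization percent substrate utilized at each time, in `[0, 100]`.
#' @param n_starts number of random multi-start initialisations.
#' @return List with `A1`, `k1`, `A2`, `k2`, `degenerate` flag, `fitted`,
#'   `rss`, `model`.
#' @export
two_phase_fit <- function(times, utilization, n_starts = 8L) {
  if (length(times) < 5L) stop("need at least 5 time points")
  if (length(utilization) != length(times))
    stop("times and utilization differ in length")
  if (any(utilization < 0 | utilization > 100))
    stop("utilization must be a percentage in [0, 100]")
  d <- data.frame(t = times, y = utilization)
  ymax <- max(d$y)
  t_scale <- stats::median(d$t[d$t > 0])
  set.seed(7L)  # reproducible multi-start grid
  starts <- lapply(seq_len(n_starts), function(i) {
    list(A1 = ymax * stats::runif(1, 0.3, 0.7),
         A2 = ymax * stats::runif(1, 0.2, 0.6),
         k1 = 10^stats::runif(1, -0.5, 1.5) / t_scale,
         k2 = 10^stats::runif(1, -2.5, -0.5) / t_scale)
  })
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A1 * (1 - exp(-k1 * t)) + A2 * (1 - exp(-k2 * t)),
                        data = d, start = s,
                        lower = c(0, 0, 1e-9, 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("two-phase fit did not converge from any start")
  co <- stats::coef(best$fit)
  # enforce k1 >= k2 by relabelling
  if (co[["k1"]] < co[["k2"]])
    co <- c(A1 = co[["A2"]], A2 = co[["A1"]], k1 = co[["k2"]], k2 = co[["k1"]])
  amp_floor <- 1e-3 * max(ymax, 1)
  degenerate <- (co[["k1"]] / co[["k2"]] < 3) ||
    (min(co[["A1"]], co[["A2"]]) < amp_floor)
  list(A1 = co[["A1"]], k1 = co[["k1"]], A2 = co[["A2"]], k2 = co[["k2"]],
       degenerate = degenerate, fitted = stats::fitted(best$fit),
       rss = best$rss, model = best$fit)
}
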