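#' Kinetic-trap model of dimeric cleavage
#'
#' A minimal mass-action embodiment of the idea that rapid, high-affinity
#' monomer binding to an excess of nonproductive sites ("decoys") traps
#' most protein, so that only substrate molecules that assembled a dimer
#' before the reaction starts are cut quickly, and further cleavage is
#' limited by slow exchange (low off-rate). Species per substrate batch:
#' free substrate S, singly bound SP, doubly bound (cleavage-competent)
#' SP2, cleaved C, plus decoy sites D and bound decoys DP; free protein P
#' is shared across batches.
#'
#' Reactions (concentrations in nM, time in minutes):
#' \preformatted{
#'   S  + P <-> SP    on 2*k_on,        off k_off
#'   SP + P <-> SP2   on boost*k_on,    off 2*k_off
#'   SP2    ->  C     k_cut  (only after t = 0; t < 0 is the "on ice"
#'                            pre-equilibration with cleavage off)
#'   D  + P <-> DP    on k_on,          off k_off
#' }
#' The binomial statistical factors (2*k_on into SP, 2*k_off out of SP2)
#' make the k_cut = 0 equilibrium coincide exactly with the closed-form
#' two-independent-site occupancy: the doubly bound fraction is
#' `(Pf/(Kd+Pf))^2` at free protein Pf with Kd = k_off/k_on.
#' `dimer_on_boost > 1` mimics pre-paired protomers (e.g. an artificial
#' dimerization module) by accelerating the second binding step.
#' Cleavage sequesters the two bound protomers (no recycling), so protein
#' is conserved as `P + sum(SP + 2*SP2 + DP + 2*C)`.
#'
#' @param k_on association rate, per nM per min.
#' @param k_off dissociation rate, per min.
#' @param k_cut cleavage rate of the doubly bound complex, per min.
#' @param P0 total protein, nM.
#' @param batches data.frame with one row per substrate addition:
#'   `name`, `S0` (cleavable-site concentration, nM), `D0` (decoy
#'   monomer-site concentration, nM), `t_add` (minutes; negative = present
#'   during the pre-equilibration on ice, 0 = added at reaction start,
#'   positive = staged addition during the reaction).
#' @param dimer_on_boost multiplier on the second-binding on-rate.
#' @return An object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(k_on = 0.1, k_off = 0.06, k_cut = 1,
                           P0 = 100,
                           batches = data.frame(name = "substrate",
                                                S0 = 2, D0 = 200, t_add = -30),
                           dimer_on_boost = 1) {
  stopifnot(k_on >= 0, k_off >= 0, k_cut >= 0, P0 >= 0, dimer_on_boost > 0)
  req <- c("name", "S0", "D0", "t_add")
  if (!all(req %in% names(batches))) stop("batches needs columns: ",
                                          paste(req, collapse = ", "))
  if (any(batches$S0 < 0) || any(batches$D0 < 0))
    stop("site pools must be >= 0")
  if (anyDuplicated(batches$name)) stop("batch names must be unique")
  structure(list(k_on = k_on, k_off = k_off, k_cut = k_cut, P0 = P0,
                 batches = batches, dimer_on_boost = dimer_on_boost),
            class = "kinetic_scheme")
}

# Species layout: P, then per batch (S, SP, SP2, C, D, DP).
.scheme_state_names <- function(scheme) {
  per <- c("S", "SP", "SP2", "C", "D", "DP")
  c("P", as.vector(t(outer(scheme$batches$name, per, paste, sep = "."))))
}

.trap_derivs <- function(t, y, parms) {
  with(parms, {
    P <- y[1L]
    d <- numeric(length(y))
    dP <- 0
    for (j in seq_len(nb)) {
      i <- 1L + (j - 1L) * 6L
      S <- y[i + 1L]; SP <- y[i + 2L]; SP2 <- y[i + 3L]
      D <- y[i + 5L]; DP <- y[i + 6L]
      v_on1 <- 2 * k_on * P * S
      v_off1 <- k_off * SP
      v_on2 <- boost * k_on * P * SP
      v_off2 <- 2 * k_off * SP2
      v_cut <- k_cut_eff * SP2
      v_ond <- k_on * P * D
      v_offd <- k_off * DP
      d[i + 1L] <- -v_on1 + v_off1                     # S
      d[i + 2L] <- v_on1 - v_off1 - v_on2 + v_off2     # SP
      d[i + 3L] <- v_on2 - v_off2 - v_cut              # SP2
      d[i + 4L] <- v_cut                               # C
      d[i + 5L] <- -v_ond + v_offd                     # D
      d[i + 6L] <- v_ond - v_offd                      # DP
      dP <- dP - v_on1 + v_off1 - v_on2 + v_off2 - v_ond + v_offd
    }
    d[1L] <- dP
    list(d)
  })
}

#' Integrate the kinetic-trap model
#'
#' Deterministic integration of the mass-action scheme. Time t = 0 is the
#' shift to reaction temperature: for t < 0 (assembly on ice) cleavage is
#' off (`k_cut` forced to 0); substrate batches are injected at their
#' `t_add`. Integration starts at `min(t_add, min(t_grid))`.
#'
#' @param scheme a `kinetic_scheme`.
#' @param t_grid output times in minutes (may include negative times to
#'   observe the pre-equilibration).
#' @param rtol,atol solver tolerances ([deSolve::lsoda]).
#' @return data.frame of trajectories: `time`, free `P`, and per batch
#'   `<name>.S`, `.SP`, `.SP2`, `.C`, `.D`, `.DP`.
#' @export
simulate_cleavage_kinetics <- function(scheme, t_grid,
                                       rtol = 1e-10, atol = 1e-10) {
  t_grid <- sort(unique(as.numeric(t_grid)))
  nb <- nrow(scheme$batches)
  nm <- .scheme_state_names(scheme)
  y <- stats::setNames(numeric(length(nm)), nm)
  y["P"] <- scheme$P0

  t0 <- min(c(t_grid, scheme$batches$t_add, 0))
  # breakpoints: batch additions and the ice -> 37C switch at t = 0
  brk <- sort(unique(c(scheme$batches$t_add, 0, max(t_grid))))
  brk <- brk[brk >= t0]
  if (brk[1L] > t0) brk <- c(t0, brk)

  # inject batches present at the very start
  for (j in which(scheme$batches$t_add <= t0)) {
    y[sprintf("%s.S", scheme$batches$name[j])] <- scheme$batches$S0[j]
    y[sprintf("%s.D", scheme$batches$name[j])] <- scheme$batches$D0[j]
  }

  rows <- list()
  if (t0 %in% t_grid) rows[[length(rows) + 1L]] <- c(time = t0, y)
  cur_t <- t0
  for (b in brk[brk > t0]) {
    inner <- t_grid[t_grid > cur_t & t_grid < b]
    times <- unique(c(cur_t, inner, b))
    parms <- list(k_on = scheme$k_on, k_off = scheme$k_off,
                  k_cut_eff = if (b <= 0) 0 else scheme$k_cut,
                  boost = scheme$dimer_on_boost, nb = nb)
    sol <- deSolve::lsoda(y, times, .trap_derivs, parms,
                          rtol = rtol, atol = atol)
    if (any(sol[, -1L] < -1e-6))
      stop("integration produced negative concentrations")
    for (r in seq_len(nrow(sol))[-1L]) {
      tt <- sol[r, 1L]
      if (tt %in% t_grid && tt < b)
        rows[[length(rows) + 1L]] <- sol[r, ]
    }
    y <- pmax(sol[nrow(sol), -1L], 0)
    names(y) <- nm
    cur_t <- b
    # staged additions arriving exactly at this breakpoint
    for (j in which(scheme$batches$t_add == b)) {
      y[sprintf("%s.S", scheme$batches$name[j])] <-
        y[sprintf("%s.S", scheme$batches$name[j])] + scheme$batches$S0[j]
      y[sprintf("%s.D", scheme$batches$name[j])] <-
        y[sprintf("%s.D", scheme$batches$name[j])] + scheme$batches$D0[j]
    }
    if (b %in% t_grid) rows[[length(rows) + 1L]] <- c(time = b, y)
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("time", nm)
  rownames(out) <- NULL
  out[match(t_grid[t_grid >= t0], out$time), , drop = FALSE]
}

#' Substrate utilization from a trajectory
#'
#' Percent of each batch's cleavable substrate cut over time:
#' `100 * C / S0`. Monotone non-decreasing by construction.
#'
#' @param trajectory output of [simulate_cleavage_kinetics()].
#' @param scheme the `kinetic_scheme` that produced it.
#' @return data.frame: `time` plus one percent column per batch.
#' @export
substrate_utilization <- function(trajectory, scheme) {
  out <- data.frame(time = trajectory$time)
  for (j in seq_len(nrow(scheme$batches))) {
    nm <- scheme$batches$name[j]
    S0 <- scheme$batches$S0[j]
    out[[nm]] <- if (S0 > 0) 100 * trajectory[[paste0(nm, ".C")]] / S0 else 0
  }
  out
}

#' Conserved totals of a trajectory
#'
#' Total protein (`P + sum(SP + 2 SP2 + DP + 2 C)`; cleaved sites retain
#' their two protomers) and per-batch DNA-site totals, for conservation
#' checks.
#'
#' @param trajectory output of [simulate_cleavage_kinetics()].
#' @param scheme the `kinetic_scheme`.
#' @return data.frame with `time`, `protein`, and `<name>.sites` columns.
#' @export
conserved_totals <- function(trajectory, scheme) {
  out <- data.frame(time = trajectory$time, protein = trajectory$P)
  for (nm in scheme$batches$name) {
    g <- function(sp) trajectory[[paste0(nm, ".", sp)]]
    out$protein <- out$protein + g("SP") + 2 * g("SP2") + g("DP") + 2 * g("C")
    out[[paste0(nm, ".sites")]] <- g("S") + g("SP") + g("SP2") + g("C")
  }
  out
}
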