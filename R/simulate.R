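#' Library-preparation parameters
#'
#' Controls the generative model of an end-capture cleavage library:
#' the nick/DSB mixture, the incomplete fill-in read-shift artifact, the
#' uniform nonspecific background, and read multiplicity.
#'
#' @param p_nick probability that an event is a single-strand nick rather
#'   than a DSB (nicks split evenly between strands unless `p_nick_top`
#'   is given).
#' @param f_partial probability that a read is misassigned one nucleotide
#'   inward by incomplete fill-in of the 2-nt 5' overhang before adaptor
#'   ligation (top: p -> p+1; bottom: p+1 -> p).
#' @param background_rate expected uniform background reads per position
#'   per strand (Poisson), emulating a nonspecific control library.
#' @param reads_per_event mean read multiplicity per captured end (Poisson).
#' @param p_nick_top fraction of nicks on the top strand.
#' @return An object of class `prep_params`.
#' @export
library_prep_params <- function(p_nick = 0, f_partial = 0,
                                background_rate = 0, reads_per_event = 1,
                                p_nick_top = 0.5) {
  for (nm in c("p_nick", "f_partial", "p_nick_top")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(nm, " must be a probability in [0, 1]")
  }
  if (background_rate < 0) stop("background_rate must be >= 0")
  if (reads_per_event < 0) stop("reads_per_event must be >= 0")
  structure(list(p_nick = p_nick, f_partial = f_partial,
                 background_rate = background_rate,
                 reads_per_event = reads_per_event,
                 p_nick_top = p_nick_top),
            class = "prep_params")
}

#' Sample cleavage events under a bias model
#'
#' Dyads are drawn with replacement with probability proportional to
#' [site_weight()]; each event is a DSB with probability `1 - p_nick`,
#' otherwise a nick assigned to the top or bottom strand.
#'
#' An event is described by `dyad_left`, the 0-based coordinate of the base
#' at relative position -1; the dyad axis (centre of the 2-nt 5' overhang)
#' lies between `dyad_left` and `dyad_left + 1`.
#'
#' @param ref a `ref_seq`.
#' @param model a `bias_model`.
#' @param n_events number of events to draw (>= 0).
#' @param prep a `prep_params` (only `p_nick`/`p_nick_top` used here).
#' @param seed integer RNG seed.
#' @return data.frame with columns `dyad_left` (integer) and `kind`
#'   (factor: dsb, nick_top, nick_bottom).
#' @export
sample_cleavage_events <- function(ref, model, n_events,
                                   prep = library_prep_params(), seed = 1L) {
  if (ref_length(ref) < 1L) stop("empty reference")
  if (n_events < 0) stop("n_events must be >= 0")
  kinds <- c("dsb", "nick_top", "nick_bottom")
  if (n_events == 0)
    return(data.frame(dyad_left = integer(0),
                      kind = factor(character(0), levels = kinds)))
  set.seed(seed)
  w <- site_weight_landscape(model, ref)
  if (all(w == 0)) stop("no valid dyad placements on this reference")
  dyad <- sample.int(ref_length(ref), size = n_events, replace = TRUE,
                     prob = w) - 1L
  kind <- ifelse(stats::runif(n_events) < prep$p_nick,
                 ifelse(stats::runif(n_events) < prep$p_nick_top,
                        "nick_top", "nick_bottom"),
                 "dsb")
  data.frame(dyad_left = dyad, kind = factor(kind, levels = kinds))
}

#' Simulate strand-assigned reads from cleavage events
#'
#' Emulates end capture with fill-in and adaptor ligation: each captured end
#' yields a read assigned to the nucleotide immediately next to the adaptor.
#' With full fill-in, a DSB at `dyad_left = p` produces a top-strand read at
#' `p` and a bottom-strand read at `p + 1` (so the strand-to-strand
#' cross-correlation of the resulting maps peaks at lag +1). A top nick
#' yields only the top read, a bottom nick only the bottom read. With
#' probability `f_partial` a read is shifted one nucleotide inward
#' (top `p -> p+1`, bottom `p+1 -> p`), the incomplete fill-in artifact.
#' Read multiplicity per end is Poisson with mean `reads_per_event`;
#' uniform background reads are Poisson per position per strand.
#'
#' @param events data.frame from [sample_cleavage_events()].
#' @param prep a `prep_params`.
#' @param ref_length reference length in bp.
#' @param topology `"circular"` or `"linear"`.
#' @param seed integer RNG seed.
#' @return data.frame with columns `pos` (0-based integer) and `strand`
#'   (factor: top, bottom).
#' @export
simulate_library <- function(events, prep, ref_length,
                             topology = c("circular", "linear"), seed = 1L) {
  topology <- match.arg(topology)
  L <- as.integer(ref_length)
  set.seed(seed)

  top_kind <- events$kind %in% c("dsb", "nick_top")
  bot_kind <- events$kind %in% c("dsb", "nick_bottom")
  top_pos <- events$dyad_left[top_kind]
  bot_pos <- events$dyad_left[bot_kind] + 1L
  if (topology == "circular") {
    bot_pos <- bot_pos %% L
  } else if (any(bot_pos >= L) || any(top_pos < 0L)) {
    stop("event window exceeds linear reference bounds")
  }

  # one multiplicity per event, shared by its two ends: both ends of a DSB
  # enter the library together, so top and bottom totals balance exactly
  mult <- stats::rpois(nrow(events), prep$reads_per_event)
  top <- rep(top_pos, mult[top_kind])
  bot <- rep(bot_pos, mult[bot_kind])
  if (topology == "circular") top <- top %% L

  # incomplete fill-in: shift a read one nucleotide inward
  if (prep$f_partial > 0) {
    shift_top <- stats::runif(length(top)) < prep$f_partial
    shift_bot <- stats::runif(length(bot)) < prep$f_partial
    top[shift_top] <- top[shift_top] + 1L
    bot[shift_bot] <- bot[shift_bot] - 1L
    if (topology == "circular") {
      top <- top %% L
      bot <- bot %% L
    } else {
      top <- pmin(top, L - 1L)
      bot <- pmax(bot, 0L)
    }
  }

  # uniform nonspecific background
  if (prep$background_rate > 0) {
    n_bg_top <- stats::rpois(1L, prep$background_rate * L)
    n_bg_bot <- stats::rpois(1L, prep$background_rate * L)
    top <- c(top, sample.int(L, n_bg_top, replace = TRUE) - 1L)
    bot <- c(bot, sample.int(L, n_bg_bot, replace = TRUE) - 1L)
  }

  data.frame(
    pos = c(top, bot),
    strand = factor(rep(c("top", "bottom"), c(length(top), length(bot))),
                    levels = c("top", "bottom"))
  )
}
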