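#' Stochastic engine configuration
#'
#' Controls how one cell's reactions are advanced inside each outer
#' (volume-frozen) step of the multi-scale loop.
#'
#' @param method `"ssa"` for the exact Gillespie direct method, or
#'   `"tauleap"` for fixed-step tau-leaping with automatic whole-window
#'   SSA fallback whenever a leap would drive a species negative.
#' @param outer_step the hybrid step (h) over which cell volume and TMZ
#'   are frozen; default 0.1 h (6 min).  Summary outputs are
#'   statistically insensitive to halving this.
#' @param n_sub number of tau leaps per outer step; the leap size is
#'   `outer_step / n_sub` so leaps always tile the window exactly.
#'   Default 1 (the coarsest fixed leap).
#' @return An object of class `phenosel_engine`.
#' @export
engine_config <- function(method = c("tauleap", "ssa"), outer_step = 0.1,
                          n_sub = 1L) {
  method <- match.arg(method)
  if (!is.numeric(outer_step) || outer_step <= 0) {
    stop("`outer_step` must be > 0", call. = FALSE)
  }
  n_sub <- as.integer(n_sub)
  if (n_sub < 1L) stop("`n_sub` must be >= 1", call. = FALSE)
  structure(list(method = method, outer_step = outer_step, n_sub = n_sub),
            class = "phenosel_engine")
}

#' Advance one cell's reactions over a time window
#'
#' Runs the chosen stochastic engine on a reaction network for a fixed
#' window with frozen TMZ concentration.  The SSA path is statistically
#' exact; the tau-leap path fires Poisson-distributed channel counts per
#' leap and redoes the *whole* window with SSA if any species would go
#' negative.  If the death channel fires, the firing time is recorded
#' and all later events in the window are discarded.
#'
#' @param state named or unnamed vector of non-negative integer molecule
#'   counts, one per network species.
#' @param network a [build_network()] or [custom_network()] object.
#' @param window window length (h).
#' @param cfg an [engine_config()]; `cfg$method` picks the engine and
#'   `cfg$n_sub` the leap subdivision (the leap is `window / n_sub`).
#' @param tmz frozen TMZ concentration over the window (uM).
#' @param log_events keep an event log (SSA path only)?  Off by default.
#' @return A list with `state` (updated counts), `death_fired`,
#'   `death_time` (h into the window, `NA` if no death), `n_events`,
#'   `fell_back` (tau-leap redone with SSA?), and, when requested,
#'   `events` (a tibble of time/channel).
#' @export
#' @examples
#' net <- custom_network("X", list(
#'   list(stoich = 1L, kind = 0L, rate = 0.1),
#'   list(stoich = -1L, kind = 1L, rate = 0.01, dep1 = 1)
#' ))
#' advance_reactions(c(X = 10), net, window = 100, cfg = engine_config("ssa"))
advance_reactions <- function(state, network, window,
                              cfg = engine_config(), tmz = 0,
                              log_events = FALSE) {
  stopifnot(inherits(network, "phenosel_network"),
            inherits(cfg, "phenosel_engine"))
  state <- as.numeric(state)
  if (length(state) != length(network$species)) {
    stop("`state` must have one entry per species", call. = FALSE)
  }
  if (any(!is.finite(state)) || any(state < 0) ||
      any(state != floor(state))) {
    stop("`state` must be non-negative integer counts", call. = FALSE)
  }
  if (!is.finite(tmz) || tmz < 0) stop("`tmz` must be >= 0", call. = FALSE)
  res <- advance_cell_cpp(state, net_as_list(network), tmz, window,
                          method = if (cfg$method == "ssa") 0L else 1L,
                          n_sub = cfg$n_sub, log_events = log_events)
  out <- list(
    state = stats::setNames(res$state, network$species),
    death_fired = res$death_fired,
    death_time = res$death_time,
    n_events = res$n_events,
    fell_back = res$fell_back
  )
  if (log_events) {
    out$events <- tibble::tibble(
      time = res$event_time,
      channel = network$reactions$label[res$event_channel + 1L]
    )
  }
  out
}

#' Poisson event counts for a tau leap
#'
#' The tau-leap primitive: the number of firings of a channel with
#' constant propensity over a leap of length `tau` is
#' Poisson(propensity * tau).
#'
#' @param propensity channel propensity(ies), 1/h, `>= 0`.
#' @param tau leap length (h).
#' @return Integer event count(s), one per propensity.
#' @export
poisson_counts <- function(propensity, tau) {
  if (any(!is.finite(propensity)) || any(propensity < 0)) {
    stop("`propensity` must be finite and >= 0", call. = FALSE)
  }
  stats::rpois(length(propensity), propensity * tau)
}
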