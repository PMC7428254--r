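#' Simulate the constant-slot cell population
#'
#' Runs the multi-scale model: `K` slots of cells, each carrying its own
#' molecule counts, volume and division-volume target.  Per outer step
#' (default 6 min) the TMZ concentration and cell volume are frozen, the
#' stochastic reactions (including the death channel) are advanced with
#' the configured engine, dead cells vacate their slot, survivors grow
#' exponentially at the TMZ-inhibited rate, and any cell at or past its
#' division volume divides: daughter 1 keeps the parent slot, daughter 2
#' displaces another slot chosen by the replacement policy, molecules are
#' split binomially and both daughters draw fresh division targets from
#' the noisy linear size map.
#'
#' @param params a [model_params()] object.
#' @param schedule a [dose_schedule()].
#' @param t_end simulation end time (h).
#' @param K number of slots; defaults to `params$K`.  The published runs
#'   use `K = 10000`; desk-scale runs use 500-1000.
#' @param engine an [engine_config()].
#' @param variant reaction-network variant, see [build_network()].
#' @param include_basal death channel includes the basal rate `eps`?
#'   Default: yes when `params$eps > 0` (data-constrained model).
#' @param bounded_vf draw division volumes from the bounded (truncated)
#'   size map?  Default `TRUE`, the interval being `params$vf_bounds`.
#' @param replacement `"random"` (daughter 2 displaces a uniformly random
#'   other slot, live or dead) or `"dead_first"` (dead slots refilled
#'   preferentially).
#' @param record_every record the population series every this many outer
#'   steps (default 10 = hourly at the 6-min step).
#' @param init optional initial cell table as produced by
#'   [init_population()]; defaults to [init_population()] itself.
#' @param snapshot_t optional time (h) at which to keep a full per-cell
#'   snapshot of the live population.
#' @param t0 start time (h), default 0.
#' @return An object of class `phenosel_sim` with elements `series`
#'   (tibble: `t`, `M` live cells, `N = M/K`, per-species live-cell
#'   means, `ratio` = mean MGMT / mean REF), `cells` (final per-slot
#'   state), `snapshot` (tibble or `NULL`), and run metadata.
#' @export
#' @examples
#' p <- params_constrained(K = 100)
#' sim <- simulate_population(p, dose_schedule("sigmoid", dose = 800),
#'                            t_end = 24, engine = engine_config("ssa"))
#' tail(sim$series)
simulate_population <- function(params, schedule, t_end,
                                K = params$K,
                                engine = engine_config(),
                                variant = c("reduced", "full"),
                                include_basal = NULL,
                                bounded_vf = TRUE,
                                replacement = c("random", "dead_first"),
                                record_every = 10L,
                                init = NULL,
                                snapshot_t = NULL,
                                t0 = 0) {
  stopifnot(inherits(params, "phenosel_params"),
            inherits(schedule, "phenosel_schedule"),
            inherits(engine, "phenosel_engine"))
  variant <- match.arg(variant)
  replacement <- match.arg(replacement)
  if (variant == "full" && engine$method != "ssa") {
    stop("the full variant carries a binary gene state; use the SSA engine",
         call. = FALSE)
  }
  net <- build_network(params, variant, include_basal)
  if (is.null(init)) init <- init_population(params, K, variant = variant)
  K <- nrow(init)
  if (K < 1L) stop("empty population", call. = FALSE)

  cm <- cells_to_matrices(init, net$species)
  res <- simulate_population_cpp(
    net_as_list(net),
    list(mu0 = params$mu0, I50 = params$I50, sigma1 = params$sigma1,
         sigma2 = params$sigma2, a_map = params$a_map, b_map = params$b_map,
         vf_lo = params$vf_bounds[1], vf_hi = params$vf_bounds[2]),
    schedule_as_list(schedule),
    cm$counts, cm$volume, cm$vf_target, cm$alive,
    t0, t_end, engine$outer_step,
    method = if (engine$method == "ssa") 0L else 1L,
    n_sub = engine$n_sub,
    bounded_vf = bounded_vf,
    policy = if (replacement == "dead_first") 1L else 0L,
    record_every = as.integer(record_every),
    snapshot_t = if (is.null(snapshot_t)) NA_real_ else snapshot_t
  )

  means <- res$means
  colnames(means) <- paste0("mean_", tolower(net$species))
  series <- dplyr::bind_cols(
    tibble::tibble(t = res$t, M = as.integer(res$M), N = res$N),
    tibble::as_tibble(means),
    tibble::tibble(ratio = res$ratio)
  )
  cells <- matrices_to_cells(res$counts, res$volume, res$vf_target,
                             res$alive, net$species)
  snapshot <- NULL
  if (!is.null(snapshot_t) && nrow(res$snapshot) > 0) {
    snap <- res$snapshot
    colnames(snap) <- c(tolower(net$species), "volume")
    snapshot <- tibble::as_tibble(snap)
    attr(snapshot, "time") <- res$snapshot_time
  }
  structure(
    list(series = series, cells = cells, snapshot = snapshot,
         params = params, schedule = schedule, engine = engine,
         K = K, variant = variant, replacement = replacement,
         n_fallback = res$n_fallback, n_divisions = res$n_divisions,
         n_deaths = res$n_deaths, t0 = t0, t_end = t_end),
    class = "phenosel_sim"
  )
}

#' @export
print.phenosel_sim <- function(x, ...) {
  n <- nrow(x$series)
  cat("<phenosel_sim> ", x$variant, " model, K = ", x$K, ", ",
      x$schedule$kind, " dose ", x$schedule$dose, " uM, t in [",
      x$t0, ", ", x$t_end, "] h\n", sep = "")
  cat("final: N = ", signif(x$series$N[n], 4),
      ", ratio = ", signif(x$series$ratio[n], 4),
      "; divisions ", x$n_divisions, ", deaths ", x$n_deaths, "\n", sep = "")
  invisible(x)
}

#' Initial cell population
#'
#' Default initial conditions: every slot live, volumes uniform on
#' `[V_I, 2 V_I)`, per-cell division targets drawn from the size map,
#' and molecule counts started at the rounded mean-field steady state
#' (symmetric between the MGMT and REF genes).  A pre-dose burn-in
#' (e.g. 144 h before `t_in`) erases the arbitrariness of this choice.
#'
#' @inheritParams simulate_population
#' @param variant `"reduced"` or `"full"` (adds the undamaged gene
#'   state).
#' @return A tibble with one row per slot: `volume`, `vf_target`,
#'   species counts, `alive`.
#' @export
init_population <- function(params, K = params$K,
                            variant = c("reduced", "full"),
                            bounded_vf = TRUE) {
  variant <- match.arg(variant)
  mf <- mean_field(params)
  vol <- stats::runif(K, params$V_I, 2 * params$V_I)
  out <- tibble::tibble(
    volume = vol,
    vf_target = draw_vf_target(vol, params, bounded = bounded_vf),
    mrna_mgmt = round(mf$mean_mrna),
    mgmt = round(mf$mean_protein),
    mrna_ref = round(mf$mean_mrna),
    ref = round(mf$mean_protein),
  )
  if (variant == "full") out$dna_dam <- 0
  out$alive <- TRUE
  out
}

cells_to_matrices <- function(cells, species) {
  cols <- tolower(species)
  missing <- setdiff(cols, names(cells))
  if (length(missing) > 0) {
    stop("cell table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  list(
    counts = as.matrix(cells[cols]),
    volume = cells$volume,
    vf_target = cells$vf_target,
    alive = cells$alive
  )
}

matrices_to_cells <- function(counts, volume, vf_target, alive, species) {
  colnames(counts) <- tolower(species)
  dplyr::bind_cols(
    tibble::tibble(volume = volume, vf_target = vf_target),
    tibble::as_tibble(counts),
    tibble::tibble(alive = alive)
  )
}

schedule_as_list <- function(schedule) {
  list(
    kind = match(schedule$kind, c("step", "pulse", "sigmoid")) - 1L,
    dose = schedule$dose,
    t_in = schedule$t_in %||% 0,
    t_out = schedule$t_out %||% Inf,
    Q = schedule$Q %||% 1,
    hill = schedule$hill %||% 1
  )
}

#' Deterministic exponential volume growth
#'
#' Updates cell volume over `dt` hours at the given growth rate:
#' `V <- V * exp(rate * dt)`.  Molecule counts are untouched.
#'
#' @param cells a cell tibble (one or more rows) with a `volume` column.
#' @param rate growth rate (1/h), e.g. from [growth_rate()].
#' @param dt time increment (h), `>= 0`.
#' @return The cell tibble with updated volumes.
#' @export
grow_volume <- function(cells, rate, dt) {
  if (!is.numeric(dt) || any(dt < 0)) stop("`dt` must be >= 0",
                                           call. = FALSE)
  cells$volume <- cells$volume * exp(rate * dt)
  cells
}

#' Draw a division-volume target from the noisy linear size map
#'
#' `V_F = a_map * V_I + b_map + eta1`, `eta1 ~ Normal(0, sigma1)`.  In
#' bounded mode the draw is confined to `params$vf_bounds` — the
#' distribution conditioned on landing inside the interval (sampled by
#' inverse CDF, which is exactly the resampling scheme whenever the
#' interval carries mass, and degrades gracefully to the nearest bound
#' when the map mean is many s.d. outside it).
#'
#' @param v_init initial (birth) volume(s), 1e-13 l.
#' @param params a [model_params()] object.
#' @param bounded confine the draw to `params$vf_bounds`?
#' @return Division volume(s), 1e-13 l.
#' @export
draw_vf_target <- function(v_init, params, bounded = TRUE) {
  stopifnot(inherits(params, "phenosel_params"))
  if (any(v_init <= 0)) stop("`v_init` must be > 0", call. = FALSE)
  m <- params$a_map * v_init + params$b_map
  s <- params$sigma1
  if (!bounded) {
    return(if (s > 0) stats::rnorm(length(m), m, s) else m)
  }
  lo <- params$vf_bounds[1]
  hi <- params$vf_bounds[2]
  if (s <= 0) return(pmin(pmax(m, lo), hi))
  plo <- stats::pnorm(lo, m, s)
  phi <- stats::pnorm(hi, m, s)
  degenerate <- (phi - plo) < 1e-12
  u <- plo + stats::runif(length(m)) * (phi - plo)
  out <- stats::qnorm(u, m, s)
  out[degenerate] <- ifelse(m[degenerate] < lo, lo, hi)
  out
}

#' Divide one cell into two daughters
#'
#' Draws the division fraction `eta2 ~ Normal(0.5, sigma2)` (redrawn
#' until inside (0,1)), gives the daughters volumes `V_F * eta2` and
#' `V_F * (1 - eta2)`, splits every molecular species
#' Binomial(n, eta2) to daughter 1 with the remainder to daughter 2,
#' and draws fresh division targets for both.  Each daughter inherits
#' one (undamaged-state-preserving) gene copy.
#'
#' @param parent a one-row cell tibble (must be alive).
#' @param params a [model_params()] object.
#' @param bounded_vf passed to [draw_vf_target()].
#' @param eta2 optional forced division fraction in (0, 1); by default
#'   drawn from the truncated Normal(0.5, sigma2).
#' @return A two-row cell tibble (daughter 1 first).
#' @export
divide_cell <- function(parent, params, bounded_vf = TRUE, eta2 = NULL) {
  stopifnot(inherits(params, "phenosel_params"), nrow(parent) == 1L)
  if (!isTRUE(parent$alive)) stop("parent must be alive", call. = FALSE)
  if (is.null(eta2)) {
    eta2 <- if (params$sigma2 > 0) {
      repeat {
        e <- stats::rnorm(1, 0.5, params$sigma2)
        if (e > 0 && e < 1) break
      }
      e
    } else 0.5
  } else if (!is.numeric(eta2) || eta2 <= 0 || eta2 >= 1) {
    stop("`eta2` must lie in (0, 1)", call. = FALSE)
  }
  VF <- parent$volume
  species <- setdiff(names(parent), c("volume", "vf_target", "alive"))
  split_cols <- setdiff(species, "dna_dam")
  d1 <- parent
  d2 <- parent
  for (cn in split_cols) {
    n1 <- stats::rbinom(1, size = parent[[cn]], prob = eta2)
    d1[[cn]] <- n1
    d2[[cn]] <- parent[[cn]] - n1
  }
  d1$volume <- VF * eta2
  d2$volume <- VF * (1 - eta2)
  d1$vf_target <- draw_vf_target(d1$volume, params, bounded = bounded_vf)
  d2$vf_target <- draw_vf_target(d2$volume, params, bounded = bounded_vf)
  dplyr::bind_rows(d1, d2)
}

#' Advance a population by one outer step
#'
#' Single-step version of [simulate_population()]: advances the cell
#' table from `t` to `t + outer_step` (reactions, death removal, growth,
#' division with slot replacement) and returns the updated table with
#' its new clock.
#'
#' @param cells a cell tibble (see [init_population()]).
#' @param t current simulation time (h).
#' @inheritParams simulate_population
#' @return A list with `cells` (updated tibble) and `t` (advanced
#'   clock).
#' @export
step_population <- function(cells, t, params, schedule,
                            engine = engine_config(), ...) {
  sim <- simulate_population(params, schedule,
                             t_end = t + engine$outer_step,
                             K = nrow(cells), engine = engine,
                             record_every = 1L, init = cells, t0 = t, ...)
  list(cells = sim$cells, t = t + engine$outer_step, sim = sim)
}

#' Fraction of live slots
#'
#' `N(t) = M(t) / K`, the viability bookkeeping of the constant-slot
#' population.  For a completed simulation this is the final recorded
#' value.
#'
#' @param x a `phenosel_sim` object or a cell tibble with an `alive`
#'   column.
#' @return A fraction in `[0, 1]`.
#' @export
viability <- function(x) {
  if (inherits(x, "phenosel_sim")) {
    return(x$series$N[nrow(x$series)])
  }
  if (is.data.frame(x) && "alive" %in% names(x)) {
    return(mean(x$alive))
  }
  stop("`x` must be a phenosel_sim or a cell table", call. = FALSE)
}

#' Viability recovery
#'
#' Post-nadir regrowth of the live fraction: `N(t_f) - min N(t)` over
#' the recorded series.
#'
#' @param x a `phenosel_sim` object or a numeric `N(t)` series.
#' @return The recovery (non-negative when the final point is the
#'   post-nadir state; 0 for monotone-decreasing or constant series).
#' @export
viability_recovery <- function(x) {
  n_series <- if (inherits(x, "phenosel_sim")) x$series$N else as.numeric(x)
  if (length(n_series) == 0) stop("empty series", call. = FALSE)
  n_series[length(n_series)] - min(n_series)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
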