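#' Cross-sectional summary statistics
#'
#' Mean, variance, noise and skewness of a per-cell sample.  Noise is
#' the squared coefficient of variation `var / mean^2`; skewness is the
#' third standardized moment `E[((X - mean)/sd)^3]`.  For a pure
#' birth-death (constitutively expressed mRNA) process the stationary
#' law is Poisson(lambda), giving the closed forms
#' `noise = 1/lambda` and `skewness = lambda^(-1/2)`.
#'
#' A constant sample has zero variance; its skewness is reported as 0 by
#' convention so sweep tables never carry indeterminate values.
#'
#' @param samples numeric vector of per-cell values (length >= 2).
#' @return A one-row tibble: `mean`, `variance`, `noise`, `skewness`.
#' @export
#' @examples
#' summary_stats(rpois(1e4, 10))
summary_stats <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("need at least 2 samples", call. = FALSE)
  m <- mean(samples)
  v <- stats::var(samples) * (length(samples) - 1) / length(samples)
  sk <- if (v > 0) mean(((samples - m) / sqrt(v))^3) else 0
  tibble::tibble(
    mean = m,
    variance = v,
    noise = if (m != 0) v / m^2 else NA_real_,
    skewness = sk
  )
}

#' Phenotypic selection ratio
#'
#' `<MGMT> / <REF>` over live cells: 1 means the protection protein and
#' the kinetically identical reference are expressed at similar levels;
#' ratios above 1 indicate selective upregulation of MGMT (phenotypic
#' selection through cell death, since the two genes share all rates).
#'
#' @param x a `phenosel_sim` (final recorded ratio), or a cell tibble
#'   with `mgmt`, `ref` and `alive` columns.
#' @return The ratio; `+Inf` when MGMT is present but mean REF is 0
#'   (unbounded upregulation), `NA` when there is no live cell or both
#'   means are 0.
#' @export
selection_ratio <- function(x) {
  if (inherits(x, "phenosel_sim")) {
    return(x$series$ratio[nrow(x$series)])
  }
  if (is.data.frame(x) && all(c("mgmt", "ref") %in% names(x))) {
    live <- if ("alive" %in% names(x)) x[x$alive, ] else x
    if (nrow(live) == 0) return(NA_real_)
    mr <- mean(live$ref)
    if (mr <= 0) {
      return(if (mean(live$mgmt) > 0) Inf else NA_real_)
    }
    return(mean(live$mgmt) / mr)
  }
  stop("`x` must be a phenosel_sim or a cell table", call. = FALSE)
}

#' mRNA noise sweep
#'
#' Probes how mRNA noise and skewness drive phenotypic selection.  For
#' each factor `f`, the transcription rate is divided by `f` and the
#' translation rate multiplied by `f`, which lowers the mean mRNA level
#' while holding the mean-field protein level fixed — so any change in
#' outcome is attributable to expression noise.  Division noise is
#' switched off (`sigma1 = sigma2 = 0`, exact halving at division, the
#' unbounded deterministic size map) to isolate the expression-noise
#' effect.  Each run uses the step regimen at the given dose with the
#' mRNA statistics taken cross-sectionally at `t_in` (end of the
#' dose-free burn-in) and the selection ratio and viability recovery at
#' the final time.
#'
#' @param params baseline parameters (the general best-fit set).
#' @param factors positive multipliers, e.g. `c(1, 4, 16, 64)`.
#' @param dose TMZ dose (uM); use 0 for the no-drug control sweep.
#' @param t_in dosing start (h).
#' @param t_end simulation end (h).
#' @param K slots per run.
#' @param engine an [engine_config()].
#' @return A tibble with one row per factor: `factor`, the birth-death
#'   closed forms `mrna_noise = 1/lambda` and
#'   `mrna_skewness = lambda^(-1/2)` at the mean-field mean
#'   `lambda = b1/f / (d + mu0)` (exact, and well-defined even when the
#'   mRNA level is too low for a stable cross-sectional estimate), the
#'   empirical snapshot statistics (`NA` when inestimable), `ratio`,
#'   `recovery` and `final_N`.
#' @details
#' The burst physics at high factors is a population-scale effect: the
#' population-wide transcription rate is `K * b1 / f`, so at strongly
#' reduced transcription the chance that *some* cell bursts (and then
#' repopulates) before the population dies scales with `K`.  Sweeps at
#' strongly reduced `K` therefore understate recovery at the highest
#' factors; keep `K` at a few thousand.
#' @export
noise_sweep <- function(params, factors = c(1, 4, 16, 64), dose = 800,
                        t_in = 144, t_end = 288, K = 2000,
                        engine = engine_config()) {
  stopifnot(inherits(params, "phenosel_params"))
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    stop("`factors` must be positive", call. = FALSE)
  }
  purrr::map_dfr(factors, function(f) {
    p <- params
    p$b1 <- params$b1 / f
    p$b2 <- params$b2 * f
    p$sigma1 <- 0
    p$sigma2 <- 0
    if (p$b1 * engine$outer_step > 100) {
      stop("factor ", f, " makes the transcription propensity pathological",
           call. = FALSE)
    }
    sched <- dose_schedule("step", dose = dose, t_in = t_in)
    sim <- simulate_population(p, sched, t_end = t_end, K = K,
                               engine = engine, bounded_vf = FALSE,
                               snapshot_t = t_in)
    snap <- sim$snapshot
    mrna <- c(snap$mrna_mgmt, snap$mrna_ref)  # two kinetically equal genes
    st <- summary_stats(mrna)
    lambda <- p$b1 / (p$d + p$mu0)
    tibble::tibble(
      factor = f,
      mrna_mean = lambda,
      mrna_noise = 1 / lambda,
      mrna_skewness = lambda^(-0.5),
      mrna_mean_obs = st$mean,
      mrna_noise_obs = st$noise,
      mrna_skewness_obs = if (st$variance > 0) st$skewness else NA_real_,
      ratio = selection_ratio(sim),
      recovery = viability_recovery(sim),
      final_N = viability(sim)
    )
  })
}
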