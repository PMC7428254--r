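#' Synthetic cell-growth assay
#'
#' Emulates the 6-day live-cell counting assay: cells seeded at `n0`
#' grow exponentially at `mu_true`, counted at each time in triplicate
#' with multiplicative Gaussian measurement noise (relative s.d. `cv`,
#' redrawn in the vanishingly rare case a count would be non-positive).
#'
#' @param mu_true true growth rate (1/h); default the fitted
#'   patient-derived-line value 0.01388 (doubling time ~49.9 h).
#' @param n0 seeded cells per well (default 8e4).
#' @param cv relative measurement noise (default 0.05).
#' @param times count times (h); default daily over 144 h.
#' @param replicates wells per time point.
#' @return A growth table: `time_h`, `rep1..repN`.
#' @export
#' @examples
#' synth_growth(cv = 0)  # exact exponential table
synth_growth <- function(mu_true = 0.01388, n0 = 8e4, cv = 0.05,
                         times = seq(0, 144, by = 24), replicates = 3) {
  if (!is.finite(mu_true) || mu_true <= 0) {
    stop("`mu_true` must be > 0", call. = FALSE)
  }
  if (cv < 0) stop("`cv` must be >= 0", call. = FALSE)
  clean <- n0 * exp(mu_true * times)
  out <- tibble::tibble(time_h = times)
  for (r in seq_len(replicates)) {
    v <- clean * (1 + stats::rnorm(length(times), 0, cv))
    while (any(v <= 0)) {
      bad <- v <= 0
      v[bad] <- clean[bad] * (1 + stats::rnorm(sum(bad), 0, cv))
    }
    out[[paste0("rep", r)]] <- v
  }
  attr(out, "manifest") <- list(mu_true = mu_true, n0 = n0, cv = cv,
                                replicates = replicates)
  out
}

#' Synthetic cell-viability assay
#'
#' Emulates the WST-1 dose-response assay with the model itself as the
#' generator: for each dose the data-constrained model (reduced
#' network, basal death included, sigmoidal TMZ uptake) is simulated
#' and the live fraction at the assay times is expressed as percent of
#' the dose-0 control run; replicates add multiplicative Gaussian
#' measurement noise (`meas_cv`), truncated at 0.  Finite-`K_sim`
#' sampling error is part of the effective measurement noise.
#'
#' @param theta_true generating parameters (a [model_params()]
#'   object); default [params_constrained()].
#' @param doses TMZ panel (uM), must include 0.
#' @param times assay times (h).
#' @param replicates technical replicates per condition.
#' @param meas_cv relative measurement noise (default 0.05).
#' @param K_sim slots per generating run (default 1000).
#' @param engine an [engine_config()].
#' @param Q,hill sigmoid uptake parameters.
#' @return A viability table: `dose_uM`, `time_h`, `rep1..repN`, with a
#'   `"manifest"` attribute recording the generator settings.
#' @export
synth_viability <- function(theta_true = params_constrained(),
                            doses = c(0, 75, 150, 300, 600, 800),
                            times = c(72, 96, 120, 144),
                            replicates = 3, meas_cv = 0.05,
                            K_sim = 1000, engine = engine_config(),
                            Q = 77.6434, hill = 9.5362) {
  stopifnot(inherits(theta_true, "phenosel_params"))
  if (!0 %in% doses) stop("`doses` must include the 0 control",
                          call. = FALSE)
  t_end <- max(times)
  sims <- purrr::map(doses, function(dd) {
    simulate_population(theta_true,
                        dose_schedule("sigmoid", dose = dd, Q = Q,
                                      hill = hill),
                        t_end = t_end, K = K_sim, engine = engine,
                        include_basal = TRUE)
  })
  names(sims) <- as.character(doses)
  out <- purrr::map_dfr(as.character(doses), function(dd) {
    pct <- sim_viability_pct(sims[[dd]], sims[["0"]], times)
    row <- tibble::tibble(dose_uM = as.numeric(dd), time_h = times)
    for (r in seq_len(replicates)) {
      row[[paste0("rep", r)]] <-
        pmax(pct * (1 + stats::rnorm(length(times), 0, meas_cv)), 0)
    }
    row
  })
  attr(out, "manifest") <- list(
    theta = unclass(theta_true), doses = doses, times = times,
    replicates = replicates, meas_cv = meas_cv, K_sim = K_sim,
    Q = Q, hill = hill, engine = unclass(engine)
  )
  out
}
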