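#' TMZ-dependent growth rate
#'
#' Per-cell exponential growth rate.  Before dosing begins the rate is
#' the baseline `mu0`; once dosing is active TMZ inhibits growth
#' hyperbolically, `f1 = mu0 / (1 + tmz / I50)`.
#'
#' @param params a [model_params()] object.
#' @param tmz intracellular TMZ concentration (uM), vectorised.
#' @param dosing_active logical; whether the dosing switch has turned on
#'   (growth inhibition applies only from administration onwards).
#' @return Growth rate(s) in 1/h, in `(0, mu0]`.
#' @export
#' @examples
#' growth_rate(params_general(), tmz = 800, dosing_active = FALSE)
#' growth_rate(params_general(I50 = 0.0013), tmz = 800, dosing_active = TRUE)
growth_rate <- function(params, tmz, dosing_active = TRUE) {
  stopifnot(inherits(params, "phenosel_params"))
  if (!is.numeric(tmz) || any(!is.finite(tmz)) || any(tmz < 0)) {
    stop("`tmz` must be finite and >= 0", call. = FALSE)
  }
  if (!dosing_active) {
    return(rep_len(params$mu0, length(tmz)))
  }
  params$mu0 / (1 + tmz / params$I50)
}

#' TMZ- and MGMT-dependent cell death rate
#'
#' Death rate under the pseudo-steady-state reduction of the DNA
#' damage/repair cycle:
#' `f2 = kd2 * kd * tmz / (kd * tmz + s * mgmt)`.
#' High MGMT shields the cell (repair outcompetes damage); at `mgmt = 0`
#' the rate saturates at `kd2`.  With `include_basal = TRUE` the basal
#' death rate `eps` is added (the death channel of the data-constrained
#' model); the general model uses the bare `f2`.
#'
#' The `tmz = 0, mgmt = 0` indeterminacy is defined as 0: with no
#' alkylating agent there is no damage source.
#'
#' @inheritParams growth_rate
#' @param mgmt MGMT molecule count(s), vectorised with `tmz`.
#' @param include_basal add the basal death rate `eps`?
#' @return Death rate(s) in 1/h; `f2` lies in `[0, kd2]`.
#' @export
#' @examples
#' death_rate(params_general(), mgmt = 100, tmz = 800)
death_rate <- function(params, mgmt, tmz, include_basal = FALSE) {
  f2 <- params$kd2 * dna_dam_pss(params, mgmt, tmz)
  if (include_basal) f2 + params$eps else f2
}

#' Pseudo-steady-state damaged-DNA fraction
#'
#' Fraction of time the (single-copy) gene locus carries unrepaired TMZ
#' alkylation damage, under the fast damage/repair equilibrium:
#' `kd * tmz / (kd * tmz + s * mgmt)`.  Equals `death_rate() / kd2`
#' (without the basal term).
#'
#' @inheritParams death_rate
#' @return Damaged fraction(s) in `[0, 1]`.
#' @export
dna_dam_pss <- function(params, mgmt, tmz) {
  stopifnot(inherits(params, "phenosel_params"))
  if (!is.numeric(tmz) || any(!is.finite(tmz)) || any(tmz < 0)) {
    stop("`tmz` must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(mgmt) || any(!is.finite(mgmt)) || any(mgmt < 0)) {
    stop("`mgmt` must be finite and >= 0", call. = FALSE)
  }
  num <- params$kd * tmz
  den <- num + params$s * mgmt
  out <- ifelse(den > 0, num / den, 0)
  as.numeric(out)
}
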