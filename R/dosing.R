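#' TMZ dosing schedule
#'
#' Describes how the intracellular TMZ concentration depends on time.
#' Three regimens are supported:
#'
#' * `"step"` — instant submersion: 0 for `t <= t_in`, `dose` after
#'   (fast uptake).
#' * `"pulse"` — transient dosing: `dose` on `(t_in, t_out]`, 0 outside.
#' * `"sigmoid"` — slow saturating uptake from the medium,
#'   `dose * t^hill / (Q^hill + t^hill)`, applied from `t = 0` of the
#'   assay clock (calibration experiments begin dosing at seeding).
#'
#' TMZ is neither degraded nor diluted.
#'
#' @param kind one of `"step"`, `"pulse"`, `"sigmoid"`.
#' @param dose TMZ concentration in the medium (uM).
#' @param t_in administration start (h; step/pulse).
#' @param t_out administration end (h; pulse only, must exceed `t_in`).
#' @param Q half-uptake time (h; sigmoid only).
#' @param hill Hill coefficient controlling uptake sharpness (sigmoid).
#' @return An object of class `phenosel_schedule`.
#' @export
#' @examples
#' sched <- dose_schedule("step", dose = 800, t_in = 144)
#' tmz_at(sched, c(100, 144, 144.1))
dose_schedule <- function(kind = c("step", "pulse", "sigmoid"),
                          dose = 800, t_in = 144, t_out = NULL,
                          Q = 77.6434, hill = 9.5362) {
  kind <- match.arg(kind)
  if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) || dose < 0) {
    stop("`dose` must be a single finite number >= 0", call. = FALSE)
  }
  if (kind == "pulse") {
    if (is.null(t_out) || !is.finite(t_out) || t_out <= t_in) {
      stop("pulse schedule needs `t_out` > `t_in`", call. = FALSE)
    }
  }
  if (kind == "sigmoid" && (Q <= 0 || hill <= 0)) {
    stop("sigmoid schedule needs `Q` > 0 and `hill` > 0", call. = FALSE)
  }
  structure(
    list(kind = kind, dose = dose, t_in = t_in, t_out = t_out,
         Q = Q, hill = hill),
    class = "phenosel_schedule"
  )
}

#' @export
print.phenosel_schedule <- function(x, ...) {
  cat("<phenosel_schedule> ", x$kind, ", dose ", x$dose, " uM", sep = "")
  if (x$kind == "step") cat(", t_in ", x$t_in, " h", sep = "")
  if (x$kind == "pulse") {
    cat(", (t_in, t_out] = (", x$t_in, ", ", x$t_out, "] h", sep = "")
  }
  if (x$kind == "sigmoid") {
    cat(", Q ", x$Q, " h, hill ", x$hill, sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Intracellular TMZ concentration at time t
#'
#' Evaluates the uptake function of a [dose_schedule()].  Piecewise
#' constant for step/pulse (open at `t_in`, closed at `t_out`), monotone
#' non-decreasing and bounded by `dose` for the sigmoid.
#'
#' @param schedule a [dose_schedule()].
#' @param t time(s) in hours, `t >= 0`.
#' @return TMZ concentration(s) in uM.
#' @export
tmz_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "phenosel_schedule"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and >= 0", call. = FALSE)
  }
  switch(schedule$kind,
    step = ifelse(t > schedule$t_in, schedule$dose, 0),
    pulse = ifelse(t > schedule$t_in & t <= schedule$t_out,
                   schedule$dose, 0),
    sigmoid = {
      th <- t^schedule$hill
      ifelse(t > 0, schedule$dose * th / (schedule$Q^schedule$hill + th), 0)
    }
  )
}
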