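#' Prior specification for ABC
#'
#' One row per free parameter: a box `(lower, upper)` sampled uniformly
#' on the `linear` or the `log` scale.  Log-scale priors require
#' `lower > 0`.
#'
#' @param name parameter names (character).
#' @param lower,upper box bounds.
#' @param scale `"linear"` or `"log"`, recycled.
#' @return A `phenosel_priors` tibble.
#' @seealso [priors_general()], [priors_constrained()] for the two
#'   published prior boxes.
#' @export
prior_spec <- function(name, lower, upper, scale = "linear") {
  out <- tibble::tibble(name = as.character(name), lower = lower,
                        upper = upper,
                        scale = rep_len(scale, length(name)))
  if (!all(out$scale %in% c("linear", "log"))) {
    stop("`scale` must be \"linear\" or \"log\"", call. = FALSE)
  }
  if (any(out$lower >= out$upper)) {
    stop("priors need `lower` < `upper`", call. = FALSE)
  }
  if (any(out$scale == "log" & out$lower <= 0)) {
    stop("log-scale priors need `lower` > 0", call. = FALSE)
  }
  class(out) <- c("phenosel_priors", class(out))
  out
}

#' Published prior boxes
#'
#' `priors_general()` returns the wide exponential-notation prior box of
#' the general model, sampled log-uniformly (the `e^-10 .. e^10` style
#' bounds only make sense on the log scale).  `priors_constrained()`
#' returns the modest linear-scale box of the data-constrained model
#' (`mu0` is fixed from the growth fit and is not in the box).
#'
#' @return A `phenosel_priors` tibble.
#' @export
priors_general <- function() {
  prior_spec(
    name = c("mu0", "b1", "d", "s", "I50", "b2", "kd"),
    lower = exp(-10),
    upper = c(exp(1), exp(1), 1, exp(10), exp(10), exp(10), exp(10)),
    scale = "log"
  )
}

#' @rdname priors_general
#' @export
priors_constrained <- function() {
  prior_spec(
    name = c("b1", "d", "s", "I50", "b2", "eps", "kd"),
    lower = 0,
    upper = c(1, 0.1, 100, 1, 100, 0.1, 10),
    scale = "linear"
  )
}

#' Draw parameter vectors from a prior box
#'
#' @param priors a [prior_spec()] tibble.
#' @param n number of draws.
#' @return A tibble with one column per parameter.
#' @export
sample_priors <- function(priors, n) {
  draws <- purrr::pmap(priors, function(name, lower, upper, scale) {
    if (scale == "log") {
      exp(stats::runif(n, log(lower), log(upper)))
    } else {
      stats::runif(n, lower, upper)
    }
  })
  names(draws) <- priors$name
  tibble::as_tibble(draws)
}

#' Rejection ABC
#'
#' Likelihood-free inference: propose `budget` parameter vectors from
#' the prior box, score each with a user loss, and retain the `keep`
#' best.  Multi-error losses are combined by min-max normalizing each
#' error across the proposals and summing (no acceptance thresholds are
#' assumed); `keep` then acts as a top-n rule.  A proposal whose loss
#' errors out or is non-finite scores `+Inf` and never crashes the
#' sweep.
#'
#' @param priors a [prior_spec()] tibble.
#' @param loss_fn function taking a named list of parameter values and
#'   returning a named numeric vector of one or more error values
#'   (smaller is better).
#' @param budget number of proposals (`>= keep`).
#' @param keep number of accepted draws (the posterior sample size).
#' @return A `phenosel_abc` object: `accepted` (tibble of kept draws
#'   with their errors and combined `score`), `proposals` (all draws),
#'   `priors`, and bookkeeping.  [tidy()] returns the accepted draws,
#'   [glance()] a one-row summary; see also [posterior_mode()],
#'   [posterior_correlations()], [posterior_sensitivity()].
#' @export
#' @examples
#' pr <- prior_spec("theta", 0, 1)
#' post <- abc_rejection(pr, function(th) c(err = abs(th$theta - 0.3)),
#'                       budget = 200, keep = 20)
#' posterior_mode(post)
abc_rejection <- function(priors, loss_fn, budget, keep) {
  stopifnot(inherits(priors, "phenosel_priors"))
  budget <- as.integer(budget)
  keep <- as.integer(keep)
  if (budget < keep) stop("`budget` must be >= `keep`", call. = FALSE)
  proposals <- sample_priors(priors, budget)
  errs <- purrr::map(seq_len(budget), function(i) {
    th <- as.list(proposals[i, ])
    e <- tryCatch(loss_fn(th), error = function(cnd) NA_real_)
    if (!is.numeric(e) || length(e) < 1L) e <- NA_real_
    e
  })
  n_err <- max(purrr::map_int(errs, length))
  err_names <- names(errs[[which.max(purrr::map_int(errs, length))]])
  if (is.null(err_names)) err_names <- paste0("error_", seq_len(n_err))
  em <- vapply(errs, function(e) {
    out <- rep(Inf, n_err)
    e[!is.finite(e)] <- Inf
    out[seq_along(e)] <- e
    out
  }, numeric(n_err))
  err_mat <- if (n_err == 1L) matrix(em, ncol = 1L) else t(em)
  colnames(err_mat) <- err_names

  # min-max normalize each error over the finite proposals, then sum
  norm <- apply(err_mat, 2, function(v) {
    f <- is.finite(v)
    if (!any(f)) return(rep(Inf, length(v)))
    r <- range(v[f])
    if (r[2] > r[1]) (v - r[1]) / (r[2] - r[1]) else ifelse(f, 0, Inf)
  })
  norm <- matrix(norm, nrow = budget)
  score <- rowSums(norm)

  draws <- dplyr::bind_cols(proposals, tibble::as_tibble(err_mat),
                            tibble::tibble(score = score))
  ord <- order(score)
  accepted <- draws[ord[seq_len(keep)], ]
  structure(
    list(accepted = accepted, proposals = draws, priors = priors,
         budget = budget, keep = keep, error_names = err_names),
    class = "phenosel_abc"
  )
}

#' @export
print.phenosel_abc <- function(x, ...) {
  cat("<phenosel_abc> ", x$keep, " draws kept of ", x$budget,
      " proposals; errors: ", paste(x$error_names, collapse = ", "),
      "\n", sep = "")
  print(posterior_mode(x))
  invisible(x)
}

#' @export
tidy.phenosel_abc <- function(x, ...) x$accepted

#' @export
glance.phenosel_abc <- function(x, ...) {
  tibble::tibble(
    n_proposed = x$budget,
    n_kept = x$keep,
    best_score = min(x$accepted$score),
    worst_kept_score = max(x$accepted$score),
    n_failed = sum(!is.finite(x$proposals$score))
  )
}

#' Posterior mode (best fit)
#'
#' The single best-scoring accepted draw — the "mode" in the top-n
#' rejection sense.
#'
#' @param post a `phenosel_abc` object.
#' @return A one-row tibble of parameter values (error columns dropped).
#' @export
posterior_mode <- function(post) {
  stopifnot(inherits(post, "phenosel_abc"))
  if (nrow(post$accepted) == 0) stop("empty posterior", call. = FALSE)
  best <- post$accepted[which.min(post$accepted$score), ]
  best[, post$priors$name]
}

#' Pairwise posterior correlations
#'
#' Correlations between parameters over the accepted draws, computed on
#' the sampling scale (log where the prior is log-uniform).  A parameter
#' with zero variance gets correlation 0 by convention.
#'
#' @param post a `phenosel_abc` object.
#' @return A tibble `param1`, `param2`, `correlation` (each unordered
#'   pair once), with the full matrix as attribute `"matrix"`.
#' @export
posterior_correlations <- function(post) {
  x <- posterior_scaled(post)
  if (nrow(x) < 3) stop("need >= 3 accepted draws", call. = FALSE)
  cm <- suppressWarnings(stats::cor(x))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 1
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  out <- tibble::tibble(
    param1 = rownames(cm)[pairs[, 1]],
    param2 = colnames(cm)[pairs[, 2]],
    correlation = cm[pairs]
  )
  attr(out, "matrix") <- cm
  out
}

#' Posterior precision (sensitivity) per parameter
#'
#' Inverts the covariance matrix of the accepted draws (on the sampling
#' scale); the diagonal of the precision matrix ranks parameters by how
#' tightly the fit constrains them — large precision means the model
#' output is sensitive to that parameter.  A singular covariance is
#' ridge-regularized (flagged in the output).
#'
#' @param post a `phenosel_abc` object.
#' @return A tibble `parameter`, `precision`, `regularized`.
#' @export
posterior_sensitivity <- function(post) {
  x <- posterior_scaled(post)
  cv <- stats::cov(x)
  regularized <- FALSE
  prec <- tryCatch(solve(cv), error = function(cnd) NULL)
  if (is.null(prec) || !all(is.finite(prec))) {
    regularized <- TRUE
    ridge <- diag(ncol(cv)) * max(mean(diag(cv)), .Machine$double.eps) * 1e-8
    prec <- solve(cv + ridge)
  }
  tibble::tibble(
    parameter = colnames(x),
    precision = diag(prec),
    regularized = regularized
  )
}

# accepted draws on the sampling scale (log where the prior is log)
posterior_scaled <- function(post) {
  stopifnot(inherits(post, "phenosel_abc"))
  x <- as.matrix(post$accepted[, post$priors$name])
  logs <- post$priors$scale == "log"
  x[, logs] <- log(x[, logs])
  colnames(x) <- ifelse(logs, paste0("log_", post$priors$name),
                        post$priors$name)
  x
}

#' Calibration error functions
#'
#' The three errors that, minimized together, produce MGMT-mediated
#' resistance consistent with the viability assay:
#'
#' * `E1 = <REF> / <MGMT>` over live cells at the final time — small
#'   when MGMT is selectively upregulated.
#' * `E2 = |1 - N(t_f)|` — small when the population stays viable.
#' * `E3` — mean square error between the simulated viability (percent
#'   of the dose-0 control run) and the replicate-mean assay values at
#'   the assay time points, summed over the 0 and 800 uM conditions.
#'
#' @param sims a single `phenosel_sim` (E1/E2 only) or a list of runs
#'   named by dose (`"0"`, `"800"`, ...); E1/E2 are evaluated on the
#'   highest-dose run, E3 needs at least the `"0"` and `"800"` entries.
#' @param data a viability table (`dose_uM`, `time_h`, `rep*` columns);
#'   required for E3.
#' @param which subset of `c("E1", "E2", "E3")`.
#' @return Named numeric vector of the requested errors.  `E1` is
#'   `+Inf` when mean MGMT is 0 (worst score).
#' @export
compute_errors <- function(sims, data = NULL,
                           which = c("E1", "E2", "E3")) {
  which <- match.arg(which, several.ok = TRUE)
  if (inherits(sims, "phenosel_sim")) {
    sim_list <- list(sims)
    names(sim_list) <- "treated"
    treated <- sims
  } else {
    sim_list <- sims
    stopifnot(length(sim_list) > 0,
              all(purrr::map_lgl(sim_list, inherits, "phenosel_sim")))
    treated <- sim_list[[which.max(as.numeric(names(sim_list)))]]
  }
  out <- c()
  last <- function(v) v[length(v)]
  if ("E1" %in% which) {
    s <- treated$series
    mgmt <- last(s$mean_mgmt)
    ref <- last(s$mean_ref)
    e1 <- if (!is.finite(mgmt) || mgmt <= 0) Inf else ref / mgmt
    out <- c(out, E1 = e1)
  }
  if ("E2" %in% which) {
    out <- c(out, E2 = abs(1 - last(treated$series$N)))
  }
  if ("E3" %in% which) {
    if (is.null(data)) stop("E3 needs a viability table", call. = FALSE)
    if (!all(c("0", "800") %in% names(sim_list))) {
      stop("E3 needs simulations for doses 0 and 800", call. = FALSE)
    }
    means <- viability_means(data)
    sq <- purrr::map_dbl(c(0, 800), function(dd) {
      dm <- means[means$dose_uM == dd, ]
      sim_pct <- sim_viability_pct(sim_list[[as.character(dd)]],
                                   sim_list[["0"]], dm$time_h)
      mean((sim_pct - dm$mean_pct)^2)
    })
    out <- c(out, E3 = sum(sq))
  }
  out
}

# simulated viability as percent of the dose-0 control run, interpolated
# at the assay time points
sim_viability_pct <- function(sim, control, times) {
  n_trt <- stats::approx(sim$series$t, sim$series$N, xout = times)$y
  n_ctl <- stats::approx(control$series$t, control$series$N, xout = times)$y
  ifelse(n_ctl > 0, 100 * n_trt / n_ctl, 0)
}

# replicate means of a wide viability table
viability_means <- function(data) {
  check_viability(data)
  reps <- grep("^rep", names(data), value = TRUE)
  data$mean_pct <- rowMeans(data[reps])
  data[, c("dose_uM", "time_h", "mean_pct")]
}

check_viability <- function(data) {
  need <- c("dose_uM", "time_h")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    stop("viability table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!any(grepl("^rep", names(data)))) {
    stop("viability table needs rep1..repN columns", call. = FALSE)
  }
  if (!0 %in% data$dose_uM) {
    stop("viability table must include the dose-0 control", call. = FALSE)
  }
  invisible(data)
}

check_growth <- function(data) {
  if (!"time_h" %in% names(data)) {
    stop("growth table lacks column: time_h", call. = FALSE)
  }
  if (!any(grepl("^rep", names(data)))) {
    stop("growth table needs rep1..repN columns", call. = FALSE)
  }
  reps <- grep("^rep", names(data), value = TRUE)
  if (any(as.matrix(data[reps]) <= 0)) {
    stop("growth counts must be > 0", call. = FALSE)
  }
  invisible(data)
}

#' Calibrate the model to a viability assay
#'
#' Rejection ABC over the data-constrained prior box with the combined
#' `E1 + E2 + E3` loss: each proposal simulates the reduced model
#' (basal death included, sigmoidal TMZ uptake) at doses 0 and 800 uM
#' and is scored against the assay table.  Inference runs use a reduced
#' slot count and the tau-leap engine with SSA fallback for speed.
#'
#' @param data viability table (`dose_uM`, `time_h`, `rep*`), percent
#'   survival relative to control.
#' @param mu0 growth rate fixed from the growth-curve fit (1/h).
#' @param priors prior box (default [priors_constrained()]).
#' @param budget,keep ABC proposal and acceptance counts.
#' @param K slots per inference simulation (default 500).
#' @param engine an [engine_config()].
#' @param Q,hill sigmoid uptake parameters (h, dimensionless).
#' @param errors which error functions to combine.
#' @return A `phenosel_abc` object.
#' @export
calibrate_viability <- function(data, mu0 = 0.01388,
                                priors = priors_constrained(),
                                budget = 200, keep = 50, K = 500,
                                engine = engine_config(),
                                Q = 77.6434, hill = 9.5362,
                                errors = c("E1", "E2", "E3")) {
  check_viability(data)
  t_end <- max(data$time_h)
  loss_fn <- function(th) {
    p <- rlang::exec(model_params, mu0 = mu0, !!!th, K = as.integer(K))
    sims <- purrr::map(c("0" = 0, "800" = 800), function(dd) {
      simulate_population(p, dose_schedule("sigmoid", dose = dd,
                                           Q = Q, hill = hill),
                          t_end = t_end, K = K, engine = engine,
                          include_basal = TRUE)
    })
    compute_errors(sims, data = data, which = errors)
  }
  abc_rejection(priors, loss_fn, budget = budget, keep = keep)
}

#' Fit the cell growth curve
#'
#' ABC fit of exponential (`N0 * exp(mu t)`) versus logistic
#' (`Kc N0 e^{mu t} / (Kc + N0 (e^{mu t} - 1))`) growth with Bayesian
#' model comparison: both models are proposed with equal budget, scored
#' by the mean square error over *all replicate points* (not the
#' replicate means, so the data's variability enters the fit), and the
#' posterior model probability is each model's share of the pooled
#' top-`keep` draws.
#'
#' @param data growth table (`time_h`, `rep*` columns; live-cell
#'   counts including the seeding time).
#' @param budget proposals per model.
#' @param keep pooled acceptance count.
#' @param mu_max upper bound of the uniform growth-rate prior (1/h).
#' @return A `phenosel_growth_fit`: best-fit `mu`, `doubling_time =
#'   ln 2 / mu`, `model_probs`, and the accepted draws.  [glance()]
#'   gives the one-row summary.
#' @export
#' @examples
#' g <- synth_growth(cv = 0.02)
#' fit <- fit_growth(g, budget = 1000)
#' glance(fit)
fit_growth <- function(data, budget = 4000, keep = 100, mu_max = 0.1) {
  check_growth(data)
  reps <- grep("^rep", names(data), value = TRUE)
  y <- as.matrix(data[reps])
  tt <- data$time_h
  y0 <- mean(y[which.min(tt), ])
  ymax <- max(y)

  mse <- function(pred) mean((y - pred)^2)  # recycles pred over replicates
  exp_curve <- function(mu, N0) N0 * exp(mu * tt)
  logi_curve <- function(mu, N0, Kc) {
    Kc * N0 * exp(mu * tt) / (Kc + N0 * (exp(mu * tt) - 1))
  }

  n <- as.integer(budget)
  prop <- tibble::tibble(
    model = rep(c("exponential", "logistic"), each = n),
    mu = stats::runif(2 * n, 0, mu_max),
    N0 = stats::runif(2 * n, 0.5 * y0, 2 * y0),
    Kc = exp(stats::runif(2 * n, log(ymax), log(1000 * ymax)))
  )
  prop$mse <- purrr::pmap_dbl(prop, function(model, mu, N0, Kc, ...) {
    if (model == "exponential") mse(exp_curve(mu, N0))
    else mse(logi_curve(mu, N0, Kc))
  })
  accepted <- prop[order(prop$mse)[seq_len(keep)], ]
  probs <- c(
    exponential = mean(accepted$model == "exponential"),
    logistic = mean(accepted$model == "logistic")
  )
  best <- accepted[1, ]
  structure(
    list(mu = best$mu, N0 = best$N0, best_model = best$model,
         doubling_time = log(2) / best$mu, model_probs = probs,
         accepted = accepted, data = data, budget = budget, keep = keep),
    class = "phenosel_growth_fit"
  )
}

#' @export
print.phenosel_growth_fit <- function(x, ...) {
  cat("<phenosel_growth_fit> best model: ", x$best_model,
      sprintf(" (p_exp = %.2f)", x$model_probs[["exponential"]]),
      "\n  mu = ", signif(x$mu, 4), " /h, doubling time ",
      signif(x$doubling_time, 5), " h\n", sep = "")
  invisible(x)
}

#' @export
tidy.phenosel_growth_fit <- function(x, ...) x$accepted

#' @export
glance.phenosel_growth_fit <- function(x, ...) {
  tibble::tibble(
    mu = x$mu,
    doubling_time = x$doubling_time,
    p_exponential = x$model_probs[["exponential"]],
    p_logistic = x$model_probs[["logistic"]],
    best_mse = min(x$accepted$mse),
    best_model = x$best_model
  )
}

#' Predict viability and selection for a dose panel
#'
#' Simulates the calibrated (data-constrained) model at each dose with
#' sigmoidal uptake and reports percent survival relative to the dose-0
#' control run, plus the selection ratio, at the requested times.
#'
#' @param params a [model_params()] object (the posterior mode).
#' @param doses TMZ doses (uM); 0 is always simulated as the control.
#' @param times report times (h).
#' @param K slots per run.
#' @param engine an [engine_config()].
#' @param Q,hill sigmoid uptake parameters.
#' @return A tibble `dose_uM`, `time_h`, `pct_survival`, `ratio`.
#' @export
predict_viability <- function(params, doses = c(75, 150, 300, 600),
                              times = c(72, 96, 120, 144), K = 500,
                              engine = engine_config(),
                              Q = 77.6434, hill = 9.5362) {
  stopifnot(inherits(params, "phenosel_params"))
  t_end <- max(times)
  all_doses <- union(0, doses)
  sims <- purrr::map(all_doses, function(dd) {
    simulate_population(params,
                        dose_schedule("sigmoid", dose = dd, Q = Q,
                                      hill = hill),
                        t_end = t_end, K = K, engine = engine,
                        include_basal = TRUE)
  })
  names(sims) <- as.character(all_doses)
  purrr::map_dfr(as.character(doses), function(dd) {
    sim <- sims[[dd]]
    tibble::tibble(
      dose_uM = as.numeric(dd),
      time_h = times,
      pct_survival = sim_viability_pct(sim, sims[["0"]], times),
      ratio = stats::approx(sim$series$t, sim$series$ratio,
                            xout = times)$y
    )
  })
}
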