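#' Read / write the package's delimited-text layouts
#'
#' All datasets travel as delimited text with a header row (comma by
#' default; tab for `.tsv`/`.txt`).  Layouts:
#'
#' * `growth` — `time_h`, `rep1..repN` (live-cell counts, > 0,
#'   including the seeding time).
#' * `viability` — `dose_uM`, `time_h`, `rep1..repN` (% survival
#'   relative to control; the dose-0 control must be present).
#' * `timeseries` — a simulation series (`t`, `M`, `N`, per-species
#'   means, `ratio`).
#' * `posterior` — accepted ABC draws (parameters + errors + score).
#'
#' Reading validates the layout and names any missing column.  The
#' deposited spreadsheets behind the growth/viability assays must be
#' exported to delimited text first; no spreadsheet reader is available
#' here.  Writing then reading reproduces values to full precision.
#'
#' @param path file path; delimiter chosen from the extension.
#' @param layout one of `"growth"`, `"viability"`, `"timeseries"`,
#'   `"posterior"`.
#' @return `read_assay_table()`: a tibble.  `write_assay_table()`: the
#'   input, invisibly.
#' @export
read_assay_table <- function(path,
                             layout = c("growth", "viability",
                                        "timeseries", "posterior")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  delim <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  switch(layout,
    growth = check_growth(x),
    viability = check_viability(x),
    timeseries = {
      missing <- setdiff(c("t", "N"), names(x))
      if (length(missing) > 0) {
        stop("timeseries table lacks column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
    },
    posterior = {
      if (!"score" %in% names(x)) {
        stop("posterior table lacks column: score", call. = FALSE)
      }
    }
  )
  x
}

#' @rdname read_assay_table
#' @param x the tibble to write.
#' @export
write_assay_table <- function(x, path,
                              layout = c("growth", "viability",
                                         "timeseries", "posterior")) {
  layout <- match.arg(layout)
  delim <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  readr::write_delim(x, path, delim = delim)
  invisible(x)
}

#' Read a run configuration
#'
#' A single JSON file mirrors the package's objects: a `params` section
#' (flat key -> value entries named as the model symbols: `mu0`, `b1`,
#' `d`, `b2`, `s`, `I50`, `kd`, `kd2`, `eps`, `sigma1`, `sigma2`, `a`,
#' `b`, `V_I`, `K`, `d2`), a `schedule` section (`kind` plus the
#' relevant fields), an `engine` section (`method`, `outer_step`,
#' `n_sub`), and a `run` section (`t_end`, `K`, `seed`, `variant`,
#' `replacement`, `record_every`).  Omitted entries fall back to the
#' defaults of the corresponding constructor.
#'
#' @param path path to the JSON config.
#' @return A list with elements `params` ([model_params()]),
#'   `schedule` ([dose_schedule()]), `engine` ([engine_config()]) and
#'   `run` (list).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path,
                               call. = FALSE)
  cfg <- jsonlite::fromJSON(path)
  pp <- cfg$params %||% list()
  # table symbols a/b map to the size-map slope/intercept
  if (!is.null(pp$a)) { pp$a_map <- pp$a; pp$a <- NULL }
  if (!is.null(pp$b)) { pp$b_map <- pp$b; pp$b <- NULL }
  params <- rlang::exec(model_params, !!!pp)
  sc <- cfg$schedule %||% list(kind = "step")
  schedule <- rlang::exec(dose_schedule, !!!sc)
  en <- cfg$engine %||% list()
  engine <- rlang::exec(engine_config, !!!en)
  run <- cfg$run %||% list()
  list(params = params, schedule = schedule, engine = engine, run = run,
       raw = cfg)
}

run_log <- function(outdir, seed, cfg_hash) {
  msg <- sprintf("phenosel %s | seed %s | config %s",
                 as.character(utils::packageVersion("phenosel")),
                 seed, cfg_hash)
  message(msg)
  writeLines(msg, file.path(outdir, "run_log.txt"))
}

#' Run one population simulation from a config file
#'
#' Reads the config, seeds the RNG, simulates, and writes
#' `timeseries.csv` plus `summary.json` (final viability, selection
#' ratio, viability recovery, seed, config hash) into `outdir`.
#'
#' @param config path to a JSON config ([read_config()]).
#' @param outdir output directory (created if needed).
#' @param dose,seed,K,engine optional overrides of the config values.
#' @return `outdir`, invisibly.
#' @export
cmd_simulate <- function(config, outdir = "phenosel_run", dose = NULL,
                         seed = NULL, K = NULL, engine = NULL) {
  cfg <- read_config(config)
  if (!is.null(dose)) cfg$schedule$dose <- dose
  if (!is.null(K)) cfg$run$K <- K
  if (!is.null(engine)) cfg$engine$method <- match.arg(engine,
                                                       c("tauleap", "ssa"))
  seed <- seed %||% cfg$run$seed %||% 1L
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  run_log(outdir, seed, rlang::hash(cfg$raw))
  set.seed(seed)
  sim <- simulate_population(
    cfg$params, cfg$schedule,
    t_end = cfg$run$t_end %||% 288,
    K = cfg$run$K %||% cfg$params$K,
    engine = cfg$engine,
    variant = cfg$run$variant %||% "reduced",
    replacement = cfg$run$replacement %||% "random",
    record_every = cfg$run$record_every %||% 10L
  )
  write_assay_table(sim$series, file.path(outdir, "timeseries.csv"),
                    "timeseries")
  jsonlite::write_json(
    list(final_N = viability(sim),
         ratio = selection_ratio(sim),
         recovery = viability_recovery(sim),
         n_divisions = sim$n_divisions, n_deaths = sim$n_deaths,
         seed = seed, config_hash = rlang::hash(cfg$raw)),
    file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Calibrate the model to growth and viability tables
#'
#' Full calibration pipeline: fit the growth curve (fixing `mu0`), run
#' rejection ABC with the combined `E1 + E2 + E3` loss against the
#' viability table, and write `growth_fit.json`, `posterior.csv`,
#' `mode.json`, `correlations.csv` and `sensitivity.csv` into `outdir`.
#'
#' @param config path to a JSON config; its `abc` section may set
#'   `budget`, `keep`, `K`, and its `run` section `seed`.
#' @param growth_file,viability_file delimited-text data files (see
#'   [read_assay_table()]).
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
cmd_calibrate <- function(config, growth_file, viability_file,
                          outdir = "phenosel_calibration") {
  cfg <- read_config(config)
  abc_cfg <- cfg$raw$abc %||% list()
  seed <- cfg$run$seed %||% 1L
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  run_log(outdir, seed, rlang::hash(cfg$raw))
  set.seed(seed)
  growth <- read_assay_table(growth_file, "growth")
  viability_tbl <- read_assay_table(viability_file, "viability")

  gfit <- fit_growth(growth, budget = abc_cfg$growth_budget %||% 4000)
  jsonlite::write_json(as.list(glance(gfit)),
                       file.path(outdir, "growth_fit.json"),
                       auto_unbox = TRUE, digits = NA)
  post <- calibrate_viability(
    viability_tbl, mu0 = gfit$mu,
    budget = abc_cfg$budget %||% 200,
    keep = abc_cfg$keep %||% 50,
    K = abc_cfg$K %||% 500,
    engine = cfg$engine
  )
  write_assay_table(post$accepted, file.path(outdir, "posterior.csv"),
                    "posterior")
  jsonlite::write_json(c(as.list(posterior_mode(post)),
                         list(mu0 = gfit$mu)),
                       file.path(outdir, "mode.json"),
                       auto_unbox = TRUE, digits = NA)
  write_assay_table(posterior_correlations(post),
                    file.path(outdir, "correlations.csv"), "timeseries")
  write_assay_table(posterior_sensitivity(post),
                    file.path(outdir, "sensitivity.csv"), "timeseries")
  invisible(outdir)
}

#' Predict held-out doses from a calibration directory
#'
#' Loads the posterior mode written by [cmd_calibrate()] and simulates
#' the validation dose panel, writing one `prediction_<dose>uM.csv`
#' per dose (percent survival relative to control, and the selection
#' ratio, at the assay times).
#'
#' @param posterior_dir directory containing `mode.json`.
#' @param doses held-out dose panel (uM).
#' @param outdir output directory (defaults to `posterior_dir`).
#' @param times report times (h).
#' @param K slots per run.
#' @param seed RNG seed.
#' @return Invisibly, the prediction tibble (all doses).
#' @export
cmd_validate <- function(posterior_dir, doses = c(75, 150, 300, 600),
                         outdir = posterior_dir,
                         times = c(72, 96, 120, 144), K = 500,
                         seed = 1L) {
  if (length(doses) == 0) {
    warning("empty dose list; nothing to validate")
    return(invisible(NULL))
  }
  mode_file <- file.path(posterior_dir, "mode.json")
  if (!file.exists(mode_file)) stop("no mode.json in ", posterior_dir,
                                    call. = FALSE)
  mode <- jsonlite::fromJSON(mode_file)
  params <- rlang::exec(model_params, !!!mode)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  pred <- predict_viability(params, doses = doses, times = times, K = K)
  for (dd in doses) {
    write_assay_table(pred[pred$dose_uM == dd, ],
                      file.path(outdir,
                                sprintf("prediction_%suM.csv", dd)),
                      "timeseries")
  }
  invisible(pred)
}
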