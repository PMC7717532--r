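# Cohort run orchestration: simulate, screen, score, aggregate, export.

.PRESET_STRATEGIES <- c("acs", "uspstf", "triennial", "none")

#' Configuration for cohort runs
#'
#' @param n_women cohort size per strategy (>= 1). The default, 100,000, is a
#'   desk-scale cohort; full one-million-woman runs are supported by passing
#'   `n_women = 1e6`.
#' @param master_seed integer master seed; every random draw derives from it.
#' @param strategies character vector of preset names, or a list mixing
#'   preset names and [screening_strategy()] objects.
#' @param calibration `"fixture"` (the synthetic calibration), a directory
#'   path for [load_calibration()], or a [calibration_bundle].
#' @param common_random_numbers logical; when `TRUE` (default) all strategies
#'   share natural-history draws, so curve differences reflect the schedules
#'   alone. When `FALSE` each strategy gets an independent cohort.
#' @param output_dir optional output directory for [write_outputs()].
#' @return an object of class `run_config`.
#' @export
run_config <- function(n_women = 1e5, master_seed = 1L,
                       strategies = c("none", "uspstf"),
                       calibration = "fixture",
                       common_random_numbers = TRUE,
                       output_dir = NULL) {
  stopifnot(n_women >= 1, length(strategies) >= 1)
  if (is.character(strategies)) strategies <- as.list(strategies)
  strategies <- lapply(strategies, function(s) {
    if (is.character(s)) screening_strategy(match.arg(s, .PRESET_STRATEGIES))
    else if (inherits(s, "screening_strategy")) s
    else stop("each strategy must be a preset name or a screening_strategy",
              call. = FALSE)
  })
  structure(list(n_women = as.integer(n_women),
                 master_seed = as.integer(master_seed),
                 strategies = strategies,
                 calibration = calibration,
                 common_random_numbers = isTRUE(common_random_numbers),
                 output_dir = output_dir),
            class = "run_config")
}

.resolve_calibration <- function(calibration) {
  if (inherits(calibration, "calibration_bundle")) return(calibration)
  if (identical(calibration, "fixture")) return(make_fixture_calibration())
  load_calibration(calibration)
}

#' Simulate one screening strategy over a cohort
#'
#' For each woman: natural history, exam schedule, screening detection, and
#' the individual screen-PLL trajectory; trajectories are summed into the
#' cohort curve. Fully reproducible from `(master_seed, strategy, calib)`.
#'
#' @param strategy a [screening_strategy()] or preset name.
#' @param config a [run_config()].
#' @param calib optional [calibration_bundle]; defaults to the config's.
#' @param histories optional pre-simulated cohort (for common random
#'   numbers across strategies); must match `config$master_seed`.
#' @return a list of class `cohort_run` with elements `strategy`, `curve`
#'   (a [cohort_curve()]), `summary` (see below), `exams`, `histories`,
#'   `detections`, `trajectories`. The summary records the curve peak and its
#'   age, curve values at ages 30/45/65/80, realized breast-cancer deaths,
#'   screen detections, overdiagnosed (non-progressive) detections, and mean
#'   exams per woman.
#' @export
run_cohort <- function(strategy, config, calib = NULL, histories = NULL) {
  if (is.character(strategy)) {
    strategy <- screening_strategy(match.arg(strategy, .PRESET_STRATEGIES))
  }
  if (is.null(calib)) calib <- .resolve_calibration(config$calibration)
  if (is.null(histories)) {
    histories <- simulate_cohort(calib, config$n_women, config$master_seed)
  }
  p <- calib$params
  exams <- schedule_exams(strategy, calib$life_table)
  det <- apply_screening_cohort(histories, exams, p, config$master_seed)
  traj <- cohort_pll(histories, det, p$pll_counterfactual)
  curve <- cohort_curve(traj)

  # realized deaths under this strategy: detection (screen or clinical)
  # before metastasis is curative; metastatic disease is incurable
  det_mo <- ifelse(det$mode == "none", Inf, det$age_detect)
  dies_bca <- histories$has_tumor & !is.na(histories$age_metastasis) &
    !is.na(histories$age_bca_death) &
    histories$age_metastasis < det_mo &
    histories$age_bca_death < histories$age_other_death
  peak_i <- which.max(curve$screen_pll_life_months)
  at_age <- function(yrs) curve$screen_pll_life_months[yrs * 12 + 1]
  summary <- list(
    strategy = strategy$name,
    n_women = config$n_women,
    n_exam_ages = length(exams),
    peak_life_months = curve$screen_pll_life_months[peak_i],
    peak_age_years = curve$age_months[peak_i] / 12,
    value_at_age_30 = at_age(30), value_at_age_45 = at_age(45),
    value_at_age_65 = at_age(65), value_at_age_80 = at_age(80),
    n_bca_deaths = sum(dies_bca),
    n_screen_detections = sum(det$mode == "screen"),
    n_overdiagnosed = sum(det$np_detected),
    mean_exams_per_woman = mean(det$n_exams)
  )
  structure(list(strategy = strategy, curve = curve, summary = summary,
                 exams = exams, histories = histories, detections = det,
                 trajectories = traj),
            class = "cohort_run")
}

#' Compare screening strategies on a common cohort
#'
#' Runs every strategy in the config; under common random numbers all
#' strategies share the same simulated natural histories, so pointwise curve
#' differences isolate the effect of the schedules. Differences are taken
#' against the first listed strategy. The convergence age of a pair is the
#' first month after the later strategy's last exam from which the absolute
#' difference stays below `tol` through the end of the grid (`NA` if never).
#'
#' @param config a [run_config()] with at least two strategies.
#' @param calib optional [calibration_bundle] override.
#' @param tol convergence tolerance in life-months.
#' @return a list of class `strategy_comparison`: `runs` (named list of
#'   [run_cohort()] results), `curves` (named list of curves), `differences`
#'   (long data frame `strategy, age_months, diff_life_months` vs the
#'   reference), `convergence_age_months` (named vector), `reference`.
#' @export
compare_strategies <- function(config, calib = NULL, tol = 1e-8) {
  stopifnot(length(config$strategies) >= 2)
  if (is.null(calib)) calib <- .resolve_calibration(config$calibration)
  names_ <- vapply(config$strategies, function(s) s$name, character(1))
  names_ <- make.unique(names_)

  shared <- if (config$common_random_numbers) {
    simulate_cohort(calib, config$n_women, config$master_seed)
  } else NULL
  runs <- vector("list", length(config$strategies))
  for (j in seq_along(config$strategies)) {
    cfg_j <- config
    if (!config$common_random_numbers) {
      cfg_j$master_seed <- substream_seed(config$master_seed, j)
    }
    runs[[j]] <- run_cohort(config$strategies[[j]], cfg_j, calib,
                            histories = shared)
  }
  names(runs) <- names_
  curves <- lapply(runs, `[[`, "curve")

  ref <- curves[[1]]$screen_pll_life_months
  diffs <- list()
  conv <- rep(NA_real_, length(runs))
  names(conv) <- names_
  for (j in seq_along(runs)[-1]) {
    d <- curves[[j]]$screen_pll_life_months - ref
    diffs[[names_[j]]] <- data.frame(strategy = names_[j],
                                     age_months = curves[[j]]$age_months,
                                     diff_life_months = d)
    last_exam_mo <- max(c(runs[[1]]$exams, runs[[j]]$exams, 0)) * 12
    below <- rev(cumprod(rev(abs(d) < tol))) == 1 # stays below tol to the end
    cand <- which(below & curves[[j]]$age_months > last_exam_mo)
    if (length(cand)) conv[j] <- curves[[j]]$age_months[cand[1]]
  }
  structure(list(runs = runs, curves = curves,
                 differences = do.call(rbind, diffs),
                 convergence_age_months = conv, reference = names_[1]),
            class = "strategy_comparison")
}

#' Pre-flight check that an output directory is writable
#'
#' Creates the directory if needed and verifies a file can be written there,
#' so long simulations cannot fail at the export step.
#'
#' @param dir output directory.
#' @return `dir`, invisibly; errors if unwritable.
#' @export
check_output_dir <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  probe <- file.path(dir, ".write_probe")
  ok <- tryCatch({
    writeLines("ok", probe)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("output directory is not writable: ", dir, call. = FALSE)
  unlink(probe)
  invisible(dir)
}

#' Write curves, summaries, plot and run log for a set of runs
#'
#' Writes one curve CSV per strategy (`curve_<name>.csv`), a combined
#' long-format CSV (`curves_long.csv`: strategy, age_months,
#' screen_pll_life_months), a JSON summary (`summary.json`), an optional PNG
#' of all curves, and a run log echoing the configuration and seed.
#'
#' @param runs a named list of [run_cohort()] results, a single result, or a
#'   [compare_strategies()] result.
#' @param output_dir output directory.
#' @param config optional [run_config()] echoed into the log.
#' @param plot write `curves.png`?
#' @return paths of the written files, invisibly.
#' @export
write_outputs <- function(runs, output_dir, config = NULL, plot = TRUE) {
  if (inherits(runs, "strategy_comparison")) runs <- runs$runs
  if (inherits(runs, "cohort_run")) {
    runs <- stats::setNames(list(runs), runs$strategy$name)
  }
  check_output_dir(output_dir)
  paths <- character(0)
  long <- list()
  for (nm in names(runs)) {
    pth <- file.path(output_dir, paste0("curve_", nm, ".csv"))
    write_cohort_curve(runs[[nm]]$curve, pth)
    paths <- c(paths, pth)
    long[[nm]] <- cbind(strategy = nm, as.data.frame(runs[[nm]]$curve))
  }
  long_path <- file.path(output_dir, "curves_long.csv")
  utils::write.csv(do.call(rbind, long), long_path, row.names = FALSE)

  summary_path <- file.path(output_dir, "summary.json")
  summaries <- lapply(runs, `[[`, "summary")
  jsonlite::write_json(summaries, summary_path, auto_unbox = TRUE, digits = NA)

  log_path <- file.path(output_dir, "run.log")
  log_lines <- c(
    paste("screenPLL run at", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    if (!is.null(config)) c(
      paste("n_women:", config$n_women),
      paste("master_seed:", config$master_seed),
      paste("strategies:", paste(names(runs), collapse = ", ")),
      paste("common_random_numbers:", config$common_random_numbers)
    ),
    paste("curves written:", paste(basename(paths), collapse = ", ")))
  writeLines(log_lines, log_path)

  out <- c(paths, long_path, summary_path, log_path)
  if (plot) {
    png_path <- file.path(output_dir, "curves.png")
    grDevices::png(png_path, width = 900, height = 600)
    plot_curves(lapply(runs, `[[`, "curve"),
                main = "Cohort screen-PLL by screening strategy")
    grDevices::dev.off()
    out <- c(out, png_path)
  }
  invisible(out)
}

#' Validate a written summary JSON against the shipped schema
#'
#' The schema (`inst/schema/run_summary.schema.json`) lists the required
#' per-strategy fields and their types; this checker enforces it without an
#' external JSON-schema engine.
#'
#' @param path path to a `summary.json` written by [write_outputs()].
#' @return `TRUE` invisibly; errors describing the first violation otherwise.
#' @export
validate_summary_json <- function(path) {
  schema <- jsonlite::read_json(
    system.file("schema", "run_summary.schema.json", package = "screenPLL"),
    simplifyVector = FALSE)
  required <- names(schema$items$properties)
  numeric_fields <- required[vapply(schema$items$properties,
                                    function(pr) pr$type == "number",
                                    logical(1))]
  summaries <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!length(summaries)) stop("summary JSON is empty", call. = FALSE)
  for (s in summaries) {
    miss <- setdiff(required, names(s))
    if (length(miss)) {
      stop("summary entry missing field(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    for (f in numeric_fields) {
      if (!is.numeric(s[[f]])) {
        stop("summary field not numeric: ", f, call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}
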