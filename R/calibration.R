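# Calibration bundle: life table + incidence table + model parameters.

#' Bundle the simulator's calibration inputs
#'
#' @param life_table a [life_table].
#' @param incidence an [incidence_table] spanning the same age range.
#' @param params a [model_params()] object.
#' @return an object of class `calibration_bundle`.
#' @export
calibration_bundle <- function(life_table, incidence, params = model_params()) {
  validate_life_table(life_table)
  validate_incidence_table(incidence)
  validate_model_params(params)
  if (!identical(attr(life_table, "max_age"), attr(incidence, "max_age"))) {
    stop("life table and incidence table must span the same age range",
         call. = FALSE)
  }
  structure(list(life_table = life_table, incidence = incidence,
                 params = params),
            class = "calibration_bundle")
}

#' Deterministic synthetic calibration
#'
#' Builds a fully synthetic but realistically scaled calibration bundle for
#' testing and demonstration; real SEER-style incidence and NVSS-style life
#' tables are drop-in CSV replacements with the same headers.
#'
#' The life table is Gompertz-Makeham,
#' `qx = 1 - exp(-(A + B exp(C x)))` with `A = 5e-4`, `B = 1.5e-5`,
#' `C = 0.1` over ages 0-100, giving life expectancy at birth of about 81
#' years and remaining life expectancy first dropping below 10 years at age
#' 80 - the profile of a contemporary US female period table. The incidence
#' curve is logistic in age, `rate = 380 / (1 + exp(-(age - 53)/7))` per
#' 100,000 woman-years: negligible before 30, rising through the 40s and 50s
#' to a plateau of ~380 per 100,000 in the late 60s and beyond. Both tables
#' are rounded to 7 significant digits so CSV round-trips are exact.
#'
#' @param max_age final (absorbing) age of both tables.
#' @param params a [model_params()] object; defaults to [model_params()].
#' @return a [calibration_bundle].
#' @examples
#' calib <- make_fixture_calibration()
#' life_expectancy(calib$life_table, 80)
#' @export
make_fixture_calibration <- function(max_age = 100, params = model_params()) {
  x <- 0:max_age
  qx <- signif(1 - exp(-(5e-4 + 1.5e-5 * exp(0.1 * x))), 7)
  qx[length(qx)] <- 1
  rate <- signif(380 / (1 + exp(-(x - 53) / 7)), 7)
  calibration_bundle(life_table(x, qx), incidence_table(x, rate), params)
}

#' Write the synthetic calibration tables as CSV files
#'
#' @param dir output directory (created if needed).
#' @param calib a [calibration_bundle]; defaults to the synthetic fixture.
#' @return paths of the written files, invisibly.
#' @export
write_fixture_csvs <- function(dir, calib = make_fixture_calibration()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lt_path <- file.path(dir, "life_table.csv")
  inc_path <- file.path(dir, "incidence.csv")
  par_path <- file.path(dir, "params.yaml")
  write_life_table(calib$life_table, lt_path)
  write_incidence_table(calib$incidence, inc_path)
  write_model_params(calib$params, par_path)
  invisible(c(lt_path, inc_path, par_path))
}

#' Load a calibration bundle from a directory of CSV/config files
#'
#' Expects `life_table.csv`, `incidence.csv` and optionally `params.yaml`
#' (or `params.json`); missing parameter file means defaults.
#'
#' @param dir directory containing the calibration files.
#' @return a [calibration_bundle].
#' @export
load_calibration <- function(dir) {
  lt <- load_life_table(file.path(dir, "life_table.csv"))
  it <- load_incidence_table(file.path(dir, "incidence.csv"))
  par_path <- c(file.path(dir, "params.yaml"), file.path(dir, "params.yml"),
                file.path(dir, "params.json"))
  par_path <- par_path[file.exists(par_path)]
  p <- if (length(par_path)) load_model_params(par_path[1]) else model_params()
  calibration_bundle(lt, it, p)
}

#' Onset-rate factor of the non-progressive tumor reservoir
#'
#' Non-progressive tumors are modeled as an independent asymptomatic onset
#' process: they never surface clinically, never metastasize and never kill,
#' and are discoverable only by mammography (their screen detection is
#' overdiagnosis). Their per-year onset probability is `factor * rate/1e5`,
#' with `factor` calibrated here so that the expected share of
#' non-progressive tumors among all tumors arising over a lifetime equals
#' `p_nonprogressive` exactly:
#' `1 - prod(1 - factor * r) = p/(1-p) * (1 - prod(1 - r))`.
#'
#' Because the lethal-pathway (clinically surfacing) onset process is
#' untouched by this factor, the overdiagnosis proportion can be changed
#' without altering any woman at risk of breast-cancer death - which is what
#' makes screen-PLL curves invariant to the overdiagnosis rate.
#'
#' @param incidence an [incidence_table].
#' @param p_nonprogressive target non-progressive share of tumors, in `[0, 1)`.
#' @return a non-negative scalar factor.
#' @export
np_rate_factor <- function(incidence, p_nonprogressive) {
  if (p_nonprogressive <= 0) return(0)
  r <- incidence$rate_per_100k / 1e5
  p_prog <- 1 - prod(1 - r)
  if (p_prog <= 0) return(0)
  target <- p_nonprogressive / (1 - p_nonprogressive) * p_prog
  if (target >= 1) {
    stop("p_nonprogressive too large for this incidence table", call. = FALSE)
  }
  f <- function(cc) (1 - prod(1 - pmin(cc * r, 1))) - target
  stats::uniroot(f, c(1e-12, 1 / max(r)), tol = 1e-12)$root
}
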