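# Screen-preventable loss of life: per-woman trajectories and cohort curves.
#
# A woman carries positive screen-PLL only if her no-intervention path ends
# in a premature breast-cancer death: metastasis before clinical surfacing,
# and breast-cancer death before other-cause death. For such a woman the
# trajectory is a plateau: zero before the tumor reaches mammographic
# detectability, equal to (other-cause death age - breast-cancer death age)
# in months from detectability until screen detection or metastasis
# (whichever comes first), and zero thereafter. Everyone else - no tumor,
# non-progressive tumor, metastasis after surfacing (cured by clinical
# detection anyway), or other-cause death first - contributes zero at every
# age.

.MAX_MONTH <- 1212L # curve grid: ages 0..101 years, 1213 monthly points

#' Compute one woman's screen-PLL trajectory
#'
#' @param h a one-row history data frame from [simulate_natural_history()].
#' @param det a one-row detection data frame from [apply_screening()]; use a
#'   no-screening detection (empty exam list) for the unscreened trajectory.
#' @param counterfactual overrides the bundle's `pll_counterfactual`; see
#'   [model_params()].
#' @return an object of class `pll_trajectory`: list with `value`
#'   (life-months, a constant plateau, possibly 0), `window_start` and
#'   `window_end` (months; the half-open interval over which the value
#'   applies) and `premature` (does her no-intervention path end in
#'   premature breast-cancer death?).
#' @examples
#' # the canonical timeline: detectable at 60, metastasis at 65, breast-cancer
#' # death at 72, other-cause death at 92 -> 240 life-months over ages [60, 65)
#' h <- data.frame(id = 1, has_tumor = TRUE, progressive = TRUE,
#'                 age_fmc = 690, age_detectable = 720, age_surface = 792,
#'                 age_metastasis = 780, age_bca_death = 864,
#'                 age_other_death = 1104)
#' det <- data.frame(id = 1, mode = "clinical", age_detect = 792)
#' individual_pll(h, det)
#' @export
individual_pll <- function(h, det, counterfactual = c("destined_death",
                                                      "any_progressive")) {
  counterfactual <- match.arg(counterfactual)
  if (identical(det$mode, "screen")) {
    if (is.na(h$age_detectable) || det$age_detect < h$age_detectable - 1e-9) {
      stop("inconsistent history/detection pair: screen detection before ",
           "the tumor is detectable", call. = FALSE)
    }
  }
  zero <- structure(list(value = 0, window_start = NA_real_,
                         window_end = NA_real_, premature = FALSE),
                    class = "pll_trajectory")
  if (!isTRUE(h$has_tumor) || !isTRUE(h$progressive)) return(zero)
  if (is.na(h$age_metastasis) || is.na(h$age_bca_death)) return(zero)
  dies_of_bca <- h$age_bca_death < h$age_other_death
  premature <- dies_of_bca && h$age_metastasis < h$age_surface
  eligible <- if (counterfactual == "destined_death") premature else dies_of_bca
  if (!eligible) {
    zero$premature <- premature
    return(zero)
  }
  screen_mo <- if (identical(det$mode, "screen")) det$age_detect else Inf
  w_start <- max(0, h$age_detectable)
  w_end <- if (counterfactual == "destined_death") {
    min(screen_mo, h$age_metastasis)
  } else {
    min(screen_mo, h$age_surface, h$age_metastasis)
  }
  if (w_end <= w_start) {
    # metastasis (or detection) before the tumor was ever screen-detectable:
    # screening could never have averted this death
    zero$premature <- premature
    return(zero)
  }
  structure(list(value = (h$age_other_death - h$age_bca_death),
                 window_start = w_start, window_end = w_end,
                 premature = premature),
            class = "pll_trajectory")
}

#' Compute screen-PLL trajectories for a whole cohort
#'
#' @param histories cohort data frame from [simulate_cohort()].
#' @param detections matching data frame from [apply_screening_cohort()].
#' @inheritParams individual_pll
#' @return a data frame with one row per woman: `id`, `value`,
#'   `window_start`, `window_end`, `premature`.
#' @export
cohort_pll <- function(histories, detections,
                       counterfactual = c("destined_death", "any_progressive")) {
  counterfactual <- match.arg(counterfactual)
  stopifnot(nrow(histories) == nrow(detections),
            all(histories$id == detections$id))
  scr <- detections$mode == "screen"
  if (any(scr & (is.na(histories$age_detectable) |
                   detections$age_detect < histories$age_detectable - 1e-9))) {
    stop("inconsistent history/detection pair: screen detection before ",
         "the tumor is detectable", call. = FALSE)
  }
  dies_of_bca <- histories$has_tumor & histories$progressive &
    !is.na(histories$age_metastasis) & !is.na(histories$age_bca_death) &
    histories$age_bca_death < histories$age_other_death
  premature <- dies_of_bca &
    !is.na(histories$age_surface) &
    histories$age_metastasis < histories$age_surface
  eligible <- if (counterfactual == "destined_death") premature else dies_of_bca
  screen_mo <- ifelse(scr, detections$age_detect, Inf)
  ws <- pmax(0, histories$age_detectable)
  we <- if (counterfactual == "destined_death") {
    pmin(screen_mo, histories$age_metastasis)
  } else {
    pmin(screen_mo, histories$age_surface, histories$age_metastasis)
  }
  pos <- eligible & !is.na(ws) & !is.na(we) & we > ws
  value <- ifelse(pos, histories$age_other_death - histories$age_bca_death, 0)
  data.frame(id = histories$id, value = value,
             window_start = ifelse(pos, ws, NA_real_),
             window_end = ifelse(pos, we, NA_real_),
             premature = premature)
}

#' Sum individual trajectories into a cohort screen-PLL curve
#'
#' The curve grid is fixed at monthly ages 0..1212 (0-101 years). A
#' trajectory contributes its plateau value at every integer month `m` with
#' `window_start <= m < window_end` (half-open months: an event at an exact
#' month boundary belongs to the later month).
#'
#' @param trajectories a data frame with columns `value`, `window_start`,
#'   `window_end` (from [cohort_pll()]), or a list of `pll_trajectory`
#'   objects.
#' @return an object of class `cohort_curve`: a data frame with columns
#'   `age_months` (0..1212) and `screen_pll_life_months`.
#' @export
cohort_curve <- function(trajectories) {
  if (is.list(trajectories) && !is.data.frame(trajectories)) {
    trajectories <- data.frame(
      value = vapply(trajectories, `[[`, numeric(1), "value"),
      window_start = vapply(trajectories, `[[`, numeric(1), "window_start"),
      window_end = vapply(trajectories, `[[`, numeric(1), "window_end"))
  }
  total <- numeric(.MAX_MONTH + 1L)
  keep <- which(trajectories$value > 0 & !is.na(trajectories$window_start))
  for (k in keep) {
    lo <- max(0L, as.integer(ceiling(trajectories$window_start[k])))
    hi <- min(.MAX_MONTH, as.integer(ceiling(trajectories$window_end[k])) - 1L)
    if (hi >= lo) total[(lo:hi) + 1L] <- total[(lo:hi) + 1L] + trajectories$value[k]
  }
  structure(data.frame(age_months = 0:.MAX_MONTH,
                       screen_pll_life_months = total),
            class = c("cohort_curve", "data.frame"))
}

#' Write / read a cohort curve CSV
#'
#' Header `age_months,screen_pll_life_months`, one row per month 0..1212.
#'
#' @param curve a [cohort_curve()].
#' @param path file path.
#' @return `write_cohort_curve` returns `path` invisibly;
#'   `load_cohort_curve` returns a `cohort_curve`.
#' @export
write_cohort_curve <- function(curve, path) {
  df <- data.frame(age_months = curve$age_months,
                   screen_pll_life_months =
                     sprintf("%.17g", curve$screen_pll_life_months))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_curve
#' @export
load_cohort_curve <- function(path) {
  df <- utils::read.csv(path, colClasses = c(age_months = "integer",
                                             screen_pll_life_months = "numeric"))
  structure(df, class = c("cohort_curve", "data.frame"))
}

#' Plot cohort screen-PLL curves
#'
#' @param x a [cohort_curve()] or a named list of them.
#' @param ... passed to [graphics::matplot()].
#' @export
plot_curves <- function(x, ...) {
  if (inherits(x, "cohort_curve")) x <- list(`screen-PLL` = x)
  ages <- x[[1]]$age_months / 12
  y <- sapply(x, function(cv) cv$screen_pll_life_months)
  graphics::matplot(ages, y, type = "l", lty = 1, lwd = 1.5,
                    col = seq_along(x),
                    xlab = "Age (years)",
                    ylab = "Cohort screen-PLL (life-months)", ...)
  graphics::legend("topleft", legend = names(x), col = seq_along(x),
                   lty = 1, lwd = 1.5, bty = "n")
  invisible(x)
}
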