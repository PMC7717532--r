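# Natural-history and screening model parameters.

#' Model parameters for tumor growth, progression, detection and survival
#'
#' Returns the full parameter set with documented defaults; any subset can be
#' overridden by name. Diameters are in cm, times in months unless noted.
#'
#' Growth follows a Gompertz law from the diameter of the first malignant
#' cell (`d_cell`) toward an asymptotic diameter (`d_max`), with per-woman
#' rate `alpha` drawn lognormal. The default `alpha` median (0.0181/month)
#' corresponds to a volume doubling time of about 5 months at 1 cm diameter,
#' a mid-range figure for invasive breast cancer. Clinical surfacing diameter
#' (median 2 cm), metastasis-threshold diameter (median 3 cm) and
#' post-metastasis survival (median 84 months) are likewise lognormal; with
#' these medians a tumor that reaches mammographic detectability (0.2 cm) at
#' age 60 typically metastasizes near 65 and, if uninterrupted, causes death
#' near 72 - i.e. the defaults make the canonical worked timeline typical.
#'
#' Mammography sensitivity is zero below `d_detect` (0.2 cm, the assumed
#' limit of mammographic detectability) and otherwise a logistic function of
#' log-diameter scaled to an asymptote that is higher after menopause.
#'
#' @param d_detect mammographic detectability threshold diameter, cm.
#' @param d_cell diameter of the first malignant cell, cm.
#' @param d_max Gompertz asymptotic diameter, cm.
#' @param alpha_log_mean,alpha_log_sd lognormal parameters of the per-woman
#'   Gompertz rate, 1/month.
#' @param d_surface_log_mean,d_surface_log_sd lognormal parameters of the
#'   clinical-surfacing diameter, cm.
#' @param d_met_log_mean,d_met_log_sd lognormal parameters of the per-woman
#'   metastasis-threshold diameter, cm.
#' @param p_nonprogressive proportion of all tumors that are non-progressive
#'   (never metastasize, never surface clinically, never kill; their screen
#'   detection constitutes overdiagnosis).
#' @param surv_met_log_mean,surv_met_log_sd lognormal parameters of survival
#'   after metastasis, months.
#' @param sens_max_pre,sens_max_post asymptotic mammography sensitivity
#'   before/after menopause (`sens_max_post >= sens_max_pre`).
#' @param sens_slope,sens_mid logistic shape of sensitivity in log-diameter:
#'   slope, and the diameter (cm) at which sensitivity reaches half its
#'   asymptote.
#' @param menopause_age deterministic menopause age, years.
#' @param pll_counterfactual which women carry positive screen-PLL:
#'   `"destined_death"` (default) restricts it to women whose no-intervention
#'   path ends in premature breast-cancer death; `"any_progressive"` also
#'   credits interim PLL to women whose metastasis draw falls after clinical
#'   surfacing (they would be cured anyway).
#' @param ... overrides passed as name = value.
#' @return an object of class `model_params` (named list).
#' @export
model_params <- function(d_detect = 0.2,
                         d_cell = 0.01,
                         d_max = 12.8,
                         alpha_log_mean = log(0.0181),
                         alpha_log_sd = 0.35,
                         d_surface_log_mean = log(2.0),
                         d_surface_log_sd = 0.4,
                         d_met_log_mean = log(3.0),
                         d_met_log_sd = 0.6,
                         p_nonprogressive = 0.30,
                         surv_met_log_mean = log(84),
                         surv_met_log_sd = 0.5,
                         sens_max_pre = 0.75,
                         sens_max_post = 0.95,
                         sens_slope = 2.5,
                         sens_mid = 0.5,
                         menopause_age = 50,
                         pll_counterfactual = c("destined_death", "any_progressive"),
                         ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("unknown model parameter(s): ", paste(names(extra), collapse = ", "),
         call. = FALSE)
  }
  p <- list(
    d_detect = d_detect, d_cell = d_cell, d_max = d_max,
    alpha_log_mean = alpha_log_mean, alpha_log_sd = alpha_log_sd,
    d_surface_log_mean = d_surface_log_mean,
    d_surface_log_sd = d_surface_log_sd,
    d_met_log_mean = d_met_log_mean, d_met_log_sd = d_met_log_sd,
    p_nonprogressive = p_nonprogressive,
    surv_met_log_mean = surv_met_log_mean, surv_met_log_sd = surv_met_log_sd,
    sens_max_pre = sens_max_pre, sens_max_post = sens_max_post,
    sens_slope = sens_slope, sens_mid = sens_mid,
    menopause_age = menopause_age,
    pll_counterfactual = match.arg(pll_counterfactual)
  )
  validate_model_params(p)
  structure(p, class = "model_params")
}

#' @rdname model_params
#' @param p a candidate parameter list.
#' @export
validate_model_params <- function(p) {
  chk <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
  chk(p$d_cell > 0 && p$d_cell < p$d_detect && p$d_detect < p$d_max,
      "require 0 < d_cell < d_detect < d_max")
  chk(p$p_nonprogressive >= 0 && p$p_nonprogressive < 1,
      "p_nonprogressive must be in [0, 1)")
  chk(all(c(p$sens_max_pre, p$sens_max_post) >= 0) &&
        all(c(p$sens_max_pre, p$sens_max_post) <= 1),
      "sensitivity asymptotes must be probabilities")
  chk(p$sens_max_post >= p$sens_max_pre,
      "post-menopause sensitivity asymptote must be >= pre-menopause")
  chk(all(c(p$alpha_log_sd, p$d_surface_log_sd, p$d_met_log_sd,
            p$surv_met_log_sd) > 0),
      "lognormal sd parameters must be > 0")
  chk(p$sens_slope > 0 && p$sens_mid > 0, "sens_slope and sens_mid must be > 0")
  chk(p$menopause_age >= 0, "menopause_age must be >= 0")
  chk(p$pll_counterfactual %in% c("destined_death", "any_progressive"),
      "pll_counterfactual must be 'destined_death' or 'any_progressive'")
  invisible(p)
}

#' Read / write model parameters as a flat key-value config file
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`), keys exactly as in
#' [model_params()]. Missing keys take the defaults; unknown keys error.
#'
#' @param path file path.
#' @return `load_model_params` returns a validated [model_params()] object;
#'   `write_model_params` returns `path` invisibly.
#' @export
load_model_params <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(model_params, vals)
}

#' @rdname load_model_params
#' @param p a [model_params()] object.
#' @export
write_model_params <- function(p, path) {
  vals <- unclass(p)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path, precision = 15)
  }
  invisible(path)
}
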