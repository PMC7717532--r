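# Natural-history sampling: each woman's complete no-intervention disease
# timeline. All event ages are exact fractional months.
#
# Sampling order per woman (each step on its own RNG substream, so any one
# draw family can change without disturbing the others):
#   1. other-cause death age from the life table;
#   2. clinical surfacing age by yearly Bernoulli against the incidence rate
#      (applied regardless of vital status; competing risks are resolved at
#      PLL evaluation, keeping common-random-number comparisons exact);
#   3. surfacing diameter and Gompertz rate alpha (lognormal); the first
#      malignant cell (FMC) age is back-computed from the surfacing age, and
#      the detectability age is where the curve crosses d_detect;
#   4. metastasis-threshold diameter (lognormal); the metastasis age is where
#      the curve crosses it (absent if the threshold exceeds d_max), and the
#      breast-cancer death age adds a lognormal post-metastasis survival;
#   5. an independent non-progressive (overdiagnosis-reservoir) tumor with
#      onset probability np_rate_factor * rate: asymptomatic, non-lethal,
#      discoverable only by mammography.
# A surfacing draw implying a negative FMC age is rejected and the history
# resampled with fresh surfacing and growth draws.

# lognormal draw truncated to (lo, hi) by rejection; deterministic given the
# substream seed
.rlnorm_trunc <- function(meanlog, sdlog, lo = 0, hi = Inf, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    x <- stats::rlnorm(1, meanlog, sdlog)
    if (x > lo && x < hi) return(x)
  }
  stop("truncated lognormal rejection sampling failed; check parameters",
       call. = FALSE)
}

# sample a surfacing year from per-year probabilities; fixed draw count
.sample_onset_age <- function(pr_year) {
  u <- stats::runif(length(pr_year))
  frac <- stats::runif(1)
  yr <- which(u < pr_year)[1]
  if (is.na(yr)) NA_real_ else ((yr - 1) + frac) * 12
}

# one tumor's onset + growth geometry, with negative-FMC rejection across
# attempt-keyed substreams; returns NULL when no onset is drawn
.sample_tumor <- function(master_seed, woman_id, pur_onset, pur_growth,
                          pr_year, p, max_attempts = 1000L) {
  for (attempt in seq_len(max_attempts)) {
    set.seed(substream_seed(master_seed, woman_id, pur_onset, attempt))
    age_surface <- .sample_onset_age(pr_year)
    if (is.na(age_surface)) return(NULL)
    set.seed(substream_seed(master_seed, woman_id, pur_growth, attempt))
    d_surface <- .rlnorm_trunc(p$d_surface_log_mean, p$d_surface_log_sd,
                               lo = p$d_detect, hi = p$d_max)
    alpha <- stats::rlnorm(1, p$alpha_log_mean, p$alpha_log_sd)
    g <- growth_curve(alpha, p$d_cell, p$d_max)
    age_fmc <- age_surface - time_to_diameter(g, d_surface)
    if (age_fmc >= 0) {
      return(list(age_surface = age_surface, d_surface = d_surface,
                  alpha = alpha, age_fmc = age_fmc,
                  age_detectable = age_fmc + time_to_diameter(g, p$d_detect)))
    }
  }
  stop(sprintf("woman %d: could not sample a history with non-negative FMC age",
               woman_id), call. = FALSE)
}

#' Simulate one woman's no-intervention disease timeline
#'
#' All event ages are fractional months. Histories are a pure function of
#' `(master_seed, woman_id, calib)`: identical inputs give bit-identical
#' histories, independently of how many other women are simulated.
#'
#' @param calib a [calibration_bundle].
#' @param master_seed integer master seed.
#' @param woman_id integer woman index (>= 1).
#' @return a one-row data frame with columns `id`, `has_tumor`, `progressive`,
#'   `age_fmc`, `age_detectable`, `age_surface`, `age_metastasis`,
#'   `age_bca_death`, `age_other_death` (months), the growth draws `alpha`,
#'   `d_surface`, `d_met`, and the non-progressive reservoir fields `has_np`,
#'   `np_age_fmc`, `np_age_detectable`, `np_alpha`. Absent events are `NA`.
#' @export
simulate_natural_history <- function(calib, master_seed = 1L, woman_id = 1L) {
  simulate_cohort(calib, n_women = 1L, master_seed = master_seed,
                  first_id = woman_id)
}

#' Simulate a cohort of no-intervention disease timelines
#'
#' @inheritParams simulate_natural_history
#' @param n_women number of women.
#' @param first_id id of the first woman (ids run `first_id, first_id+1, ...`).
#' @return a data frame with one row per woman; see
#'   [simulate_natural_history()] for columns.
#' @export
simulate_cohort <- function(calib, n_women, master_seed = 1L, first_id = 1L) {
  stopifnot(inherits(calib, "calibration_bundle"), n_women >= 1)
  p <- calib$params
  lt <- calib$life_table
  pr_year <- calib$incidence$rate_per_100k / 1e5
  np_factor <- np_rate_factor(calib$incidence, p$p_nonprogressive)

  n <- as.integer(n_women)
  ids <- seq.int(first_id, length.out = n)
  has_tumor <- logical(n)
  age_fmc <- age_detectable <- age_surface <- age_metastasis <-
    age_bca_death <- age_other_death <- alpha <- d_surface <- d_met <-
    np_age_fmc <- np_age_detectable <- np_alpha <- rep(NA_real_, n)
  has_np <- logical(n)

  for (k in seq_len(n)) {
    i <- ids[k]
    set.seed(substream_seed(master_seed, i, .PUR$other_death))
    age_other_death[k] <- sample_death_age(lt) * 12

    tum <- .sample_tumor(master_seed, i, .PUR$onset, .PUR$growth, pr_year, p)
    if (!is.null(tum)) {
      has_tumor[k] <- TRUE
      age_surface[k] <- tum$age_surface
      d_surface[k] <- tum$d_surface
      alpha[k] <- tum$alpha
      age_fmc[k] <- tum$age_fmc
      age_detectable[k] <- tum$age_detectable

      set.seed(substream_seed(master_seed, i, .PUR$met_threshold))
      dm <- .rlnorm_trunc(p$d_met_log_mean, p$d_met_log_sd, lo = p$d_cell)
      d_met[k] <- dm
      if (dm < p$d_max) {
        g <- growth_curve(tum$alpha, p$d_cell, p$d_max)
        age_metastasis[k] <- tum$age_fmc + time_to_diameter(g, dm)
        set.seed(substream_seed(master_seed, i, .PUR$met_survival))
        age_bca_death[k] <- age_metastasis[k] +
          stats::rlnorm(1, p$surv_met_log_mean, p$surv_met_log_sd)
      }
    }

    if (np_factor > 0) {
      np <- .sample_tumor(master_seed, i, .PUR$np_onset, .PUR$np_growth,
                          pmin(np_factor * pr_year, 1), p)
      if (!is.null(np)) {
        has_np[k] <- TRUE
        np_age_fmc[k] <- np$age_fmc
        np_age_detectable[k] <- np$age_detectable
        np_alpha[k] <- np$alpha
      }
    }
  }

  data.frame(id = ids, has_tumor = has_tumor, progressive = has_tumor,
             age_fmc = age_fmc, age_detectable = age_detectable,
             age_surface = age_surface, age_metastasis = age_metastasis,
             age_bca_death = age_bca_death, age_other_death = age_other_death,
             alpha = alpha, d_surface = d_surface, d_met = d_met,
             has_np = has_np, np_age_fmc = np_age_fmc,
             np_age_detectable = np_age_detectable, np_alpha = np_alpha)
}

#' Export simulated histories to CSV
#'
#' One row per woman, columns as in [simulate_natural_history()]; absent
#' events are written as empty fields.
#'
#' @param histories a cohort data frame from [simulate_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_histories_csv <- function(histories, path) {
  utils::write.csv(histories, path, row.names = FALSE, na = "")
  invisible(path)
}
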