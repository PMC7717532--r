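# Screening strategies, exam scheduling, mammography sensitivity, and
# per-woman detection outcomes.

#' Define a mammography screening strategy
#'
#' A strategy is a list of age segments, each expanded to exam ages
#' `start, start + interval, ...` up to `end`, plus an optional
#' life-expectancy stopping rule (exams are dropped from the first scheduled
#' age at which remaining life expectancy falls below the threshold).
#'
#' Built-in presets:
#' \describe{
#'   \item{acs}{annual exams at ages 45-54, then biennial from 55 until
#'     remaining life expectancy is under 10 years (the age-55 boundary
#'     belongs to the biennial segment, so there is no double exam).}
#'   \item{uspstf}{biennial exams at ages 50-74.}
#'   \item{triennial}{exams every 3 years from age 50 to 70 (50, 53, ..., 68;
#'     set `include_age_70 = TRUE` to append a terminal exam at 70).}
#'   \item{none}{no exams.}
#' }
#'
#' @param name `"acs"`, `"uspstf"`, `"triennial"`, `"none"`, or `"custom"`.
#' @param segments for `"custom"`: a data frame with integer columns
#'   `start`, `end`, `interval` (years, interval >= 1), segments ordered and
#'   non-overlapping.
#' @param stop_rule_years optional life-expectancy threshold in years.
#' @param stop_comparator `"lt"` (strict `<`, default) or `"le"` (`<=`) for
#'   the stop rule comparison.
#' @param include_age_70 logical; add a terminal age-70 exam to the
#'   triennial preset.
#' @return an object of class `screening_strategy`.
#' @examples
#' schedule_exams(screening_strategy("uspstf"),
#'                make_fixture_calibration()$life_table)
#' @export
screening_strategy <- function(name = c("acs", "uspstf", "triennial", "none",
                                        "custom"),
                               segments = NULL, stop_rule_years = NULL,
                               stop_comparator = c("lt", "le"),
                               include_age_70 = FALSE) {
  name <- match.arg(name)
  stop_comparator <- match.arg(stop_comparator)
  seg <- function(start, end, interval) {
    data.frame(start = start, end = end, interval = interval)
  }
  if (name == "acs") {
    if (is.null(segments)) segments <- rbind(seg(45, 54, 1), seg(55, Inf, 2))
    if (is.null(stop_rule_years)) stop_rule_years <- 10
  } else if (name == "uspstf") {
    if (is.null(segments)) segments <- seg(50, 74, 2)
  } else if (name == "triennial") {
    if (is.null(segments)) {
      segments <- seg(50, 70, 3)
      if (include_age_70) segments <- rbind(segments, seg(70, 70, 1))
    }
  } else if (name == "none") {
    segments <- seg(numeric(0), numeric(0), numeric(0))
  } else if (is.null(segments)) {
    stop("custom strategy requires segments", call. = FALSE)
  }
  if (nrow(segments) > 0) {
    stopifnot(all(segments$interval >= 1),
              all(segments$end >= segments$start))
    if (nrow(segments) > 1) {
      stopifnot(all(diff(segments$start) > 0),
                all(segments$start[-1] > utils::head(segments$end, -1) |
                      segments$start[-1] > utils::head(segments$start, -1)))
    }
  }
  structure(list(name = name, segments = segments,
                 stop_rule_years = stop_rule_years,
                 stop_comparator = stop_comparator),
            class = "screening_strategy")
}

#' Expand a strategy into scheduled exam ages
#'
#' Segments are expanded to integer exam ages; ages beyond the life table are
#' dropped; if the strategy carries a stopping rule, the schedule is
#' truncated at the first exam age whose remaining life expectancy fails the
#' threshold (strict `<` by default).
#'
#' @param s a [screening_strategy].
#' @param lt a [life_table] used for the stopping rule and the maximum age.
#' @return sorted vector of exam ages in whole years (possibly empty).
#' @export
schedule_exams <- function(s, lt) {
  stopifnot(inherits(s, "screening_strategy"))
  max_age <- attr(lt, "max_age")
  ages <- numeric(0)
  for (j in seq_len(nrow(s$segments))) {
    end <- min(s$segments$end[j], max_age)
    if (end >= s$segments$start[j]) {
      ages <- c(ages, seq(s$segments$start[j], end, by = s$segments$interval[j]))
    }
  }
  ages <- sort(unique(ages))
  if (!is.null(s$stop_rule_years) && length(ages)) {
    le <- vapply(ages, function(a) life_expectancy(lt, a), numeric(1))
    fail <- if (s$stop_comparator == "lt") le < s$stop_rule_years
            else le <= s$stop_rule_years
    if (any(fail)) ages <- ages[seq_len(which(fail)[1] - 1)]
  }
  ages
}

#' Mammography sensitivity as a function of tumor diameter
#'
#' Zero below the detectability threshold `d_detect`; above it, a logistic
#' function of log-diameter scaled to the menopause-specific asymptote:
#' `s(d) = s_max * plogis(sens_slope * (log(d) - log(sens_mid)))`.
#' Non-decreasing in diameter, and the post-menopause curve dominates the
#' pre-menopause curve everywhere.
#'
#' @param d tumor diameter(s), cm; vectorized, all `>= 0`.
#' @param postmenopausal logical: is the woman past the menopause age?
#' @param p a [model_params()] object.
#' @return per-exam detection probability in `[0, 1]`.
#' @export
sensitivity <- function(d, postmenopausal, p) {
  if (any(d < 0)) stop("diameter must be >= 0", call. = FALSE)
  s_max <- if (isTRUE(postmenopausal)) p$sens_max_post else p$sens_max_pre
  s <- s_max * stats::plogis(p$sens_slope * (log(pmax(d, 1e-300)) -
                                               log(p$sens_mid)))
  s[d < p$d_detect] <- 0
  s
}

#' Apply a screening schedule to one woman's history
#'
#' Walks the scheduled exams in order while the woman is alive and her
#' progressive tumor is present and undetected. At each exam with diameter at
#' or above `d_detect`, detection succeeds with probability
#' [sensitivity()]; the earliest success wins and ends screening for that
#' tumor. If no screen detection occurs before the clinical surfacing age and
#' the woman is alive then, the tumor is detected clinically at surfacing.
#' No detection is attempted at or after death (`min(age_bca_death,
#' age_other_death)`). Menopausal status at an exam is `exam age >=
#' menopause_age`. Exams after metastasis are still administered (a detection
#' then is recorded but carries no screen-PLL benefit).
#'
#' Per-exam Bernoulli draws sit on a substream keyed by
#' `(master_seed, woman id, exam age)`, so adding or removing exams from a
#' schedule never changes the draws at shared exam ages - schedules can be
#' compared with common random numbers, and adding an exam can never delay
#' detection.
#'
#' A co-existing non-progressive reservoir tumor is screened with its own
#' draw substream; its detection is recorded as overdiagnosis and does not
#' interact with the progressive tumor's screening.
#'
#' @param h a one-row history data frame from [simulate_natural_history()].
#' @param exams exam ages in whole years, from [schedule_exams()].
#' @param p a [model_params()] object.
#' @param master_seed integer master seed (must match the history's).
#' @return a one-row data frame: `id`, `mode` (`"screen"`, `"clinical"` or
#'   `"none"`), `age_detect` (months, `NA` when mode is `"none"`),
#'   `np_detected` (overdiagnosis flag), `np_age_detect`, and `n_exams`
#'   (exams actually administered).
#' @export
apply_screening <- function(h, exams, p, master_seed = 1L) {
  apply_screening_cohort(h, exams, p, master_seed)
}

# scalar detection walk for one tumor; returns the detection month or NA
.screen_walk <- function(id, age_fmc, alpha, exam_mo, stop_before_mo,
                         death_mo, p, master_seed, purpose) {
  g <- growth_curve(alpha, p$d_cell, p$d_max)
  log_dcdm <- log(p$d_cell / p$d_max)
  for (m in exam_mo) {
    if (m >= stop_before_mo || m >= death_mo) break
    if (m < age_fmc) next
    d <- p$d_max * exp(log_dcdm * exp(-alpha * (m - age_fmc)))
    if (d < p$d_detect) next
    s_max <- if ((m / 12) >= p$menopause_age) p$sens_max_post else p$sens_max_pre
    s <- s_max * stats::plogis(p$sens_slope * (log(d) - log(p$sens_mid)))
    set.seed(substream_seed(master_seed, id, purpose, m))
    if (stats::runif(1) < s) return(m)
  }
  NA_real_
}

#' Apply a screening schedule to a cohort of histories
#'
#' Vector-friendly form of [apply_screening()]; accepts one or many history
#' rows.
#'
#' @param histories cohort data frame from [simulate_cohort()].
#' @param exams exam ages in whole years.
#' @param p a [model_params()] object.
#' @param master_seed integer master seed used for the histories.
#' @return a data frame with one row per woman; see [apply_screening()].
#' @export
apply_screening_cohort <- function(histories, exams, p, master_seed = 1L) {
  exam_mo <- exams * 12
  n <- nrow(histories)
  death_mo <- pmin(ifelse(is.na(histories$age_bca_death), Inf,
                          histories$age_bca_death),
                   histories$age_other_death)
  mode <- rep("none", n)
  age_detect <- rep(NA_real_, n)
  np_detected <- logical(n)
  np_age_detect <- rep(NA_real_, n)
  n_exams <- integer(n)

  for (k in seq_len(n)) {
    if (histories$has_tumor[k]) {
      m <- .screen_walk(histories$id[k], histories$age_fmc[k],
                        histories$alpha[k], exam_mo,
                        histories$age_surface[k], death_mo[k],
                        p, master_seed, .PUR$exam)
      if (!is.na(m)) {
        mode[k] <- "screen"
        age_detect[k] <- m
      } else if (histories$age_surface[k] < death_mo[k]) {
        mode[k] <- "clinical"
        age_detect[k] <- histories$age_surface[k]
      }
    }
    if (histories$has_np[k]) {
      m <- .screen_walk(histories$id[k], histories$np_age_fmc[k],
                        histories$np_alpha[k], exam_mo, Inf, death_mo[k],
                        p, master_seed, .PUR$np_exam)
      if (!is.na(m)) {
        np_detected[k] <- TRUE
        np_age_detect[k] <- m
      }
    }
    stop_mo <- min(death_mo[k], if (!is.na(age_detect[k])) age_detect[k] else Inf)
    n_exams[k] <- sum(exam_mo < stop_mo)
  }

  data.frame(id = histories$id, mode = mode, age_detect = age_detect,
             np_detected = np_detected, np_age_detect = np_age_detect,
             n_exams = n_exams)
}
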