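# Period life tables: validation, I/O, life expectancy and death-age sampling.

#' Construct a period life table
#'
#' A life table holds, for each integer age, the conditional probability `qx`
#' of dying within the year given survival to that age. Ages must be
#' contiguous from 0 and the final age is absorbing (`qx = 1`), so every
#' simulated woman dies at or before `max_age + 1`.
#'
#' @param age integer vector of ages, contiguous from 0.
#' @param qx conditional one-year death probabilities in `[0, 1]`.
#' @return an object of class `life_table` (a data frame with columns
#'   `age`, `qx`) with attribute `max_age`.
#' @examples
#' lt <- life_table(0:100, c(rep(0.01, 100), 1))
#' life_expectancy(lt, 65)
#' @export
life_table <- function(age, qx) {
  lt <- data.frame(age = as.integer(age), qx = as.numeric(qx))
  validate_life_table(lt)
  lt$qx[nrow(lt)] <- 1 # force absorbing final row
  structure(lt, class = c("life_table", "data.frame"),
            max_age = lt$age[nrow(lt)])
}

#' @rdname life_table
#' @param lt a candidate life table data frame.
#' @export
validate_life_table <- function(lt) {
  if (!all(c("age", "qx") %in% names(lt))) {
    stop("life table must have columns 'age' and 'qx'", call. = FALSE)
  }
  if (nrow(lt) < 2) stop("life table needs at least two ages", call. = FALSE)
  if (!identical(as.integer(lt$age), seq.int(0L, nrow(lt) - 1L))) {
    bad <- which(as.integer(lt$age) != seq.int(0L, nrow(lt) - 1L))[1]
    stop(sprintf("life table ages must be contiguous from 0; problem at row %d (age %s)",
                 bad, lt$age[bad]), call. = FALSE)
  }
  out <- which(!is.finite(lt$qx) | lt$qx < 0 | lt$qx > 1)
  if (length(out)) {
    stop(sprintf("life table qx outside [0, 1] at age %d (qx = %g)",
                 lt$age[out[1]], lt$qx[out[1]]), call. = FALSE)
  }
  invisible(lt)
}

#' Read / write a life table CSV
#'
#' The CSV format has header `age,qx`, one row per age contiguous from 0.
#' The final row is forced absorbing on read. Values are written with full
#' precision so a write/read cycle reproduces the table exactly.
#'
#' @param path file path.
#' @return `load_life_table` returns a validated [life_table];
#'   `write_life_table` returns `path` invisibly.
#' @export
load_life_table <- function(path) {
  df <- utils::read.csv(path, colClasses = c(age = "integer", qx = "numeric"))
  life_table(df$age, df$qx)
}

#' @rdname load_life_table
#' @param lt a [life_table].
#' @export
write_life_table <- function(lt, path) {
  df <- data.frame(age = lt$age, qx = sprintf("%.17g", lt$qx))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remaining life expectancy at an age
#'
#' Computed from the life table by survival-product summation: the curtate
#' expectation (expected whole years remaining) plus half a year, the
#' standard deaths-mid-year correction. At the absorbing age it equals 0.5.
#'
#' @param lt a [life_table].
#' @param age integer age, `0 <= age <= max_age`.
#' @return remaining life expectancy in years.
#' @export
life_expectancy <- function(lt, age) {
  max_age <- attr(lt, "max_age")
  if (length(age) != 1 || !is.finite(age) || age < 0 || age > max_age) {
    stop(sprintf("age must be a single value in [0, %d]", max_age), call. = FALSE)
  }
  age <- as.integer(age)
  surv <- cumprod(1 - lt$qx[(age + 1):nrow(lt)])
  sum(surv) + 0.5
}

#' Sample an other-cause death age from a life table
#'
#' Walks the table year by year with a Bernoulli(qx) draw per year; the death
#' is placed uniformly within the death year. Because the final age is
#' absorbing, a death age is always produced. Draw count is fixed (one
#' uniform per age plus one for placement) so the consuming RNG stream
#' position does not depend on the outcome.
#'
#' @param lt a [life_table].
#' @return death age in fractional years, in `[0, max_age + 1)`. Uses the
#'   session RNG; seed a substream before calling for reproducibility.
#' @export
sample_death_age <- function(lt) {
  u <- stats::runif(nrow(lt))
  frac <- stats::runif(1)
  idx <- which(u < lt$qx)[1]
  (idx - 1) + frac
}
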