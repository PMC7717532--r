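# Age-specific clinical incidence tables.

#' Construct an age-specific clinical incidence table
#'
#' Holds the clinical breast-cancer incidence rate, per 100,000 woman-years,
#' for each integer age contiguous from 0. The simulator treats each rate as
#' a per-year surfacing probability (rate / 1e5), applied to every woman
#' regardless of vital status; competing risks are resolved at evaluation
#' time, not during sampling, so strategy arms can share draws.
#'
#' @param age integer ages, contiguous from 0.
#' @param rate_per_100k non-negative incidence rates per 100,000 woman-years.
#' @return an object of class `incidence_table` (data frame with columns
#'   `age`, `rate_per_100k`) with attribute `max_age`.
#' @export
incidence_table <- function(age, rate_per_100k) {
  it <- data.frame(age = as.integer(age),
                   rate_per_100k = as.numeric(rate_per_100k))
  validate_incidence_table(it)
  structure(it, class = c("incidence_table", "data.frame"),
            max_age = it$age[nrow(it)])
}

#' @rdname incidence_table
#' @param it a candidate incidence table data frame.
#' @export
validate_incidence_table <- function(it) {
  if (!all(c("age", "rate_per_100k") %in% names(it))) {
    stop("incidence table must have columns 'age' and 'rate_per_100k'",
         call. = FALSE)
  }
  if (!identical(as.integer(it$age), seq.int(0L, nrow(it) - 1L))) {
    bad <- which(as.integer(it$age) != seq.int(0L, nrow(it) - 1L))[1]
    stop(sprintf("incidence ages must be contiguous from 0; problem at row %d (age %s)",
                 bad, it$age[bad]), call. = FALSE)
  }
  out <- which(!is.finite(it$rate_per_100k) | it$rate_per_100k < 0 |
                 it$rate_per_100k > 1e5)
  if (length(out)) {
    stop(sprintf("incidence rate out of range at age %d (rate = %g)",
                 it$age[out[1]], it$rate_per_100k[out[1]]), call. = FALSE)
  }
  invisible(it)
}

#' Read / write an incidence table CSV
#'
#' Header `age,rate_per_100k`, one row per age contiguous from 0. Written
#' with full precision so write/read round-trips exactly.
#'
#' @param path file path.
#' @return `load_incidence_table` returns a validated [incidence_table];
#'   `write_incidence_table` returns `path` invisibly.
#' @export
load_incidence_table <- function(path) {
  df <- utils::read.csv(path, colClasses = c(age = "integer",
                                             rate_per_100k = "numeric"))
  incidence_table(df$age, df$rate_per_100k)
}

#' @rdname load_incidence_table
#' @param it an [incidence_table].
#' @export
write_incidence_table <- function(it, path) {
  df <- data.frame(age = it$age,
                   rate_per_100k = sprintf("%.17g", it$rate_per_100k))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
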