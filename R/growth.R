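# Gompertzian tumor growth: diameter as a function of time since the first
# malignant cell, and its closed-form inverse.

#' Per-woman Gompertz growth curve
#'
#' Diameter grows from `d_cell` at time 0 toward the asymptote `d_max`:
#' `d(t) = d_max * exp(log(d_cell / d_max) * exp(-alpha t))`.
#' The curve is strictly increasing and never reaches `d_max`.
#'
#' @param alpha Gompertz rate, 1/month; must be > 0.
#' @param d_cell diameter of the first malignant cell, cm.
#' @param d_max asymptotic diameter, cm.
#' @return an object of class `growth_curve`.
#' @export
growth_curve <- function(alpha, d_cell = 0.01, d_max = 12.8) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (!(d_cell > 0 && d_cell < d_max)) {
    stop("require 0 < d_cell < d_max", call. = FALSE)
  }
  structure(list(alpha = alpha, d_cell = d_cell, d_max = d_max),
            class = "growth_curve")
}

#' Tumor diameter at a time since the first malignant cell
#'
#' @param g a [growth_curve].
#' @param t months since the first malignant cell; vectorized, all `>= 0`.
#' @return diameter(s) in cm, in `[d_cell, d_max)`.
#' @export
diameter_at <- function(g, t) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  g$d_max * exp(log(g$d_cell / g$d_max) * exp(-g$alpha * t))
}

#' Months for the tumor to grow from the first malignant cell to a diameter
#'
#' Closed-form inverse of [diameter_at()]:
#' `t(d) = -log(log(d / d_max) / log(d_cell / d_max)) / alpha`.
#'
#' @param g a [growth_curve].
#' @param d target diameter(s), cm; must satisfy `d_cell <= d < d_max`
#'   (the asymptote is unreachable).
#' @return months since the first malignant cell.
#' @export
time_to_diameter <- function(g, d) {
  if (any(d < g$d_cell | d >= g$d_max)) {
    stop(sprintf("d must be in [d_cell, d_max) = [%g, %g)", g$d_cell, g$d_max),
         call. = FALSE)
  }
  -log(log(d / g$d_max) / log(g$d_cell / g$d_max)) / g$alpha
}
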