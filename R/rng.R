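# Deterministic substream seeding.
#
# Every random draw in the simulator comes from a substream whose seed is a
# hash of (master seed, woman id, purpose code, ...). Substreams make cohorts
# order-independent and let screening strategies share natural-history draws
# (common random numbers): two runs with the same master seed give the same
# woman the same disease timeline no matter which strategy, cohort size or
# evaluation order is used.

# purpose codes, one per independent draw family
.PUR <- list(
  other_death  = 1L,
  onset        = 2L,
  growth       = 3L,
  met_threshold = 4L,
  met_survival = 5L,
  np_onset     = 6L,
  np_growth    = 7L,
  exam         = 8L,
  np_exam      = 9L
)

.SEED_MOD <- 2147483629 # largest prime < 2^31; keeps seeds valid R integers

#' Derive a reproducible substream seed from integer keys
#'
#' Folds a sequence of integer keys (master seed, woman index, purpose code,
#' exam month, ...) into a single seed in `[1, 2^31 - 2]` by iterated modular
#' multiply-add. All arithmetic stays below 2^53 so it is exact in doubles.
#'
#' @param ... integer-valued keys.
#' @return a single integer seed suitable for [set.seed()].
#' @keywords internal
substream_seed <- function(...) {
  keys <- c(...)
  stopifnot(length(keys) >= 1, all(is.finite(keys)))
  h <- 17
  for (k in keys) {
    h <- (h * 69069 + (k %% .SEED_MOD)) %% .SEED_MOD
  }
  as.integer(h + 1)
}
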