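#' Derive a module-level seed from a global seed
#'
#' A single global seed is expanded into per-module seeds by a fixed counter
#' scheme, so any pipeline stage can be re-run in isolation and still produce
#' the stream it would have seen inside a full run. The scheme is
#' `(seed mod 21000) * 100003 + 131 * module_offset + index`, kept inside the
#' 32-bit integer range accepted by [set.seed()]; the stride between
#' consecutive global seeds far exceeds any per-run counter range, so
#' cohorts generated from different seeds never share a stream.
#'
#' @param seed integer global seed.
#' @param module character, one of the registered module names.
#' @param index nonnegative integer counter (e.g. subject number) for repeated
#'   draws within a module.
#' @return an integer usable with [set.seed()].
#' @export
module_seed <- function(seed, module, index = 0L) {
  offsets <- c(
    design = 1L, schedule = 2L, recall_trials = 3L, dnms_trials = 4L,
    reinstatement = 5L, dnms_responses = 6L, recall_responses = 7L,
    memory_test = 8L, pattern_bank = 9L, localizer = 10L, bold = 11L,
    bootstrap = 12L, permutation = 13L, cohort = 14L
  )
  if (!module %in% names(offsets)) {
    stop("unknown module name: ", module)
  }
  base <- (as.integer(seed) %% 21000L) * 100003L
  (base + 131L * offsets[[module]] + as.integer(index)) %% 2147483647L
}
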