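#' Generative parameters for the behavioural and BOLD simulators
#'
#' Bundles every tunable of the synthetic cohort. Defaults are calibrated so
#' that a default DNMS cohort reproduces the probe-type zRT separation seen in
#' behavioural data (lure slowest, target fastest), and so that recall error
#' rates rise from near zero (no distraction) through partial to full
#' distraction. See the methods vignette for the calibration arithmetic.
#'
#' @param rt_mu_ms grand-mean reaction time, ms.
#' @param rt_subject_sd_ms SD of the Gaussian per-subject RT intercept, ms.
#' @param rt_resid_sd_ms residual RT SD, ms (additive Gaussian on the ms scale).
#' @param beta_target,beta_lure,beta_other probe-type RT offsets, ms.
#' @param gamma_probe RT slowing per unit of delay-period probe-context
#'   reinstatement on mismatch trials, ms per evidence unit.
#' @param gamma_nonprobe RT speeding per unit of mean nonprobe-context
#'   delay reinstatement, ms per evidence unit.
#' @param reinstatement_baseline baseline context intensity, in [0,1].
#' @param reinstatement_boost additional intensity for the target-set context,
#'   in [0,1]; the delay-period boost is scaled by the subject's
#'   `memory_strength`.
#' @param reinstatement_noise_sd SD of the Gaussian intensity noise.
#' @param memory_strength latent context-learning strength in [0,1]; scales
#'   the delay-period target-context boost.
#' @param accuracy probability that a DNMS response is correct.
#' @param timeout_ms response deadline; slower responses become no-responses.
#' @param recall_error_rate named per-condition probability that a target word
#'   is replaced by a substitution error during free recall.
#' @param error_weights mixture weights (previous_target, same_context, other)
#'   for the substitution-error word; nonnegative, summing to 1.
#' @param pi_mem probability that a word's context is genuinely remembered in
#'   the posttask memory test (guessing uniform over 4 contexts otherwise);
#'   the default puts group accuracy near 41% observed in scanned cohorts.
#' @return a list of class `generative_params`.
#' @export
generative_params <- function(rt_mu_ms = 1000,
                              rt_subject_sd_ms = 100,
                              rt_resid_sd_ms = 150,
                              beta_target = -12.5,
                              beta_lure = 9.25,
                              beta_other = -5.8,
                              gamma_probe = 35,
                              gamma_nonprobe = 20,
                              reinstatement_baseline = 0.2,
                              reinstatement_boost = 0.25,
                              reinstatement_noise_sd = 0.08,
                              memory_strength = 1,
                              accuracy = 0.95,
                              timeout_ms = 4000,
                              recall_error_rate = c(none = 0.015,
                                                    "break" = 0.07,
                                                    full = 0.14),
                              error_weights = c(previous_target = 0.45,
                                                same_context = 0.30,
                                                other = 0.25),
                              pi_mem = 0.216) {
  w <- error_weights
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop("error_weights must be nonnegative and sum to 1")
  }
  stopifnot(rt_subject_sd_ms >= 0, rt_resid_sd_ms >= 0,
            reinstatement_noise_sd >= 0,
            memory_strength >= 0, memory_strength <= 1,
            accuracy >= 0, accuracy <= 1, pi_mem >= 0, pi_mem <= 1)
  names(recall_error_rate) <- c("none", "break", "full")
  names(w) <- c("previous_target", "same_context", "other")
  structure(
    list(rt_mu_ms = rt_mu_ms, rt_subject_sd_ms = rt_subject_sd_ms,
         rt_resid_sd_ms = rt_resid_sd_ms,
         beta_target = beta_target, beta_lure = beta_lure,
         beta_other = beta_other,
         gamma_probe = gamma_probe, gamma_nonprobe = gamma_nonprobe,
         reinstatement_baseline = reinstatement_baseline,
         reinstatement_boost = reinstatement_boost,
         reinstatement_noise_sd = reinstatement_noise_sd,
         memory_strength = memory_strength,
         accuracy = accuracy, timeout_ms = timeout_ms,
         recall_error_rate = recall_error_rate,
         error_weights = w, pi_mem = pi_mem),
    class = "generative_params"
  )
}

#' Null generative parameters
#'
#' All planted effects zeroed: no probe-type RT offsets, no
#' reinstatement-context boost, no evidence-to-RT coupling, equal
#' substitution-error rates across distraction conditions, and
#' chance-matched substitution-error mixture weights (4/68, 8/68, 56/68 for
#' the 6-set, 12-word free-recall design). Useful for type-I-error
#' calibration of the downstream tests.
#'
#' @param ... overrides passed on to [generative_params()].
#' @return a `generative_params` object.
#' @export
null_params <- function(...) {
  args <- list(
    beta_target = 0, beta_lure = 0, beta_other = 0,
    gamma_probe = 0, gamma_nonprobe = 0,
    reinstatement_boost = 0,
    recall_error_rate = c(none = 0.07, "break" = 0.07, full = 0.07),
    error_weights = c(previous_target = 4 / 68, same_context = 8 / 68,
                      other = 56 / 68)
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(generative_params, args)
}
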