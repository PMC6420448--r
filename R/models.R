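#' Fit a random-intercept linear mixed model
#'
#' REML fit of a Gaussian linear model with a random intercept per subject,
#' via [lme4::lmer()]. Fixed effects are reported with Wald 95% confidence
#' intervals. p-values use a normal approximation to the Wald statistic by
#' default; with `df_method = "satterthwaite"` (requires the lmerTest
#' package) Satterthwaite degrees of freedom are used instead.
#'
#' @param data a model table; one row per accurate, responded trial.
#' @param fixed right-hand-side formula of fixed effects, e.g.
#'   `~ ev_probe_delay * overlap`.
#' @param response response column name (default `"rt_ms"`).
#' @param subject grouping column name (default `"subject"`).
#' @param df_method `"normal"` or `"satterthwaite"`.
#' @return object of class `ri_fit`: `coefficients` (data.frame term,
#'   estimate, se, ci_low, ci_high, p), `sigma_subject`, `sigma_resid`,
#'   `n_trials`, `n_subjects`, `converged`, `formula`, and the underlying
#'   `fit`.
#' @export
fit_random_intercept_lm <- function(data, fixed, response = "rt_ms",
                                    subject = "subject",
                                    df_method = c("normal", "satterthwaite")) {
  df_method <- match.arg(df_method)
  if (length(unique(data[[subject]])) < 2L) stop("need >= 2 subjects")
  rhs <- paste(deparse(fixed[[length(fixed)]]), collapse = " ")
  mm <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = data)
  if (qr(mm)$rank < ncol(mm)) {
    stop("fixed-effect design matrix is rank deficient")
  }
  form <- stats::as.formula(
    paste(response, "~", rhs, "+ (1 |", subject, ")"))
  fit <- if (df_method == "satterthwaite") {
    if (!requireNamespace("lmerTest", quietly = TRUE)) {
      stop("df_method = 'satterthwaite' requires the lmerTest package")
    }
    lmerTest::lmer(form, data = data, REML = TRUE)
  } else {
    lme4::lmer(form, data = data, REML = TRUE)
  }
  converged <- length(fit@optinfo$conv$lme4$messages) == 0L
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- beta / se
  p <- if (df_method == "satterthwaite") {
    stats::coef(summary(fit))[, "Pr(>|t|)"]
  } else {
    2 * stats::pnorm(-abs(z))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  coefs <- data.frame(
    term = names(beta), estimate = unname(beta), se = unname(se),
    ci_low = unname(beta - stats::qnorm(0.975) * se),
    ci_high = unname(beta + stats::qnorm(0.975) * se),
    p = unname(p), stringsAsFactors = FALSE)
  structure(
    list(coefficients = coefs,
         sigma_subject = vc$sdcor[vc$grp == subject],
         sigma_resid = vc$sdcor[vc$grp == "Residual"],
         n_trials = nrow(data),
         n_subjects = length(unique(data[[subject]])),
         converged = converged, formula = form, df_method = df_method,
         fit = fit),
    class = "ri_fit"
  )
}

#' @export
print.ri_fit <- function(x, digits = 3, ...) {
  cat("Random-intercept linear mixed model (REML):\n  ",
      deparse(x$formula), "\n")
  cat(sprintf("  %d trials, %d subjects; subject SD = %.1f, residual SD = %.1f%s\n",
              x$n_trials, x$n_subjects, x$sigma_subject, x$sigma_resid,
              if (x$converged) "" else "  [convergence warning]"))
  tab <- x$coefficients
  tab$estimate <- round(tab$estimate, digits)
  tab$se <- round(tab$se, digits)
  tab$ci_low <- round(tab$ci_low, digits)
  tab$ci_high <- round(tab$ci_high, digits)
  tab$p <- signif(tab$p, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ri_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
summary.ri_fit <- function(object, ...) object$coefficients

# accurate, responded trials with probe_type as a factor (reference "other")
model_ready <- function(table) {
  keep <- !is.na(table$rt_ms)
  if (!is.null(table$accurate)) keep <- keep & table$accurate
  out <- table[keep, , drop = FALSE]
  out$probe_type <- factor(out$probe_type)
  if ("other" %in% levels(out$probe_type)) {
    out$probe_type <- stats::relevel(out$probe_type, ref = "other")
  }
  out
}

#' Model 1: does target-context memory modulate probe-type RT effects?
#'
#' `RT ~ 1 + TargetMemoryScore * TrialType + (1 | Subject)` on accurate,
#' responded trials of all three probe types. Trial type uses treatment
#' coding with the other-context probe as reference; the memory score is the
#' raw 0-4 count of target words whose context was correctly identified.
#'
#' @param table model table with `subject`, `rt_ms`, `probe_type`,
#'   `target_memory_score`, `accurate`.
#' @param ... passed to [fit_random_intercept_lm()].
#' @return an `ri_fit`.
#' @export
model1 <- function(table, ...) {
  tab <- model_ready(table)
  if (length(unique(tab$probe_type)) < 3L) {
    stop("all three probe types must be present")
  }
  fit_random_intercept_lm(tab, ~ target_memory_score * probe_type, ...)
}

#' Model 2: does period-wise probe-context reinstatement predict RT?
#'
#' `RT ~ 1 + ProbeContextReinstatement(TargetsPresentation) +
#' ProbeContextReinstatement(Delay) + ProbeContextReinstatement(Probe) +
#' (1 | Subject)`, fitted separately per probe type on accurate, responded
#' trials. With `evidence_source = "nonprobe"` the mean nonprobe-context
#' evidence replaces probe-context evidence in all three periods (this is
#' the variant that shows nonmisleading reinstatement speeding responses).
#'
#' @param table model table with the evidence scalar columns
#'   (`ev_probe_*` / `ev_nonprobe_*` for the three periods).
#' @param probe_type which trial type to fit (default `"lure"`).
#' @param evidence_source `"probe"` or `"nonprobe"`.
#' @param ... passed to [fit_random_intercept_lm()].
#' @return an `ri_fit`.
#' @export
model2 <- function(table, probe_type = "lure",
                   evidence_source = c("probe", "nonprobe"), ...) {
  evidence_source <- match.arg(evidence_source)
  tab <- model_ready(table)
  tab <- tab[tab$probe_type == probe_type, , drop = FALSE]
  prefix <- paste0("ev_", evidence_source, "_")
  terms <- paste0(prefix, c("target_presentation", "delay",
                            "probe_presentation"))
  missing_cols <- setdiff(terms, names(tab))
  if (length(missing_cols)) {
    stop("model table lacks evidence columns: ",
         paste(missing_cols, collapse = ", "))
  }
  for (cn in terms) {
    if (stats::sd(tab[[cn]]) == 0) stop("constant evidence column: ", cn)
  }
  fit_random_intercept_lm(
    tab, stats::as.formula(paste("~", paste(terms, collapse = " + "))), ...)
}

#' Model 3: does probe-target overlap amplify the reinstatement effect?
#'
#' `RT ~ 1 + ProbeContextReinstatement(Delay) * Overlap + (1 | Subject)` on
#' accurate, responded lure trials. Overlap (the count of learning-phase
#' probe-target co-presentations) enters uncentered, so the main effects are
#' interpretable at overlap zero.
#'
#' @param table model table with `ev_probe_delay` and `overlap` columns.
#' @param ... passed to [fit_random_intercept_lm()].
#' @return an `ri_fit`.
#' @export
model3 <- function(table, ...) {
  tab <- model_ready(table)
  tab <- tab[tab$probe_type == "lure", , drop = FALSE]
  if (stats::sd(tab$overlap) == 0) stop("overlap has zero variance")
  fit_random_intercept_lm(tab, ~ ev_probe_delay * overlap, ...)
}
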