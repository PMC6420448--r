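#' Apply DNMS exclusion rules
#'
#' Removes (a) whole subjects whose accuracy is strictly below
#' `chance_accuracy` — a constant-"mismatch" responder is correct on 2/3 of
#' trials, so that is the chance baseline — and (b) no-response (timeout)
#' trials, which have no RT. Inaccurate trials are flagged (`included =
#' FALSE`, reason `"inaccurate"`) and so drop out of RT analyses, but remain
#' in the table for accuracy summaries.
#'
#' @param trials pooled trial table with columns `subject`, `response`,
#'   `rt_ms`, `accurate` (e.g. `simulate_dnms_cohort(...)$trials`).
#' @param chance_accuracy exclusion threshold (default 2/3).
#' @return list with `trials` (input plus `included`, `exclusion_reason`
#'   columns, subject-excluded rows removed), `excluded_subjects` (data.frame
#'   subject, accuracy) and `n_timeout_trials`.
#' @export
apply_exclusions <- function(trials, chance_accuracy = 2 / 3) {
  acc <- tapply(trials$accurate, trials$subject, mean)
  bad_subjects <- as.integer(names(acc)[acc < chance_accuracy])
  excluded_subjects <- data.frame(subject = bad_subjects,
                                  accuracy = as.numeric(acc[as.character(bad_subjects)]))
  keep <- !(trials$subject %in% bad_subjects)
  out <- trials[keep, , drop = FALSE]
  timeout <- out$response == "none"
  out$included <- !timeout & out$accurate
  out$exclusion_reason <- ifelse(timeout, "no_response",
                                 ifelse(out$accurate, NA_character_,
                                        "inaccurate"))
  n_timeout <- sum(timeout)
  out <- out[!timeout, , drop = FALSE]
  list(trials = out, excluded_subjects = excluded_subjects,
       n_timeout_trials = n_timeout)
}

#' Within-subject z-scored log reaction times
#'
#' Natural-log-transforms RTs and standardizes them within subject over the
#' included trials (sample SD, denominator n-1), so that every subject's
#' included zRTs have mean 0 and SD 1. Subjects with fewer than 2 included
#' trials or zero log-RT variance are flagged and their zRTs left `NA`.
#'
#' @param trials trial table with `subject`, `rt_ms` and (optionally)
#'   `included`; rows with `included = FALSE` get `NA` zRT and do not enter
#'   the standardization.
#' @return the table with added `log_rt` and `zrt` columns; attribute
#'   `degenerate_subjects` lists subjects that could not be standardized.
#' @export
zscore_log_rt <- function(trials) {
  if (is.null(trials$included)) trials$included <- !is.na(trials$rt_ms)
  trials$log_rt <- ifelse(trials$included, log(trials$rt_ms), NA_real_)
  trials$zrt <- NA_real_
  degenerate <- integer(0)
  for (s in unique(trials$subject)) {
    idx <- which(trials$subject == s & trials$included)
    x <- trials$log_rt[idx]
    if (length(x) < 2L || stats::sd(x) == 0) {
      degenerate <- c(degenerate, s)
      next
    }
    trials$zrt[idx] <- (x - mean(x)) / stats::sd(x)
  }
  attr(trials, "degenerate_subjects") <- degenerate
  trials
}

# per-subject mean zrt by probe type, wide format
subject_condition_means <- function(trials, value = "zrt") {
  ok <- trials$included & !is.na(trials[[value]])
  agg <- stats::aggregate(trials[ok, value, drop = FALSE],
                          by = list(subject = trials$subject[ok],
                                    probe_type = trials$probe_type[ok]),
                          FUN = mean)
  wide <- stats::reshape(agg, idvar = "subject", timevar = "probe_type",
                         direction = "wide")
  names(wide) <- sub(paste0("^", value, "\\."), "", names(wide))
  wide
}

#' Probe-type reaction-time contrasts
#'
#' Paired two-sided t tests on per-subject mean zRT (or raw RT) for the three
#' probe-type pairs: target vs lure, lure vs other, target vs other.
#' Subjects missing any of the three condition means are dropped.
#'
#' @param trials output of [zscore_log_rt()].
#' @param value column to contrast (default `"zrt"`).
#' @return list with `contrasts` (data.frame pair, mean_diff, t, df, p),
#'   `condition_means` (group mean and SD per probe type) and `n_subjects`.
#' @export
probe_type_contrasts <- function(trials, value = "zrt") {
  wide <- subject_condition_means(trials, value)
  complete <- stats::complete.cases(wide[, c("target", "lure", "other")])
  wide <- wide[complete, , drop = FALSE]
  if (nrow(wide) < 2L) stop("need >= 2 subjects with all three probe types")
  pairs <- list(c("target", "lure"), c("lure", "other"), c("target", "other"))
  contrasts <- do.call(rbind, lapply(pairs, function(pr) {
    d <- wide[[pr[1]]] - wide[[pr[2]]]
    if (stats::sd(d) == 0) {
      tt <- list(statistic = 0, parameter = length(d) - 1L, p.value = 1)
    } else {
      tt <- stats::t.test(wide[[pr[1]]], wide[[pr[2]]], paired = TRUE)
    }
    data.frame(pair = paste(pr, collapse = "_vs_"),
               mean_diff = mean(d), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  condition_means <- data.frame(
    probe_type = c("target", "lure", "other"),
    mean = vapply(c("target", "lure", "other"),
                  function(cn) mean(wide[[cn]]), numeric(1)),
    sd = vapply(c("target", "lure", "other"),
                function(cn) stats::sd(wide[[cn]]), numeric(1))
  )
  list(contrasts = contrasts, condition_means = condition_means,
       n_subjects = nrow(wide))
}

#' Split trials by posttask target-context memory
#'
#' Labels each trial "learned" when more than half of its target words had
#' their encoding context correctly identified in the posttask memory test
#' (score 3 or 4 out of 4), then runs the lure-vs-other zRT contrast within
#' each subset.
#'
#' @param trials output of [zscore_log_rt()] with a `target_memory_score`
#'   column (0-4 count of correctly assigned target words per trial).
#' @return list with `learned`, `unlearned` (the subset tables) and
#'   `contrasts` (lure-vs-other paired t within each subset, `NULL` when a
#'   subset has too few subjects).
#' @export
split_by_target_memory <- function(trials) {
  if (is.null(trials$target_memory_score)) {
    stop("trials must carry a target_memory_score column")
  }
  ok <- !is.na(trials$target_memory_score)
  trials <- trials[ok, , drop = FALSE]
  learned <- trials[trials$target_memory_score / 4 > 0.5, , drop = FALSE]
  unlearned <- trials[trials$target_memory_score / 4 <= 0.5, , drop = FALSE]
  lure_other <- function(tab) {
    res <- tryCatch(probe_type_contrasts(tab), error = function(e) NULL)
    if (is.null(res)) return(NULL)
    res$contrasts[res$contrasts$pair == "lure_vs_other", , drop = FALSE]
  }
  list(learned = learned, unlearned = unlearned,
       contrasts = list(learned = lure_other(learned),
                        unlearned = lure_other(unlearned)))
}
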