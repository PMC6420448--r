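#' Score a free-recall response
#'
#' Counts correctly recalled targets and collects substitution errors.
#' Tokens not in the experiment's vocabulary are dropped (and returned in
#' `out_of_vocabulary`) rather than scored, since substitutions are defined
#' over learned words only.
#'
#' @param trial one row of a [generate_recall_trials()] table.
#' @param response_words character vector of transcribed response words.
#' @param design the [build_design()] the trial came from.
#' @return list with `n_correct` (0-4), `errors` (in-vocabulary non-target
#'   words) and `out_of_vocabulary` (dropped tokens).
#' @export
score_recall <- function(trial, response_words, design) {
  targets <- as.character(word_matrix(trial)[1L, ])
  vocab <- design$words$word_id
  in_vocab <- response_words %in% vocab
  resp <- unique(response_words[in_vocab])
  list(
    n_correct = length(intersect(resp, targets)),
    errors = setdiff(resp, targets),
    out_of_vocabulary = unique(response_words[!in_vocab])
  )
}

#' Categorize a substitution error
#'
#' An erroneous word is a `previous_target` if it was a target on the
#' immediately preceding recall trial, otherwise a `same_context` word if it
#' belongs to the current trial's context set, otherwise `other`. With the
#' generator's consecutive-context constraint the first two categories are
#' mutually exclusive; `previous_target` takes precedence if a degenerate
#' trial sequence ever made both true.
#'
#' @param word the substituted word identifier.
#' @param trial current recall-trial row.
#' @param prev_trial previous recall-trial row, or `NULL` for the first trial.
#' @param design the design.
#' @return one of `"previous_target"`, `"same_context"`, `"other"`.
#' @export
categorize_error <- function(word, trial, prev_trial, design) {
  targets <- as.character(word_matrix(trial)[1L, ])
  if (!word %in% design$words$word_id) stop("word not in vocabulary: ", word)
  if (word %in% targets) stop("word is a current target, not an error: ", word)
  if (!is.null(prev_trial) &&
      word %in% as.character(word_matrix(prev_trial)[1L, ])) {
    return("previous_target")
  }
  if (word %in% set_words(design, trial$context_id)) {
    return("same_context")
  }
  "other"
}

#' Score and categorize a whole recall session
#'
#' @param trials a [generate_recall_trials()] table.
#' @param responses list of response-word vectors, one per trial (e.g. from
#'   [simulate_recall()]).
#' @param design the design.
#' @param subject optional subject label attached to the output.
#' @return data.frame with one row per error: `subject`, `trial`,
#'   `condition`, `word_id`, `category`; attribute `n_correct` holds the
#'   per-trial correct counts.
#' @export
score_recall_session <- function(trials, responses, design, subject = 1L) {
  stopifnot(length(responses) == nrow(trials))
  rows <- list()
  n_correct <- integer(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    sc <- score_recall(trials[i, ], responses[[i]], design)
    n_correct[i] <- sc$n_correct
    prev <- if (i == 1L) NULL else trials[i - 1L, ]
    for (w in sc$errors) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject, trial = trials$trial[i],
        condition = trials$condition[i], word_id = w,
        category = categorize_error(w, trials[i, ], prev, design),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject = integer(0), trial = integer(0),
               condition = character(0), word_id = character(0),
               category = character(0), stringsAsFactors = FALSE)
  attr(out, "n_correct") <- n_correct
  out
}

#' Bootstrap chance null for categorized substitution errors
#'
#' Tests whether a category of substitution errors is over-represented
#' relative to uniform substitution. Each bootstrap iteration replaces every
#' subject's observed errors with the same number of uniform draws from the
#' pool of `total_pool` candidate non-target words, counts how many land in
#' the category of interest (pool size `k`), and averages the counts across
#' subjects. The one-sided p-value is `(1 + #{null >= observed}) / (B + 1)`.
#'
#' @param errors_per_subject integer vector: each subject's total error count
#'   (in one condition).
#' @param observed_per_subject integer vector: each subject's observed count
#'   of errors in the category of interest.
#' @param k category pool size (4 for previous-target, 8 for same-context in
#'   the 6-set design).
#' @param total_pool number of candidate non-target words (default 68).
#' @param B bootstrap iterations (default 10000).
#' @param seed integer seed.
#' @return list of class `bootstrap_result`: `observed_mean`, `null_mean`,
#'   `null_sd`, `p`, `B`, `k`, `total_pool`, `degenerate` (TRUE when no
#'   errors were observed at all, in which case `p = 1`).
#' @export
bootstrap_category_null <- function(errors_per_subject, observed_per_subject,
                                    k, total_pool = 68L, B = 10000L,
                                    seed = 1L) {
  stopifnot(B >= 1L, k <= total_pool,
            length(errors_per_subject) == length(observed_per_subject),
            all(observed_per_subject <= errors_per_subject))
  observed_mean <- mean(observed_per_subject)
  n_total <- sum(errors_per_subject)
  if (n_total == 0L) {
    out <- list(observed_mean = 0, null_mean = 0, null_sd = 0, p = 1,
                B = B, k = k, total_pool = total_pool, degenerate = TRUE)
    class(out) <- "bootstrap_result"
    return(out)
  }
  set.seed(seed)
  n_subj <- length(errors_per_subject)
  # uniform word draws over the candidate pool; the category of interest is
  # identified with the first k pool indices
  draws <- matrix(sample.int(total_pool, n_total * B, replace = TRUE) <= k,
                  nrow = n_total, ncol = B)
  subj_id <- rep(seq_len(n_subj), errors_per_subject)
  per_subj_counts <- rowsum(draws + 0L, subj_id)   # n_subj x B
  null_means <- colSums(per_subj_counts) / n_subj
  p <- (1 + sum(null_means >= observed_mean)) / (B + 1)
  out <- list(observed_mean = observed_mean,
              null_mean = mean(null_means),
              null_sd = stats::sd(null_means),
              p = p, B = B, k = k, total_pool = total_pool,
              degenerate = FALSE)
  class(out) <- "bootstrap_result"
  out
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "Bootstrap category null (k = %d / %d, B = %d):\n  observed mean = %.3f, null mean = %.3f (SD %.3f), one-sided p = %.4g\n",
    x$k, x$total_pool, x$B, x$observed_mean, x$null_mean, x$null_sd, x$p))
  invisible(x)
}

#' Paired condition comparisons of substitution-error totals
#'
#' Paired two-sided t tests of per-subject error totals for the three delay
#' conditions: full vs break, full vs none, break vs none.
#'
#' @param totals data.frame with columns `subject`, `condition`, `n_errors`
#'   (one row per subject x condition).
#' @return data.frame with one row per comparison: `pair`, `mean_diff`, `t`,
#'   `df`, `p`.
#' @export
condition_error_test <- function(totals) {
  wide <- stats::reshape(totals, idvar = "subject", timevar = "condition",
                         direction = "wide")
  names(wide) <- sub("^n_errors\\.", "", names(wide))
  if (nrow(wide) < 2L || anyNA(wide[, c("none", "break", "full")])) {
    stop("need >= 2 subjects with totals in all three conditions")
  }
  pairs <- list(c("full", "break"), c("full", "none"), c("break", "none"))
  do.call(rbind, lapply(pairs, function(pr) {
    d <- wide[[pr[1]]] - wide[[pr[2]]]
    if (stats::sd(d) == 0) {
      tt <- list(statistic = 0, parameter = length(d) - 1L, p.value = 1)
    } else {
      tt <- stats::t.test(wide[[pr[1]]], wide[[pr[2]]], paired = TRUE)
    }
    data.frame(pair = paste(pr, collapse = "_vs_"),
               mean_diff = mean(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  }))
}
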