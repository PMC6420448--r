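#' Simulate a latent reinstatement trace
#'
#' For every DNMS trial, trial period (target presentation, delay, probe
#' presentation) and context, draws a reinstatement intensity in [0,1]: the
#' target-set context receives `baseline + boost + noise`, every other context
#' `baseline + noise`, truncated to [0,1]. The delay-period boost is scaled by
#' the subject's `memory_strength`, so a subject who never learned the
#' contexts shows no delay-period elevation. The same trace drives both the
#' behavioural RT simulator and the synthetic BOLD simulator, which is what
#' couples decoded evidence to response slowing.
#'
#' @param trials a [generate_dnms_trials()] table.
#' @param design the [build_design()] the trials came from.
#' @param params [generative_params()].
#' @param seed integer seed.
#' @return a 3-d array `[trial, period, context]` of class
#'   `reinstatement_trace` with dimnames; periods are
#'   `target_presentation`, `delay`, `probe_presentation`.
#' @export
simulate_reinstatement <- function(trials, design, params, seed) {
  set.seed(seed)
  periods <- c("target_presentation", "delay", "probe_presentation")
  ctx <- design$contexts$context_id
  n <- nrow(trials)
  arr <- array(
    rnorm(n * 3L * length(ctx), 0, params$reinstatement_noise_sd),
    dim = c(n, 3L, length(ctx)),
    dimnames = list(NULL, periods, ctx)
  )
  arr <- arr + params$reinstatement_baseline
  boost <- params$reinstatement_boost
  for (i in seq_len(n)) {
    tc <- trials$context_id[i]
    arr[i, "target_presentation", tc] <-
      arr[i, "target_presentation", tc] + boost
    arr[i, "delay", tc] <- arr[i, "delay", tc] +
      boost * params$memory_strength
    arr[i, "probe_presentation", tc] <-
      arr[i, "probe_presentation", tc] + boost
  }
  arr[arr < 0] <- 0
  arr[arr > 1] <- 1
  class(arr) <- c("reinstatement_trace", class(arr))
  arr
}

# context of the probe word: the target context on target/lure trials, the
# drawn other context otherwise
probe_context <- function(trials, design) {
  vapply(trials$probe_id, function(w) {
    design$words$set_id[match(w, design$words$word_id)]
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate DNMS responses and reaction times
#'
#' Reaction time is a linear function of the latent trace:
#' `RT = mu + b_subject + beta_type + gamma_probe * e_probe_delay * 1[mismatch]
#'  - gamma_nonprobe * mean(e_nonprobe_delay) + eps`,
#' where `e_probe_delay` is the delay-period intensity of the probe word's
#' context and the nonprobe term averages the other contexts. Responses are
#' correct with probability `accuracy`; responses slower than `timeout_ms`
#' become no-responses with no RT.
#'
#' @param trials a [generate_dnms_trials()] table.
#' @param trace a [simulate_reinstatement()] trace covering `trials`.
#' @param design the design the trials came from.
#' @param params [generative_params()].
#' @param seed integer seed.
#' @param subject_intercept optional fixed subject intercept (ms); drawn from
#'   `N(0, rt_subject_sd_ms)` when `NULL`.
#' @return data.frame with columns `trial`, `probe_type`, `response`
#'   (`match`/`mismatch`/`none`), `rt_ms` (NA for no-response) and `accurate`.
#' @export
simulate_dnms <- function(trials, trace, design, params, seed,
                          subject_intercept = NULL) {
  stopifnot(nrow(trials) == dim(trace)[1L])
  set.seed(seed)
  n <- nrow(trials)
  if (is.null(subject_intercept)) {
    subject_intercept <- rnorm(1, 0, params$rt_subject_sd_ms)
  }
  pctx <- probe_context(trials, design)
  ctx_ids <- dimnames(trace)[[3L]]
  e_probe <- vapply(seq_len(n), function(i) trace[i, "delay", pctx[i]],
                    numeric(1))
  e_nonprobe <- vapply(seq_len(n), function(i) {
    mean(trace[i, "delay", setdiff(ctx_ids, pctx[i])])
  }, numeric(1))
  beta <- c(target = params$beta_target, lure = params$beta_lure,
            other = params$beta_other)[trials$probe_type]
  mismatch <- as.numeric(trials$correct_response == "mismatch")
  rt <- params$rt_mu_ms + subject_intercept + beta +
    params$gamma_probe * e_probe * mismatch -
    params$gamma_nonprobe * e_nonprobe +
    rnorm(n, 0, params$rt_resid_sd_ms)
  rt <- pmax(rt, 1)
  accurate <- runif(n) < params$accuracy
  response <- ifelse(accurate, trials$correct_response,
                     ifelse(trials$correct_response == "match",
                            "mismatch", "match"))
  timed_out <- rt > params$timeout_ms
  response[timed_out] <- "none"
  accurate[timed_out] <- FALSE
  rt[timed_out] <- NA_real_
  data.frame(
    trial = trials$trial,
    probe_type = trials$probe_type,
    response = response,
    rt_ms = rt,
    accurate = accurate,
    e_probe_delay = e_probe,
    e_nonprobe_delay = e_nonprobe,
    stringsAsFactors = FALSE
  )
}

#' Simulate free-recall responses
#'
#' Each of the four target words is recalled correctly or replaced by a
#' substitution error with the per-condition probability
#' `recall_error_rate[condition]`. The substituted word is drawn from the
#' mixture over candidate pools: the previous trial's targets
#' (`previous_target`), the current context's non-target words
#' (`same_context`), and every other learned word (`other`). On the first
#' trial the previous-target pool is empty and its mixture mass is reassigned
#' proportionally to the remaining categories.
#'
#' @param trials a [generate_recall_trials()] table.
#' @param design the design the trials came from.
#' @param params [generative_params()].
#' @param seed integer seed.
#' @return a list with one character vector of responded words per trial,
#'   of class `recall_responses`.
#' @export
simulate_recall <- function(trials, design, params, seed) {
  set.seed(seed)
  vocab <- design$words$word_id
  tg <- word_matrix(trials)
  responses <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    targets <- as.character(tg[i, ])
    prev_pool <- if (i == 1L) character(0) else
      setdiff(as.character(tg[i - 1L, ]), targets)
    same_pool <- setdiff(set_words(design, trials$context_id[i]),
                         c(targets, prev_pool))
    other_pool <- setdiff(vocab, c(targets, prev_pool, same_pool))
    w <- params$error_weights
    if (length(prev_pool) == 0L) {
      w["previous_target"] <- 0
      w <- w / sum(w)
    }
    rate <- params$recall_error_rate[[trials$condition[i]]]
    is_error <- runif(length(targets)) < rate
    errs <- character(0)
    for (j in which(is_error)) {
      pool <- switch(sample(names(w), 1L, prob = w),
                     previous_target = prev_pool,
                     same_context = same_pool,
                     other = other_pool)
      cand <- setdiff(pool, errs)
      if (length(cand) == 0L) cand <- pool
      errs <- c(errs, sample(cand, 1L))
    }
    responses[[i]] <- c(targets[!is_error], errs)
  }
  class(responses) <- c("recall_responses", "list")
  responses
}

#' Simulate the posttask context-memory test
#'
#' Every word in the design is tested once: with probability `pi_mem` the
#' subject genuinely remembers the word's context; otherwise they guess
#' uniformly over the four contexts, so expected accuracy is
#' `pi_mem + (1 - pi_mem) / n_contexts`. Confidence (1-4) is drawn higher on
#' remembered trials than on guesses.
#'
#' @param design a [build_design()] result.
#' @param params [generative_params()].
#' @param seed integer seed.
#' @return data.frame with columns `word_id`, `true_context_id`,
#'   `chosen_context_id`, `confidence`, `correct`.
#' @export
simulate_memory_test <- function(design, params, seed) {
  set.seed(seed)
  ctx <- design$contexts$context_id
  n <- nrow(design$words)
  remembered <- runif(n) < params$pi_mem
  chosen <- character(n)
  for (i in seq_len(n)) {
    chosen[i] <- if (remembered[i]) design$words$set_id[i] else
      sample(ctx, 1L)
  }
  correct <- chosen == design$words$set_id
  confidence <- ifelse(
    remembered,
    sample(2:4, n, replace = TRUE, prob = c(0.15, 0.35, 0.5)),
    sample(1:4, n, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  )
  data.frame(
    word_id = design$words$word_id,
    true_context_id = design$words$set_id,
    chosen_context_id = chosen,
    confidence = as.integer(confidence),
    correct = correct,
    stringsAsFactors = FALSE
  )
}

#' Simulate a multi-subject DNMS cohort
#'
#' Builds an independent design, learning schedule, trial sequence, latent
#' reinstatement trace, response set and posttask memory test per subject
#' (each subject's word-context assignment is randomized, as in the real
#' experiments), and returns the pooled trial table.
#'
#' @param n_subjects number of subjects.
#' @param params [generative_params()]; `memory_strength` may be a vector of
#'   length `n_subjects` of per-subject strengths.
#' @param seed integer global seed, expanded per subject via [module_seed()].
#' @param n_trials DNMS trials per subject (default 60).
#' @param config design configuration (default [exp3_config()]).
#' @param memory_strength optional vector overriding
#'   `params$memory_strength` per subject.
#' @return a list of class `dnms_cohort` with elements `trials` (pooled
#'   data.frame with `subject` column), `memory` (pooled memory-test table),
#'   and `subjects` (per-subject list of design, schedule, trials, trace).
#' @export
simulate_dnms_cohort <- function(n_subjects, params = generative_params(),
                                 seed = 1L, n_trials = 60L,
                                 config = exp3_config(),
                                 memory_strength = NULL) {
  if (is.null(memory_strength)) {
    memory_strength <- rep(params$memory_strength, n_subjects)
  }
  stopifnot(length(memory_strength) == n_subjects)
  subjects <- vector("list", n_subjects)
  trial_tabs <- vector("list", n_subjects)
  mem_tabs <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    p_s <- params
    p_s$memory_strength <- memory_strength[s]
    # context-memory accuracy and delay-period reinstatement share the
    # subject's latent memory strength
    p_s$pi_mem <- params$pi_mem * memory_strength[s]
    design <- build_design(config, module_seed(seed, "design", s))
    schedule <- generate_learning_schedule(design,
                                           module_seed(seed, "schedule", s))
    trials <- generate_dnms_trials(design, module_seed(seed, "dnms_trials", s),
                                   n_trials = n_trials, schedule = schedule)
    trace <- simulate_reinstatement(trials, design, p_s,
                                    module_seed(seed, "reinstatement", s))
    resp <- simulate_dnms(trials, trace, design, p_s,
                          module_seed(seed, "dnms_responses", s))
    mem <- simulate_memory_test(design, p_s,
                                module_seed(seed, "memory_test", s))
    tab <- cbind(subject = s, trials[, c("trial", "context_id", "probe_id",
                                         "probe_type", "correct_response",
                                         "overlap")],
                 resp[, c("response", "rt_ms", "accurate",
                          "e_probe_delay", "e_nonprobe_delay")])
    # per-trial target-memory score: how many of the 4 targets had their
    # context correctly identified in the posttask test
    tgt <- word_matrix(trials)
    mem_ok <- stats::setNames(mem$correct, mem$word_id)
    tab$target_memory_score <- as.integer(rowSums(
      matrix(mem_ok[tgt], nrow = nrow(tgt))))
    trial_tabs[[s]] <- tab
    mem_tabs[[s]] <- cbind(subject = s, mem)
    subjects[[s]] <- list(design = design, schedule = schedule,
                          trials = trials, trace = trace)
  }
  structure(
    list(trials = do.call(rbind, trial_tabs),
         memory = do.call(rbind, mem_tabs),
         subjects = subjects,
         params = params, seed = seed),
    class = "dnms_cohort"
  )
}

#' @export
print.dnms_cohort <- function(x, ...) {
  cat("Synthetic DNMS cohort:", length(x$subjects), "subjects x",
      sum(x$trials$subject == 1L), "trials\n")
  invisible(x)
}
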