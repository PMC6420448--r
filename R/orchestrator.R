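#' Model table from the latent reinstatement trace
#'
#' Builds the trial-wise table the mixed models consume, using the latent
#' trace itself as the evidence source (the noiseless-measurement limit of
#' the fMRI pipeline). Useful for fast calibration studies; [decode_cohort()]
#' is the full route through synthetic BOLD and the decoder.
#'
#' @param cohort a [simulate_dnms_cohort()] result.
#' @return data.frame: `subject`, `trial`, `probe_type`, `rt_ms`,
#'   `accurate`, `overlap`, `target_memory_score`, and evidence scalar
#'   columns (`ev_probe_*`, `ev_nonprobe_*`, `ev_target_ctx_*`,
#'   `ev_nontarget_ctx_*` per period).
#' @export
trace_model_table <- function(cohort) {
  tabs <- lapply(seq_along(cohort$subjects), function(s) {
    sub <- cohort$subjects[[s]]
    trace <- sub$trace
    # latent trace in the shape of a per-period evidence table
    periods <- dimnames(trace)[[2L]]
    kinds <- context_kinds(sub$design)
    n <- dim(trace)[1L]
    flat <- matrix(aperm(trace[, , names(kinds), drop = FALSE], c(2L, 1L, 3L)),
                   nrow = 3L * n)
    colnames(flat) <- unname(kinds)
    ev <- data.frame(trial = rep(sub$trials$trial, each = 3L),
                     period = rep(periods, n), flat,
                     stringsAsFactors = FALSE, check.names = FALSE)
    scal <- evidence_scalars(ev, sub$trials, sub$design)
    beh <- cohort$trials[cohort$trials$subject == s, , drop = FALSE]
    merge(beh[, c("subject", "trial", "probe_type", "rt_ms", "accurate",
                  "overlap", "target_memory_score")],
          scal, by = "trial")
  })
  out <- do.call(rbind, tabs)
  out[order(out$subject, out$trial), , drop = FALSE]
}

#' Decode a cohort's synthetic BOLD and assemble the model table
#'
#' For every subject: simulate a localizer run, train the one-vs-rest
#' evidence model on the shifted, labeled localizer TRs; simulate the DNMS
#' run from the subject's latent trace; score per-TR evidence; average it
#' over the shifted trial-period windows; and merge the evidence scalars
#' with behaviour, overlap and memory scores.
#'
#' @param cohort a [simulate_dnms_cohort()] result.
#' @param bparams [bold_params()].
#' @param lambda decoder ridge penalty (default 1).
#' @param shift_seconds,window_seconds,gap_trs window parameters passed to
#'   [extract_trial_evidence()].
#' @param seed integer seed for the BOLD noise streams (expanded per
#'   subject).
#' @param crossval also run the 4-fold localizer cross-validation per subject
#'   (default FALSE, it is not needed for the model table).
#' @return list with `table` (pooled model table) and, if requested,
#'   `cv_accuracy` (per-subject cross-validated localizer accuracy).
#' @export
decode_cohort <- function(cohort, bparams = bold_params(), lambda = 1,
                          shift_seconds = 5, window_seconds = 6, gap_trs = 1L,
                          seed = 1L, crossval = FALSE) {
  n_subj <- length(cohort$subjects)
  tabs <- vector("list", n_subj)
  cv <- rep(NA_real_, n_subj)
  for (s in seq_len(n_subj)) {
    sub <- cohort$subjects[[s]]
    bank <- make_pattern_bank(bparams$n_voxels, bparams$selectivity,
                              module_seed(seed, "pattern_bank", s))
    loc <- simulate_localizer_run(bank, bparams,
                                  module_seed(seed, "localizer", s))
    labels <- label_localizer_trs(loc$events, bparams$tr_seconds,
                                  shift_seconds)
    model <- train_evidence_model(loc$run$signal[labels$tr + 1L, , drop = FALSE],
                                  labels$label, lambda)
    if (crossval) {
      folds <- split_folds_by_time(labels)
      cv[s] <- crossval_accuracy(loc$run$signal, folds, lambda)$accuracy
    }
    task <- simulate_dnms_run(sub$trials, sub$trace, sub$design, bank,
                              bparams, module_seed(seed, "bold", s))
    trace <- score_evidence(model, task$run)
    ev <- extract_trial_evidence(trace, task$events, bparams$tr_seconds,
                                 shift_seconds, window_seconds, gap_trs)
    scal <- evidence_scalars(ev, sub$trials, sub$design)
    beh <- cohort$trials[cohort$trials$subject == s, , drop = FALSE]
    tabs[[s]] <- merge(
      beh[, c("subject", "trial", "probe_type", "rt_ms", "accurate",
              "overlap", "target_memory_score")],
      scal, by = "trial")
  }
  table <- do.call(rbind, tabs)
  table <- table[order(table$subject, table$trial), , drop = FALSE]
  out <- list(table = table)
  if (crossval) out$cv_accuracy <- cv
  out
}

#' Run configuration for a full synthetic experiment
#'
#' @param experiment `"exp1"` (free recall), `"exp2"` (behavioural DNMS) or
#'   `"exp3"` (DNMS with synthetic BOLD decoding).
#' @param n_subjects cohort size.
#' @param n_trials DNMS trials per subject (exp2/exp3).
#' @param params [generative_params()].
#' @param bparams [bold_params()] (exp3 only).
#' @param bootstrap_B bootstrap iterations for the error-category null.
#' @param lambda decoder ridge penalty.
#' @param seed global seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(experiment = c("exp2", "exp1", "exp3"),
                       n_subjects = 20L, n_trials = 60L,
                       params = generative_params(),
                       bparams = bold_params(),
                       bootstrap_B = 10000L, lambda = 1, seed = 1L) {
  experiment <- match.arg(experiment)
  structure(as.list(environment()), class = "run_config")
}

#' Run a full synthetic experiment
#'
#' Executes the generation and analysis chain for the configured experiment
#' and returns (and optionally writes) the result bundle:
#' * `exp1`: design, learning schedule, recall trials, simulated recall,
#'   error categorization, per-condition bootstrap nulls (previous-target and
#'   same-context categories) and paired condition t tests.
#' * `exp2`: DNMS cohort, exclusions, zRT, probe-type contrasts.
#' * `exp3`: as exp2, plus synthetic BOLD decoding, target-context contrast,
#'   memory split, and mixed Models 1-3.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, tables are written as TSV
#'   and results as JSON.
#' @return a list bundle; see Details.
#' @export
run_synthetic_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  bundle <- switch(config$experiment,
                   exp1 = run_exp1(config),
                   exp2 = run_exp2(config),
                   exp3 = run_exp3(config))
  bundle$config <- config
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  invisible(bundle)
}

run_exp1 <- function(config) {
  seed <- config$seed
  n_subj <- config$n_subjects
  errs <- vector("list", n_subj)
  for (s in seq_len(n_subj)) {
    design <- build_design(exp1_config(), module_seed(seed, "design", s))
    trials <- generate_recall_trials(design,
                                     module_seed(seed, "recall_trials", s))
    resp <- simulate_recall(trials, design, config$params,
                            module_seed(seed, "recall_responses", s))
    errs[[s]] <- score_recall_session(trials, resp, design, subject = s)
  }
  errors <- do.call(rbind, errs)
  conditions <- c("none", "break", "full")
  subjects <- seq_len(n_subj)
  totals <- expand.grid(subject = subjects, condition = conditions,
                        stringsAsFactors = FALSE)
  totals$n_errors <- mapply(function(su, co) {
    sum(errors$subject == su & errors$condition == co)
  }, totals$subject, totals$condition)
  boot <- list()
  for (co in conditions) {
    n_err <- totals$n_errors[totals$condition == co][order(subjects)]
    for (cat in c("previous_target", "same_context")) {
      obs <- vapply(subjects, function(su) {
        sum(errors$subject == su & errors$condition == co &
              errors$category == cat)
      }, integer(1))
      k <- if (cat == "previous_target") 4L else 8L
      boot[[paste(co, cat, sep = ".")]] <- bootstrap_category_null(
        n_err, obs, k = k, total_pool = 68L, B = config$bootstrap_B,
        seed = module_seed(seed, "bootstrap"))
    }
  }
  list(errors = errors, totals = totals,
       condition_tests = condition_error_test(totals),
       bootstrap = boot)
}

run_exp2 <- function(config) {
  cohort <- simulate_dnms_cohort(config$n_subjects, config$params,
                                 seed = config$seed,
                                 n_trials = config$n_trials)
  excl <- apply_exclusions(cohort$trials)
  ztab <- zscore_log_rt(excl$trials)
  list(cohort = cohort, exclusions = excl, trials = ztab,
       contrasts = probe_type_contrasts(ztab))
}

run_exp3 <- function(config) {
  bundle <- run_exp2(config)
  decoded <- decode_cohort(bundle$cohort, config$bparams,
                           lambda = config$lambda, seed = config$seed,
                           crossval = TRUE)
  tab <- decoded$table
  # keep zRT/memory bookkeeping aligned with the decoded table
  ztab <- bundle$trials
  key <- paste(tab$subject, tab$trial)
  zkey <- paste(ztab$subject, ztab$trial)
  tab <- tab[key %in% zkey, , drop = FALSE]
  bundle$model_table <- tab
  bundle$cv_accuracy <- decoded$cv_accuracy
  bundle$target_context <- target_context_contrast(tab)
  bundle$memory_split <- split_by_target_memory(
    merge(ztab, tab[, c("subject", "trial",
                        grep("^ev_", names(tab), value = TRUE))],
          by = c("subject", "trial")))
  bundle$fits <- list(
    model1 = model1(tab),
    model2_lure = model2(tab, "lure"),
    model2_target = model2(tab, "target"),
    model2_other = model2(tab, "other"),
    model2_lure_nonprobe = model2(tab, "lure", evidence_source = "nonprobe"),
    model3 = model3(tab))
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- bundle$config
  results <- list(
    seed = cfg$seed,
    experiment = cfg$experiment,
    # every analysis decision in force for the run
    parameters = list(
      n_subjects = cfg$n_subjects, n_trials = cfg$n_trials,
      bootstrap_B = cfg$bootstrap_B, lambda = cfg$lambda,
      shift_seconds = 5, window_seconds = 6, gap_trs = 1,
      chance_accuracy = 2 / 3, learned_rule = "score/4 > 0.5",
      rt_log = "natural", zscore_ddof = 1,
      trial_type_reference = "other",
      generative = unclass(cfg$params)))
  if (!is.null(bundle$errors)) {
    write_tsv_table(bundle$errors, file.path(out_dir, "errors.tsv"))
    write_tsv_table(bundle$totals, file.path(out_dir, "error_totals.tsv"))
    results$condition_tests <- bundle$condition_tests
    results$bootstrap <- lapply(bundle$bootstrap, unclass)
  }
  if (!is.null(bundle$trials)) {
    write_tsv_table(bundle$trials, file.path(out_dir, "trials.tsv"))
    results$contrasts <- bundle$contrasts$contrasts
    results$condition_means <- bundle$contrasts$condition_means
  }
  if (!is.null(bundle$model_table)) {
    write_tsv_table(bundle$model_table, file.path(out_dir, "model_table.tsv"))
    results$cv_accuracy <- bundle$cv_accuracy
    results$target_context <- bundle$target_context[
      c("mean_diff", "t", "df", "p")]
    results$fits <- lapply(bundle$fits, function(f) {
      list(coefficients = f$coefficients, sigma_subject = f$sigma_subject,
           sigma_resid = f$sigma_resid, n_trials = f$n_trials,
           n_subjects = f$n_subjects, converged = f$converged)
    })
  }
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Analyze real (or exported) fMRI data
#'
#' The file-based route through the same analysis chain: reads a localizer
#' run and a DNMS run as NIfTI (any spatial layout) with a binary ROI mask,
#' BIDS-style event TSVs, and a behavioural trial TSV; optionally discards
#' leading volumes and high-pass filters; trains the decoder on the
#' localizer; extracts trial-period evidence; and fits Models 1-3 where the
#' behavioural table provides the needed columns.
#'
#' @param localizer_nifti,dnms_nifti paths to 4-D functional images.
#' @param mask path to the binary ROI mask.
#' @param localizer_events,dnms_events paths to events TSVs (onset, duration,
#'   trial_type, block/trial).
#' @param behavior path to a behavioural trial TSV (subject, trial,
#'   probe_type, rt_ms, accurate, and optionally overlap,
#'   target_memory_score); trials must match the DNMS events.
#' @param design_dir directory written by [write_design()] describing the
#'   word/context layout (used to map class evidence onto contexts).
#' @param discard_volumes leading volumes dropped from each run (default 0;
#'   8 is typical for real acquisitions).
#' @param highpass_cutoff high-pass cutoff in seconds, or `NULL` to skip.
#' @param lambda,shift_seconds,window_seconds,gap_trs analysis parameters.
#' @return list with `cv_accuracy`, `model_table`, `fits` (Models 1-3 where
#'   estimable).
#' @export
analyze_real_data <- function(localizer_nifti, dnms_nifti, mask,
                              localizer_events, dnms_events, behavior,
                              design_dir,
                              discard_volumes = 0L, highpass_cutoff = NULL,
                              lambda = 1, shift_seconds = 5,
                              window_seconds = 6, gap_trs = 1L) {
  for (f in c(localizer_nifti, dnms_nifti, mask, localizer_events,
              dnms_events, behavior)) {
    if (!file.exists(f)) stop("missing input file: ", f)
  }
  design <- read_design(design_dir)
  loc_run <- read_bold_nifti(localizer_nifti, mask, label = "localizer")
  task_run <- read_bold_nifti(dnms_nifti, mask, label = "dnms")
  loc_ev <- read_tsv_table(localizer_events)
  task_ev <- read_tsv_table(dnms_events)
  beh <- read_tsv_table(behavior)
  need <- c("subject", "trial", "probe_type", "rt_ms", "accurate")
  miss <- setdiff(need, names(beh))
  if (length(miss)) {
    stop("behaviour table lacks required columns: ",
         paste(miss, collapse = ", "))
  }
  drop_lead <- function(run, events) {
    if (discard_volumes > 0L) {
      run$signal <- run$signal[-seq_len(discard_volumes), , drop = FALSE]
      events$onset <- events$onset - discard_volumes * run$tr
    }
    if (!is.null(highpass_cutoff)) run <- highpass(run, highpass_cutoff)
    list(run = run, events = events)
  }
  loc <- drop_lead(loc_run, loc_ev)
  task <- drop_lead(task_run, task_ev)
  labels <- label_localizer_trs(loc$events, loc$run$tr, shift_seconds)
  folds <- split_folds_by_time(labels)
  cv <- crossval_accuracy(loc$run$signal, folds, lambda)
  model <- train_evidence_model(
    loc$run$signal[labels$tr + 1L, , drop = FALSE], labels$label, lambda)
  trace <- score_evidence(model, task$run)
  ev <- extract_trial_evidence(trace, task$events, task$run$tr,
                               shift_seconds, window_seconds, gap_trs)
  trials <- beh[order(beh$trial), , drop = FALSE]
  trial_spec <- rebuild_trials_from_behavior(trials, design)
  scal <- evidence_scalars(ev, trial_spec, design)
  table <- merge(beh, scal, by = "trial")
  fits <- list()
  fits$model2_lure <- try_fit(function() model2(table, "lure"))
  if (!is.null(table$target_memory_score)) {
    fits$model1 <- try_fit(function() model1(table))
  }
  if (!is.null(table$overlap)) {
    fits$model3 <- try_fit(function() model3(table))
  }
  list(cv_accuracy = cv$accuracy, model_table = table, fits = fits)
}

try_fit <- function(fn) tryCatch(fn(), error = function(e) e$message)

# behaviour tables on the file route must carry the trial's context and the
# probe word so evidence can be mapped onto contexts
rebuild_trials_from_behavior <- function(beh, design) {
  need <- c("trial", "context_id", "probe_id", "probe_type")
  miss <- setdiff(need, names(beh))
  if (length(miss)) {
    stop("behaviour table lacks columns needed to map evidence onto ",
         "contexts: ", paste(miss, collapse = ", "))
  }
  beh[, need, drop = FALSE]
}
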