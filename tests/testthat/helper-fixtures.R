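# Small fixtures shared across test files; everything is generated in code.

fixture_exp1 <- function(seed = 101L) {
  design <- build_design(exp1_config(), seed)
  list(design = design,
       trials = generate_recall_trials(design, seed + 1L))
}

fixture_exp3 <- function(seed = 202L, n_trials = 60L) {
  design <- build_design(exp3_config(), seed)
  schedule <- generate_learning_schedule(design, seed + 1L)
  trials <- generate_dnms_trials(design, seed + 2L, n_trials,
                                 schedule = schedule)
  list(design = design, schedule = schedule, trials = trials)
}

# one default 80-subject behavioural cohort, computed once per test run
default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dnms_cohort(80L, generative_params(), seed = 11L)
    }
    cache
  }
})

# a tiny localizer + trained model at low noise, shared by mvpa tests
fixture_decoder <- function(seed = 303L, lambda = 1,
                            bp = bold_params(noise_ar_sd = 0.05,
                                             noise_white_sd = 0.05)) {
  bank <- make_pattern_bank(bp$n_voxels, bp$selectivity, seed)
  loc <- simulate_localizer_run(bank, bp, seed + 1L)
  labels <- label_localizer_trs(loc$events, bp$tr_seconds)
  model <- train_evidence_model(loc$run$signal[labels$tr + 1L, ],
                                labels$label, lambda)
  list(bank = bank, loc = loc, labels = labels, model = model, bp = bp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
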