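test_that("recall scoring counts targets and flags unknown tokens", {
  fx <- fixture_exp1()
  trial <- fx$trials[1, ]
  targets <- as.character(wmintrude:::word_matrix(trial)[1, ])
  same_set <- setdiff(wmintrude:::set_words(fx$design, trial$context_id),
                      targets)

  sc <- score_recall(trial, targets, fx$design)
  expect_equal(sc$n_correct, 4L)
  expect_length(sc$errors, 0L)

  sc2 <- score_recall(trial, c(targets[1:2], same_set[1]), fx$design)
  expect_equal(sc2$n_correct, 2L)
  expect_equal(sc2$errors, same_set[1])

  sc3 <- score_recall(trial, c(targets[1], "notaword"), fx$design)
  expect_equal(sc3$n_correct, 1L)
  expect_length(sc3$errors, 0L)
  expect_equal(sc3$out_of_vocabulary, "notaword")
})

test_that("error categories are previous-target > same-context > other", {
  fx <- fixture_exp1()
  trials <- fx$trials
  i <- 5L
  trial <- trials[i, ]
  prev <- trials[i - 1L, ]
  prev_targets <- as.character(wmintrude:::word_matrix(prev)[1, ])
  targets <- as.character(wmintrude:::word_matrix(trial)[1, ])
  same_set <- setdiff(wmintrude:::set_words(fx$design, trial$context_id),
                      targets)
  other_word <- setdiff(fx$design$words$word_id,
                        c(targets, prev_targets, same_set,
                          wmintrude:::set_words(fx$design, prev$context_id)))[1]

  expect_equal(categorize_error(prev_targets[1], trial, prev, fx$design),
               "previous_target")
  expect_equal(categorize_error(same_set[1], trial, prev, fx$design),
               "same_context")
  expect_equal(categorize_error(other_word, trial, prev, fx$design), "other")
  expect_error(categorize_error(targets[1], trial, prev, fx$design),
               "current target")
  expect_error(categorize_error("nope", trial, prev, fx$design),
               "not in vocabulary")
})

test_that("category pools are disjoint and sum to 68 on every trial", {
  fx <- fixture_exp1(seed = 321L)
  trials <- fx$trials
  for (i in 2:nrow(trials)) {
    trial <- trials[i, ]
    prev <- trials[i - 1L, ]
    targets <- as.character(wmintrude:::word_matrix(trial)[1, ])
    nontargets <- setdiff(fx$design$words$word_id, targets)
    cats <- vapply(nontargets, categorize_error, character(1),
                   trial = trial, prev_trial = prev, design = fx$design)
    expect_equal(as.vector(table(factor(cats, c("previous_target",
                                                "same_context", "other")))),
                 c(4L, 8L, 56L))
  }
})

test_that("categorization matches brute-force set logic on random small designs", {
  # independent oracle: direct set membership checks, no precedence machinery
  brute <- function(word, targets, prev_targets, ctx_words) {
    if (word %in% prev_targets) return("previous_target")
    if (word %in% ctx_words) return("same_context")
    "other"
  }
  set.seed(99)
  n_checked <- 0L
  for (rep in 1:50) {
    cfg <- design_config(sample(2:4, 1), words_per_set = sample(c(6L, 8L), 1),
                         words_per_trial = 4L)
    design <- build_design(cfg, 5000 + rep)
    trials <- generate_recall_trials(design, 6000 + rep,
                                     n_per_condition = 4L)
    for (i in 2:nrow(trials)) {
      trial <- trials[i, ]
      prev <- trials[i - 1L, ]
      targets <- as.character(wmintrude:::word_matrix(trial)[1, ])
      prev_targets <- as.character(wmintrude:::word_matrix(prev)[1, ])
      ctx_words <- wmintrude:::set_words(design, trial$context_id)
      candidates <- sample(setdiff(design$words$word_id, targets), 2L)
      for (w in candidates) {
        expect_identical(categorize_error(w, trial, prev, design),
                         brute(w, targets, prev_targets, ctx_words))
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gte(n_checked, 1000L)
})

test_that("bootstrap null mean matches the analytic uniform expectation", {
  # one subject, 17 errors, k = 4: expectation 17 * 4/68 = 1
  b <- bootstrap_category_null(17L, 5L, k = 4L, B = 10000L, seed = 1)
  expect_lt(abs(b$null_mean - 1) / 1, 0.02)
  expect_equal(b$observed_mean, 5)

  # several subjects, k = 8
  n_err <- c(10L, 20L, 4L)
  b8 <- bootstrap_category_null(n_err, c(2L, 3L, 0L), k = 8L, B = 10000L,
                                seed = 2)
  expect_lt(abs(b8$null_mean - mean(n_err * 8 / 68)) / mean(n_err * 8 / 68),
            0.02)
})

test_that("bootstrap handles degenerate and extreme observations", {
  b0 <- bootstrap_category_null(c(0L, 0L), c(0L, 0L), k = 4L, B = 100L,
                                seed = 3)
  expect_true(b0$degenerate)
  expect_equal(b0$p, 1)
  expect_equal(b0$null_mean, 0)

  # all errors in the category -> smallest attainable p
  bx <- bootstrap_category_null(6L, 6L, k = 4L, B = 2000L, seed = 4)
  expect_equal(bx$p, 1 / 2001)
})

test_that("category counts conserve the total error count", {
  fx <- fixture_exp1(seed = 11L)
  resp <- simulate_recall(fx$trials, fx$design,
                          generative_params(), seed = 12L)
  errors <- score_recall_session(fx$trials, resp, fx$design)
  n_correct <- attr(errors, "n_correct")
  expect_equal(nrow(errors) + sum(n_correct), 4L * nrow(fx$trials))
  expect_true(all(errors$category %in%
                    c("previous_target", "same_context", "other")))
})

test_that("condition t tests flag the planted distraction gradient", {
  b <- run_synthetic_experiment(run_config("exp1", n_subjects = 15L,
                                           seed = 7L, bootstrap_B = 2000L))
  expect_equal(unique(b$condition_tests$df), 14)
  expect_true(all(b$condition_tests$p < 0.05))
  expect_true(all(b$condition_tests$mean_diff > 0))
  # near-zero errors without distraction
  mean_none <- mean(b$totals$n_errors[b$totals$condition == "none"])
  mean_full <- mean(b$totals$n_errors[b$totals$condition == "full"])
  expect_lt(mean_none, 2)
  expect_gt(mean_full, mean_none)
  # elevated previous-target and same-context substitution rates are detected
  expect_lt(b$bootstrap[["full.previous_target"]]$p, 0.01)
  expect_lt(b$bootstrap[["full.same_context"]]$p, 0.01)
})

test_that("identical condition totals give t = 0, p = 1", {
  totals <- expand.grid(subject = 1:5,
                        condition = c("none", "break", "full"),
                        stringsAsFactors = FALSE)
  totals$n_errors <- rep(c(3L, 5L, 2L, 4L, 1L), 3L)
  res <- condition_error_test(totals)
  expect_true(all(res$t == 0))
  expect_true(all(res$p == 1))
})

test_that("degenerate mixtures place all errors in one category", {
  fx <- fixture_exp1(seed = 21L)
  p <- generative_params(error_weights = c(1, 0, 0),
                         recall_error_rate = c(none = 0.3, "break" = 0.3,
                                               full = 0.3))
  resp <- simulate_recall(fx$trials, fx$design, p, seed = 22L)
  errors <- score_recall_session(fx$trials, resp, fx$design)
  expect_gt(nrow(errors), 10L)
  expect_true(all(errors$category[errors$trial > 1L] == "previous_target"))
})

test_that("bootstrap p-values are roughly uniform under chance substitutions", {
  # chance-matched mixture; moderate per-subject error counts
  p <- null_params(recall_error_rate = c(none = 0.15, "break" = 0.15,
                                         full = 0.15))
  pvals <- vapply(1:200, function(r) {
    n_err <- integer(4)
    obs <- integer(4)
    for (s in 1:4) {
      design <- build_design(exp1_config(), module_seed(r, "design", s))
      trials <- generate_recall_trials(design,
                                       module_seed(r, "recall_trials", s),
                                       n_per_condition = 6L)
      resp <- simulate_recall(trials, design, p,
                              module_seed(r, "recall_responses", s))
      errors <- score_recall_session(trials, resp, design)
      n_err[s] <- nrow(errors)
      obs[s] <- sum(errors$category == "same_context")
    }
    bootstrap_category_null(n_err, obs, k = 8L, B = 500L,
                            seed = module_seed(r, "bootstrap"))$p
  }, numeric(1))
  # ties are expected (resampled p-values are discrete); the KS statistic is
  # still a fair uniformity gauge at this resolution
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
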