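test_that("localizer TR labels follow the shifted half-open window", {
  events <- data.frame(onset = c(100, 140), duration = 20,
                       trial_type = c("left_face", "left_object"),
                       block = 1:2, stringsAsFactors = FALSE)
  lab <- label_localizer_trs(events, tr_seconds = 1, shift_seconds = 5)
  expect_equal(lab$tr, 105:124)
  expect_true(all(lab$label == "left_face"))
  # object blocks and interblock intervals are unlabeled
  expect_false(any(lab$tr >= 125 & lab$tr < 145))

  # overlapping shifted windows are an error
  bad <- data.frame(onset = c(0, 10), duration = 20,
                    trial_type = c("left_face", "right_face"), block = 1:2,
                    stringsAsFactors = FALSE)
  expect_error(label_localizer_trs(bad), "overlap")
})

test_that("temporal folds keep blocks whole and contiguous", {
  fx <- fixture_decoder()
  labels <- split_folds_by_time(fx$labels, k = 4L)
  # 12 trained-class blocks -> 3 per fold
  per_fold_blocks <- tapply(labels$block, labels$fold,
                            function(b) length(unique(b)))
  expect_true(all(per_fold_blocks == 3L))
  # no block straddles folds
  expect_true(all(tapply(labels$fold, labels$block,
                         function(f) length(unique(f))) == 1L))
  # folds are contiguous in time
  ord <- labels$fold[order(labels$tr)]
  expect_true(all(diff(ord) >= 0))
  # sizes differ by at most one block when counts do not divide evenly
  l5 <- split_folds_by_time(fx$labels, k = 5L)
  sizes <- tapply(l5$block, l5$fold, function(b) length(unique(b)))
  expect_lte(max(sizes) - min(sizes), 1L)
  expect_error(split_folds_by_time(fx$labels, k = 13L), "fewer blocks")
})

test_that("the one-vs-rest units behave like ridge logistic regressions", {
  set.seed(42)
  n <- 120L
  X <- cbind(rnorm(n), rnorm(n))
  y <- ifelse(X[, 1] + 0.5 * X[, 2] + rnorm(n, 0, 0.4) > 0, "a", "b")
  # near-unpenalized fit agrees with glm
  Xs <- scale(X)
  ours <- wmintrude:::ridge_logistic(Xs, as.numeric(y == "a"), lambda = 1e-8)
  ref <- stats::glm(I(y == "a") ~ Xs, family = binomial())
  expect_equal(c(ours$b, ours$w), unname(stats::coef(ref)), tolerance = 1e-4)

  # separable toy: own-class probability > .9 on training points
  set.seed(8)
  toy_X <- rbind(matrix(rnorm(40, 4), 20), matrix(rnorm(40, -4), 20))
  toy_y <- rep(c("a", "b"), each = 20)
  model <- train_evidence_model(toy_X, toy_y, lambda = 0.1)
  ev <- score_evidence(model, toy_X)
  expect_true(all(ev[1:20, "a"] > 0.9))
  expect_true(all(ev[21:40, "b"] > 0.9))
  expect_true(all(ev >= 0 & ev <= 1))

  # huge penalty shrinks weights to ~0; outputs approach the class base rate
  heavy <- train_evidence_model(toy_X, rep(c("a", "b"), c(10, 30)),
                                lambda = 1e7)
  expect_lt(max(abs(heavy$W)), 1e-4)
  ev_h <- score_evidence(heavy, toy_X)
  expect_equal(mean(ev_h[, "a"]), 0.25, tolerance = 0.01)
  expect_equal(mean(ev_h[, "b"]), 0.75, tolerance = 0.01)
})

test_that("ridge logistic agrees with glmnet at matched penalty", {
  skip_if_not_installed("glmnet")
  set.seed(7)
  n <- 200L
  X <- matrix(rnorm(n * 5L), n)
  y <- as.numeric(X %*% c(1, -0.5, 0.3, 0, 0.8) + rnorm(n, 0, 1) > 0)
  Xs <- scale(X)
  lambda <- 3
  ours <- wmintrude:::ridge_logistic(Xs, y, lambda)
  # glmnet minimizes (1/n) loglik + lambda_g/2 ||w||^2 on standardized X
  g <- glmnet::glmnet(Xs, y, family = "binomial", alpha = 0,
                      lambda = lambda / n, standardize = FALSE,
                      thresh = 1e-12)
  expect_equal(ours$w, as.numeric(g$beta), tolerance = 1e-3)
  expect_equal(ours$b, as.numeric(g$a0), tolerance = 1e-3)
})

test_that("evidence scoring is deterministic and shape-checked", {
  fx <- fixture_decoder()
  X <- fx$loc$run$signal[1:10, ]
  ev1 <- score_evidence(fx$model, X)
  ev2 <- score_evidence(fx$model, X[c(1, 1, 2), ])
  expect_equal(ev2[1, ], ev2[2, ])
  expect_equal(ev1[1, ], ev2[1, ])
  expect_error(score_evidence(fx$model, X[, 1:5]), "dimensionality")
})

test_that("evidence is invariant to per-voxel affine rescaling of the data", {
  fx <- fixture_decoder()
  X_train <- fx$loc$run$signal[fx$labels$tr + 1L, ]
  X_test <- fx$loc$run$signal[1:20, ]
  a <- runif(ncol(X_train), 0.5, 2)
  b <- rnorm(ncol(X_train), 0, 10)
  resc <- function(X) sweep(sweep(X, 2L, a, "*"), 2L, b, "+")
  m1 <- train_evidence_model(X_train, fx$labels$label, lambda = 1)
  m2 <- train_evidence_model(resc(X_train), fx$labels$label, lambda = 1)
  expect_equal(score_evidence(m1, X_test), score_evidence(m2, resc(X_test)),
               tolerance = 1e-6)
})

test_that("cross-validation reaches ceiling on clean data and chance on permuted labels", {
  clean <- fixture_decoder(seed = 404L,
                           bp = bold_params(n_voxels = 40L, selectivity = 5,
                                            noise_ar_sd = 0.05,
                                            noise_white_sd = 0.05))
  folds <- split_folds_by_time(clean$labels)
  expect_gte(crossval_accuracy(clean$loc$run$signal, folds)$accuracy, 0.95)

  # block-level label permutations drop accuracy to ~25%
  set.seed(1)
  accs <- vapply(1:8, function(r) {
    perm <- folds
    blocks <- unique(perm$block)
    relab <- stats::setNames(sample(tapply(perm$label, perm$block, unique)),
                             blocks)
    perm$label <- unname(relab[as.character(perm$block)])
    crossval_accuracy(clean$loc$run$signal, perm)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.25), 0.06)
})

test_that("default-noise localizer decoding sits in the calibrated band", {
  accs <- vapply(1:4, function(r) {
    bp <- bold_params()
    bank <- make_pattern_bank(bp$n_voxels, bp$selectivity, 900 + r)
    loc <- simulate_localizer_run(bank, bp, 950 + r)
    folds <- split_folds_by_time(label_localizer_trs(loc$events))
    crossval_accuracy(loc$run$signal, folds)$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.50)
  expect_lt(mean(accs), 0.85)
})

test_that("decoding accuracy rises with pattern selectivity", {
  mean_acc <- function(sel) {
    mean(vapply(1:6, function(r) {
      bp <- bold_params(n_voxels = 30L, selectivity = sel)
      bank <- make_pattern_bank(bp$n_voxels, sel, 700 + r)
      loc <- simulate_localizer_run(bank, bp, 800 + r)
      folds <- split_folds_by_time(label_localizer_trs(loc$events))
      crossval_accuracy(loc$run$signal, folds)$accuracy
    }, numeric(1)))
  }
  accs <- vapply(c(0, 0.5, 2), mean_acc, numeric(1))
  expect_true(all(diff(accs) > 0))
  expect_lt(accs[1], 0.35)   # zero selectivity decodes at ~chance
})

test_that("trial-period windows are disjoint and follow the stated rule", {
  # target onset 0, delay onset 2, probe onset 20; shift 5, window 6, TR 1
  wins <- wmintrude:::period_windows(
    c(target_presentation = 0, delay = 2, probe_presentation = 20),
    tr_seconds = 1, shift_seconds = 5, window_seconds = 6, gap_trs = 1L)
  expect_equal(wins$target_presentation, 5:10)
  expect_equal(wins$delay, 12L)
  expect_equal(wins$probe_presentation, 26:30)
  expect_equal(length(unlist(wins)), length(unique(unlist(wins))))
})

test_that("trial evidence averages the right TRs", {
  # constant trace -> every period evidence equals the constant
  n_t <- 60L
  trace <- matrix(rep(c(0.3, 0.6, 0.1, 0.9), each = n_t), n_t, 4L)
  colnames(trace) <- c("left_face", "right_face", "left_scene", "right_scene")
  events <- data.frame(
    onset = c(0, 2, 20), duration = c(2, 18, 4),
    trial_type = c("target_presentation", "delay", "probe_presentation"),
    trial = 1L, stringsAsFactors = FALSE)
  ev <- extract_trial_evidence(trace, events, tr_seconds = 1)
  expect_equal(nrow(ev), 3L)
  for (p in unique(ev$period)) {
    expect_equal(unlist(ev[ev$period == p, colnames(trace)]),
                 c(left_face = 0.3, right_face = 0.6, left_scene = 0.1,
                   right_scene = 0.9))
  }

  # class active only in the delay window shows up only there
  trace2 <- trace
  trace2[, "left_face"] <- 0.1
  trace2[13, "left_face"] <- 0.9   # TR 12 (0-based) is the delay window
  ev2 <- extract_trial_evidence(trace2, events, tr_seconds = 1)
  expect_gt(ev2[ev2$period == "delay", "left_face"],
            max(ev2[ev2$period != "delay", "left_face"]))
})

test_that("decoded delay evidence tracks the planted reinstatement trace", {
  fx <- fixture_exp3(seed = 505L, n_trials = 60L)
  p <- generative_params()
  trace <- simulate_reinstatement(fx$trials, fx$design, p, 50)
  run_r <- function(bp, dec_seed) {
    dec <- fixture_decoder(seed = 606L, bp = bp)
    task <- simulate_dnms_run(fx$trials, trace, fx$design, dec$bank, bp,
                              dec_seed)
    evtr <- score_evidence(dec$model, task$run)
    scal <- evidence_scalars(extract_trial_evidence(evtr, task$events),
                             fx$trials, fx$design)
    pctx <- wmintrude:::probe_context(fx$trials, fx$design)
    true_delay <- vapply(seq_len(nrow(fx$trials)), function(i) {
      trace[i, "delay", pctx[i]]
    }, numeric(1))
    cor(scal$ev_probe_delay, true_delay)
  }
  lown <- bold_params(noise_ar_sd = 0.02, noise_white_sd = 0.02)
  expect_gt(run_r(lown, 51), 0.5)
  # at the default (paper-anchored) SNR the coupling is weaker but present
  expect_gt(mean(vapply(52:54, function(s) run_r(bold_params(), s),
                        numeric(1))), 0.15)
})

test_that("the group target-context contrast behaves under signal and null", {
  planted <- simulate_dnms_cohort(8L, generative_params(), seed = 61L,
                                  n_trials = 24L)
  tab <- trace_model_table(planted)
  res <- target_context_contrast(tab)
  expect_equal(res$df, 7)
  expect_gt(res$mean_diff, 0)
  expect_lt(res$p, 0.01)

  nullco <- simulate_dnms_cohort(8L, null_params(), seed = 62L,
                                 n_trials = 24L)
  res0 <- target_context_contrast(trace_model_table(nullco))
  expect_lt(abs(res0$mean_diff), 0.02)
})
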