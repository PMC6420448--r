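#' Label localizer TRs by miniblock class
#'
#' Shifts every miniblock window forward by `shift_seconds` to account for
#' haemodynamic lag and labels the TRs inside the shifted half-open window
#' `[onset + shift, onset + duration + shift)` with the block's class.
#' Only the four trained classes (left/right face/scene) are labeled;
#' object and scrambled-scene blocks and interblock intervals stay unlabeled.
#'
#' @param events localizer event table (onset, duration, trial_type, block).
#' @param tr_seconds sampling interval of the run.
#' @param shift_seconds haemodynamic shift (default 5).
#' @param classes the trained classes.
#' @return data.frame with columns `tr` (0-based index), `label`, `block`.
#' @export
label_localizer_trs <- function(events, tr_seconds = 1, shift_seconds = 5,
                                classes = c("left_face", "right_face",
                                            "left_scene", "right_scene")) {
  ev <- events[events$trial_type %in% classes, , drop = FALSE]
  rows <- lapply(seq_len(nrow(ev)), function(i) {
    lo <- ev$onset[i] + shift_seconds
    hi <- ev$onset[i] + ev$duration[i] + shift_seconds
    trs <- seq(ceiling(lo / tr_seconds), ceiling(hi / tr_seconds) - 1L)
    trs <- trs[trs * tr_seconds >= lo & trs * tr_seconds < hi]
    data.frame(tr = trs, label = ev$trial_type[i], block = ev$block[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$tr), , drop = FALSE]
  if (anyDuplicated(out$tr)) {
    stop("shifted miniblock label windows overlap")
  }
  rownames(out) <- NULL
  out
}

#' Split labeled TRs into temporally contiguous folds
#'
#' Assigns whole miniblocks, in temporal order, to `k` contiguous groups of
#' near-equal block count (sizes differing by at most one block), so no block
#' straddles folds and each fold is one contiguous stretch of the run.
#'
#' @param labels a [label_localizer_trs()] table.
#' @param k number of folds (default 4).
#' @return the table with an added `fold` column.
#' @export
split_folds_by_time <- function(labels, k = 4L) {
  stopifnot(k >= 2L)
  blocks <- unique(labels$block[order(labels$tr)])
  if (length(blocks) < k) stop("fewer blocks than folds")
  sizes <- rep(length(blocks) %/% k, k)
  extra <- length(blocks) %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold_of_block <- stats::setNames(rep(seq_len(k), sizes), blocks)
  labels$fold <- unname(fold_of_block[as.character(labels$block)])
  labels
}

# L2-penalized binary logistic regression by Newton / IRLS.
# Intercept unpenalized; returns list(w, b). X must already be standardized.
ridge_logistic <- function(X, y, lambda, max_iter = 100L, tol = 1e-9) {
  n <- nrow(X)
  p <- ncol(X)
  Xa <- cbind(1, X)
  beta <- numeric(p + 1L)
  pen <- c(0, rep(lambda, p))
  for (it in seq_len(max_iter)) {
    eta <- drop(Xa %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(Xa, y - mu)) - pen * beta
    H <- crossprod(Xa * w, Xa)
    diag(H) <- diag(H) + pen
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(b = beta[1L], w = beta[-1L])
}

#' Train the one-vs-rest evidence model
#'
#' Fits four independent L2-regularized binary logistic units, one per class
#' against all other labeled TRs. Because the units are independent their
#' probability outputs are each in [0,1] but do not sum to 1, so simultaneous
#' evidence for several contexts is representable. Features are standardized
#' with training-set mean and SD (stored in the model and re-applied at
#' scoring time); the intercepts are unpenalized.
#'
#' @param X numeric matrix of training features (labeled TRs x voxels).
#' @param y character/factor vector of class labels.
#' @param lambda ridge penalty on standardized features (default 1).
#' @return object of class `evidence_model`: `classes`, `W` (voxels x
#'   classes), `b` (intercepts), `center`, `scale`, `lambda`.
#' @export
train_evidence_model <- function(X, y, lambda = 1) {
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least 2 classes in training data")
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  fits <- lapply(classes, function(cl) {
    ridge_logistic(Xs, as.numeric(y == cl), lambda)
  })
  W <- vapply(fits, function(f) f$w, numeric(ncol(X)))
  colnames(W) <- classes
  structure(
    list(classes = classes, W = W,
         b = vapply(fits, function(f) f$b, numeric(1)),
         center = center, scale = scale, lambda = lambda),
    class = "evidence_model"
  )
}

#' @export
print.evidence_model <- function(x, ...) {
  cat("One-vs-rest L2 logistic evidence model:",
      length(x$classes), "classes,", nrow(x$W), "features, lambda =",
      x$lambda, "\n")
  invisible(x)
}

#' Score per-TR class evidence
#'
#' Applies the trained units to every volume, after standardizing features
#' with the training-set parameters. Each output is an independent
#' probability in [0,1]; the four outputs do not sum to 1.
#'
#' @param model an [train_evidence_model()] result.
#' @param run a `bold_run`, or a plain T x voxels matrix.
#' @return T x n_classes matrix of class `evidence_trace` (attribute `tr`
#'   carries the sampling interval when a `bold_run` was scored).
#' @export
score_evidence <- function(model, run) {
  X <- if (inherits(run, "bold_run")) run$signal else run
  if (ncol(X) != nrow(model$W)) {
    stop("feature dimensionality (", ncol(X),
         ") does not match training (", nrow(model$W), ")")
  }
  Xs <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  ev <- stats::plogis(sweep(Xs %*% model$W, 2L, model$b, "+"))
  colnames(ev) <- model$classes
  if (inherits(run, "bold_run")) attr(ev, "tr") <- run$tr
  class(ev) <- c("evidence_trace", class(ev))
  ev
}

#' Cross-validated localizer decoding accuracy
#'
#' Leave-one-fold-out cross-validation over the temporally contiguous folds:
#' train the evidence model on k-1 folds, predict the held-out fold by argmax
#' over the four unit outputs, and average the fraction correct over folds.
#'
#' @param X T x voxels feature matrix for the whole run.
#' @param labels a [split_folds_by_time()] table (`tr` 0-based, `label`,
#'   `fold`).
#' @param lambda ridge penalty.
#' @return list with `accuracy` (mean over folds), `fold_accuracy`, `k`.
#' @export
crossval_accuracy <- function(X, labels, lambda = 1) {
  if (is.null(labels$fold)) stop("labels must carry a fold column")
  folds <- sort(unique(labels$fold))
  fold_acc <- vapply(folds, function(f) {
    train <- labels[labels$fold != f, ]
    test <- labels[labels$fold == f, ]
    model <- train_evidence_model(X[train$tr + 1L, , drop = FALSE],
                                  train$label, lambda)
    ev <- score_evidence(model, X[test$tr + 1L, , drop = FALSE])
    pred <- model$classes[max.col(ev, ties.method = "first")]
    mean(pred == test$label)
  }, numeric(1))
  list(accuracy = mean(fold_acc), fold_accuracy = fold_acc,
       k = length(folds))
}

# TR windows for the three periods of one trial, after the
# earlier-period-wins conflict rule and the 1-TR gap
period_windows <- function(period_onsets, tr_seconds, shift_seconds,
                           window_seconds, gap_trs) {
  claimed <- integer(0)
  out <- list()
  for (i in seq_along(period_onsets)) {
    lo <- period_onsets[[i]] + shift_seconds
    hi <- lo + window_seconds
    trs <- seq(ceiling(lo / tr_seconds), ceiling(hi / tr_seconds) - 1L)
    trs <- trs[trs * tr_seconds >= lo & trs * tr_seconds < hi]
    trs <- setdiff(trs, claimed)
    if (i > 1L && gap_trs > 0L && length(trs) > 0L) {
      trs <- trs[-seq_len(min(gap_trs, length(trs)))]
    }
    if (length(trs) == 0L) {
      stop("empty TR window for period ", names(period_onsets)[i],
           " after conflict resolution")
    }
    claimed <- c(claimed, trs)
    out[[names(period_onsets)[i]]] <- trs
  }
  out
}

#' Extract per-trial, per-period class evidence
#'
#' For each DNMS trial and each period (target presentation, delay, probe
#' presentation), averages the per-TR class evidence over the haemodynamically
#' shifted window `[onset + shift, onset + shift + window)`. TRs already
#' claimed by an earlier period's window are dropped from later windows, and
#' each non-first window then loses its first remaining TR (the 1-TR gap that
#' limits signal bleed between periods), so the three windows never share a
#' TR.
#'
#' @param trace an [score_evidence()] trace covering the run.
#' @param events DNMS event table (onset, duration, trial_type, trial).
#' @param tr_seconds sampling interval (defaults to the trace's `tr`
#'   attribute, else 1).
#' @param shift_seconds haemodynamic shift (default 5).
#' @param window_seconds window length (default 6).
#' @param gap_trs leading TRs dropped from each non-first window (default 1).
#' @return data.frame: `trial`, `period`, one evidence column per class.
#' @export
extract_trial_evidence <- function(trace, events, tr_seconds = NULL,
                                   shift_seconds = 5, window_seconds = 6,
                                   gap_trs = 1L) {
  if (is.null(tr_seconds)) {
    tr_seconds <- attr(trace, "tr")
    if (is.null(tr_seconds)) tr_seconds <- 1
  }
  period_names <- c("target_presentation", "delay", "probe_presentation")
  rows <- list()
  for (tr_id in unique(events$trial)) {
    ev <- events[events$trial == tr_id, ]
    onsets <- stats::setNames(
      ev$onset[match(period_names, ev$trial_type)], period_names)
    if (anyNA(onsets)) stop("trial ", tr_id, " missing a period event")
    wins <- period_windows(onsets, tr_seconds, shift_seconds,
                           window_seconds, gap_trs)
    for (p in period_names) {
      idx <- wins[[p]] + 1L
      if (max(idx) > nrow(trace)) stop("evidence trace does not cover trial ",
                                       tr_id)
      m <- colMeans(trace[idx, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        trial = tr_id, period = p, t(m), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reduce class evidence to probe/target context scalars
#'
#' Maps the four class evidences onto the trial's contexts and derives, per
#' trial and period: the probe-word context's evidence (`ev_probe_*`), the
#' mean over the other three contexts (`ev_nonprobe_*`), the target-set
#' context's evidence (`ev_target_ctx_*`) and the mean over non-target
#' contexts (`ev_nontarget_ctx_*`).
#'
#' @param evidence an [extract_trial_evidence()] table.
#' @param trials the [generate_dnms_trials()] table for the run.
#' @param design the design (lateralized contexts).
#' @return data.frame with one row per trial and the derived scalar columns,
#'   suffixed by period (`target_presentation`, `delay`,
#'   `probe_presentation`).
#' @export
evidence_scalars <- function(evidence, trials, design) {
  kinds <- context_kinds(design)  # context_id -> class name
  pctx <- probe_context(trials, design)
  out <- data.frame(trial = trials$trial)
  periods <- unique(evidence$period)
  for (p in periods) {
    evp <- evidence[evidence$period == p, , drop = FALSE]
    evp <- evp[match(trials$trial, evp$trial), , drop = FALSE]
    get_ev <- function(ctx_ids) {
      m <- as.matrix(evp[, kinds[ctx_ids], drop = FALSE])
      rowMeans(m)
    }
    probe_ev <- vapply(seq_len(nrow(trials)), function(i) {
      evp[[kinds[[pctx[i]]]]][i]
    }, numeric(1))
    nonprobe_ev <- vapply(seq_len(nrow(trials)), function(i) {
      others <- setdiff(names(kinds), pctx[i])
      mean(as.numeric(evp[i, kinds[others]]))
    }, numeric(1))
    target_ev <- vapply(seq_len(nrow(trials)), function(i) {
      evp[[kinds[[trials$context_id[i]]]]][i]
    }, numeric(1))
    nontarget_ev <- vapply(seq_len(nrow(trials)), function(i) {
      others <- setdiff(names(kinds), trials$context_id[i])
      mean(as.numeric(evp[i, kinds[others]]))
    }, numeric(1))
    out[[paste0("ev_probe_", p)]] <- probe_ev
    out[[paste0("ev_nonprobe_", p)]] <- nonprobe_ev
    out[[paste0("ev_target_ctx_", p)]] <- target_ev
    out[[paste0("ev_nontarget_ctx_", p)]] <- nontarget_ev
  }
  out
}

#' Group test of target- vs nontarget-context delay evidence
#'
#' Per subject, averages (target-context minus mean nontarget-context)
#' delay-period evidence over trials, then tests the subject means against
#' zero with a two-sided one-sample t test.
#'
#' @param scalars table with columns `subject`, `ev_target_ctx_delay`,
#'   `ev_nontarget_ctx_delay` (e.g. pooled [evidence_scalars()] output).
#' @return list with `subject_means`, `mean_diff`, `t`, `df`, `p`.
#' @export
target_context_contrast <- function(scalars) {
  d <- scalars$ev_target_ctx_delay - scalars$ev_nontarget_ctx_delay
  subj_means <- tapply(d, scalars$subject, mean)
  if (length(subj_means) < 2L) stop("need >= 2 subjects")
  tt <- stats::t.test(subj_means)
  list(subject_means = subj_means, mean_diff = mean(subj_means),
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}
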