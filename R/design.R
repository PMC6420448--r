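#' Experiment design configuration
#'
#' Builds the configuration for a word-context experiment: a vocabulary
#' partitioned into context sets, each set bound to a picture context.
#' Two canonical layouts are provided by [exp1_config()] (six scene contexts
#' of 12 words, as in the free-recall experiment) and [exp3_config()] (four
#' contexts of 12 words crossing picture kind face/scene with side
#' left/right, as in the scanned DNMS experiment).
#'
#' @param n_sets number of context sets.
#' @param words_per_set words per context set (default 12).
#' @param words_per_trial words shown per learning trial (default 4).
#' @param repetitions times each word is presented during learning (default 3).
#' @param context_style `"scene"` for scene-only contexts (side `"none"`), or
#'   `"face_scene"` for the crossed face/scene x left/right layout, in which
#'   case `n_sets` must be 4 and each of the four (kind, side) combinations
#'   is used exactly once.
#' @return a list of class `design_config`.
#' @export
design_config <- function(n_sets, words_per_set = 12L, words_per_trial = 4L,
                          repetitions = 3L,
                          context_style = c("scene", "face_scene")) {
  context_style <- match.arg(context_style)
  stopifnot(n_sets >= 1L, words_per_set >= words_per_trial,
            words_per_trial >= 1L, repetitions >= 1L)
  if (context_style == "face_scene" && n_sets != 4L) {
    stop("face_scene context style requires exactly 4 sets")
  }
  structure(
    list(n_sets = as.integer(n_sets),
         words_per_set = as.integer(words_per_set),
         words_per_trial = as.integer(words_per_trial),
         repetitions = as.integer(repetitions),
         context_style = context_style),
    class = "design_config"
  )
}

#' @rdname design_config
#' @export
exp1_config <- function() design_config(6L, context_style = "scene")

#' @rdname design_config
#' @export
exp3_config <- function() design_config(4L, context_style = "face_scene")

#' Build an experiment design
#'
#' Partitions a vocabulary into context sets and assigns each set a picture
#' context. Word-to-set and context-to-set assignments are randomized by
#' `seed`. If no vocabulary is supplied, synthetic word identifiers
#' `w001, w002, ...` are generated.
#'
#' @param config a [design_config()].
#' @param seed integer seed.
#' @param vocabulary optional character vector of at least
#'   `n_sets * words_per_set` unique word identifiers.
#' @return an object of class `experiment_design` with elements `words`
#'   (data.frame: word_id, set_id), `contexts` (data.frame: context_id,
#'   picture_kind, side), `params` (the config) and `seed`.
#' @export
build_design <- function(config, seed, vocabulary = NULL) {
  stopifnot(inherits(config, "design_config"))
  n_words <- config$n_sets * config$words_per_set
  if (is.null(vocabulary)) {
    vocabulary <- sprintf("w%03d", seq_len(n_words))
  }
  if (anyDuplicated(vocabulary)) stop("vocabulary contains duplicates")
  if (length(vocabulary) < n_words) {
    stop("vocabulary smaller than n_sets * words_per_set (need ",
         n_words, ", got ", length(vocabulary), ")")
  }
  set.seed(seed)
  chosen <- sample(vocabulary, n_words)
  set_ids <- sprintf("set%d", seq_len(config$n_sets))
  words <- data.frame(
    word_id = chosen,
    set_id = rep(set_ids, each = config$words_per_set),
    stringsAsFactors = FALSE
  )
  if (config$context_style == "scene") {
    contexts <- data.frame(
      context_id = set_ids,
      picture_kind = "scene",
      side = "none",
      stringsAsFactors = FALSE
    )
  } else {
    combos <- expand.grid(picture_kind = c("face", "scene"),
                          side = c("left", "right"),
                          stringsAsFactors = FALSE)
    combos <- combos[sample.int(nrow(combos)), , drop = FALSE]
    contexts <- data.frame(
      context_id = set_ids,
      picture_kind = combos$picture_kind,
      side = combos$side,
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(words = words, contexts = contexts, params = config, seed = seed),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Experiment design:", x$params$n_sets, "context sets x",
      x$params$words_per_set, "words (", nrow(x$words), "words total)\n")
  cat("  context style:", x$params$context_style,
      "| learning repetitions:", x$params$repetitions,
      "| words per trial:", x$params$words_per_trial, "\n")
  invisible(x)
}

# words belonging to one set, in vocabulary order
set_words <- function(design, set_id) {
  design$words$word_id[design$words$set_id == set_id]
}

#' Generate a context-learning schedule
#'
#' Emits learning trials of `words_per_trial` words, all drawn from the same
#' context set, such that every word in the design appears exactly
#' `repetitions` times across the schedule. Companions within a trial are
#' sampled uniformly without replacement within the set, subject to the exact
#' repetition quota (random quota-respecting assignment with rejection and a
#' swap-repair fallback).
#'
#' @param design an [build_design()] result.
#' @param seed integer seed.
#' @return data.frame of class `learning_schedule` with columns `trial`,
#'   `context_id`, `w1..w4` (one column per within-trial slot).
#' @export
generate_learning_schedule <- function(design, seed) {
  p <- design$params
  per_set_slots <- p$words_per_set * p$repetitions
  if (per_set_slots %% p$words_per_trial != 0L) {
    stop("words_per_set * repetitions must be divisible by words_per_trial")
  }
  trials_per_set <- per_set_slots %/% p$words_per_trial
  set.seed(seed)
  blocks <- lapply(design$contexts$context_id, function(cid) {
    words <- set_words(design, cid)
    groups <- quota_groups(words, p$repetitions, p$words_per_trial)
    data.frame(
      context_id = cid,
      t(vapply(groups, identity, character(p$words_per_trial))),
      stringsAsFactors = FALSE
    )
  })
  sched <- do.call(rbind, blocks)
  names(sched) <- c("context_id", paste0("w", seq_len(p$words_per_trial)))
  # interleave trials of different sets in random order
  sched <- sched[sample.int(nrow(sched)), , drop = FALSE]
  sched <- cbind(trial = seq_len(nrow(sched)), sched)
  rownames(sched) <- NULL
  class(sched) <- c("learning_schedule", "data.frame")
  sched
}

# Partition `rep(words, reps)` into groups of size k with no duplicate within
# a group. Random shuffles with rejection; deterministic pairwise swap repair
# if rejection fails repeatedly.
quota_groups <- function(words, reps, k, max_tries = 200L) {
  slots <- rep(words, reps)
  n_groups <- length(slots) %/% k
  for (try in seq_len(max_tries)) {
    perm <- sample(slots)
    groups <- split(perm, rep(seq_len(n_groups), each = k))
    if (!any(vapply(groups, anyDuplicated, 0L) > 0L)) {
      return(unname(groups))
    }
  }
  # repair: swap a duplicated entry with an entry from another group that
  # does not create a new duplicate in either group
  groups <- split(sample(slots), rep(seq_len(n_groups), each = k))
  repeat {
    dup_idx <- which(vapply(groups, anyDuplicated, 0L) > 0L)
    if (length(dup_idx) == 0L) break
    g <- dup_idx[1L]
    d <- groups[[g]][anyDuplicated(groups[[g]])]
    fixed <- FALSE
    for (h in setdiff(seq_along(groups), g)) {
      for (j in seq_along(groups[[h]])) {
        cand <- groups[[h]][j]
        if (!cand %in% groups[[g]] &&
            sum(groups[[h]] == d) == 0L) {
          pos <- which(groups[[g]] == d)[1L]
          groups[[g]][pos] <- cand
          groups[[h]][j] <- d
          fixed <- TRUE
          break
        }
      }
      if (fixed) break
    }
    if (!fixed) stop("could not repair learning schedule quota assignment")
  }
  unname(groups)
}

# extract the word columns of a schedule/trial table as a character matrix
word_matrix <- function(tab) {
  cols <- grep("^w[0-9]+$", names(tab), value = TRUE)
  as.matrix(tab[, cols, drop = FALSE])
}

#' Generate free-recall trials
#'
#' Emits `3 * n_per_condition` short-term retention trials, with the three
#' delay conditions (`none`, `break`, `full`) randomly intermixed and the
#' constraint that consecutive trials never share a context (so that
#' previous-trial and same-context substitution categories are mutually
#' exclusive).
#'
#' @param design an [build_design()] result with at least 2 context sets.
#' @param seed integer seed.
#' @param n_per_condition trials per delay condition (default 18).
#' @return data.frame of class `recall_trials` with columns `trial`,
#'   `context_id`, `condition`, `w1..w4`.
#' @export
generate_recall_trials <- function(design, seed, n_per_condition = 18L) {
  p <- design$params
  if (p$n_sets < 2L) {
    stop("recall trials need >= 2 context sets (consecutive trials must differ in context)")
  }
  set.seed(seed)
  n_trials <- 3L * n_per_condition
  conditions <- sample(rep(c("none", "break", "full"), n_per_condition))
  ctx_ids <- design$contexts$context_id
  ctx_seq <- character(n_trials)
  ctx_seq[1L] <- sample(ctx_ids, 1L)
  for (i in seq_len(n_trials - 1L) + 1L) {
    ctx_seq[i] <- sample(setdiff(ctx_ids, ctx_seq[i - 1L]), 1L)
  }
  targets <- t(vapply(ctx_seq, function(cid) {
    sample(set_words(design, cid), p$words_per_trial)
  }, character(p$words_per_trial)))
  out <- data.frame(
    trial = seq_len(n_trials),
    context_id = ctx_seq,
    condition = conditions,
    targets,
    stringsAsFactors = FALSE
  )
  names(out) <- c("trial", "context_id", "condition",
                  paste0("w", seq_len(p$words_per_trial)))
  rownames(out) <- NULL
  class(out) <- c("recall_trials", "data.frame")
  out
}

#' Generate delayed-nonmatch-to-sample (DNMS) trials
#'
#' Each trial presents `words_per_trial` target words from one randomly
#' selected context and probes with a single word that is a `target` (member
#' of the target set, correct response `match`), a `lure` (same context set,
#' not a target, correct response `mismatch`), or an `other`-context word
#' (different set, `mismatch`). The three probe types occur in equal numbers.
#' When a learning `schedule` is supplied the probe-target `overlap` statistic
#' is computed with [compute_overlap()].
#'
#' @param design an [build_design()] result with at least 2 context sets.
#' @param seed integer seed.
#' @param n_trials number of trials, divisible by 3 (default 60).
#' @param schedule optional [generate_learning_schedule()] result used to
#'   populate the `overlap` column.
#' @return data.frame of class `dnms_trials` with columns `trial`,
#'   `context_id`, `w1..w4`, `probe_id`, `probe_type`, `correct_response`,
#'   `overlap`.
#' @export
generate_dnms_trials <- function(design, seed, n_trials = 60L,
                                 schedule = NULL) {
  p <- design$params
  if (n_trials %% 3L != 0L) stop("n_trials must be divisible by 3")
  if (p$n_sets < 2L) stop("DNMS trials need >= 2 context sets")
  set.seed(seed)
  probe_types <- sample(rep(c("target", "lure", "other"), n_trials %/% 3L))
  ctx_ids <- design$contexts$context_id
  ctx_seq <- sample(ctx_ids, n_trials, replace = TRUE)
  k <- p$words_per_trial
  rows <- lapply(seq_len(n_trials), function(i) {
    cid <- ctx_seq[i]
    words <- set_words(design, cid)
    targets <- sample(words, k)
    probe <- switch(probe_types[i],
      target = sample(targets, 1L),
      lure = sample(setdiff(words, targets), 1L),
      other = {
        other_ctx <- sample(setdiff(ctx_ids, cid), 1L)
        sample(set_words(design, other_ctx), 1L)
      })
    c(cid, targets, probe)
  })
  m <- do.call(rbind, rows)
  out <- data.frame(
    trial = seq_len(n_trials),
    context_id = m[, 1L],
    m[, 1L + seq_len(k), drop = FALSE],
    probe_id = m[, k + 2L],
    probe_type = probe_types,
    correct_response = ifelse(probe_types == "target", "match", "mismatch"),
    stringsAsFactors = FALSE
  )
  names(out)[2L + seq_len(k)] <- paste0("w", seq_len(k))
  out$overlap <- if (is.null(schedule)) NA_integer_ else
    vapply(seq_len(n_trials), function(i) {
      compute_overlap(schedule, out[i, ])
    }, integer(1))
  rownames(out) <- NULL
  class(out) <- c("dnms_trials", "data.frame")
  out
}

#' Probe-target overlap during context learning
#'
#' Counts, over all learning trials that contained the probe word, the number
#' of (learning-trial, target-word) co-presentations between the probe and the
#' current trial's target words, excluding the probe itself from the target
#' set. With 3 repetitions and 4-word learning trials the statistic is bounded
#' by `repetitions * (words_per_trial - 1) = 9`.
#'
#' @param schedule a [generate_learning_schedule()] result.
#' @param trial one row of a [generate_dnms_trials()] table (or any list with
#'   `probe_id` and target columns `w1..w4`).
#' @return nonnegative integer.
#' @export
compute_overlap <- function(schedule, trial) {
  probe <- trial$probe_id
  targets <- setdiff(as.character(word_matrix(trial)[1L, ]), probe)
  sched_words <- word_matrix(schedule)
  has_probe <- rowSums(sched_words == probe) > 0L
  if (!any(has_probe)) stop("probe word absent from the learning schedule")
  sum(vapply(which(has_probe), function(r) {
    companions <- setdiff(sched_words[r, ], probe)
    length(intersect(companions, targets))
  }, integer(1)))
}
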