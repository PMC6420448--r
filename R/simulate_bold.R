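#' BOLD simulation parameters
#'
#' @param n_voxels number of synthetic voxels (abstract features, no
#'   geometry).
#' @param selectivity scale of the class-specific pattern component relative
#'   to the shared component; 0 makes all class patterns identical.
#' @param noise_ar_sd innovation SD of the AR(1) noise component.
#' @param noise_white_sd SD of the additional white Gaussian noise.
#' @param ar_rho AR(1) coefficient of the temporally correlated noise.
#' @param tr_seconds sampling interval (default 1 s).
#' @param lead_in_seconds quiet period before the first event.
#' @param iti_seconds inter-trial interval appended after each DNMS probe
#'   period.
#' @param task_gain multiplies reinstatement-trace intensities on their way
#'   into the neural signal of a DNMS run. The default is calibrated so that
#'   decoded evidence is approximately on the scale of the latent trace
#'   (see the methods vignette), which is what lets the mixed models recover
#'   planted ms-per-evidence-unit couplings on their nominal scale.
#' @return list of class `bold_params`.
#' @export
bold_params <- function(n_voxels = 60L, selectivity = 1,
                        noise_ar_sd = 0.18, noise_white_sd = 0.18,
                        ar_rho = 0.3, tr_seconds = 1,
                        lead_in_seconds = 12, iti_seconds = 8,
                        task_gain = 1) {
  stopifnot(n_voxels >= 2L, selectivity >= 0, noise_ar_sd >= 0,
            noise_white_sd >= 0, abs(ar_rho) < 1, tr_seconds > 0)
  structure(as.list(environment()), class = "bold_params")
}

#' Category-selective voxel pattern bank
#'
#' One unit-norm pattern vector per stimulus kind (faces, scenes, objects and
#' scrambled scenes, each lateralized left/right). Every pattern is a shared
#' component plus `selectivity` times a class-specific random component,
#' renormalized; with `selectivity = 0` all patterns are identical and
#' nothing is decodable.
#'
#' @param n_voxels number of voxels.
#' @param selectivity nonnegative scalar.
#' @param seed integer seed.
#' @return matrix of class `pattern_bank` (8 rows, one per kind,
#'   `n_voxels` columns), rownames `left_face`, `right_face`, ...
#' @export
make_pattern_bank <- function(n_voxels, selectivity, seed) {
  stopifnot(n_voxels >= 2L, selectivity >= 0)
  set.seed(seed)
  kinds <- c("left_face", "right_face", "left_scene", "right_scene",
             "left_object", "right_object", "left_scrambled",
             "right_scrambled")
  shared <- stats::rnorm(n_voxels)
  bank <- t(vapply(kinds, function(k) {
    v <- shared + selectivity * stats::rnorm(n_voxels)
    v / sqrt(sum(v^2))
  }, numeric(n_voxels)))
  attr(bank, "selectivity") <- selectivity
  class(bank) <- c("pattern_bank", class(bank))
  bank
}

# stimulus kind ("left_face", ...) for each context of a design
context_kinds <- function(design) {
  ctx <- design$contexts
  if (any(ctx$side == "none")) {
    stop("BOLD simulation needs lateralized face/scene contexts (exp3_config)")
  }
  stats::setNames(paste(ctx$side, ctx$picture_kind, sep = "_"),
                  ctx$context_id)
}

#' Canonical double-gamma haemodynamic response kernel
#'
#' Peak response at 5 s, undershoot peaking at 15 s (one sixth amplitude),
#' normalized to unit sum so that a sustained unit boxcar plateaus at 1.
#'
#' @param tr_seconds sampling interval.
#' @param duration_seconds kernel support (default 32 s).
#' @return numeric vector sampled at `tr_seconds`.
#' @export
hrf_kernel <- function(tr_seconds = 1, duration_seconds = 32) {
  t <- seq(0, duration_seconds, by = tr_seconds)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / sum(h)
}

#' Convolve a neural time series with the haemodynamic kernel
#'
#' Linear, causal convolution; the output has the same length as the input.
#'
#' @param neural numeric vector or T x V matrix (columns convolved
#'   independently).
#' @param tr_seconds sampling interval.
#' @return object of the same shape as `neural`.
#' @export
hrf_convolve <- function(neural, tr_seconds = 1) {
  k <- hrf_kernel(tr_seconds)
  conv1 <- function(x) {
    out <- stats::convolve(x, rev(k), type = "open")[seq_along(x)]
    out
  }
  if (is.matrix(neural)) apply(neural, 2L, conv1) else conv1(neural)
}

# AR(1) + white noise matrix, T x V
bold_noise <- function(n_t, n_v, params) {
  ar <- matrix(stats::rnorm(n_t * n_v, 0, params$noise_ar_sd), n_t, n_v)
  if (params$ar_rho != 0) {
    ar <- apply(ar, 2L, function(x) {
      as.numeric(stats::filter(x, params$ar_rho, method = "recursive"))
    })
  }
  ar + matrix(stats::rnorm(n_t * n_v, 0, params$noise_white_sd), n_t, n_v)
}

new_bold_run <- function(signal, tr, label) {
  structure(list(signal = signal, tr = tr, label = label),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("BOLD run '%s': %d TRs x %d voxels (TR %gs)\n",
              x$label, nrow(x$signal), ncol(x$signal), x$tr))
  invisible(x)
}

#' Simulate a localizer run
#'
#' 24 miniblocks (8 stimulus kinds x 3 repetitions, order randomized), each
#' 10 stimuli of 500 ms + 1.5 s ITI = 20 s of sustained drive, separated by
#' 12-s interblock intervals. The neural drive of a block is a unit boxcar
#' times the block kind's pattern, HRF-convolved; AR(1)-plus-white noise is
#' added on top.
#'
#' @param bank a [make_pattern_bank()] result.
#' @param params [bold_params()].
#' @param seed integer seed.
#' @return list with `run` (a `bold_run`) and `events` (data.frame: onset,
#'   duration, trial_type, block).
#' @export
simulate_localizer_run <- function(bank, params, seed) {
  set.seed(seed)
  kinds <- rownames(bank)
  order <- sample(rep(kinds, 3L))
  block_len <- 20
  ibi <- 12
  onsets <- params$lead_in_seconds + (seq_along(order) - 1L) * (block_len + ibi)
  total_s <- params$lead_in_seconds + length(order) * (block_len + ibi)
  n_t <- ceiling(total_s / params$tr_seconds)
  times <- (seq_len(n_t) - 1L) * params$tr_seconds
  neural <- matrix(0, n_t, ncol(bank))
  for (b in seq_along(order)) {
    on <- times >= onsets[b] & times < onsets[b] + block_len
    neural[on, ] <- neural[on, ] +
      matrix(bank[order[b], ], sum(on), ncol(bank), byrow = TRUE)
  }
  signal <- hrf_convolve(neural, params$tr_seconds) +
    bold_noise(n_t, ncol(bank), params)
  events <- data.frame(onset = onsets, duration = block_len,
                       trial_type = order, block = seq_along(order),
                       stringsAsFactors = FALSE)
  list(run = new_bold_run(signal, params$tr_seconds, "localizer"),
       events = events)
}

#' Simulate a DNMS task run
#'
#' Trial timeline: 2 s of target presentation, 18 s delay (probe onset 20 s
#' after target onset), 4 s probe period, then `iti_seconds` of rest. During
#' each period every context's pattern enters the neural signal with
#' amplitude `task_gain` times that context's latent reinstatement intensity
#' for that trial and period, then the whole series is HRF-convolved and
#' noise is added — so decoded evidence inherits the trace's structure.
#'
#' @param trials a [generate_dnms_trials()] table.
#' @param trace a [simulate_reinstatement()] trace for those trials.
#' @param design the design (must have lateralized face/scene contexts).
#' @param bank a [make_pattern_bank()] result.
#' @param params [bold_params()].
#' @param seed integer seed.
#' @return list with `run` (a `bold_run`) and `events` (data.frame: onset,
#'   duration, trial_type in target_presentation/delay/probe_presentation,
#'   trial).
#' @export
simulate_dnms_run <- function(trials, trace, design, bank, params, seed) {
  stopifnot(nrow(trials) == dim(trace)[1L])
  set.seed(seed)
  kinds <- context_kinds(design)
  durations <- c(target_presentation = 2, delay = 18, probe_presentation = 4)
  trial_len <- sum(durations) + params$iti_seconds
  n <- nrow(trials)
  t0 <- params$lead_in_seconds + (seq_len(n) - 1L) * trial_len
  total_s <- params$lead_in_seconds + n * trial_len
  n_t <- ceiling(total_s / params$tr_seconds)
  times <- (seq_len(n_t) - 1L) * params$tr_seconds
  neural <- matrix(0, n_t, ncol(bank))
  period_onsets <- cumsum(c(0, durations))[1:3]
  names(period_onsets) <- names(durations)
  ev <- list()
  for (i in seq_len(n)) {
    for (p in names(durations)) {
      on_s <- t0[i] + period_onsets[[p]]
      sel <- times >= on_s & times < on_s + durations[[p]]
      for (cid in names(kinds)) {
        amp <- params$task_gain * trace[i, p, cid]
        if (amp != 0) {
          neural[sel, ] <- neural[sel, ] +
            amp * matrix(bank[kinds[[cid]], ], sum(sel), ncol(bank),
                         byrow = TRUE)
        }
      }
      ev[[length(ev) + 1L]] <- data.frame(
        onset = on_s, duration = durations[[p]], trial_type = p,
        trial = trials$trial[i], stringsAsFactors = FALSE)
    }
  }
  signal <- hrf_convolve(neural, params$tr_seconds) +
    bold_noise(n_t, ncol(bank), params)
  list(run = new_bold_run(signal, params$tr_seconds, "dnms"),
       events = do.call(rbind, ev))
}

#' High-pass filter a BOLD run
#'
#' Removes slow drift by regressing out an intercept and the discrete-cosine
#' basis functions with period longer than `cutoff_seconds` (the standard
#' 128-s default), returning the residuals.
#'
#' @param run a `bold_run`.
#' @param cutoff_seconds cutoff period.
#' @return a filtered `bold_run`.
#' @export
highpass <- function(run, cutoff_seconds = 128) {
  n_t <- nrow(run$signal)
  total_s <- n_t * run$tr
  if (total_s <= cutoff_seconds) {
    stop("run shorter than one cutoff period")
  }
  n_basis <- floor(2 * total_s / cutoff_seconds)
  t_idx <- seq_len(n_t) - 0.5
  dct <- vapply(seq_len(n_basis), function(k) {
    cos(pi * k * t_idx / n_t)
  }, numeric(n_t))
  X <- cbind(1, dct)
  resid <- run$signal - X %*% qr.coef(qr(X), run$signal)
  new_bold_run(resid, run$tr, run$label)
}
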