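# Isosbestic motion correction -------------------------------------------------

#' Regress the isosbestic channel out of the calcium channel
#'
#' Ordinary least squares of the slow-corrected 410-nm signal onto the
#' slow-corrected 470-nm signal; the mean-centred fitted control signal
#' is subtracted so that shared motion fluctuations are removed while
#' the 470 baseline level (needed for the mode-based F0) is preserved.
#' Because the residual is orthogonal to the regressor, applying the
#' operation twice changes nothing beyond numerical noise.
#'
#' @param f470c,f410c Slow-corrected channel traces (equal length).
#' @return List with `corrected` trace and regression slope `beta`.  A
#'   zero-variance 410 channel skips the regression with a warning.
#' @export
regress_out_isosbestic <- function(f470c, f410c) {
  stopifnot(length(f470c) == length(f410c))
  if (stats::var(f410c) < .Machine$double.eps) {
    warning("410 channel has zero variance; regression skipped")
    return(list(corrected = f470c, beta = NA_real_))
  }
  beta <- stats::cov(f410c, f470c) / stats::var(f410c)
  list(corrected = f470c - beta * (f410c - mean(f410c)), beta = beta)
}

#' Motion-correct a photometry session and compute dF/F
#'
#' Pipeline: both channels are slow-drift corrected
#' ([correct_slow_drift()], default 1000-frame window, 5th percentile);
#' the auto-fluorescence (410-nm) signal is fitted to the GCaMP (470-nm)
#' signal by linear regression and the fitted control signal subtracted
#' ([regress_out_isosbestic()]); dF/F is then `(F - F0)/F0` with F0 the
#' histogram mode of the corrected trace.
#'
#' @param session A `photometry_session` ([sim_photometry()]).
#' @param window_frames,percentile Slow-correction parameters (defaults
#'   1000 frames, 5).
#' @return An object of class `photometry_result`: `dff`, `corrected`,
#'   `beta`, plus the session's `events`, `trials`, `frame_rate`, `side`,
#'   `cell_type`, `contra_choice`.
#' @export
motion_correct <- function(session, window_frames = 1000, percentile = 5) {
  f470c <- correct_slow_drift(session$f470, window_frames, percentile)
  f410c <- correct_slow_drift(session$f410, window_frames, percentile)
  rg <- regress_out_isosbestic(f470c, f410c)
  dff <- compute_dff(rg$corrected)
  structure(list(dff = dff, corrected = rg$corrected, beta = rg$beta,
                 events = session$events, trials = session$trials,
                 frame_rate = session$frame_rate, side = session$side,
                 cell_type = session$cell_type,
                 contra_choice = session$contra_choice),
            class = "photometry_result")
}

# per-trial aligned, baseline-subtracted dF/F samples
photometry_trial_frames <- function(pr, align = c("delay_onset", "first_lick"),
                                    window_s = c(-1, 3), smooth_frames = 3) {
  align <- match.arg(align)
  fr <- pr$frame_rate
  # overlapping 3-frame smoothing (centered moving average)
  dff <- as.numeric(stats::filter(pr$dff, rep(1 / smooth_frames,
                                              smooth_frames), sides = 2))
  ev <- pr$events
  trials <- pr$trials
  t_rel <- seq(window_s[1], window_s[2], by = 1 / fr)
  n_t <- length(t_rel)
  mat <- matrix(NA_real_, nrow(trials), n_t)
  delay_on <- ev$sound_on + 0.5
  t0 <- if (align == "delay_onset") delay_on else ev$first_lick
  for (i in seq_len(nrow(trials))) {
    if (is.na(t0[i])) next
    base_idx <- frames_in(fr, length(dff), ev$sound_on[i] - 0.5,
                          ev$sound_on[i])
    base <- if (length(base_idx)) mean(dff[base_idx], na.rm = TRUE) else 0
    idx <- round((t0[i] + t_rel) * fr) + 1L
    ok <- idx >= 1L & idx <= length(dff)
    mat[i, ok] <- dff[idx[ok]] - base
    if (align == "delay_onset") {
      # mask samples after delay offset (go cue) for this trial
      mat[i, t_rel > (ev$go_cue[i] - t0[i])] <- NA
    }
  }
  list(mat = mat, t_rel = t_rel, delay_on = delay_on)
}

#' AUC time course of choice selectivity for a photometry session
#'
#' Trial dF/F traces (smoothed with overlapping 3-frame bins and
#' baseline-subtracted against the pre-sound window) are aligned to delay
#' onset or to the first lick; within each 150-ms centered bin the
#' ipsi-vs-contra AUC is computed across correct trials.  For
#' delay-onset alignment, samples after each trial's delay offset are
#' masked and contribute to no bin.
#'
#' @param pr A `photometry_result`.
#' @param bin_s Centered bin width (s), default 0.15.
#' @param align `"delay_onset"` or `"first_lick"`.
#' @param window_s Analysis window around the alignment point (s).
#' @param min_trials Minimum trials per side below which a warning is
#'   issued.
#' @return Data frame with `time` (bin centers), `auc` (1 =
#'   contralateral preference), `n_ipsi`, `n_contra`.
#' @export
timecourse_auc <- function(pr, bin_s = 0.15,
                           align = c("delay_onset", "first_lick"),
                           window_s = c(-1, 2.5), min_trials = 5) {
  align <- match.arg(align)
  tf <- photometry_trial_frames(pr, align, window_s)
  trials <- pr$trials
  correct <- trials$outcome == "correct"
  contra <- correct & trials$choice == pr$contra_choice
  ipsi <- correct & trials$choice == setdiff(c("left", "right"),
                                             pr$contra_choice)
  if (!any(contra) || !any(ipsi))
    stop("need correct trials on both sides")
  if (sum(contra) < min_trials || sum(ipsi) < min_trials)
    warning("fewer than ", min_trials, " correct trials on one side")
  edges <- seq(window_s[1], window_s[2], by = bin_s)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  out <- data.frame(time = centers, auc = NA_real_,
                    n_ipsi = 0L, n_contra = 0L)
  for (k in seq_along(centers)) {
    cols <- tf$t_rel >= edges[k] & tf$t_rel < edges[k + 1]
    per_trial <- rowMeans(tf$mat[, cols, drop = FALSE], na.rm = TRUE)
    a <- per_trial[contra]; b <- per_trial[ipsi]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    out$n_contra[k] <- length(a); out$n_ipsi[k] <- length(b)
    if (length(a) >= 2L && length(b) >= 2L) out$auc[k] <- roc_auc(a, b)
  }
  out
}

#' Early- and late-epoch choice AUC for a photometry session
#'
#' Early epoch: the 0.5-s sound period.  Late epoch: 1-1.5 s after delay
#' onset, using only samples before each trial's delay offset; trials
#' whose delay does not reach the start of the late window are excluded,
#' and `late_auc` is `NA` when no trial reaches it.  AUCs are across
#' correct trials, oriented so 1 = contralateral preference.
#'
#' @param pr A `photometry_result`.
#' @param late_window_s Late window relative to delay onset (s).
#' @return List with `early_auc`, `late_auc`, `n_early`, `n_late`
#'   (per-side trial counts).
#' @export
early_late_auc <- function(pr, late_window_s = c(1, 1.5)) {
  fr <- pr$frame_rate
  dff <- pr$dff
  ev <- pr$events
  trials <- pr$trials
  delay_on <- ev$sound_on + 0.5
  correct <- trials$outcome == "correct"
  contra <- trials$choice == pr$contra_choice
  n <- nrow(trials)
  early <- late <- rep(NA_real_, n)
  for (i in which(correct)) {
    base_idx <- frames_in(fr, length(dff), ev$sound_on[i] - 0.5,
                          ev$sound_on[i])
    base <- if (length(base_idx)) mean(dff[base_idx]) else 0
    s_idx <- frames_in(fr, length(dff), ev$sound_on[i], ev$sound_on[i] + 0.5)
    if (length(s_idx)) early[i] <- mean(dff[s_idx]) - base
    if (trials$delay[i] >= late_window_s[1]) {
      t1 <- min(delay_on[i] + late_window_s[2], ev$go_cue[i])
      l_idx <- frames_in(fr, length(dff), delay_on[i] + late_window_s[1], t1)
      if (length(l_idx)) late[i] <- mean(dff[l_idx]) - base
    }
  }
  auc_of <- function(v) {
    a <- v[correct & contra]; b <- v[correct & !contra]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L)
      return(list(auc = NA_real_, n = c(length(a), length(b))))
    list(auc = roc_auc(a, b), n = c(length(a), length(b)))
  }
  e <- auc_of(early); l <- auc_of(late)
  list(early_auc = e$auc, late_auc = l$auc,
       n_early = e$n, n_late = l$n)
}

#' Early/late choice-preference consistency across sessions and cell types
#'
#' A session is consistent when its early and late AUCs prefer the same
#' side of 0.5 (an AUC exactly at 0.5 is classified inconsistent and
#' flagged).  Between cell types the consistency proportions are compared
#' with a two-sided 2x2 Pearson chi-squared test (no continuity
#' correction; a corrected variant is available by flag), and the spread
#' of early AUC values with a two-sample F variance test plus a
#' permutation test on the variance difference — both reported because
#' the appropriate variance test is a design choice.
#'
#' @param sessions Data frame with columns `session_id`, `cell_type`,
#'   `early_auc`, `late_auc` (one row per session; see
#'   [early_late_auc()]).
#' @param n_perm Permutation count for the variance test.
#' @param correct Continuity correction for the chi-squared (default
#'   `FALSE`).
#' @param seed Optional integer seed.
#' @return List with `table` (per-session consistency), `counts` (2x2),
#'   `chi2` (`dd_test`), `variance_f` (F test on early AUC),
#'   `variance_perm` (`dd_test`).
#' @export
early_late_consistency <- function(sessions, n_perm = 5000, correct = FALSE,
                                   seed = NULL) {
  stopifnot(all(c("cell_type", "early_auc", "late_auc") %in% names(sessions)))
  types <- unique(sessions$cell_type)
  if (length(types) != 2L) stop("need exactly 2 cell types")
  if (any(table(sessions$cell_type) < 2L))
    stop("need at least 2 sessions per cell type")
  ties <- sessions$early_auc == 0.5 | sessions$late_auc == 0.5
  if (any(ties, na.rm = TRUE))
    message(sum(ties, na.rm = TRUE),
            " session(s) with AUC exactly 0.5 classified inconsistent")
  sessions$consistent <- (sessions$early_auc - 0.5) *
    (sessions$late_auc - 0.5) > 0
  counts <- t(vapply(types, function(tp) {
    s <- sessions$consistent[sessions$cell_type == tp]
    c(consistent = sum(s, na.rm = TRUE),
      inconsistent = sum(!s, na.rm = TRUE))
  }, numeric(2)))
  chi2 <- chi_squared_2x2(counts, correct = correct)
  a <- sessions$early_auc[sessions$cell_type == types[1]]
  b <- sessions$early_auc[sessions$cell_type == types[2]]
  if (var(a) > 0 && var(b) > 0) {
    vf <- stats::var.test(a, b)
    variance_f <- new_test_result(unname(vf$statistic), vf$p.value,
                                  "two-sample F test on early-AUC variance")
  } else {
    variance_f <- new_test_result(NA_real_, 1,
                                  "two-sample F test on early-AUC variance (degenerate: zero spread)")
  }
  variance_perm <- permutation_p(a, b,
                                 statistic = function(x, y) var(x) - var(y),
                                 n = n_perm, seed = seed, exact = FALSE)
  variance_perm$method <- "permutation test on early-AUC variance difference"
  list(table = sessions, counts = counts, chi2 = chi2,
       variance_f = variance_f, variance_perm = variance_perm)
}
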