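# Session timeline ---------------------------------------------------------

#' Lay out trial events on a continuous session clock
#'
#' Places each trial's sound onset, go cue and first lick on a single
#' session time axis (seconds), with a fixed pre-sound baseline and
#' inter-trial gap.  Violation and miss trials get `NA` first-lick times.
#'
#' @param trials Trial table from [sim_behavior()].
#' @param pre_s Pre-sound baseline per trial (s).
#' @param sound_s Stimulus duration (s).
#' @param post_s Time kept after the first lick (or after the go cue when
#'   there is no lick) before the next trial (s).
#' @return Data frame with `trial_id, sound_on, go_cue, first_lick` and an
#'   attribute `duration` (total session length, s).
#' @export
session_events <- function(trials, pre_s = 1, sound_s = 0.5, post_s = 2) {
  n <- nrow(trials)
  sound_on <- numeric(n); go_cue <- numeric(n); first_lick <- rep(NA_real_, n)
  t <- 0
  for (i in seq_len(n)) {
    sound_on[i] <- t + pre_s
    go_cue[i] <- sound_on[i] + sound_s + trials$delay[i]
    rt <- trials$rt[i]
    if (!is.na(rt)) first_lick[i] <- go_cue[i] + rt
    t <- max(go_cue[i], first_lick[i], na.rm = TRUE) + post_s
  }
  ev <- data.frame(trial_id = trials$trial_id, sound_on = sound_on,
                   go_cue = go_cue, first_lick = first_lick)
  attr(ev, "duration") <- t
  ev
}

# Calcium kernel -----------------------------------------------------------

#' Double-exponential calcium indicator kernel
#'
#' `h(t) = (1 - exp(-t/tau_rise)) * exp(-t/tau_decay)`, normalized to a
#' peak of 1.  Defaults approximate GCaMP6s dynamics.
#'
#' @param frame_rate Sampling rate (Hz).
#' @param tau_rise,tau_decay Time constants (s); both must be positive.
#' @param length_s Kernel support (s).
#' @return Numeric vector of kernel samples.
#' @export
calcium_kernel <- function(frame_rate, tau_rise = 0.2, tau_decay = 1.5,
                           length_s = 5 * tau_decay) {
  if (tau_rise <= 0 || tau_decay <= 0) stop("kernel time constants must be > 0")
  t <- seq(0, length_s, by = 1 / frame_rate)
  h <- (1 - exp(-t / tau_rise)) * exp(-t / tau_decay)
  h / max(h)
}

# Analytic AUC <-> mean separation ----------------------------------------

#' Mean separation producing a target AUC for two equal-variance Gaussians
#'
#' For responses `N(mu_a, s^2)` vs `N(mu_b, s^2)`,
#' `AUC = Phi((mu_a - mu_b) / (s * sqrt(2)))`; this inverts that relation.
#'
#' @param auc Target AUC in \[0, 1\].
#' @param sd Common standard deviation of the two distributions.
#' @return `mu_a - mu_b` giving the requested AUC.
#' @export
auc_to_separation <- function(auc, sd = 1) {
  if (any(auc < 0 | auc > 1)) stop("target AUC must be in [0, 1]")
  qnorm(auc) * sd * sqrt(2)
}

# Compensated impulse injection ---------------------------------------------

# Build an impulse train whose convolved trace realizes target window
# responses.  `plan` is a chronological list of events, each with `idx`
# (event frame), `win`/`base` (window and pre-sound-baseline frame
# indices), `mu`/`sd` (target Gaussian for the baseline-subtracted
# window-mean response).  Each amplitude is solved from the target draw
# minus the carryover of all earlier events into this window, divided by
# the event's own window gain.  Events whose net gain is tiny (window
# nearly outside the kernel support) are skipped.
compensated_impulses <- function(n_frames, kern, plan) {
  imp <- numeric(n_frames)
  hist_idx <- integer(0); hist_amp <- numeric(0)
  klen <- length(kern)
  gain <- function(ev, frames) {
    if (!length(frames)) return(0)
    off <- frames - ev + 1L
    ok <- off >= 1L & off <= klen
    if (!any(ok)) return(0)
    sum(kern[off[ok]]) / length(frames)
  }
  for (p in plan) {
    if (is.na(p$idx) || !length(p$win)) next
    g <- gain(p$idx, p$win) - gain(p$idx, p$base)
    if (g < 0.05) next
    keep <- hist_idx > min(c(p$base, p$win)) - klen
    hist_idx <- hist_idx[keep]; hist_amp <- hist_amp[keep]
    carry <- if (length(hist_idx))
      sum(hist_amp * vapply(hist_idx, function(h)
        gain(h, p$win) - gain(h, p$base), numeric(1))) else 0
    a <- (rnorm(1, p$mu, p$sd) - carry) / g
    imp[p$idx] <- imp[p$idx] + a
    hist_idx <- c(hist_idx, p$idx); hist_amp <- c(hist_amp, a)
  }
  imp
}

# Population generator ------------------------------------------------------

#' Simulate a two-photon fluorescence session with known selectivity
#'
#' Builds a frames x ROIs raw-fluorescence matrix for one imaging session.
#' Each ROI emits calcium transients at the four behavioral epochs (sound
#' onset, late delay, response, lick); per-epoch event amplitudes are
#' Gaussian with a choice-dependent mean separation chosen so that the
#' analytic AUC of the generating amplitude distributions equals the
#' per-ROI, per-epoch target.  Amplitude impulses are convolved with a
#' double-exponential indicator kernel, a multiplicative slow drift is
#' applied, and Gaussian sensor noise is added on top of a positive
#' baseline.  Selectivity is injected on event amplitudes, not on dF/F, so
#' the preprocessing stages are genuinely exercised downstream.
#'
#' Because the indicator kernel is slow, a transient evoked in one epoch
#' bleeds into the windows of later epochs.  The generator compensates
#' for this: per trial it computes the exact kernel gain of every event
#' on every epoch window and solves for the impulse amplitude that
#' realizes the target epoch-window response given the carryover from
#' earlier events.  The ground-truth targets therefore apply to the
#' epoch-window responses the downstream pipeline actually measures, up
#' to sensor noise and drift.
#'
#' @param trials Trial table ([sim_behavior()]); scored trials drive events.
#' @param n_rois Number of ROIs.
#' @param frame_rate Imaging rate (Hz), default 30.
#' @param kernel List `{tau_rise, tau_decay}` in seconds.
#' @param epoch_auc Target AUC per epoch: a single number, a length-4
#'   vector named by epoch (`sound, delay, response, lick`), or an
#'   `n_rois` x 4 matrix.  0.5 means no choice selectivity.
#' @param amp_base Mean event amplitude (fluorescence units).
#' @param amp_sd Trial-to-trial amplitude s.d. (sets the AUC scale).
#' @param noise_sd Additive Gaussian sensor noise s.d.
#' @param drift_amp Relative amplitude of the multiplicative slow drift.
#' @param drift_period_s Period of the slow drift (s).
#' @param baseline_f Baseline fluorescence level (a.u.), strictly positive.
#' @param contra_choice Which lick direction is contralateral to the imaged
#'   hemisphere (`"right"` for left-hemisphere imaging).
#' @param seed Optional integer seed.
#' @return An object of class `fluor_matrix`: list with `f` (frames x ROIs),
#'   `frame_rate`, `events`, `trials`, `roi_labels`, `contra_choice`, and
#'   `ground_truth` (per-ROI, per-epoch target AUC).
#' @export
sim_population <- function(trials, n_rois = 40, frame_rate = 30,
                           kernel = list(tau_rise = 0.2, tau_decay = 1.5),
                           epoch_auc = 0.5,
                           amp_base = 3, amp_sd = 1,
                           noise_sd = 0.2, drift_amp = 0.05,
                           drift_period_s = 120,
                           baseline_f = 100,
                           contra_choice = "right",
                           seed = NULL) {
  if (n_rois < 1L) stop("n_rois must be >= 1")
  epochs <- c("sound", "delay", "response", "lick")
  targets <- epoch_auc
  if (is.matrix(targets)) {
    if (!all(dim(targets) == c(n_rois, 4L)))
      stop("epoch_auc matrix must be n_rois x 4")
  } else {
    if (length(targets) == 1L) targets <- rep(targets, 4L)
    if (length(targets) != 4L) stop("epoch_auc must have length 1 or 4")
    targets <- matrix(targets, n_rois, 4L, byrow = TRUE)
  }
  colnames(targets) <- epochs
  if (any(targets < 0 | targets > 1)) stop("target AUC must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)

  ev <- session_events(trials)
  n_frames <- ceiling(attr(ev, "duration") * frame_rate) + 1L
  kern <- calcium_kernel(frame_rate, kernel$tau_rise, kernel$tau_decay)

  # event times per trial per epoch (seconds); NA where undefined
  go <- ev$go_cue; lick <- ev$first_lick
  ep_times <- cbind(
    sound = ev$sound_on,
    delay = go - 0.25,                      # centre of the final 500 ms
    response = ifelse(is.na(lick), NA, (go + lick) / 2),
    lick = ifelse(is.na(lick), NA, lick + 0.1))
  contra <- trials$choice == contra_choice
  scored <- trials$outcome %in% c("correct", "error")

  # per-trial epoch windows and pre-sound baseline (frame indices),
  # matching the downstream epoch extraction
  skeleton <- list()
  for (i in seq_len(nrow(trials))) {
    if (!scored[i] || is.na(lick[i])) next
    base <- frames_in(frame_rate, n_frames, ev$sound_on[i] - 0.5,
                      ev$sound_on[i])
    wins <- list(
      sound = frames_in(frame_rate, n_frames, ev$sound_on[i],
                        ev$sound_on[i] + 0.5),
      delay = frames_in(frame_rate, n_frames, go[i] - 0.5, go[i]),
      response = frames_in(frame_rate, n_frames, go[i], lick[i]),
      lick = frames_in(frame_rate, n_frames, lick[i], lick[i] + 1))
    for (e in seq_along(epochs)) {
      idx <- round(ep_times[i, e] * frame_rate) + 1L
      if (is.na(idx) || idx < 1L || idx > n_frames) next
      skeleton[[length(skeleton) + 1L]] <-
        list(idx = idx, win = wins[[e]], base = base, trial = i, epoch = e)
    }
  }

  f <- matrix(0, n_frames, n_rois)
  for (r in seq_len(n_rois)) {
    plan <- lapply(skeleton, function(s) {
      sep <- auc_to_separation(targets[r, s$epoch], amp_sd)
      s$mu <- amp_base + (if (contra[s$trial]) sep / 2 else -sep / 2)
      s$sd <- amp_sd
      s
    })
    imp <- compensated_impulses(n_frames, kern, plan)
    f[, r] <- stats::convolve(imp, rev(kern), type = "open")[seq_len(n_frames)]
  }

  t_axis <- (seq_len(n_frames) - 1) / frame_rate
  phase <- runif(n_rois, 0, 2 * pi)
  for (r in seq_len(n_rois)) {
    drift <- 1 + drift_amp * sin(2 * pi * t_axis / drift_period_s + phase[r])
    f[, r] <- pmax((baseline_f + f[, r]) * drift +
                     rnorm(n_frames, 0, noise_sd), 1e-6)
  }

  structure(list(
    f = f, frame_rate = frame_rate, events = ev, trials = trials,
    roi_labels = sprintf("roi%03d", seq_len(n_rois)),
    contra_choice = contra_choice,
    ground_truth = targets), class = "fluor_matrix")
}

#' @exportS3Method base::print
print.fluor_matrix <- function(x, ...) {
  cat(sprintf("<fluor_matrix> %d frames x %d ROIs at %g Hz, %d trials\n",
              nrow(x$f), ncol(x$f), x$frame_rate, nrow(x$trials)))
  invisible(x)
}
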