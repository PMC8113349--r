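# Dual-channel photometry generator ---------------------------------------

#' Simulate a dual-channel fiber photometry session
#'
#' Emulates interleaved 470-nm (calcium-sensitive) and 410-nm
#' (isosbestic/auto-fluorescence) recordings at 20 Hz per channel.  A
#' shared motion-artifact trace (smooth AR(1) process) is injected into
#' both channels with channel-specific gains; choice-selective calcium
#' transients are injected into the 470 channel only, at the sound onset
#' (early epoch) and 1 s after delay onset (late epoch), with Gaussian
#' amplitude separations chosen from the target AUCs.  Slow multiplicative
#' drift and sensor noise are added to both channels.
#'
#' @param trials Trial table ([sim_behavior()]).
#' @param early_auc,late_auc Target choice AUC of the generating amplitude
#'   distributions in the early (sound) and late (delay) epochs.
#' @param artifact List `{amplitude, timescale}`: s.d. (in baseline units)
#'   and autocorrelation timescale (s) of the shared motion artifact.
#' @param artifact_gain_410 Gain of the artifact in the 410 channel
#'   relative to the 470 channel.
#' @param amp_base,amp_sd Event amplitude mean and s.d. (a.u.).
#' @param noise_sd Per-channel sensor noise s.d.
#' @param drift_amp,drift_period_s Multiplicative slow drift parameters.
#' @param baseline_f Baseline fluorescence of both channels (a.u.).
#' @param frame_rate Effective per-channel rate (Hz), default 20.
#' @param kernel Indicator kernel time constants, as in [sim_population()].
#' @param side Recording hemisphere (`"left"` or `"right"`).
#' @param cell_type `"excitatory"` or `"inhibitory"` label.
#' @param seed Optional integer seed.
#' @return An object of class `photometry_session`: list with `f470`,
#'   `f410`, `frame_rate`, `events`, `trials`, `side`, `cell_type`,
#'   `contra_choice`, and `ground_truth` (targets plus the injected
#'   artifact trace).
#' @export
sim_photometry <- function(trials, early_auc = 0.7, late_auc = 0.7,
                           artifact = list(amplitude = 2, timescale = 0.5),
                           artifact_gain_410 = 0.8,
                           amp_base = 4, amp_sd = 1,
                           noise_sd = 0.2,
                           drift_amp = 0.05, drift_period_s = 200,
                           baseline_f = 100, frame_rate = 20,
                           kernel = list(tau_rise = 0.2, tau_decay = 1.5),
                           side = "left", cell_type = "excitatory",
                           seed = NULL) {
  if (any(c(early_auc, late_auc) < 0 | c(early_auc, late_auc) > 1))
    stop("target AUC must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)

  ev <- session_events(trials)
  n_frames <- ceiling(attr(ev, "duration") * frame_rate) + 1L
  kern <- calcium_kernel(frame_rate, kernel$tau_rise, kernel$tau_decay)
  contra_choice <- if (identical(side, "left")) "right" else "left"
  contra <- trials$choice == contra_choice
  scored <- trials$outcome %in% c("correct", "error")

  # compensated injection: early (sound) and late (1-1.5 s into the
  # delay) epochs, with late-event amplitudes solved so the measured
  # late-window response hits its target despite the early event's tail
  delay_onset <- ev$sound_on + 0.5
  plan <- list()
  for (i in seq_len(nrow(trials))) {
    if (!scored[i]) next
    base <- frames_in(frame_rate, n_frames, ev$sound_on[i] - 0.5,
                      ev$sound_on[i])
    sep_e <- auc_to_separation(early_auc, amp_sd)
    sep_l <- auc_to_separation(late_auc, amp_sd)
    sgn <- if (contra[i]) 0.5 else -0.5
    plan[[length(plan) + 1L]] <- list(
      idx = round(ev$sound_on[i] * frame_rate) + 1L,
      win = frames_in(frame_rate, n_frames, ev$sound_on[i],
                      ev$sound_on[i] + 0.5),
      base = base, mu = amp_base + sgn * sep_e, sd = amp_sd)
    if (trials$delay[i] >= 1.0) {
      t1 <- min(delay_onset[i] + 1.5, ev$go_cue[i])
      plan[[length(plan) + 1L]] <- list(
        idx = round((delay_onset[i] + 0.75) * frame_rate) + 1L,
        win = frames_in(frame_rate, n_frames, delay_onset[i] + 1.0, t1),
        base = base, mu = amp_base + sgn * sep_l, sd = amp_sd)
    }
  }
  imp <- compensated_impulses(n_frames, kern, plan)
  signal <- stats::convolve(imp, rev(kern), type = "open")[seq_len(n_frames)]

  # shared motion artifact: AR(1) with the requested s.d. and timescale
  phi <- exp(-1 / (artifact$timescale * frame_rate))
  innov_sd <- artifact$amplitude * sqrt(1 - phi^2)
  art <- as.numeric(stats::filter(rnorm(n_frames, 0, innov_sd), phi,
                                  method = "recursive"))

  t_axis <- (seq_len(n_frames) - 1) / frame_rate
  drift470 <- 1 + drift_amp * sin(2 * pi * t_axis / drift_period_s)
  drift410 <- 1 + drift_amp * sin(2 * pi * t_axis / drift_period_s + pi / 3)
  f470 <- pmax(baseline_f * drift470 + signal + art +
                 rnorm(n_frames, 0, noise_sd), 1e-6)
  f410 <- pmax(baseline_f * drift410 + artifact_gain_410 * art +
                 rnorm(n_frames, 0, noise_sd), 1e-6)

  structure(list(
    f470 = f470, f410 = f410, frame_rate = frame_rate,
    events = ev, trials = trials, side = side, cell_type = cell_type,
    contra_choice = contra_choice,
    ground_truth = list(early_auc = early_auc, late_auc = late_auc,
                        artifact = art)),
    class = "photometry_session")
}

#' @exportS3Method base::print
print.photometry_session <- function(x, ...) {
  cat(sprintf("<photometry_session> %d frames at %g Hz, %s side, %s, %d trials\n",
              length(x$f470), x$frame_rate, x$side, x$cell_type,
              nrow(x$trials)))
  invisible(x)
}
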