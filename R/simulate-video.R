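# Video keypoint generator --------------------------------------------------

#' Simulate keypoint tracks for a behavioral video session
#'
#' Emulates markerless tracking of the tongue and nose at 24 Hz on the
#' session clock of a trial table.  The tongue's horizontal coordinate
#' diverges between trials with ipsi- versus contralateral licks only
#' after `divergence_onset_s` seconds from delay onset (ramping over
#' 0.2 s, held until just after the first lick); before that, and on the
#' nose, the tracks are baseline plus noise.  A fraction of frames are
#' tracking dropouts with likelihood below 0.1.
#'
#' @param trials Trial table ([sim_behavior()]).
#' @param divergence_onset_s Movement divergence onset relative to delay
#'   onset (s); `Inf` for no divergence.
#' @param effect_px Horizontal tongue displacement (pixels) toward the
#'   lick side at full divergence.
#' @param likelihood_dropout_rate Fraction of frames with tracking
#'   likelihood drawn below 0.1.
#' @param noise_px Frame-to-frame tracking noise s.d. (pixels).
#' @param frame_rate Video rate (Hz), default 24.
#' @param imaged_side Hemisphere the recording is ipsilateral to
#'   (`"left"` or `"right"`); ipsi licks push the tongue positive.
#' @param seed Optional integer seed.
#' @return An object of class `video_tracks`: list with `x`, `y`,
#'   `likelihood` (frames x items, items = tongue, nose), `frame_rate`,
#'   `events`, `trials`, `imaged_side`, `divergence_onset_s`.
#' @export
sim_video <- function(trials, divergence_onset_s = 1.0,
                      effect_px = 8, likelihood_dropout_rate = 0.05,
                      noise_px = 1, frame_rate = 24,
                      imaged_side = "left", seed = NULL) {
  if (likelihood_dropout_rate < 0 || likelihood_dropout_rate > 1)
    stop("likelihood_dropout_rate must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  ev <- session_events(trials)
  n_frames <- ceiling(attr(ev, "duration") * frame_rate) + 1L
  t_axis <- (seq_len(n_frames) - 1) / frame_rate

  items <- c("tongue", "nose")
  x <- matrix(rnorm(n_frames * 2, 0, noise_px), n_frames, 2,
              dimnames = list(NULL, items))
  y <- matrix(rnorm(n_frames * 2, 0, noise_px), n_frames, 2,
              dimnames = list(NULL, items))
  x[, "tongue"] <- x[, "tongue"] + 100; y[, "tongue"] <- y[, "tongue"] + 80
  x[, "nose"] <- x[, "nose"] + 100;    y[, "nose"] <- y[, "nose"] + 40

  ipsi_choice <- imaged_side   # lick toward the imaged side = ipsilateral
  delay_on <- ev$sound_on + 0.5
  if (is.finite(divergence_onset_s)) {
    for (i in seq_len(nrow(trials))) {
      ch <- trials$choice[i]
      if (!ch %in% c("left", "right")) next
      t0 <- delay_on[i] + divergence_onset_s
      t1 <- if (!is.na(ev$first_lick[i])) ev$first_lick[i] + 0.5 else
        ev$go_cue[i] + 1
      if (t1 <= t0) next
      ramp <- pmin(pmax((t_axis - t0) / 0.2, 0), 1) *
        (t_axis >= t0 & t_axis <= t1)
      sgn <- if (ch == ipsi_choice) 1 else -1
      x[, "tongue"] <- x[, "tongue"] + sgn * effect_px * ramp
    }
  }

  likelihood <- matrix(runif(n_frames * 2, 0.3, 1), n_frames, 2,
                       dimnames = list(NULL, items))
  drop <- matrix(runif(n_frames * 2) < likelihood_dropout_rate, n_frames, 2)
  likelihood[drop] <- runif(sum(drop), 0, 0.1)

  structure(list(x = x, y = y, likelihood = likelihood,
                 frame_rate = frame_rate, events = ev, trials = trials,
                 imaged_side = imaged_side,
                 divergence_onset_s = divergence_onset_s),
            class = "video_tracks")
}

#' @exportS3Method base::print
print.video_tracks <- function(x, ...) {
  cat(sprintf("<video_tracks> %d frames x %d items at %g Hz, %d trials\n",
              nrow(x$x), ncol(x$x), x$frame_rate, nrow(x$trials)))
  invisible(x)
}
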