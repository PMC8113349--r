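# Slow-drift correction -----------------------------------------------------

#' Correct slow-timescale fluorescence drift
#'
#' Subtracts a centered rolling percentile from each trace: for every
#' time point, the distribution of fluorescence values over
#' `window_frames` surrounding frames is taken and its `percentile`-th
#' value removed.  Defaults (400 frames, 8th percentile) match a ~14-s
#' window at 30 Hz two-photon imaging; photometry uses 1000 frames and
#' the 5th percentile.  Edge windows are truncated, not reflected, so no
#' values are fabricated; the output has the same length as the input.
#'
#' @param trace Numeric vector or frames x ROIs matrix.
#' @param window_frames Window width in frames (>= 1).
#' @param percentile Percentile to subtract, in (0, 100).
#' @return Corrected trace of the same shape.
#' @export
correct_slow_drift <- function(trace, window_frames = 400, percentile = 8) {
  if (window_frames < 1) stop("window_frames must be >= 1")
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must be in (0, 100)")
  if (is.matrix(trace)) {
    if (nrow(trace) < 2L) stop("trace must have at least 2 frames")
    return(apply(trace, 2, function(col)
      col - rolling_percentile_cpp(col, as.integer(window_frames),
                                   percentile / 100)))
  }
  if (length(trace) < 2L) stop("trace must have at least 2 frames")
  trace - rolling_percentile_cpp(trace, as.integer(window_frames),
                                 percentile / 100)
}

# Histogram mode -------------------------------------------------------------

#' Histogram mode of a continuous trace
#'
#' Mode estimated as the mean of the values inside the fullest histogram
#' bin (Freedman-Diaconis bin width); degenerate spreads fall back to
#' the most frequent value.  The within-bin mean (rather than the bin
#' center) keeps the estimate inside the support of the data and exactly
#' equivariant under rescaling.
#'
#' @param x Numeric vector.
#' @return Scalar mode estimate.
#' @export
histogram_mode <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite values")
  bw <- 2 * stats::IQR(x) / length(x)^(1 / 3)
  if (bw <= 0 || !is.finite(bw)) {
    tab <- table(x)
    return(as.numeric(names(tab)[which.max(tab)]))
  }
  breaks <- seq(min(x), max(x) + bw, by = bw)
  h <- findInterval(x, breaks, rightmost.closed = TRUE)
  best <- as.integer(names(which.max(table(h))))
  mean(x[h == best])
}

# dF/F ------------------------------------------------------------------------

#' Compute dF/F from a drift-corrected trace
#'
#' `(F - F0) / F0` elementwise, where `F0` is the histogram mode of the
#' trace over the entire session (per ROI for matrices).  Invariant under
#' multiplicative rescaling of the raw trace.  Per-trial pre-sound
#' baseline subtraction is applied downstream in [epoch_average()], where
#' the trial events are known.
#'
#' @param trace Drift-corrected numeric vector or frames x ROIs matrix.
#' @param f0 Optional fixed baseline(s) overriding the mode estimate.
#' @return dF/F of the same shape.
#' @export
compute_dff <- function(trace, f0 = NULL) {
  one <- function(v, f0v, label) {
    if (is.null(f0v)) f0v <- histogram_mode(v)
    if (!is.finite(f0v) || f0v <= 0)
      stop("nonpositive baseline F0 for ", label)
    (v - f0v) / f0v
  }
  if (is.matrix(trace)) {
    labels <- colnames(trace)
    if (is.null(labels)) labels <- sprintf("ROI %d", seq_len(ncol(trace)))
    out <- vapply(seq_len(ncol(trace)), function(j)
      one(trace[, j], if (is.null(f0)) NULL else f0[j], labels[j]),
      numeric(nrow(trace)))
    dimnames(out) <- dimnames(trace)
    return(out)
  }
  one(trace, f0, "trace")
}

# Epoch-structured responses ---------------------------------------------------

frames_in <- function(frame_rate, n_frames, t0, t1) {
  # frames whose timestamps fall in [t0, t1)
  i0 <- max(1L, ceiling(t0 * frame_rate) + 1L)
  i1 <- min(n_frames, ceiling(t1 * frame_rate))
  if (i1 < i0) integer(0) else i0:i1
}

#' Extract trial- and epoch-averaged dF/F responses
#'
#' Converts a fluorescence session into a trials x ROIs x epochs response
#' array.  Per trial, the mean pre-sound dF/F is first subtracted from
#' the trial's activity; epoch means are then taken over: the 0.5-s
#' stimulus window (`sound`), exactly the final 500 ms before the go cue
#' (`delay`), the go cue to the first lick (`response`), and a
#' configurable window after the first lick (`lick`).  Only scored
#' trials (correct/error) enter; trials with missing events or an empty
#' response window are excluded and counted.
#'
#' @param fluor A `fluor_matrix` from [sim_population()] (or a compatible
#'   list with `f`, `frame_rate`, `events`, `trials`).
#' @param dff Optional precomputed dF/F matrix; by default the raw trace
#'   is drift-corrected ([correct_slow_drift()]) and passed through
#'   [compute_dff()].
#' @param window_frames,percentile Drift-correction parameters.
#' @param lick_window_s Length of the post-first-lick window (s).
#' @param pre_sound_s Pre-sound baseline window (s).
#' @param short_delay For trials with delay < 0.5 s the 500-ms delay
#'   window necessarily overlaps the stimulus tail: `"keep"` (default)
#'   retains them flagged, `"exclude"` drops them from the delay epoch
#'   (set to `NA`).
#' @return An object of class `epoch_response`: list with `dff_epoch`
#'   (trials x ROIs x 4 array), `trials` (metadata of the included
#'   trials), `epochs`, `contra_choice`, `n_excluded`, `short_delay_flag`.
#' @export
epoch_average <- function(fluor, dff = NULL, window_frames = 400,
                          percentile = 8, lick_window_s = 1,
                          pre_sound_s = 0.5,
                          short_delay = c("keep", "exclude")) {
  short_delay <- match.arg(short_delay)
  if (is.null(dff))
    dff <- compute_dff(correct_slow_drift(fluor$f, window_frames, percentile))
  fr <- fluor$frame_rate
  n_frames <- nrow(dff)
  ev <- fluor$events
  trials <- fluor$trials
  epochs <- c("sound", "delay", "response", "lick")

  ok <- trials$outcome %in% c("correct", "error") &
    !is.na(ev$first_lick) & (ev$first_lick > ev$go_cue)
  n_excluded <- sum(trials$outcome %in% c("correct", "error")) - sum(ok)
  if (n_excluded > 0)
    message(n_excluded, " scored trial(s) excluded (missing events or ",
            "zero-length response window)")
  idx <- which(ok)
  n_use <- length(idx)
  out <- array(NA_real_, dim = c(n_use, ncol(dff), 4L),
               dimnames = list(NULL, colnames(dff), epochs))
  short_flag <- logical(n_use)
  for (k in seq_len(n_use)) {
    i <- idx[k]
    base_fr <- frames_in(fr, n_frames, ev$sound_on[i] - pre_sound_s,
                         ev$sound_on[i])
    base <- if (length(base_fr)) colMeans(dff[base_fr, , drop = FALSE]) else 0
    win <- list(sound = c(ev$sound_on[i], ev$sound_on[i] + 0.5),
                delay = c(ev$go_cue[i] - 0.5, ev$go_cue[i]),
                response = c(ev$go_cue[i], ev$first_lick[i]),
                lick = c(ev$first_lick[i], ev$first_lick[i] + lick_window_s))
    short_flag[k] <- trials$delay[i] < 0.5
    for (e in seq_along(epochs)) {
      if (epochs[e] == "delay" && short_flag[k] && short_delay == "exclude")
        next
      f_idx <- frames_in(fr, n_frames, win[[e]][1], win[[e]][2])
      if (length(f_idx))
        out[k, , e] <- colMeans(dff[f_idx, , drop = FALSE]) - base
    }
  }
  structure(list(dff_epoch = out, trials = trials[idx, , drop = FALSE],
                 epochs = epochs,
                 contra_choice = fluor$contra_choice %||% "right",
                 n_excluded = n_excluded,
                 short_delay_flag = short_flag),
            class = "epoch_response")
}

#' @exportS3Method base::print
print.epoch_response <- function(x, ...) {
  d <- dim(x$dff_epoch)
  cat(sprintf("<epoch_response> %d trials x %d ROIs x %d epochs (%s)\n",
              d[1], d[2], d[3], paste(x$epochs, collapse = ", ")))
  invisible(x)
}
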