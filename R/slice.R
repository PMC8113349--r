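# Evoked-response detection in voltage sweeps ---------------------------------

# baseline mean/sd over the 1 s before stimulation onset
sweep_baseline <- function(v, stim_time, sample_rate, baseline_s = 1) {
  i1 <- round(stim_time * sample_rate)
  i0 <- i1 - round(baseline_s * sample_rate) + 1L
  if (i0 < 1L) stop("baseline shorter than ", baseline_s, " s before stimulation")
  list(mean = mean(v[i0:i1]), sd = sd(v[i0:i1]))
}

# is there a significant positive transient within `window_s` after `stim`?
pulse_significant <- function(v, stim, base, sample_rate, window_s = 0.05,
                              threshold_sd = 3) {
  i0 <- round(stim * sample_rate) + 1L
  i1 <- min(round((stim + window_s) * sample_rate), length(v))
  any(v[i0:i1] - base$mean > threshold_sd * base$sd)
}

#' Classify a cell as responsive to optogenetic terminal stimulation
#'
#' The train sweeps (ten 10-Hz pulses) are averaged across repeats; a
#' pulse counts as a significant transient when the trial-averaged
#' voltage within 50 ms after light onset exceeds the baseline mean by
#' more than 3 s.d. of the baseline (computed over the 1 s before the
#' first pulse, on the averaged trace).  The cell is responsive when the
#' fraction of significant transients is strictly greater than 40%.
#' Only depolarizing deflections count.
#'
#' @param cell A `slice_cell` (element of [sim_slice()]'s `cells`).
#' @param threshold_sd Detection threshold in baseline s.d. (default 3).
#' @param window_s Post-pulse detection window (s), default 0.05.
#' @param responsive_frac Responsiveness criterion (strict >), default 0.4.
#' @return List with `responsive`, `frac_significant`, `per_pulse`
#'   logical vector.
#' @export
classify_responsive <- function(cell, threshold_sd = 3, window_s = 0.05,
                                responsive_frac = 0.4) {
  stims <- cell$stim_times$train
  if (length(stims) < 1L) stop("no train sweeps")
  avg <- colMeans(cell$train)
  base <- sweep_baseline(avg, stims[1], cell$sample_rate)
  per_pulse <- vapply(stims, function(st)
    pulse_significant(avg, st, base, cell$sample_rate, window_s,
                      threshold_sd), logical(1))
  frac <- mean(per_pulse)
  list(responsive = frac > responsive_frac, frac_significant = frac,
       per_pulse = per_pulse)
}

#' Characterize reliability, latency and amplitude of evoked responses
#'
#' Reliability is the fraction of single-pulse sweeps with a significant
#' transient (each sweep tested against its own 1-s baseline).  Latency
#' and amplitude are computed on the mean trace over all single-pulse
#' sweeps: latency is the time from light onset to the first sample
#' whose voltage change exceeds 3 s.d. of the mean-trace baseline;
#' amplitude is the maximum voltage change above baseline within 50 ms
#' after light onset.
#'
#' @param cell A `slice_cell` with at least 5 single-pulse sweeps.
#' @param threshold_sd,window_s As in [classify_responsive()].
#' @return List with `reliability`, `latency_ms` (`NA` and flagged when
#'   the mean trace never crosses threshold), `amplitude_mv`,
#'   `per_sweep` logical vector.
#' @export
characterize_response <- function(cell, threshold_sd = 3, window_s = 0.05) {
  stim <- cell$stim_times$single[1]
  sw <- cell$single
  if (nrow(sw) < 5L) stop("need at least 5 single-pulse sweeps")
  sr <- cell$sample_rate
  per_sweep <- vapply(seq_len(nrow(sw)), function(s) {
    base <- sweep_baseline(sw[s, ], stim, sr)
    pulse_significant(sw[s, ], stim, base, sr, window_s, threshold_sd)
  }, logical(1))
  avg <- colMeans(sw)
  base <- sweep_baseline(avg, stim, sr)
  i0 <- round(stim * sr) + 1L
  i1 <- min(round((stim + window_s) * sr), length(avg))
  dv <- avg[i0:i1] - base$mean
  cross <- which(dv > threshold_sd * base$sd)
  latency_ms <- if (length(cross)) (cross[1] - 1) / sr * 1000 else NA_real_
  list(reliability = mean(per_sweep),
       latency_ms = latency_ms,
       amplitude_mv = max(dv),
       latency_defined = length(cross) > 0L,
       per_sweep = per_sweep)
}

#' Summarize every cell of a slice sweep set
#'
#' @param sweeps A `slice_sweep_set`.
#' @param ... Passed to [classify_responsive()] and
#'   [characterize_response()].
#' @return Data frame with one row per cell: `cell_id`, `cell_type`,
#'   `responsive`, `frac_significant`, `reliability`, `latency_ms`,
#'   `amplitude_mv`.  Reliability/latency/amplitude are reported for
#'   responsive cells (NA otherwise, matching the single-pulse protocol
#'   being run on responsive cells).
#' @export
slice_cell_table <- function(sweeps, ...) {
  do.call(rbind, lapply(sweeps$cells, function(cell) {
    cls <- classify_responsive(cell, ...)
    if (cls$responsive) {
      ch <- characterize_response(cell, ...)
      data.frame(cell_id = cell$cell_id, cell_type = cell$cell_type,
                 responsive = TRUE, frac_significant = cls$frac_significant,
                 reliability = ch$reliability, latency_ms = ch$latency_ms,
                 amplitude_mv = ch$amplitude_mv, stringsAsFactors = FALSE)
    } else {
      data.frame(cell_id = cell$cell_id, cell_type = cell$cell_type,
                 responsive = FALSE, frac_significant = cls$frac_significant,
                 reliability = NA_real_, latency_ms = NA_real_,
                 amplitude_mv = NA_real_, stringsAsFactors = FALSE)
    }
  }))
}

#' Compare evoked responses between two cell groups
#'
#' Chi-squared test (two-sided, uncorrected) on the responsive
#' proportions, and two-sided 5000-shuffle permutation tests on latency,
#' reliability and amplitude among responsive cells.
#'
#' @param cells_a,cells_b Data frames as returned by [slice_cell_table()]
#'   (or the rows for each cell type).
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return List with `chi2_responsive` and a `dd_test` per metric;
#'   metrics missing for all cells are skipped with a warning.
#' @export
compare_groups <- function(cells_a, cells_b, n_perm = 5000, seed = NULL) {
  if (!nrow(cells_a) || !nrow(cells_b)) stop("both groups must be non-empty")
  counts <- rbind(a = c(sum(cells_a$responsive), sum(!cells_a$responsive)),
                  b = c(sum(cells_b$responsive), sum(!cells_b$responsive)))
  colnames(counts) <- c("responsive", "nonresponsive")
  chi2 <- tryCatch(chi_squared_2x2(counts), error = function(e) {
    warning("chi-squared undefined (zero margin): ", conditionMessage(e))
    NULL
  })
  out <- list(chi2_responsive = chi2, counts = counts)
  for (m in c("latency_ms", "reliability", "amplitude_mv")) {
    a <- cells_a[[m]][is.finite(cells_a[[m]])]
    b <- cells_b[[m]][is.finite(cells_b[[m]])]
    if (!length(a) || !length(b)) {
      warning("metric ", m, " missing for a whole group; test skipped")
      next
    }
    tst <- permutation_p(a, b, n = n_perm, seed = seed, exact = FALSE)
    tst$method <- sprintf("permutation test on %s", m)
    out[[m]] <- tst
  }
  out
}
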