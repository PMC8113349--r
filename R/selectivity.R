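# ROC / AUC ------------------------------------------------------------------

#' Area under the ROC curve for two response groups
#'
#' Rank-based AUC: `P(a > b) + 0.5 P(a = b)`, equal to the Mann-Whitney
#' rank-sum statistic divided by `n_a * n_b`.  Ties receive half credit.
#'
#' @param a,b Numeric response vectors for the two trial groups; with the
#'   convention used throughout, `a` holds contralateral-choice (or
#'   high-rate) trials so 1 means contralateral (high) preference.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  r <- rank(c(a, b))
  na <- length(a)
  (sum(r[seq_len(na)]) - na * (na + 1) / 2) / (na * length(b))
}

# vectorized permutation null for one response vector:
# AUC of `n_shuffles` random relabelings, reusing the ranks
auc_perm_null <- function(x, n_a, n_shuffles) {
  r <- rank(x)
  n <- length(x)
  denom <- n_a * (n - n_a)
  vapply(seq_len(n_shuffles), function(i)
    (sum(r[sample.int(n, n_a)]) - n_a * (n_a + 1) / 2) / denom,
    numeric(1))
}

# labels for a selectivity mode, oriented so group a -> AUC of 1
selectivity_groups <- function(trials, mode, contra_choice) {
  if (mode == "choice") {
    a <- trials$choice == contra_choice
    b <- trials$choice == setdiff(c("left", "right"), contra_choice)
  } else {
    a <- trials$category == "high"
    b <- trials$category == "low"
  }
  list(a = a, b = b)
}

#' Per-ROI selectivity with a trial-shuffle permutation null
#'
#' For every ROI and behavioral epoch, computes the choice (or sensory)
#' AUC across trials — correct and error trials included — oriented so 1
#' means contralateral (high-rate) preference, then shuffles the trial
#' labels `n_shuffles` times to build a null distribution.  An ROI is
#' labeled selective when its AUC falls outside the null confidence
#' interval (default 99%: the 0.5th-99.5th percentiles of the shuffled
#' AUCs) in any epoch.  A per-epoch two-sided empirical p-value is also
#' returned (the display threshold p < 0.05 can be applied to it).
#'
#' @param er An `epoch_response` from [epoch_average()].
#' @param mode `"choice"` or `"sensory"`.
#' @param n_shuffles Number of label shuffles (default 1000; fewer than
#'   100 triggers a warning).
#' @param ci Null confidence level (default 0.99).
#' @param seed Session seed; each ROI uses `seed + roi index` so results
#'   are reproducible under parallel or partial execution.
#' @return An object of class `selectivity_result`: data frame `table`
#'   (roi, epoch, auc, null_lo, null_hi, p, sig) plus `selective`
#'   (per-ROI logical), `mode`, `n_shuffles`, `ci`.  ROIs with fewer than
#'   2 trials in either class are skipped.
#' @export
permutation_significance <- function(er, mode = c("choice", "sensory"),
                                     n_shuffles = 1000, ci = 0.99,
                                     seed = NULL) {
  mode <- match.arg(mode)
  if (n_shuffles < 100) warning("fewer than 100 shuffles: null CI is coarse")
  g <- selectivity_groups(er$trials, mode, er$contra_choice)
  if (sum(g$a) < 2L || sum(g$b) < 2L)
    stop("need at least 2 trials per class")
  n_rois <- dim(er$dff_epoch)[2]
  epochs <- er$epochs
  lo_q <- (1 - ci) / 2
  rows <- vector("list", n_rois * length(epochs))
  selective <- logical(n_rois)
  roi_names <- dimnames(er$dff_epoch)[[2]]
  if (is.null(roi_names)) roi_names <- sprintf("roi%03d", seq_len(n_rois))
  k <- 0L
  for (r in seq_len(n_rois)) {
    if (!is.null(seed)) set.seed(seed + r)
    for (e in seq_along(epochs)) {
      x <- er$dff_epoch[, r, e]
      ok <- is.finite(x) & (g$a | g$b)
      aa <- x[ok & g$a]; bb <- x[ok & g$b]
      if (length(aa) < 2L || length(bb) < 2L) next
      auc <- roc_auc(aa, bb)
      null <- auc_perm_null(c(aa, bb), length(aa), n_shuffles)
      # type-6 quantiles put the bounds at the (B+1)p-th order statistics,
      # which makes the coverage of the null interval exact
      qs <- unname(quantile(null, c(lo_q, 1 - lo_q), type = 6))
      p <- min(1, 2 * min((sum(null >= auc - 1e-12) + 1),
                          (sum(null <= auc + 1e-12) + 1)) / (n_shuffles + 1))
      sig <- auc < qs[1] | auc > qs[2]
      selective[r] <- selective[r] || sig
      k <- k + 1L
      rows[[k]] <- data.frame(roi = roi_names[r], epoch = epochs[e],
                              auc = auc, null_lo = qs[1], null_hi = qs[2],
                              p = p, sig = sig, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows[seq_len(k)])
  structure(list(table = tab, selective = setNames(selective, roi_names),
                 mode = mode, n_shuffles = n_shuffles, ci = ci),
            class = "selectivity_result")
}

#' @exportS3Method base::print
print.selectivity_result <- function(x, ...) {
  cat(sprintf("<selectivity_result> %s mode: %d/%d ROIs selective (%d%% null CI, %d shuffles)\n",
              x$mode, sum(x$selective), length(x$selective),
              round(100 * x$ci), x$n_shuffles))
  invisible(x)
}

#' Wide AUC table (ROI x epoch) from a selectivity result
#' @param sel A `selectivity_result`.
#' @return Numeric matrix, rows = ROIs, columns = epochs.
#' @export
auc_matrix <- function(sel) {
  tab <- sel$table
  epochs <- unique(tab$epoch)
  rois <- unique(tab$roi)
  m <- matrix(NA_real_, length(rois), length(epochs),
              dimnames = list(rois, epochs))
  m[cbind(match(tab$roi, rois), match(tab$epoch, epochs))] <- tab$auc
  m
}

# Epoch-distribution comparison ------------------------------------------------

#' Compare AUC distributions between behavioral epochs
#'
#' For each requested epoch pair, tests the difference in mean AUC across
#' ROIs with a paired permutation test (epoch labels swapped within ROI,
#' `n_shuffles` times, two-sided), and fits a Gaussian (mean, s.d.) to
#' each epoch's AUC histogram for display.
#'
#' @param aucs ROI x epoch AUC matrix (see [auc_matrix()]).
#' @param pairs List of length-2 character vectors of epoch names;
#'   default: consecutive epochs.
#' @param n_shuffles Number of within-ROI label swaps (default 5000).
#' @param seed Optional integer seed.
#' @return List with `tests` (a `dd_test` per pair) and `gaussian_fits`
#'   (per-epoch mean and s.d.).  Fewer than 10 ROIs triggers a low-n
#'   warning.
#' @export
epoch_distribution_compare <- function(aucs, pairs = NULL, n_shuffles = 5000,
                                       seed = NULL) {
  epochs <- colnames(aucs)
  if (length(epochs) < 2L) stop("need at least 2 epochs")
  if (nrow(aucs) < 10L) warning("fewer than 10 ROIs: permutation p is coarse")
  if (is.null(pairs))
    pairs <- lapply(seq_len(length(epochs) - 1L),
                    function(i) epochs[c(i, i + 1L)])
  if (!is.null(seed)) set.seed(seed)
  tests <- lapply(pairs, function(pr) {
    x <- aucs[, pr[1]]; y <- aucs[, pr[2]]
    ok <- is.finite(x) & is.finite(y)
    d <- x[ok] - y[ok]
    obs <- mean(d)
    perm <- replicate(n_shuffles,
                      mean(d * sample(c(-1, 1), length(d), replace = TRUE)))
    p <- min(1, (sum(abs(perm) >= abs(obs) - 1e-12) + 1) / (n_shuffles + 1))
    new_test_result(obs, p,
                    sprintf("paired permutation on mean AUC: %s vs %s",
                            pr[1], pr[2]),
                    "two", n_shuffles,
                    if (is.null(seed)) NA_integer_ else seed)
  })
  names(tests) <- vapply(pairs, paste, "", collapse = "_vs_")
  fits <- data.frame(epoch = epochs,
                     mean = colMeans(aucs, na.rm = TRUE),
                     sd = apply(aucs, 2, sd, na.rm = TRUE),
                     row.names = NULL)
  list(tests = tests, gaussian_fits = fits)
}

# Video movement divergence ------------------------------------------------------

# per-session binned delta-pixel by trial, aligned to delay onset
video_binned_dpixel <- function(tracks, item, coord, bin_frames,
                                likelihood_min, window_s) {
  fr <- tracks$frame_rate
  v <- if (coord == "x") tracks$x[, item] else tracks$y[, item]
  lik_ok <- tracks$likelihood[, item] > likelihood_min
  if (!any(lik_ok)) stop("no frames survive the likelihood filter")
  dpix <- v - mean(v[lik_ok])          # session-mean baseline
  dpix[!lik_ok] <- NA
  ev <- tracks$events
  trials <- tracks$trials
  scored <- trials$outcome %in% c("correct", "error")
  bin_s <- bin_frames / fr
  bin_edges <- seq(window_s[1], window_s[2], by = bin_s)
  n_bins <- length(bin_edges) - 1L
  delay_on <- ev$sound_on + 0.5
  out <- matrix(NA_real_, nrow(trials), n_bins)
  for (i in which(scored)) {
    for (bN in seq_len(n_bins)) {
      idx <- frames_in(fr, length(dpix),
                       delay_on[i] + bin_edges[bN],
                       delay_on[i] + bin_edges[bN + 1L])
      if (length(idx)) out[i, bN] <- mean(dpix[idx], na.rm = TRUE)
    }
  }
  list(dpix = out, centers = (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2,
       ipsi = scored & trials$choice == tracks$imaged_side,
       contra = scored & trials$choice == setdiff(c("left", "right"),
                                                  tracks$imaged_side))
}

#' Earliest time of choice-predictive movement divergence
#'
#' Per session, tracked coordinates are baseline-subtracted against their
#' session mean (after dropping frames whose tracking likelihood is at or
#' below `likelihood_min`) and binned in time (default 2 video frames)
#' relative to delay onset.  Within each session, a per-bin ipsi-vs-contra
#' AUC is computed with a 1000-shuffle 99% null interval.  Across
#' sessions, the ipsi-contra difference in each bin is tested with a
#' bootstrap over sessions, and the earliest bin with p below `alpha`
#' (default 0.01) is reported.
#'
#' @param sessions A list of `video_tracks` objects (at least 2 for the
#'   across-session bootstrap).
#' @param item,coord Tracked item and coordinate (default tongue, x).
#' @param bin_frames Frames per time bin (default 2, ~80 ms at 24 Hz).
#' @param likelihood_min Minimum tracking likelihood (exclusive; default
#'   0.1).  A threshold of 1 filters every frame and is an error.
#' @param window_s Analysis window relative to delay onset (s).
#' @param n_shuffles Shuffles for the per-session AUC null.
#' @param alpha Across-session significance level (default 0.01).
#' @param n_boot Bootstrap resamples across sessions.
#' @param seed Optional integer seed.
#' @return List with `first_sig_s` (earliest significant bin center, `NA`
#'   if none), `time` (bin centers), `p_by_bin`, `diff_by_session`
#'   (sessions x bins), and `per_session_auc` with its null bounds.
#' @export
movement_divergence_time <- function(sessions, item = "tongue", coord = "x",
                                     bin_frames = 2, likelihood_min = 0.1,
                                     window_s = c(-0.5, 2), n_shuffles = 1000,
                                     alpha = 0.01, n_boot = 1000,
                                     seed = NULL) {
  if (inherits(sessions, "video_tracks")) sessions <- list(sessions)
  if (length(sessions) < 2L)
    stop("need at least 2 sessions for the across-session bootstrap")
  if (likelihood_min >= 1) stop("likelihood_min of 1 filters all frames")
  if (!is.null(seed)) set.seed(seed)
  binned <- lapply(sessions, video_binned_dpixel, item = item, coord = coord,
                   bin_frames = bin_frames, likelihood_min = likelihood_min,
                   window_s = window_s)
  centers <- binned[[1]]$centers
  n_bins <- length(centers)

  auc_mat <- matrix(NA_real_, length(sessions), n_bins)
  lo_mat <- auc_mat; hi_mat <- auc_mat
  diff_mat <- auc_mat
  for (s in seq_along(binned)) {
    b <- binned[[s]]
    for (bn in seq_len(n_bins)) {
      a <- b$dpix[b$ipsi, bn]; cc <- b$dpix[b$contra, bn]
      a <- a[is.finite(a)]; cc <- cc[is.finite(cc)]
      if (length(a) < 2L || length(cc) < 2L) next
      auc_mat[s, bn] <- roc_auc(a, cc)
      null <- auc_perm_null(c(a, cc), length(a), n_shuffles)
      lo_mat[s, bn] <- quantile(null, 0.005, type = 6)
      hi_mat[s, bn] <- quantile(null, 0.995, type = 6)
      diff_mat[s, bn] <- mean(a) - mean(cc)
    }
  }
  p_by_bin <- rep(NA_real_, n_bins)
  for (bn in seq_len(n_bins)) {
    d <- diff_mat[, bn]
    d <- d[is.finite(d)]
    if (length(d) >= 2L)
      p_by_bin[bn] <- bootstrap_p(d, n = n_boot)$p_value
  }
  sig <- which(is.finite(p_by_bin) & p_by_bin < alpha & centers >= 0)
  list(first_sig_s = if (length(sig)) centers[min(sig)] else NA_real_,
       time = centers, p_by_bin = p_by_bin,
       diff_by_session = diff_mat,
       per_session_auc = list(auc = auc_mat, null_lo = lo_mat,
                              null_hi = hi_mat))
}
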