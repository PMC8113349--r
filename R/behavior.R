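# Psychometric fitting ------------------------------------------------------

#' Fit a four-parameter psychometric sigmoid
#'
#' Fits `P(lick right) = y0 + a / (1 + exp(-(x - x0)/b))` to the scored
#' trials of a trial table, with `x = log(click rate)`, by bounded
#' weighted least squares on the per-rate choice proportions (weights =
#' trial counts; equivalent to least squares on the per-trial binary
#' responses up to a parameter-free constant).  Five multi-starts guard
#' against local minima; ties are broken by lowest residual sum of
#' squares.  Bounds keep `y0` and `a + y0` within \[0, 1\] and fix the
#' sign of `b` by the stimulus-response mapping (high rates -> right).
#'
#' @param trials Trial table; only trials with outcome correct/error are
#'   used.  A pre-aggregated summary with columns `click_rate`, `p`
#'   (proportion of right licks) and `n` (trial counts) is also accepted.
#' @param level `"pooled"` (one fit), `"animal"` or `"session"` (a list of
#'   fits, one per group).
#' @return For `level = "pooled"`, a `psychometric_fit`: list with
#'   `x0, b, y0, a`, `rss`, `rates` (per-rate empirical proportions and
#'   counts), `converged`, and `flags` (e.g. degenerate boundary fits).
#'   Otherwise a named list of such fits.
#' @export
fit_psychometric <- function(trials, level = c("pooled", "animal", "session")) {
  level <- match.arg(level)
  if (level != "pooled") {
    key <- if (level == "animal") trials$subject_id else trials$session_id
    return(lapply(split(trials, key), fit_psychometric, level = "pooled"))
  }
  if (all(c("p", "n") %in% names(trials)) && !"choice" %in% names(trials)) {
    tab <- trials[order(trials$click_rate), c("click_rate", "p", "n")]
  } else {
    sc <- scored_trials(trials)
    tab <- stats::aggregate(cbind(p = sc$choice == "right") ~ click_rate,
                            data = sc, FUN = mean)
    tab$n <- as.integer(table(factor(sc$click_rate,
                                     levels = sort(unique(sc$click_rate)))))
  }
  if (nrow(tab) < 2L)
    stop("need at least 2 distinct click rates with scored choices")
  x <- log(tab$click_rate); p <- tab$p; w <- tab$n
  if (diff(range(p)) < 1e-10) {
    # one-sided responder: sigmoid collapses to a constant
    return(structure(list(x0 = NA_real_, b = NA_real_, y0 = p[1], a = 0,
                          rss = 0, rates = tab, converged = TRUE,
                          flags = "degenerate one-sided responder"),
                     class = "psychometric_fit"))
  }

  starts <- list(
    list(x0 = mean(x), b = diff(range(x)) / 6,
         y0 = max(min(p), 0.01), a = min(max(p) - min(p), 0.98)),
    list(x0 = mean(x), b = diff(range(x)) / 2, y0 = 0.02, a = 0.96),
    list(x0 = unname(stats::quantile(x, 0.25)), b = 0.2, y0 = 0.05, a = 0.9),
    list(x0 = unname(stats::quantile(x, 0.75)), b = 0.2, y0 = 0.05, a = 0.9),
    list(x0 = mean(x), b = 0.05, y0 = 0.01, a = 0.98))
  lower <- c(x0 = min(x) - diff(range(x)), b = 1e-4, y0 = 0, a = 0)
  upper <- c(x0 = max(x) + diff(range(x)), b = 10, y0 = 1, a = 1)

  best <- NULL; best_rss <- Inf; converged <- FALSE
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(p ~ y0 + a / (1 + exp(-(x - x0) / b)),
                        start = st, lower = lower, upper = upper,
                        weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(w * stats::residuals(fit)^2)
    if (rss < best_rss) { best <- fit; best_rss <- rss; converged <- TRUE }
  }
  if (!converged)
    return(structure(list(x0 = NA, b = NA, y0 = NA, a = NA, rss = NA,
                          rates = tab, converged = FALSE,
                          flags = "non-convergence in all starts"),
                     class = "psychometric_fit"))
  cf <- as.list(coef(best))
  flags <- character()
  if (cf$y0 + cf$a > 1 + 1e-6) flags <- c(flags, "upper bound clipped")
  if (cf$y0 > 0.9 || cf$y0 + cf$a < 0.1)
    flags <- c(flags, "degenerate one-sided responder")
  if (cf$b <= 2e-4 || cf$b >= 9.99) flags <- c(flags, "slope at bound")
  structure(list(x0 = cf$x0, b = cf$b, y0 = cf$y0,
                 a = min(cf$a, 1 - cf$y0), rss = best_rss,
                 rates = tab, converged = TRUE, flags = flags),
            class = "psychometric_fit")
}

#' @exportS3Method base::print
print.psychometric_fit <- function(x, ...) {
  cat("Four-parameter psychometric fit\n")
  if (!x$converged) { cat("  DID NOT CONVERGE\n"); return(invisible(x)) }
  cat(sprintf("  x0 = %.4f (%.1f clicks/s), b = %.4f, y0 = %.4f, a = %.4f\n",
              x$x0, exp(x$x0), x$b, x$y0, x$a))
  cat(sprintf("  RSS = %.5g over %d rates (%d trials)\n",
              x$rss, nrow(x$rates), sum(x$rates$n)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Predict from a psychometric fit
#' @param object A `psychometric_fit`.
#' @param rate Click rates (clicks/s) at which to predict P(lick right).
#' @param ... Unused.
#' @export
predict.psychometric_fit <- function(object, rate, ...) {
  sigmoid4(log(rate), object$x0, object$b, object$y0, object$a)
}

# Session metrics -----------------------------------------------------------

#' Session-level behavioral metrics
#'
#' Accuracy over scored (correct/error) trials, violation and miss rates
#' over all trials, and the median response time over correct trials,
#' plus per-delay-bin breakdowns of accuracy, violation rate and median
#' RT.
#'
#' @param trials Trial table.
#' @param delay_bins Number of equal-width delay bins (default 4 over the
#'   observed delay range).
#' @param delay_range Bin support; defaults to the task range 0.3-1.5 s.
#' @return A list of class `session_metrics` with `accuracy`,
#'   `violation_rate`, `miss_rate`, `median_rt`, `n_trials`, and
#'   `by_delay` (data frame per bin).  `accuracy` and `median_rt` are `NA`
#'   with a flag when no trials were scored.
#' @export
session_metrics <- function(trials, delay_bins = 4,
                            delay_range = c(0.3, 1.5)) {
  if (nrow(trials) == 0L) stop("empty trial table")
  n <- nrow(trials)
  scored <- trials$outcome %in% c("correct", "error")
  viol <- trials$outcome == "violation"
  miss <- trials$outcome == "miss"
  acc <- if (any(scored)) mean(trials$outcome[scored] == "correct") else NA_real_
  corr <- trials$outcome == "correct"
  med_rt <- if (any(corr)) median(trials$rt[corr]) else NA_real_

  breaks <- seq(delay_range[1], delay_range[2], length.out = delay_bins + 1)
  breaks[1] <- min(breaks[1], min(trials$delay))
  breaks[length(breaks)] <- max(breaks[length(breaks)], max(trials$delay))
  bin <- cut(trials$delay, breaks, include.lowest = TRUE)
  by_delay <- do.call(rbind, lapply(levels(bin), function(lv) {
    i <- which(bin == lv)
    si <- i[scored[i]]; ci <- i[corr[i]]
    data.frame(delay_bin = lv,
               n = length(i),
               accuracy = if (length(si)) mean(trials$outcome[si] == "correct")
                          else NA_real_,
               violation_rate = if (length(i)) mean(viol[i]) else NA_real_,
               median_rt = if (length(ci)) median(trials$rt[ci]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(accuracy = acc, violation_rate = mean(viol),
                 miss_rate = mean(miss), median_rt = med_rt,
                 n_trials = n, n_scored = sum(scored),
                 by_delay = by_delay,
                 flags = if (!any(scored)) "no scored trials" else character()),
            class = "session_metrics")
}

#' @exportS3Method base::print
print.session_metrics <- function(x, ...) {
  cat(sprintf(paste0("Session metrics (%d trials, %d scored)\n",
                     "  accuracy %.3f | violation %.3f | miss %.3f | ",
                     "median RT %.3f s\n"),
              x$n_trials, x$n_scored, x$accuracy, x$violation_rate,
              x$miss_rate, x$median_rt))
  invisible(x)
}

# Paired condition comparison -----------------------------------------------

#' Compare behavior between paired condition sessions
#'
#' For each session pair (e.g., CNO infusion vs its saline control),
#' computes the change in error rate, violation rate and miss rate
#' (means) and in RT (medians over correct trials), then tests each delta
#' across pairs with a two-sided sign-flip permutation test on the mean
#' paired difference.
#'
#' @param a,b Trial tables for the two conditions; sessions are paired by
#'   the `paired_by` column (values must match one-to-one between `a` and
#'   `b`).
#' @param paired_by Column name identifying pairs (default
#'   `"session_id"`).
#' @param n_resamples Number of sign-flip permutations.
#' @param seed Optional integer seed.
#' @return A list of class `condition_comparison` with `deltas` (one row
#'   per pair) and `tests` (a `dd_test` per metric, a minus b).
#' @export
compare_conditions <- function(a, b, paired_by = "session_id",
                               n_resamples = 5000, seed = NULL) {
  ka <- unique(a[[paired_by]]); kb <- unique(b[[paired_by]])
  orphans <- c(setdiff(ka, kb), setdiff(kb, ka))
  if (length(orphans))
    stop("unpairable sessions: ", paste(orphans, collapse = ", "))
  keys <- sort(unique(ka))
  one <- function(tr) {
    m <- session_metrics(tr)
    c(error = 1 - m$accuracy, violation = m$violation_rate,
      miss = m$miss_rate, rt = m$median_rt)
  }
  deltas <- t(vapply(keys, function(k)
    one(a[a[[paired_by]] == k, ]) - one(b[b[[paired_by]] == k, ]),
    numeric(4)))
  rownames(deltas) <- keys
  if (!is.null(seed)) set.seed(seed)
  tests <- lapply(colnames(deltas), function(m) {
    d <- deltas[, m]
    d <- d[is.finite(d)]
    if (length(d) < 2L)
      return(new_test_result(NA_real_, 1, paste0("sign-flip permutation (",
                                                 m, "): too few pairs")))
    obs <- mean(d)
    perm <- replicate(n_resamples,
                      mean(d * sample(c(-1, 1), length(d), replace = TRUE)))
    p <- (sum(abs(perm) >= abs(obs) - 1e-12) + 1) / (n_resamples + 1)
    new_test_result(obs, min(p, 1),
                    sprintf("paired sign-flip permutation on %s", m),
                    "two", n_resamples,
                    if (is.null(seed)) NA_integer_ else seed)
  })
  names(tests) <- colnames(deltas)
  structure(list(deltas = as.data.frame(deltas), tests = tests,
                 n_pairs = length(keys)),
            class = "condition_comparison")
}

#' @exportS3Method base::print
print.condition_comparison <- function(x, ...) {
  cat(sprintf("Condition comparison over %d session pairs\n", x$n_pairs))
  for (m in names(x$tests))
    cat(sprintf("  d_%-9s = %+.4f  (p = %.4g)\n", m,
                x$tests[[m]]$statistic, x$tests[[m]]$p_value))
  invisible(x)
}
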