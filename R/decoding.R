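# Balanced linear decoding -----------------------------------------------------

# subsample the majority class among training indices so classes match
balance_classes <- function(idx, is_a) {
  a <- idx[is_a[idx]]; b <- idx[!is_a[idx]]
  m <- min(length(a), length(b))
  if (m < 1L) stop("a class is absent from the training set")
  out <- c(if (length(a) > m) sample(a, m) else a,
           if (length(b) > m) sample(b, m) else b)
  stopifnot(sum(is_a[out]) == sum(!is_a[out]))   # balancing guarantee
  out
}

# The response array is divided by one global factor (the training set's
# overall s.d.) before fitting: dF/F units are arbitrary per session, so
# this pins the effective regularization of cost = 1 to the data's own
# scale without touching the relative geometry of the features (no
# per-feature standardization).
fit_linear_decoder <- function(X, y) {
  s <- stats::sd(X)
  if (!is.finite(s) || s == 0) s <- 1
  fit <- e1071::svm(x = X / s, y = factor(y, levels = c(FALSE, TRUE)),
                    kernel = "linear", cost = 1, scale = FALSE)
  list(fit = fit, s = s)
}

predict_linear_decoder <- function(model, X) {
  predict(model$fit, X / model$s) == "TRUE"
}

decoder_labels <- function(trials, mode, contra_choice) {
  if (mode == "choice") trials$choice == contra_choice
  else trials$category == "high"
}

#' Cross-validated population decoding of choice or sensory category
#'
#' For each behavioral epoch, repeatedly (default 100 resamples) splits
#' trials into a random 90% training / 10% test set, balances the
#' training classes by subsampling the majority class, fits a linear
#' maximum-margin classifier (L2-regularized, cost 1) on the
#' epoch-averaged population vectors, and scores the held-out trials.
#' The shuffled-label chance control is computed identically after
#' permuting the labels.
#'
#' @param er An `epoch_response`.
#' @param mode `"choice"` (left vs right lick) or `"sensory"` (high vs
#'   low click rate).
#' @param epochs Epoch names to decode (default: all four).
#' @param n_resamples Number of train/test resamples.
#' @param train_frac Fraction of trials used for training.
#' @param shuffle Shuffle labels independently on every resample
#'   (chance-level control).
#' @param seed Optional integer seed (drives both the splits and the
#'   per-resample balancing subsamples).
#' @return An object of class `decode_result`: data frame `accuracy`
#'   (epoch, mean, sem, n_resamples) and matrix `per_resample`.
#' @export
cv_decode <- function(er, mode = c("choice", "sensory"), epochs = er$epochs,
                      n_resamples = 100, train_frac = 0.9, shuffle = FALSE,
                      seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  labels_full <- decoder_labels(er$trials, mode, er$contra_choice)
  acc <- matrix(NA_real_, n_resamples, length(epochs),
                dimnames = list(NULL, epochs))
  for (e in epochs) {
    X <- er$dff_epoch[, , e, drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, ncol = 1)
    ok <- stats::complete.cases(X)
    Xe <- X[ok, , drop = FALSE]; ye <- labels_full[ok]
    if (sum(ye) < 2L || sum(!ye) < 2L)
      stop("a class is absent (or has < 2 trials) in epoch ", e)
    n <- nrow(Xe)
    n_train <- max(2L, floor(train_frac * n))
    for (r in seq_len(n_resamples)) {
      y <- if (shuffle) sample(ye) else ye
      tr <- sample.int(n, n_train)
      te <- setdiff(seq_len(n), tr)
      if (!length(te)) next
      trb <- tryCatch(balance_classes(tr, y), error = function(e) NULL)
      if (is.null(trb)) next
      fit <- fit_linear_decoder(Xe[trb, , drop = FALSE], y[trb])
      pred <- predict_linear_decoder(fit, Xe[te, , drop = FALSE])
      acc[r, e] <- mean(pred == y[te])
    }
  }
  summ <- data.frame(epoch = epochs,
                     mean = colMeans(acc, na.rm = TRUE),
                     sem = apply(acc, 2, function(v)
                       sd(v, na.rm = TRUE) / sqrt(sum(is.finite(v)))),
                     n_resamples = colSums(is.finite(acc)),
                     row.names = NULL)
  structure(list(accuracy = summ, per_resample = acc, mode = mode,
                 shuffled = shuffle),
            class = "decode_result")
}

#' @exportS3Method base::print
print.decode_result <- function(x, ...) {
  cat(sprintf("<decode_result> %s decoding%s\n", x$mode,
              if (x$shuffled) " (shuffled labels)" else ""))
  print(transform(x$accuracy, mean = round(mean, 3), sem = round(sem, 4)))
  invisible(x)
}

#' Leave-one-out population decoding
#'
#' Classifies every trial with a balanced linear decoder trained on all
#' remaining trials, yielding a per-trial 0/1 classification outcome
#' (the trial-wise "amount of choice information" used to model RT).
#'
#' @param er An `epoch_response`.
#' @param mode `"choice"` or `"sensory"`.
#' @param epoch Epoch to decode (default `"delay"`).
#' @param seed Optional integer seed (balancing subsamples).
#' @return Data frame with `trial_id`, `outcome01` (1 = correctly
#'   classified), aligned with the scored trials of `er`.
#' @export
loo_decode <- function(er, mode = c("choice", "sensory"), epoch = "delay",
                       seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  X <- er$dff_epoch[, , epoch, drop = TRUE]
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  y <- decoder_labels(er$trials, mode, er$contra_choice)
  ok <- stats::complete.cases(X)
  if (sum(y[ok]) < 2L || sum(!y[ok]) < 2L)
    stop("a class is absent (or has < 2 trials) in epoch ", epoch)
  out <- rep(NA_real_, nrow(X))
  idx_ok <- which(ok)
  for (i in idx_ok) {
    rest <- setdiff(idx_ok, i)
    trb <- balance_classes(rest, y)
    fit <- fit_linear_decoder(X[trb, , drop = FALSE], y[trb])
    pred <- predict_linear_decoder(fit, X[i, , drop = FALSE])
    out[i] <- as.numeric(pred == y[i])
  }
  data.frame(trial_id = er$trials$trial_id, outcome01 = out)
}

# RT linkage ---------------------------------------------------------------------

#' Correlate decoding accuracy and delay with response time across RT bins
#'
#' Per session, trials are binned at RT quantiles (default quintiles, the
#' "each 20 percentile of RT" binning) within `rt_range`; per-bin mean
#' decoding accuracy, mean delay and mean RT are computed.  Pearson
#' correlations (with t-test p, df = n - 2) are reported both across all
#' session-bin points and across bin means over sessions.
#'
#' @param loo Output of [loo_decode()].
#' @param trials Trial table aligned with `loo` via `trial_id`.
#' @param n_bins Number of RT quantile bins (default 5).
#' @param rt_range RT window in seconds (default 0-2.5).
#' @return List of class `rt_link` with `bins` (per session x bin),
#'   `pooled` and `session_means` correlation results for accuracy-vs-RT
#'   and delay-vs-RT.
#' @export
rt_link <- function(loo, trials, n_bins = 5, rt_range = c(0, 2.5)) {
  d <- merge(trials, loo, by = "trial_id")
  d <- d[is.finite(d$rt) & is.finite(d$outcome01) &
           d$rt >= rt_range[1] & d$rt <= rt_range[2], ]
  if (nrow(d) < n_bins) stop("fewer trials than RT bins")
  if (length(unique(d$rt)) < n_bins)
    stop("degenerate RT distribution: too few distinct RTs to bin")
  bins <- do.call(rbind, lapply(split(d, d$session_id), function(s) {
    qs <- unique(quantile(s$rt, seq(0, 1, length.out = n_bins + 1)))
    if (length(qs) < 3L) stop("degenerate RT distribution within a session")
    b <- cut(s$rt, qs, include.lowest = TRUE, labels = FALSE)
    do.call(rbind, lapply(sort(unique(b)), function(k)
      data.frame(session_id = s$session_id[1], bin = k,
                 rt = mean(s$rt[b == k]),
                 accuracy = mean(s$outcome01[b == k]),
                 delay = mean(s$delay[b == k]))))
  }))
  corr <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    ct <- suppressWarnings(cor.test(x[ok], y[ok]))
    list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  }
  sess_means <- stats::aggregate(cbind(rt, accuracy, delay) ~ bin,
                                 data = bins, FUN = mean)
  structure(list(
    bins = bins,
    pooled = list(accuracy = corr(bins$rt, bins$accuracy),
                  delay = corr(bins$rt, bins$delay)),
    session_means = list(accuracy = corr(sess_means$rt, sess_means$accuracy),
                         delay = corr(sess_means$rt, sess_means$delay))),
    class = "rt_link")
}

#' @exportS3Method base::print
print.rt_link <- function(x, ...) {
  cat("RT linkage (pooled session-bin points):\n")
  cat(sprintf("  accuracy vs RT: r = %+.3f (p = %.3g, n = %d)\n",
              x$pooled$accuracy$r, x$pooled$accuracy$p, x$pooled$accuracy$n))
  cat(sprintf("  delay    vs RT: r = %+.3f (p = %.3g, n = %d)\n",
              x$pooled$delay$r, x$pooled$delay$p, x$pooled$delay$n))
  invisible(x)
}

#' Linear mixed model of response time
#'
#' Models per-trial RT as a linear combination of delay duration and
#' leave-one-out choice-classification outcome (optionally plus
#' behavioral performance and tongue/nose positions), with
#' subject-level random effects, fitted by maximum likelihood.  Random
#' slopes are attempted first; on a singular random-effect covariance the
#' model falls back to random intercepts only (logged).
#'
#' @param trials Trial table (must contain any extra covariate columns).
#' @param loo Output of [loo_decode()] (`decode` covariate).
#' @param covariates Character vector among `"delay"`, `"decode"`,
#'   `"performance"`, `"tongue"`, `"nose"`.
#' @param random `"slope"` (random intercept + slopes) or `"intercept"`.
#' @return Object of class `rt_lmm_fit`: `fixed` (estimate, se, df, t, p
#'   per fixed effect), `varcor`, `fallback` flag, and the underlying
#'   `lmerMod` (or `lm` when only one subject is present).
#' @export
fit_rt_lmm <- function(trials, loo, covariates = c("delay", "decode"),
                       random = c("slope", "intercept")) {
  random <- match.arg(random)
  d <- merge(trials, loo, by = "trial_id")
  d <- d[is.finite(d$rt) & is.finite(d$outcome01), ]
  d$decode <- d$outcome01
  d$performance <- as.numeric(d$outcome == "correct")
  miss <- setdiff(covariates, c(names(d)))
  if (length(miss)) stop("missing covariate column(s): ",
                         paste(miss, collapse = ", "))
  for (v in covariates)
    if (!all(is.finite(d[[v]]))) stop("non-finite values in covariate ", v)
  fixed <- paste(covariates, collapse = " + ")
  if (length(unique(d$subject_id)) < 2L) {
    fit <- lm(stats::as.formula(paste("rt ~", fixed)), data = d)
    sm <- summary(fit)$coefficients
    fixed_tab <- data.frame(term = rownames(sm), estimate = sm[, 1],
                            se = sm[, 2], df = fit$df.residual,
                            t = sm[, 3], p = sm[, 4], row.names = NULL)
    return(structure(list(fixed = fixed_tab, varcor = NULL,
                          fallback = TRUE, model = fit,
                          note = "single subject: ordinary least squares"),
                     class = "rt_lmm_fit"))
  }
  re <- if (random == "slope")
    paste0("(1 + ", fixed, " | subject_id)") else "(1 | subject_id)"
  form <- stats::as.formula(paste("rt ~", fixed, "+", re))
  fit <- suppressWarnings(suppressMessages(
    lmerTest::lmer(form, data = d, REML = FALSE)))
  fallback <- FALSE
  if (random == "slope" && lme4::isSingular(fit, tol = 1e-4)) {
    message("singular random-slope covariance; falling back to random intercepts")
    fit <- suppressWarnings(suppressMessages(
      lmerTest::lmer(stats::as.formula(
        paste("rt ~", fixed, "+ (1 | subject_id)")), data = d, REML = FALSE)))
    fallback <- TRUE
  }
  sm <- summary(fit)$coefficients
  fixed_tab <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                          se = sm[, "Std. Error"], df = sm[, "df"],
                          t = sm[, "t value"], p = sm[, "Pr(>|t|)"],
                          row.names = NULL)
  structure(list(fixed = fixed_tab,
                 varcor = lme4::VarCorr(fit), fallback = fallback,
                 model = fit, note = NULL),
            class = "rt_lmm_fit")
}

#' @exportS3Method base::print
print.rt_lmm_fit <- function(x, ...) {
  cat("Linear mixed model of RT\n")
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  if (isTRUE(x$fallback) && is.null(x$note))
    cat("  (random-intercept fallback)\n")
  print(transform(x$fixed, estimate = signif(estimate, 4),
                  se = signif(se, 3), t = round(t, 2), p = signif(p, 3)))
  invisible(x)
}
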