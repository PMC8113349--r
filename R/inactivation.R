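# Normalized ipsilateral bias ----------------------------------------------

# which lick direction is ipsilateral on each trial
ipsi_choice_side <- function(trials, ipsi_side = NULL) {
  side <- if (is.null(ipsi_side)) trials$hemisphere else
    rep(ipsi_side, nrow(trials))
  if (any(!side %in% c("left", "right")))
    stop("ipsilateral side undefined (bilateral hemisphere); supply ipsi_side")
  side
}

#' Normalized ipsilateral bias from unilateral inactivation
#'
#' For each session, the mean P(lick ipsi) on control trials is
#' subtracted from the ipsilateral-choice indicator of every inactivation
#' trial; the resulting per-trial bias changes are concatenated across
#' sessions and summarized as mean +/- s.e.m. across trials, in
#' percentage points (positive = more ipsilateral choices).
#'
#' @param trials Trial table containing control (`manipulation == "none"`)
#'   and inactivation trials.  Only scored trials are used.
#' @param by Optional character vector of grouping columns (e.g.
#'   `c("manip_epoch", "manip_region")`) to summarize separately.
#' @param ipsi_side Override for the ipsilateral lick direction; by
#'   default taken from the `hemisphere` column (unilateral sessions).
#' @return Data frame with one row per group: `delta_ipsi` (percentage
#'   points), `sem`, `n_trials`.  Sessions without control trials are
#'   dropped with a warning.
#' @export
normalized_ipsi_bias <- function(trials, by = NULL, ipsi_side = NULL) {
  sc <- scored_trials(trials)
  sc$.ipsi <- as.numeric(sc$choice == ipsi_choice_side(sc, ipsi_side))
  parts <- split(sc, sc$session_id)
  rows <- list()
  for (s in parts) {
    ctrl <- s$manipulation == "none"
    inact <- !ctrl
    if (!any(ctrl)) {
      warning("session ", s$session_id[1],
              " has no control trials; excluded")
      next
    }
    if (!any(inact)) next
    d <- s[inact, , drop = FALSE]
    d$.delta <- 100 * (d$.ipsi - mean(s$.ipsi[ctrl]))
    rows[[length(rows) + 1L]] <- d
  }
  if (!length(rows)) stop("no sessions with both control and inactivation trials")
  all_d <- do.call(rbind, rows)
  grp <- if (is.null(by)) rep("all", nrow(all_d)) else
    interaction(all_d[by], drop = TRUE, sep = ":")
  out <- do.call(rbind, lapply(split(all_d$.delta, grp), function(v)
    data.frame(delta_ipsi = mean(v), sem = sd(v) / sqrt(length(v)),
               n_trials = length(v))))
  out <- cbind(group = rownames(out), out)
  rownames(out) <- NULL
  out
}

# Logistic choice models ----------------------------------------------------

# design matrix for the perturbation choice models
choice_model_design <- function(trials, model = c("model1", "model2"),
                                subject_intercepts = TRUE) {
  model <- match.arg(model)
  sc <- scored_trials(trials)
  y <- as.numeric(sc$choice == "right")
  lrn <- sc$log_rate_norm
  difficulty <- 1 - lrn^2
  X <- cbind(`(Intercept)` = 1, log_rate_norm = lrn)
  epochs <- setdiff(sort(unique(sc$manip_epoch)), "none")
  regions <- setdiff(sort(unique(sc$manip_region)), "none")
  nm <- function(...) make.names(paste(..., sep = "_"))
  for (e in epochs)
    X <- cbind(X, setNames(data.frame(as.numeric(sc$manip_epoch == e)),
                           nm("epoch", e)))
  for (r in regions)
    X <- cbind(X, setNames(data.frame(as.numeric(sc$manip_region == r)),
                           nm("region", r)))
  if (model == "model2") {
    for (e in epochs) for (r in regions) {
      v <- as.numeric(sc$manip_epoch == e & sc$manip_region == r) * difficulty
      if (any(v != 0))
        X <- cbind(X, setNames(data.frame(v),
                               nm("epoch", e, "region", r, "difficulty")))
    }
  }
  if (subject_intercepts && length(unique(sc$subject_id)) > 1L) {
    subj <- factor(sc$subject_id)
    mm <- model.matrix(~ subj)[, -1, drop = FALSE]
    colnames(mm) <- paste0("subject_", levels(subj)[-1])
    X <- cbind(X, mm)
  }
  list(X = as.matrix(X), y = y, subject = sc$subject_id, model_id = model)
}

# plain ridge-penalized logistic Newton solver (used when glm separates)
ridge_logistic <- function(X, y, lambda = 1e-2, maxit = 100, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  pen <- rep(lambda, ncol(X)); pen[colnames(X) == "(Intercept)"] <- 0
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    H <- crossprod(X, X * w) + diag(pen, ncol(X))
    g <- crossprod(X, y - mu) - pen * beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  list(coef = setNames(drop(beta), colnames(X)),
       vcov = solve(H),
       loglik = sum(y * log(plogis(drop(X %*% beta))) +
                      (1 - y) * log(1 - plogis(drop(X %*% beta)))))
}

#' Logistic choice model for perturbation effects
#'
#' Maximum-likelihood logistic regression of the per-trial choice (lick
#' right) on the normalized log click rate plus perturbation terms.
#' Model 1 has additive inactivation-epoch and inactivation-region
#' effects; Model 2 adds three-way epoch x region x difficulty
#' interaction terms, where difficulty is `1 - log_rate_norm^2` (a
#' quadratic function of the normalized log click rate).  Per-subject
#' fixed intercepts stand in for subject random effects, and the default
#' covariance is cluster-robust by subject.
#'
#' @param trials Trial table (scored trials are used).
#' @param model `"model1"` or `"model2"`.
#' @param subject_intercepts Include fixed per-subject intercepts when
#'   there are multiple subjects.
#' @param vcov_type `"cluster"` (robust, clustered by subject; default
#'   when >1 subject) or `"model"` (inverse Fisher information).
#' @return An object of class `choice_model_fit`: `coefficients`, `vcov`,
#'   `z`, `p`, `loglik`, `n_trials`, `model_id`, `separation` flag.
#'   Aliased (rank-deficient) columns are dropped with a message; an
#'   all-constant design is an error.  If complete separation is
#'   detected, a ridge-stabilized refit is returned and flagged.
#' @export
fit_choice_logistic <- function(trials, model = c("model1", "model2"),
                                subject_intercepts = TRUE,
                                vcov_type = c("cluster", "model")) {
  vcov_type <- match.arg(vcov_type)
  d <- choice_model_design(trials, match.arg(model), subject_intercepts)
  if (length(unique(d$y)) < 2L) stop("need both choice outcomes present")
  qrX <- qr(d$X)
  if (qrX$rank < ncol(d$X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(d$X)[-keep]
    if (!"(Intercept)" %in% colnames(d$X)[keep] || qrX$rank < 2L)
      stop("design matrix rank-deficient beyond repair (all-identical predictors)")
    message("dropping aliased columns: ", paste(dropped, collapse = ", "))
    d$X <- d$X[, keep, drop = FALSE]
  }
  df <- data.frame(.y = d$y, d$X[, -1, drop = FALSE], check.names = FALSE)
  fit <- suppressWarnings(glm(.y ~ ., family = binomial(), data = df,
                              control = stats::glm.control(epsilon = 1e-12,
                                                           maxit = 100)))
  mu <- fitted(fit)
  separated <- any(mu > 1 - 1e-8 | mu < 1e-8) || max(abs(coef(fit))) > 15
  if (separated) {
    rf <- ridge_logistic(d$X, d$y)
    beta <- rf$coef; V <- rf$vcov; ll <- rf$loglik
  } else {
    beta <- coef(fit)
    names(beta) <- colnames(d$X)
    V <- if (vcov_type == "cluster" && length(unique(d$subject)) > 1L)
      sandwich::vcovCL(fit, cluster = d$subject) else vcov(fit)
    dimnames(V) <- list(names(beta), names(beta))
    ll <- as.numeric(logLik(fit))
  }
  z <- beta / sqrt(diag(V))
  structure(list(coefficients = beta, vcov = V, z = z,
                 p = 2 * pnorm(-abs(z)), loglik = ll,
                 n_trials = length(d$y), model_id = d$model_id,
                 separation = separated, vcov_type = vcov_type),
            class = "choice_model_fit")
}

#' @exportS3Method base::print
print.choice_model_fit <- function(x, ...) {
  cat(sprintf("Logistic choice model (%s), %d trials, logLik %.2f%s\n",
              x$model_id, x$n_trials, x$loglik,
              if (x$separation) " [separation: ridge-stabilized]" else ""))
  tab <- data.frame(estimate = x$coefficients,
                    se = sqrt(diag(x$vcov)), z = x$z, p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' Likelihood-ratio test between nested choice models
#'
#' @param fit_small,fit_big Nested `choice_model_fit`s on the same trials
#'   (the smaller model's coefficient names must be a subset of the
#'   bigger's).
#' @return A `dd_test` with `2 * (logLik_big - logLik_small)` referred to
#'   a chi-squared with df = difference in parameter count.  Identical
#'   models give statistic 0 and p = 1.
#' @export
lrt_nested <- function(fit_small, fit_big) {
  stopifnot(inherits(fit_small, "choice_model_fit"),
            inherits(fit_big, "choice_model_fit"))
  if (fit_small$n_trials != fit_big$n_trials)
    stop("models were fitted on different numbers of trials")
  if (!all(names(fit_small$coefficients) %in% names(fit_big$coefficients)))
    stop("models are not nested")
  df <- length(fit_big$coefficients) - length(fit_small$coefficients)
  stat <- max(2 * (fit_big$loglik - fit_small$loglik), 0)
  p <- if (df == 0L) 1 else pchisq(stat, df, lower.tail = FALSE)
  new_test_result(stat, p, "likelihood-ratio test (nested logistic models)",
                  "two", extra = list(df = df))
}

#' Single-step adjusted p-values for model contrasts
#'
#' Joint max-|z| adjustment over a family of linear contrasts of the
#' fitted coefficients: z-scores are simulated from the multivariate
#' normal implied by the fit's covariance, and each contrast's adjusted
#' p-value is the probability that the maximum absolute simulated z
#' exceeds its observed |z|.  With a single contrast this reduces to the
#' unadjusted two-sided Wald p within Monte-Carlo error.
#'
#' @param fit A `choice_model_fit`.
#' @param contrasts Named list of numeric vectors (length = number of
#'   coefficients) or a contrast matrix with one row per contrast.
#' @param n_draws Number of multivariate-normal draws (default 1e5).
#' @param seed Optional integer seed.
#' @return Data frame with estimate, se, z, unadjusted and adjusted p per
#'   contrast.
#' @export
single_step_contrasts <- function(fit, contrasts, n_draws = 1e5,
                                  seed = NULL) {
  stopifnot(inherits(fit, "choice_model_fit"))
  L <- if (is.matrix(contrasts)) contrasts else do.call(rbind, contrasts)
  if (ncol(L) != length(fit$coefficients))
    stop("contrast length must match number of coefficients")
  est <- drop(L %*% fit$coefficients)
  V <- L %*% fit$vcov %*% t(L)
  se <- sqrt(diag(V))
  if (any(!is.finite(se)) || any(se <= 0))
    stop("singular covariance for the requested contrasts")
  z <- est / se
  R <- V / tcrossprod(se)
  ee <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ee) < -1e-8) stop("contrast covariance is not positive semi-definite")
  if (!is.null(seed)) set.seed(seed)
  Z <- MASS::mvrnorm(n_draws, mu = rep(0, nrow(L)),
                     Sigma = R + diag(1e-10, nrow(L)))
  maxabs <- apply(abs(Z), 1, max)
  data.frame(contrast = if (is.null(rownames(L)))
               paste0("C", seq_len(nrow(L))) else rownames(L),
             estimate = est, se = se, z = z,
             p_unadjusted = 2 * pnorm(-abs(z)),
             p_adjusted = vapply(abs(z), function(zz) mean(maxabs >= zz),
                                 numeric(1)),
             row.names = NULL)
}
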