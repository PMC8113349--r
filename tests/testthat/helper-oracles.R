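# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths.

# brute-force AUC: explicit pairwise comparison probability
auc_bruteforce <- function(a, b) {
  tot <- 0
  for (x in a) for (y in b) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(a) * length(b))
}

# brute-force centered truncated rolling percentile (quantile type 7)
rolling_pctl_bruteforce <- function(x, window, p) {
  n <- length(x)
  lo <- (window - 1) %/% 2
  hi <- window - 1 - lo
  sapply(seq_len(n), function(i)
    quantile(x[max(1, i - lo):min(n, i + hi)], p / 100, type = 7,
             names = FALSE))
}

# hand-rolled IRLS for unpenalized logistic regression
irls_logistic <- function(X, y, maxit = 200, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, X * w), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  drop(beta)
}

# closed-form Pearson statistic for a 2x2 table
pearson_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + cc + d
  n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
}

# minimal hand-built trial table
make_trials <- function(outcomes, choices = NULL, rts = NULL,
                        rates = NULL, delays = NULL,
                        session = "s1", subject = "m01",
                        manipulation = "none", manip_epoch = "none",
                        manip_region = "none", hemisphere = "right") {
  n <- length(outcomes)
  if (is.null(choices))
    choices <- ifelse(outcomes %in% c("correct", "error"), "right", "none")
  if (is.null(rts))
    rts <- ifelse(outcomes %in% c("correct", "error"), 0.5, NA_real_)
  if (is.null(rates)) rates <- rep(125, n)
  if (is.null(delays)) delays <- rep(1, n)
  data.frame(trial_id = seq_len(n), subject_id = subject,
             session_id = session, click_rate = rates,
             log_rate_norm = log_rate_norm(rates),
             category = ifelse(rates > 50, "high", "low"),
             delay = delays, choice = choices, outcome = outcomes,
             rt = rts, manipulation = manipulation,
             manip_epoch = manip_epoch, manip_region = manip_region,
             hemisphere = hemisphere, stringsAsFactors = FALSE)
}

# hand-built epoch_response with direct control of the response array
make_epoch_response <- function(dff_epoch, trials,
                                contra_choice = "right") {
  structure(list(dff_epoch = dff_epoch, trials = trials,
                 epochs = dimnames(dff_epoch)[[3]],
                 contra_choice = contra_choice,
                 n_excluded = 0L,
                 short_delay_flag = logical(nrow(trials))),
            class = "epoch_response")
}

# a quick standard synthetic imaging session for decoding tests
quick_session <- function(n_trials = 120, n_rois = 10, auc = 0.8,
                          seed = 1) {
  tr <- sim_behavior(n_trials, seed = seed,
                     violation_hazard = list(intercept = -6, delay_coef = 0),
                     miss_prob = 0)
  pop <- sim_population(tr, n_rois = n_rois, epoch_auc = auc,
                        seed = seed + 1000)
  suppressMessages(epoch_average(pop))
}
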