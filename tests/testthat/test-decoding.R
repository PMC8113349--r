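make_separable_er <- function(n_trials, n_rois = 4, gap = 10) {
  choices <- rep(c("right", "left"), n_trials / 2)
  arr <- array(rnorm(n_trials * n_rois, sd = 0.1) +
                 rep(ifelse(choices == "right", gap, -gap), n_rois),
               dim = c(n_trials, n_rois, 1),
               dimnames = list(NULL, NULL, "delay"))
  make_epoch_response(arr, make_trials(rep("correct", n_trials),
                                       choices = choices))
}

test_that("linearly separable populations decode perfectly", {
  er <- make_separable_er(40)
  res <- cv_decode(er, "choice", epochs = "delay", n_resamples = 30,
                   seed = 1)
  expect_equal(res$accuracy$mean, 1)
  loo <- loo_decode(er, "choice", seed = 2)
  expect_true(all(loo$outcome01 == 1))
})

test_that("leave-one-out classifies all of four separable trials", {
  er <- make_separable_er(4)
  loo <- loo_decode(er, "choice", seed = 3)
  expect_equal(loo$outcome01, rep(1, 4))
})

test_that("shuffled labels decode at chance", {
  er <- quick_session(150, n_rois = 15, auc = 0.85, seed = 21)
  res <- cv_decode(er, "choice", epochs = "delay", n_resamples = 60,
                   shuffle = TRUE, seed = 4)
  expect_lt(abs(res$accuracy$mean - 0.5), 0.05)
})

test_that("accuracy increases with generating selectivity", {
  levels <- c(0.5, 0.6, 0.7, 0.8, 0.9)
  tr <- sim_behavior(130, seed = 31,
                     violation_hazard = list(intercept = -6, delay_coef = 0),
                     miss_prob = 0)
  accs <- vapply(seq_along(levels), function(i) {
    pop <- sim_population(tr, n_rois = 10, epoch_auc = levels[i],
                          seed = 100 + i)
    er <- suppressMessages(epoch_average(pop))
    cv_decode(er, "choice", epochs = "delay", n_resamples = 25,
              seed = 5)$accuracy$mean
  }, numeric(1))
  expect_gt(cor(levels, accs, method = "spearman"), 0.8)
  expect_gt(accs[5], accs[1] + 0.2)
})

test_that("leave-one-out agrees with cross-validated accuracy", {
  er <- quick_session(120, n_rois = 10, auc = 0.8, seed = 41)
  cv <- cv_decode(er, "choice", epochs = "delay", n_resamples = 50,
                  seed = 6)
  loo <- loo_decode(er, "choice", seed = 7)
  expect_equal(mean(loo$outcome01, na.rm = TRUE), cv$accuracy$mean,
               tolerance = 0.1)
})

test_that("decoding is invariant to ROI order and response offsets", {
  er <- quick_session(80, n_rois = 6, auc = 0.8, seed = 51)
  r1 <- cv_decode(er, "choice", epochs = "delay", n_resamples = 20,
                  seed = 8)
  er2 <- er
  er2$dff_epoch <- er$dff_epoch[, sample(6), , drop = FALSE]
  r2 <- cv_decode(er2, "choice", epochs = "delay", n_resamples = 20,
                  seed = 8)
  er3 <- er
  er3$dff_epoch <- er$dff_epoch + 100
  r3 <- cv_decode(er3, "choice", epochs = "delay", n_resamples = 20,
                  seed = 8)
  expect_equal(r1$accuracy$mean, r2$accuracy$mean, tolerance = 1e-12)
  expect_equal(r1$accuracy$mean, r3$accuracy$mean, tolerance = 1e-12)
})

test_that("decoding errors when a class is absent", {
  er <- make_separable_er(20)
  er$trials$choice <- "right"
  expect_error(cv_decode(er, "choice", epochs = "delay"), "class")
})

test_that("RT binning yields an exactly linear relation when constructed", {
  trials <- make_trials(rep("correct", 20), rts = seq_len(20) / 10,
                        delays = rep(1, 20))
  trials$rt <- seq_len(20) / 10
  loo <- data.frame(trial_id = trials$trial_id,
                    outcome01 = rep(c(1, 1, 1, 1, 1, 1, 1, 0,
                                      1, 1, 0, 0, 1, 0, 0, 0,
                                      0, 0, 0, 0), 1))
  rl <- rt_link(loo, trials, n_bins = 5, rt_range = c(0, 2.5))
  expect_equal(rl$pooled$accuracy$r, -1, tolerance = 1e-9)
})

test_that("RT link detects simulated negative coupling and not its absence", {
  set.seed(9)
  n <- 400
  sess <- rep(sprintf("s%d", 1:4), each = n / 4)
  strength <- runif(n)                     # latent choice-signal strength
  rts <- pmax(1.2 - 0.8 * strength + rnorm(n, 0, 0.15), 0.05)
  trials <- make_trials(rep("correct", n), rts = rts,
                        delays = runif(n, 0.3, 1.5), session = sess)
  trials$session_id <- sess
  loo <- data.frame(trial_id = trials$trial_id,
                    outcome01 = rbinom(n, 1, 0.35 + 0.6 * strength))
  rl <- rt_link(loo, trials)
  expect_lt(rl$pooled$accuracy$r, 0)
  expect_lt(rl$pooled$accuracy$p, 0.05)
  # independence: no significant correlation at a fixed seed
  loo0 <- data.frame(trial_id = trials$trial_id,
                     outcome01 = rbinom(n, 1, 0.7))
  rl0 <- rt_link(loo0, trials)
  expect_gt(rl0$pooled$accuracy$p, 0.05)
  expect_error(rt_link(loo[1:3, ], trials[1:3, ]), "fewer trials")
})

test_that("RT mixed model recovers simulated fixed effects", {
  set.seed(10)
  n <- 2000
  subj <- rep(sprintf("m%02d", 1:8), each = n / 8)
  delay <- runif(n, 0.3, 1.5)
  decode <- rbinom(n, 1, 0.7)
  u <- rnorm(8, 0, 0.08)[as.integer(factor(subj))]
  rts <- 1.0 - 0.3 * delay - 0.2 * decode + u + rnorm(n, 0, 0.12)
  trials <- make_trials(rep("correct", n), rts = rts, delays = delay,
                        subject = subj)
  trials$subject_id <- subj
  loo <- data.frame(trial_id = trials$trial_id, outcome01 = decode)
  fit <- suppressMessages(fit_rt_lmm(trials, loo))
  est <- setNames(fit$fixed$estimate, fit$fixed$term)
  expect_lt(abs(est[["delay"]] + 0.3), 0.05)
  expect_lt(abs(est[["decode"]] + 0.2), 0.05)
  expect_lt(fit$fixed$p[fit$fixed$term == "decode"], 0.05)
})

test_that("with zero random-effect variance the LMM matches OLS", {
  # this draw yields a boundary (zero-variance) random-effect estimate,
  # where the equivalence is exact
  set.seed(2)
  n <- 800
  subj <- rep(sprintf("m%02d", 1:8), each = 100)
  delay <- runif(n, 0.3, 1.5)
  decode <- rbinom(n, 1, 0.7)
  rts <- 1 - 0.3 * delay - 0.2 * decode + rnorm(n, 0, 0.1)
  trials <- make_trials(rep("correct", n), rts = rts, delays = delay,
                        subject = subj)
  trials$subject_id <- subj
  loo <- data.frame(trial_id = trials$trial_id, outcome01 = decode)
  fit <- suppressMessages(fit_rt_lmm(trials, loo, random = "intercept"))
  ols <- coef(lm(rts ~ delay + decode))
  expect_equal(fit$fixed$estimate, unname(ols), tolerance = 1e-6)
})

test_that("a null covariate has uniform p-values over replicates", {
  set.seed(12)
  ps <- replicate(60, {
    n <- 400
    subj <- rep(sprintf("m%02d", 1:4), each = 100)
    delay <- runif(n, 0.3, 1.5)
    decode <- rbinom(n, 1, 0.7)
    nose <- rnorm(n)                      # no true effect
    rts <- 1 - 0.3 * delay - 0.1 * decode +
      rnorm(4, 0, 0.05)[as.integer(factor(subj))] + rnorm(n, 0, 0.1)
    trials <- make_trials(rep("correct", n), rts = rts, delays = delay,
                          subject = subj)
    trials$subject_id <- subj
    trials$nose <- nose
    loo <- data.frame(trial_id = trials$trial_id, outcome01 = decode)
    fit <- suppressMessages(
      fit_rt_lmm(trials, loo, covariates = c("delay", "decode", "nose"),
                 random = "intercept"))
    fit$fixed$p[fit$fixed$term == "nose"]
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 1e-3)
})
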