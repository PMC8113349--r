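test_that("logistic fit matches a hand-rolled IRLS oracle to 1e-6", {
  tr <- sim_behavior(400, seed = 3,
                     psycho = list(x0 = log(50), b = 0.3, y0 = 0, a = 1),
                     manipulation = list(label = "laser", frac = 0.4,
                                         region = "m2", hemisphere = "right",
                                         bias_shift = 0.8))
  fit <- fit_choice_logistic(tr, "model1", vcov_type = "model")
  sc <- tr[tr$outcome %in% c("correct", "error"), ]
  X <- cbind(1, sc$log_rate_norm,
             sapply(c("delay", "iti", "response", "stimulus"),
                    function(e) as.numeric(sc$manip_epoch == e)))
  beta <- irls_logistic(X, as.numeric(sc$choice == "right"))
  expect_equal(unname(fit$coefficients[1:6]),
               unname(beta[c(1, 2, 3:6)]), tolerance = 1e-6)
})

test_that("normalized ipsilateral bias does the documented arithmetic", {
  # control P(ipsi) = 0.5; inactivation trials all ipsi -> delta = 50
  tr <- make_trials(rep("correct", 20),
                    choices = c(rep(c("right", "left"), 5),
                                rep("right", 10)),
                    manipulation = c(rep("none", 10), rep("laser", 10)),
                    hemisphere = "right")
  out <- normalized_ipsi_bias(tr)
  expect_equal(out$delta_ipsi, 50)
  expect_equal(out$n_trials, 10)
})

test_that("an injected ipsilateral probability shift is recovered", {
  # control P(right)=0.5 everywhere; laser trials shifted to 0.65
  set.seed(5)
  n <- 6000
  laser <- rep(c(FALSE, TRUE), n / 2)
  p <- ifelse(laser, 0.65, 0.5)
  tr <- make_trials(rep("correct", n),
                    choices = ifelse(runif(n) < p, "right", "left"),
                    manipulation = ifelse(laser, "laser", "none"),
                    hemisphere = "right")
  out <- normalized_ipsi_bias(tr)
  expect_equal(out$delta_ipsi, 15, tolerance = 3 * out$sem)
  # identical choice frequencies in both conditions: no bias
  tr0 <- tr
  tr0$choice <- rep(c("right", "left", "left", "right"), n / 4)
  expect_lt(abs(normalized_ipsi_bias(tr0)$delta_ipsi), 1e-9)
})

test_that("a logit bias on delay-epoch trials is recovered within 0.15", {
  tr <- sim_behavior(6000, seed = 31,
                     psycho = list(x0 = log(50), b = 0.3, y0 = 0, a = 1),
                     manipulation = list(label = "laser", frac = 0.5,
                                         region = "m2", hemisphere = "right",
                                         epochs = c("delay", "stimulus"),
                                         per_epoch = list(
                                           delay = list(bias_shift = 1),
                                           stimulus = list(bias_shift = 0))))
  fit <- fit_choice_logistic(tr, "model1")
  expect_equal(unname(fit$coefficients["epoch_delay"]), 1, tolerance = 0.15)
})

test_that("manipulation coefficients are calibrated under the null", {
  set.seed(41)
  cover <- mean(replicate(300, {
    tr <- sim_behavior(800,
                       psycho = list(x0 = log(50), b = 0.3, y0 = 0, a = 1),
                       manipulation = list(label = "laser", frac = 0.4,
                                           region = "m2",
                                           hemisphere = "right",
                                           bias_shift = 0))
    fit <- fit_choice_logistic(tr, "model1", vcov_type = "model")
    abs(fit$z["epoch_delay"]) < 1.96
  }))
  expect_gte(cover, 0.92)
})

test_that("degenerate designs raise a rank-deficiency error", {
  tr <- make_trials(rep(c("correct", "error"), 20),
                    choices = rep(c("right", "left"), 20),
                    rates = rep(125, 40))
  # single click rate: log_rate_norm constant and collinear with intercept
  expect_error(suppressMessages(fit_choice_logistic(tr, "model1")),
               "rank-deficient")
})

test_that("likelihood-ratio test behaves on identical and nested models", {
  tr <- sim_behavior(1500, seed = 51,
                     psycho = list(x0 = log(50), b = 0.3, y0 = 0, a = 1),
                     manipulation = list(label = "laser", frac = 0.4,
                                         region = "m2", hemisphere = "right",
                                         bias_shift = 0.5))
  f1 <- fit_choice_logistic(tr, "model1")
  f2 <- fit_choice_logistic(tr, "model2")
  same <- lrt_nested(f1, f1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  res <- lrt_nested(f1, f2)
  expect_gte(res$statistic, 0)
  expect_true(res$df == length(f2$coefficients) - length(f1$coefficients))
  expect_error(lrt_nested(f2, f1), "not nested")
})

test_that("the LRT detects a true three-way difficulty interaction", {
  # difficulty-dependent bias only on delay-epoch inactivation trials
  set.seed(61)
  hits <- replicate(25, {
    tr <- sim_behavior(10000,
                       psycho = list(x0 = log(50), b = 0.3, y0 = 0, a = 1))
    laser <- runif(nrow(tr)) < 0.4
    tr$manipulation[laser] <- "laser"
    tr$manip_epoch[laser] <- sample(c("delay", "stimulus"), sum(laser),
                                    replace = TRUE)
    tr$manip_region[laser] <- "m2"
    on <- laser & tr$manip_epoch == "delay" &
      tr$outcome %in% c("correct", "error")
    difficulty <- 1 - tr$log_rate_norm^2
    p <- sigmoid4(log(tr$click_rate), log(50), 0.3, 0, 1)
    flip <- on & (runif(nrow(tr)) <
                    plogis(1.5 * difficulty) - 0.5)
    tr$choice[flip & tr$choice == "left"] <- "right"
    tr$outcome[on] <- ifelse(
      (tr$category[on] == "high") == (tr$choice[on] == "right"),
      "correct", "error")
    f1 <- fit_choice_logistic(tr, "model1")
    f2 <- fit_choice_logistic(tr, "model2")
    lrt_nested(f1, f2)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("LRT p-values are uniform under the null", {
  set.seed(71)
  ps <- replicate(200, {
    tr <- sim_behavior(1200,
                       psycho = list(x0 = log(50), b = 0.3, y0 = 0, a = 1),
                       manipulation = list(label = "laser", frac = 0.4,
                                           region = "m2",
                                           hemisphere = "right",
                                           bias_shift = 0))
    f1 <- fit_choice_logistic(tr, "model1", vcov_type = "model")
    f2 <- fit_choice_logistic(tr, "model2", vcov_type = "model")
    lrt_nested(f1, f2)$p_value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 1e-3)
})

test_that("single-step adjustment reduces to the unadjusted p for one contrast", {
  tr <- sim_behavior(3000, seed = 81,
                     psycho = list(x0 = log(50), b = 0.3, y0 = 0, a = 1),
                     manipulation = list(label = "laser", frac = 0.4,
                                         region = "m2", hemisphere = "right",
                                         bias_shift = 0.3))
  fit <- fit_choice_logistic(tr, "model1")
  k <- length(fit$coefficients)
  one <- as.numeric(names(fit$coefficients) == "epoch_delay")
  res <- single_step_contrasts(fit, list(delay = one), n_draws = 2e5,
                               seed = 1)
  expect_lt(abs(res$p_adjusted - res$p_unadjusted), 0.01)
  # perfectly correlated contrasts: no adjustment penalty
  res2 <- single_step_contrasts(fit, list(a = one, b = one, c = one),
                                n_draws = 2e5, seed = 2)
  expect_lt(abs(res2$p_adjusted[1] - res2$p_unadjusted[1]), 0.01)
})

test_that("single-step adjustment controls family-wise error for independent contrasts", {
  # synthetic fit with identity covariance: 3 independent z-statistics
  fake <- structure(list(
    coefficients = c(a = 1.96, b = 0.5, c = -0.2),
    vcov = diag(3), z = c(1.96, 0.5, -0.2),
    p = 2 * pnorm(-abs(c(1.96, 0.5, -0.2))), loglik = 0,
    n_trials = 100L, model_id = "model1", separation = FALSE,
    vcov_type = "model"), class = "choice_model_fit")
  L <- diag(3)
  rownames(L) <- c("a", "b", "c")
  res <- single_step_contrasts(fake, L, n_draws = 2e5, seed = 3)
  # adjusted p for |z| = 1.96 over 3 independent tests: 1 - 0.95^3
  expect_equal(res$p_adjusted[1], 1 - 0.95^3, tolerance = 0.01)
})
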