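test_that("rolling-percentile correction equals the brute-force oracle", {
  set.seed(2)
  for (cfg in list(c(100, 11, 8), c(250, 50, 8), c(80, 400, 5),
                   c(120, 2, 20), c(60, 61, 8))) {
    x <- rnorm(cfg[1]) + sin(seq_len(cfg[1]) / 10)
    got <- correct_slow_drift(x, cfg[2], cfg[3])
    want <- x - rolling_pctl_bruteforce(x, cfg[2], cfg[3])
    expect_equal(got, want, tolerance = 1e-12)
  }
  # photometry configuration (1000-frame window, 5th percentile)
  x <- cumsum(rnorm(1500, 0, 0.1)) + 100
  expect_equal(correct_slow_drift(x, 1000, 5),
               x - rolling_pctl_bruteforce(x, 1000, 5), tolerance = 1e-12)
})

test_that("slow-drift correction handles degenerate traces", {
  expect_equal(correct_slow_drift(rep(5, 100), 20, 8), rep(0, 100))
  # window covering the whole trace at every position: constant subtraction
  ramp <- seq(0, 1, length.out = 100)
  got <- correct_slow_drift(ramp, 200, 8)
  expect_equal(got, ramp - quantile(ramp, 0.08, type = 7, names = FALSE),
               tolerance = 1e-12)
  expect_error(correct_slow_drift(1, 10, 8), "2 frames")
  expect_error(correct_slow_drift(rnorm(10), 10, 0), "percentile")
})

test_that("dF/F does the documented arithmetic", {
  expect_equal(compute_dff(c(2, 2, 2, 4)), c(0, 0, 0, 1))
  expect_equal(compute_dff(rep(3, 50)), rep(0, 50))
  expect_error(compute_dff(c(-2, -2, -1)), "nonpositive")
})

test_that("dF/F is invariant under multiplicative rescaling", {
  set.seed(4)
  x <- abs(rnorm(500, 10, 1)) + 5
  expect_equal(compute_dff(3 * x), compute_dff(x), tolerance = 1e-10)
})

test_that("epoch extraction recovers a boxcar placed in the delay window", {
  trials <- make_trials(rep("correct", 3), delays = c(1, 1, 1),
                        rts = c(0.5, 0.5, 0.5),
                        choices = c("right", "left", "right"))
  ev <- session_events(trials)
  fr <- 30
  n_frames <- ceiling(attr(ev, "duration") * fr) + 1
  dff <- matrix(0, n_frames, 2)
  # amplitude-2 boxcar exactly in the final 500 ms before the go cue of trial 2
  t_axis <- (seq_len(n_frames) - 1) / fr
  dff[t_axis >= ev$go_cue[2] - 0.5 & t_axis < ev$go_cue[2], 1] <- 2
  fl <- list(f = NULL, frame_rate = fr, events = ev, trials = trials,
             contra_choice = "right")
  er <- epoch_average(fl, dff = dff)
  expect_equal(unname(er$dff_epoch[2, 1, "delay"]), 2, tolerance = 1e-9)
  expect_equal(unname(er$dff_epoch[2, 1, "sound"]), 0, tolerance = 1e-9)
  expect_equal(unname(er$dff_epoch[2, 1, "response"]), 0, tolerance = 1e-9)
  expect_equal(unname(er$dff_epoch[1, 1, "delay"]), 0, tolerance = 1e-9)
})

test_that("short delays keep a full 500-ms delay window and are flagged", {
  trials <- make_trials(rep("correct", 2), delays = c(0.3, 1.2),
                        rts = c(0.4, 0.4))
  ev <- session_events(trials)
  n_frames <- ceiling(attr(ev, "duration") * 30) + 1
  fl <- list(f = NULL, frame_rate = 30, events = ev, trials = trials)
  er <- epoch_average(fl, dff = matrix(1, n_frames, 1))
  expect_identical(er$short_delay_flag, c(TRUE, FALSE))
  expect_true(is.finite(er$dff_epoch[1, 1, "delay"]))
  er2 <- epoch_average(fl, dff = matrix(1, n_frames, 1),
                       short_delay = "exclude")
  expect_true(is.na(er2$dff_epoch[1, 1, "delay"]))
})

test_that("trials with missing events or zero-length response are excluded", {
  trials <- make_trials(c("correct", "correct", "violation"),
                        rts = c(0.5, 0, NA))
  ev <- session_events(trials)
  n_frames <- ceiling(attr(ev, "duration") * 30) + 1
  fl <- list(f = NULL, frame_rate = 30, events = ev, trials = trials)
  expect_message(er <- epoch_average(fl, dff = matrix(1, n_frames, 1)),
                 "excluded")
  expect_equal(nrow(er$trials), 1L)
  expect_equal(er$n_excluded, 1L)
})

test_that("epoch extraction commutes with trial reordering", {
  er <- quick_session(60, n_rois = 3, auc = 0.7, seed = 6)
  pop <- sim_population(sim_behavior(60, seed = 6,
                                     violation_hazard = list(intercept = -6,
                                                             delay_coef = 0),
                                     miss_prob = 0),
                        n_rois = 3, epoch_auc = 0.7, seed = 1006)
  perm <- sample(nrow(pop$trials))
  pop2 <- pop
  pop2$trials <- pop$trials[perm, ]
  pop2$events <- pop$events[perm, ]
  attr(pop2$events, "duration") <- attr(pop$events, "duration")
  er1 <- suppressMessages(epoch_average(pop))
  er2 <- suppressMessages(epoch_average(pop2))
  ord1 <- order(er1$trials$trial_id)
  ord2 <- order(er2$trials$trial_id)
  expect_equal(er1$dff_epoch[ord1, , ], er2$dff_epoch[ord2, , ],
               tolerance = 1e-12)
})

test_that("generator selectivity targets are realized in measured responses", {
  # sound-epoch AUC lands within +/-0.05 of the 0.9 target at ~200 trials;
  # later epochs are attenuated by the signal-correlated rolling baseline
  tr <- sim_behavior(230, seed = 1,
                     violation_hazard = list(intercept = -6, delay_coef = 0),
                     miss_prob = 0)
  pop <- sim_population(tr, n_rois = 8, epoch_auc = 0.9, seed = 101)
  er <- suppressMessages(epoch_average(pop))
  sel <- permutation_significance(er, "choice", n_shuffles = 200, seed = 11)
  m <- auc_matrix(sel)
  expect_equal(mean(m[, "sound"]), 0.9, tolerance = 0.05)
  expect_true(all(colMeans(m) > 0.75))
  # no-selectivity target stays at chance
  pop0 <- sim_population(tr, n_rois = 8, epoch_auc = 0.5, seed = 102)
  er0 <- suppressMessages(epoch_average(pop0))
  sel0 <- permutation_significance(er0, "choice", n_shuffles = 200, seed = 12)
  expect_equal(mean(auc_matrix(sel0)), 0.5, tolerance = 0.05)
})
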