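# hand-built cell: deterministic EPSPs on chosen pulses, near-zero noise
build_cell <- function(respond_pulses, amplitude = 5, latency_ms = 5,
                       noise_sd = 0.01, sample_rate = 2000,
                       n_single = 10, single_responds = NULL,
                       seed = 1) {
  set.seed(seed)
  baseline_s <- 1.1
  stims <- baseline_s + seq(0, 0.9, by = 0.1)
  n_tr <- round((baseline_s + 1.2) * sample_rate)
  n_si <- round((baseline_s + 0.3) * sample_rate)
  # fast decay keeps each EPSP inside its own 100-ms inter-pulse interval
  kern_t <- seq(0, 0.06, by = 1 / sample_rate)
  kern <- exp(-kern_t / 0.01) - exp(-kern_t / 0.002)
  kern <- kern / max(kern)
  mk <- function(n_samp, stim_list, hit) {
    v <- matrix(rnorm(n_samp, 0, noise_sd), 1, n_samp) - 65
    for (k in seq_along(stim_list)) {
      if (!hit[k]) next
      i0 <- round((stim_list[k] + latency_ms / 1000) * sample_rate) + 1
      idx <- i0:min(i0 + length(kern) - 1, n_samp)
      v[1, idx] <- v[1, idx] + amplitude * kern[seq_along(idx)]
    }
    v
  }
  train <- mk(n_tr, stims, seq_along(stims) %in% respond_pulses)
  if (is.null(single_responds)) single_responds <- rep(TRUE, n_single)
  single <- do.call(rbind, lapply(seq_len(n_single), function(s)
    mk(n_si, baseline_s, single_responds[s])))
  structure(list(cell_id = "cell", cell_type = "excitatory",
                 sample_rate = sample_rate, train = train, single = single,
                 stim_times = list(train = stims, single = baseline_s)),
            class = "slice_cell")
}

test_that("the >40% transient criterion is strict at the boundary", {
  at4 <- build_cell(respond_pulses = 1:4, noise_sd = 0)
  expect_false(classify_responsive(at4)$responsive)
  expect_equal(classify_responsive(at4)$frac_significant, 0.4)
  at5 <- build_cell(respond_pulses = 1:5, noise_sd = 0)
  expect_true(classify_responsive(at5)$responsive)
})

test_that("latency and amplitude are recovered on clean responses", {
  cell <- build_cell(1:10, amplitude = 8, latency_ms = 5, noise_sd = 0.005)
  ch <- characterize_response(cell)
  expect_equal(ch$reliability, 1)
  expect_equal(ch$latency_ms, 5, tolerance = 1000 / cell$sample_rate + 1e-9)
  expect_equal(ch$amplitude_mv, 8, tolerance = 0.5)
})

test_that("flat sweeps give zero reliability and undefined latency", {
  cell <- build_cell(integer(0), single_responds = rep(FALSE, 10),
                     noise_sd = 0)
  ch <- characterize_response(cell)
  expect_equal(ch$reliability, 0)
  expect_true(is.na(ch$latency_ms))
  expect_false(ch$latency_defined)
})

test_that("reliability matches the generating probability", {
  ss <- sim_slice(n_cells = c(excitatory = 10), responsive_frac = 1,
                  reliability = 1, noise_sd = 0.05, amplitude_mv = 8,
                  sample_rate = 2000, seed = 5)
  tab <- slice_cell_table(ss)
  expect_true(all(tab$responsive))
  expect_true(all(tab$reliability == 1))
  ss2 <- sim_slice(n_cells = c(excitatory = 20), responsive_frac = 1,
                   reliability = 0.7, noise_sd = 0.2, amplitude_mv = 8,
                   n_single_sweeps = 20, sample_rate = 2000, seed = 6)
  tab2 <- slice_cell_table(ss2)
  expect_equal(mean(tab2$reliability), 0.7, tolerance = 0.08)
})

test_that("high-SNR cells are classified without error", {
  ss <- sim_slice(n_cells = c(excitatory = 20), responsive_frac = 0.5,
                  amplitude_mv = 5, noise_sd = 0.5,   # 10x noise
                  n_train_sweeps = 20, sample_rate = 2000, seed = 7)
  tab <- slice_cell_table(ss)
  gt <- vapply(ss$cells, function(cc) cc$ground_truth$responsive, logical(1))
  expect_identical(tab$responsive, gt)
})

test_that("noise-only cells are rarely called responsive", {
  ss <- sim_slice(n_cells = c(excitatory = 100), responsive_frac = 0,
                  sample_rate = 2000, seed = 8)
  tab <- slice_cell_table(ss)
  expect_gte(mean(!tab$responsive), 0.97)
})

test_that("significance flags are invariant to voltage rescaling", {
  ss <- sim_slice(n_cells = c(excitatory = 8), responsive_frac = 0.5,
                  sample_rate = 2000, seed = 9)
  flags1 <- slice_cell_table(ss)$responsive
  ss2 <- ss
  ss2$cells <- lapply(ss$cells, function(cc) {
    cc$train <- cc$train * 3 - 2 * (-65)   # scale around rest
    cc$single <- cc$single * 3 - 2 * (-65)
    cc
  })
  flags2 <- slice_cell_table(ss2)$responsive
  expect_identical(flags1, flags2)
})

test_that("latency bias stays below a millisecond at high SNR", {
  ss <- sim_slice(n_cells = c(excitatory = 60), responsive_frac = 1,
                  reliability = 1, jitter_ms = 0, latency_ms = 5,
                  amplitude_mv = 10, noise_sd = 0.1,
                  sample_rate = 10000, seed = 10)
  tab <- slice_cell_table(ss)
  expect_lt(abs(mean(tab$latency_ms) - 5), 1)
})

test_that("group comparison reproduces the responsive-proportion test", {
  # 18/24 excitatory vs 28/44 inhibitory responsive
  mk <- function(n, k, type) data.frame(
    cell_id = sprintf("%s%02d", type, seq_len(n)), cell_type = type,
    responsive = seq_len(n) <= k, frac_significant = 1,
    reliability = ifelse(seq_len(n) <= k, 0.9, NA),
    latency_ms = ifelse(seq_len(n) <= k, 5, NA),
    amplitude_mv = ifelse(seq_len(n) <= k, 6, NA))
  res <- compare_groups(mk(24, 18, "exc"), mk(44, 28, "inh"),
                        n_perm = 200, seed = 1)
  expect_gt(res$chi2_responsive$p_value, 0.05)
  expect_equal(res$chi2_responsive$statistic, 0.916, tolerance = 1e-3)
  # identical metric distributions: p near 1
  expect_gt(res$amplitude_mv$p_value, 0.5)
})

test_that("a 3-sd amplitude shift between groups is detected", {
  set.seed(2)
  hits <- replicate(50, {
    a <- data.frame(cell_id = sprintf("a%d", 1:20), cell_type = "exc",
                    responsive = TRUE, frac_significant = 1,
                    reliability = 0.9, latency_ms = 5,
                    amplitude_mv = rnorm(20, 6, 1))
    b <- a
    b$amplitude_mv <- rnorm(20, 9, 1)     # +3 s.d.
    suppressWarnings(compare_groups(a, b, n_perm = 200))$amplitude_mv$p_value < 0.01
  })
  expect_gte(mean(hits), 0.8)
})

test_that("baseline shorter than 1 s is an error", {
  cell <- build_cell(1:10)
  cell$stim_times$train <- cell$stim_times$train - 0.5
  expect_error(classify_responsive(cell), "baseline")
})
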