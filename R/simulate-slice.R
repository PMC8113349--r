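# Slice recording generator ------------------------------------------------

# EPSP waveform: difference of exponentials, peak normalized to 1
epsp_kernel <- function(sample_rate, tau_rise_ms = 2, tau_decay_ms = 20,
                        length_ms = 120) {
  t <- seq(0, length_ms / 1000, by = 1 / sample_rate)
  h <- exp(-t / (tau_decay_ms / 1000)) - exp(-t / (tau_rise_ms / 1000))
  h / max(h)
}

#' Simulate whole-cell voltage sweeps under optogenetic terminal stimulation
#'
#' Generates membrane-potential sweeps for a set of excitatory and
#' inhibitory cells.  Responsive cells emit EPSP-shaped depolarizations
#' after each light pulse with per-pulse probability `reliability`, onset
#' `latency_ms` (plus Gaussian jitter) after pulse onset; non-responsive
#' cells emit noise only.  Each cell gets train sweeps (ten 5-ms pulses at
#' 10 Hz) and single-pulse sweeps, all with at least 1 s of
#' pre-stimulation baseline.
#'
#' @param n_cells Named vector `c(excitatory =, inhibitory =)`.
#' @param responsive_frac Fraction of responsive cells per type (scalar or
#'   named like `n_cells`).
#' @param latency_ms,jitter_ms EPSP onset latency after pulse onset and
#'   its Gaussian jitter (ms).
#' @param amplitude_mv EPSP peak amplitude (mV).
#' @param reliability Per-pulse response probability in \[0, 1\].
#' @param noise_sd Baseline noise s.d. (mV).  Membrane noise is an AR(1)
#'   process with correlation time `noise_tau_ms` (synaptic background
#'   noise is autocorrelated on the millisecond scale, which is what
#'   makes a threshold crossing within a 50-ms window informative).
#' @param noise_tau_ms Noise correlation time constant (ms).
#' @param sample_rate Sampling rate (Hz), default 10000.
#' @param n_train_sweeps,n_single_sweeps Sweeps per stimulation mode.
#' @param baseline_s Pre-stimulation baseline (s), must be >= 1.
#' @param v_rest Resting potential (mV).
#' @param seed Optional integer seed.
#' @return An object of class `slice_sweep_set`: list of cells, each with
#'   `train` and `single` sweep matrices (sweeps x samples), `stim_times`
#'   per mode (s), `cell_type`, `sample_rate` and per-cell `ground_truth`
#'   (`responsive`, `latency_ms`, `amplitude_mv`, `reliability`).
#' @export
sim_slice <- function(n_cells = c(excitatory = 24, inhibitory = 44),
                      responsive_frac = 0.75,
                      latency_ms = 5, jitter_ms = 0.5,
                      amplitude_mv = 8, reliability = 0.9,
                      noise_sd = 0.5, noise_tau_ms = 5, sample_rate = 10000,
                      n_train_sweeps = 5, n_single_sweeps = 10,
                      baseline_s = 1.2, v_rest = -65,
                      seed = NULL) {
  if (baseline_s < 1) stop("baseline_s must be >= 1 s")
  if (reliability < 0 || reliability > 1) stop("reliability must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (length(responsive_frac) == 1L)
    responsive_frac <- setNames(rep(responsive_frac, length(n_cells)),
                                names(n_cells))

  kern <- epsp_kernel(sample_rate)
  train_stims <- baseline_s + seq(0, by = 0.1, length.out = 10)  # 10 Hz
  single_stims <- baseline_s
  dur_train <- baseline_s + 1.2
  dur_single <- baseline_s + 0.3
  n_tr <- round(dur_train * sample_rate)
  n_si <- round(dur_single * sample_rate)

  phi <- exp(-1000 / (noise_tau_ms * sample_rate))
  make_sweeps <- function(n_sweeps, n_samp, stims, responsive) {
    v <- t(vapply(seq_len(n_sweeps), function(s)
      as.numeric(stats::filter(rnorm(n_samp, 0, noise_sd * sqrt(1 - phi^2)),
                               phi, method = "recursive")),
      numeric(n_samp))) + v_rest
    if (responsive) {
      for (s in seq_len(n_sweeps)) {
        for (st in stims) {
          if (runif(1) < reliability) {
            lat <- (latency_ms + max(rnorm(1, 0, jitter_ms), 0)) / 1000
            i0 <- round((st + lat) * sample_rate) + 1L
            idx <- i0:min(i0 + length(kern) - 1L, n_samp)
            v[s, idx] <- v[s, idx] + amplitude_mv * kern[seq_along(idx)]
          }
        }
      }
    }
    v
  }

  cells <- list()
  for (ct in names(n_cells)) {
    n <- n_cells[[ct]]
    n_resp <- round(responsive_frac[[ct]] * n)
    resp_flags <- sample(c(rep(TRUE, n_resp), rep(FALSE, n - n_resp)))
    for (i in seq_len(n)) {
      cells[[length(cells) + 1L]] <- structure(list(
        cell_id = sprintf("%s_%02d", substr(ct, 1, 3), i),
        cell_type = ct,
        sample_rate = sample_rate,
        train = make_sweeps(n_train_sweeps, n_tr, train_stims, resp_flags[i]),
        single = make_sweeps(n_single_sweeps, n_si, single_stims,
                             resp_flags[i]),
        stim_times = list(train = train_stims, single = single_stims),
        ground_truth = list(responsive = resp_flags[i],
                            latency_ms = latency_ms,
                            amplitude_mv = amplitude_mv,
                            reliability = reliability)),
        class = "slice_cell")
    }
  }
  structure(list(cells = cells, sample_rate = sample_rate),
            class = "slice_sweep_set")
}

#' @exportS3Method base::print
print.slice_sweep_set <- function(x, ...) {
  types <- table(vapply(x$cells, `[[`, "", "cell_type"))
  cat(sprintf("<slice_sweep_set> %d cells (%s) at %g Hz\n",
              length(x$cells),
              paste(sprintf("%s: %d", names(types), types), collapse = ", "),
              x$sample_rate))
  invisible(x)
}
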