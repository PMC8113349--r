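# End-to-end synthetic pipeline ---------------------------------------------

#' Run the full analysis pipeline on synthetic data
#'
#' Generates one synthetic experiment from a single configuration and
#' seed, then runs every analysis stage: behavior (psychometric fit,
#' session metrics), two-photon imaging (drift correction, dF/F, epoch
#' extraction), single-ROI selectivity, population decoding (90/10
#' cross-validation and leave-one-out) with the RT linkage, photometry
#' (motion correction, early/late AUC), and slice-response
#' classification.  All randomness derives from `seed`, so two runs with
#' the same config and seed are bit-identical.
#'
#' @param config A named list of generator settings, or the path to a
#'   YAML file holding one.  Recognized keys (all optional):
#'   `n_trials`, `n_rois`, `epoch_auc`, `psycho`, `rt_model`,
#'   `photometry` (list passed to [sim_photometry()]), `slice` (list
#'   passed to [sim_slice()]), `decode_resamples`.
#' @param seed Integer seed for the entire run.
#' @return A list with elements `behavior`, `selectivity`, `decoding`,
#'   `rt`, `photometry`, `slice` summarizing every stage.
#' @export
run_pipeline <- function(config = list(), seed = 1) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    n_trials = 150, n_rois = 12, epoch_auc = 0.75,
    psycho = default_psychometric(),
    rt_model = list(intercept = 0.597, delay_slope = 0.099, noise_sd = 0.1),
    photometry = list(early_auc = 0.75, late_auc = 0.75),
    slice = list(n_cells = c(excitatory = 6, inhibitory = 6),
                 sample_rate = 2000, noise_sd = 0.4, amplitude_mv = 6),
    decode_resamples = 25), config)

  trials <- sim_behavior(cfg$n_trials, psycho = cfg$psycho,
                         rt_model = cfg$rt_model, seed = seed)
  psy <- fit_psychometric(trials)
  metrics <- session_metrics(trials)

  pop <- sim_population(trials, n_rois = cfg$n_rois,
                        epoch_auc = cfg$epoch_auc, seed = seed + 1)
  er <- suppressMessages(epoch_average(pop))
  sel <- permutation_significance(er, "choice", n_shuffles = 1000,
                                  seed = seed + 2)
  dec <- cv_decode(er, "choice", epochs = "delay",
                   n_resamples = cfg$decode_resamples, seed = seed + 3)
  loo <- loo_decode(er, "choice", seed = seed + 4)
  rt <- rt_link(loo, er$trials)

  ps <- do.call(sim_photometry,
                c(list(trials = trials, seed = seed + 5), cfg$photometry))
  pr <- motion_correct(ps)
  el <- early_late_auc(pr)

  ss <- do.call(sim_slice, c(list(seed = seed + 6), cfg$slice))
  slice_tab <- slice_cell_table(ss)

  list(behavior = list(psychometric = psy, metrics = metrics),
       selectivity = list(fraction_selective = mean(sel$selective),
                          table = sel$table),
       decoding = dec$accuracy,
       rt = rt$pooled,
       photometry = el,
       slice = slice_tab)
}
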