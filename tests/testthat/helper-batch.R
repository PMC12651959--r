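# Batched simulation: replicate-level draws are iid, so one simulator call
# with n_experiments * reps_per_exp replicates, split into consecutive
# triples, is distributionally identical to independent small experiments —
# and much faster than looping the full pipeline.

batch_shifts <- function(n_experiments, reps_per_exp = 3, seed = 1,
                         modes = c("raw", "spikein_normalized"), ...) {
  cfg <- sim_config(n_replicates = n_experiments * reps_per_exp,
                    seed = seed, ...)
  sim <- simulate_experiment(cfg)
  shifts <- quantify_cq(sim$cq, spikein_gene = cfg$spikein_gene,
                        efficiency = cfg$efficiency) |>
    dplyr::filter(mode %in% modes) |>
    percent_signal(window = cfg$window) |>
    weighted_average_fw() |>
    delta_fw(control = cfg$treatments[["control"]],
             treated = cfg$treatments[["treated"]]) |>
    dplyr::mutate(experiment = ceiling(replicate / reps_per_exp))
  truth <- sim$truth$fw |>
    dplyr::mutate(experiment = ceiling(replicate / reps_per_exp))
  list(shifts = shifts, truth = truth, config = cfg)
}

# one paired t-test (arm2 vs arm1) per experiment for one quantification mode
per_experiment_tests <- function(shifts, arms, mode, direction = "greater") {
  md <- mode
  shifts |>
    dplyr::filter(.data$mode == md) |>
    dplyr::select(sample_id, replicate, experiment, delta_fw) |>
    tidyr::pivot_wider(names_from = sample_id, values_from = delta_fw) |>
    dplyr::group_by(experiment) |>
    dplyr::group_split() |>
    purrr::map(function(d) {
      polyspike::tidy(paired_one_tailed_ttest(d[[arms[2]]], d[[arms[1]]],
                                              direction = direction))
    }) |>
    purrr::list_rbind()
}
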