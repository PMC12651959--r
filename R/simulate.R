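#' Simulation configuration for a synthetic polysome-profiling experiment
#'
#' Describes the generative model used by [simulate_experiment()]: per-gene
#' baseline fraction distributions over a sucrose gradient, arm-specific
#' treatment shifts of the window-restricted weighted mean fraction (F_W),
#' per-fraction multiplicative RNA-isolation loss, a constant amount of
#' spike-in RNA added to every fraction, and a Cq readout with a given
#' amplification efficiency and Gaussian cycle noise.
#'
#' @param genes Character vector of target gene names.
#' @param arms Named numeric vector: one experimental arm (sample) per entry,
#'   the value being the arm's true treatment-induced F_W shift in fraction
#'   units. Arms model independently processed samples (e.g. siRNA groups),
#'   each with its own gradient and therefore its own isolation losses.
#' @param baseline Baseline fraction weights: `NULL` (a [bimodal_profile()]
#'   shared by all genes), a single numeric vector, or a list of vectors, one
#'   per gene. Weights must be non-negative with positive mass in `window`.
#' @param n_fractions Number of gradient fractions collected (default 20).
#' @param window Inclusive analysis window of fractions used for percentages
#'   and F_W (default 2–16, covering 40S/60S/80S and polysomes).
#' @param n_replicates Number of paired replicates (default 3).
#' @param loss_sigma Standard deviation of the log-normal per-fraction
#'   RNA-isolation loss factor (log scale, dimensionless; 0 = lossless).
#' @param cq_sigma Standard deviation of Gaussian Cq measurement noise, in
#'   cycles.
#' @param rep_shift_sigma Standard deviation of a per-replicate additive
#'   perturbation of the treatment shift (fraction units), shared by all arms
#'   and genes within a replicate. Models day-to-day variation in the global
#'   stress response — the component of variance that motivates the paired
#'   design. Set to 0 for a fixed shift.
#' @param loss_correlation Correlation (on the log scale) between the loss
#'   factor experienced by target RNA and by the spike-in within the same
#'   fraction. The spike-in method assumes 1 (shared loss); values < 1 let
#'   tests probe violations of that assumption.
#' @param efficiency Amplification efficiency E per PCR cycle (default 2,
#'   i.e. perfect doubling).
#' @param spikein_amount Constant spike-in quantity added per fraction, in
#'   arbitrary units (default 320, the ng of yeast total RNA per fraction).
#' @param cq_anchor Cq assigned to one quantity unit (cycles); sets the
#'   overall Cq scale only.
#' @param spikein_gene Name of the spike-in reference amplicon (default
#'   "RLP24", a yeast gene absent from the target species).
#' @param treatments Named length-2 character vector `c(control = , treated = )`
#'   giving the labels of the two conditions (default DMEM / SOR).
#' @param seed Integer RNG seed; the generator never touches the global RNG
#'   state.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(arms = c(siCTRL = 0.3, siARK5 = 1), seed = 7)
#' cfg
#' @export
sim_config <- function(genes = "BCLX",
                       arms = c(siARK5 = 1),
                       baseline = NULL,
                       n_fractions = 20,
                       window = c(2, 16),
                       n_replicates = 3,
                       loss_sigma = 0.5,
                       cq_sigma = 0.2,
                       rep_shift_sigma = 0.5,
                       loss_correlation = 1,
                       efficiency = 2,
                       spikein_amount = 320,
                       cq_anchor = 30,
                       spikein_gene = "RLP24",
                       treatments = c(control = "DMEM", treated = "SOR"),
                       seed = 1L) {
  stopifnot(is.character(genes), length(genes) >= 1, !anyDuplicated(genes))
  if (is.null(names(arms)) || any(!nzchar(names(arms)))) {
    abort("`arms` must be a named numeric vector (arm label = true shift)")
  }
  stopifnot(is.numeric(arms), !anyDuplicated(names(arms)))
  n_fractions <- as.integer(n_fractions)
  stopifnot(n_fractions >= 2)
  window <- check_window(window, n_fractions)
  n_replicates <- as.integer(n_replicates)
  stopifnot(n_replicates >= 1)
  if (loss_sigma < 0 || cq_sigma < 0 || rep_shift_sigma < 0) {
    abort("`loss_sigma`, `cq_sigma` and `rep_shift_sigma` must be >= 0")
  }
  if (loss_correlation < 0 || loss_correlation > 1) {
    abort("`loss_correlation` must be in [0, 1]")
  }
  if (efficiency <= 1) abort("`efficiency` must be > 1")
  if (spikein_amount <= 0) abort("`spikein_amount` must be > 0")
  if (spikein_gene %in% genes) {
    abort("the spike-in gene must be distinct from every target gene")
  }
  if (length(treatments) != 2 ||
      !setequal(names(treatments), c("control", "treated"))) {
    abort("`treatments` must be c(control = ..., treated = ...)")
  }
  if (treatments[["control"]] == treatments[["treated"]]) {
    abort("control and treated labels must differ")
  }

  if (is.null(baseline)) {
    baseline <- rep(list(bimodal_profile(n_fractions)), length(genes))
  } else if (is.numeric(baseline)) {
    baseline <- rep(list(as.numeric(baseline)), length(genes))
  } else if (is.list(baseline) && length(baseline) == 1) {
    baseline <- rep(baseline, length(genes))
  }
  if (!is.list(baseline) || length(baseline) != length(genes)) {
    abort("`baseline` must be NULL, one weight vector, or one per gene")
  }
  names(baseline) <- genes
  for (g in genes) {
    w <- baseline[[g]]
    if (length(w) != n_fractions || anyNA(w) || any(w < 0)) {
      abort(sprintf(
        "baseline weights for %s must be %d non-negative values", g, n_fractions
      ))
    }
    if (sum(w[window[1]:window[2]]) <= 0) {
      abort(sprintf("baseline weights for %s have no mass in the window", g))
    }
  }

  structure(
    list(
      genes = genes, arms = arms, baseline = baseline,
      n_fractions = n_fractions, window = window,
      n_replicates = n_replicates, loss_sigma = loss_sigma,
      cq_sigma = cq_sigma, rep_shift_sigma = rep_shift_sigma,
      loss_correlation = loss_correlation, efficiency = efficiency,
      spikein_amount = spikein_amount, cq_anchor = cq_anchor,
      spikein_gene = spikein_gene, treatments = treatments,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  genes:      ", paste(x$genes, collapse = ", "), "\n")
  cat("  arms (shift):", paste(sprintf("%s=%.3g", names(x$arms), x$arms),
                               collapse = ", "), "\n")
  cat(sprintf("  fractions:   1..%d, window %d-%d\n",
              x$n_fractions, x$window[1], x$window[2]))
  cat(sprintf("  replicates:  %d; loss_sigma %.3g; cq_sigma %.3g; rep_shift_sigma %.3g\n",
              x$n_replicates, x$loss_sigma, x$cq_sigma, x$rep_shift_sigma))
  cat(sprintf("  efficiency:  %.3g; spike-in %s (%.4g units/fraction); seed %d\n",
              x$efficiency, x$spikein_gene, x$spikein_amount, x$seed))
  invisible(x)
}

#' Simulate a spike-in polysome-profiling RT-qPCR experiment
#'
#' Generates a tidy Cq table together with the ground truth it was generated
#' from. For every arm, condition, replicate and fraction a multiplicative
#' RNA-isolation loss factor `L = exp(N(0, loss_sigma^2))` is drawn; the
#' measured quantity of a target gene is its true fraction weight times `L`,
#' and the spike-in quantity is `spikein_amount` times the same `L` (losses
#' act on the tube, not the transcript — the identifiability assumption that
#' makes spike-in normalization exact). Quantities are read out as
#' `Cq = cq_anchor - log_E(quantity) + N(0, cq_sigma^2)`; structural zero
#' quantities yield a missing Cq (no amplification). Treated-condition
#' profiles are the baseline shifted by the arm's configured delta plus the
#' replicate-level perturbation (see [sim_config()]), realised with
#' [apply_shift()].
#'
#' @param config A [sim_config()] object.
#' @param seed Optional seed overriding `config$seed`.
#'
#' @return An object of class `polysome_sim`: a list with
#' \describe{
#'   \item{cq}{tibble with columns `sample_id`, `treatment`, `replicate`,
#'     `fraction`, `gene`, `cq` — one row per qPCR well, spike-in included.}
#'   \item{truth}{list of tibbles: `distributions` (true weights and window
#'     percentages per gene/arm/condition/replicate/fraction), `fw` (true
#'     F_W per condition and true dF_W per gene/arm/replicate), `losses`
#'     (realised loss factors), `rep_shift` (per-replicate shift
#'     perturbation).}
#'   \item{config}{the configuration used.}
#' }
#' Two calls with identical config and seed return identical objects.
#' @examples
#' sim <- simulate_experiment(sim_config(seed = 42))
#' sim$cq
#' sim$truth$fw
#' @export
simulate_experiment <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- as.integer(seed %||% config$seed)
  # seed locally; leave the caller's RNG stream untouched
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  nf <- config$n_fractions
  reps <- seq_len(config$n_replicates)
  arms <- names(config$arms)
  trt <- config$treatments
  win <- config$window

  # 1. replicate-level shift perturbation (shared across arms and genes)
  b <- if (config$rep_shift_sigma > 0) {
    rnorm(length(reps), 0, config$rep_shift_sigma)
  } else {
    rep(0, length(reps))
  }
  rep_shift <- tibble(replicate = reps, shift_perturbation = b)

  # 2. true weights per gene x arm x condition x replicate
  key <- tidyr::expand_grid(gene = config$genes, sample_id = arms,
                            replicate = reps)
  n_key <- nrow(key)
  weight_blocks <- vapply(seq_len(n_key), function(i) {
    base <- config$baseline[[key$gene[i]]]
    delta <- config$arms[[key$sample_id[i]]] + b[[key$replicate[i]]]
    c(base, apply_shift(base, delta, win))
  }, numeric(2L * nf))
  weights_tbl <- tibble(
    gene = rep(key$gene, each = 2L * nf),
    sample_id = rep(key$sample_id, each = 2L * nf),
    replicate = rep(key$replicate, each = 2L * nf),
    treatment = rep(rep(unname(trt), each = nf), n_key),
    fraction = rep(seq_len(nf), 2L * n_key),
    weight = as.numeric(weight_blocks)
  )

  # 3. per-fraction isolation losses, one tube per arm x condition x replicate
  losses <- tidyr::expand_grid(
    sample_id = arms, treatment = unname(trt), replicate = reps,
    fraction = seq_len(nf)
  )
  z <- rnorm(nrow(losses), 0, config$loss_sigma)
  losses$loss <- exp(z)
  if (config$loss_correlation < 1) {
    z2 <- rnorm(nrow(losses), 0, config$loss_sigma)
    rho <- config$loss_correlation
    losses$loss_spikein <- exp(rho * z + sqrt(1 - rho^2) * z2)
  } else {
    losses$loss_spikein <- losses$loss
  }

  # 4. measured quantities and Cq readout
  targets <- weights_tbl |>
    left_join(losses, by = c("sample_id", "treatment", "replicate", "fraction")) |>
    mutate(quantity = weight * loss)
  spike <- losses |>
    mutate(gene = config$spikein_gene,
           quantity = config$spikein_amount * loss_spikein)
  cq_tbl <- bind_rows(
    targets |> select(sample_id, treatment, replicate, fraction, gene, quantity),
    spike |> select(sample_id, treatment, replicate, fraction, gene, quantity)
  ) |>
    arrange(sample_id, treatment, replicate, fraction, gene) |>
    mutate(
      cq = if_else(quantity > 0,
                   config$cq_anchor - log(quantity) / log(config$efficiency),
                   NA_real_)
    )
  noise <- rnorm(nrow(cq_tbl), 0, config$cq_sigma)
  cq_tbl <- cq_tbl |>
    mutate(cq = cq + noise) |>
    select(-quantity)

  # 5. truth record
  widx <- win[1]:win[2]
  distributions <- weights_tbl |>
    group_by(gene, sample_id, treatment, replicate) |>
    mutate(percent = if_else(fraction %in% widx,
                             100 * weight / sum(weight[fraction %in% widx]),
                             NA_real_)) |>
    ungroup()
  fw_truth <- distributions |>
    filter(fraction %in% widx) |>
    group_by(gene, sample_id, treatment, replicate) |>
    summarise(fw = sum(fraction * percent) / 100, .groups = "drop") |>
    mutate(treatment = if_else(treatment == trt[["control"]],
                               "fw_control", "fw_treated")) |>
    tidyr::pivot_wider(names_from = treatment, values_from = fw) |>
    mutate(delta_fw = fw_treated - fw_control)

  structure(
    list(
      cq = cq_tbl,
      truth = list(distributions = distributions, fw = fw_truth,
                   losses = losses, rep_shift = rep_shift),
      config = config
    ),
    class = "polysome_sim"
  )
}

#' @export
print.polysome_sim <- function(x, ...) {
  cat("<polysome_sim>\n")
  print(x$config)
  cat(sprintf("  cq table:    %d wells (%d missing Cq)\n",
              nrow(x$cq), sum(is.na(x$cq$cq))))
  cat("  truth:       $distributions, $fw, $losses, $rep_shift\n")
  invisible(x)
}
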