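req_cols <- function(data, cols, fn) {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("%s: missing required column(s): %s",
                  fn, paste(missing, collapse = ", ")))
  }
}

profile_key <- c("sample_id", "treatment", "replicate", "gene")

#' Efficiency-based relative quantity from quantification cycles
#'
#' Converts Cq values to relative quantities (the per-fraction RQ, the
#' "relative quantity" readout of qPCR software) within each amplification
#' profile — one gene measured across the fractions of one
#' sample/treatment/replicate. The calibrator is the fraction with the lowest
#' Cq in the profile, so `RQ_i = E^(Cq_min - Cq_i)` and the maximum RQ is 1.
#' The calibrator choice is a global scale only: the downstream percentage
#' step removes it, so F_W does not depend on it. Missing (undetermined) Cq
#' values propagate as missing RQ.
#'
#' @param data Tidy Cq table with columns `sample_id`, `treatment`,
#'   `replicate`, `fraction`, `gene`, `cq`.
#' @param efficiency Amplification efficiency E (> 1): a single value, or a
#'   named vector keyed by gene for per-gene efficiencies.
#'
#' @return The input tibble with an `rq` column added.
#' @examples
#' cq <- tibble::tibble(
#'   sample_id = "s", treatment = "DMEM", replicate = 1L,
#'   fraction = 1:3, gene = "BCLX", cq = c(20, 21, 22)
#' )
#' relative_quantity(cq)$rq  # 1, 0.5, 0.25
#' @export
relative_quantity <- function(data, efficiency = 2) {
  req_cols(data, c(profile_key, "fraction", "cq"), "relative_quantity")
  if (!is.numeric(efficiency) || any(efficiency <= 1)) {
    abort("`efficiency` must be numeric and > 1")
  }
  if (any(!is.na(data$cq) & data$cq <= 0)) {
    abort("Cq values must be positive where present")
  }
  if (anyDuplicated(data[c(profile_key, "fraction")])) {
    abort("duplicate (sample_id, treatment, replicate, fraction, gene) keys")
  }
  eff_of <- function(gene) {
    if (is.null(names(efficiency))) return(efficiency[[1]])
    e <- efficiency[gene]
    if (anyNA(e)) {
      abort(sprintf("no efficiency given for gene(s): %s",
                    paste(unique(gene[is.na(e)]), collapse = ", ")))
    }
    unname(e)
  }
  out <- data |>
    group_by(across(all_of(profile_key))) |>
    mutate(rq = {
      if (all(is.na(cq))) {
        abort(sprintf(
          "all Cq missing for gene %s in sample %s/%s replicate %s",
          gene[1], sample_id[1], treatment[1], replicate[1]
        ))
      }
      eff_of(gene[1])^(min(cq, na.rm = TRUE) - cq)
    }) |>
    ungroup()
  as_tibble(out)
}

#' Normalize target relative quantities to the spike-in reference
#'
#' Divides each target gene's per-fraction relative quantity by the spike-in
#' reference gene's relative quantity in the same fraction of the same
#' sample/treatment/replicate (the normalized relative quantity of the
#' delta-delta-Cq method). Because the spike-in was added in equal amount to
#' every fraction before RNA isolation, any per-fraction loss multiplies the
#' target and the spike-in alike and cancels in the ratio.
#'
#' @param data Output of [relative_quantity()] containing both target genes
#'   and the spike-in gene.
#' @param spikein_gene Name of the spike-in reference gene (default "RLP24").
#'
#' @return Tibble of the target-gene rows with an `nrq` column added
#'   (`rq / rq_spikein`); missing target RQ propagates.
#' @export
normalize_to_spikein <- function(data, spikein_gene = "RLP24") {
  req_cols(data, c(profile_key, "fraction", "rq"), "normalize_to_spikein")
  spike <- data |> filter(gene == spikein_gene)
  if (nrow(spike) == 0) {
    abort(sprintf("spike-in gene '%s' not found in the data", spikein_gene))
  }
  targets <- data |> filter(gene != spikein_gene)
  if (nrow(targets) == 0) abort("no target genes besides the spike-in")
  out <- targets |>
    left_join(
      spike |>
        select(sample_id, treatment, replicate, fraction, rq_spikein = rq),
      by = c("sample_id", "treatment", "replicate", "fraction")
    )
  bad <- out |>
    filter(!is.na(rq) & (is.na(rq_spikein) | rq_spikein <= 0))
  if (nrow(bad) > 0) {
    abort(sprintf(
      "spike-in RQ missing or zero where the target is measured (fraction%s %s)",
      if (nrow(bad) > 1) "s" else "",
      paste(sort(unique(bad$fraction)), collapse = ", ")
    ))
  }
  out |>
    mutate(nrq = rq / rq_spikein) |>
    select(-rq_spikein)
}

#' Cq table to raw and spike-in normalized quantities in one step
#'
#' Convenience wrapper: [relative_quantity()] then [normalize_to_spikein()],
#' returning the two quantification modes side by side in long format, ready
#' for [percent_signal()].
#'
#' @inheritParams relative_quantity
#' @inheritParams normalize_to_spikein
#'
#' @return Long tibble with columns `sample_id`, `treatment`, `replicate`,
#'   `gene`, `fraction`, `mode` (`"raw"` or `"spikein_normalized"`) and
#'   `quantity`. Only target genes are returned.
#' @examples
#' sim <- simulate_experiment(sim_config(seed = 1))
#' quant <- quantify_cq(sim$cq)
#' head(quant)
#' @export
quantify_cq <- function(data, spikein_gene = "RLP24", efficiency = 2) {
  data |>
    relative_quantity(efficiency = efficiency) |>
    normalize_to_spikein(spikein_gene = spikein_gene) |>
    select(sample_id, treatment, replicate, gene, fraction,
           raw = rq, spikein_normalized = nrq) |>
    tidyr::pivot_longer(c("raw", "spikein_normalized"),
                        names_to = "mode", values_to = "quantity")
}
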