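quant_value_col <- function(data, values) {
  if (!is.null(values)) {
    req_cols(data, values, "percent_signal")
    return(values)
  }
  for (v in c("quantity", "nrq", "rq")) if (v %in% names(data)) return(v)
  abort("no quantity column found (expected one of quantity, nrq, rq)")
}

metric_groups <- function(data) {
  intersect(c("sample_id", "treatment", "replicate", "gene", "mode"),
            names(data))
}

#' Percentage RNA signal across an analysis window of fractions
#'
#' Expresses each profile's per-fraction quantity as a percentage of the total
#' signal over the analysis window, so distributions are comparable between
#' samples regardless of absolute yield. Fractions outside the window are
#' dropped; missing fractions are excluded from the total (renormalization
#' over the observed window fractions, so the reported percentages always sum
#' to 100).
#'
#' @param data Quantity table, e.g. from [quantify_cq()]; grouped per
#'   profile by whichever of `sample_id`, `treatment`, `replicate`, `gene`,
#'   `mode` are present.
#' @param window Inclusive fraction window, default 2–16 (40S, 60S, 80S and
#'   polysome region of a 20-fraction gradient).
#' @param fractions Optional subset of fraction numbers to keep within the
#'   window (e.g. `seq(2, 16, by = 2)` when only even fractions were assayed).
#' @param values Name of the quantity column; by default the first of
#'   `quantity`, `nrq`, `rq` found.
#'
#' @return Tibble with the grouping columns, `fraction` and `percent`.
#' @examples
#' tbl <- tibble::tibble(
#'   sample_id = "s", treatment = "DMEM", replicate = 1L, gene = "g",
#'   fraction = 2:4, quantity = c(2, 3, 5)
#' )
#' percent_signal(tbl, window = c(2, 4))$percent  # 20, 30, 50
#' @export
percent_signal <- function(data, window = c(2, 16), fractions = NULL,
                           values = NULL) {
  req_cols(data, "fraction", "percent_signal")
  window <- check_window(window, max(c(window[2], data$fraction), na.rm = TRUE))
  vcol <- quant_value_col(data, values)
  keep <- data$fraction >= window[1] & data$fraction <= window[2]
  if (!is.null(fractions)) keep <- keep & data$fraction %in% fractions
  grp <- metric_groups(data)
  windowed <- data[keep, , drop = FALSE]
  out <- windowed[!is.na(windowed[[vcol]]), , drop = FALSE]
  if (nrow(out) == 0) abort("no observed fractions inside the window")
  lost <- anti_join(distinct(windowed[grp]), distinct(out[grp]), by = grp)
  if (nrow(lost) > 0) {
    abort(sprintf("%d profile(s) have no observed fraction in the window",
                  nrow(lost)))
  }
  out <- out |>
    group_by(across(all_of(grp))) |>
    mutate(percent = {
      tot <- sum(.data[[vcol]])
      if (tot <= 0) {
        abort(sprintf("profile %s has no positive signal in the window",
                      paste(unlist(cur_group()), collapse = "/")))
      }
      100 * .data[[vcol]] / tot
    }) |>
    ungroup()
  as_tibble(out[c(grp, "fraction", "percent")])
}

#' Signal-weighted mean fraction number of a percentage distribution
#'
#' The scalar kernel of the shift statistic: `fw_stat()` computes
#' `F_W = sum(f_i * p_i) / 100` for one distribution, where `f_i` is the
#' integer fraction number and `p_i` the percentage of signal in fraction
#' `i`. Larger F_W means signal concentrated in heavier, more ribosome-loaded
#' fractions, i.e. higher translational engagement.
#'
#' @param fractions Integer fraction numbers.
#' @param percent Percentages summing to 100 over `fractions`.
#' @return The weighted mean fraction number (a value between
#'   `min(fractions)` and `max(fractions)`).
#' @examples
#' fw_stat(2:16, rep(100 / 15, 15))  # 9
#' @export
fw_stat <- function(fractions, percent) {
  stopifnot(length(fractions) == length(percent), !anyNA(fractions),
            !anyNA(percent))
  if (any(percent < 0)) abort("percentages must be non-negative")
  if (abs(sum(percent) - 100) > 1e-6) {
    abort("percentages must sum to 100")
  }
  sum(fractions * percent) / 100
}

#' Weighted-average F_W per profile
#'
#' Applies [fw_stat()] to every percentage distribution in a table produced
#' by [percent_signal()].
#'
#' @param data Output of [percent_signal()] (columns `fraction`, `percent`
#'   plus grouping columns).
#' @return Tibble with one row per profile and an `fw` column.
#' @export
weighted_average_fw <- function(data) {
  req_cols(data, c("fraction", "percent"), "weighted_average_fw")
  grp <- metric_groups(data)
  data |>
    group_by(across(all_of(grp))) |>
    summarise(fw = fw_stat(fraction, percent), .groups = "drop")
}

#' Translational shift dF_W between treated and control conditions
#'
#' Pairs the F_W of the treated condition with the control condition within
#' each gene, sample and replicate (and mode, if present) and returns the
#' shift `dF_W = F_W(treated) - F_W(control)`. Positive values indicate a
#' shift of the transcript toward heavier polysomes under treatment.
#'
#' @param data Output of [weighted_average_fw()].
#' @param control,treated Treatment labels of the two conditions.
#' @return Tibble with columns `fw_control`, `fw_treated`, `delta_fw` per
#'   gene/sample/replicate (/mode).
#' @export
delta_fw <- function(data, control = "DMEM", treated = "SOR") {
  req_cols(data, c("treatment", "fw"), "delta_fw")
  lv <- unique(data$treatment)
  if (!all(c(control, treated) %in% lv)) {
    abort(sprintf("treatments '%s' and '%s' not both present (found: %s)",
                  control, treated, paste(lv, collapse = ", ")))
  }
  out <- data |>
    filter(treatment %in% c(control, treated)) |>
    mutate(treatment = if_else(treatment == control,
                               "fw_control", "fw_treated")) |>
    tidyr::pivot_wider(names_from = treatment, values_from = fw)
  if (anyNA(out$fw_control) || anyNA(out$fw_treated)) {
    miss <- out |> filter(is.na(fw_control) | is.na(fw_treated))
    abort(sprintf(
      "unmatched control/treated pairs for %d profile(s), e.g. %s replicate %s",
      nrow(miss), miss$sample_id[1], miss$replicate[1]
    ))
  }
  out |> mutate(delta_fw = fw_treated - fw_control)
}

#' Per-fraction RNA-recovery report from spike-in measurements
#'
#' Since the same spike-in amount was added to every fraction, variation of
#' the spike-in relative quantity across fractions of one sample directly
#' measures unevenness of RNA isolation. The report gives, per sample, the
#' coefficient of variation of spike-in RQ across fractions, and flags
#' fractions whose RQ deviates from the within-sample median by more than a
#' fold threshold.
#'
#' @param data Output of [relative_quantity()] containing the spike-in gene.
#' @param spikein_gene Spike-in reference gene name (default "RLP24").
#' @param fold_threshold Flag fractions deviating from the sample median by
#'   more than this factor in either direction (default 2).
#'
#' @return Tibble with one row per sample and fraction: `rq`, the
#'   within-sample `median_rq` and `cv`, the `fold_change` versus the median
#'   (always >= 1), and a `flagged` indicator.
#' @export
fraction_recovery_report <- function(data, spikein_gene = "RLP24",
                                     fold_threshold = 2) {
  req_cols(data, c(profile_key, "fraction", "rq"), "fraction_recovery_report")
  stopifnot(fold_threshold >= 1)
  spike <- data |> filter(gene == spikein_gene, !is.na(rq))
  if (nrow(spike) == 0) {
    abort(sprintf("no spike-in ('%s') measurements found", spikein_gene))
  }
  spike |>
    group_by(sample_id, treatment, replicate) |>
    mutate(
      median_rq = median(rq),
      cv = sd(rq) / mean(rq),
      fold_change = pmax(rq / median_rq, median_rq / rq),
      flagged = fold_change > fold_threshold
    ) |>
    ungroup() |>
    select(sample_id, treatment, replicate, fraction, rq, median_rq, cv,
           fold_change, flagged)
}
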