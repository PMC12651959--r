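cq_cols <- c("sample_id", "treatment", "replicate", "fraction", "gene", "cq")

#' Read a tidy Cq table from CSV
#'
#' Reads the canonical interchange format: one row per qPCR well with columns
#' `sample_id`, `treatment`, `replicate`, `fraction`, `gene`, `cq`. Vendor
#' exports with other column names can be mapped with `col_map`.
#' Non-numeric Cq entries (e.g. "Undetermined") are carried as missing, with
#' a message reporting how many; duplicate well keys are an error.
#'
#' @param path CSV file path.
#' @param col_map Optional named character vector mapping canonical names to
#'   the file's column names, e.g.
#'   `c(sample_id = "Sample", gene = "Target", cq = "Cq")`. Unmapped
#'   canonical names are looked up directly.
#' @param n_fractions If given, fraction numbers are validated against
#'   `1..n_fractions`.
#'
#' @return A validated tibble with the canonical columns.
#' @export
read_cq_table <- function(path, col_map = NULL, n_fractions = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0) abort("empty Cq table")
  if (!is.null(col_map)) {
    bad <- setdiff(unname(col_map), names(raw))
    if (length(bad)) {
      abort(sprintf("mapped column(s) not in file: %s",
                    paste(bad, collapse = ", ")))
    }
    raw <- rename(raw, !!!setNames(unname(col_map), names(col_map)))
  }
  req_cols(raw, cq_cols, "read_cq_table")
  cq_num <- suppressWarnings(as.numeric(raw$cq))
  unparseable <- sum(is.na(cq_num) & !is.na(raw$cq) & nzchar(trimws(raw$cq)))
  if (unparseable > 0) {
    inform(sprintf("%d Cq value(s) were not numeric and are carried as missing",
                   unparseable))
  }
  out <- tibble(
    sample_id = as.character(raw$sample_id),
    treatment = as.character(raw$treatment),
    replicate = as.integer(raw$replicate),
    fraction = as.integer(raw$fraction),
    gene = as.character(raw$gene),
    cq = cq_num
  )
  if (anyNA(out$fraction) || any(out$fraction < 1)) {
    abort("`fraction` must be a positive integer")
  }
  if (!is.null(n_fractions) && any(out$fraction > n_fractions)) {
    abort(sprintf("fraction numbers exceed n_fractions = %d", n_fractions))
  }
  if (any(!is.na(out$cq) & out$cq <= 0)) abort("Cq values must be positive")
  dup <- duplicated(out[c("sample_id", "treatment", "replicate", "fraction",
                          "gene")])
  if (any(dup)) {
    k <- out[dup, ][1, ]
    abort(sprintf("duplicate well key(s), e.g. %s/%s r%d fraction %d gene %s",
                  k$sample_id, k$treatment, k$replicate, k$fraction, k$gene))
  }
  out
}

#' Write a Cq table to CSV
#'
#' @param data Cq tibble with the canonical columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(data, path) {
  req_cols(data, cq_cols, "write_cq_table")
  readr::write_csv(data[cq_cols], path)
  invisible(path)
}

#' Run the full spike-in normalization pipeline
#'
#' Chains quantification (raw and spike-in normalized), percentage
#' distributions, F_W, per-replicate dF_W and — when two arms are present —
#' the mode comparison, from either a measured Cq table or a simulation
#' configuration. With an `out_prefix`, all intermediate tables are written
#' as CSV together with a JSON manifest of the parameters, so the same
#' config and seed reproduce byte-identical outputs.
#'
#' @param x A tidy Cq tibble, a path to a Cq CSV, or a [sim_config()] (in
#'   which case the data is simulated first and the truth is attached).
#' @param spikein_gene Spike-in reference gene name.
#' @param efficiency Amplification efficiency (scalar or named per gene).
#' @param window Analysis window of fractions.
#' @param fractions Optional fraction subset within the window.
#' @param control,treated Treatment labels.
#' @param arms Optional `c(reference, test)` arm pair for the comparison.
#'   For a simulated config the default is the declaration order of
#'   `config$arms` (first arm = reference); otherwise the two arms present,
#'   alphabetically (state `arms` explicitly for real data).
#' @param direction Tail of the paired test.
#' @param out_prefix Optional path prefix for CSV/JSON outputs.
#' @param seed Seed forwarded to [simulate_experiment()] when `x` is a
#'   config.
#'
#' @return Object of class `polysome_pipeline`: list with `cq`, `quant`,
#'   `percent`, `fw`, `shifts`, `recovery`, `comparison` (NULL for a single
#'   arm), `truth` (simulations only) and `manifest`.
#' @examples
#' res <- run_pipeline(sim_config(arms = c(siCTRL = 0.3, siARK5 = 1), seed = 2))
#' res$comparison
#' @export
run_pipeline <- function(x,
                         spikein_gene = "RLP24",
                         efficiency = 2,
                         window = c(2, 16),
                         fractions = NULL,
                         control = "DMEM",
                         treated = "SOR",
                         arms = NULL,
                         direction = "greater",
                         out_prefix = NULL,
                         seed = NULL) {
  truth <- NULL
  source_kind <- "table"
  if (inherits(x, "sim_config")) {
    sim <- simulate_experiment(x, seed = seed)
    cq_tbl <- sim$cq
    truth <- sim$truth
    spikein_gene <- x$spikein_gene
    efficiency <- x$efficiency
    window <- x$window
    control <- x$treatments[["control"]]
    treated <- x$treatments[["treated"]]
    seed <- seed %||% x$seed
    source_kind <- "simulation"
    # arms in declaration order: first arm is the reference
    if (is.null(arms) && length(x$arms) == 2) arms <- names(x$arms)
  } else if (is.character(x) && length(x) == 1) {
    cq_tbl <- read_cq_table(x)
    source_kind <- x
  } else {
    cq_tbl <- as_tibble(x)
    req_cols(cq_tbl, cq_cols, "run_pipeline")
  }

  rq <- relative_quantity(cq_tbl, efficiency = efficiency)
  quant <- rq |>
    normalize_to_spikein(spikein_gene = spikein_gene) |>
    select(sample_id, treatment, replicate, gene, fraction,
           raw = rq, spikein_normalized = nrq) |>
    tidyr::pivot_longer(c("raw", "spikein_normalized"),
                        names_to = "mode", values_to = "quantity")
  pct <- percent_signal(quant, window = window, fractions = fractions)
  fw_tbl <- weighted_average_fw(pct)
  shifts <- delta_fw(fw_tbl, control = control, treated = treated)
  recovery <- fraction_recovery_report(rq, spikein_gene = spikein_gene)
  n_arms <- length(unique(shifts$sample_id))
  comparison <- if (n_arms >= 2) {
    compare_normalization_modes(shifts, arms = arms, direction = direction)
  } else {
    NULL
  }

  manifest <- list(
    package = "polyspike",
    version = as.character(packageVersion("polyspike")),
    source = source_kind,
    spikein_gene = spikein_gene,
    efficiency = efficiency,
    window = window,
    fractions = fractions,
    control = control, treated = treated,
    direction = direction,
    seed = seed
  )

  out <- structure(
    list(cq = cq_tbl, quant = quant, percent = pct, fw = fw_tbl,
         shifts = shifts, recovery = recovery, comparison = comparison,
         truth = truth, manifest = manifest),
    class = "polysome_pipeline"
  )

  if (!is.null(out_prefix)) {
    dir.create(dirname(out_prefix), showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(cq_tbl, paste0(out_prefix, "_cq.csv"))
    readr::write_csv(quant, paste0(out_prefix, "_quantities.csv"))
    readr::write_csv(pct, paste0(out_prefix, "_percent.csv"))
    readr::write_csv(fw_tbl, paste0(out_prefix, "_fw.csv"))
    readr::write_csv(shifts, paste0(out_prefix, "_shifts.csv"))
    readr::write_csv(recovery, paste0(out_prefix, "_recovery.csv"))
    if (!is.null(comparison)) {
      readr::write_csv(comparison, paste0(out_prefix, "_comparison.csv"))
    }
    jsonlite::write_json(manifest, paste0(out_prefix, "_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' @export
print.polysome_pipeline <- function(x, ...) {
  cat("<polysome_pipeline>\n")
  cat(sprintf("  source:    %s\n", x$manifest$source))
  cat(sprintf("  wells:     %d; window %d-%d\n", nrow(x$cq),
              x$manifest$window[1], x$manifest$window[2]))
  cat(sprintf("  genes:     %s; arms: %s\n",
              paste(unique(x$shifts$gene), collapse = ", "),
              paste(unique(x$shifts$sample_id), collapse = ", ")))
  if (!is.null(x$comparison)) {
    cat("  mode comparison:\n")
    print(x$comparison |>
            select(gene, mode, t_statistic, p_one_tailed, pairing_r,
                   more_discernible))
  } else {
    cat("  single arm: no between-arm comparison\n")
  }
  invisible(x)
}
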