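#' Pairing-effectiveness correlation of a paired design
#'
#' Pearson correlation between the two arms of a paired comparison, with a
#' one-tailed p-value for positive association from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom. A
#' correlation near 1 means the replicate-level pairing captures most of the
#' between-replicate variation, i.e. the paired test is working as intended.
#' At `|r| = 1` the statistic is unbounded and the p-value is reported as its
#' limit, 0.
#'
#' @param x,y Paired numeric vectors (same replicate order), `n >= 3`.
#' @return One-row tibble with `pairing_r`, `df` and `p_one_tailed`.
#' @examples
#' pairing_correlation(c(1, 2, 3), c(2, 4, 6))
#' @export
pairing_correlation <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (anyNA(x) || anyNA(y)) abort("paired values must not be missing")
  n <- length(x)
  if (n < 3) abort("pairing correlation needs at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("pairing correlation undefined: zero variance in one arm")
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- if (r > 0) 0 else 1
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- pt(t, df = n - 2, lower.tail = FALSE)
  }
  tibble(pairing_r = r, df = n - 2L, p_one_tailed = p)
}

#' One-tailed paired Student's t-test
#'
#' Tests whether the paired differences `d = x - y` are directionally shifted
#' from zero: `t = mean(d) / (sd(d) / sqrt(n))` with the sample standard
#' deviation (`n - 1` denominator), referred to the Student t distribution on
#' `n - 1` degrees of freedom, one tail. When every difference is identical
#' (zero variance) the p-value is reported as 0 for a nonzero mean (with a
#' degeneracy warning) and 0.5 for an all-zero difference. The pairing
#' diagnostic of [pairing_correlation()] is attached when computable.
#'
#' @param x,y Paired numeric vectors of equal length `n >= 2`.
#' @param direction `"greater"` tests H1: mean(x - y) > 0, `"less"` the
#'   opposite tail. There is no default-by-convention: state the hypothesized
#'   direction explicitly in analyses.
#' @param labels Length-2 character labels for the two arms, for printing.
#'
#' @return Object of class `paired_comparison`; see [tidy.paired_comparison()]
#'   for the rectangular form.
#' @examples
#' fit <- paired_one_tailed_ttest(c(1.5, 1.6, 1.7), c(1, 1, 1))
#' tidy(fit)
#' @export
paired_one_tailed_ttest <- function(x, y, direction = c("greater", "less"),
                                    labels = c("x", "y")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (anyNA(x) || anyNA(y)) abort("paired values must not be missing")
  n <- length(x)
  if (n < 2) abort("paired t-test needs at least 2 pairs")
  d <- x - y
  m <- mean(d)
  s <- sd(d)
  degenerate <- s == 0
  if (degenerate) {
    if (m == 0) {
      t_stat <- 0
      p <- 0.5
    } else {
      t_stat <- sign(m) * Inf
      p <- if ((direction == "greater") == (m > 0)) 0 else 1
      warn("paired differences have zero variance with nonzero mean; p reported as a limit")
    }
  } else {
    t_stat <- m / (s / sqrt(n))
    p <- pt(t_stat, df = n - 1,
            lower.tail = (direction == "less"))
  }
  pairing <- if (n >= 3 && sd(x) > 0 && sd(y) > 0) {
    pairing_correlation(x, y)
  } else {
    tibble(pairing_r = NA_real_, df = NA_integer_, p_one_tailed = NA_real_)
  }
  structure(
    list(
      labels = labels, x = x, y = y, n = n,
      mean_difference = m, sd_difference = s,
      t_statistic = t_stat, df = n - 1L, p_one_tailed = p,
      direction = direction, degenerate = degenerate,
      pairing_r = pairing$pairing_r[1],
      pairing_p_one_tailed = pairing$p_one_tailed[1]
    ),
    class = "paired_comparison"
  )
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("One-tailed paired t-test: %s %s %s\n",
              x$labels[1], if (x$direction == "greater") ">" else "<",
              x$labels[2]))
  cat(sprintf("  n = %d pairs, mean difference = %.4g\n",
              x$n, x$mean_difference))
  cat(sprintf("  t = %.4g on %d df, one-tailed p = %.4g%s\n",
              x$t_statistic, x$df, x$p_one_tailed,
              if (x$degenerate) " (degenerate variance)" else ""))
  if (!is.na(x$pairing_r)) {
    cat(sprintf("  pairing r = %.4g (one-tailed p = %.4g)\n",
                x$pairing_r, x$pairing_p_one_tailed))
  }
  invisible(x)
}

#' Tidy a paired comparison
#'
#' @param x A `paired_comparison` object.
#' @param ... Unused.
#' @return One-row tibble with the test and pairing statistics.
#' @method tidy paired_comparison
#' @export
tidy.paired_comparison <- function(x, ...) {
  tibble(
    n_pairs = x$n,
    mean_difference = x$mean_difference,
    t_statistic = x$t_statistic,
    df = x$df,
    p_one_tailed = x$p_one_tailed,
    pairing_r = x$pairing_r,
    pairing_p_one_tailed = x$pairing_p_one_tailed,
    direction = x$direction,
    degenerate = x$degenerate
  )
}

#' @rdname tidy.paired_comparison
#' @method glance paired_comparison
#' @export
glance.paired_comparison <- function(x, ...) tidy(x)

#' Compare translational-shift inference with and without spike-in
#' normalization
#'
#' For each gene and quantification mode, runs the one-tailed paired t-test
#' of dF_W between two experimental arms (replicate-matched) together with
#' the pairing-effectiveness correlation, and reports the two modes side by
#' side. The question it answers is the method-validation one: does spike-in
#' normalization give a more statistically discernible outcome (lower
#' p-value) than raw percentages for the same underlying data?
#'
#' @param shifts Output of [delta_fw()] with a `mode` column covering both
#'   quantification modes and a `sample_id` column naming the arms.
#' @param arms Length-2 character vector `c(reference_arm, test_arm)`; the
#'   hypothesis is that the test arm's dF_W is `direction` than the
#'   reference arm's. Defaults to the two arms present (alphabetical:
#'   reference first) when exactly two exist.
#' @param direction Tail of the test, as in [paired_one_tailed_ttest()].
#'
#' @return Tibble with one row per gene and mode: test statistics, pairing
#'   diagnostics, `more_discernible` (this mode has the strictly lower
#'   p-value within the gene) and `tie`.
#' @export
compare_normalization_modes <- function(shifts, arms = NULL,
                                        direction = c("greater", "less")) {
  direction <- match.arg(direction)
  req_cols(shifts, c("gene", "sample_id", "replicate", "mode", "delta_fw"),
           "compare_normalization_modes")
  found <- sort(unique(shifts$sample_id))
  if (is.null(arms)) {
    if (length(found) != 2) {
      abort(sprintf("`arms` must be given when the data has %d arm(s)",
                    length(found)))
    }
    arms <- found
  }
  stopifnot(length(arms) == 2)
  if (!all(arms %in% found)) {
    abort(sprintf("arm(s) not present in the data: %s",
                  paste(setdiff(arms, found), collapse = ", ")))
  }
  keyed <- shifts |> filter(sample_id %in% arms)
  by_gm <- keyed |>
    group_by(gene, mode) |>
    group_split()
  rows <- purrr::map(by_gm, function(df) {
    wide <- df |>
      select(gene, mode, sample_id, replicate, delta_fw) |>
      tidyr::pivot_wider(names_from = sample_id, values_from = delta_fw) |>
      arrange(replicate)
    if (anyNA(wide[[arms[1]]]) || anyNA(wide[[arms[2]]])) {
      miss <- wide$replicate[is.na(wide[[arms[1]]]) | is.na(wide[[arms[2]]])]
      abort(sprintf("replicate(s) %s missing in one arm for gene %s (%s)",
                    paste(miss, collapse = ", "), df$gene[1], df$mode[1]))
    }
    fit <- paired_one_tailed_ttest(wide[[arms[2]]], wide[[arms[1]]],
                                   direction = direction,
                                   labels = c(arms[2], arms[1]))
    g <- df$gene[1]
    md <- df$mode[1]
    tidy(fit) |>
      mutate(gene = g, mode = md, .before = 1)
  }) |>
    purrr::list_rbind()
  rows |>
    group_by(gene) |>
    mutate(
      tie = length(unique(p_one_tailed)) == 1,
      more_discernible = !tie & p_one_tailed == min(p_one_tailed)
    ) |>
    ungroup()
}
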