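test_that("the paired t-test matches its closed forms", {
  # identical arms: symmetric null
  fit <- paired_one_tailed_ttest(c(1, 2, 3), c(1, 2, 3) - 0)
  expect_equal(fit$t_statistic, 0)
  expect_equal(fit$p_one_tailed, 0.5)

  # d = (0.5, 0.6, 0.7): t = 10.392..., df = 2; with df = 2 the t CDF has the
  # closed form F(t) = 1/2 + t / (2 * sqrt(2 + t^2))
  fit <- paired_one_tailed_ttest(c(1.5, 2.6, 3.7), c(1, 2, 3))
  t_expect <- 0.6 / (0.1 / sqrt(3))
  expect_equal(fit$t_statistic, t_expect, tolerance = 1e-12)
  expect_equal(fit$df, 2L)
  p_closed <- 0.5 - t_expect / (2 * sqrt(2 + t_expect^2))
  expect_equal(fit$p_one_tailed, p_closed, tolerance = 1e-6)
  expect_equal(fit$p_one_tailed, 0.004566, tolerance = 1e-4)
})

test_that("the paired t-test agrees with stats::t.test on random data", {
  set.seed(406)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    x <- rnorm(n); y <- rnorm(n)
    for (dir in c("greater", "less")) {
      fit <- paired_one_tailed_ttest(x, y, direction = dir)
      ref <- stats::t.test(x, y, paired = TRUE, alternative = dir)
      expect_equal(fit$t_statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(fit$p_one_tailed, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("the paired t-test is shift invariant and antisymmetric under arm swap", {
  set.seed(407)
  x <- rnorm(5); y <- rnorm(5)
  a <- paired_one_tailed_ttest(x, y, "greater")
  b <- paired_one_tailed_ttest(x + 2.5, y + 2.5, "greater")
  expect_equal(a$p_one_tailed, b$p_one_tailed, tolerance = 1e-12)
  swapped <- paired_one_tailed_ttest(y, x, "less")
  expect_equal(a$t_statistic, -swapped$t_statistic)
  expect_equal(a$p_one_tailed, swapped$p_one_tailed, tolerance = 1e-12)
})

test_that("degenerate differences are reported with a warning and limiting p", {
  expect_warning(fit <- paired_one_tailed_ttest(c(2, 3, 4), c(1, 2, 3)),
                 "zero variance")
  expect_true(fit$degenerate)
  expect_equal(fit$p_one_tailed, 0)
  expect_error(paired_one_tailed_ttest(1, 2), "at least 2")
})

test_that("pairing correlation matches the direct formula and its limits", {
  pc <- pairing_correlation(c(1, 2, 3), c(2, 4, 6))
  expect_equal(pc$pairing_r, 1)
  expect_equal(pc$p_one_tailed, 0)

  x <- c(1, 2, 4); y <- c(2, 3, 9)
  pc <- pairing_correlation(x, y)
  r <- oracle_pearson(x, y)
  expect_equal(pc$pairing_r, r, tolerance = 1e-12)
  t <- r * sqrt((3 - 2) / (1 - r^2))
  expect_equal(pc$p_one_tailed, pt(t, 1, lower.tail = FALSE), tolerance = 1e-12)
  ref <- stats::cor.test(x, y, alternative = "greater")
  expect_equal(pc$p_one_tailed, ref$p.value, tolerance = 1e-9)

  # affine images are perfectly paired
  set.seed(408)
  z <- rnorm(6)
  expect_equal(pairing_correlation(z, 3 + 2 * z)$pairing_r, 1)

  expect_error(pairing_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pairing_correlation(c(1, 2), c(1, 2)), "at least 3")
})

test_that("mode comparison ties when both modes carry identical shifts", {
  shifts <- tidyr::expand_grid(
    gene = "G", sample_id = c("siCTRL", "siARK5"), replicate = 1:3,
    mode = c("raw", "spikein_normalized")
  ) |>
    dplyr::mutate(delta_fw = rep(c(0.1, 0.3, 0.2, 0.9, 1.2, 1.0), 2))
  out <- compare_normalization_modes(shifts, arms = c("siCTRL", "siARK5"))
  expect_true(all(out$tie))
  expect_false(any(out$more_discernible))
  expect_equal(out$p_one_tailed[1], out$p_one_tailed[2])
})

test_that("mode comparison equals componentwise recomputation on simulated data", {
  cfg <- sim_config(arms = c(siCTRL = 0.3, siARK5 = 1), seed = 55)
  res <- run_pipeline(cfg)
  cmp <- res$comparison
  for (md in c("raw", "spikein_normalized")) {
    sub <- dplyr::filter(res$shifts, mode == md) |>
      dplyr::arrange(replicate)
    x <- sub$delta_fw[sub$sample_id == "siARK5"]
    y <- sub$delta_fw[sub$sample_id == "siCTRL"]
    expect_equal(cmp$t_statistic[cmp$mode == md], oracle_t_paired(x, y),
                 tolerance = 1e-12)
    expect_equal(cmp$pairing_r[cmp$mode == md], oracle_pearson(x, y),
                 tolerance = 1e-12)
    expect_equal(cmp$mean_difference[cmp$mode == md], mean(x - y),
                 tolerance = 1e-12)
  }
  expect_equal(sum(cmp$more_discernible), 1)
})

test_that("mode comparison rejects mismatched replicate sets", {
  shifts <- tidyr::expand_grid(
    gene = "G", sample_id = c("a", "b"), replicate = 1:3,
    mode = "raw"
  ) |>
    dplyr::mutate(delta_fw = rnorm(6)) |>
    dplyr::filter(!(sample_id == "b" & replicate == 2))
  expect_error(compare_normalization_modes(shifts, arms = c("a", "b")),
               "replicate")
  expect_error(compare_normalization_modes(shifts, arms = c("a", "zzz")),
               "not present")
})
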