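quant_profile <- function(q, fraction = seq_along(q), mode = "raw") {
  tibble::tibble(
    sample_id = "s1", treatment = "DMEM", replicate = 1L, gene = "G",
    fraction = as.integer(fraction), mode = mode, quantity = q
  )
}

test_that("percent_signal renormalizes over the observed window", {
  expect_equal(percent_signal(quant_profile(rep(1, 4), 2:5),
                              window = c(2, 5))$percent,
               rep(25, 4))
  expect_equal(percent_signal(quant_profile(c(0, 1, 0), 2:4),
                              window = c(2, 4))$percent,
               c(0, 100, 0))
  expect_equal(percent_signal(quant_profile(c(2, 3, 5), 2:4),
                              window = c(2, 4))$percent,
               c(20, 30, 50))
  # fractions outside the window and missing fractions are excluded
  p <- percent_signal(quant_profile(c(9, 2, NA, 3, 9), c(1, 2, 3, 4, 17)),
                      window = c(2, 16))
  expect_equal(p$fraction, c(2L, 4L))
  expect_equal(p$percent, c(40, 60))
})

test_that("percent_signal errors on empty or zero-signal windows", {
  expect_error(percent_signal(quant_profile(c(1, 1), 18:19), window = c(2, 16)),
               "no observed fractions")
  expect_error(percent_signal(quant_profile(c(NA, NA, 1), c(2, 3, 18)),
                              window = c(2, 16)),
               "no observed fraction")
  expect_error(percent_signal(quant_profile(c(0, 0, 0), 2:4), window = c(2, 16)),
               "no positive signal")
})

test_that("percent_signal is scale invariant, making F_W calibrator-free", {
  set.seed(403)
  for (i in 1:25) {
    v <- runif(15, 0, 3)
    c_ <- runif(1, 0.01, 50)
    p1 <- percent_signal(quant_profile(v, 2:16))$percent
    p2 <- percent_signal(quant_profile(c_ * v, 2:16))$percent
    expect_equal(p1, p2, tolerance = 1e-12)
    expect_equal(sum(p1), 100, tolerance = 1e-9)
  }
})

test_that("F_W matches its closed forms and stays inside the window", {
  point <- function(k) percent_signal(quant_profile(as.numeric(2:16 == k), 2:16))
  for (k in c(2, 9, 16)) {
    expect_equal(weighted_average_fw(point(k))$fw, k)
  }
  unif <- percent_signal(quant_profile(rep(1, 15), 2:16))
  expect_equal(weighted_average_fw(unif)$fw, 9)
  ends <- percent_signal(quant_profile(c(1, rep(0, 13), 1), 2:16))
  expect_equal(weighted_average_fw(ends)$fw, 9)

  set.seed(404)
  for (i in 1:25) {
    v <- runif(15)
    fw <- weighted_average_fw(percent_signal(quant_profile(v, 2:16)))$fw
    expect_gte(fw, 2); expect_lte(fw, 16)
  }
})

test_that("moving mass to a heavier fraction strictly increases F_W", {
  set.seed(405)
  for (i in 1:25) {
    v <- runif(15, 0.05, 2)
    ab <- sort(sample(15, 2))
    v2 <- v
    moved <- v[ab[1]] * 0.5
    v2[ab[1]] <- v2[ab[1]] - moved
    v2[ab[2]] <- v2[ab[2]] + moved
    fw1 <- weighted_average_fw(percent_signal(quant_profile(v, 2:16)))$fw
    fw2 <- weighted_average_fw(percent_signal(quant_profile(v2, 2:16)))$fw
    expect_gt(fw2, fw1)
  }
})

test_that("an even-fraction subset uses the actual fraction numbers", {
  v <- rep(1, 15)
  p <- percent_signal(quant_profile(v, 2:16), fractions = seq(2, 16, 2))
  expect_equal(p$fraction, seq(2L, 16L, 2L))
  expect_equal(weighted_average_fw(p)$fw, mean(seq(2, 16, 2)))
})

test_that("delta_fw pairs conditions within replicate and subtracts", {
  fw_tbl <- tidyr::expand_grid(
    gene = "G", sample_id = "s1", replicate = 1:3,
    treatment = c("DMEM", "SOR"), mode = "raw"
  ) |>
    dplyr::mutate(fw = c(9, 9, 9.5, 11.2, 10, 10.3))
  d <- delta_fw(fw_tbl)
  expect_equal(d$delta_fw, d$fw_treated - d$fw_control)
  expect_equal(sort(d$delta_fw), sort(c(0, 1.7, 0.3)))
  expect_error(delta_fw(dplyr::filter(fw_tbl, !(replicate == 2 & treatment == "SOR"))),
               "unmatched")
  expect_error(delta_fw(fw_tbl, treated = "XYZ"), "not both present")
})

test_that("fraction recovery report flags uneven isolation", {
  flat <- cq_profile(rep(20, 10), gene = "RLP24") |> relative_quantity()
  rep_flat <- fraction_recovery_report(flat)
  expect_equal(rep_flat$cv, rep(0, 10))
  expect_false(any(rep_flat$flagged))

  # one fraction at 10x the median, threshold 2x -> exactly that one flagged
  rq10 <- c(rep(1, 9), 10)
  tbl <- cq_profile(30 - log2(rq10), gene = "RLP24") |> relative_quantity()
  rep10 <- fraction_recovery_report(tbl, fold_threshold = 2)
  expect_equal(rep10$fraction[rep10$flagged], 10L)
})

test_that("recovery flags match a brute-force threshold scan on noisy losses", {
  cfg <- sim_config(loss_sigma = 0.7, cq_sigma = 0, seed = 61)
  sim <- simulate_experiment(cfg)
  rq <- relative_quantity(sim$cq)
  rep_tbl <- fraction_recovery_report(rq, fold_threshold = 2)

  spike <- dplyr::filter(rq, gene == "RLP24")
  keys <- unique(spike[c("sample_id", "treatment", "replicate")])
  for (k in seq_len(nrow(keys))) {
    sub <- dplyr::semi_join(spike, keys[k, ],
                            by = c("sample_id", "treatment", "replicate"))
    med <- median(sub$rq)
    expected <- sub$fraction[sub$rq / med > 2 | med / sub$rq > 2]
    got <- dplyr::semi_join(rep_tbl, keys[k, ],
                            by = c("sample_id", "treatment", "replicate"))
    expect_setequal(got$fraction[got$flagged], expected)
  }
})
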