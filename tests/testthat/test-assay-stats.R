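test_that("frequencies reproduce printed plate-count arithmetic", {
  counts <- tibble::tibble(
    label = c("attC_ts_Lbox", "attC_dT23_ts_Lbox", "none"),
    recombinant = c(1L, 3L, 0L),
    total = c(607L, 642L, 500L)
  )
  freq <- recombination_frequency(counts)
  expect_equal(freq$estimate, c(1 / 607, 3 / 642, 0))
  expect_identical(freq$pct, c("0.16%", "0.47%", "0%"))
  # zero-count case: point estimate 0 but a strictly positive Wilson upper bound
  expect_equal(freq$conf_low[3], 0)
  expect_gt(freq$conf_high[3], 0)

  expect_error(
    recombination_frequency(tibble::tibble(recombinant = 1L, total = 0L)),
    class = "crossmapr_data_error"
  )
  expect_error(
    recombination_frequency(tibble::tibble(recombinant = 5L, total = 4L)),
    class = "crossmapr_data_error"
  )
})

test_that("Wilson intervals contain the estimate, stay in [0,1], and the
           estimate is monotone in the recombinant count", {
  grid <- tidyr::expand_grid(
    recombinant = c(0L, 1L, 3L, 50L, 99L),
    total = c(100L, 607L, 10000L)
  )
  freq <- recombination_frequency(grid)
  expect_true(all(freq$conf_low >= 0 & freq$conf_high <= 1))
  expect_true(all(freq$conf_low <= freq$estimate + 1e-12))
  expect_true(all(freq$estimate <= freq$conf_high + 1e-12))
  for (n in unique(freq$total)) {
    est <- freq$estimate[freq$total == n][order(freq$recombinant[freq$total == n])]
    expect_true(all(diff(est) >= 0))
  }
})

test_that("adjusted activity follows the normalised count-ratio definition", {
  expect_equal(adjusted_activity(117, 100000)$activity, 1.17e-3)
  # te_ratio = 1 reduces to the simple count ratio; the estimate is linear in it
  expect_equal(adjusted_activity(40, 200)$activity, 0.2)
  expect_equal(
    adjusted_activity(117, 100000, te_ratio = 2)$activity,
    2 * adjusted_activity(117, 100000)$activity
  )
  expect_equal(
    adjusted_activity(
      tibble::tibble(recombinant = 117L),
      tibble::tibble(recombinant = 100000L)
    )$activity,
    1.17e-3
  )
  expect_error(adjusted_activity(5, 0), class = "crossmapr_data_error")
  expect_error(adjusted_activity(5, 10, te_ratio = 0), class = "crossmapr_config_error")
})

test_that("fold changes: arithmetic, reciprocity and log-scale intervals", {
  expect_equal(fold_change(2e-4, 2e-4)$fold, 1)
  expect_equal(fold_change(4.4e-3, 1.0e-4)$fold, 44)
  expect_equal(
    fold_change(4.4e-3, 1.0e-4)$fold * fold_change(1.0e-4, 4.4e-3)$fold, 1
  )

  a <- recombination_frequency(tibble::tibble(recombinant = 440L, total = 100000L))
  b <- recombination_frequency(tibble::tibble(recombinant = 10L, total = 100000L))
  fc <- fold_change(a, b)
  expect_equal(fc$fold, 44)
  expect_true(fc$conf_low < 44 && 44 < fc$conf_high)
  # zero numerator count: point estimate defined, interval is not
  zero <- recombination_frequency(tibble::tibble(recombinant = 0L, total = 1000L))
  expect_true(is.na(fold_change(zero, b)$conf_low))
  expect_error(fold_change(a, 0), class = "crossmapr_data_error")
})

test_that("profile summaries apportion percentages that sum to exactly 100", {
  one <- profile_summary(tibble::tibble(marker_class = rep("NarI+/SacII-", 7)))
  expect_equal(one$percent, 100)

  # the mismatched-circle assembly control: 50/49/1/1 of 101 clones
  ctrl <- profile_summary(tibble::tibble(
    class = c("NarI+/SacII-", "NarI-/SacII+", "NarI+/SacII+", "NarI-/SacII-"),
    count = c(50L, 49L, 1L, 1L)
  ))
  expect_equal(ctrl$percent, c(49.5, 48.5, 1, 1))
  expect_equal(sum(ctrl$percent), 100)

  # awkward apportionments still sum to exactly 100 at 1 decimal
  for (counts in list(c(1, 1, 1), c(2, 1), c(333, 333, 334), c(7, 11, 13, 17))) {
    s <- profile_summary(tibble::tibble(
      class = paste0("c", seq_along(counts)), count = counts
    ))
    expect_equal(sum(s$percent), 100)
  }

  expect_error(
    profile_summary(tibble::tibble(class = character(), count = integer())),
    class = "crossmapr_data_error"
  )
})

test_that("equal strand reactivity segregates the two single-strand classes near 50/50", {
  clones <- simulate_strand_transfer(10000, bs_prob = 0.5, seed = 1)
  s <- profile_summary(clones)
  expect_setequal(s$class, c("NarI-/SacII+", "NarI+/SacII-"))
  se_pct <- 100 * sqrt(0.25 / 10000)
  expect_true(all(abs(s$percent - 50) <= 3 * se_pct))
  # anomaly classes appear only when requested
  with_anom <- profile_summary(
    simulate_strand_transfer(10000, anomaly_rate = 0.02, seed = 2)
  )
  expect_true(all(
    c("NarI+/SacII+", "NarI-/SacII-") %in% with_anom$class
  ))
})
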