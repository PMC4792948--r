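test_that("boundary recovery on noiseless pools and degenerate splits", {
  spec <- default_spec()
  jp <- simulate_junction_profiles(spec,
    boundary = 8, depth = 2000,
    error_rate = 0, seed = 1
  )
  call <- infer_boundary(jp, error_floor = 1e-4)
  expect_identical(call$boundary_hat, 8L)
  expect_identical(call$curve$loglik[call$curve$boundary == 8], max(call$curve$loglik))
  expect_gt(call$confidence, 0)

  # left retains non-WT everywhere, right nowhere -> boundary = P
  pair <- new_junction_profiles(
    left = profile_from_counts(rep(95L, 10), rep(5L, 10)),
    right = profile_from_counts(rep(100L, 10), rep(0L, 10)),
    wt_window = strrep("A", 10)
  )
  expect_identical(infer_boundary(pair, expected_nonwt = 0.05)$boundary_hat, 10L)
  # and the mirror image gives boundary 0
  expect_identical(infer_boundary(mirror_pair(pair), expected_nonwt = 0.05)$boundary_hat, 0L)

  # all-zero counts are a data error
  empty <- new_junction_profiles(
    left = profile_from_counts(rep(0L, 10), rep(0L, 10)),
    right = profile_from_counts(rep(0L, 10), rep(0L, 10)),
    wt_window = strrep("A", 10)
  )
  expect_error(infer_boundary(empty, expected_nonwt = 0.075), class = "crossmapr_data_error")
})

test_that("estimator agrees with an exhaustively re-enumerated likelihood search", {
  spec <- default_spec()
  for (i in 1:10) {
    b <- (2L * i) %% 11L
    jp <- simulate_junction_profiles(spec,
      boundary = b, depth = 500,
      error_rate = 0.002, seed = 100 + i, include_library = FALSE
    )
    call <- infer_boundary(jp, expected_nonwt = 0.075, error_floor = 0.002)
    expect_identical(
      call$boundary_hat,
      brute_force_boundary(jp, expected_nonwt = 0.075, error_floor = 0.002)
    )
    # the curve matches the kernel evaluated point by point
    expect_equal(
      call$curve$loglik,
      boundary_loglik(jp, 0:10, 0.075, 0.002)
    )
  }
})

test_that("swapping products and reversing positions mirrors the boundary", {
  spec <- default_spec()
  for (b in c(0L, 3L, 7L, 10L)) {
    jp <- simulate_junction_profiles(spec,
      boundary = b, depth = 1000,
      error_rate = 0.001, seed = 50 + b
    )
    call <- infer_boundary(jp, expected_nonwt = 0.075)
    call_m <- infer_boundary(mirror_pair(jp), expected_nonwt = 0.075)
    expect_identical(call_m$boundary_hat, 10L - call$boundary_hat)
  }
})

test_that("tidy and glance expose the call in broom style", {
  spec <- default_spec()
  jp <- simulate_junction_profiles(spec, 7, depth = 500, seed = 1)
  call <- infer_boundary(jp)
  td <- tidy(call)
  expect_identical(nrow(td), 11L)
  expect_identical(td$boundary[td$is_max], call$boundary_hat)
  g <- glance(call)
  expect_identical(nrow(g), 1L)
  expect_identical(g$boundary_hat, call$boundary_hat)
  expect_identical(g$P, 10L)
})

test_that("stringency skew: exact expectation, complete purging, selective retention", {
  wtw <- strrep("A", 10)

  # observed exactly at expectation: skew 0, exact test p = 1 (mode)
  at_exp <- profile_from_counts(rep(3700L, 10), rep(300L, 10))
  rep1 <- stringency_skew(at_exp, 0.075, wtw)
  expect_equal(rep1$skew, rep(0, 10))
  expect_equal(rep1$p_value, rep(1, 10))

  # zero retention at depth 10,000: skew -1, p equals the direct
  # density-enumeration of the exact two-sided binomial test
  purged <- profile_from_counts(c(10000L, rep(3700L, 9)), c(0L, rep(300L, 9)))
  rep2 <- stringency_skew(purged, 0.075, wtw)
  expect_equal(rep2$skew[1], -1)
  dens <- dbinom(0:10000, 10000, 0.075)
  p_direct <- sum(dens[dens <= dens[1] * (1 + 1e-7)])
  expect_equal(rep2$p_value[1], p_direct, tolerance = 1e-6)
  expect_lt(rep2$p_value[1], 1e-100)

  # two neutral positions among eight purged ones: the purged positions are
  # flagged as massively depleted, the neutral pair is not. Thresholds are
  # deliberately far apart: a neutral exact-binomial p-value lands below
  # 0.05 about 5% of the time by construction, so the null side is judged
  # against q > 1e-3 and a near-zero skew instead.
  withr::with_seed(21, {
    retention <- c(rep(0.005, 3), 0.075, 0.075, rep(0.005, 5))
    k <- rbinom(10, 10000, retention)
    prof <- profile_from_counts(10000L - k, k)
    rep3 <- stringency_skew(prof, 0.075, wtw)
    expect_true(all(rep3$q_value[-c(4, 5)] < 1e-6))
    expect_true(all(rep3$skew[-c(4, 5)] < -0.5))
    expect_true(all(rep3$q_value[c(4, 5)] > 1e-3))
    expect_true(all(abs(rep3$skew[c(4, 5)]) < 0.3))
  })

  # per-base variant flags the same purged positions
  rep4 <- stringency_base_skew(purged, 0.075, wtw)
  expect_identical(nrow(rep4), 30L)
  expect_equal(rep4$skew[rep4$position == 1], rep(-1, 3))
})

test_that("stringency p-values are approximately uniform under the null", {
  n_pos <- 1000L
  depth <- 10000L
  withr::with_seed(1, {
    k <- rbinom(n_pos, depth, 0.075)
    prof <- profile_from_counts(depth - k, k)
    rep_null <- stringency_skew(prof, 0.075, strrep("A", n_pos))
    d <- suppressWarnings(
      ks.test(rep_null$p_value, "punif")$statistic
    )
    expect_lt(unname(d), 0.05)
  })
})

test_that("power curve reaches certainty at depth and degrades gracefully", {
  spec <- default_spec()
  pc <- power_curve(spec, 7,
    depth_grid = c(10, 250, 5000),
    error_grid = c(0.001, 0.05), replicates = 30, seed = 1
  )
  expect_identical(nrow(pc), 6L)
  expect_true(all(pc$recovery >= 0 & pc$recovery <= 1))
  # deep, clean sequencing recovers the boundary always
  expect_equal(pc$recovery[pc$depth == 5000 & pc$error_rate == 0.001], 1)
  # shallow, noisy sequencing does not
  expect_lt(pc$recovery[pc$depth == 10 & pc$error_rate == 0.05], 1)
  # recovery is non-decreasing in depth at fixed error
  for (e in unique(pc$error_rate)) {
    r <- pc$recovery[pc$error_rate == e][order(pc$depth[pc$error_rate == e])]
    expect_true(all(diff(r) >= 0))
  }
})
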