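test_that("perfect template reads yield the exact window; anchor threshold is sharp", {
  site <- attI1_site()
  ctx <- amplicon_contexts(site)$library
  window <- "CCGTAAAACC"
  template <- crossmapr:::build_amplicons(window, site, ctx)
  reads <- tibble::tibble(sequence = template)

  out <- extract_windows(reads, ctx)
  expect_identical(out$status, "ok")
  expect_identical(out$window, window)

  # reverse-complement reads are canonicalized before extraction
  rc <- tibble::tibble(sequence = crossmapr:::revcomp(template))
  out_rc <- extract_windows(rc, ctx)
  expect_identical(out_rc$window, window)

  # exactly max_anchor_mismatch substitutions in the left anchor still pass;
  # one more fails with anchor_fail
  mutate_anchor <- function(x, k) {
    chars <- strsplit(x, "", fixed = TRUE)[[1]]
    for (i in seq_len(k)) {
      chars[i] <- setdiff(c("A", "C", "G", "T"), chars[i])[1]
    }
    paste(chars, collapse = "")
  }
  ok1 <- extract_windows(tibble::tibble(sequence = mutate_anchor(template, 1)), ctx)
  expect_identical(ok1$status, "ok")
  bad2 <- extract_windows(tibble::tibble(sequence = mutate_anchor(template, 2)), ctx)
  expect_identical(bad2$reason, "anchor_fail")

  # truncation breaks the right-anchor spacing; N in the window is ambiguous
  trunc <- extract_windows(
    tibble::tibble(sequence = substr(template, 1, nchar(template) - 25)), ctx
  )
  expect_identical(trunc$reason, "length_fail")
  amb <- template
  substr(amb, 23, 23) <- "N" # window ordinal 3
  out_amb <- extract_windows(tibble::tibble(sequence = amb), ctx)
  expect_identical(out_amb$reason, "ambiguous_base")
})

test_that("abnormal reads are rejected at exactly the injected rate", {
  spec <- default_spec()
  ctx <- amplicon_contexts(spec$site)
  reads <- simulate_amplicon_pool(spec,
    boundary = 7, depth = 1500,
    error_rate = 0, abnormal_fraction = 0.1, seed = 13
  )
  reads <- classify_reads(reads, ctx)
  reads <- extract_windows(reads, ctx)

  # without sequencing error, filter decisions match corruption labels 1:1
  expect_identical(reads$status != "ok", reads$abnormal)
  se <- sqrt(0.1 * 0.9 / nrow(reads))
  expect_lt(abs(mean(reads$abnormal) - 0.1), 3 * se)
  # every corruption mode is exercised and rejected
  expect_setequal(
    unique(reads$corruption[reads$abnormal]),
    c("truncate", "anchor_mutate", "chimera")
  )
})

test_that("profiles equal manual tallies and handle degenerate input", {
  prof <- profile_positions(rep("AAAAAAAAAA", 3))
  expect_true(all(prof$freq[prof$base == "A"] == 1))
  expect_true(all(prof$freq[prof$base != "A"] == 0))

  # hand-tallied 8-window toy set
  windows <- c("AAAA", "AAAC", "AACA", "ACAA", "CAAA", "AAAA", "AAGT", "TTTT")
  prof <- profile_positions(windows)
  get <- function(pos, base) prof$count[prof$position == pos & prof$base == base]
  expect_identical(get(1, "A"), 6L)
  expect_identical(get(1, "C"), 1L)
  expect_identical(get(1, "T"), 1L)
  expect_identical(get(3, "G"), 1L)
  expect_identical(get(4, "T"), 2L)
  expect_equal(get(2, "A") / 8, 0.75)
  # every row of the frequency matrix sums to 1
  sums <- tapply(prof$freq, prof$position, sum)
  expect_equal(as.numeric(sums), rep(1, 4))

  expect_error(profile_positions(character()), class = "crossmapr_data_error")
  expect_error(profile_positions(c(NA, NA)), class = "crossmapr_data_error")
  expect_error(profile_positions(c("AA", "AAA")), class = "crossmapr_data_error")
})

test_that("classification is exact without error and near-exact at 0.001", {
  spec <- default_spec()
  ctx <- amplicon_contexts(spec$site)

  clean <- classify_reads(
    simulate_amplicon_pool(spec, 7, depth = 300, error_rate = 0, seed = 2), ctx
  )
  expect_identical(clean$assigned_class, clean$class)
  expect_true(all(clean$orientation == "fwd"))

  none <- classify_reads(
    tibble::tibble(sequence = strrep("ACGT", 15)), ctx
  )
  expect_identical(none$assigned_class, "unassigned")

  noisy <- classify_reads(
    simulate_amplicon_pool(spec, 7, depth = 700, error_rate = 0.001, seed = 3), ctx
  )
  misassigned <- noisy$assigned_class != noisy$class &
    noisy$assigned_class != "unassigned"
  expect_lt(mean(misassigned), 0.01)
})

test_that("pipeline is idempotent on its own retained output", {
  spec <- default_spec()
  ctx <- amplicon_contexts(spec$site)
  reads <- simulate_amplicon_pool(spec, 7,
    depth = 400, error_rate = 0.002,
    abnormal_fraction = 0.05, seed = 9
  )
  pass1 <- extract_windows(classify_reads(reads, ctx), ctx)
  retained <- dplyr::filter(pass1, status == "ok")
  pass2 <- extract_windows(
    classify_reads(dplyr::select(retained, read_id, sequence), ctx), ctx
  )
  expect_true(all(pass2$status == "ok"))
  p1 <- junction_profiles(pass1, crossmapr:::wt_window(spec))
  p2 <- junction_profiles(pass2, crossmapr:::wt_window(spec))
  for (cls in c("library", "left", "right")) {
    expect_identical(p1[[cls]], p2[[cls]])
  }
})

test_that("exhaustive library profiled end-to-end equals the analytic distribution exactly", {
  spec <- default_spec()
  ctx <- amplicon_contexts(spec$site)
  ex <- draw_library(spec, exhaustive = TRUE)
  reads <- tibble::tibble(
    sequence = crossmapr:::build_amplicons(ex$window, spec$site, ctx$library)
  )
  out <- extract_windows(classify_reads(reads, ctx), ctx)
  expect_true(all(out$status == "ok"))
  prof <- profile_positions(out$window)
  for (ordinal in 1:10) {
    expected <- expected_position_distribution(spec, spec$positions[ordinal])
    got <- prof[prof$position == ordinal, ]
    expect_equal(got$freq, expected$prob)
  }
})
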