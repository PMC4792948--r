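test_that("library draws respect the one-random-base design and are seed-reproducible", {
  spec <- default_spec()
  lib <- draw_library(spec, 500, seed = 1)
  expect_identical(lib, draw_library(spec, 500, seed = 1))
  expect_false(identical(lib$window, draw_library(spec, 500, seed = 2)$window))

  # every molecule differs from WT at zero positions or exactly one
  wtw <- strsplit(crossmapr:::wt_window(spec), "", fixed = TRUE)[[1]]
  diffs <- vapply(
    strsplit(lib$window, "", fixed = TRUE),
    function(w) sum(w != wtw),
    integer(1)
  )
  expect_true(all(diffs <= 1L))
  # and the differing position is the recorded one
  mismatch <- which(diffs == 1L)
  ord <- vapply(
    strsplit(lib$window[mismatch], "", fixed = TRUE),
    function(w) which(w != wtw),
    integer(1)
  )
  expect_identical(ord, lib$ordinal[mismatch])

  expect_error(draw_library(spec, 0), class = "crossmapr_data_error")
  expect_error(draw_library(spec), class = "crossmapr_data_error")
  expect_identical(nrow(draw_library(spec, 1, seed = 3)), 1L)
})

test_that("exhaustive mode yields the nominal 4P-variant library", {
  spec <- default_spec()
  ex <- draw_library(spec, exhaustive = TRUE)
  expect_identical(nrow(ex), 40L)
  # 30 single-base variants + the WT window reached from each of the 10 sets
  expect_identical(dplyr::n_distinct(ex$window), 31L)
  expect_identical(nrow(dplyr::distinct(ex, ordinal, base)), 40L)
  expect_identical(sort(unique(ex$ordinal)), 1:10)
  expect_identical(sort(unique(ex$base)), c("A", "C", "G", "T"))
})

test_that("per-position non-WT frequency converges to the analytic 0.075", {
  spec <- default_spec()
  n <- 20000L
  lib <- draw_library(spec, n, seed = 11)
  prof <- profile_positions(lib$window)
  rates <- crossmapr:::nonwt_rates(prof, crossmapr:::wt_window(spec))
  se <- sqrt(0.075 * 0.925 / n)
  expect_true(all(abs(rates$rate - 0.075) <= 4 * se))
})

test_that("reciprocal exchange conserves the randomized window", {
  spec <- default_spec()
  recipient <- attI1_AAA_site()
  rec_win <- crossmapr:::wt_window(recipient)
  lib <- draw_library(spec, 20, seed = 7)
  for (i in seq_len(10)) {
    b <- (i - 1L) %% 11L
    ev <- recombine(lib$window[i], recipient, boundary = b)
    # donor = left[1..b] + right[b+1..P]; recipient = the reciprocal
    expect_identical(
      paste0(substr(ev$left_window, 1, b), substr(ev$right_window, b + 1, 10)),
      lib$window[i]
    )
    expect_identical(
      paste0(substr(ev$right_window, 1, b), substr(ev$left_window, b + 1, 10)),
      rec_win
    )
  }

  # boundary at the window edge: nothing of the donor enters the left product
  ev0 <- recombine(lib$window[1], recipient, boundary = 0)
  expect_identical(ev0$left_window, rec_win)
  expect_identical(ev0$right_window, lib$window[1])

  # a donor marker before the boundary segregates into the left product only
  donor <- "CCGTAAAACC" # non-WT G at ordinal 3
  ev <- recombine(donor, attI1_site(), boundary = 8)
  expect_identical(substr(ev$left_window, 3, 3), "G")
  expect_identical(substr(ev$right_window, 3, 3), "C")

  expect_error(
    recombine(donor, attI1_site(), boundary = 11),
    class = "crossmapr_coordinate_error"
  )
})

test_that("replicative pathways transfer the window unsplit and outcomes map correctly", {
  donor <- "CCGTAAAACC"
  ev <- recombine(donor, attI1_site(),
    boundary = 5,
    pathway = "replicative_bs", orientation = "intermolecular"
  )
  expect_identical(ev$left_window, donor)
  expect_identical(ev$right_window, crossmapr:::wt_window(attI1_site()))
  expect_identical(ev$outcome, "cointegrate")

  tab <- outcome_table()
  expect_identical(nrow(tab), 9L)
  lookup <- function(p, o) tab$outcome[tab$pathway == p & tab$orientation == o]
  expect_identical(lookup("second_exchange", "inverted"), "inversion")
  expect_identical(lookup("second_exchange", "direct"), "excision")
  expect_identical(lookup("replicative_bs", "inverted"), "abortive_linear")
  expect_identical(lookup("replicative_ts", "inverted"), "abortive_linear")
  expect_identical(lookup("replicative_bs", "direct"), "excision")
  expect_true(all(table(tab$pathway) == 3L)) # total over the 3 x 3 grid
  expect_error(reaction_outcome("sideways", "direct"), class = "crossmapr_config_error")
})

test_that("marker tracing reproduces the three restriction patterns", {
  bs <- trace_circle_markers("replicative_bs", n_clones = 10)
  expect_true(all(bs$marker_class == "SacII+/NarI-"))
  expect_true(all(bs$population == "homogeneous"))

  ts <- trace_circle_markers("replicative_ts", n_clones = 10)
  expect_true(all(ts$marker_class == "SacII-/NarI+"))

  dbl <- trace_circle_markers("second_exchange", n_clones = 10)
  expect_true(all(dbl$population == "mixed"))
  expect_true(all(dbl$sacII == "partial" & dbl$narI == "partial"))
})

test_that("read simulation is faithful at zero error and seed-deterministic", {
  templates <- tibble::tibble(
    class = "library",
    template = crossmapr:::build_amplicons(
      c("CCCTAAAACC", "ACCTAAAACC"), attI1_site(),
      amplicon_contexts(attI1_site())$library
    )
  )
  reads <- simulate_reads(templates, depth = 50, error_rate = 0, seed = 5)
  expect_true(all(reads$sequence %in% templates$template))
  expect_false(any(reads$abnormal))

  expect_identical(reads, simulate_reads(templates, depth = 50, error_rate = 0, seed = 5))
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, f1)
  write_fastq(simulate_reads(templates, depth = 50, error_rate = 0, seed = 5), f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(
    simulate_reads(templates, depth = 10, error_rate = 1.5),
    class = "crossmapr_config_error"
  )
})

test_that("substitution errors appear at the configured rate", {
  tmpl <- strrep("ACGT", 15)
  templates <- tibble::tibble(class = "x", template = tmpl)
  depth <- 2000L
  reads <- simulate_reads(templates, depth = depth, error_rate = 0.001, seed = 1)
  mism <- sum(string_dist(reads$sequence, tmpl))
  n_bases <- depth * nchar(tmpl)
  se <- sqrt(0.001 * 0.999 / n_bases)
  expect_lt(abs(mism / n_bases - 0.001), 3 * se)
})
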