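# Count-based assay estimators: recombination frequencies with Wilson score
# intervals, transformation-efficiency-adjusted activities, fold changes,
# and restriction-profile population summaries.

#' Recombination frequency from colony counts
#'
#' Point estimate `recombinant / total` with a Wilson score interval (chosen
#' over the Wald interval for its behaviour at small and zero counts — the
#' underlying assays routinely count 0-3 recombinants). This covers both the
#' conjugation-assay definition (transconjugants over total recipient
#' clones) and the dapA-reporter definition (colonies growing without DAP
#' over colonies on DAP-supplemented media).
#'
#' @param counts A data frame with integer columns `recombinant` and
#'   `total` (and optionally `label`), one row per assay.
#' @param conf Confidence level for the Wilson interval.
#' @return `counts` with added columns `estimate`, `conf_low`, `conf_high`
#'   and `pct` (the estimate as a percentage formatted to 2 significant
#'   figures, the reporting style used for plate counts).
#' @export
#' @examples
#' recombination_frequency(
#'   tibble::tibble(
#'     label = c("attC_aadA7_ts", "attC_aadA7_dT23_ts"),
#'     recombinant = c(1L, 3L),
#'     total = c(607L, 642L)
#'   )
#' )
recombination_frequency <- function(counts, conf = 0.95) {
  stopifnot(is.data.frame(counts), all(c("recombinant", "total") %in% names(counts)))
  if (any(counts$total <= 0)) {
    abort_data("total must be positive; frequency is undefined for total = 0")
  }
  if (any(counts$recombinant < 0) || any(counts$recombinant > counts$total)) {
    abort_data("recombinant counts must lie in 0..total")
  }
  ci <- wilson_interval(counts$recombinant, counts$total, conf)
  counts %>%
    as_tibble() %>%
    mutate(
      estimate = .data$recombinant / .data$total,
      conf_low = ci$lower,
      conf_high = ci$upper,
      pct = format_pct(.data$estimate)
    )
}

# Wilson score interval for a binomial proportion; vectorised.
wilson_interval <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(lower = pmax(0, center - half), upper = pmin(1, center + half))
}

# Percentage to 2 significant figures, the plate-count reporting style
# (0.0016470 -> "0.16%").
format_pct <- function(p) {
  paste0(formatC(signif(100 * p, 2), format = "fg"), "%")
}

#' Transformation-efficiency-adjusted recombination activity
#'
#' For the non-replicative circle assay: the ratio of resistant clones
#' obtained under non-replicating (`pir-`) conditions to those under
#' replicating (`pir+`) conditions, multiplied by the pre-measured
#' transformation-efficiency ratio that normalises the two strains.
#'
#' @param pir_minus,pir_plus Clone counts: bare numbers or one-row data
#'   frames with a `recombinant` column.
#' @param te_ratio Positive transformation-efficiency ratio.
#' @return A tibble with `pir_minus`, `pir_plus`, `te_ratio`, `activity`.
#' @export
#' @examples
#' adjusted_activity(117, 100000) # 1.17e-3
adjusted_activity <- function(pir_minus, pir_plus, te_ratio = 1) {
  k_minus <- if (is.data.frame(pir_minus)) pir_minus$recombinant[[1L]] else pir_minus
  k_plus <- if (is.data.frame(pir_plus)) pir_plus$recombinant[[1L]] else pir_plus
  if (is.na(k_plus) || k_plus <= 0) {
    abort_data("pir+ clone count must be positive")
  }
  if (te_ratio <= 0) abort_config("te_ratio must be positive")
  tibble(
    pir_minus = k_minus, pir_plus = k_plus, te_ratio = te_ratio,
    activity = k_minus / k_plus * te_ratio
  )
}

#' Fold change between two recombination frequencies
#'
#' Ratio of point estimates, e.g. integrase-induced over repressed. When
#' both inputs carry counts (rows from [recombination_frequency()]), a
#' confidence interval is propagated on the log scale using the delta-method
#' standard error `sqrt((1-p1)/(n1 p1) + (1-p2)/(n2 p2))`; with a zero
#' recombinant count on either side the interval is undefined (`NA`).
#'
#' @param freq_num,freq_den One-row data frames from
#'   [recombination_frequency()], or bare frequencies.
#' @param conf Confidence level.
#' @return A tibble with `fold`, `conf_low`, `conf_high`.
#' @export
#' @examples
#' fold_change(4.4e-3, 1.0e-4)$fold # 44
fold_change <- function(freq_num, freq_den, conf = 0.95) {
  get <- function(f) {
    if (is.data.frame(f)) {
      list(
        p = f$estimate[[1L]],
        x = f[["recombinant"]][[1L]] %||% NA_real_,
        n = f[["total"]][[1L]] %||% NA_real_
      )
    } else {
      list(p = as.numeric(f), x = NA_real_, n = NA_real_)
    }
  }
  a <- get(freq_num)
  b <- get(freq_den)
  if (is.na(b$p) || b$p <= 0) abort_data("denominator frequency must be positive")
  fold <- a$p / b$p
  lo <- hi <- NA_real_
  if (!is.na(a$x) && !is.na(b$x) && a$x > 0 && b$x > 0) {
    se <- sqrt((1 - a$p) / (a$n * a$p) + (1 - b$p) / (b$n * b$p))
    z <- qnorm(1 - (1 - conf) / 2)
    lo <- fold * exp(-z * se)
    hi <- fold * exp(z * se)
  }
  tibble(fold = fold, conf_low = lo, conf_high = hi)
}

#' Restriction-profile population summary
#'
#' Tallies clone marker classes (e.g. `NarI+/SacII-`) and reports
#' percentages that sum to exactly 100 at the requested precision, using
#' largest-remainder rounding — the convention that reproduces summaries
#' like 49.5 / 48.5 / 1 / 1 from 50/49/1/1 of 101 clones.
#'
#' @param clones A data frame with a `marker_class` (or `class`) column, one
#'   row per clone; or a pre-tallied table with `class`/`marker_class` and
#'   `count` columns.
#' @param digits Decimal places of the reported percentages.
#' @return A tibble with `class`, `count`, `percent` (sums to 100).
#' @export
#' @examples
#' profile_summary(
#'   tibble::tibble(
#'     class = c("NarI+/SacII-", "NarI-/SacII+", "NarI+/SacII+", "NarI-/SacII-"),
#'     count = c(50, 49, 1, 1)
#'   )
#' )
profile_summary <- function(clones, digits = 1L) {
  stopifnot(is.data.frame(clones))
  cls_col <- intersect(c("marker_class", "class"), names(clones))[1]
  if (is.na(cls_col)) {
    abort_config("clones must have a marker_class (or class) column")
  }
  tallied <- if ("count" %in% names(clones)) {
    clones %>%
      as_tibble() %>%
      select(class = dplyr::all_of(cls_col), "count")
  } else {
    count(clones, class = .data[[cls_col]], name = "count")
  }
  if (nrow(tallied) == 0L || sum(tallied$count) == 0) {
    abort_data("no clones to summarise")
  }
  tallied %>%
    arrange(dplyr::desc(.data$count), .data$class) %>%
    mutate(percent = largest_remainder_percent(.data$count, digits = digits))
}

# Largest-remainder (Hamilton) apportionment of 100% at a fixed precision;
# guarantees the reported percentages sum to exactly 100.
largest_remainder_percent <- function(counts, digits = 1L) {
  unit <- 10^digits
  total_units <- 100L * unit
  shares <- counts / sum(counts) * total_units
  base <- floor(shares)
  left <- total_units - sum(base)
  if (left > 0) {
    top_up <- order(shares - base, decreasing = TRUE)[seq_len(left)]
    base[top_up] <- base[top_up] + 1
  }
  base / unit
}
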