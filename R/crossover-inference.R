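# Crossover-boundary inference: a two-rate binomial changepoint model on the
# segregation of non-wild-type bases between the two cointegrate junction
# profiles, plus per-position sequence-stringency tests.

#' Log-likelihood of one candidate boundary
#'
#' The segregation model: under candidate boundary `b`, the left junction
#' site retains the library's randomized bases at window ordinals `<= b`, so
#' its per-position non-WT counts are Binomial with rate `expected_nonwt`
#' there and `error_floor` (sequencing error) elsewhere; the right junction
#' is the reciprocal. Position-wise binomial log-likelihoods are summed over
#' both products. A pseudocount is added to each success/failure cell to keep
#' the likelihood finite for empty cells; binomial coefficients are dropped
#' (they do not depend on `b`).
#'
#' @param pair A [junction_profiles] object with count-bearing `left` and
#'   `right` profiles.
#' @param boundary Candidate window boundary `b` in `0..P` (vectorised).
#' @param expected_nonwt Non-WT rate at retained randomized positions
#'   (`(3/4)/P` under the uniform design; 0.075 for P = 10).
#' @param error_floor Non-WT rate expected from sequencing error alone.
#' @param pseudocount Added to each success and failure cell.
#' @return Numeric vector of log-likelihoods, one per boundary.
#' @export
boundary_loglik <- function(pair, boundary, expected_nonwt, error_floor = 1e-3,
                            pseudocount = 0.5) {
  curve <- loglik_curve(pair, expected_nonwt, error_floor, pseudocount)
  if (any(boundary < 0L | boundary > max(curve$boundary))) {
    abort_coordinate("boundary out of range 0..P")
  }
  curve$loglik[match(boundary, curve$boundary)]
}

# Full curve over b = 0..P via cumulative sums of the per-position
# "retained" vs "floor" log-likelihood contributions.
loglik_curve <- function(pair, expected_nonwt, error_floor, pseudocount) {
  stopifnot(inherits(pair, "junction_profiles"))
  if (is.null(pair$left) || is.null(pair$right)) {
    abort_data("both left and right junction profiles are required")
  }
  L <- nonwt_rates(pair$left, pair$wt_window)
  R <- nonwt_rates(pair$right, pair$wt_window)
  if (sum(L$n) == 0 || sum(R$n) == 0) {
    abort_data("profiles carry no counts; cannot infer a boundary")
  }
  P <- nrow(L)
  q <- clamp_rate(expected_nonwt)
  f <- clamp_rate(error_floor)
  cell <- function(k, n, r) {
    (k + pseudocount) * log(r) + (n - k + pseudocount) * log(1 - r)
  }
  l_ret <- cell(L$non_wt, L$n, q) # left position retained (i <= b)
  l_flo <- cell(L$non_wt, L$n, f)
  r_ret <- cell(R$non_wt, R$n, q) # right position retained (i > b)
  r_flo <- cell(R$non_wt, R$n, f)
  # ll(b) = sum_{i<=b} (l_ret + r_flo) + sum_{i>b} (l_flo + r_ret)
  gain <- cumsum(c(0, l_ret + r_flo))
  rest <- rev(cumsum(rev(c(l_flo + r_ret, 0))))
  tibble(boundary = 0:P, loglik = gain + rest)
}

clamp_rate <- function(r) {
  if (r < 0 || r > 1) abort_config("rates must lie in [0, 1]")
  min(max(r, 1e-12), 1 - 1e-12)
}

#' Infer the crossover boundary from junction profiles
#'
#' Maximum likelihood changepoint estimate of the crossover point: evaluates
#' the segregation model of [boundary_loglik()] at every candidate boundary
#' `b` in `0..P` and returns the argmax with the full curve. Ties (within
#' `1e-8` of the maximum) resolve to the smallest boundary and are reported.
#' The confidence field is the log-likelihood gap between the best and
#' runner-up boundaries — an artifact of this estimator, not an
#' experimentally defined quantity.
#'
#' @param pair A [junction_profiles] object.
#' @param expected_nonwt Non-WT rate at retained randomized positions; when
#'   `NULL` it is estimated as the mean per-position non-WT rate of the
#'   library profile (falling back to the analytic `(3/4)/P` is the caller's
#'   choice when no library profile exists).
#' @param error_floor Non-WT rate from sequencing error alone (default
#'   `1e-3`; ideally the error estimate from non-randomized positions).
#' @param pseudocount Stabilising pseudocount per likelihood cell.
#' @return A `crossover_call`: `boundary_hat`, `curve` (tibble of boundary
#'   and loglik), `confidence`, `ties`, `side_convention`, and the model
#'   rates used. Supports [tidy()], [glance()], [autoplot()].
#' @export
#' @examples
#' spec <- library_spec(attI1_site())
#' jp <- simulate_junction_profiles(spec, boundary = 7, depth = 2000, seed = 1)
#' call <- infer_boundary(jp)
#' glance(call)
infer_boundary <- function(pair, expected_nonwt = NULL, error_floor = 1e-3,
                           pseudocount = 0.5) {
  stopifnot(inherits(pair, "junction_profiles"))
  if (is.null(expected_nonwt)) {
    if (is.null(pair$library)) {
      abort_config(
        "expected_nonwt not given and no library profile to estimate it from"
      )
    }
    lib <- nonwt_rates(pair$library, pair$wt_window)
    expected_nonwt <- sum(lib$non_wt) / sum(lib$n)
  }
  curve <- loglik_curve(pair, expected_nonwt, error_floor, pseudocount)
  best <- max(curve$loglik)
  ties <- curve$boundary[curve$loglik >= best - 1e-8]
  boundary_hat <- min(ties)
  runner_up <- if (nrow(curve) > 1L) {
    max(curve$loglik[curve$boundary != boundary_hat])
  } else {
    NA_real_
  }
  structure(
    list(
      boundary_hat = boundary_hat,
      curve = curve,
      confidence = best - runner_up,
      ties = ties,
      side_convention = "left_retains_1_to_b",
      expected_nonwt = expected_nonwt,
      error_floor = error_floor,
      pseudocount = pseudocount,
      P = max(curve$boundary)
    ),
    class = "crossover_call"
  )
}

#' @export
print.crossover_call <- function(x, ...) {
  cat("<crossover_call> boundary_hat = ", x$boundary_hat,
    " (between window ordinals ", x$boundary_hat, " and ", x$boundary_hat + 1L,
    ")\n",
    sep = ""
  )
  cat("  log-likelihood gap to runner-up: ", format(x$confidence, digits = 4),
    "\n",
    sep = ""
  )
  if (length(x$ties) > 1L) {
    cat("  ties: ", paste(x$ties, collapse = ", "), "\n", sep = "")
  }
  cat("  model: non-WT ", format(x$expected_nonwt, digits = 4),
    " at retained positions, floor ", format(x$error_floor, digits = 4),
    "; left product retains ordinals <= b\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.crossover_call <- function(x, ...) {
  mutate(x$curve, is_max = .data$boundary == x$boundary_hat)
}

#' @export
glance.crossover_call <- function(x, ...) {
  tibble(
    boundary_hat = x$boundary_hat,
    confidence = x$confidence,
    n_ties = length(x$ties),
    P = x$P,
    expected_nonwt = x$expected_nonwt,
    error_floor = x$error_floor
  )
}

#' Per-position sequence stringency of a post-recombination profile
#'
#' After recombination, a randomized position that matters for integrase
#' binding is depleted of non-WT bases relative to the neutral library
#' expectation (7.5% under the uniform P = 10 design). For each window
#' position this runs an exact two-sided binomial test of the observed
#' non-WT retention count against `expected_nonwt`, reports the relative
#' skew `(observed - expected) / expected` (0 at expectation, -1 at complete
#' purging), and adds Benjamini-Hochberg adjusted q-values across the P
#' positions.
#'
#' @param profile A count-bearing profile tibble (from
#'   [profile_positions()]), typically the retained side of each junction
#'   product (see [retained_profile()]).
#' @param expected_nonwt Neutral non-WT retention rate.
#' @param wt_window Wild-type window string.
#' @return A tibble with `position`, `n`, `non_wt`, `observed`, `expected`,
#'   `skew`, `p_value`, `q_value`.
#' @export
stringency_skew <- function(profile, expected_nonwt, wt_window) {
  rates <- nonwt_rates(profile, wt_window)
  if (sum(rates$n) == 0) abort_data("profile carries no counts")
  p_value <- vapply(seq_len(nrow(rates)), function(i) {
    if (rates$n[i] == 0) {
      return(NA_real_)
    }
    binom.test(rates$non_wt[i], rates$n[i], p = expected_nonwt)$p.value
  }, numeric(1))
  tibble(
    position = rates$position,
    n = rates$n,
    non_wt = rates$non_wt,
    observed = rates$rate,
    expected = expected_nonwt,
    skew = (rates$rate - expected_nonwt) / expected_nonwt,
    p_value = p_value,
    q_value = p.adjust(p_value, method = "BH")
  )
}

#' @describeIn stringency_skew Per-base variant: tests each non-WT base
#'   against `expected_nonwt / 3`, since base identity (not just non-WT
#'   status) can matter for binding.
#' @export
stringency_base_skew <- function(profile, expected_nonwt, wt_window) {
  wt <- strsplit(wt_window, "", fixed = TRUE)[[1]]
  per_base <- expected_nonwt / 3
  profile %>%
    group_by(.data$position) %>%
    mutate(n = sum(.data$count)) %>%
    ungroup() %>%
    filter(.data$base != wt[.data$position]) %>%
    mutate(
      observed = ifelse(.data$n > 0, .data$count / .data$n, NA_real_),
      expected = per_base,
      skew = (.data$observed - per_base) / per_base,
      p_value = purrr::map2_dbl(
        .data$count, .data$n,
        function(k, n) binom.test(k, n, p = per_base)$p.value
      ),
      q_value = p.adjust(.data$p_value, method = "BH")
    ) %>%
    select(
      "position", "base", "n",
      non_wt = "count", "observed", "expected", "skew", "p_value", "q_value"
    )
}

#' Library-derived (retained) side of the two junction profiles
#'
#' Under the side convention of [infer_boundary()], the left junction site
#' carries the library's randomized bases at window ordinals `<= b` and the
#' right junction site at ordinals `> b`. This helper stitches those rows
#' into one P-position profile — the input for [stringency_skew()].
#'
#' @param pair A [junction_profiles] object.
#' @param call A `crossover_call` (or an integer boundary).
#' @return A profile tibble covering all P positions.
#' @export
retained_profile <- function(pair, call) {
  b <- if (inherits(call, "crossover_call")) call$boundary_hat else as.integer(call)
  bind_rows(
    filter(pair$left, .data$position <= b),
    filter(pair$right, .data$position > b)
  ) %>% arrange(.data$position, .data$base)
}

#' Boundary-recovery power surface
#'
#' Method calibration for low-activity recombination systems: for each
#' (sequencing depth, error rate) cell, simulates `replicates` independent
#' crossover-mapping experiments at the true boundary with
#' [simulate_junction_profiles()] and records the fraction in which
#' [infer_boundary()] recovers it. Useful to size an experiment before
#' sequencing.
#'
#' @param spec A [library_spec()].
#' @param true_boundary True window boundary.
#' @param depth_grid,error_grid Numeric vectors of depths and error rates.
#' @param replicates Simulations per cell.
#' @param seed Integer seed for the whole grid.
#' @param error_floor_min Lower bound used for the model's error floor (the
#'   floor tracks the simulated error rate, bounded away from 0).
#' @return A tibble of class `power_curve` with `depth`, `error_rate`,
#'   `replicates`, `recovery`.
#' @export
#' @examples
#' spec <- library_spec(attI1_site())
#' power_curve(spec, 7, depth_grid = c(50, 500), error_grid = 0.001,
#'   replicates = 5, seed = 1)
power_curve <- function(spec, true_boundary, depth_grid, error_grid,
                        replicates = 20L, seed = 1L, error_floor_min = 1e-4) {
  stopifnot(inherits(spec, "library_spec"), replicates >= 1L)
  expected <- 0.75 / spec$P
  grid <- tidyr::expand_grid(depth = depth_grid, error_rate = error_grid)
  recovery <- with_seed_maybe(seed, {
    vapply(seq_len(nrow(grid)), function(i) {
      hits <- vapply(seq_len(replicates), function(r) {
        jp <- simulate_junction_profiles(
          spec, true_boundary,
          depth = grid$depth[i],
          error_rate = grid$error_rate[i], include_library = FALSE
        )
        infer_boundary(jp,
          expected_nonwt = expected,
          error_floor = max(grid$error_rate[i], error_floor_min)
        )$boundary_hat == true_boundary
      }, logical(1))
      mean(hits)
    }, numeric(1))
  })
  out <- mutate(grid,
    replicates = as.integer(replicates),
    recovery = recovery
  )
  class(out) <- c("power_curve", class(out))
  out
}
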