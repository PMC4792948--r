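# Shared fixtures and independent oracles for the test suite.

default_spec <- function() library_spec(attI1_site())

# Independent boundary search: re-enumerates every candidate boundary and
# takes the argmax (smallest boundary on ties). Shares only the likelihood
# kernel with the estimator under test, per the dual-route design.
brute_force_boundary <- function(pair, expected_nonwt, error_floor = 1e-3,
                                 pseudocount = 0.5) {
  P <- nchar(pair$wt_window)
  ll <- vapply(
    0:P,
    function(b) boundary_loglik(pair, b, expected_nonwt, error_floor, pseudocount),
    numeric(1)
  )
  candidates <- (0:P)[ll >= max(ll) - 1e-8]
  min(candidates)
}

# Build a count-bearing profile tibble from per-position (wt_count, alt_count)
# pairs, using A as the wild-type base and C as the alternative.
profile_from_counts <- function(wt_count, alt_count) {
  P <- length(wt_count)
  dplyr::bind_rows(lapply(seq_len(P), function(i) {
    n <- wt_count[i] + alt_count[i]
    tibble::tibble(
      position = i,
      base = c("A", "C", "G", "T"),
      count = c(wt_count[i], alt_count[i], 0L, 0L),
      freq = c(wt_count[i], alt_count[i], 0L, 0L) / n
    )
  }))
}

# Hamming distances between equal-length reads and one template.
string_dist <- function(x, template) {
  crossmapr:::hamming_to(x, template)
}

# Mirror a junction profile pair: swap left/right products and reverse the
# window order, as in the estimator's symmetry property.
mirror_pair <- function(pair) {
  P <- nchar(pair$wt_window)
  flip <- function(prof) {
    dplyr::arrange(
      dplyr::mutate(prof, position = P + 1L - position),
      position, base
    )
  }
  new_junction_profiles(
    library = if (is.null(pair$library)) NULL else flip(pair$library),
    left = flip(pair$right),
    right = flip(pair$left),
    counts = pair$counts,
    wt_window = paste(rev(strsplit(pair$wt_window, "", fixed = TRUE)[[1]]), collapse = "")
  )
}
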