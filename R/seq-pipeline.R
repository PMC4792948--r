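# Read ingestion pipeline: classify reads into amplicon classes by their
# primer-context anchors, extract the randomized window, filter abnormal
# events, and tally per-position base frequencies.

# Position of the first fuzzy occurrence of `anchor` in each read (NA when
# absent). Returns the 1-based end coordinate of the anchor match.
anchor_match_end <- function(anchor, sequences, max_mismatch) {
  dss <- Biostrings::DNAStringSet(sequences)
  idx <- Biostrings::startIndex(
    Biostrings::vmatchPattern(anchor, dss, max.mismatch = max_mismatch)
  )
  starts <- vapply(
    idx, function(s) if (length(s) > 0L) s[[1L]] else NA_integer_, integer(1)
  )
  starts + nchar(anchor) - 1L
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Classify amplicon reads by their primer-context anchors
#'
#' Assigns every read to the amplicon class (library, left junction site,
#' right junction site) whose left *and* right anchors both occur in the
#' read, in either orientation; reads matching no class, or more than one,
#' are `"unassigned"`. Classification is deterministic. Reads matched in
#' reverse-complement orientation are flagged so the extractor can
#' canonicalize them to the top strand.
#'
#' @param reads A tibble with a `sequence` column (e.g. from
#'   [read_amplicons()] or [simulate_amplicon_pool()]).
#' @param contexts An [amplicon_contexts()] object; anchor pairs must be
#'   pairwise distinguishable (enforced at construction).
#' @param max_anchor_mismatch Substitutions tolerated per anchor.
#' @return `reads` with columns `assigned_class` and `orientation`
#'   (`"fwd"`, `"rev"` or `NA`).
#' @export
classify_reads <- function(reads, contexts, max_anchor_mismatch = 1L) {
  stopifnot(is.data.frame(reads), "sequence" %in% names(reads))
  stopifnot(inherits(contexts, "amplicon_contexts"))
  n <- nrow(reads)
  fwd <- reads$sequence
  rev <- revcomp(fwd)
  hit <- matrix(FALSE, n, length(contexts),
    dimnames = list(NULL, names(contexts))
  )
  ori <- matrix(NA_character_, n, length(contexts))
  for (j in seq_along(contexts)) {
    ctx <- contexts[[j]]
    f <- !is.na(anchor_match_end(ctx$anchor_left, fwd, max_anchor_mismatch)) &
      !is.na(anchor_match_end(ctx$anchor_right, fwd, max_anchor_mismatch))
    r <- !is.na(anchor_match_end(ctx$anchor_left, rev, max_anchor_mismatch)) &
      !is.na(anchor_match_end(ctx$anchor_right, rev, max_anchor_mismatch))
    hit[, j] <- f | r
    ori[, j] <- ifelse(f, "fwd", ifelse(r, "rev", NA_character_))
  }
  n_hits <- rowSums(hit)
  assigned <- rep("unassigned", n)
  orientation <- rep(NA_character_, n)
  one <- n_hits == 1L
  j_hit <- max.col(hit, ties.method = "first")
  assigned[one] <- colnames(hit)[j_hit[one]]
  orientation[one] <- ori[cbind(which(one), j_hit[one])]
  reads$assigned_class <- assigned
  reads$orientation <- orientation
  reads
}

#' Extract the randomized window from classified reads
#'
#' For each read, locates the class left anchor (tolerating
#' `max_anchor_mismatch` substitutions; the reverse complement is tried and
#' canonicalized to the top strand when the forward orientation fails),
#' requires the right anchor at exactly the expected spacing, and reads the
#' window bases at their per-ordinal offsets. Reads failing any step are
#' rejected with a reason:
#' \describe{
#'   \item{`anchor_fail`}{left anchor absent in both orientations, or right
#'     anchor at the expected spacing but with too many mismatches.}
#'   \item{`length_fail`}{read too short for the window or right anchor, or
#'     right anchor found only at a shifted position (indel/chimera).}
#'   \item{`ambiguous_base`}{extracted window contains a non-ACGT base.}
#' }
#'
#' @param reads A tibble with `sequence` and, when `contexts` holds several
#'   classes, an `assigned_class` column (from [classify_reads()]).
#' @param contexts An [amplicon_contexts()] object, or a single anchor-spec
#'   entry of one (then all reads are treated as that class).
#' @param max_anchor_mismatch Substitutions tolerated per anchor.
#' @return `reads` with columns `window` (NA when rejected), `status`
#'   (`"ok"` or `"rejected"`) and `reason`.
#' @export
extract_windows <- function(reads, contexts, max_anchor_mismatch = 1L) {
  stopifnot(is.data.frame(reads), "sequence" %in% names(reads))
  if (inherits(contexts, "amplicon_contexts")) {
    if (!"assigned_class" %in% names(reads)) {
      abort_config(
        "reads must carry an assigned_class column (run classify_reads()) or pass a single anchor spec"
      )
    }
    reads$window <- NA_character_
    reads$status <- "rejected"
    reads$reason <- "anchor_fail"
    for (cls in names(contexts)) {
      sel <- which(reads$assigned_class == cls)
      if (length(sel) == 0L) next
      part <- extract_windows_one(
        reads$sequence[sel], contexts[[cls]], max_anchor_mismatch
      )
      reads$window[sel] <- part$window
      reads$status[sel] <- part$status
      reads$reason[sel] <- part$reason
    }
    unassigned <- reads$assigned_class == "unassigned"
    reads$reason[unassigned] <- "anchor_fail"
    return(reads)
  }
  part <- extract_windows_one(reads$sequence, contexts, max_anchor_mismatch)
  reads$window <- part$window
  reads$status <- part$status
  reads$reason <- part$reason
  reads
}

extract_windows_one <- function(sequences, ctx, max_mismatch) {
  n <- length(sequences)
  window <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  # orient: left anchor forward, else reverse complement, else anchor_fail
  ends <- anchor_match_end(ctx$anchor_left, sequences, max_mismatch)
  misses <- which(is.na(ends))
  if (length(misses) > 0L) {
    rc <- revcomp(sequences[misses])
    rc_ends <- anchor_match_end(ctx$anchor_left, rc, max_mismatch)
    found <- !is.na(rc_ends)
    sequences[misses[found]] <- rc[found]
    ends[misses[found]] <- rc_ends[found]
    reason[misses[!found]] <- "anchor_fail"
  }

  ok <- is.na(reason)
  len <- nchar(sequences)
  # right anchor must sit at exactly the expected spacing
  r_start <- ends + ctx$right_offset
  r_len <- nchar(ctx$anchor_right)
  too_short <- ok & (r_start + r_len - 1L > len)
  reason[too_short] <- "length_fail"
  ok <- is.na(reason)

  if (any(ok)) {
    r_seq <- substr(sequences, r_start, r_start + r_len - 1L)
    dist <- hamming_to(r_seq, ctx$anchor_right)
    bad_right <- ok & (is.na(dist) | dist > max_mismatch)
    if (any(bad_right)) {
      # distinguish spacing failures (anchor present elsewhere) from
      # anchor corruption (absent everywhere)
      elsewhere <- !is.na(
        anchor_match_end(ctx$anchor_right, sequences[bad_right], max_mismatch)
      )
      reason[which(bad_right)[elsewhere]] <- "length_fail"
      reason[which(bad_right)[!elsewhere]] <- "anchor_fail"
    }
  }
  ok <- is.na(reason)

  if (any(ok)) {
    idx <- which(ok)
    offs <- ctx$window_offsets
    m <- matrix(NA_character_, length(idx), length(offs))
    for (k in seq_along(offs)) {
      at <- ends[idx] + offs[k]
      m[, k] <- substr(sequences[idx], at, at)
    }
    w <- matrix_strings(m)
    ambiguous <- !grepl("^[ACGT]+$", w)
    reason[idx[ambiguous]] <- "ambiguous_base"
    window[idx[!ambiguous]] <- w[!ambiguous]
  }

  list(
    window = window,
    status = ifelse(is.na(reason), "ok", "rejected"),
    reason = reason
  )
}

#' Per-position base-frequency profile of extracted windows
#'
#' Tallies base counts at every window ordinal and converts them to
#' frequencies. Frequencies are raw counts over the column total — no
#' pseudocounts — so the descriptive output stays faithful; likelihood-based
#' inference applies its own stabilisation (see [infer_boundary()]).
#'
#' @param windows Character vector of equal-length window strings, or a
#'   tibble with a `window` column (rejected rows with `NA` are dropped).
#' @return A tibble with `position` (window ordinal), `base`, `count`,
#'   `freq`; within each position the frequencies sum to 1.
#' @export
#' @examples
#' profile_positions(c("ACGT", "ACGA", "ACGT"))
profile_positions <- function(windows) {
  if (is.data.frame(windows)) {
    windows <- windows$window
  }
  windows <- windows[!is.na(windows)]
  if (length(windows) == 0L) {
    abort_data("no usable windows to profile")
  }
  P <- nchar(windows[[1L]])
  if (any(nchar(windows) != P)) {
    abort_data("all windows must have the same length")
  }
  m <- string_matrix(windows)
  counts <- vapply(
    DNA_BASES,
    function(b) colSums(m == b),
    numeric(P)
  )
  if (P == 1L) counts <- matrix(counts, nrow = 1L)
  tibble(
    position = rep(seq_len(P), times = 4L),
    base = rep(DNA_BASES, each = P),
    count = as.integer(counts),
    freq = as.numeric(counts / rowSums(counts))
  ) %>% arrange(.data$position, .data$base)
}

#' Junction profile pair
#'
#' Container for the three per-position base-frequency profiles of the
#' crossover-mapping design — the pre-recombination library and the left and
#' right cointegrate junction sites — plus retain/discard bookkeeping and
#' the wild-type window used to call bases non-WT.
#'
#' @param library,left,right Profile tibbles from [profile_positions()]
#'   (`library` may be `NULL`).
#' @param counts Tibble with per-class `retained`/`discarded` read counts.
#' @param wt_window Wild-type window string (P characters).
#' @param discard_log Optional tibble of discard reasons per class.
#' @return An object of class `junction_profiles`.
#' @name junction_profiles
#' @export
new_junction_profiles <- function(library = NULL, left, right, counts = NULL,
                                  wt_window, discard_log = NULL) {
  P <- nchar(wt_window)
  for (prof in list(library, left, right)) {
    if (!is.null(prof) && max(prof$position) != P) {
      abort_data("profile length does not match wt_window length")
    }
  }
  structure(
    list(
      library = library, left = left, right = right,
      counts = counts, wt_window = wt_window,
      discard_log = discard_log
    ),
    class = "junction_profiles"
  )
}

#' Build junction profiles from classified, extracted reads
#'
#' Convenience builder running [profile_positions()] on the retained windows
#' of each amplicon class and recording retained/discarded counts and
#' discard reasons.
#'
#' @param reads A tibble carrying `assigned_class`, `window`, `status`,
#'   `reason` (from [classify_reads()] + [extract_windows()]).
#' @param wt_window Wild-type window string.
#' @return A [junction_profiles] object.
#' @export
junction_profiles <- function(reads, wt_window) {
  stopifnot(all(c("assigned_class", "window", "status") %in% names(reads)))
  prof <- function(cls) {
    w <- reads$window[reads$assigned_class == cls & reads$status == "ok"]
    if (length(w) == 0L) {
      return(NULL)
    }
    profile_positions(w)
  }
  counts <- reads %>%
    group_by(class = .data$assigned_class) %>%
    summarise(
      retained = sum(.data$status == "ok"),
      discarded = sum(.data$status != "ok"),
      .groups = "drop"
    )
  discard_log <- reads %>%
    filter(.data$status != "ok") %>%
    count(class = .data$assigned_class, reason = .data$reason, name = "n")
  new_junction_profiles(
    library = prof("library"),
    left = prof("left_site"),
    right = prof("right_site"),
    counts = counts,
    wt_window = wt_window,
    discard_log = discard_log
  )
}

#' @export
print.junction_profiles <- function(x, ...) {
  P <- nchar(x$wt_window)
  cat("<junction_profiles> P = ", P, ", wild-type window ", x$wt_window, "\n", sep = "")
  for (cls in c("library", "left", "right")) {
    prof <- x[[cls]]
    if (is.null(prof)) next
    nonwt <- nonwt_rates(prof, x$wt_window)
    cat(
      sprintf(
        "  %-8s n = %-8.0f non-WT by position: %s\n",
        cls, sum(prof$count) / P,
        paste(sprintf("%.3f", nonwt$rate), collapse = " ")
      )
    )
  }
  invisible(x)
}

#' @export
tidy.junction_profiles <- function(x, ...) {
  bind_rows(lapply(
    c("library", "left", "right"),
    function(cls) {
      if (is.null(x[[cls]])) {
        return(NULL)
      }
      mutate(x[[cls]], class = cls, .before = 1L)
    }
  ))
}

# Per-position non-WT counts and rates of one profile.
nonwt_rates <- function(profile, wt_window) {
  wt <- strsplit(wt_window, "", fixed = TRUE)[[1]]
  profile %>%
    group_by(.data$position) %>%
    summarise(
      n = sum(.data$count),
      non_wt = sum(.data$count[.data$base != wt[.data$position[1L]]]),
      .groups = "drop"
    ) %>%
    mutate(rate = ifelse(.data$n > 0, .data$non_wt / .data$n, NA_real_))
}
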