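# Forward simulator: library construction, integrase recombination with a
# configurable crossover boundary and HJ-resolution pathway, strand-marker
# tracing for mismatched covalent circles, and sequencing-read generation.

# Evaluate `code` under a fixed RNG seed when one is given.
with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) {
    return(code)
  }
  withr::with_seed(as.integer(seed), code)
}

# Draw n window strings (ordinal order) from the randomization design:
# each molecule picks one position set (mixing weights) and one uniform base.
draw_windows <- function(spec, n) {
  wtw <- wt_window(spec)
  ordinal <- sample.int(spec$P, n, replace = TRUE, prob = spec$mixing)
  base <- sample(spec$alphabet, n, replace = TRUE)
  windows <- paste0(
    substr(rep(wtw, n), 1L, ordinal - 1L),
    base,
    substr(rep(wtw, n), ordinal + 1L, spec$P)
  )
  list(windows = windows, ordinal = ordinal, base = base)
}

#' Draw a randomized site library
#'
#' Simulates the pooled library: every molecule carries exactly one fully
#' random base at one of the P window positions (so it differs from wild type
#' at zero positions, when the random draw happens to be the WT base, or at
#' exactly one). With `exhaustive = TRUE` the nominal library is returned
#' instead: one molecule per (position, base) combination, i.e. `4 * P`
#' molecules (40 for the paper-style P = 10 design).
#'
#' @param spec A [library_spec()].
#' @param n_molecules Number of molecules to draw (ignored when
#'   `exhaustive = TRUE`).
#' @param seed Optional integer seed; identical seeds give identical output.
#' @param exhaustive Return the nominal one-per-variant library.
#' @return A tibble with one row per molecule: `molecule`, `position`
#'   (template coordinate of the randomized base), `ordinal` (window ordinal),
#'   `base` (the drawn base), `window` (P-character window string) and
#'   `sequence` (full top strand).
#' @export
#' @examples
#' spec <- library_spec(attI1_site())
#' nrow(draw_library(spec, exhaustive = TRUE)) # 40
#' draw_library(spec, n_molecules = 5, seed = 1)
draw_library <- function(spec, n_molecules = NULL, seed = NULL, exhaustive = FALSE) {
  stopifnot(inherits(spec, "library_spec"))
  wtw <- wt_window(spec)
  if (exhaustive) {
    grid <- tidyr::expand_grid(ordinal = seq_len(spec$P), base = spec$alphabet)
    ordinal <- grid$ordinal
    base <- grid$base
    windows <- paste0(
      substr(rep(wtw, nrow(grid)), 1L, ordinal - 1L),
      base,
      substr(rep(wtw, nrow(grid)), ordinal + 1L, spec$P)
    )
  } else {
    if (is.null(n_molecules) || length(n_molecules) != 1L ||
      is.na(n_molecules) || n_molecules < 1L) {
      abort_data("n_molecules must be a positive count (or use exhaustive = TRUE)")
    }
    drawn <- with_seed_maybe(seed, draw_windows(spec, as.integer(n_molecules)))
    ordinal <- drawn$ordinal
    base <- drawn$base
    windows <- drawn$windows
  }
  position <- spec$positions[ordinal]
  top <- spec$site$top_strand
  len <- nchar(top)
  tibble(
    molecule = seq_along(windows),
    position = position,
    ordinal = as.integer(ordinal),
    base = base,
    window = windows,
    sequence = paste0(
      substr(rep(top, length(windows)), 1L, position - 1L),
      base,
      substr(rep(top, length(windows)), position + 1L, len)
    )
  )
}

# Reciprocal strand-exchange bookkeeping on window strings, vectorised over
# donors. Left junction = donor ordinals 1..b + recipient b+1..P; right
# junction is the reciprocal partition.
recombine_windows <- function(donor_windows, recipient_window, boundary) {
  P <- nchar(recipient_window)
  n <- length(donor_windows)
  list(
    left = paste0(
      substr(donor_windows, 1L, boundary),
      substr(rep(recipient_window, n), boundary + 1L, P)
    ),
    right = paste0(
      substr(rep(recipient_window, n), 1L, boundary),
      substr(donor_windows, boundary + 1L, P)
    )
  )
}

#' Outcome of a reaction, by pathway and orientation
#'
#' The outcome of one integrase reaction is a pure function of the
#' HJ-resolution pathway and the relative orientation of the partner sites.
#' Intermolecular reactions fuse the two replicons into a cointegrate under
#' every pathway. For intramolecular reactions between direct repeats, both
#' the second strand exchange and replicative resolution excise the
#' intervening segment; between inverted repeats only the second strand
#' exchange is productive (it inverts the segment), while replicative
#' resolution linearizes the replicon and is abortive.
#'
#' @param pathway One of `"second_exchange"`, `"replicative_bs"`,
#'   `"replicative_ts"` (vectorised).
#' @param orientation One of `"intermolecular"`, `"direct"`, `"inverted"`
#'   (vectorised).
#' @return Character vector of outcomes: `"cointegrate"`, `"excision"`,
#'   `"inversion"` or `"abortive_linear"`.
#' @export
#' @examples
#' reaction_outcome("second_exchange", "inverted") # inversion
#' reaction_outcome("replicative_bs", "inverted") # abortive_linear
#' outcome_table()
reaction_outcome <- function(pathway, orientation) {
  ok_p <- pathway %in% c("second_exchange", "replicative_bs", "replicative_ts")
  ok_o <- orientation %in% c("intermolecular", "direct", "inverted")
  if (!all(ok_p) || !all(ok_o)) {
    abort_config("invalid pathway or orientation")
  }
  dplyr::case_when(
    orientation == "intermolecular" ~ "cointegrate",
    orientation == "direct" ~ "excision",
    pathway == "second_exchange" ~ "inversion",
    TRUE ~ "abortive_linear"
  )
}

#' @rdname reaction_outcome
#' @export
outcome_table <- function() {
  grid <- tidyr::expand_grid(
    pathway = c("second_exchange", "replicative_bs", "replicative_ts"),
    orientation = c("intermolecular", "direct", "inverted")
  )
  mutate(grid, outcome = reaction_outcome(.data$pathway, .data$orientation))
}

#' Simulate one recombination event
#'
#' Performs the reciprocal strand-exchange bookkeeping for a single reaction
#' between a library molecule (donor) and a partner site (recipient) at
#' window boundary `b`: under the second strand exchange the left junction
#' site carries donor window ordinals `1..b` and recipient ordinals
#' `b+1..P`, the right junction the reciprocal partition. Under the
#' replicative pathways only one strand of the incoming molecule is
#' transferred and copied, so the randomized window is not split: the left
#' junction carries the full donor window and the right junction the full
#' recipient window.
#'
#' @param donor A P-character window string, or a one-row tibble from
#'   [draw_library()] (its `window` column is used).
#' @param recipient A [site_model()] (its wild-type window and sequence are
#'   used) or a P-character window string.
#' @param boundary Integer window boundary `b` in `0..P`.
#' @param pathway,orientation Reaction enums; see [reaction_outcome()].
#' @param site Optional `site_model` used to build full-length product
#'   sequences when `recipient` is given as a bare window string.
#' @return A `recombination_event`: a list with the donor/recipient windows,
#'   `boundary`, `pathway`, `orientation`, `left_window`, `right_window`,
#'   full `left_site`/`right_site` sequences (when a site is available) and
#'   the `outcome` label.
#' @export
#' @examples
#' spec <- library_spec(attI1_site())
#' mol <- draw_library(spec, 1, seed = 42)
#' recombine(mol, attI1_AAA_site(), boundary = 7)
recombine <- function(donor, recipient, boundary,
                      pathway = c("second_exchange", "replicative_bs", "replicative_ts"),
                      orientation = c("intermolecular", "direct", "inverted"),
                      site = NULL) {
  pathway <- match.arg(pathway)
  orientation <- match.arg(orientation)
  donor_window <- if (is.data.frame(donor)) donor$window[[1L]] else as.character(donor)
  if (inherits(recipient, "site_model")) {
    site <- site %||% recipient
    recipient_window <- wt_window(recipient)
  } else {
    recipient_window <- as.character(recipient)
  }
  P <- nchar(recipient_window)
  if (nchar(donor_window) != P) {
    abort_coordinate("donor and recipient windows must have the same length P")
  }
  if (length(boundary) != 1L || is.na(boundary) || boundary < 0L || boundary > P) {
    abort_coordinate(paste0("boundary must lie in 0..", P))
  }
  boundary <- as.integer(boundary)
  if (pathway == "second_exchange") {
    prods <- recombine_windows(donor_window, recipient_window, boundary)
  } else {
    prods <- list(left = donor_window, right = recipient_window)
  }
  ev <- list(
    donor_window = donor_window,
    recipient_window = recipient_window,
    boundary = boundary,
    pathway = pathway,
    orientation = orientation,
    left_window = prods$left,
    right_window = prods$right,
    left_site = NULL,
    right_site = NULL,
    outcome = reaction_outcome(pathway, orientation)
  )
  if (!is.null(site)) {
    ev$left_site <- substitute_window(site, prods$left)
    ev$right_site <- substitute_window(site, prods$right)
  }
  structure(ev, class = "recombination_event")
}

#' @export
print.recombination_event <- function(x, ...) {
  cat("<recombination_event> ", x$pathway, " / ", x$orientation,
    " -> ", x$outcome, "\n",
    sep = ""
  )
  cat("  boundary b = ", x$boundary, "\n", sep = "")
  cat("  donor  window: ", x$donor_window, "\n", sep = "")
  cat("  recip. window: ", x$recipient_window, "\n", sep = "")
  cat("  left   window: ", x$left_window, "\n", sep = "")
  cat("  right  window: ", x$right_window, "\n", sep = "")
  invisible(x)
}

# Write window characters into a site's top strand at its window positions.
substitute_window <- function(site, windows) {
  pos <- site$randomized_window
  n <- length(windows)
  chars <- strsplit(site$top_strand, "", fixed = TRUE)[[1]]
  m <- matrix(chars, nrow = n, ncol = length(chars), byrow = TRUE)
  m[, pos] <- string_matrix(windows)
  matrix_strings(m)
}

# i.i.d. per-base substitution errors on equal-length strings; a hit base is
# rotated to one of the three other bases, so an "error" always changes it.
apply_substitution_errors <- function(x, error_rate) {
  if (length(x) == 0L || error_rate <= 0) {
    return(x)
  }
  m <- string_matrix(x)
  hit <- which(runif(length(m)) < error_rate)
  if (length(hit) > 0L) {
    idx <- match(m[hit], DNA_BASES)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    ok <- !is.na(idx)
    m[hit[ok]] <- DNA_BASES[((idx[ok] - 1L + shift[ok]) %% 4L) + 1L]
  }
  matrix_strings(m)
}

#' Trace the strand markers of a mismatched covalent circle
#'
#' A mismatched covalent circle tags its two strands with strand-specific
#' restriction-site mutations (SacII on one strand, NarI on the other), so
#' the restriction profile of recombinant clones reveals which strand was
#' transferred. Transfer and replication of the bottom strand yields a
#' homogeneous SacII+/NarI- clone population, the top strand a homogeneous
#' SacII-/NarI+ one. Resolution through a second strand exchange transfers
#' both mismatches, so the replicated clone carries a mixed plasmid
#' population and shows partial restriction profiles with both enzymes.
#'
#' @param pathway One of `"second_exchange"`, `"replicative_bs"`,
#'   `"replicative_ts"`.
#' @param n_clones Number of clones in the reported population.
#' @return A tibble with one row per clone: `clone`, `pathway`, `sacII` and
#'   `narI` (`"+"`, `"-"` or `"partial"`), `marker_class` and `population`
#'   (`"homogeneous"` or `"mixed"`). Deterministic.
#' @export
#' @examples
#' unique(trace_circle_markers("replicative_bs")$marker_class)
trace_circle_markers <- function(pathway = c(
                                   "second_exchange",
                                   "replicative_bs", "replicative_ts"
                                 ),
                                 n_clones = 100L) {
  pathway <- match.arg(pathway)
  prof <- switch(pathway,
    replicative_bs = list(sacII = "+", narI = "-", pop = "homogeneous"),
    replicative_ts = list(sacII = "-", narI = "+", pop = "homogeneous"),
    second_exchange = list(sacII = "partial", narI = "partial", pop = "mixed")
  )
  marker_class <- if (prof$pop == "mixed") {
    "mixed"
  } else {
    paste0("SacII", prof$sacII, "/NarI", prof$narI)
  }
  tibble(
    clone = seq_len(n_clones),
    pathway = pathway,
    sacII = prof$sacII,
    narI = prof$narI,
    marker_class = marker_class,
    population = prof$pop
  )
}

#' Simulate single-strand transfer of mismatched circles
#'
#' Models the control experiment in which circles replicate without
#' recombining: each clone derives from one of the two transferred strands,
#' drawn with bottom-strand probability `bs_prob` (default 0.5, the
#' "no clear strand bias" case). A small `anomaly_rate` assigns clones to the
#' double-positive/double-negative classes seen at ~1% each in the wet
#' control (circle-assembly artifacts); it defaults to 0 since those classes
#' are not part of the strand-reactivity model.
#'
#' @param n_clones Number of clones.
#' @param bs_prob Probability that a clone derives from the bottom strand.
#' @param anomaly_rate Probability of an anomalous (double +/+ or -/-) clone.
#' @param seed Optional integer seed.
#' @return A tibble with `clone`, `strand` (`"bs"`, `"ts"` or `"anomaly"`)
#'   and `marker_class` (`"NarI-/SacII+"`, `"NarI+/SacII-"`,
#'   `"NarI+/SacII+"`, `"NarI-/SacII-"`).
#' @seealso [profile_summary()]
#' @export
#' @examples
#' profile_summary(simulate_strand_transfer(101, seed = 1))
simulate_strand_transfer <- function(n_clones, bs_prob = 0.5, anomaly_rate = 0,
                                     seed = NULL) {
  if (n_clones < 1L) abort_data("n_clones must be positive")
  stopifnot(bs_prob >= 0, bs_prob <= 1, anomaly_rate >= 0, anomaly_rate < 1)
  with_seed_maybe(seed, {
    strand <- sample(c("bs", "ts"), n_clones,
      replace = TRUE,
      prob = c(bs_prob, 1 - bs_prob)
    )
    marker_class <- ifelse(strand == "bs", "NarI-/SacII+", "NarI+/SacII-")
    if (anomaly_rate > 0) {
      odd <- runif(n_clones) < anomaly_rate
      if (any(odd)) {
        marker_class[odd] <- sample(c("NarI+/SacII+", "NarI-/SacII-"),
          sum(odd),
          replace = TRUE
        )
        strand[odd] <- "anomaly"
      }
    }
    tibble(clone = seq_len(n_clones), strand = strand, marker_class = marker_class)
  })
}

#' Fast count-level simulation of cointegrate junction profiles
#'
#' Runs library draw, reciprocal recombination at a fixed window boundary and
#' substitution sequencing error entirely at the window level, and tallies
#' the per-position base frequencies of the pre-recombination library and the
#' left/right junction sites. This is the count-level twin of the full FASTQ
#' pipeline ([simulate_amplicon_pool()] + [classify_reads()] +
#' [extract_windows()]): it skips read anchoring and filtering, which makes
#' parameter-recovery studies over thousands of replicates cheap.
#'
#' @param spec A [library_spec()].
#' @param boundary True window boundary `b` in `0..P`.
#' @param depth Number of molecules sequenced per junction site.
#' @param error_rate Per-base substitution error rate.
#' @param seed Optional integer seed.
#' @param recipient Partner site: a `site_model` or P-character window; the
#'   donor site's wild-type window by default.
#' @param include_library Also draw and profile a pre-recombination library
#'   pool of `library_depth` molecules.
#' @param library_depth Depth of the library pool.
#' @return A [junction_profiles] object.
#' @export
#' @examples
#' spec <- library_spec(attI1_site())
#' jp <- simulate_junction_profiles(spec, boundary = 7, depth = 2000, seed = 1)
#' infer_boundary(jp)
simulate_junction_profiles <- function(spec, boundary, depth,
                                       error_rate = 0.001, seed = NULL,
                                       recipient = NULL,
                                       include_library = TRUE,
                                       library_depth = depth) {
  stopifnot(inherits(spec, "library_spec"))
  if (depth < 1L) abort_data("depth must be positive")
  if (length(boundary) != 1L || is.na(boundary) ||
    boundary < 0L || boundary > spec$P) {
    abort_coordinate(paste0("boundary must lie in 0..", spec$P))
  }
  recipient_window <- if (is.null(recipient)) {
    wt_window(spec)
  } else if (inherits(recipient, "site_model")) {
    wt_window(recipient)
  } else {
    as.character(recipient)
  }
  with_seed_maybe(seed, {
    lib_profile <- NULL
    if (include_library) {
      lib <- apply_substitution_errors(
        draw_windows(spec, as.integer(library_depth))$windows, error_rate
      )
      lib_profile <- profile_positions(lib)
    }
    donors <- draw_windows(spec, as.integer(depth))$windows
    prods <- recombine_windows(donors, recipient_window, as.integer(boundary))
    left <- profile_positions(apply_substitution_errors(prods$left, error_rate))
    right <- profile_positions(apply_substitution_errors(prods$right, error_rate))
    counts <- tibble(
      class = c(
        if (include_library) "library",
        "left_site", "right_site"
      ),
      retained = c(
        if (include_library) as.integer(library_depth),
        as.integer(depth), as.integer(depth)
      ),
      discarded = 0L
    )
    new_junction_profiles(
      library = lib_profile, left = left, right = right,
      counts = counts, wt_window = wt_window(spec)
    )
  })
}
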