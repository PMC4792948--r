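# Read-level simulation: amplicon construction per sequencing class,
# substitution error, abnormal-read corruption, and FASTQ-ready read tables.

# Fixed synthetic primer contexts distinguishing the three amplicon classes
# (library, left junction site, right junction site). 20-mers, pairwise very
# dissimilar so one substitution error can never flip a class.
default_flanks <- function() {
  list(
    library = c(
      left = "AGCGTCAGTTGCAGGACTTC",
      right = "CTGGAGTTCACGTTAGCCTG"
    ),
    left_site = c(
      left = "TACGGATCCTTGCACTGAGA",
      right = "GATCCAGTTGGCTAACGTCA"
    ),
    right_site = c(
      left = "CCATGACGTTAGGCTTCAGT",
      right = "TGCAACTGGATCGTTACAGG"
    )
  )
}

#' Amplicon anchors for read classification and window extraction
#'
#' Describes, for each sequencing class (pre-recombination library, left
#' junction site, right junction site), the amplicon built around the site
#' core: a class-specific left primer context, the site core spanning all
#' randomized window positions, and a class-specific right primer context.
#' The left flank is used as the left anchor; the first 12 bases of the right
#' flank as the right anchor. Window positions are stored as offsets after
#' the left anchor end, so extraction works for non-contiguous windows.
#'
#' @param site A [site_model()].
#' @param flanks Named list (`library`, `left_site`, `right_site`) of
#'   `c(left =, right =)` flank sequences; synthetic defaults are bundled.
#' @param anchor_right_length Length of the right anchor taken from the
#'   right flank.
#' @return An `amplicon_contexts` object: a named list of per-class anchor
#'   specs with fields `left_flank`, `right_flank`, `anchor_left`,
#'   `anchor_right`, `window_offsets`, `right_offset`, `core_start`,
#'   `core_end`.
#' @export
amplicon_contexts <- function(site, flanks = default_flanks(),
                              anchor_right_length = 12L) {
  stopifnot(inherits(site, "site_model"))
  pos <- site$randomized_window
  core_start <- min(pos)
  core_end <- max(pos)
  core_len <- core_end - core_start + 1L
  ctx <- lapply(flanks, function(fl) {
    list(
      left_flank = unname(fl[["left"]]),
      right_flank = unname(fl[["right"]]),
      anchor_left = unname(fl[["left"]]),
      anchor_right = substr(unname(fl[["right"]]), 1L, anchor_right_length),
      window_offsets = pos - core_start + 1L,
      right_offset = core_len + 1L,
      core_start = core_start,
      core_end = core_end
    )
  })
  keys <- vapply(ctx, function(e) paste(e$anchor_left, e$anchor_right), character(1))
  if (anyDuplicated(keys)) {
    abort_config("amplicon classes must have distinguishable anchor pairs")
  }
  structure(ctx, class = "amplicon_contexts", site_core = c(core_start, core_end))
}

# Build amplicon sequences for one class: left flank + core carrying the
# given windows + right flank.
build_amplicons <- function(windows, site, context) {
  core_wt <- substr(site$top_strand, context$core_start, context$core_end)
  n <- length(windows)
  m <- matrix(strsplit(core_wt, "", fixed = TRUE)[[1]],
    nrow = n, ncol = nchar(core_wt), byrow = TRUE
  )
  m[, context$window_offsets] <- string_matrix(windows)
  paste0(context$left_flank, matrix_strings(m), context$right_flank)
}

#' Simulate sequencing reads from template molecules
#'
#' Each read is one template drawn (with replacement) from its class pool,
#' with i.i.d. per-base substitution errors at `error_rate`, and — for a
#' fraction `abnormal_fraction` of reads — one of three synthetic corruption
#' modes standing in for abnormal recombination events and library artifacts:
#' `truncate` (the read loses its 3' end including the right anchor),
#' `anchor_mutate` (three substitutions in the left anchor) and `chimera`
#' (the read switches template mid-core with a 3-base deletion at the
#' junction). All three are built to fail the default anchor/spacing filters,
#' so injected corruption labels can be compared against filter decisions.
#' These modes are this simulator's own taxonomy, not an observed error
#' model.
#'
#' @param products A tibble with columns `class` and `template` (one row per
#'   template molecule).
#' @param depth Reads per class.
#' @param error_rate Per-base substitution probability (`0 <= e < 1`).
#' @param abnormal_fraction Fraction of reads corrupted (`0 <= a < 1`).
#' @param seed Optional integer seed; identical seeds give byte-identical
#'   read sets.
#' @param phred Constant Phred quality emitted for every base (Phred+33).
#' @param geometry Flank geometry used by the corruption modes:
#'   `list(left_flank_len =, right_flank_len =)`.
#' @return A tibble with `read_id`, `class`, `sequence`, `quality`,
#'   `abnormal` and `corruption` (`NA` for normal reads).
#' @export
simulate_reads <- function(products, depth, error_rate = 0,
                           abnormal_fraction = 0, seed = NULL, phred = 40L,
                           geometry = list(left_flank_len = 20L, right_flank_len = 20L)) {
  stopifnot(is.data.frame(products), all(c("class", "template") %in% names(products)))
  if (depth < 1L) abort_data("depth must be positive")
  if (error_rate < 0 || error_rate >= 1 || abnormal_fraction < 0 || abnormal_fraction >= 1) {
    abort_config("error_rate and abnormal_fraction must lie in [0, 1)")
  }
  with_seed_maybe(seed, {
    out <- lapply(split(products$template, products$class), function(pool) {
      idx <- sample.int(length(pool), depth, replace = TRUE)
      seqs <- apply_substitution_errors(pool[idx], error_rate)
      abnormal <- runif(depth) < abnormal_fraction
      corruption <- rep(NA_character_, depth)
      if (any(abnormal)) {
        corruption[abnormal] <- sample(c("truncate", "anchor_mutate", "chimera"),
          sum(abnormal),
          replace = TRUE
        )
        seqs[abnormal] <- corrupt_reads(
          seqs[abnormal], corruption[abnormal], pool, geometry
        )
      }
      tibble(sequence = seqs, abnormal = abnormal, corruption = corruption)
    })
    classes <- names(out)
    reads <- bind_rows(out)
    reads$class <- rep(classes, each = depth)
    reads$read_id <- paste0(
      reads$class, "_",
      formatC(rep(seq_len(depth), times = length(classes)),
        width = nchar(depth), flag = "0"
      )
    )
    reads$quality <- strrep(rawToChar(as.raw(33L + as.integer(phred))), nchar(reads$sequence))
    select(
      reads, "read_id", "class", "sequence", "quality", "abnormal", "corruption"
    )
  })
}

# Apply one corruption mode per read. Each mode is designed to be caught by
# the default filters (anchor match + exact spacing).
corrupt_reads <- function(seqs, modes, pool, geometry) {
  lf <- geometry$left_flank_len
  rf <- geometry$right_flank_len
  n <- length(seqs)
  for (i in seq_len(n)) {
    len <- nchar(seqs[i])
    seqs[i] <- switch(modes[i],
      truncate = {
        # lose the 3' end including the whole right anchor
        substr(seqs[i], 1L, sample(seq.int(lf + 5L, len - rf), 1L))
      },
      anchor_mutate = {
        # three substitutions inside the left anchor (> any sane threshold)
        chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        at <- sample.int(lf, 3L)
        idx <- match(chars[at], DNA_BASES)
        chars[at] <- DNA_BASES[(idx %% 4L) + 1L]
        paste(chars, collapse = "")
      },
      chimera = {
        # switch template mid-core with a 3-nt deletion at the junction
        partner <- pool[[sample.int(length(pool), 1L)]]
        s <- sample(seq.int(lf + 3L, len - rf - 6L), 1L)
        paste0(substr(seqs[i], 1L, s), substr(partner, s + 4L, nchar(partner)))
      }
    )
  }
  seqs
}

#' Simulate a full amplicon sequencing pool
#'
#' End-to-end fixture generator for the crossover-mapping design: draws the
#' randomized library, recombines a fresh draw of donor molecules with the
#' recipient site at the given window boundary (second strand exchange),
#' builds class-specific amplicons for the pre-recombination library and the
#' two cointegrate junction sites, and sequences each class at `depth` with
#' substitution error and optional abnormal-read corruption.
#'
#' @inheritParams simulate_reads
#' @inheritParams simulate_junction_profiles
#' @param contexts An [amplicon_contexts()] object.
#' @return A tibble of reads as from [simulate_reads()]; the `class` column
#'   is the simulation truth label.
#' @export
#' @examples
#' spec <- library_spec(attI1_site())
#' reads <- simulate_amplicon_pool(spec,
#'   boundary = 7, depth = 200,
#'   error_rate = 0.001, seed = 1
#' )
#' dplyr::count(reads, class)
simulate_amplicon_pool <- function(spec, boundary, depth, error_rate = 0.001,
                                   abnormal_fraction = 0, seed = NULL,
                                   recipient = NULL,
                                   contexts = amplicon_contexts(spec$site),
                                   library_depth = depth) {
  stopifnot(inherits(spec, "library_spec"))
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
  site <- spec$site
  with_seed_maybe(seed, {
    lib_windows <- draw_windows(spec, as.integer(library_depth))$windows
    donors <- draw_windows(spec, as.integer(depth))$windows
    prods <- recombine_windows(donors, recipient_window, as.integer(boundary))
    products <- bind_rows(
      tibble(class = "library", template = build_amplicons(lib_windows, site, contexts$library)),
      tibble(class = "left_site", template = build_amplicons(prods$left, site, contexts$left_site)),
      tibble(class = "right_site", template = build_amplicons(prods$right, site, contexts$right_site))
    )
    geometry <- list(
      left_flank_len = nchar(contexts$library$left_flank),
      right_flank_len = nchar(contexts$library$right_flank)
    )
    simulate_reads(products, depth,
      error_rate = error_rate,
      abnormal_fraction = abnormal_fraction, geometry = geometry
    )
  })
}
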