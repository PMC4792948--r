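#' Describe a double-stranded recombination site
#'
#' A site model is the shared coordinate frame of the package: the top strand
#' written 5'->3', the two integrase-binding boxes (R and L) as 1-based
#' inclusive intervals on that strand, the known bottom-strand crossover
#' boundary, an optional top-strand crossover boundary (the inference target),
#' and the ordered list of template positions eligible for randomization.
#'
#' Crossover points are *boundaries*, not positions: a boundary index `k`
#' means "between template base `k` and `k + 1`". The randomized window is an
#' ordered list of template positions and need not be contiguous (in the
#' bundled attI1-like site the R-box crossover base is separated from the
#' L box by non-randomized spacer bases). Window *ordinals* 1..P index the
#' window positions in template order, and window boundaries `b` in 0..P mean
#' "between window ordinals `b` and `b + 1`" (`b = 0` and `b = P` place the
#' exchange entirely outside the window).
#'
#' @param name Identifier for the site.
#' @param top_strand Top-strand sequence, 5'->3', A/C/G/T only.
#' @param r_box,l_box Integer length-2 vectors, 1-based inclusive intervals.
#' @param bs_crossover Boundary index of the bottom-strand exchange point
#'   mapped to top-strand coordinates (between base `k` and `k + 1`).
#' @param ts_crossover Optional window boundary (0..P) of the top-strand
#'   crossover; `NA` when unknown before inference.
#' @param randomized_window Ordered integer vector of template positions
#'   eligible for randomization.
#'
#' @return An object of class `site_model`.
#' @seealso [validate_site()], [attI1_site()], [library_spec()]
#' @export
#' @examples
#' site <- attI1_site()
#' site
#' validate_site(site)
site_model <- function(name, top_strand, r_box, l_box, bs_crossover,
                       ts_crossover = NA_integer_, randomized_window) {
  structure(
    list(
      name = as.character(name),
      top_strand = toupper(as.character(top_strand)),
      r_box = as.integer(r_box),
      l_box = as.integer(l_box),
      bs_crossover = as.integer(bs_crossover),
      ts_crossover = as.integer(ts_crossover),
      randomized_window = as.integer(randomized_window)
    ),
    class = "site_model"
  )
}

#' @export
print.site_model <- function(x, ...) {
  cat("<site_model> ", x$name, "\n", sep = "")
  cat("  top strand (", nchar(x$top_strand), " nt): ", x$top_strand, "\n", sep = "")
  cat("  R box: ", x$r_box[1], "-", x$r_box[2],
    "   L box: ", x$l_box[1], "-", x$l_box[2], "\n",
    sep = ""
  )
  cat("  bs crossover boundary (template): ", x$bs_crossover, "\n", sep = "")
  cat("  ts crossover boundary (window):   ",
    if (is.na(x$ts_crossover)) "unknown" else x$ts_crossover, "\n",
    sep = ""
  )
  cat("  randomized window (P = ", length(x$randomized_window), "): ",
    paste(x$randomized_window, collapse = ","), "\n",
    sep = ""
  )
  invisible(x)
}

#' Bundled attI1-like site
#'
#' The default site used throughout: an integron attI1-like architecture with
#' the L box `5'-CCCTAAA-3'`, two adjacent spacer base pairs, and an R box
#' whose bottom-strand crossover triplet is `5'-AAC-3'`. The randomized window
#' is the paper-style P = 10 design: the seven L-box positions, the two spacer
#' positions adjacent to the L box, and the crossover C of the R box. The
#' flanking sequence is a documented synthetic placeholder (the exact genomic
#' flanks are not part of the model); every coordinate is configurable through
#' [site_model()].
#'
#' With this layout the top strand reads `...CCCTAAA AC...`, so the site
#' carries a second `5'-AAC-3'` triplet at the L-box border (window ordinals
#' 7, 8, 9). The top-strand crossover sits between the two adenines of that
#' triplet, i.e. at window boundary `b = 7`, which is the bundled default
#' `ts_crossover`.
#'
#' @return A `site_model`.
#' @export
#' @examples
#' attI1_site()$ts_crossover
attI1_site <- function() {
  # layout (template coords):
  #   1-20   synthetic left flank
  #   21-27  L box CCCTAAA          (window ordinals 1-7)
  #   28-29  spacer AC              (window ordinals 8-9)
  #   30-33  spacer AAAG
  #   34-40  R box TTAACGC, bs crossover AA|C at boundary 37, C at 38
  #          (window ordinal 10)
  #   41-60  synthetic right flank
  site_model(
    name = "attI1_synthetic",
    top_strand = paste0(
      "TGCAGGTCATCGGATCCAAG",
      "CCCTAAA", "AC", "AAAG", "TTAACGC",
      "GTCCTAGGAGATCTACCGTT"
    ),
    r_box = c(34L, 40L),
    l_box = c(21L, 27L),
    bs_crossover = 37L,
    ts_crossover = 7L,
    randomized_window = c(21:29, 38L)
  )
}

#' Bottom-strand-dead attI1 variant
#'
#' The attI1_AAA partner site: the crossover C of the R box is mutated to A
#' (bottom-strand triplet AAC -> AAA), which kills bottom-strand exchange and
#' forces the reaction through the top strand. Used as the recipient in the
#' crossover-mapping design.
#'
#' @return A `site_model`.
#' @export
attI1_AAA_site <- function() {
  site <- attI1_site()
  cross_base <- site$bs_crossover + 1L
  substr(site$top_strand, cross_base, cross_base) <- "A"
  site$name <- "attI1_AAA_synthetic"
  site
}

#' Validate a site model
#'
#' Checks the structural invariants of a [site_model()] and returns the
#' violations as a tibble (empty when the site is well formed). Violations are
#' returned, never raised, so a loader can report all problems at once.
#'
#' Invariants: the top strand contains only A/C/G/T; the R and L boxes are
#' in-range, ordered and non-overlapping; crossover boundaries are in range;
#' the randomized window is strictly increasing and every window position lies
#' within the L box, the two spacer positions adjacent to the L box (on the
#' side facing the R box), or the R-box crossover base.
#'
#' @param site A `site_model`.
#' @return A tibble with columns `invariant`, `position`, `message`;
#'   zero rows iff the site is valid.
#' @export
#' @examples
#' bad <- attI1_site()
#' bad$randomized_window <- c(bad$randomized_window, 55L)
#' validate_site(bad)
validate_site <- function(site) {
  stopifnot(inherits(site, "site_model"))
  v <- list()
  add <- function(invariant, position, message) {
    v[[length(v) + 1L]] <<- tibble(
      invariant = invariant, position = as.integer(position), message = message
    )
  }
  len <- nchar(site$top_strand)

  bad_chars <- setdiff(unique(strsplit(site$top_strand, "", fixed = TRUE)[[1]]), DNA_BASES)
  if (length(bad_chars) > 0L) {
    pos <- which(!strsplit(site$top_strand, "", fixed = TRUE)[[1]] %in% DNA_BASES)[1L]
    add(
      "alphabet", pos,
      paste0(
        "top_strand contains non-ACGT character(s): ",
        paste(bad_chars, collapse = ", ")
      )
    )
  }

  check_box <- function(box, label) {
    if (length(box) != 2L || anyNA(box) || box[1] > box[2] ||
      box[1] < 1L || box[2] > len) {
      add(
        "box_interval", box[1],
        paste0(label, " interval is not a valid 1-based interval on top_strand")
      )
      return(FALSE)
    }
    TRUE
  }
  r_ok <- check_box(site$r_box, "r_box")
  l_ok <- check_box(site$l_box, "l_box")
  if (r_ok && l_ok &&
    site$r_box[1] <= site$l_box[2] && site$l_box[1] <= site$r_box[2]) {
    add("box_overlap", site$r_box[1], "r_box and l_box overlap")
  }

  if (is.na(site$bs_crossover) || site$bs_crossover < 0L || site$bs_crossover > len) {
    add(
      "bs_crossover", site$bs_crossover,
      "bs_crossover boundary is outside 0..length(top_strand)"
    )
  }

  w <- site$randomized_window
  if (length(w) == 0L || anyNA(w)) {
    add("window_defined", NA_integer_, "randomized_window is empty or has NA positions")
  } else {
    if (is.unsorted(w, strictly = TRUE)) {
      add(
        "window_order", w[which(diff(w) <= 0)[1] + 1L],
        "randomized_window positions must be strictly increasing"
      )
    }
    if (!is.na(site$ts_crossover) &&
      (site$ts_crossover < 0L || site$ts_crossover > length(w))) {
      add(
        "ts_crossover", site$ts_crossover,
        "ts_crossover window boundary is outside 0..P"
      )
    }
    if (r_ok && l_ok) {
      allowed <- eligible_window_positions(site)
      for (pos in setdiff(w, allowed)) {
        add(
          "window_eligibility", pos,
          paste0(
            "window position ", pos, " is outside the L box, its two ",
            "spacer-adjacent positions, and the R-box crossover base"
          )
        )
      }
    }
  }

  if (length(v) == 0L) {
    tibble(invariant = character(), position = integer(), message = character())
  } else {
    bind_rows(v)
  }
}

# Template positions where randomization is allowed: the L box, the two spacer
# positions adjacent to it on the side facing the R box, and the base 3' of
# the bottom-strand crossover boundary (the crossover C of the R box).
eligible_window_positions <- function(site) {
  l <- site$l_box
  spacer <- if (site$r_box[1] > l[2]) c(l[2] + 1L, l[2] + 2L) else c(l[1] - 2L, l[1] - 1L)
  sort(unique(c(seq.int(l[1], l[2]), spacer, site$bs_crossover + 1L)))
}

#' Randomization design of a site library
#'
#' A library spec records how the randomized library was built: each molecule
#' carries exactly one fully random base (drawn uniformly from the alphabet,
#' so 1/4 of "randomized" molecules are in fact wild type) at one of the P
#' window positions, and the P single-position sets are mixed with weights
#' `mixing` (uniform 1/P by default, matching the paper-style pooled design).
#'
#' @param site A [site_model()].
#' @param positions Template positions randomized; defaults to the site's
#'   `randomized_window`.
#' @param alphabet Base alphabet (size 4).
#' @param mixing Per-position-set mixing weights; must sum to 1.
#' @return An object of class `library_spec` with fields `site`, `positions`,
#'   `alphabet`, `mixing` and `P`.
#' @export
#' @examples
#' spec <- library_spec(attI1_site())
#' spec$P
library_spec <- function(site, positions = site$randomized_window,
                         alphabet = DNA_BASES,
                         mixing = rep(1 / length(positions), length(positions))) {
  stopifnot(inherits(site, "site_model"))
  positions <- as.integer(positions)
  if (length(positions) < 1L) {
    abort_config("library_spec needs at least one randomized position")
  }
  if (length(alphabet) != 4L || anyDuplicated(alphabet)) {
    abort_config("alphabet must be 4 distinct bases")
  }
  if (length(mixing) != length(positions) || any(mixing < 0) ||
    abs(sum(mixing) - 1) > 1e-8) {
    abort_config("mixing must be a probability vector over the P position sets")
  }
  if (any(positions < 1L) || any(positions > nchar(site$top_strand))) {
    abort_coordinate("randomized positions fall outside the site sequence")
  }
  structure(
    list(
      site = site, positions = positions, alphabet = as.character(alphabet),
      mixing = as.numeric(mixing), P = length(positions)
    ),
    class = "library_spec"
  )
}

#' @export
print.library_spec <- function(x, ...) {
  cat("<library_spec> ", x$site$name, ": P = ", x$P,
    " randomized positions (", paste(x$positions, collapse = ","), ")\n",
    sep = ""
  )
  cat(
    "  per-molecule: one fully random base; mixing ",
    if (length(unique(round(x$mixing, 12))) == 1L) "uniform 1/P" else "non-uniform",
    "\n",
    sep = ""
  )
  invisible(x)
}

# Wild-type bases of the window, in ordinal order, as one P-character string.
wt_window <- function(spec) {
  site <- if (inherits(spec, "library_spec")) spec$site else spec
  pos <- if (inherits(spec, "library_spec")) spec$positions else site$randomized_window
  paste(strsplit(site$top_strand, "", fixed = TRUE)[[1]][pos], collapse = "")
}

#' Expected per-base distribution at a site position
#'
#' Closed-form marginal base distribution of the pooled library at one
#' template position. For a randomized position carried by position set `j`
#' with mixing weight `w_j`, a molecule is non-wild-type there with
#' probability `w_j * 3/4` (it must belong to set `j` and draw one of the
#' three non-WT bases); each non-WT base has probability `w_j / 4`. Under the
#' uniform P-set design this is the paper-style `1 - (3/4)/P` wild type
#' (92.5% for P = 10, each other base 2.5%). Non-randomized positions are
#' wild type with probability 1.
#'
#' @param spec A [library_spec()].
#' @param position Template position (1-based) on the site top strand.
#' @return A tibble with columns `position`, `base`, `prob`, `is_wt`;
#'   `prob` sums to 1.
#' @export
#' @examples
#' spec <- library_spec(attI1_site())
#' expected_position_distribution(spec, spec$positions[1])
expected_position_distribution <- function(spec, position) {
  stopifnot(inherits(spec, "library_spec"))
  position <- as.integer(position)
  if (length(position) != 1L || is.na(position) ||
    position < 1L || position > nchar(spec$site$top_strand)) {
    abort_coordinate("position must be a single index within the site sequence")
  }
  wt <- substr(spec$site$top_strand, position, position)
  j <- match(position, spec$positions)
  w <- if (is.na(j)) 0 else spec$mixing[j]
  prob <- rep(w / 4, 4)
  names(prob) <- spec$alphabet
  prob[wt] <- 1 - w * 3 / 4
  tibble(
    position = position,
    base = spec$alphabet,
    prob = unname(prob[spec$alphabet]),
    is_wt = spec$alphabet == wt
  )
}

#' Read or write a site definition as a plain-text config
#'
#' Sites are stored in DCF (`key: value`) format with intervals written as
#' `start-end` and the window as a comma-separated list of positions or
#' ranges (e.g. `21-29,38`). `read_site_config()` validates the result with
#' [validate_site()] and raises a configuration error naming each violated
#' invariant.
#'
#' @param path File path.
#' @param site A `site_model` (for writing).
#' @return `read_site_config()` returns a `site_model`;
#'   `write_site_config()` returns `path` invisibly.
#' @export
read_site_config <- function(path) {
  d <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  need <- c("name", "top_strand", "r_box", "l_box", "bs_crossover", "randomized_window")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0L) {
    abort_config(paste0(
      "site config is missing field(s): ", paste(missing, collapse = ", ")
    ))
  }
  site <- site_model(
    name = d$name,
    top_strand = gsub("[[:space:]]", "", d$top_strand),
    r_box = parse_interval(d$r_box),
    l_box = parse_interval(d$l_box),
    bs_crossover = as.integer(d$bs_crossover),
    ts_crossover = if (is.null(d$ts_crossover)) NA_integer_ else as.integer(d$ts_crossover),
    randomized_window = parse_positions(d$randomized_window)
  )
  bad <- validate_site(site)
  if (nrow(bad) > 0L) {
    abort_config(paste0(
      "site config violates invariant(s): ",
      paste(unique(bad$invariant), collapse = ", ")
    ))
  }
  site
}

#' @rdname read_site_config
#' @export
write_site_config <- function(site, path) {
  stopifnot(inherits(site, "site_model"))
  m <- cbind(
    name = site$name,
    top_strand = site$top_strand,
    r_box = paste0(site$r_box[1], "-", site$r_box[2]),
    l_box = paste0(site$l_box[1], "-", site$l_box[2]),
    bs_crossover = as.character(site$bs_crossover),
    ts_crossover = as.character(site$ts_crossover),
    randomized_window = format_positions(site$randomized_window)
  )
  write.dcf(m, path)
  invisible(path)
}

parse_interval <- function(x) {
  parts <- as.integer(strsplit(trimws(x), "-", fixed = TRUE)[[1]])
  if (length(parts) != 2L || anyNA(parts)) {
    abort_config(paste0("cannot parse interval: ", x))
  }
  parts
}

parse_positions <- function(x) {
  out <- unlist(lapply(strsplit(trimws(x), ",", fixed = TRUE)[[1]], function(tok) {
    if (grepl("-", tok, fixed = TRUE)) {
      iv <- parse_interval(tok)
      seq.int(iv[1], iv[2])
    } else {
      as.integer(tok)
    }
  }))
  if (anyNA(out)) abort_config(paste0("cannot parse positions: ", x))
  as.integer(out)
}

format_positions <- function(pos) {
  runs <- split(pos, cumsum(c(1L, diff(pos) != 1L)))
  paste(vapply(runs, function(r) {
    if (length(r) > 1L) paste0(r[1], "-", r[length(r)]) else as.character(r)
  }, character(1)), collapse = ",")
}
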