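# End-to-end orchestration: simulate -> classify -> extract -> profile ->
# infer, with config validation and a reproducible provenance record.

#' Configuration for an end-to-end crossover-mapping run
#'
#' Defaults state the bundled experimental design: the attI1-like site with
#' the P = 10 randomized window, true top-strand boundary from the site
#' (b = 7, between the two L-box-border adenines), sequencing depth 10,000
#' reads per amplicon class, substitution error 0.001 and 2% abnormal reads
#' (depth and error are declared defaults — the original experiment's
#' per-site depth and error profile were not reported).
#'
#' @param ... Named overrides of the default fields: `site` (a
#'   [site_model()] or path to a site config), `boundary` (window boundary
#'   or `"unknown"` to use the site's annotated `ts_crossover`), `depth`,
#'   `library_depth`, `error_rate`, `abnormal_fraction`,
#'   `max_anchor_mismatch`, `expected_nonwt` (`NULL` = estimate from the
#'   library profile), `error_floor` (`NULL` = `max(error_rate, 1e-4)`),
#'   `seed` (mandatory for stochastic runs).
#' @return A named list of class `e2e_config`.
#' @export
e2e_config <- function(...) {
  config <- modifyList(
    list(
      site = NULL,
      boundary = "unknown",
      depth = 10000L,
      library_depth = 10000L,
      error_rate = 0.001,
      abnormal_fraction = 0.02,
      max_anchor_mismatch = 1L,
      expected_nonwt = NULL,
      error_floor = NULL,
      seed = NULL
    ),
    list(...)
  )
  structure(config, class = c("e2e_config", "list"))
}

#' Validate an end-to-end configuration
#'
#' @param config A list as from [e2e_config()] or [read_config()].
#' @return Character vector of violation messages, each naming the offending
#'   key; empty when valid.
#' @export
validate_config <- function(config) {
  v <- character()
  site <- resolve_site(config$site)
  if (!inherits(site, "site_model")) {
    v <- c(v, "site: not a site_model or readable site config path")
  } else {
    P <- length(site$randomized_window)
    b <- config$boundary
    if (!(identical(b, "unknown") ||
      (is.numeric(b) && length(b) == 1L && !is.na(b) && b >= 0 && b <= P))) {
      v <- c(v, paste0("boundary: must be 'unknown' or an integer in 0..", P))
    }
    if (identical(b, "unknown") && is.na(site$ts_crossover)) {
      v <- c(v, "boundary: 'unknown' but the site has no annotated ts_crossover")
    }
  }
  num_ok <- function(x, lo, hi) {
    is.numeric(x) && length(x) == 1L && !is.na(x) && x >= lo && x <= hi
  }
  if (!num_ok(config$depth, 1, Inf)) v <- c(v, "depth: must be a positive count")
  if (!num_ok(config$library_depth, 1, Inf)) {
    v <- c(v, "library_depth: must be a positive count")
  }
  if (!num_ok(config$error_rate, 0, 1 - 1e-9)) {
    v <- c(v, "error_rate: must lie in [0, 1)")
  }
  if (!num_ok(config$abnormal_fraction, 0, 1 - 1e-9)) {
    v <- c(v, "abnormal_fraction: must lie in [0, 1)")
  }
  if (!num_ok(config$max_anchor_mismatch, 0, Inf)) {
    v <- c(v, "max_anchor_mismatch: must be a non-negative integer")
  }
  if (is.null(config$seed) || !num_ok(config$seed, -2^31, 2^31)) {
    v <- c(v, "seed: an integer seed is mandatory for stochastic runs")
  }
  v
}

resolve_site <- function(site) {
  if (is.null(site)) {
    return(attI1_site())
  }
  if (inherits(site, "site_model")) {
    return(site)
  }
  if (is.character(site) && length(site) == 1L && file.exists(site)) {
    return(tryCatch(read_site_config(site), error = function(e) NULL))
  }
  NULL
}

#' Read an end-to-end configuration from JSON
#'
#' @param path Path to a JSON config file; keys as in [e2e_config()].
#' @return An `e2e_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_config(paste0("config file not found: ", path))
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(e2e_config, vals)
}

#' Run the full crossover-mapping pipeline on simulated data
#'
#' Executes simulate -> classify -> extract -> profile -> infer in one call:
#' draws the randomized library, recombines it with the site at the
#' configured boundary, sequences all three amplicon classes with error and
#' abnormal-read corruption, filters and profiles the reads, infers the
#' crossover boundary, and scores per-position stringency on the
#' library-derived side of the junction profiles. Re-running with identical
#' config and seed reproduces identical outputs.
#'
#' @param config An [e2e_config()] (validated; a config error lists every
#'   offending key).
#' @param out_dir Optional directory; when given, profiles (TSV), the
#'   crossover call (JSON + TSV curve), the stringency report (TSV), the
#'   discard log (TSV), the config and the provenance record (JSON) are
#'   written there.
#' @return A list of class `crossmapr_e2e`: `call` (crossover_call),
#'   `stringency`, `profiles`, `reads_summary`, `provenance`, `config`.
#' @export
#' @examples
#' res <- run_e2e(e2e_config(depth = 300, library_depth = 300, seed = 1))
#' res$call$boundary_hat
run_e2e <- function(config = e2e_config(), out_dir = NULL) {
  violations <- validate_config(config)
  if (length(violations) > 0L) {
    abort_config(paste0(
      "invalid configuration:\n",
      paste0("  - ", violations, collapse = "\n")
    ))
  }
  site <- resolve_site(config$site)
  spec <- library_spec(site)
  boundary <- if (identical(config$boundary, "unknown")) {
    site$ts_crossover
  } else {
    as.integer(config$boundary)
  }
  contexts <- amplicon_contexts(site)

  reads <- simulate_amplicon_pool(
    spec, boundary,
    depth = as.integer(config$depth),
    error_rate = config$error_rate,
    abnormal_fraction = config$abnormal_fraction,
    seed = as.integer(config$seed),
    contexts = contexts,
    library_depth = as.integer(config$library_depth)
  )
  reads <- classify_reads(reads, contexts, config$max_anchor_mismatch)
  reads <- extract_windows(reads, contexts, config$max_anchor_mismatch)
  profiles <- junction_profiles(reads, wt_window(spec))

  error_floor <- config$error_floor %||% max(config$error_rate, 1e-4)
  call <- infer_boundary(
    profiles,
    expected_nonwt = config$expected_nonwt,
    error_floor = error_floor
  )
  stringency <- stringency_skew(
    retained_profile(profiles, call),
    expected_nonwt = call$expected_nonwt,
    wt_window = profiles$wt_window
  )
  reads_summary <- count(reads, .data$class, .data$assigned_class, .data$status)

  hash_input <- unclass(config)
  hash_input$site <- site$top_strand
  provenance <- list(
    package = "crossmapr",
    version = as.character(utils::packageVersion("crossmapr")),
    seed = as.integer(config$seed),
    config_hash = rlang::hash(hash_input),
    site = site$name,
    true_boundary = boundary
  )
  result <- structure(
    list(
      call = call, stringency = stringency, profiles = profiles,
      reads_summary = reads_summary, provenance = provenance, config = config
    ),
    class = "crossmapr_e2e"
  )
  if (!is.null(out_dir)) {
    write_e2e(result, out_dir)
  }
  result
}

#' @export
print.crossmapr_e2e <- function(x, ...) {
  cat("<crossmapr_e2e> simulated boundary ", x$provenance$true_boundary,
    ", inferred ", x$call$boundary_hat, "\n",
    sep = ""
  )
  print(x$call)
  invisible(x)
}

write_e2e <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_profiles_tsv(result$profiles, file.path(out_dir, "profiles"))
  readr::write_tsv(tidy(result$call), file.path(out_dir, "loglik_curve.tsv"))
  jsonlite::write_json(
    as.list(glance(result$call)),
    file.path(out_dir, "crossover_call.json"),
    auto_unbox = TRUE, digits = NA
  )
  readr::write_tsv(result$stringency, file.path(out_dir, "stringency.tsv"))
  if (!is.null(result$profiles$discard_log)) {
    readr::write_tsv(result$profiles$discard_log, file.path(out_dir, "discard_log.tsv"))
  }
  readr::write_tsv(result$reads_summary, file.path(out_dir, "reads_summary.tsv"))
  jsonlite::write_json(
    result$provenance, file.path(out_dir, "provenance.json"),
    auto_unbox = TRUE
  )
  cfg <- unclass(result$config)
  cfg$site <- resolve_site(cfg$site)$name
  jsonlite::write_json(
    cfg[!vapply(cfg, is.null, logical(1))],
    file.path(out_dir, "config.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}
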