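# File formats: FASTQ/FASTA via Biostrings (gzip-transparent), profile and
# count tables as TSV via readr.

#' Read amplicon reads from FASTQ or FASTA
#'
#' Format is chosen from the file extension (`.fastq`/`.fq` vs
#' `.fasta`/`.fa`/`.fna`, with optional `.gz`). Qualities are not used by the
#' profiling pipeline and are not returned.
#'
#' @param path Path to a FASTQ or FASTA file.
#' @return A tibble with `read_id` and `sequence`.
#' @export
read_amplicons <- function(path) {
  base <- sub("\\.gz$", "", path)
  fmt <- if (grepl("\\.(fastq|fq)$", base, ignore.case = TRUE)) "fastq" else "fasta"
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = fmt),
    error = function(e) {
      abort_data(paste0("cannot parse ", fmt, " file '", path, "': ", conditionMessage(e)))
    }
  )
  tibble(
    read_id = sub("\\s.*$", "", names(set)),
    sequence = as.character(set)
  )
}

#' Write reads as FASTQ (Phred+33)
#'
#' @param reads A tibble with `read_id`, `sequence` and optionally `quality`
#'   (constant Phred 40 is emitted when absent), e.g. from
#'   [simulate_reads()].
#' @param path Output path (`.gz` for compressed output).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  qual <- reads$quality %||% strrep("I", nchar(reads$sequence))
  seqs <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  Biostrings::writeXStringSet(
    seqs, path,
    format = "fastq",
    qualities = Biostrings::BStringSet(setNames(qual, reads$read_id)),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

#' Write named sequences as FASTA
#'
#' @param x A named character vector of sequences, or a tibble with columns
#'   `read_id`/`name` and `sequence`/`template`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.data.frame(x)) {
    nm <- x[["name"]] %||% x[["read_id"]] %||% as.character(seq_len(nrow(x)))
    sq <- x[["sequence"]] %||% x[["template"]]
    x <- setNames(sq, nm)
  }
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(x), path,
    format = "fasta",
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

#' Write and read junction profiles as TSV
#'
#' `write_profiles_tsv()` writes one TSV per profile class
#' (`<prefix>_library.tsv`, `<prefix>_left.tsv`, `<prefix>_right.tsv`, each
#' with columns position, base, count, frequency), a `<prefix>_counts.tsv`
#' retain/discard table and a `<prefix>_meta.json` carrying the wild-type
#' window. `read_profiles_tsv()` reassembles the [junction_profiles] object
#' from the same prefix.
#'
#' @param profiles A [junction_profiles] object.
#' @param prefix Path prefix for the output files.
#' @return The written file paths (invisibly) for the writer; a
#'   `junction_profiles` for the reader.
#' @export
write_profiles_tsv <- function(profiles, prefix) {
  stopifnot(inherits(profiles, "junction_profiles"))
  paths <- character()
  for (cls in c("library", "left", "right")) {
    prof <- profiles[[cls]]
    if (is.null(prof)) next
    p <- paste0(prefix, "_", cls, ".tsv")
    readr::write_tsv(prof, p)
    paths <- c(paths, p)
  }
  p_counts <- paste0(prefix, "_counts.tsv")
  readr::write_tsv(profiles$counts, p_counts)
  p_meta <- paste0(prefix, "_meta.json")
  jsonlite::write_json(
    list(wt_window = profiles$wt_window),
    p_meta,
    auto_unbox = TRUE
  )
  invisible(c(paths, p_counts, p_meta))
}

#' @rdname write_profiles_tsv
#' @export
read_profiles_tsv <- function(prefix) {
  read_one <- function(cls) {
    p <- paste0(prefix, "_", cls, ".tsv")
    if (!file.exists(p)) {
      return(NULL)
    }
    readr::read_tsv(p, show_col_types = FALSE)
  }
  meta_path <- paste0(prefix, "_meta.json")
  if (!file.exists(meta_path)) {
    abort_data(paste0("missing profile metadata file: ", meta_path))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  counts_path <- paste0(prefix, "_counts.tsv")
  counts <- if (file.exists(counts_path)) {
    readr::read_tsv(counts_path, show_col_types = FALSE)
  } else {
    NULL
  }
  new_junction_profiles(
    library = read_one("library"),
    left = read_one("left"),
    right = read_one("right"),
    counts = counts,
    wt_window = meta$wt_window
  )
}
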