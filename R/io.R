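#' Internal: validate and normalise a probe table against a build
#' @noRd
validate_probes <- function(df, build, drop_excluded = TRUE) {
  req <- c("chrom", "start", "end", "log2ratio")
  if (!all(req %in% names(df))) {
    abort(paste0("probe table must have columns: ", paste(req, collapse = ", ")))
  }
  unknown <- setdiff(unique(df$chrom), build$chrom)
  if (length(unknown) > 0) {
    abort(paste0("chromosomes not in build: ", paste(unknown, collapse = ", ")))
  }
  if (drop_excluded) df <- df[df$chrom %in% analysis_chroms(build), , drop = FALSE]
  if (nrow(df) == 0) abort("no probes remain after applying the build's excluded set")
  if (any(df$start >= df$end)) abort("probe with start >= end")
  if (any(df$start < 0)) abort("probe with negative start")
  df$chrom <- as.character(df$chrom)
  ord <- order(match(df$chrom, build$chrom), df$start)
  df <- df[ord, , drop = FALSE]
  # half-open intervals: an overlap means next start < previous end
  by_ch <- split(seq_len(nrow(df)), df$chrom)
  for (idx in by_ch) {
    if (length(idx) > 1 && any(df$start[idx][-1] < df$end[idx][-length(idx)])) {
      abort(paste0("overlapping probes on ", df$chrom[idx[1]]))
    }
  }
  as_tibble(df[, req])
}

#' Load a probe-level copy-number profile
#'
#' Reads a tab-delimited bedGraph-like file with four columns
#' (`chrom`, `start`, `end`, `log2ratio`; `#` comments allowed), validates
#' it against a genome build, sorts probes into build order, and drops
#' probes on excluded chromosomes (sex chromosomes, typically).
#'
#' @param path Path to the probe file.
#' @param build A [genome_build()].
#' @param sample_id Sample label attached to the profile.
#' @param genotype One of `"+/+"`, `"+/-"`, `"-/-"`, `"unknown"`.
#' @return A tibble of class `cnv_profile` with columns `chrom`, `start`,
#'   `end`, `log2ratio` and attributes `sample_id`, `genotype`, `build`.
#' @export
read_probe_profile <- function(path, build, sample_id = basename(path),
                               genotype = c("unknown", "+/+", "+/-", "-/-")) {
  genotype <- match.arg(genotype)
  df <- suppressWarnings(
    readr::read_tsv(path, col_names = c("chrom", "start", "end", "log2ratio"),
                    col_types = "cddd", comment = "#",
                    show_col_types = FALSE, progress = FALSE))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(paste0("malformed probe file ", path, ": ", probs$expected[1],
                 " at line ", probs$row[1]))
  }
  if (nrow(df) == 0) abort(paste0("empty probe file: ", path))
  if (any(!complete.cases(df))) {
    abort(paste0("malformed row (missing field) at line ",
                 which(!complete.cases(df))[1], " of ", path))
  }
  new_cnv_profile(validate_probes(df, build), sample_id, genotype, build)
}

#' Construct a probe profile from an in-memory table
#'
#' Same validation as [read_probe_profile()] but starting from a data
#' frame; the entry point used by the simulator.
#'
#' @param probes Data frame with columns `chrom`, `start`, `end`, `log2ratio`.
#' @inheritParams read_probe_profile
#' @return A `cnv_profile` tibble.
#' @export
as_cnv_profile <- function(probes, build, sample_id = "sample",
                           genotype = c("unknown", "+/+", "+/-", "-/-")) {
  genotype <- match.arg(genotype)
  new_cnv_profile(validate_probes(probes, build), sample_id, genotype, build)
}

new_cnv_profile <- function(df, sample_id, genotype, build) {
  attr(df, "sample_id") <- sample_id
  attr(df, "genotype") <- genotype
  attr(df, "build") <- build
  class(df) <- unique(c("cnv_profile", class(df)))
  df
}

#' Write a segmented profile to a BED-like file
#'
#' Six tab-separated columns: `chrom`, `start`, `end`, `state`,
#' `mean_log2`, `n_probes` (plus a `cn_level` seventh column so the
#' round-trip through [read_segments()] is lossless when copy-number
#' levels have been assigned).
#'
#' @param segments A `cnv_segments` tibble (see [segment_profile()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  df <- as_tibble(segments)[, c("chrom", "start", "end", "state",
                                "mean_log2", "n_probes", "cn_level")]
  tryCatch(
    readr::write_tsv(df, path, col_names = FALSE, progress = FALSE),
    error = function(e) abort(paste0("cannot write segments to ", path, ": ",
                                     conditionMessage(e)))
  )
  invisible(path)
}

#' Read a segmented profile written by [write_segments()]
#'
#' @param path Path to the BED-like segment file.
#' @param build Optional [genome_build()] used to order chromosomes.
#' @return A `cnv_segments` tibble.
#' @export
read_segments <- function(path, build = NULL) {
  df <- readr::read_tsv(path,
                        col_names = c("chrom", "start", "end", "state",
                                      "mean_log2", "n_probes", "cn_level"),
                        col_types = "cddccii", comment = "#",
                        show_col_types = FALSE, progress = FALSE)
  # parse means via strtod for an exact round trip of write_segments output
  df$mean_log2 <- as.numeric(df$mean_log2)
  if (!is.null(build)) {
    df <- df[order(match(df$chrom, build$chrom), df$start), , drop = FALSE]
  }
  df <- df[, c("chrom", "start", "end", "n_probes", "mean_log2",
               "state", "cn_level")]
  new_cnv_segments(as_tibble(df), sample_id = basename(path))
}

new_cnv_segments <- function(df, sample_id = NULL, thresholds = NULL,
                             penalty = NULL, min_probes = NULL) {
  attr(df, "sample_id") <- sample_id %||% attr(df, "sample_id")
  attr(df, "thresholds") <- thresholds %||% attr(df, "thresholds")
  attr(df, "penalty") <- penalty %||% attr(df, "penalty")
  attr(df, "min_probes") <- min_probes %||% attr(df, "min_probes")
  class(df) <- unique(c("cnv_segments", class(df)))
  df
}

#' Read gene annotation intervals from a 4-column BED file
#'
#' Columns: `chrom`, `start`, `end`, `gene` (0-based half-open). Used to
#' annotate amplified oncogenes inside breakage-fusion-bridge stair runs.
#'
#' @param path Path to the BED file.
#' @param build Optional [genome_build()]; when given, chromosomes are
#'   checked against it.
#' @return Tibble with columns `gene`, `chrom`, `start`, `end`.
#' @export
read_gene_bed <- function(path, build = NULL) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "gene"),
                        col_types = "cddc", comment = "#",
                        show_col_types = FALSE, progress = FALSE)
  if (any(df$start >= df$end)) abort("gene interval with start >= end")
  if (!is.null(build)) {
    unknown <- setdiff(unique(df$chrom), build$chrom)
    if (length(unknown) > 0) {
      abort(paste0("gene chromosomes not in build: ", paste(unknown, collapse = ", ")))
    }
  }
  as_tibble(df[, c("gene", "chrom", "start", "end")])
}

#' Write simulated reads as FASTQ
#'
#' Standard 4-line records with a constant Phred+33 quality string.
#'
#' @param reads Tibble with columns `read_id`, `sequence` (and optionally
#'   `quality`), as produced by [simulate_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("quality" %in% names(reads)) reads$quality else
    strrep("I", nchar(reads$sequence))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' Uses Biostrings for parsing; qualities are not retained (the telomeric
#' classifier is sequence-only).
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return Tibble with columns `read_id`, `sequence`.
#' @export
read_fastq <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading FASTQ requires the Biostrings package")
  }
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = unname(names(ss)), sequence = unname(as.character(ss)))
}

#' Write a truth manifest as JSON lines
#'
#' One JSON object per injected event, as emitted by the simulator.
#'
#' @param truth Truth component of [simulate_profile()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(truth, path) {
  ev <- truth$events
  lines <- vapply(seq_len(nrow(ev)), function(i) {
    jsonlite::toJSON(as.list(ev[i, ]), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
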