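#' Define a genome build
#'
#' A genome build fixes the chromosome order, chromosome lengths and
#' (optionally) centromere positions used by every coordinate-aware
#' operation in the package. Chromosomes named in `exclude` (by default
#' the sex chromosomes) are dropped from every profile on load and never
#' appear in downstream structures.
#'
#' Coordinates are 0-based half-open throughout, as in BED. When no
#' centromere is recorded a chromosome is treated as single-armed, i.e.
#' the whole chromosome is its only arm; this matches the mostly
#' acrocentric rat karyotype for which the package was designed.
#'
#' @param chrom Character vector of chromosome names, in genome order.
#' @param length Integer vector of chromosome lengths in bp.
#' @param centromere Optional numeric vector of centromere positions in bp
#'   (`NA` for acrocentric/single-armed chromosomes). Must be strictly
#'   inside `(0, length)` where present.
#' @param exclude Character vector of chromosome names excluded from
#'   analysis (subset of `chrom`). Defaults to none; see
#'   [synthetic_build()] for the sex-chromosome default used there.
#'
#' @return A tibble of class `genome_build` with columns `chrom`, `length`,
#'   `centromere`, and an `exclude` attribute.
#' @export
#' @examples
#' genome_build(c("chr1", "chr2"), c(2e6, 1e6))
genome_build <- function(chrom, length, centromere = NA_real_, exclude = character()) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  centromere <- rep_len(as.numeric(centromere), base::length(chrom))
  if (anyDuplicated(chrom)) abort("duplicate chromosome names in build")
  if (any(!is.finite(length)) || any(length <= 0)) {
    abort("every chromosome length must be a positive number")
  }
  bad_cen <- !is.na(centromere) & (centromere <= 0 | centromere >= length)
  if (any(bad_cen)) {
    abort(paste0("centromere not strictly inside (0, length) for: ",
                 paste(chrom[bad_cen], collapse = ", ")))
  }
  exclude <- as.character(exclude)
  if (!all(exclude %in% chrom)) {
    abort("excluded set must be a subset of the build's chromosome names")
  }
  out <- tibble(chrom = chrom, length = length, centromere = centromere)
  attr(out, "exclude") <- exclude
  class(out) <- c("genome_build", class(out))
  out
}

#' Read a genome build from a tab-delimited file
#'
#' Expects 2 or 3 tab-separated columns: chromosome name, length in bp,
#' and optional centromere position in bp. Lines starting with `#` are
#' ignored.
#'
#' @param path Path to the build file.
#' @inheritParams genome_build
#' @return A [genome_build()] object.
#' @export
read_genome_build <- function(path, exclude = character()) {
  df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) abort("empty genome build file")
  if (!ncol(df) %in% c(2, 3)) abort("genome build file must have 2 or 3 columns")
  cen <- if (ncol(df) == 3) as.numeric(df[[3]]) else NA_real_
  genome_build(df[[1]], df[[2]], cen, exclude = exclude)
}

#' Chromosomes retained for analysis
#' @param build A [genome_build()].
#' @return Character vector of non-excluded chromosome names in build order.
#' @export
analysis_chroms <- function(build) {
  setdiff(build$chrom, attr(build, "exclude"))
}

#' Chromosome arms of a build
#'
#' Expands a build into one row per arm. Chromosomes without a recorded
#' centromere contribute a single `"whole"` arm; otherwise a `"p"` arm
#' `[0, centromere)` and a `"q"` arm `[centromere, length)`.
#'
#' @param build A [genome_build()].
#' @param include_excluded Keep arms of excluded chromosomes? Default `FALSE`.
#' @return Tibble with columns `chrom`, `arm`, `arm_start`, `arm_end`.
#' @export
genome_arms <- function(build, include_excluded = FALSE) {
  keep <- if (include_excluded) build$chrom else analysis_chroms(build)
  b <- build[build$chrom %in% keep, , drop = FALSE]
  purrr::pmap_dfr(list(b$chrom, b$length, b$centromere), function(ch, len, cen) {
    if (is.na(cen)) {
      tibble(chrom = ch, arm = "whole", arm_start = 0, arm_end = len)
    } else {
      tibble(chrom = ch, arm = c("p", "q"),
             arm_start = c(0, cen), arm_end = c(cen, len))
    }
  })
}

#' Fraction of a chromosomal arm covered by segments
#'
#' Computes the total length of the supplied segments intersected with one
#' arm, divided by the arm length. Used by the aneuploidy caller, where an
#' arm-level alteration requires the covered fraction to exceed 0.75.
#'
#' @param segments Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param chrom Chromosome of the arm.
#' @param arm `"whole"`, `"p"` or `"q"`; must match the build's arm table.
#' @param build A [genome_build()].
#' @return A single number in `[0, 1]`.
#' @export
#' @examples
#' b <- genome_build("chr1", 4e7)
#' segs <- tibble::tibble(chrom = "chr1", start = 0, end = 3e7)
#' arm_fraction(segs, "chr1", "whole", b)  # 0.75
arm_fraction <- function(segments, chrom, arm = "whole", build) {
  arms <- genome_arms(build, include_excluded = TRUE)
  a <- arms[arms$chrom == chrom & arms$arm == arm, , drop = FALSE]
  if (nrow(a) != 1) abort(paste0("arm ", arm, " of ", chrom, " not defined in build"))
  segs <- segments[segments$chrom == chrom, , drop = FALSE]
  if (nrow(segs) == 0) return(0)
  len <- build$length[match(chrom, build$chrom)]
  if (any(segs$start < 0) || any(segs$end > len)) {
    abort(paste0("segment outside chromosome ", chrom, " (length ", len, ")"))
  }
  ov <- pmin(segs$end, a$arm_end) - pmax(segs$start, a$arm_start)
  sum(pmax(ov, 0)) / (a$arm_end - a$arm_start)
}

#' Synthetic desk-scale genome build
#'
#' A small build for simulation and examples: `n_chrom` autosomes of equal
#' length plus sex chromosomes `chrX`/`chrY`, which are placed on the
#' excluded list (sex chromosomes are excluded from copy-number analysis
#' because hybridizations against opposite-sex or pooled references shift
#' their log2 ratios).
#'
#' @param n_chrom Number of autosomes.
#' @param chrom_length Length of each autosome in bp.
#' @param sex_chroms Add excluded `chrX`/`chrY`? Default `TRUE`.
#' @return A [genome_build()].
#' @export
synthetic_build <- function(n_chrom = 5, chrom_length = 1e7, sex_chroms = TRUE) {
  chrom <- paste0("chr", seq_len(n_chrom))
  len <- rep(chrom_length, n_chrom)
  excl <- character()
  if (sex_chroms) {
    chrom <- c(chrom, "chrX", "chrY")
    len <- c(len, chrom_length, chrom_length / 2)
    excl <- c("chrX", "chrY")
  }
  genome_build(chrom, len, exclude = excl)
}
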