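#' Run the full copy-number signature pipeline over a set of profiles
#'
#' End-to-end execution for each sample: segmentation, state assignment,
#' arm-level aneuploidy calling, altered-bp counting, chromothripsis and
#' BFB detection, amplified-gene annotation and LOH-mechanism
#' classification — then cohort aggregation. Thresholds come from a
#' self-self control profile when supplied, otherwise from
#' [default_thresholds()].
#'
#' @param profiles Named list of `cnv_profile` objects (or a
#'   [simulate_cohort()] result, whose samples and genotypes are used).
#' @param build A [genome_build()].
#' @param null_profile Optional self-self control `cnv_profile` for
#'   threshold calibration.
#' @param thresholds Optional [cn_thresholds()]; overrides calibration.
#' @param penalty,min_probes Segmentation parameters
#'   (see [segment_profile()]).
#' @param genes Optional gene annotation (see [read_gene_bed()]) for
#'   amplified-oncogene annotation.
#' @param locus Optional locus (list with `chrom`, `start`, `end`) for
#'   LOH-mechanism classification of samples with established LOH
#'   (heterozygous genotype).
#' @param out_dir Optional directory; when given, writes `report.json`,
#'   `cohort.tsv` and one BED segment track per sample.
#' @return List of class `karyosig_report`: `records` (cohort-table
#'   schema), `summary` (a [summarize_cohort()] object), `segments`,
#'   `arm_events`, `ct_calls`, `bfb_calls`, `altered_bp`, `thresholds`.
#' @export
run_pipeline <- function(profiles, build, null_profile = NULL,
                         thresholds = NULL, penalty = NULL, min_probes = 5L,
                         genes = NULL, locus = NULL, out_dir = NULL) {
  if (is.list(profiles) && !is.null(profiles$samples)) {
    profiles <- purrr::map(profiles$samples, "profile")
  }
  if (is.null(names(profiles)) || any(names(profiles) == "")) {
    names(profiles) <- purrr::map_chr(profiles, ~ attr(.x, "sample_id") %||% "sample")
  }
  thr <- thresholds %||%
    (if (!is.null(null_profile)) calibrate_thresholds(null_profile) else default_thresholds())
  per_sample <- purrr::imap(profiles, function(p, id) {
    seg <- tryCatch(
      assign_states(segment_profile(p, penalty = penalty, min_probes = min_probes), thr),
      error = function(e) abort(paste0("segmentation failed for sample ", id, ": ",
                                       conditionMessage(e))))
    arm <- call_arm_events(seg, build)
    ct <- detect_chromothripsis(seg)
    bfb <- detect_bfb(seg)
    if (!is.null(genes)) bfb <- annotate_amplified_genes(bfb, seg, genes)
    genotype <- attr(p, "genotype") %||% "unknown"
    has_loh <- genotype == "+/-"
    loh_type <- if (has_loh && !is.null(locus)) {
      classify_loh_mechanism(seg, ct, locus, build)
    } else NA_character_
    ct_chrom_str <- paste(sort(unique(ct$chrom)), collapse = ",")
    bfb_chrom_str <- paste(sort(unique(bfb$chrom)), collapse = ",")
    amp_genes_str <- if (!is.null(genes) && nrow(bfb) > 0) {
      paste(sort(unique(unlist(bfb$genes))), collapse = ",")
    } else ""
    record <- tibble(
      rat_id = id, genotype = genotype, sex = NA_character_,
      age_weeks = NA_real_, diagnosis = NA_character_,
      loh = has_loh, loh_type = loh_type,
      chromothripsis = nrow(ct) > 0,
      ct_chroms = ct_chrom_str,
      bfb = nrow(bfb) > 0,
      bfb_chroms = bfb_chrom_str,
      amplified_oncogenes = amp_genes_str)
    list(segments = seg, arm_events = arm, ct = ct, bfb = bfb,
         altered_bp = count_altered_bp(seg, arm, build), record = record)
  })
  records <- purrr::map_dfr(per_sample, "record")
  report <- structure(list(
    records = records,
    summary = summarize_cohort(records),
    segments = purrr::map(per_sample, "segments"),
    arm_events = purrr::map(per_sample, "arm_events"),
    ct_calls = purrr::map(per_sample, "ct"),
    bfb_calls = purrr::map(per_sample, "bfb"),
    altered_bp = tibble(rat_id = names(per_sample),
                        altered_bp = purrr::map_dbl(per_sample, "altered_bp")),
    thresholds = thr,
    schema_version = "1.0"), class = "karyosig_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report bundle to disk
#'
#' Emits `report.json` (versioned schema with per-sample calls and the
#' cohort summary), `cohort.tsv` in the cohort-table dialect, and one
#' BED-like segment track per sample. Output is deterministic: rerunning
#' an identically-configured pipeline writes byte-identical files.
#'
#' @param report A `karyosig_report` from [run_pipeline()].
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_table(report$records, file.path(out_dir, "cohort.tsv"))
  for (id in names(report$segments)) {
    write_segments(report$segments[[id]], file.path(out_dir, paste0(id, ".segments.bed")))
  }
  payload <- list(
    schema_version = report$schema_version,
    thresholds = unclass(report$thresholds),
    records = report$records,
    altered_bp = report$altered_bp,
    arm_events = purrr::map(report$arm_events, ~ as.data.frame(.x)),
    ct_calls = purrr::map(report$ct_calls, ~ as.data.frame(.x)),
    bfb_calls = purrr::map(report$bfb_calls,
                           ~ as.data.frame(dplyr::select(.x, -dplyr::any_of("genes")))),
    headline = report$summary$headline)
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.karyosig_report <- function(x, ...) {
  cat("<karyosig_report> schema", x$schema_version, "\n")
  print(x$summary)
  invisible(x)
}

#' @export
#' @method glance karyosig_report
glance.karyosig_report <- function(x, ...) x$summary$headline

#' @export
#' @method tidy karyosig_report
tidy.karyosig_report <- function(x, ...) x$records
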