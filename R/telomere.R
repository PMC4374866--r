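# the 12 periodic references of length L: 6 phases x 2 orientations
repeat_patterns <- function(L) {
  reps <- ceiling((L + 6) / 6) + 1
  purrr::map(c("TTAGGG", "CCCTAA"), function(unit) {
    tandem <- strrep(unit, reps)
    vapply(1:6, function(p) substr(tandem, p, p + L - 1), character(1))
  }) |> unlist()
}

# per-read maximum match fraction against the periodic telomeric repeat
repeat_match_fraction <- function(sequences) {
  out <- numeric(length(sequences))
  lens <- nchar(sequences)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    m <- matrix(utf8ToInt(paste(sequences[idx], collapse = "")), nrow = L)
    best <- rep(0, length(idx))
    for (pat in repeat_patterns(L)) {
      frac <- colMeans(m == utf8ToInt(pat))
      best <- pmax(best, frac)
    }
    out[idx] <- best
  }
  out
}

#' Classify reads as telomeric by repeat content
#'
#' A read is telomeric when the best match fraction against the periodic
#' vertebrate telomeric repeat — maximised over the six phases and both
#' orientations (TTAGGG / CCCTAA) — reaches `min_repeat_fraction`. The
#' phase-and-orientation maximum emulates alignment against a tandem
#' TTAGGG reference while needing no external aligner.
#'
#' @param reads Tibble with a `sequence` column (e.g. from
#'   [simulate_reads()] or [read_fastq()]), or a character vector of
#'   sequences.
#' @param min_repeat_fraction Minimum matching fraction (default 0.9,
#'   tolerating ~10% sequencing error without admitting interstitial
#'   telomere-like sequence).
#' @return One-row tibble: `n_total`, `n_telomeric`, `telomeric_bases`.
#' @export
classify_telomeric_reads <- function(reads, min_repeat_fraction = 0.9) {
  seqs <- if (is.character(reads)) reads else reads$sequence
  if (length(seqs) == 0) {
    return(tibble(n_total = 0L, n_telomeric = 0L, telomeric_bases = 0))
  }
  if (any(nchar(seqs) < 12)) abort("reads must be at least 12 bp")
  frac <- repeat_match_fraction(toupper(seqs))
  tel <- frac >= min_repeat_fraction
  tibble(n_total = length(seqs),
         n_telomeric = sum(tel),
         telomeric_bases = sum(nchar(seqs)[tel]))
}

#' Estimate genome coverage from read counts
#'
#' Coverage of the non-telomeric reference:
#' `(n_reads - n_telomeric) * read_length / genome_size`.
#'
#' @param n_reads Total read count.
#' @param read_length Read length in bp.
#' @param genome_size Non-telomeric genome size in bp.
#' @param n_telomeric Telomeric read count subtracted before the ratio
#'   (default 0).
#' @return Coverage in x.
#' @export
estimate_genome_coverage <- function(n_reads, read_length, genome_size,
                                     n_telomeric = 0) {
  if (genome_size <= 0) abort("genome_size must be positive")
  if (n_reads - n_telomeric <= 0) {
    abort("estimation error: no non-telomeric reads")
  }
  (n_reads - n_telomeric) * read_length / genome_size
}

#' Estimate mean telomere length from telomeric base content
#'
#' The standard shallow-WGS estimator: telomeric bases scale with
#' coverage and with the summed telomere length across all chromosome
#' ends, so `length = telomeric_bases / (coverage * n_ends)`.
#'
#' @param telomeric_bases Total bases in telomeric reads.
#' @param coverage Genome coverage in x (see
#'   [estimate_genome_coverage()]).
#' @param n_ends Number of telomeres (default 84: rat 2n = 42
#'   chromosomes, two ends each).
#' @return Mean telomere length in bp per end.
#' @export
estimate_telomere_length <- function(telomeric_bases, coverage, n_ends = 84) {
  if (coverage <= 0) abort("coverage must be positive")
  if (n_ends <= 0) abort("n_ends must be positive")
  telomeric_bases / (coverage * n_ends)
}

#' Full telomere-length estimate for one read set
#'
#' Runs [classify_telomeric_reads()], [estimate_genome_coverage()] and
#' [estimate_telomere_length()] in sequence.
#'
#' @inheritParams classify_telomeric_reads
#' @param genome_size Non-telomeric genome size in bp.
#' @param read_length Read length in bp.
#' @param n_ends Number of telomeres (default 84).
#' @param sample_id Label carried into the result.
#' @return One-row tibble: `sample_id`, `n_total`, `n_telomeric`,
#'   `telomeric_bases`, `coverage`, `n_ends`, `telomere_length`.
#' @export
estimate_telomeres <- function(reads, genome_size, read_length,
                               n_ends = 84, min_repeat_fraction = 0.9,
                               sample_id = "sample") {
  cls <- classify_telomeric_reads(reads, min_repeat_fraction)
  cov <- estimate_genome_coverage(cls$n_total, read_length, genome_size,
                                  cls$n_telomeric)
  tibble(sample_id = sample_id,
         n_total = cls$n_total, n_telomeric = cls$n_telomeric,
         telomeric_bases = cls$telomeric_bases,
         coverage = cov, n_ends = n_ends,
         telomere_length = estimate_telomere_length(cls$telomeric_bases, cov, n_ends))
}

#' Normalize telomerase (TRAP) and ALT (C-circle) assay signals
#'
#' Divides each raw signal by its positive-control signal (e.g. the
#' ALT-positive cell line U-2 OS for C-circle assays, or the kit's
#' telomerase-positive control for TRAP) and flags samples whose relative
#' activity strictly exceeds the activation threshold.
#'
#' @param signals Tibble with columns `sample`, `assay`, `raw`, `control`.
#' @param activation_threshold Relative activity above which a sample
#'   counts as activated (default 0.1, i.e. 10% of the positive control).
#' @return `signals` with added columns `relative_activity`, `activated`.
#' @export
normalize_assay <- function(signals, activation_threshold = 0.1) {
  req <- c("sample", "assay", "raw", "control")
  if (!all(req %in% names(signals))) {
    abort(paste0("signals must have columns: ", paste(req, collapse = ", ")))
  }
  if (any(signals$control <= 0)) abort("control signal must be positive")
  if (any(signals$raw < 0)) abort("raw signal must be non-negative")
  mutate(as_tibble(signals),
         relative_activity = .data$raw / .data$control,
         activated = .data$relative_activity > activation_threshold)
}

#' Two-sample pooled-variance Student's t-test
#'
#' The classical group contrast used for cohort comparisons (telomere
#' lengths, aneuploidy counts, altered bp): equal-variance Student's t by
#' default, Welch's correction behind `var_equal = FALSE`.
#'
#' @param a,b Numeric vectors of group values (each of length >= 2).
#' @param var_equal Pool the variances (classical Student's t, default
#'   `TRUE`)?
#' @return One-row tibble: `statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`, `method`.
#' @export
compare_groups <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) abort("each group needs >= 2 values")
  if (sd(c(a - mean(a), b - mean(b))) == 0) {
    abort("degenerate variance: all values identical within groups")
  }
  ht <- t.test(a, b, var.equal = var_equal)
  tibble(statistic = unname(ht$statistic),
         df = unname(ht$parameter),
         p_value = ht$p.value,
         mean_a = mean(a), mean_b = mean(b),
         method = if (var_equal) "Student's t (pooled)" else "Welch's t")
}
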