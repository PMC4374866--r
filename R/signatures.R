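# state class used by the aneuploidy caller: gains and amplifications are
# one class, losses the other
level_class <- function(level) {
  dplyr::case_when(level < 0 ~ "LOSS", level > 0 ~ "GAIN", TRUE ~ "NEUTRAL")
}

#' Call arm- and chromosome-level aneuploidy events
#'
#' An arm-level alteration is a single alteration or an aggregate of
#' same-class alterations (LOSS vs GAIN-or-AMP) covering strictly more
#' than `fraction_threshold` of a chromosomal arm. At most one call is
#' emitted per arm: when both classes qualify the larger fraction wins and
#' ties produce no call (with a message). Builds without centromere
#' records treat each chromosome as a single arm, so these calls are
#' whole-chromosome gains/losses.
#'
#' @param segments A state-assigned `cnv_segments` tibble
#'   (see [assign_states()]).
#' @param build A [genome_build()].
#' @param fraction_threshold Minimum covered arm fraction, exclusive
#'   (default 0.75).
#' @return Tibble with columns `chrom`, `arm`, `state` (`LOSS`/`GAIN`),
#'   `fraction`.
#' @export
call_arm_events <- function(segments, build, fraction_threshold = 0.75) {
  if (any(is.na(segments$cn_level))) abort("states not assigned; run assign_states() first")
  arms <- genome_arms(build)
  df <- as_tibble(segments)
  df$class <- level_class(df$cn_level)
  altered <- df[df$class != "NEUTRAL", , drop = FALSE]
  out <- purrr::pmap_dfr(arms, function(chrom, arm, arm_start, arm_end) {
    segs <- altered[altered$chrom == chrom, , drop = FALSE]
    if (nrow(segs) == 0) return(tibble())
    fr <- segs |>
      mutate(ov = pmax(pmin(.data$end, arm_end) - pmax(.data$start, arm_start), 0)) |>
      group_by(.data$class) |>
      summarise(fraction = sum(.data$ov) / (arm_end - arm_start), .groups = "drop") |>
      filter(.data$fraction > fraction_threshold)
    if (nrow(fr) == 0) return(tibble())
    if (nrow(fr) > 1) {
      if (abs(diff(fr$fraction)) < 1e-12) {
        inform(paste0("tied arm fractions on ", chrom, " ", arm, "; no call"))
        return(tibble())
      }
      fr <- fr[which.max(fr$fraction), , drop = FALSE]
    }
    tibble(chrom = chrom, arm = arm, state = fr$class, fraction = fr$fraction)
  })
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), arm = character(),
                  state = character(), fraction = numeric())
  }
  out
}

# arm membership of a segment: the arm containing its midpoint
segment_arm <- function(segments, build) {
  arms <- genome_arms(build, include_excluded = TRUE)
  mid <- (segments$start + segments$end) / 2
  vapply(seq_len(nrow(segments)), function(i) {
    a <- arms[arms$chrom == segments$chrom[i] &
                arms$arm_start <= mid[i] & mid[i] < arms$arm_end, ]
    if (nrow(a) == 0) NA_character_ else a$arm[1]
  }, character(1))
}

#' Count base pairs altered by focal copy-number variants
#'
#' Sums the lengths of all non-NEUTRAL segments, excluding segments lying
#' on arms that carry an aneuploidy call of the same state class — i.e.
#' the focal CNV burden with whole-arm/whole-chromosome events removed.
#'
#' @param segments A state-assigned `cnv_segments` tibble.
#' @param arm_events Output of [call_arm_events()] for the same profile.
#' @param build A [genome_build()] (used to resolve arm membership).
#' @return Total altered bp (a single number).
#' @export
count_altered_bp <- function(segments, arm_events, build) {
  df <- as_tibble(segments)
  df <- df[!is.na(df$cn_level) & df$cn_level != 0, , drop = FALSE]
  if (nrow(df) == 0) return(0)
  df$class <- level_class(df$cn_level)
  df$arm <- segment_arm(df, build)
  if (nrow(arm_events) > 0) {
    key <- paste(df$chrom, df$arm, df$class)
    drop <- key %in% paste(arm_events$chrom, arm_events$arm, arm_events$state)
    df <- df[!drop, , drop = FALSE]
  }
  sum(df$end - df$start)
}

#' Detect chromothripsis signatures
#'
#' Chromothripsis — catastrophic shattering and reassembly of a chromosome
#' — leaves a copy-number signature of many segmental switches oscillating
#' among few states. A chromosome is called when it shows at least
#' `min_switches` changes in segmental copy-number (adjacent-segment level
#' switches after same-level merging) involving a number of distinct
#' copy-number levels in `allowed_states` (default 2 or 3).
#'
#' @param segments A state-assigned `cnv_segments` tibble.
#' @param min_switches Minimum adjacent-segment state changes (default 10).
#' @param allowed_states Allowed counts of distinct copy-number levels on
#'   the chromosome (default `c(2, 3)`).
#' @return Tibble with columns `chrom`, `n_switches`, `n_states`,
#'   `span_start`, `span_end`.
#' @export
detect_chromothripsis <- function(segments, min_switches = 10,
                                  allowed_states = c(2L, 3L)) {
  if (any(is.na(segments$cn_level))) abort("states not assigned; run assign_states() first")
  as_tibble(segments) |>
    group_by(.data$chrom) |>
    summarise(n_switches = sum(diff(.data$cn_level) != 0),
              n_states = dplyr::n_distinct(.data$cn_level),
              span_start = min(.data$start), span_end = max(.data$end),
              .groups = "drop") |>
    filter(.data$n_switches >= min_switches,
           .data$n_states %in% allowed_states)
}

# stair run scan from one terminus: levels in terminus-inward order
bfb_scan <- function(lv, starts, ends, anchor, min_stairs, drop_levels) {
  n <- length(lv)
  idx <- if (anchor == "end") rev(seq_len(n)) else seq_len(n)
  v <- lv[idx]
  # maximal run from the terminus: strictly decreasing inward, all > NEUTRAL
  r <- 0L
  while (r < n && v[r + 1] >= 1 && (r == 0 || v[r + 1] < v[r])) r <- r + 1L
  if (r < min_stairs) return(NULL)
  interior <- if (r < n) v[r + 1] else NA_integer_
  if (is.na(interior)) return(NULL)           # no interior segment, no drop
  if (!(interior <= 0 || interior <= min(v[seq_len(r)]) - drop_levels)) return(NULL)
  run_idx <- idx[seq_len(r)]
  tibble(anchor = anchor, n_stairs = r, peak_level = v[1],
         run_start = min(starts[run_idx]), run_end = max(ends[run_idx]))
}

#' Detect breakage-fusion-bridge (BFB) amplification signatures
#'
#' BFB cycles leave a stair-like increase in copy number toward one
#' chromosome terminus: a run of at least `min_stairs` segments whose
#' copy-number level strictly increases toward the chromosome start or
#' end (every stair above NEUTRAL), bounded on the interior side by a
#' single sharp drop — a segment at least `drop_levels` levels below the
#' lowest stair, or at NEUTRAL or below.
#'
#' @param segments A state-assigned `cnv_segments` tibble.
#' @param min_stairs Minimum number of increasing copy-number states
#'   (default 3).
#' @param drop_levels Minimum interior drop in levels (default 2); a drop
#'   to NEUTRAL or below always qualifies.
#' @return Tibble with columns `chrom`, `anchor` (`start`/`end`),
#'   `n_stairs`, `peak_level`, `run_start`, `run_end` (bp span of the
#'   stair run).
#' @export
detect_bfb <- function(segments, min_stairs = 3, drop_levels = 2) {
  if (any(is.na(segments$cn_level))) abort("states not assigned; run assign_states() first")
  df <- as_tibble(segments)
  proto <- tibble(chrom = character(), anchor = character(),
                  n_stairs = integer(), peak_level = integer(),
                  run_start = numeric(), run_end = numeric())
  out <- purrr::map_dfr(unique(df$chrom), function(ch) {
    s <- df[df$chrom == ch, , drop = FALSE]
    calls <- dplyr::bind_rows(
      bfb_scan(s$cn_level, s$start, s$end, "start", min_stairs, drop_levels),
      bfb_scan(s$cn_level, s$start, s$end, "end", min_stairs, drop_levels))
    if (nrow(calls) == 0) return(tibble())
    mutate(calls, chrom = ch, .before = 1)
  })
  if (nrow(out) == 0) proto else out
}

#' Annotate amplified genes within BFB stair runs
#'
#' Lists, per BFB call, the genes whose interval intersects (any overlap,
#' half-open arithmetic) a segment of the stair run at amplification level
#' (`cn_level >= 2`).
#'
#' @param bfb_calls Output of [detect_bfb()].
#' @param segments The state-assigned `cnv_segments` the calls came from.
#' @param genes Gene annotation tibble from [read_gene_bed()].
#' @return `bfb_calls` with an added list-column `genes` and its
#'   comma-collapsed counterpart `amplified_genes`.
#' @export
annotate_amplified_genes <- function(bfb_calls, segments, genes) {
  if (nrow(bfb_calls) == 0) {
    return(mutate(bfb_calls, genes = list(), amplified_genes = character()))
  }
  df <- as_tibble(segments)
  hits <- purrr::map(seq_len(nrow(bfb_calls)), function(i) {
    call <- bfb_calls[i, ]
    amp <- df[df$chrom == call$chrom & df$cn_level >= 2 &
                df$start < call$run_end & df$end > call$run_start, , drop = FALSE]
    if (nrow(amp) == 0) return(character())
    g <- genes[genes$chrom == call$chrom, , drop = FALSE]
    if (nrow(g) == 0) return(character())
    keep <- vapply(seq_len(nrow(g)), function(k) {
      any(g$start[k] < amp$end & g$end[k] > amp$start)
    }, logical(1))
    sort(unique(g$gene[keep]))
  })
  bfb_calls$genes <- hits
  bfb_calls$amplified_genes <- vapply(hits, paste, character(1), collapse = ",")
  bfb_calls
}

#' Classify the mechanism behind loss of heterozygosity at a locus
#'
#' Given that LOH at the locus has been established independently (e.g.
#' by sequencing), classifies the copy-number mechanism with the
#' precedence: a chromothripsis call on the locus chromosome ->
#' `"affected by chromothripsis"`; otherwise a LOSS segment overlapping
#' the locus -> `"deletion"`; otherwise
#' `"gene conversion or copy-neutral SV"`. Chromothripsis takes precedence
#' because a shattered chromosome carries losses that are part of the
#' chromothripsis event, not independent deletions.
#'
#' @param segments A state-assigned `cnv_segments` tibble.
#' @param ct_calls Output of [detect_chromothripsis()] on the same profile.
#' @param locus List or one-row data frame with `chrom`, `start`, `end`.
#' @param build Optional [genome_build()]; an excluded locus chromosome is
#'   an error.
#' @return One of the three mechanism labels.
#' @export
classify_loh_mechanism <- function(segments, ct_calls, locus, build = NULL) {
  if (!is.null(build) && locus$chrom %in% attr(build, "exclude")) {
    abort(paste0("locus chromosome ", locus$chrom, " is excluded from analysis"))
  }
  if (!locus$chrom %in% segments$chrom) {
    abort(paste0("locus chromosome ", locus$chrom, " absent from profile"))
  }
  if (locus$chrom %in% ct_calls$chrom) return("affected by chromothripsis")
  s <- as_tibble(segments)
  hit <- s$chrom == locus$chrom & s$cn_level < 0 &
    s$start < locus$end & s$end > locus$start
  if (any(hit)) return("deletion")
  "gene conversion or copy-neutral SV"
}

#' Co-occurrence of BFB and chromothripsis across a cohort
#'
#' Exact set logic on per-tumor flags and affected-chromosome lists:
#' how many tumors carry a BFB signature, how many of those also carry
#' chromothripsis, and in how many the two events share an affected
#' chromosome.
#'
#' @param records A `TumorRecord` tibble (see [read_cohort_table()]) with
#'   logical `chromothripsis`/`bfb` columns and list-columns or
#'   comma-separated strings `ct_chroms`/`bfb_chroms`.
#' @return One-row tibble: `n_bfb`, `n_bfb_with_ct`, `n_shared_chrom`.
#' @export
cooccurrence_summary <- function(records) {
  ct_l <- parse_chrom_list(records$ct_chroms)
  bfb_l <- parse_chrom_list(records$bfb_chroms)
  shared <- purrr::map2_lgl(ct_l, bfb_l, ~ length(intersect(.x, .y)) > 0)
  tibble(n_bfb = sum(records$bfb),
         n_bfb_with_ct = sum(records$bfb & records$chromothripsis),
         n_shared_chrom = sum(shared))
}

# accepts a list-column of character vectors or comma-separated strings
parse_chrom_list <- function(x) {
  if (is.list(x)) return(purrr::map(x, ~ trimws(as.character(.x))))
  purrr::map(x, function(s) {
    if (is.na(s) || s %in% c("", "-")) return(character())
    trimws(strsplit(as.character(s), ",")[[1]])
  })
}
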