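#' Default copy-number level to log2-ratio map
#'
#' Single-copy changes on a diploid background: LOSS (level -1) at
#' log2(1/2) = -1, NEUTRAL (0) at 0, GAIN (1) at log2(3/2) ~ 0.58, and
#' amplification tiers (levels 2, 3, ...) at `1.5 + 0.5 * (level - 2)`.
#'
#' @param loss,neutral,gain Log2 ratios for levels -1, 0, 1.
#' @param amp_base Log2 ratio of the first amplification tier (level 2).
#' @param amp_step Log2 spacing between successive amplification tiers.
#' @return A function mapping integer levels to log2 ratios.
#' @export
state_log2_map <- function(loss = -1, neutral = 0, gain = 0.58,
                           amp_base = 1.5, amp_step = 0.5) {
  function(level) {
    dplyr::case_when(level <= -1 ~ loss,
                     level == 0 ~ neutral,
                     level == 1 ~ gain,
                     TRUE ~ amp_base + amp_step * (level - 2))
  }
}

state_to_level <- function(state) {
  if (is.numeric(state)) return(as.integer(state))
  m <- c(LOSS = -1L, NEUTRAL = 0L, GAIN = 1L, AMP = 2L)
  if (!all(state %in% names(m))) abort("unknown state label")
  unname(m[state])
}

#' Event specifications for the profile simulator
#'
#' Constructors for the four event kinds the simulator can inject into a
#' chromosome: whole-chromosome aneuploidy, a focal CNV, a chromothripsis
#' plan (many breakpoints oscillating among 2-3 states) and a BFB
#' terminal amplification stair. Each returns a one-row tibble; bind rows
#' to build an event list for [simulate_profile()].
#'
#' @param chrom Chromosome the event lives on.
#' @param state State label (`"LOSS"`, `"GAIN"`, ...) or integer level for
#'   aneuploidy/focal events.
#' @param start,end Focal interval in bp (0-based half-open).
#' @param n_breakpoints Chromothripsis breakpoint count (>= 11, so the
#'   plan carries >= 10 switches).
#' @param alphabet Chromothripsis state alphabet: 2 or 3 state labels or
#'   integer levels.
#' @param n_stairs Number of increasing copy-number states in the BFB
#'   stair (>= 3).
#' @param anchor `"start"` or `"end"`: chromosome terminus carrying the
#'   stair.
#' @param max_level Copy-number level of the terminal (highest) stair;
#'   defaults to `n_stairs` so the lowest stair is a single-copy gain.
#' @return A one-row event tibble with columns `kind`, `chrom`, `params`.
#' @name event_spec
NULL

#' @rdname event_spec
#' @export
event_aneuploidy <- function(chrom, state = "GAIN") {
  tibble(kind = "ANEUPLOIDY", chrom = chrom,
         params = list(list(level = state_to_level(state))))
}

#' @rdname event_spec
#' @export
event_focal <- function(chrom, start, end, state = "LOSS") {
  if (start >= end) abort("focal event needs start < end")
  tibble(kind = "FOCAL_CNV", chrom = chrom,
         params = list(list(start = start, end = end,
                            level = state_to_level(state))))
}

#' @rdname event_spec
#' @export
event_chromothripsis <- function(chrom, n_breakpoints = 11,
                                 alphabet = c("NEUTRAL", "LOSS")) {
  if (n_breakpoints < 11) abort("chromothripsis needs >= 11 breakpoints")
  lv <- state_to_level(alphabet)
  if (length(unique(lv)) < 2 || length(unique(lv)) > 3) {
    abort("chromothripsis alphabet must hold 2 or 3 distinct states")
  }
  tibble(kind = "CHROMOTHRIPSIS", chrom = chrom,
         params = list(list(n_breakpoints = as.integer(n_breakpoints),
                            alphabet = unique(lv))))
}

#' @rdname event_spec
#' @export
event_bfb <- function(chrom, n_stairs = 3, anchor = c("end", "start"),
                      max_level = NULL) {
  anchor <- match.arg(anchor)
  if (n_stairs < 3) abort("BFB stair needs >= 3 increasing states")
  max_level <- max_level %||% n_stairs
  if (max_level < n_stairs) abort("max_level must be >= n_stairs")
  tibble(kind = "BFB", chrom = chrom,
         params = list(list(n_stairs = as.integer(n_stairs), anchor = anchor,
                            max_level = as.integer(max_level))))
}

# sample n breakpoints on the probe grid of G cells with every segment
# >= min_gap cells wide; returns grid indices (1..G-1)
sample_breakpoints <- function(G, n, min_gap = 5L) {
  slack <- G - min_gap * (n + 1L)
  if (slack < 0) abort("chromosome too short for requested breakpoints")
  c_sorted <- sort(sample.int(slack + 1L, n, replace = TRUE) - 1L)
  c_sorted + min_gap * seq_len(n)
}

#' Plan a chromothripsis event
#'
#' Partitions a chromosome at uniformly random probe-grid breakpoints
#' (every segment at least `min_gap` probe spacings wide, so events stay
#' detectable at the simulated probe density) and assigns states from the
#' alphabet so that adjacent segments always differ — the switch count of
#' the plan therefore equals `n_breakpoints` by construction.
#'
#' @param chrom_length Chromosome length in bp.
#' @param n_breakpoints Number of breakpoints (>= 11).
#' @param alphabet 2 or 3 distinct states (labels or integer levels).
#' @param seed Integer seed; all randomness flows from it.
#' @param probe_spacing Probe grid spacing in bp (default 5e4).
#' @param min_gap Minimum segment width in probe spacings (default 5,
#'   matching the segmenter's default min_probes so injected events stay
#'   recoverable).
#' @return Plan tibble with columns `start`, `end`, `level`.
#' @export
inject_chromothripsis <- function(chrom_length, n_breakpoints = 11,
                                  alphabet = c("NEUTRAL", "LOSS"), seed,
                                  probe_spacing = 5e4, min_gap = 5L) {
  if (n_breakpoints < 11) abort("chromothripsis needs >= 11 breakpoints")
  lv <- unique(state_to_level(alphabet))
  if (length(lv) < 2 || length(lv) > 3) {
    abort("chromothripsis alphabet must hold 2 or 3 distinct states")
  }
  G <- floor(chrom_length / probe_spacing)
  withr::with_seed(seed, {
    bp <- sample_breakpoints(G, as.integer(n_breakpoints), as.integer(min_gap))
    bounds <- c(0, bp * probe_spacing, G * probe_spacing)
    n_seg <- length(bounds) - 1L
    levels <- integer(n_seg)
    levels[1] <- sample(lv, 1)
    for (i in seq_len(n_seg - 1L)) {
      levels[i + 1] <- sample(setdiff(lv, levels[i]), 1)
    }
    tibble(start = bounds[-length(bounds)], end = bounds[-1], level = levels)
  })
}

#' Plan a breakage-fusion-bridge amplification stair
#'
#' Produces `n_stairs` terminal segments whose copy-number level strictly
#' increases toward the anchored terminus, ending at `max_level`, with the
#' neighbouring interior segment at NEUTRAL (the sharp drop). Stair widths
#' are drawn uniformly between `min_gap` and `max_width` probe spacings.
#'
#' @inheritParams inject_chromothripsis
#' @param n_stairs Number of increasing states (>= 3).
#' @param anchor `"start"` or `"end"`.
#' @param max_level Level of the terminal stair (default `n_stairs`).
#' @param max_width Maximum stair width in probe spacings (default 10).
#' @return Plan tibble with columns `start`, `end`, `level`.
#' @export
inject_bfb <- function(chrom_length, n_stairs = 3, anchor = c("end", "start"),
                       max_level = NULL, seed, probe_spacing = 5e4,
                       min_gap = 5L, max_width = 10L) {
  anchor <- match.arg(anchor)
  if (n_stairs < 3) abort("BFB stair needs >= 3 increasing states")
  max_level <- max_level %||% n_stairs
  if (max_level < n_stairs) abort("max_level must be >= n_stairs")
  G <- floor(chrom_length / probe_spacing)
  withr::with_seed(seed, {
    widths <- sample(seq.int(min_gap, max_width), n_stairs, replace = TRUE)
    if (sum(widths) + min_gap > G) abort("chromosome too short for requested stair")
    # levels inward-from-terminus: max_level, max_level-1, ...
    stair_levels <- seq.int(max_level, max_level - n_stairs + 1L)
    if (anchor == "end") {
      stair_levels <- rev(stair_levels)        # increasing toward the end
      # widths assigned terminus-outward so start/end plans mirror exactly
      bounds <- c(0, G - rev(cumsum(widths)), G) * probe_spacing
      levels <- c(0L, stair_levels)
    } else {
      bounds <- c(0, cumsum(widths), G) * probe_spacing
      levels <- c(stair_levels, 0L)
    }
    tibble(start = bounds[-length(bounds)], end = bounds[-1], level = levels)
  })
}

# expand an event list into a per-chromosome segment plan
plan_chromosome <- function(len, ch_events, probe_spacing, seed_offset) {
  G <- floor(len / probe_spacing)
  base <- tibble(start = 0, end = G * probe_spacing, level = 0L)
  if (nrow(ch_events) == 0) return(base)
  structural <- ch_events$kind %in% c("CHROMOTHRIPSIS", "BFB", "ANEUPLOIDY")
  if (sum(structural) > 1 || (any(structural) && any(!structural))) {
    abort(paste0("overlapping events on one chromosome: ",
                 paste(ch_events$kind, collapse = ", ")))
  }
  ev <- ch_events[1, ]
  p <- ev$params[[1]]
  if (ev$kind == "ANEUPLOIDY") {
    return(tibble(start = 0, end = G * probe_spacing, level = p$level))
  }
  if (ev$kind == "CHROMOTHRIPSIS") {
    return(inject_chromothripsis(len, p$n_breakpoints, p$alphabet,
                                 seed = seed_offset, probe_spacing = probe_spacing))
  }
  if (ev$kind == "BFB") {
    return(inject_bfb(len, p$n_stairs, p$anchor, p$max_level,
                      seed = seed_offset, probe_spacing = probe_spacing))
  }
  # focal CNVs: carve intervals out of the neutral baseline
  focal <- purrr::map_dfr(seq_len(nrow(ch_events)), function(i) {
    q <- ch_events$params[[i]]
    s <- round(q$start / probe_spacing) * probe_spacing
    e <- round(q$end / probe_spacing) * probe_spacing
    if (s >= e) abort("focal event narrower than one probe spacing")
    tibble(start = s, end = pmin(e, G * probe_spacing), level = q$level)
  }) |> arrange(.data$start)
  if (any(focal$start[-1] < focal$end[-nrow(focal)])) {
    abort("overlapping focal events on one chromosome")
  }
  pieces <- list()
  cursor <- 0
  for (i in seq_len(nrow(focal))) {
    if (focal$start[i] > cursor) {
      pieces[[length(pieces) + 1]] <- tibble(start = cursor, end = focal$start[i], level = 0L)
    }
    pieces[[length(pieces) + 1]] <- focal[i, ]
    cursor <- focal$end[i]
  }
  if (cursor < G * probe_spacing) {
    pieces[[length(pieces) + 1]] <- tibble(start = cursor, end = G * probe_spacing, level = 0L)
  }
  dplyr::bind_rows(pieces)
}

#' Simulate a probe-level copy-number profile with known events
#'
#' Lays out a per-chromosome segment plan from the event list, tiles each
#' chromosome with probes of width `probe_spacing`, and sets each probe's
#' log2 ratio to its segment's true mean (via the state-to-log2 map) plus
#' Gaussian noise. Event breakpoints snap to the probe grid so noise-free
#' profiles are exactly recoverable by the segmenter.
#'
#' @param build A [genome_build()]; excluded chromosomes get no probes.
#' @param events Event tibble built from the [event_spec] constructors
#'   (or `NULL` for an all-neutral genome).
#' @param probe_spacing Probe width/spacing in bp (default 5e4).
#' @param noise_sd Gaussian probe noise, log2 units (default 0.15,
#'   a typical aCGH probe scatter).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param sample_id,genotype Labels attached to the profile.
#' @param state_map Level-to-log2 map (default [state_log2_map()]).
#' @return List with `profile` (a `cnv_profile`) and `truth` — a list with
#'   `events` (the event table with resolved chromosomes) and `segments`
#'   (the exact bp-resolved plan with columns `chrom`, `start`, `end`,
#'   `level`).
#' @export
simulate_profile <- function(build, events = NULL, probe_spacing = 5e4,
                             noise_sd = 0.15, seed,
                             sample_id = "sim", genotype = "unknown",
                             state_map = state_log2_map()) {
  if (probe_spacing <= 0) abort("probe_spacing must be positive")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  chroms <- analysis_chroms(build)
  events <- events %||% tibble(kind = character(), chrom = character(), params = list())
  if (!all(events$chrom %in% chroms)) {
    abort("events reference chromosomes not in the build's analysis set")
  }
  withr::with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max, length(chroms))
    plans <- purrr::map2_dfr(chroms, sub_seeds, function(ch, sub_seed) {
      len <- build$length[match(ch, build$chrom)]
      plan <- plan_chromosome(len, events[events$chrom == ch, , drop = FALSE],
                              probe_spacing, seed_offset = sub_seed)
      mutate(plan, chrom = ch, .before = 1)
    })
    n_per_seg <- as.integer(round((plans$end - plans$start) / probe_spacing))
    probe_start <- unlist(purrr::map2(plans$start, n_per_seg, function(s, n) {
      s + probe_spacing * (seq_len(n) - 1)
    }))
    probes <- tibble(chrom = rep(plans$chrom, n_per_seg),
                     start = probe_start,
                     end = probe_start + probe_spacing,
                     level = rep(plans$level, n_per_seg)) |>
      mutate(log2ratio = state_map(.data$level) +
               if (noise_sd > 0) rnorm(dplyr::n(), 0, noise_sd) else 0) |>
      select("chrom", "start", "end", "log2ratio")
    profile <- as_cnv_profile(probes, build, sample_id = sample_id,
                              genotype = if (genotype %in% c("+/+", "+/-", "-/-")) genotype else "unknown")
    list(profile = profile,
         truth = list(events = events, segments = plans))
  })
}

#' Cohort simulation design
#'
#' Group sizes and per-group event rates for [simulate_cohort()]. The
#' defaults emulate the study contrast the package was built around:
#' 16 heterozygous tumors with frequent chromothripsis (9/16), BFB (6/16)
#' and massive aneuploidy, versus 10 homozygous tumors with near-null
#' genomes.
#'
#' @param n_het,n_hom Group sizes.
#' @param p_ct Per-sample chromothripsis probability, by group.
#' @param p_bfb Per-sample BFB probability, by group.
#' @param aneuploidy_rate Per-chromosome gain/loss probability, by group.
#' @param focal_rate Per-chromosome focal CNV probability, by group.
#' @param noise_sd Probe noise in log2 units.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_het = 16, n_hom = 10,
                          p_ct = c(het = 9 / 16, hom = 0),
                          p_bfb = c(het = 6 / 16, hom = 0),
                          aneuploidy_rate = c(het = 0.2, hom = 0.015),
                          focal_rate = c(het = 0.1, hom = 0.02),
                          noise_sd = 0.15) {
  ps <- c(p_ct, p_bfb, aneuploidy_rate, focal_rate)
  if (any(ps < 0 | ps > 1)) abort("rates must lie in [0, 1]")
  if (n_het < 0 || n_hom < 0) abort("group sizes must be >= 0")
  structure(list(n_het = n_het, n_hom = n_hom, p_ct = p_ct, p_bfb = p_bfb,
                 aneuploidy_rate = aneuploidy_rate, focal_rate = focal_rate,
                 noise_sd = noise_sd),
            class = "cohort_design")
}

#' Simulate a two-genotype tumor cohort with ground truth
#'
#' Draws events per sample from the design rates (chromothripsis and BFB
#' each on one randomly chosen chromosome; aneuploidies and focal CNVs
#' independently per remaining chromosome), simulates the probe profile,
#' and records a per-sample truth row mirroring the cohort-table schema
#' so detector output can be compared record-by-record.
#'
#' @param design A [cohort_design()].
#' @param build A [genome_build()].
#' @param probe_spacing Probe spacing in bp.
#' @param seed Integer seed.
#' @return List with `samples` (named list of [simulate_profile()]
#'   results) and `truth_records` (a tibble in the cohort-table schema).
#' @export
simulate_cohort <- function(design, build, probe_spacing = 5e4, seed) {
  stopifnot(inherits(design, "cohort_design"))
  chroms <- analysis_chroms(build)
  groups <- c(rep("het", design$n_het), rep("hom", design$n_hom))
  ids <- sprintf("sim%03d", seq_along(groups))
  withr::with_seed(seed, {
    sample_seeds <- sample.int(.Machine$integer.max, length(groups))
    samples <- purrr::map(seq_along(groups), function(i) {
      g <- groups[i]
      avail <- chroms
      evs <- list()
      if (runif(1) < design$p_ct[[g]]) {
        ch <- sample(avail, 1); avail <- setdiff(avail, ch)
        evs[[length(evs) + 1]] <- event_chromothripsis(
          ch, n_breakpoints = sample(11:15, 1),
          alphabet = if (runif(1) < 0.5) c("NEUTRAL", "LOSS") else c("NEUTRAL", "LOSS", "GAIN"))
      }
      if (runif(1) < design$p_bfb[[g]] && length(avail) > 0) {
        ch <- sample(avail, 1); avail <- setdiff(avail, ch)
        evs[[length(evs) + 1]] <- event_bfb(ch, n_stairs = sample(3:5, 1),
                                            anchor = sample(c("start", "end"), 1))
      }
      for (ch in avail) {
        if (runif(1) < design$aneuploidy_rate[[g]]) {
          evs[[length(evs) + 1]] <- event_aneuploidy(
            ch, state = sample(c("GAIN", "LOSS"), 1))
        } else if (runif(1) < design$focal_rate[[g]]) {
          len <- build$length[match(ch, build$chrom)]
          w <- sample(5:10, 1) * probe_spacing
          s <- sample.int(max(floor(len / probe_spacing) - w / probe_spacing, 1), 1) * probe_spacing
          evs[[length(evs) + 1]] <- event_focal(ch, s, min(s + w, len),
                                                state = sample(c("GAIN", "LOSS"), 1))
        }
      }
      events <- if (length(evs)) dplyr::bind_rows(evs) else NULL
      simulate_profile(build, events, probe_spacing = probe_spacing,
                       noise_sd = design$noise_sd, seed = sample_seeds[i],
                       sample_id = ids[i],
                       genotype = if (g == "het") "+/-" else "-/-")
    })
    names(samples) <- ids
    truth_records <- purrr::map2_dfr(samples, ids, function(s, id) {
      ev <- s$truth$events
      ct <- ev$chrom[ev$kind == "CHROMOTHRIPSIS"]
      bfb <- ev$chrom[ev$kind == "BFB"]
      tibble(rat_id = id,
             genotype = attr(s$profile, "genotype"),
             sex = NA_character_, age_weeks = NA_real_,
             diagnosis = NA_character_,
             loh = attr(s$profile, "genotype") == "+/-",
             loh_type = NA_character_,
             chromothripsis = length(ct) > 0,
             ct_chroms = paste(ct, collapse = ","),
             bfb = length(bfb) > 0,
             bfb_chroms = paste(bfb, collapse = ","),
             amplified_oncogenes = "")
    })
    list(samples = samples, truth_records = truth_records, design = design)
  })
}

#' Simulate shallow whole-genome sequencing reads with telomeric content
#'
#' Emits single-end reads from a genome of `genome_size` bp carrying
#' `n_ends` telomeres of `telomere_length` bp each. Each read is telomeric
#' with probability `telomere_bases / (genome_size + telomere_bases)` — a
#' phase-shifted tandem of the vertebrate repeat TTAGGG or its reverse
#' complement CCCTAA with per-base substitution errors — and background
#' (uniform random sequence) otherwise. The read count is
#' `coverage * (genome_size + telomere_bases) / read_length`.
#'
#' @param genome_size Non-telomeric genome size in bp.
#' @param telomere_length True mean telomere length in bp per chromosome
#'   end.
#' @param n_ends Number of telomeres (rat default: 2n = 42 chromosomes,
#'   84 ends).
#' @param coverage Sequencing depth in x.
#' @param read_length Read length in bp (>= 6).
#' @param error_rate Per-base substitution error rate in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return Tibble with columns `read_id`, `sequence`, `quality` and
#'   attributes `truth` (the simulation parameters) and
#'   `n_telomeric_true`.
#' @export
simulate_reads <- function(genome_size, telomere_length, n_ends = 84,
                           coverage, read_length = 50, error_rate = 0.01,
                           seed) {
  if (coverage <= 0) abort("coverage must be positive")
  if (read_length < 6) abort("read_length must be >= 6")
  if (error_rate < 0 || error_rate >= 0.5) abort("error_rate must be in [0, 0.5)")
  tel_bases <- telomere_length * n_ends
  total <- genome_size + tel_bases
  n_reads <- max(round(coverage * total / read_length), 1)
  p_tel <- tel_bases / total
  withr::with_seed(seed, {
    is_tel <- runif(n_reads) < p_tel
    n_tel <- sum(is_tel)
    seqs <- character(n_reads)
    if (n_reads - n_tel > 0) {
      seqs[!is_tel] <- stringi::stri_rand_strings(n_reads - n_tel, read_length,
                                                  pattern = "[ACGT]")
    }
    if (n_tel > 0) {
      unit <- ifelse(runif(n_tel) < 0.5, "TTAGGG", "CCCTAA")
      phase <- sample.int(6, n_tel, replace = TRUE)
      tandem <- strrep(unit, ceiling((read_length + 6) / 6) + 1)
      tel_seq <- substr(tandem, phase, phase + read_length - 1)
      if (error_rate > 0) {
        n_err <- rbinom(n_tel, read_length, error_rate)
        for (i in which(n_err > 0)) {
          pos <- sample.int(read_length, n_err[i])
          s <- strsplit(tel_seq[i], "")[[1]]
          s[pos] <- vapply(s[pos], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                           character(1))
          tel_seq[i] <- paste(s, collapse = "")
        }
      }
      seqs[is_tel] <- tel_seq
    }
    out <- tibble(read_id = sprintf("read%07d", seq_len(n_reads)),
                  sequence = seqs,
                  quality = strrep("I", read_length))
    attr(out, "truth") <- list(genome_size = genome_size,
                               telomere_length = telomere_length,
                               n_ends = n_ends, coverage = coverage,
                               read_length = read_length,
                               error_rate = error_rate)
    attr(out, "n_telomeric_true") <- n_tel
    out
  })
}
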