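test_that("a null genome at zero noise is exactly flat", {
  b <- toy_build(2)
  sim <- simulate_profile(b, NULL, noise_sd = 0, seed = 1)
  expect_true(all(sim$profile$log2ratio == 0))
  expect_equal(nrow(sim$truth$events), 0)
})

test_that("whole-chromosome gains put every probe at the gain mean", {
  b <- toy_build(3)
  sim <- simulate_profile(b, event_aneuploidy("chr2", "GAIN"),
                          noise_sd = 0, seed = 3)
  p <- sim$profile
  expect_true(all(p$log2ratio[p$chrom == "chr2"] == 0.58))
  expect_true(all(p$log2ratio[p$chrom != "chr2"] == 0))
})

test_that("simulation is bit-identical under a fixed seed", {
  b <- toy_build(3)
  ev <- dplyr::bind_rows(event_chromothripsis("chr1", 12),
                         event_bfb("chr2", 4, "start"))
  s1 <- simulate_profile(b, ev, noise_sd = 0.15, seed = 99)
  s2 <- simulate_profile(b, ev, noise_sd = 0.15, seed = 99)
  expect_identical(s1$profile$log2ratio, s2$profile$log2ratio)
  expect_identical(s1$truth$segments, s2$truth$segments)
  s3 <- simulate_profile(b, ev, noise_sd = 0.15, seed = 100)
  expect_false(identical(s1$profile$log2ratio, s3$profile$log2ratio))
})

test_that("chromothripsis plans have the promised switch and state counts", {
  plan <- inject_chromothripsis(1e7, 11, c("NEUTRAL", "LOSS"), seed = 5)
  expect_equal(nrow(plan), 12)
  expect_equal(sum(diff(plan$level) != 0), 11)
  expect_equal(dplyr::n_distinct(plan$level), 2)

  plan3 <- inject_chromothripsis(2e7, 15, c("NEUTRAL", "LOSS", "GAIN"), seed = 6)
  expect_equal(nrow(plan3), 16)
  expect_equal(sum(diff(plan3$level) != 0), 15)
  expect_lte(dplyr::n_distinct(plan3$level), 3)

  expect_identical(inject_chromothripsis(1e7, 11, c("NEUTRAL", "LOSS"), seed = 5),
                   plan)
  expect_error(inject_chromothripsis(1e7, 11, "NEUTRAL", seed = 1), "2 or 3")
  expect_error(inject_chromothripsis(1e7, 9, c("NEUTRAL", "LOSS"), seed = 1),
               ">= 11")
})

test_that("chromothripsis plans respect the minimum segment width", {
  for (seed in 1:10) {
    plan <- inject_chromothripsis(1e7, 13, c("NEUTRAL", "LOSS"), seed = seed,
                                  probe_spacing = 5e4, min_gap = 5L)
    expect_true(all(plan$end - plan$start >= 5 * 5e4))
    expect_equal(plan$start[-1], plan$end[-nrow(plan)])  # exact partition
  }
})

test_that("BFB plans build increasing stairs with a terminal anchor and sharp drop", {
  plan <- inject_bfb(1e7, 3, "end", seed = 8)
  # reading toward the chromosome end: NEUTRAL | GAIN | AMP1 | AMP2
  expect_equal(plan$level, c(0L, 1L, 2L, 3L))
  expect_equal(plan$start[1], 0)
  expect_equal(plan$end[nrow(plan)], 1e7)

  plan5 <- inject_bfb(1e7, 5, "end", seed = 9)
  stair <- plan5$level[plan5$level >= 1]
  expect_equal(length(unique(stair)), 5)
  expect_true(all(diff(stair) > 0))

  # mirror symmetry: the start-anchored plan is the coordinate mirror
  pe <- inject_bfb(1e7, 4, "end", seed = 10)
  ps <- inject_bfb(1e7, 4, "start", seed = 10)
  expect_equal(rev(ps$level), pe$level)
  expect_equal(rev(1e7 - ps$end), pe$start)
  expect_error(inject_bfb(1e7, 2, "end", seed = 1), ">= 3")
})

test_that("overlapping structural events on one chromosome are rejected", {
  b <- toy_build(2)
  ev <- dplyr::bind_rows(event_chromothripsis("chr1", 11),
                         event_aneuploidy("chr1", "GAIN"))
  expect_error(simulate_profile(b, ev, seed = 1), "overlapping")
  ev2 <- dplyr::bind_rows(event_focal("chr1", 0, 1e6, "LOSS"),
                          event_focal("chr1", 5e5, 2e6, "GAIN"))
  expect_error(simulate_profile(b, ev2, seed = 1), "overlapping")
})

test_that("cohort event rates are honoured at the deterministic extremes", {
  b <- toy_build(4)
  design <- cohort_design(n_het = 5, n_hom = 5,
                          p_ct = c(het = 1, hom = 0),
                          p_bfb = c(het = 0, hom = 0),
                          aneuploidy_rate = c(het = 0, hom = 0),
                          focal_rate = c(het = 0, hom = 0))
  coh <- simulate_cohort(design, b, seed = 21)
  tr <- coh$truth_records
  expect_equal(sum(tr$chromothripsis[tr$genotype == "+/-"]), 5)
  expect_equal(sum(tr$chromothripsis[tr$genotype == "-/-"]), 0)
  expect_equal(sum(tr$bfb), 0)
  # all-null design produces event-free manifests
  null_design <- cohort_design(n_het = 3, n_hom = 3,
                               p_ct = c(het = 0, hom = 0),
                               p_bfb = c(het = 0, hom = 0),
                               aneuploidy_rate = c(het = 0, hom = 0),
                               focal_rate = c(het = 0, hom = 0))
  coh0 <- simulate_cohort(null_design, b, seed = 22)
  expect_true(all(vapply(coh0$samples, function(s) nrow(s$truth$events) == 0,
                         logical(1))))
  # reproducible under the seed
  coh2 <- simulate_cohort(design, b, seed = 21)
  expect_identical(coh$truth_records, coh2$truth_records)
})

test_that("truth manifests are sufficient to reproduce the noise-free profile plan", {
  b <- toy_build(3)
  ev <- dplyr::bind_rows(event_chromothripsis("chr1", 12),
                         event_bfb("chr2", 3, "end"),
                         event_focal("chr3", 1e6, 1.5e6, "LOSS"))
  sim <- simulate_profile(b, ev, noise_sd = 0, seed = 33)
  seg <- assign_states(segment_profile(sim$profile), default_thresholds())
  truth <- sim$truth$segments
  # merge truth rows only where levels repeat (focal plans carry flanks)
  for (ch in unique(truth$chrom)) {
    tr <- truth[truth$chrom == ch, ]
    keep <- c(TRUE, diff(tr$level) != 0)
    tr <- tr[keep, ]
    sg <- seg[seg$chrom == ch, ]
    expect_equal(sg$start, tr$start)
    expect_equal(sg$cn_level, tr$level)
  }
})

test_that("simulated read sets honour the telomeric mixture proportions", {
  # zero telomere length -> no telomeric reads
  r0 <- simulate_reads(1e5, 0, n_ends = 84, coverage = 0.5, seed = 1)
  expect_equal(attr(r0, "n_telomeric_true"), 0)
  expect_equal(classify_telomeric_reads(r0)$n_telomeric, 0)

  # an error-free telomeric read is an exact phase-shifted repeat tandem
  r1 <- simulate_reads(1e3, 5e4, n_ends = 2, coverage = 1, read_length = 48,
                       error_rate = 0, seed = 2)
  tel_frac <- classify_telomeric_reads(r1)
  expect_equal(tel_frac$n_telomeric, attr(r1, "n_telomeric_true"))

  # binomial oracle on the mixture proportion
  r <- simulate_reads(2e6, 5e4, n_ends = 8, coverage = 1.0, read_length = 50,
                      error_rate = 0.01, seed = 3)
  p <- (5e4 * 8) / (2e6 + 5e4 * 8)
  n <- nrow(r)
  obs <- attr(r, "n_telomeric_true")
  expect_lt(abs(obs - n * p), 3 * sqrt(n * p * (1 - p)))
  expect_equal(n, round(1.0 * (2e6 + 4e5) / 50))

  expect_error(simulate_reads(1e5, 1e4, coverage = 1, read_length = 5, seed = 1),
               "read_length")
  expect_error(simulate_reads(1e5, 1e4, coverage = 0, seed = 1), "coverage")
})

test_that("FASTQ output round-trips through the reader", {
  r <- simulate_reads(1e4, 1e4, n_ends = 4, coverage = 0.5, read_length = 36,
                      seed = 4)
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(r, f)
  back <- read_fastq(f)
  expect_equal(back$read_id, r$read_id)
  expect_equal(back$sequence, r$sequence)
})
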