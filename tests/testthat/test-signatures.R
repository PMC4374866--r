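test_that("arm events require >75% same-class coverage", {
  b <- toy_build(1, 1e7)
  # fully lost chromosome
  segs <- make_segments("chr1", c(0, 1e7), -1)
  ev <- call_arm_events(segs, b)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$state, "LOSS")
  expect_equal(ev$fraction, 1.0)

  # 74% gained -> no call; 76% -> call (strict threshold)
  segs74 <- make_segments("chr1", c(0, 7.4e6, 1e7), c(1, 0))
  expect_equal(nrow(call_arm_events(segs74, b)), 0)
  segs76 <- make_segments("chr1", c(0, 7.6e6, 1e7), c(1, 0))
  ev76 <- call_arm_events(segs76, b)
  expect_equal(nrow(ev76), 1)
  expect_equal(ev76$fraction, 0.76)

  # 40% LOSS + 40% GAIN: no single class exceeds the threshold
  mixed <- make_segments("chr1", c(0, 4e6, 8e6, 1e7), c(-1, 1, 0))
  expect_equal(nrow(call_arm_events(mixed, b)), 0)
})

test_that("AMP aggregates with GAIN into one class for arm calls", {
  b <- toy_build(1, 1e7)
  segs <- make_segments("chr1", c(0, 5e6, 1e7), c(1, 2))
  ev <- call_arm_events(segs, b)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$state, "GAIN")
  expect_equal(ev$fraction, 1.0)
})

test_that("altered-bp counting excludes aneuploid arms but keeps focal events", {
  b <- toy_build(2, 1e7)
  flat <- make_segments("chr1", c(0, 1e7), 0)
  expect_equal(count_altered_bp(flat, call_arm_events(flat, b), b), 0)

  # focal losses of 1 Mb and 2 Mb
  focal <- dplyr::bind_rows(
    make_segments("chr1", c(0, 2e6, 3e6, 1e7), c(0, -1, 0)),
    make_segments("chr2", c(0, 1e6, 3e6, 1e7), c(0, -1, 0)))
  ev <- call_arm_events(focal, b)
  expect_equal(nrow(ev), 0)
  expect_equal(count_altered_bp(focal, ev, b), 3e6)

  # a whole-chromosome gain is an aneuploidy, not focal burden
  gain <- make_segments("chr1", c(0, 1e7), 1)
  expect_equal(count_altered_bp(gain, call_arm_events(gain, b), b), 0)
})

test_that("altered bp plus aneuploid bp conserves total non-neutral bp", {
  b <- toy_build(4)
  design <- cohort_design(n_het = 4, n_hom = 0)
  coh <- simulate_cohort(design, b, seed = 44)
  for (s in coh$samples) {
    seg <- assign_states(segment_profile(s$profile), default_thresholds())
    ev <- call_arm_events(seg, b)
    focal_bp <- count_altered_bp(seg, ev, b)
    total_alt <- sum((seg$end - seg$start)[seg$cn_level != 0])
    segs_alt <- as_tibble(seg)[seg$cn_level != 0, ]
    if (nrow(ev) > 0 && nrow(segs_alt) > 0) {
      cls <- ifelse(segs_alt$cn_level > 0, "GAIN", "LOSS")
      on_called <- paste(segs_alt$chrom, cls) %in% paste(ev$chrom, ev$state)
      excluded_bp <- sum((segs_alt$end - segs_alt$start)[on_called])
    } else {
      excluded_bp <- 0
    }
    expect_equal(focal_bp + excluded_bp, total_alt)
  }
})

test_that("chromothripsis calls need >= 10 switches among 2-3 states", {
  # 12 segments alternating NEUTRAL/LOSS: 11 switches, 2 states -> call
  osc <- make_segments("chr1", seg_bounds(12), rep(c(0, -1), 6))
  ct <- detect_chromothripsis(osc)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$n_switches, 11)
  expect_equal(ct$n_states, 2)

  # a flat chromosome has no switches
  expect_equal(nrow(detect_chromothripsis(make_segments("chr1", c(0, 5e6), 0))), 0)

  # 13 segments cycling through 4 distinct states: switch-rich but too many states
  wild <- make_segments("chr1", seg_bounds(13), rep(c(-1, 0, 1, 2), length.out = 13))
  expect_equal(nrow(detect_chromothripsis(wild)), 0)

  # 10 segments -> 9 switches: below the cut
  osc9 <- make_segments("chr1", seg_bounds(10), rep(c(0, -1), 5))
  expect_equal(nrow(detect_chromothripsis(osc9)), 0)
})

test_that("switch count equals merged segment count minus one on alternating chromosomes", {
  for (n_seg in c(11, 12, 15, 20)) {
    segs <- make_segments("chr1", seg_bounds(n_seg), rep(c(0, 1), length.out = n_seg))
    ct <- detect_chromothripsis(segs, min_switches = 1)
    expect_equal(ct$n_switches, n_seg - 1)
  }
})

test_that("BFB detection follows the stair-and-drop rule", {
  # inward from chromosome end: AMP2, AMP1, GAIN, then NEUTRAL -> call at end
  segs <- make_segments("chr1", seg_bounds(4), c(0, 1, 2, 3))
  call <- detect_bfb(segs)
  expect_equal(nrow(call), 1)
  expect_equal(call$anchor, "end")
  expect_equal(call$n_stairs, 3)
  expect_equal(call$peak_level, 3)

  # only two increasing levels at the terminus: below min stairs
  two <- make_segments("chr1", seg_bounds(3), c(0, 1, 2))
  expect_equal(nrow(detect_bfb(two)), 0)

  # stair without a sharp drop (interior GAIN, run min GAIN): no call
  nodrop <- make_segments("chr1", seg_bounds(4), c(1, 2, 3, 4))
  expect_equal(nrow(detect_bfb(nodrop, drop_levels = 2)), 0)

  # interior only 1 level below the run minimum and above NEUTRAL: no call
  shallow <- make_segments("chr1", seg_bounds(5), c(1, 1, 2, 3, 4))
  expect_equal(nrow(detect_bfb(shallow, drop_levels = 2)), 0)
})

test_that("BFB calls mirror with the anchor flipped", {
  segs <- make_segments("chr1", seg_bounds(5), c(0, 0, 1, 2, 3))
  fwd <- detect_bfb(segs)
  L <- max(segs$end)
  mirrored <- segs |>
    dplyr::mutate(s = L - end, end = L - start, start = s) |>
    dplyr::select(-s) |>
    dplyr::arrange(start)
  rev_call <- detect_bfb(mirrored)
  expect_equal(fwd$anchor, "end")
  expect_equal(rev_call$anchor, "start")
  expect_equal(fwd$n_stairs, rev_call$n_stairs)
})

test_that("amplified-gene annotation uses any-overlap half-open arithmetic", {
  b <- toy_build(2, 1e7)
  segs <- make_segments("chr1", seg_bounds(4), c(0, 1, 2, 3))
  call <- detect_bfb(segs)
  amp_seg <- segs[segs$cn_level >= 2, ][1, ]   # [1e6, 1.5e6)
  genes <- tibble(gene = c("Myc", "Alk", "Edge", "Outside"),
                  chrom = c("chr1", "chr2", "chr1", "chr1"),
                  start = c(amp_seg$start + 1e4, 0, amp_seg$start - 100, amp_seg$start - 200),
                  end = c(amp_seg$start + 2e4, 1e4, amp_seg$start + 1, amp_seg$start))
  ann <- annotate_amplified_genes(call, segs, genes)
  # gene inside an AMP segment and a 1-bp straddler are hits; half-open
  # abutment (end == segment start) and other chromosomes are not
  expect_equal(ann$genes[[1]], c("Edge", "Myc"))
})

test_that("LOH mechanism classification follows the documented precedence", {
  locus <- list(chrom = "chr1", start = 4e6, end = 4.1e6)
  no_ct <- tibble(chrom = character(), n_switches = integer())

  lossy <- make_segments("chr1", c(0, 3e6, 5e6, 1e7), c(0, -1, 0))
  expect_equal(classify_loh_mechanism(lossy, no_ct, locus), "deletion")

  ct_here <- tibble(chrom = "chr1", n_switches = 12L)
  expect_equal(classify_loh_mechanism(lossy, ct_here, locus),
               "affected by chromothripsis")

  flat <- make_segments("chr1", c(0, 1e7), 0)
  expect_equal(classify_loh_mechanism(flat, no_ct, locus),
               "gene conversion or copy-neutral SV")

  b <- synthetic_build(2)
  expect_error(classify_loh_mechanism(flat, no_ct,
                                      list(chrom = "chrX", start = 0, end = 100), b),
               "excluded")
})

test_that("co-occurrence summary applies exact set logic", {
  empty <- tibble(chromothripsis = logical(), ct_chroms = character(),
                  bfb = logical(), bfb_chroms = character())
  expect_equal(unlist(cooccurrence_summary(empty)), c(n_bfb = 0, n_bfb_with_ct = 0,
                                                      n_shared_chrom = 0))
  one <- tibble(chromothripsis = TRUE, ct_chroms = "1,2",
                bfb = TRUE, bfb_chroms = "2")
  expect_equal(unlist(cooccurrence_summary(one)),
               c(n_bfb = 1, n_bfb_with_ct = 1, n_shared_chrom = 1))
  disjoint <- tibble(chromothripsis = c(TRUE, FALSE), ct_chroms = c("1", ""),
                     bfb = c(TRUE, TRUE), bfb_chroms = c("3", "5"))
  expect_equal(unlist(cooccurrence_summary(disjoint)),
               c(n_bfb = 2, n_bfb_with_ct = 1, n_shared_chrom = 0))
})

test_that("injected signatures are always detected on noise-free profiles", {
  b <- toy_build(4)
  for (seed in 1:8) {
    ev <- dplyr::bind_rows(
      event_chromothripsis("chr1", n_breakpoints = 11 + (seed %% 4)),
      event_bfb("chr2", n_stairs = 3 + (seed %% 3),
                anchor = if (seed %% 2 == 0) "start" else "end"))
    sim <- simulate_profile(b, ev, noise_sd = 0, seed = seed)
    seg <- assign_states(segment_profile(sim$profile), default_thresholds())
    expect_equal(detect_chromothripsis(seg)$chrom, "chr1")
    expect_equal(detect_bfb(seg)$chrom, "chr2")
  }
})

test_that("detectors are mirror-invariant up to the anchor flip", {
  b <- toy_build(2)
  ev <- dplyr::bind_rows(event_chromothripsis("chr1", 13),
                         event_bfb("chr2", 4, "end"))
  sim <- simulate_profile(b, ev, noise_sd = 0, seed = 55)
  seg_f <- assign_states(segment_profile(sim$profile), default_thresholds())
  seg_m <- assign_states(segment_profile(mirror_profile(sim$profile, b)),
                         default_thresholds())
  ct_f <- detect_chromothripsis(seg_f); ct_m <- detect_chromothripsis(seg_m)
  expect_equal(ct_f$n_switches, ct_m$n_switches)
  expect_equal(ct_f$n_states, ct_m$n_states)
  bfb_f <- detect_bfb(seg_f); bfb_m <- detect_bfb(seg_m)
  expect_equal(bfb_f$n_stairs, bfb_m$n_stairs)
  expect_equal(bfb_f$anchor, "end")
  expect_equal(bfb_m$anchor, "start")
})
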