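suppressMessages(library(dplyr))

# small single-armed build without sex chromosomes, for hand-built cases
toy_build <- function(n_chrom = 3, chrom_length = 1e7) {
  synthetic_build(n_chrom = n_chrom, chrom_length = chrom_length,
                  sex_chroms = FALSE)
}

# hand-build a state-assigned cnv_segments object from levels; widths in bp
make_segments <- function(chrom, bounds, levels, thresholds = default_thresholds()) {
  lv <- as.integer(levels)
  log2 <- karyosig::state_log2_map()(lv)
  tibble(chrom = chrom,
         start = bounds[-length(bounds)], end = bounds[-1],
         n_probes = as.integer(pmax((bounds[-1] - bounds[-length(bounds)]) / 5e4, 1)),
         mean_log2 = log2,
         state = c("LOSS", "NEUTRAL", "GAIN", "AMP")[pmin(pmax(lv, -1L), 2L) + 2L],
         cn_level = lv) |>
    structure(class = c("cnv_segments", class(tibble())))
}

# equal-width segments covering [0, n*w)
seg_bounds <- function(n, w = 5e5) seq(0, n * w, by = w)

# mirror a profile's coordinates within each chromosome
mirror_profile <- function(profile, build) {
  df <- as_tibble(profile)
  len <- build$length[match(df$chrom, build$chrom)]
  new_start <- len - df$end
  df$end <- len - df$start
  df$start <- new_start
  as_cnv_profile(df, build, sample_id = attr(profile, "sample_id"))
}

# exhaustive penalized-SSE segmentation by recursion over segment ends;
# independent oracle for the dynamic programme (feasible for n <= ~25)
exhaustive_segmentation_cost <- function(x, penalty, min_probes) {
  n <- length(x)
  seg_sse <- function(i, j) {
    v <- x[i:j]
    sum((v - mean(v))^2)
  }
  best <- Inf
  recurse <- function(start, cost_so_far, n_bp) {
    for (end in seq.int(start + min_probes - 1, n)) {
      if (end < n && n - end < min_probes) next
      c2 <- cost_so_far + seg_sse(start, end) + if (start > 1) penalty else 0
      if (end == n) {
        if (c2 < best) best <<- c2
      } else if (c2 < best) {
        recurse(end + 1, c2, n_bp + 1)
      }
    }
  }
  recurse(1, 0, 0)
  best
}

# closed-form pooled-variance Student's t-test (independent oracle)
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

table1_path <- function() {
  system.file("extdata", "table1.tsv", package = "karyosig")
}
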