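#' Copy-number state thresholds
#'
#' Log2-ratio cutoffs separating LOSS / NEUTRAL / GAIN / AMP states.
#' Invariant: `loss < 0 < gain < amp`.
#'
#' @param loss Loss cutoff (negative log2 ratio).
#' @param gain Gain cutoff (positive log2 ratio).
#' @param amp Amplification cutoff (> gain).
#' @return A list of class `cn_thresholds`.
#' @export
cn_thresholds <- function(loss, gain, amp) {
  if (!(loss < 0 && 0 < gain && gain < amp)) {
    abort("thresholds must satisfy loss < 0 < gain < amp")
  }
  structure(list(loss = loss, gain = gain, amp = amp), class = "cn_thresholds")
}

#' @export
print.cn_thresholds <- function(x, ...) {
  cat(sprintf("<cn_thresholds> loss < %.4g | gain >= %.4g | amp >= %.4g\n",
              x$loss, x$gain, x$amp))
  invisible(x)
}

#' Default thresholds for the simulator's state-to-log2 map
#'
#' Midway cutoffs for a diploid background where a single-copy loss sits at
#' log2(1/2) = -1, a single-copy gain at log2(3/2) = 0.58 and amplification
#' tiers start at 1.5: loss -0.3, gain 0.3, amp 1.2. Used where no
#' self-self control hybridization is available (e.g. noise-free
#' simulations, where a calibrated cutoff is undefined).
#'
#' @return A [cn_thresholds()] object.
#' @export
default_thresholds <- function() cn_thresholds(-0.3, 0.3, 1.2)

#' Calibrate gain/loss cutoffs from a self-self control hybridization
#'
#' A control-versus-control (null) hybridization measures the spread of
#' log2 ratios in the absence of true copy-number change. After discarding
#' the extreme `trim` fraction of probes on each tail, the gain and loss
#' cutoffs are placed `k` standard deviations above and below the trimmed
#' mean, and the amplification cutoff at `amp_multiplier` times the gain
#' cutoff.
#'
#' @param null_profile A `cnv_profile` (or any data frame with a
#'   `log2ratio` column) from a self-self hybridization.
#' @param k Multiplier on the trimmed standard deviation (default 3,
#'   the three-sigma rule).
#' @param amp_multiplier Amplification cutoff as a multiple of the gain
#'   cutoff (default 5).
#' @param trim Fraction of probes removed from each tail before moments
#'   are computed (default 0.01).
#' @return A [cn_thresholds()] object.
#' @export
calibrate_thresholds <- function(null_profile, k = 3, amp_multiplier = 5,
                                 trim = 0.01) {
  x <- null_profile$log2ratio
  if (length(x) < 100) abort("calibration requires at least 100 probes (unstable sd)")
  if (k <= 0) abort("k must be positive")
  lo <- quantile(x, trim, names = FALSE, type = 7)
  hi <- quantile(x, 1 - trim, names = FALSE, type = 7)
  xt <- x[x >= lo & x <= hi]
  m <- mean(xt)
  s <- sd(xt)
  if (!is.finite(s) || s == 0) abort("calibration error: zero spread in null profile")
  gain <- m + k * s
  loss <- m - k * s
  if (!(loss < 0 && gain > 0)) {
    abort("calibration error: null profile is not centred near zero")
  }
  cn_thresholds(loss, gain, amp_multiplier * gain)
}

# Exact penalized least-squares changepoint search for one chromosome.
# Minimizes total within-segment SSE + penalty * (number of breakpoints),
# every segment holding >= min_probes probes. Returns segment start
# indices. O(n^2) dynamic programme with vectorized inner loop.
segment_dp <- function(x, penalty, min_probes) {
  n <- length(x)
  if (n < 2 * min_probes) return(1L)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  sse <- function(e, j) {           # cost of segment (e+1)..j, e vector
    len <- j - e
    (cs2[j + 1] - cs2[e + 1]) - (cs[j + 1] - cs[e + 1])^2 / len
  }
  F <- rep(Inf, n + 1)              # F[e+1] = best cost of x[1..e]
  F[1] <- -penalty
  prev <- integer(n + 1)
  for (j in seq_len(n)) {
    if (j < min_probes) next
    # last segment is (e+1)..j; e is 0 (chromosome start) or a previous
    # segment end leaving both sides >= min_probes
    e_hi <- j - min_probes
    e <- if (e_hi >= min_probes) c(0L, seq.int(min_probes, e_hi)) else 0L
    cand <- F[e + 1] + sse(e, j) + penalty
    best <- which.min(cand)
    F[j + 1] <- cand[best]
    prev[j + 1] <- e[best]
  }
  # backtrack segment start indices
  starts <- integer(0)
  j <- n
  while (j > 0) {
    s <- prev[j + 1] + 1L
    starts <- c(s, starts)
    j <- prev[j + 1]
  }
  as.integer(starts)
}

# robust per-probe noise estimate from successive differences
estimate_noise_sd <- function(x) {
  d <- diff(x)
  d <- d[is.finite(d)]
  if (length(d) == 0) return(0)
  median(abs(d)) / (0.6744898 * sqrt(2))
}

#' Segment a probe profile into constant copy-number runs
#'
#' Per chromosome, finds the breakpoints minimizing the total
#' within-segment sum of squared deviations plus `penalty` per breakpoint,
#' subject to every segment holding at least `min_probes` probes. The
#' search is an exact dynamic programme, so for small chromosomes the
#' result provably equals exhaustive enumeration over all breakpoint
#' subsets.
#'
#' With `penalty = NULL` the penalty is set per chromosome to
#' `max(2 * sigma^2 * log(n), 1e-8)`, a BIC-flavoured default where
#' `sigma` is a robust noise estimate from successive probe differences;
#' the floor keeps noise-free profiles at their minimal exact
#' segmentation.
#'
#' @param profile A `cnv_profile` (see [read_probe_profile()]).
#' @param penalty Per-breakpoint cost in squared-log2 units, or `NULL`
#'   for the data-driven default.
#' @param min_probes Minimum probes per segment (default 5; suppresses
#'   single-probe artifacts). Chromosomes with fewer probes than
#'   `min_probes` become a single segment with a warning.
#' @return A tibble of class `cnv_segments` with columns `chrom`, `start`,
#'   `end`, `n_probes`, `mean_log2`, `state`, `cn_level` (states `NA`
#'   until [assign_states()] is applied).
#' @export
segment_profile <- function(profile, penalty = NULL, min_probes = 5L) {
  if (is.null(min_probes) || min_probes < 1) abort("min_probes must be >= 1")
  if (!is.null(penalty) && penalty <= 0) abort("penalty must be positive")
  sigma <- estimate_noise_sd(profile$log2ratio)
  chroms <- unique(profile$chrom)
  segs <- purrr::map_dfr(chroms, function(ch) {
    p <- profile[profile$chrom == ch, , drop = FALSE]
    n <- nrow(p)
    pen <- penalty %||% max(2 * sigma^2 * log(max(n, 2)), 1e-8)
    if (n < min_probes) {
      warn(paste0("chromosome ", ch, " has fewer than min_probes probes; ",
                  "kept as a single segment"))
      starts <- 1L
    } else {
      starts <- segment_dp(p$log2ratio, pen, min_probes)
    }
    ends <- c(starts[-1] - 1L, n)
    tibble(chrom = ch,
           start = p$start[starts],
           end = p$end[ends],
           n_probes = as.integer(ends - starts + 1L),
           mean_log2 = vapply(seq_along(starts), function(i) {
             mean(p$log2ratio[starts[i]:ends[i]])
           }, numeric(1)),
           state = NA_character_,
           cn_level = NA_integer_)
  })
  new_cnv_segments(segs, sample_id = attr(profile, "sample_id"),
                   penalty = penalty %||% "auto", min_probes = min_probes)
}

state_levels <- c("LOSS", "NEUTRAL", "GAIN", "AMP")

# integer copy-number level: LOSS -1, NEUTRAL 0, GAIN 1, AMP tiers 2,3,...
# AMP tiers are spaced by amp_tier_step in log2 units above the amp cutoff
# so that stair-step amplifications keep distinct levels after merging.
log2_to_level <- function(mean_log2, thresholds, amp_tier_step = 0.5) {
  lvl <- integer(length(mean_log2))
  lvl[mean_log2 < thresholds$loss] <- -1L
  lvl[mean_log2 >= thresholds$gain] <- 1L
  amp <- mean_log2 >= thresholds$amp
  lvl[amp] <- 2L + as.integer(floor((mean_log2[amp] - thresholds$amp) /
                                      amp_tier_step + 1e-9))
  lvl
}

level_to_state <- function(level) {
  dplyr::case_when(level <= -1 ~ "LOSS",
                   level == 0 ~ "NEUTRAL",
                   level == 1 ~ "GAIN",
                   TRUE ~ "AMP")
}

#' Assign discrete copy-number states to segments
#'
#' Maps each segment's mean log2 ratio to a state under the thresholds:
#' `LOSS` if below the loss cutoff, `AMP` if at or above the amplification
#' cutoff, `GAIN` if at or above the gain cutoff (boundary values classify
#' into the altered state), `NEUTRAL` otherwise. An integer `cn_level` is
#' recorded alongside (-1 LOSS, 0 NEUTRAL, 1 GAIN, 2+ amplification tiers
#' spaced `amp_tier_step` log2 units apart) so that amplification stairs
#' remain distinguishable. Consecutive segments sharing a level are merged,
#' with probe counts summed and means recomputed bp-weighted.
#'
#' @param segments A `cnv_segments` tibble from [segment_profile()].
#' @param thresholds A [cn_thresholds()] object.
#' @param amp_tier_step Log2 spacing between amplification tiers
#'   (default 0.5).
#' @return The segments with `state`/`cn_level` filled in and same-level
#'   neighbours merged.
#' @export
assign_states <- function(segments, thresholds, amp_tier_step = 0.5) {
  stopifnot(inherits(thresholds, "cn_thresholds"))
  df <- as_tibble(segments)
  df$cn_level <- log2_to_level(df$mean_log2, thresholds, amp_tier_step)
  df$state <- level_to_state(df$cn_level)
  out <- df |>
    group_by(.data$chrom) |>
    mutate(run = cumsum(c(1L, as.integer(diff(.data$cn_level) != 0)))) |>
    group_by(.data$chrom, .data$run) |>
    summarise(mean_log2 = sum(.data$mean_log2 * (.data$end - .data$start)) /
                sum(.data$end - .data$start),
              start = min(.data$start), end = max(.data$end),
              n_probes = as.integer(sum(.data$n_probes)),
              state = .data$state[1], cn_level = .data$cn_level[1],
              .groups = "drop") |>
    arrange(match(.data$chrom, unique(df$chrom)), .data$start) |>
    select("chrom", "start", "end", "n_probes", "mean_log2", "state", "cn_level")
  new_cnv_segments(out, sample_id = attr(segments, "sample_id"),
                   thresholds = thresholds,
                   penalty = attr(segments, "penalty"),
                   min_probes = attr(segments, "min_probes"))
}

#' @export
#' @method tidy cnv_segments
tidy.cnv_segments <- function(x, ...) as_tibble(unclass_keep(x))

#' @export
#' @method glance cnv_segments
glance.cnv_segments <- function(x, ...) {
  tibble(sample_id = attr(x, "sample_id") %||% NA_character_,
         n_segments = nrow(x),
         n_breakpoints = nrow(x) - length(unique(x$chrom)),
         n_chromosomes = length(unique(x$chrom)),
         n_probes = sum(x$n_probes),
         frac_altered = sum((x$end - x$start)[!is.na(x$cn_level) & x$cn_level != 0]) /
           sum(x$end - x$start))
}

unclass_keep <- function(x) {
  class(x) <- setdiff(class(x), c("cnv_segments", "cnv_profile"))
  attr(x, "build") <- NULL
  attr(x, "thresholds") <- NULL
  attr(x, "sample_id") <- NULL
  attr(x, "genotype") <- NULL
  attr(x, "penalty") <- NULL
  attr(x, "min_probes") <- NULL
  as_tibble(x)
}
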