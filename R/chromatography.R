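#' Chromatogram extraction and peak processing
#'
#' Chromatograms are plain tibbles with columns `rt` (minutes, strictly
#' increasing) and `intensity` (counts, non-negative), carrying their
#' channel descriptor in the `"channel"` attribute. They come from three
#' sources: extracted-ion chromatograms ([extract_xic()]), total-ion
#' chromatograms ([extract_tic()]) and SIM traces ([extract_sim()]).
#'
#' @name chromatograms
NULL

new_chromatogram <- function(rt, intensity, channel) {
  out <- tibble(rt = rt, intensity = intensity)
  attr(out, "channel") <- channel
  class(out) <- c("ms_chromatogram", class(out))
  out
}

check_chromatogram <- function(chrom) {
  if (!all(c("rt", "intensity") %in% names(chrom))) {
    abort("a chromatogram needs `rt` and `intensity` columns")
  }
  if (nrow(chrom) == 0) abort("chromatogram is empty")
  if (is.unsorted(chrom$rt, strictly = TRUE)) {
    abort("`rt` must be strictly increasing")
  }
  invisible(chrom)
}

#' Extracted-ion chromatogram from the full scans
#'
#' Sums, cycle by cycle, the full-scan intensity of all m/z bins within
#' `mz - tol` to `mz + tol` for one polarity. A channel with no ions gives
#' an all-zero trace over the full run length.
#'
#' @param run An `ms_run` (must contain full scans).
#' @param mz Nominal m/z, within the acquisition scan range.
#' @param tol m/z tolerance in Da (>= 0); 0.5 covers one unit-resolution bin.
#' @param polarity `"positive"` or `"negative"`.
#' @return A chromatogram tibble (`rt`, `intensity`).
#' @export
extract_xic <- function(run, mz, tol = 0.5, polarity = "positive") {
  stopifnot(inherits(run, "ms_run"))
  if (!polarity %in% c("positive", "negative")) {
    abort("`polarity` must be 'positive' or 'negative'")
  }
  if (tol < 0) abort("`tol` must be >= 0")
  sr <- run$metadata$scan_range
  if (mz < sr[1] || mz > sr[2]) {
    abort(paste0("`mz` outside scan range ", sr[1], "-", sr[2], " Da"))
  }
  if (is.null(run$full_scans)) abort("run has no full scans")
  grid <- run$metadata$rt
  sel <- run$full_scans[run$full_scans$polarity == polarity &
                          run$full_scans$mz >= mz - tol &
                          run$full_scans$mz <= mz + tol, ]
  y <- rep(0, length(grid))
  if (nrow(sel) > 0) {
    agg <- sel %>% group_by(.data$rt) %>%
      summarise(intensity = sum(.data$intensity), .groups = "drop")
    y[match(agg$rt, grid)] <- agg$intensity
  }
  new_chromatogram(grid, y, list(type = "xic", mz = mz, tol = tol,
                                 polarity = polarity))
}

#' Total-ion chromatogram
#'
#' @param run An `ms_run` with full scans.
#' @param polarity `"positive"`, `"negative"`, or `"both"` (summed).
#' @return A chromatogram tibble.
#' @export
extract_tic <- function(run, polarity = "both") {
  stopifnot(inherits(run, "ms_run"))
  if (is.null(run$full_scans)) abort("run has no full scans")
  grid <- run$metadata$rt
  sel <- run$full_scans
  if (polarity != "both") sel <- sel[sel$polarity == polarity, ]
  y <- rep(0, length(grid))
  if (nrow(sel) > 0) {
    agg <- sel %>% group_by(.data$rt) %>%
      summarise(intensity = sum(.data$intensity), .groups = "drop")
    y[match(agg$rt, grid)] <- agg$intensity
  }
  new_chromatogram(grid, y, list(type = "tic", polarity = polarity))
}

#' SIM trace for one acquisition channel
#'
#' @param run An `ms_run`.
#' @param mz Channel nominal m/z.
#' @param polarity Channel polarity.
#' @return A chromatogram tibble restricted to the channel's time window.
#' @export
extract_sim <- function(run, mz, polarity = "positive") {
  stopifnot(inherits(run, "ms_run"))
  sel <- run$sim_traces[run$sim_traces$channel_mz == mz &
                          run$sim_traces$polarity == polarity, ]
  if (nrow(sel) == 0) {
    abort(paste0("no SIM channel at m/z ", mz, " (", polarity, ")"))
  }
  new_chromatogram(sel$rt, sel$intensity,
                   list(type = "sim", mz = mz, polarity = polarity,
                        window = c(sel$window_start[1], sel$window_stop[1])))
}

# centred moving average with shrinking windows at the trace ends
smooth_ma <- function(y, k = 5) {
  n <- length(y)
  if (n == 0 || k <= 1) return(y)
  half <- k %/% 2
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# robust, offset-invariant noise estimate from first differences
diff_noise <- function(y) {
  if (length(y) < 3) return(0)
  mad(diff(y)) / sqrt(2)
}

#' Detect chromatographic peaks
#'
#' Finds local maxima of the moving-average smoothed trace, sets
#' peak boundaries where the smoothed trace returns to the local baseline
#' (first point, walking out from the apex, at which the
#' baseline-subtracted smoothed intensity falls to 0.1% of the
#' baseline-subtracted apex height, capped at the flanking local minima),
#' and keeps peaks whose baseline-subtracted raw apex height is at least
#' `min_snr` times the internal noise estimate and whose width is at least
#' `min_width`. The noise estimate is the scaled median absolute deviation
#' of the first differences, which is insensitive to the peaks themselves
#' and to any constant offset. A flat trace yields an empty peak list.
#'
#' Peaks separated only by a valley (partial co-elution on a shared
#' channel) are treated as one cluster: a single linear baseline is drawn
#' across the cluster's outer edges and the peaks are split at the valley
#' (drop-line), so neither peak's area is biased by the other's flank.
#'
#' @param chrom Chromatogram tibble (`rt`, `intensity`).
#' @param min_snr Minimum signal-to-noise ratio (height / noise SD).
#' @param min_width Minimum peak width in minutes.
#' @param smooth_window Moving-average window, points. The default of 3
#'   preserves a small peak eluting next to a much larger one on a shared
#'   SIM channel at the default 0.05-min cycle period; widen it for
#'   noisier, more densely sampled traces.
#' @param boundary_frac Fraction of apex height (above local baseline) at
#'   which a boundary is placed.
#' @return A tibble of peaks ordered by `apex_rt` with columns `apex_rt`,
#'   `start_rt`, `end_rt`, `height`, `area`, `snr`.
#' @export
detect_peaks <- function(chrom, min_snr = 3, min_width = 0.02,
                         smooth_window = 3, boundary_frac = 0.001) {
  check_chromatogram(chrom)
  y <- chrom$intensity
  rt <- chrom$rt
  n <- length(y)
  empty <- tibble(apex_rt = numeric(), start_rt = numeric(),
                  end_rt = numeric(), height = numeric(),
                  area = numeric(), snr = numeric())
  if (n < 3) return(empty)
  s <- smooth_ma(y, smooth_window)
  noise <- diff_noise(y)

  apex <- which(diff(sign(diff(s))) < 0) + 1L
  apex <- apex[s[apex] > 0]
  if (length(apex) == 0) return(empty)
  apex <- apex[order(s[apex], decreasing = TRUE)]

  claimed <- rep(FALSE, n)
  rows <- list()
  for (a in apex) {
    if (claimed[a]) next
    # flanking local minima of the smoothed trace
    l <- a
    while (l > 1 && s[l - 1] <= s[l]) l <- l - 1
    r <- a
    while (r < n && s[r + 1] <= s[r]) r <- r + 1
    # flat local base level: a flanking valley shared with a larger
    # neighbour is elevated, so taking the lower of the two minima keeps
    # the boundary walk from being cut short under the neighbour's flank
    base_lvl <- min(s[l], s[r])
    h_apex <- s[a] - base_lvl
    if (h_apex <= 0) next
    # pull boundaries in to where the trace has rejoined the baseline
    thr <- boundary_frac * h_apex
    i <- a
    while (i > l && (s[i] - base_lvl) > thr) i <- i - 1
    j <- a
    while (j < r && (s[j] - base_lvl) > thr) j <- j + 1
    if (i >= a || j <= a) next
    raw_base <- y[i] + (y[j] - y[i]) * (rt[a] - rt[i]) / (rt[j] - rt[i])
    height <- max(y[a] - raw_base, 0)
    width <- rt[j] - rt[i]
    snr <- if (noise > 0) height / noise else Inf
    if (snr < min_snr || width < min_width) next
    rows[[length(rows) + 1]] <-
      tibble(a = a, i = i, j = j, height = height, snr = snr)
    claimed[i:j] <- TRUE
  }
  if (length(rows) == 0) return(empty)
  pk <- arrange(list_rbind(rows), .data$a)

  # Overlapping peaks share a valley boundary; integrating each against a
  # baseline anchored at the (elevated) valley intensity would steal area
  # from both. Group valley-joined peaks into clusters and draw one linear
  # baseline across each cluster's outer edges (drop-line at the valleys).
  cluster <- cumsum(c(1, as.integer(pk$i[-1] != pk$j[-nrow(pk)])))
  out <- map(split(seq_len(nrow(pk)), cluster), function(rowset) {
    i0 <- pk$i[rowset[1]]; j0 <- pk$j[rowset[length(rowset)]]
    bl <- function(idx) {
      y[i0] + (y[j0] - y[i0]) * (rt[idx] - rt[i0]) / (rt[j0] - rt[i0])
    }
    map(rowset, function(k) {
      i <- pk$i[k]; j <- pk$j[k]; a <- pk$a[k]
      idx <- i:j
      d <- y[idx] - bl(idx)
      area <- max(sum(diff(rt[idx]) * (head(d, -1) + tail(d, -1)) / 2), 0)
      height <- max(y[a] - bl(a), 0)
      tibble(apex_rt = rt[a], start_rt = rt[i], end_rt = rt[j],
             height = height, area = area,
             snr = if (noise > 0) height / noise else Inf)
    }) %>% list_rbind()
  }) %>% list_rbind()
  arrange(out, .data$apex_rt)
}

#' Integrate one peak
#'
#' Trapezoidal integral of the raw intensity minus a linear baseline drawn
#' between the intensities at the two boundary points; clipped at zero.
#'
#' @param chrom Chromatogram tibble.
#' @param peak A one-row peak tibble (or list) with `start_rt` and
#'   `end_rt`, both inside the chromatogram's time range.
#' @return Area in counts.min.
#' @export
integrate_peak <- function(chrom, peak) {
  check_chromatogram(chrom)
  lo <- peak$start_rt[1]; hi <- peak$end_rt[1]
  if (lo >= hi) abort("`start_rt` must be < `end_rt`")
  if (lo < min(chrom$rt) || hi > max(chrom$rt)) {
    abort("peak boundaries outside chromatogram range")
  }
  inside <- chrom$rt > lo & chrom$rt < hi
  t <- c(lo, chrom$rt[inside], hi)
  y_lo <- approx(chrom$rt, chrom$intensity, lo)$y
  y_hi <- approx(chrom$rt, chrom$intensity, hi)$y
  v <- c(y_lo, chrom$intensity[inside], y_hi)
  baseline <- y_lo + (y_hi - y_lo) * (t - lo) / (hi - lo)
  d <- v - baseline
  area <- sum(diff(t) * (head(d, -1) + tail(d, -1)) / 2)
  max(area, 0)
}

#' Baseline noise from a blank region
#'
#' The standard deviation of the raw intensities inside a peak-free time
#' window — the "baseline noise" that defines LOD (signal 3x noise) and
#' LOQ (signal 10x noise).
#'
#' @param chrom Chromatogram tibble.
#' @param blank_window `c(rt_lo, rt_hi)` in minutes; must contain at least
#'   20 points and no detected peak.
#' @param ... Passed to [detect_peaks()] for the overlap check.
#' @return Noise SD in counts (>= 0).
#' @export
estimate_baseline_noise <- function(chrom, blank_window, ...) {
  check_chromatogram(chrom)
  lo <- blank_window[1]; hi <- blank_window[2]
  idx <- chrom$rt >= lo & chrom$rt <= hi
  if (sum(idx) < 20) {
    abort("blank window must contain at least 20 points",
          class = "phenolscreen_blank_too_small")
  }
  pks <- detect_peaks(chrom, ...)
  if (nrow(pks) > 0 &&
      any(pks$start_rt <= hi & pks$end_rt >= lo)) {
    abort("blank window overlaps a detected peak",
          class = "phenolscreen_blank_has_peak")
  }
  sd(chrom$intensity[idx])
}

#' Longest peak-free stretch of a chromatogram
#'
#' Convenience for automated noise estimation: returns the longest
#' contiguous window not covered by any detected peak, or `NULL` if none
#' with at least `min_points` points exists.
#'
#' @param chrom Chromatogram tibble.
#' @param peaks Peak tibble from [detect_peaks()] (detected fresh if
#'   omitted).
#' @param min_points Minimum number of points.
#' @return `c(rt_lo, rt_hi)` or `NULL`.
#' @export
auto_blank_window <- function(chrom, peaks = NULL, min_points = 20) {
  check_chromatogram(chrom)
  if (is.null(peaks)) peaks <- detect_peaks(chrom)
  free <- rep(TRUE, nrow(chrom))
  if (nrow(peaks) > 0) {
    for (k in seq_len(nrow(peaks))) {
      free[chrom$rt >= peaks$start_rt[k] & chrom$rt <= peaks$end_rt[k]] <-
        FALSE
    }
  }
  r <- rle(free)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values & r$lengths >= min_points)
  if (length(ok) == 0) return(NULL)
  best <- ok[which.max(r$lengths[ok])]
  c(chrom$rt[starts[best]], chrom$rt[ends[best]])
}
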