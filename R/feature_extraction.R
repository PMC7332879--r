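# Per-run feature extraction: crop filter, centroid mass detection,
# chromatogram building, duration filter, baseline cut-off deconvolution
# and isotopic peak grouping.

C13_SPACING <- 1.00336  # Da, 13C - 12C

#' Crop filter
#'
#' Restricts a run to a scan-index range, an RT range and an m/z range.
#' Boundary values are kept (inclusive ranges). An empty result is allowed.
#'
#' @param run A [centroid_run()].
#' @param scan_range,rt_range,mz_range Two-element `c(lo, hi)` ranges;
#'   defaults are the standard processing values (scans 1-1130,
#'   RT 0.01-12.51 min, m/z 100-1200 Th).
#' @return The cropped [centroid_run()].
#' @export
crop <- function(run, scan_range = c(1, 1130), rt_range = c(0.01, 12.51),
                 mz_range = c(100, 1200)) {
  for (r in list(scan_range, rt_range, mz_range))
    if (length(r) != 2 || r[1] > r[2]) stop("range must be ordered c(lo, hi)")
  s <- run$scans
  keep <- s$scan >= scan_range[1] & s$scan <= scan_range[2] &
    s$rt >= rt_range[1] & s$rt <= rt_range[2] &
    s$mz >= mz_range[1] & s$mz <= mz_range[2]
  run$scans <- s[keep, , drop = FALSE]
  rownames(run$scans) <- NULL
  run
}

#' Centroid mass detection
#'
#' Keeps centroids with intensity at or above the noise level (inclusive:
#' a centroid exactly at the level survives).
#'
#' @param run A [centroid_run()].
#' @param noise_level Minimum intensity in counts (default 6.0e2).
#' @return The filtered [centroid_run()].
#' @export
detect_masses <- function(run, noise_level = 6.0e2) {
  stopifnot(noise_level >= 0)
  run$scans <- run$scans[run$scans$intensity >= noise_level, , drop = FALSE]
  rownames(run$scans) <- NULL
  run
}

#' Chromatogram builder
#'
#' Single-pass greedy connection of centroids into extracted-ion traces:
#' scan by scan, each centroid joins the open trace whose running
#' intensity-weighted mean m/z lies within the tolerance window (closest
#' wins; when two centroids of one scan compete for the same trace the more
#' intense one is assigned first). Unmatched centroids open new traces; a
#' trace accepts at most one centroid per scan. Traces whose RT span is at
#' least `min_span` and whose maximum intensity reaches `min_height` are
#' returned.
#'
#' @param run A [centroid_run()] (mass detection applied first).
#' @param min_span Minimum trace RT span in minutes (default 0.01).
#' @param min_height Minimum trace apex intensity in counts (default 5.0e3).
#' @param mz_tol An [mz_tolerance()] (default 0.01 Th or 5 ppm).
#' @return List of traces; each a data.frame (`scan`, `rt`, `mz`,
#'   `intensity`) with attribute `rep_mz` (intensity-weighted mean m/z).
#' @export
build_chromatograms <- function(run, min_span = 0.01, min_height = 5.0e3,
                                mz_tol = mz_tolerance(0.01, 5)) {
  s <- run$scans
  n <- nrow(s)
  if (!n) return(list())
  v_scan <- s$scan; v_mz <- s$mz; v_int <- s$intensity
  tol_abs <- mz_tol$abs_th; tol_rel <- mz_tol$ppm * 1e-6
  assign_id <- integer(n)
  # open-trace state, grown geometrically
  cap <- 256L
  t_rep <- numeric(cap); t_wsum <- numeric(cap); t_mzw <- numeric(cap)
  n_tr <- 0L
  scan_starts <- c(which(c(TRUE, diff(v_scan) != 0)), n + 1L)
  for (si in seq_len(length(scan_starts) - 1L)) {
    idx <- scan_starts[si]:(scan_starts[si + 1L] - 1L)
    ord <- idx[order(-v_int[idx], v_mz[idx])]
    used <- logical(n_tr)
    for (i in ord) {
      mzi <- v_mz[i]
      tid <- 0L
      if (n_tr) {
        d <- abs(t_rep[seq_len(n_tr)] - mzi)
        d[used] <- Inf
        j <- which.min(d)
        tw <- tol_rel * mzi
        if (tw < tol_abs) tw <- tol_abs
        if (length(j) && d[j] <= tw) tid <- j
      }
      if (!tid) {
        n_tr <- n_tr + 1L
        if (n_tr > cap) {
          cap <- cap * 2L
          length(t_rep) <- cap; length(t_wsum) <- cap; length(t_mzw) <- cap
        }
        tid <- n_tr
        used <- c(used, FALSE)
      }
      used[tid] <- TRUE
      w <- v_int[i]
      t_mzw[tid] <- t_mzw[tid] + w * mzi
      t_wsum[tid] <- t_wsum[tid] + w
      t_rep[tid] <- t_mzw[tid] / t_wsum[tid]
      assign_id[i] <- tid
    }
  }
  out <- list()
  for (tid in seq_len(n_tr)) {
    pts <- s[assign_id == tid, , drop = FALSE]
    if ((max(pts$rt) - min(pts$rt)) < min_span) next
    if (max(pts$intensity) < min_height) next
    rownames(pts) <- NULL
    attr(pts, "rep_mz") <- sum(pts$mz * pts$intensity) / sum(pts$intensity)
    out[[length(out) + 1L]] <- pts
  }
  out
}

.empty_features <- function() {
  data.frame(mz = numeric(0), rt = numeric(0), height = numeric(0),
             area = numeric(0), charge = integer(0), iso_group = integer(0),
             representative = logical(0))
}

#' Baseline cut-off deconvolution
#'
#' Maximal contiguous sub-regions of a trace with intensity strictly above
#' the baseline level become candidate peaks; a candidate is kept when its
#' apex is at or above the minimum peak height and its duration lies within
#' the duration range. Feature m/z is the intensity-weighted mean over the
#' region; area is the trapezoidal integral in counts.min.
#'
#' @param trace One trace from [build_chromatograms()].
#' @param baseline Baseline level in counts, exclusive cut (default 9.0e3).
#' @param min_height Minimum apex height, inclusive (default 1.0e4).
#' @param duration_range Allowed peak duration `c(lo, hi)` in minutes
#'   (default 0-2).
#' @return Feature data.frame (`mz`, `rt`, `height`, `area`, `charge`,
#'   `iso_group`, `representative`).
#' @export
deconvolve <- function(trace, baseline = 9.0e3, min_height = 1.0e4,
                       duration_range = c(0, 2)) {
  above <- trace$intensity > baseline
  if (!any(above)) return(.empty_features())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  feats <- list()
  for (k in which(r$values)) {
    i <- starts[k]:ends[k]
    apex <- max(trace$intensity[i])
    dur <- trace$rt[ends[k]] - trace$rt[starts[k]]
    if (apex < min_height) next
    if (dur < duration_range[1] || dur > duration_range[2]) next
    w <- trace$intensity[i]
    area <- if (length(i) > 1) {
      sum(diff(trace$rt[i]) * (utils::head(w, -1) + utils::tail(w, -1)) / 2)
    } else 0
    feats[[length(feats) + 1L]] <- data.frame(
      mz = sum(trace$mz[i] * w) / sum(w),
      rt = trace$rt[i][which.max(w)],
      height = apex, area = area,
      charge = NA_integer_, iso_group = NA_integer_, representative = TRUE)
  }
  if (!length(feats)) return(.empty_features())
  do.call(rbind, feats)
}

#' Peak duration (RT window) filter
#'
#' Keeps features whose apex RT lies inside the configured keep-window,
#' excluding early/late mobile-phase artifacts. The window is a keep-window
#' (see package vignette for the rationale of this reading).
#'
#' @param features Feature data.frame.
#' @param rt_window Keep-window `c(lo, hi)` in minutes (default 0.01-12.01).
#' @return Filtered feature data.frame.
#' @export
duration_filter <- function(features, rt_window = c(0.01, 12.01)) {
  features[features$rt >= rt_window[1] & features$rt <= rt_window[2], ,
           drop = FALSE]
}

#' Isotopic peak grouper
#'
#' Chains features separated by about 1.00336/z Th (z up to `max_charge`)
#' and within the RT tolerance into isotopologue groups, starting from the
#' lowest-m/z ungrouped feature. With `monotonic = TRUE` each successor's
#' height must not exceed its predecessor's. The most intense member of
#' each group is flagged representative and carries the charge; all members
#' share the group id. Every input feature appears exactly once in the
#' output.
#'
#' @param features Feature data.frame.
#' @param mz_tol An [mz_tolerance()] (default 0.01 Th or 5 ppm).
#' @param rt_tol RT tolerance in minutes (default 0.05).
#' @param max_charge Maximum charge state considered (default 1).
#' @param monotonic Require non-increasing heights along the chain
#'   (default TRUE).
#' @return Feature data.frame with `charge`, `iso_group`, `representative`
#'   filled in, ordered by group then m/z.
#' @export
group_isotopes <- function(features, mz_tol = mz_tolerance(0.01, 5),
                           rt_tol = 0.05, max_charge = 1L,
                           monotonic = TRUE) {
  n <- nrow(features)
  if (!n) return(features)
  f <- features[order(features$mz), , drop = FALSE]
  group <- rep(NA_integer_, n)
  charge <- rep(NA_integer_, n)
  gid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(group[i])) next
    gid <- gid + 1L
    group[i] <- gid
    # try charges; keep the one yielding the longest chain
    best_chain <- integer(0); best_z <- NA_integer_
    for (z in seq_len(max_charge)) {
      chain <- i
      last <- i
      repeat {
        target <- f$mz[last] + C13_SPACING / z
        cand <- which(is.na(group) &
                        abs(f$mz - target) <= tol_window(mz_tol, target) &
                        abs(f$rt - f$rt[i]) <= rt_tol)
        if (monotonic) cand <- cand[f$height[cand] <= f$height[last]]
        if (!length(cand)) break
        nxt <- cand[which.min(abs(f$mz[cand] - target))]
        chain <- c(chain, nxt)
        last <- nxt
      }
      if (length(chain) > length(best_chain)) {
        best_chain <- chain; best_z <- z
      }
    }
    if (length(best_chain) > 1L) {
      group[best_chain] <- gid
      charge[best_chain] <- best_z
    }
  }
  f$iso_group <- group
  f$charge <- charge
  f$representative <- FALSE
  for (g in unique(group)) {
    m <- which(group == g)
    f$representative[m[which.max(f$height[m])]] <- TRUE
  }
  f <- f[order(f$iso_group, f$mz), , drop = FALSE]
  rownames(f) <- NULL
  f
}

#' Full per-run feature extraction
#'
#' Runs the per-run processing chain — crop, mass detection, chromatogram
#' building, deconvolution, duration filter, isotope grouping — with one
#' parameter list (see [default_config()] for the standard values).
#'
#' @param run A [centroid_run()].
#' @param params Parameter list; any subset of the `feature_extraction`
#'   section of [default_config()] (missing entries take defaults).
#' @return Feature data.frame (all features, grouped; downstream stages use
#'   rows with `representative == TRUE`).
#' @export
extract_features <- function(run, params = list()) {
  p <- utils::modifyList(default_config()$feature_extraction, params)
  run <- crop(run, p$crop$scan_range, p$crop$rt_range, p$crop$mz_range)
  run <- detect_masses(run, p$mass_detection$noise_level)
  traces <- build_chromatograms(run, p$chromatogram$min_span,
                                p$chromatogram$min_height,
                                mz_tolerance(p$chromatogram$mz_tol_abs,
                                             p$chromatogram$mz_tol_ppm))
  feats <- do.call(rbind, c(list(.empty_features()),
                            lapply(traces, deconvolve,
                                   baseline = p$deconvolution$baseline,
                                   min_height = p$deconvolution$min_height,
                                   duration_range = p$deconvolution$duration_range)))
  feats <- duration_filter(feats, p$duration_filter$rt_window)
  group_isotopes(feats,
                 mz_tolerance(p$isotope_grouper$mz_tol_abs,
                              p$isotope_grouper$mz_tol_ppm),
                 p$isotope_grouper$rt_tol, p$isotope_grouper$max_charge,
                 p$isotope_grouper$monotonic)
}
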