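# Per-run feature extraction: crop, detection, chromatogram building,
# deconvolution, duration filter, isotope grouping.

test_that("crop keeps exactly the in-range scans and is idempotent", {
  r <- gaussian_run(data.frame(mz = c(150, 300), rt = c(1, 2),
                               height = c(5e4, 5e4)))
  inside <- crop(r, c(1, 1130), c(0.01, 12.51), c(100, 1200))
  expect_identical(inside$scans, r$scans)
  # plant 5 out-of-m/z-range centroids; crop removes exactly those
  s5 <- r$scans[!duplicated(r$scans$scan), ][1:5, ]
  bad <- data.frame(scan = s5$scan, rt = s5$rt, mz = 50 + 1:5,
                    intensity = rep(1e4, 5))
  r2 <- centroid_run(rbind(r$scans, bad))
  cropped <- crop(r2)
  expect_identical(nrow(r2$scans) - nrow(cropped$scans), 5L)
  expect_true(all(cropped$scans$mz >= 100))
  expect_identical(crop(cropped), cropped)       # idempotent
  expect_error(crop(r, scan_range = c(10, 1)), "ordered")
})

test_that("mass detection threshold is inclusive at the noise level", {
  s <- data.frame(scan = c(1, 1, 1), rt = 0.5, mz = c(200, 300, 400),
                  intensity = c(599, 600, 601))
  r <- centroid_run(s)
  kept <- detect_masses(r, 6.0e2)
  expect_identical(kept$scans$intensity, c(600, 601))
  expect_identical(detect_masses(r, 0)$scans, r$scans)     # level 0 identity
  expect_identical(detect_masses(kept, 6.0e2)$scans, kept$scans) # idempotent
  empty <- centroid_run(s[0, ])
  expect_identical(nrow(detect_masses(empty, 6.0e2)$scans), 0L)
})

test_that("chromatogram builder connects peaks and separates close masses", {
  one <- gaussian_run(data.frame(mz = 400, rt = 2, height = 2e4))
  tr <- build_chromatograms(one)
  expect_length(tr, 1L)
  expect_equal(attr(tr[[1]], "rep_mz"), 400, tolerance = 1e-9)
  # 0.1 Th apart at 0.01 Th tolerance: never merged
  two <- gaussian_run(data.frame(mz = c(400, 400.1), rt = c(2, 2),
                                 height = c(2e4, 2e4)))
  expect_length(build_chromatograms(two), 2L)
  # single-scan spike has span 0 < 0.01 min
  spike <- centroid_run(data.frame(scan = 10, rt = 1, mz = 500,
                                   intensity = 5e4))
  expect_length(build_chromatograms(spike), 0L)
  # sub-min-height trace dropped
  faint <- gaussian_run(data.frame(mz = 400, rt = 2, height = 4.9e3))
  expect_length(build_chromatograms(faint), 0L)
})

test_that("baseline cut-off deconvolution splits bimodal traces and applies thresholds", {
  rt <- seq(1, 2, by = 0.005)
  bimodal <- data.frame(scan = seq_along(rt), rt = rt, mz = 400,
                        intensity = 2e4 * exp(-(rt - 1.25)^2 / (2 * 0.03^2)) +
                          2e4 * exp(-(rt - 1.75)^2 / (2 * 0.03^2)) + 5e3)
  f <- deconvolve(bimodal, baseline = 9e3, min_height = 1e4,
                  duration_range = c(0, 2))
  expect_identical(nrow(f), 2L)
  expect_equal(sort(f$rt), c(1.25, 1.75), tolerance = 0.01)
  expect_true(all(f$area > 0))
  # flat trace below baseline: nothing
  flat <- data.frame(scan = 1:50, rt = seq(1, 1.25, length.out = 50),
                     mz = 400, intensity = 8e3)
  expect_identical(nrow(deconvolve(flat)), 0L)
  # above baseline but under the minimum peak height: nothing
  low <- data.frame(scan = 1:50, rt = seq(1, 1.25, length.out = 50), mz = 400,
                    intensity = 9.5e3 * exp(-(seq(1, 1.25, length.out = 50) - 1.1)^2 / (2 * 0.03^2)))
  expect_identical(nrow(deconvolve(low)), 0L)
})

test_that("deconvolution threshold is sharp at the minimum peak height", {
  mk <- function(h) {
    r <- gaussian_run(data.frame(mz = c(300, 500), rt = c(1, 2),
                                 height = c(h, 5e4)))
    tr <- build_chromatograms(r)
    do.call(rbind, lapply(tr, deconvolve))
  }
  expect_identical(nrow(mk(1.0e4)), 2L)   # exactly at threshold: kept
  expect_identical(nrow(mk(0.99e4)), 1L)  # just below: that peak alone lost
})

test_that("duration filter keeps apexes inside the window", {
  f <- data.frame(mz = c(200, 300, 400), rt = c(0.5, 12.3, 6),
                  height = 1e5, area = 1, charge = NA_integer_,
                  iso_group = NA_integer_, representative = TRUE)
  kept <- duration_filter(f, c(0.01, 12.01))
  expect_identical(kept$mz, c(200, 400))
  expect_identical(duration_filter(kept, c(0.01, 12.01)), kept)
  expect_identical(nrow(duration_filter(f[0, ], c(0.01, 12.01))), 0L)
})

test_that("isotope grouping chains the 13C ladder with a monotonic rule", {
  f2 <- data.frame(mz = c(400, 401.0034), rt = c(2, 2.01),
                   height = c(1e5, 1.1e4), area = 1, charge = NA_integer_,
                   iso_group = NA_integer_, representative = TRUE)
  g <- group_isotopes(f2)
  expect_identical(length(unique(g$iso_group)), 1L)
  expect_identical(g$mz[g$representative], 400)
  expect_identical(unique(g$charge), 1L)
  # unrelated features 5 Th apart: singleton groups
  f3 <- data.frame(mz = c(400, 405), rt = c(2, 2), height = c(1e5, 1e5),
                   area = 1, charge = NA_integer_, iso_group = NA_integer_,
                   representative = TRUE)
  g3 <- group_isotopes(f3)
  expect_identical(length(unique(g3$iso_group)), 2L)
  # A+1 taller than A+0 violates monotonic shape: not grouped
  f4 <- f2
  f4$height <- c(1.1e4, 1e5)
  g4 <- group_isotopes(f4, monotonic = TRUE)
  expect_identical(length(unique(g4$iso_group)), 2L)
  g4b <- group_isotopes(f4, monotonic = FALSE)
  expect_identical(length(unique(g4b$iso_group)), 1L)
})

test_that("grouping conserves features: each appears exactly once", {
  set.seed(4)
  n <- 40L
  f <- data.frame(mz = runif(n, 100, 1200), rt = runif(n, 0.5, 11),
                  height = 10^runif(n, 4, 6), area = 1,
                  charge = NA_integer_, iso_group = NA_integer_,
                  representative = TRUE)
  g <- group_isotopes(f)
  expect_identical(nrow(g), n)
  expect_setequal(round(g$mz, 9), round(f$mz, 9))
  expect_false(any(is.na(g$iso_group)))
  # exactly one representative per group
  reps <- tapply(g$representative, g$iso_group, sum)
  expect_true(all(reps == 1))
})

test_that("extraction recovers planted peaks 1-to-1 within tolerance", {
  # noise sds at half the matching tolerances (builder window is ~8 ppm at
  # the top of the m/z range, so 5 ppm per centroid would violate the
  # half-tolerance precondition and split traces)
  cfg <- small_sim_config(77, mz_error_ppm = 2.5, rt_jitter_sd = 0.02)
  sig <- make_signatures(cfg)
  r <- simulate_run(sig, c(TBR = 1), "TA", cfg, run_id = "rec")
  feats <- extract_features(r$run)
  reps <- feats[feats$representative, ]
  truth <- r$truth
  matched <- vapply(seq_len(nrow(truth)), function(i) {
    sum(abs(reps$mz - truth$mz[i]) / truth$mz[i] < 10e-6 &
          abs(reps$rt - truth$rt[i]) < 0.05)
  }, numeric(1))
  expect_true(all(matched == 1))          # every planted compound found once
  expect_identical(nrow(reps), nrow(truth))  # and nothing else survives
})
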