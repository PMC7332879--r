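# Radiocarbon calibration of a conventional 14C age against a calibration
# curve, with highest-posterior-density calendar intervals.

#' Read a radiocarbon calibration curve file
#'
#' Reads the 3-column `.14c` dialect: comment lines starting with `#`,
#' whitespace- or comma-separated columns `cal BP`, `conventional 14C age
#' (yr BP)`, `curve sigma (yr)`; any further columns are ignored. Rows are
#' sorted by cal BP.
#'
#' @param path Path to the curve file.
#' @return A `cal_curve` data.frame with columns `calbp`, `c14age`,
#'   `sigma`.
#' @export
read_cal_curve <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[,[:space:]]+")
  keep <- vapply(fields, length, integer(1)) >= 3
  vals <- t(vapply(fields[keep], function(f) as.numeric(f[1:3]), numeric(3)))
  curve <- data.frame(calbp = vals[, 1], c14age = vals[, 2], sigma = vals[, 3])
  curve <- curve[order(curve$calbp), , drop = FALSE]
  if (anyDuplicated(curve$calbp)) stop("duplicate cal BP knots in curve")
  if (any(curve$sigma < 0)) stop("negative curve sigma")
  rownames(curve) <- NULL
  class(curve) <- c("cal_curve", "data.frame")
  curve
}

#' Make a synthetic calibration curve
#'
#' Identity-like curve for testing: `c14age(t) = slope * t + intercept`
#' with constant curve sigma.
#'
#' @param calbp_range Range of cal BP years.
#' @param step Knot spacing, yr.
#' @param slope,intercept Linear map cal BP -> 14C age.
#' @param sigma Constant curve sigma, yr.
#' @return A `cal_curve`.
#' @export
synthetic_cal_curve <- function(calbp_range = c(0, 3000), step = 5,
                                slope = 1, intercept = 0, sigma = 0) {
  t <- seq(calbp_range[1], calbp_range[2], by = step)
  structure(data.frame(calbp = t, c14age = slope * t + intercept,
                       sigma = sigma),
            class = c("cal_curve", "data.frame"))
}

#' Calibrate a conventional radiocarbon age
#'
#' Grid posterior over calendar years: at each cal BP year `t` the
#' likelihood is `Normal(age; curve(t), sqrt(sigma^2 + curve_sigma(t)^2))`
#' with the curve linearly interpolated between knots; the density is
#' normalized over the grid. Highest-posterior-density intervals at the
#' requested coverage are built by accumulating grid cells in decreasing
#' density order and merging contiguous cells; `p_single` reports the mass
#' fraction of the largest interval (1.0 when a single interval carries
#' all coverage mass).
#'
#' @param age Conventional 14C age, yr BP.
#' @param sigma Measurement sigma, yr (> 0; 0 allowed as a limiting case
#'   on curves with positive curve sigma).
#' @param curve A `cal_curve`.
#' @param coverage HPD coverage (default 0.954, i.e. 2 sigma).
#' @param step Grid step in yr (default 1).
#' @return A `cal_result`: list with `grid` (cal BP years), `density`
#'   (sums to 1), `intervals` (data.frame `lo`, `hi`, `mass`, cal BP),
#'   `coverage`, `p_single`, `age`, `sigma`.
#' @export
calibrate <- function(age, sigma, curve, coverage = 0.954, step = 1) {
  stopifnot(sigma >= 0, coverage > 0, coverage < 1)
  rng <- range(curve$c14age)
  span <- 4 * sqrt(sigma^2 + max(curve$sigma)^2)
  if (age < rng[1] - span || age > rng[2] + span)
    stop(sprintf("age %g BP outside curve support [%g, %g] 14C yr BP",
                 age, rng[1], rng[2]))
  grid <- seq(min(curve$calbp), max(curve$calbp), by = step)
  mu <- stats::approx(curve$calbp, curve$c14age, grid)$y
  tau <- stats::approx(curve$calbp, curve$sigma, grid)$y
  sd_t <- sqrt(sigma^2 + tau^2)
  if (any(sd_t == 0)) sd_t[sd_t == 0] <- .Machine$double.eps
  dens <- stats::dnorm(age, mu, sd_t)
  if (sum(dens) == 0) stop("zero posterior mass on grid; age outside support")
  dens <- dens / sum(dens)
  ord <- order(dens, decreasing = TRUE)
  cum <- cumsum(dens[ord])
  n_in <- which(cum >= coverage)[1]
  sel <- sort(ord[seq_len(n_in)])
  brk <- c(0, which(diff(sel) > 1), length(sel))
  intervals <- do.call(rbind, lapply(seq_len(length(brk) - 1), function(i) {
    cells <- sel[(brk[i] + 1):brk[i + 1]]
    data.frame(lo = grid[cells[1]], hi = grid[cells[length(cells)]],
               mass = sum(dens[cells]))
  }))
  intervals <- intervals[order(-intervals$mass), , drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(grid = grid, density = dens, intervals = intervals,
                 coverage = coverage,
                 p_single = intervals$mass[1] / sum(intervals$mass),
                 age = age, sigma = sigma),
            class = "cal_result")
}

#' @export
print.cal_result <- function(x, ...) {
  cat(sprintf("Calibration of %g +/- %g 14C yr BP (%.1f%% coverage):\n",
              x$age, x$sigma, 100 * x$coverage))
  for (i in seq_len(nrow(x$intervals)))
    cat(sprintf("  %g-%g cal BP (p = %.3f)\n", x$intervals$lo[i],
                x$intervals$hi[i],
                x$intervals$mass[i] / sum(x$intervals$mass)))
  invisible(x)
}
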