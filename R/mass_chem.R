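# Elemental-formula arithmetic, adduct conventions, isotope-pattern
# simulation and constrained formula prediction from accurate mass.

# NIST/CODATA isotope masses (6 d.p.) and natural abundances.
.element_isotopes <- data.frame(
  element     = c("H","H", "C","C", "N","N", "O","O","O",
                  "Na", "P", "S","S","S","S", "K","K","K"),
  mass_number = c(1L,2L, 12L,13L, 14L,15L, 16L,17L,18L,
                  23L, 31L, 32L,33L,34L,36L, 39L,40L,41L),
  mass        = c(1.007825, 2.014102, 12.000000, 13.003355,
                  14.003074, 15.000109, 15.994915, 16.999132, 17.999160,
                  22.989769, 30.973762, 31.972071, 32.971459, 33.967867,
                  35.967081, 38.963706, 39.963998, 40.961825),
  abundance   = c(0.999885, 0.000115, 0.989300, 0.010700,
                  0.996360, 0.003640, 0.997570, 0.000380, 0.002050,
                  1.000000, 1.000000, 0.949900, 0.007500, 0.042500,
                  0.000100, 0.932581, 0.000117, 0.067302),
  stringsAsFactors = FALSE
)

.ELECTRON_MASS <- 0.000549  # Da

#' Element isotope mass and abundance table
#'
#' The bundled NIST/CODATA table of isotope monoisotopic masses (6 decimal
#' places) and natural abundances used by all mass arithmetic in the package.
#' The same table ships as a plain-text file under
#' `system.file("extdata", "element_masses.csv", package = "residuomics")`.
#'
#' @return A data.frame with columns `element`, `mass_number`, `mass` (Da)
#'   and `abundance` (fraction).
#' @export
element_table <- function() .element_isotopes

# Monoisotopic mass per element = mass of the most abundant isotope.
.mono_masses <- local({
  tab <- .element_isotopes
  vapply(split(tab, tab$element), function(d) d$mass[which.max(d$abundance)],
         numeric(1))
})

#' Parse a molecular formula string
#'
#' Turns `"C10H14N2"` into a named integer vector of element counts.
#' Multi-letter symbols (e.g. `Na`) are supported; an empty string is the
#' empty formula.
#'
#' @param formula A formula string, or an already-parsed named numeric vector
#'   (returned unchanged after validation).
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    if (length(formula) && is.null(names(formula)))
      stop("numeric formula must be a named count vector")
    counts <- formula
  } else {
    stopifnot(is.character(formula), length(formula) == 1L)
    s <- gsub("\\s", "", formula)
    counts <- integer(0)
    if (nzchar(s)) {
      m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
      parts <- regmatches(s, list(m))[[1]]
      if (sum(nchar(parts)) != nchar(s))
        stop("cannot parse formula: ", formula)
      sym <- sub("[0-9]*$", "", parts)
      n <- as.integer(ifelse(grepl("[0-9]+$", parts),
                             sub("^[A-Za-z]+", "", parts), "1"))
      counts <- tapply(n, sym, sum)
      counts <- stats::setNames(as.integer(counts), names(counts))
    }
  }
  counts <- counts[counts != 0]
  if (any(counts < 0)) stop("negative element count")
  bad <- setdiff(names(counts), names(.mono_masses))
  if (length(bad))
    stop("unsupported element symbol: ", paste(bad, collapse = ", "))
  counts
}

#' Format element counts as a formula string (Hill order)
#' @param counts Named count vector as returned by [parse_formula()].
#' @return Character scalar such as `"C10H14N2"`.
#' @export
formula_string <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) return("")
  syms <- names(counts)
  ord <- if ("C" %in% syms) {
    c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  } else sort(syms)
  counts <- counts[ord]
  paste0(names(counts), ifelse(counts == 1, "", counts), collapse = "")
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of element counts times tabulated monoisotopic atomic masses.
#' The empty formula has mass 0.
#'
#' @param formula Formula string or named count vector.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C10H14N2")   # nicotine, 162.1157
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  if (!length(counts)) return(0)
  sum(counts * .mono_masses[names(counts)])
}

#' Build an adduct specification
#'
#' Parses positive-mode adduct strings of the form `"[M+H]+"`, `"[M+Na]+"`,
#' `"[M+2Na]+"` or `"[M+2H]2+"`. Under the default `"atom"` hydrogen
#' convention, `+H` adds the hydrogen *atom* mass (1.007825 Da) with no
#' electron correction — the convention that reproduces the leucine
#' enkephalin lock mass 556.2771 printed for quadrupole time-of-flight
#' lockspray calibration. With `hydrogen = "proton"` the electron mass times
#' charge is subtracted from the delta.
#'
#' @param name Adduct string.
#' @param hydrogen `"atom"` (default) or `"proton"`.
#' @return An object of class `adduct_spec` with fields `name`, `delta`
#'   (Da), `charge`, `hydrogen`.
#' @export
adduct_spec <- function(name = "[M+H]+", hydrogen = c("atom", "proton")) {
  hydrogen <- match.arg(hydrogen)
  m <- regmatches(name,
    regexec("^\\[M((?:[+-][0-9]*[A-Za-z][A-Za-z0-9]*)+)\\]([0-9]*)\\+$", name))[[1]]
  if (!length(m)) stop("cannot parse adduct: ", name)
  charge <- if (nzchar(m[3])) as.integer(m[3]) else 1L
  if (charge < 1) stop("adduct charge must be >= 1")
  terms <- regmatches(m[2],
    gregexpr("[+-][0-9]*[A-Za-z][A-Za-z0-9]*", m[2]))[[1]]
  delta <- 0
  for (t in terms) {
    sgn <- if (substr(t, 1, 1) == "+") 1 else -1
    body <- substring(t, 2)
    mult <- 1L
    if (grepl("^[0-9]", body)) {
      mult <- as.integer(sub("^([0-9]+).*$", "\\1", body))
      body <- sub("^[0-9]+", "", body)
    }
    delta <- delta + sgn * mult * monoisotopic_mass(body)
  }
  if (hydrogen == "proton") delta <- delta - charge * .ELECTRON_MASS
  structure(list(name = name, delta = delta, charge = charge,
                 hydrogen = hydrogen),
            class = "adduct_spec")
}

#' @export
print.adduct_spec <- function(x, ...) {
  cat(sprintf("<adduct %s: delta %+0.6f Da, charge %d, %s convention>\n",
              x$name, x$delta, x$charge, x$hydrogen))
  invisible(x)
}

.as_adduct <- function(adduct) {
  if (inherits(adduct, "adduct_spec")) adduct else adduct_spec(adduct)
}

#' Theoretical m/z of a formula under an adduct
#'
#' `(monoisotopic mass + adduct delta) / charge`. The empty formula gives
#' the bare adduct m/z.
#'
#' @param formula Formula string or named count vector.
#' @param adduct Adduct string or [adduct_spec()] object.
#' @return m/z in Th.
#' @examples
#' adduct_mz("C28H37N5O7", "[M+H]+")  # leucine enkephalin lock mass 556.2771
#' @export
adduct_mz <- function(formula, adduct = "[M+H]+") {
  a <- .as_adduct(adduct)
  (monoisotopic_mass(formula) + a$delta) / a$charge
}

# Convolve two (probability, mass-moment) isotopologue distributions,
# truncated to n terms.
.iso_convolve <- function(a, b, n) {
  la <- length(a$p); lb <- length(b$p)
  p <- numeric(n); m <- numeric(n)
  for (k in seq_len(n)) {
    i <- seq_len(min(la, k))
    j <- k - i + 1L
    keep <- j <= lb
    i <- i[keep]; j <- j[keep]
    if (!length(i)) next
    p[k] <- sum(a$p[i] * b$p[j])
    m[k] <- sum(a$m[i] * b$p[j] + a$p[i] * b$m[j])
  }
  list(p = p, m = m)
}

# Per-element single-atom distribution over nucleon shifts 0,1,2,...
.element_iso_dist <- function(element, n) {
  iso <- .element_isotopes[.element_isotopes$element == element, ]
  mono <- which.max(iso$abundance)
  shift <- iso$mass_number - iso$mass_number[mono]
  dmass <- iso$mass - iso$mass[mono]
  keep <- shift >= 0
  p <- numeric(n); m <- numeric(n)
  idx <- shift[keep] + 1L
  ok <- idx <= n
  p[idx[ok]] <- iso$abundance[keep][ok]
  m[idx[ok]] <- iso$abundance[keep][ok] * dmass[keep][ok]
  list(p = p, m = m)
}

#' Simulate the isotopologue envelope of a formula
#'
#' Polynomial convolution of per-element isotope distributions, aggregated
#' by nucleon shift (A+0, A+1, ...), normalized so the base (most intense)
#' peak has relative abundance 1. Peak m/z offsets are the exact
#' probability-weighted mean mass shifts of each aggregated isotopologue,
#' divided by the adduct charge when an adduct is given. Adduct atoms are
#' not included in the envelope (negligible for the supported adducts).
#'
#' @param formula Formula string or named count vector.
#' @param adduct Optional adduct (divides offsets by charge).
#' @param n_peaks Number of envelope peaks (>= 1).
#' @return data.frame of class `isotope_pattern` with columns `offset`
#'   (m/z offset from the monoisotopic peak, Th) and `abundance`
#'   (fraction of base peak); attribute `total_prob` holds the
#'   un-normalized total isotopologue probability covered.
#' @export
simulate_isotope_pattern <- function(formula, adduct = NULL, n_peaks = 3L) {
  stopifnot(n_peaks >= 1)
  counts <- parse_formula(formula)
  dist <- list(p = c(1, numeric(n_peaks - 1L)), m = numeric(n_peaks))
  for (el in names(counts)) {
    single <- .element_iso_dist(el, n_peaks)
    # exponentiation by squaring over the convolution monoid
    k <- counts[[el]]
    base <- single
    while (k > 0) {
      if (k %% 2 == 1) dist <- .iso_convolve(dist, base, n_peaks)
      k <- k %/% 2
      if (k > 0) base <- .iso_convolve(base, base, n_peaks)
    }
  }
  offs <- ifelse(dist$p > 0, dist$m / dist$p, 0)
  z <- if (is.null(adduct)) 1L else .as_adduct(adduct)$charge
  keep <- dist$p > 0
  out <- data.frame(offset = offs[keep] / z,
                    abundance = dist$p[keep] / max(dist$p[keep]))
  attr(out, "total_prob") <- sum(dist$p)
  class(out) <- c("isotope_pattern", "data.frame")
  out
}

#' Score agreement between observed and theoretical isotope patterns
#'
#' `100 * (1 - sum|obs_i - theo_i| / sum theo_i)` over envelope peaks
#' matched by index (A+0, A+1, ...), clipped below at 0. Both patterns are
#' base-peak normalized before comparison; a peak missing from one side
#' counts as abundance 0.
#'
#' @param observed,theoretical Patterns from [simulate_isotope_pattern()]
#'   or data.frames with an `abundance` column.
#' @return Score in percent, within \[0, 100\].
#' @export
isotope_score <- function(observed, theoretical) {
  obs <- observed$abundance / max(observed$abundance)
  theo <- theoretical$abundance / max(theoretical$abundance)
  n <- max(length(obs), length(theo))
  obs <- c(obs, numeric(n - length(obs)))
  theo <- c(theo, numeric(n - length(theo)))
  max(0, 100 * (1 - sum(abs(obs - theo)) / sum(theo)))
}

#' Predict molecular formulas from an accurate m/z
#'
#' Exhaustive enumeration of element-count lattices within per-element
#' ranges, keeping formulas whose adduct m/z falls within a ppm tolerance
#' of the query. Hydrogen counts are solved arithmetically from the mass
#' window rather than looped, which makes the search exhaustive but fast;
#' the result equals a full brute-force enumeration over the ranges.
#' Candidates are sorted by absolute mass error (ppm) ascending, with ties
#' broken lexicographically by element counts in the order the ranges are
#' given. With an observed isotope pattern, candidates scoring below
#' `min_isotope_score` are dropped. Ring-double-bond-equivalent and
#' nitrogen-rule filters are available but off by default.
#'
#' @param query_mz Query m/z in Th.
#' @param tolerance_ppm Mass tolerance in ppm (> 0).
#' @param ranges Named list of `c(min, max)` element count ranges, e.g.
#'   `list(C = c(0, 50), H = c(0, 100), N = c(0, 5), O = c(0, 40))`.
#' @param adduct Adduct string or [adduct_spec()].
#' @param observed_pattern Optional observed [simulate_isotope_pattern()]
#'   style data.frame used for isotope-pattern filtering.
#' @param min_isotope_score Minimum isotope score in percent (default 95).
#' @param rdbe_filter,nitrogen_rule Optional validity filters, default off.
#' @return data.frame with one row per candidate: element counts, `formula`,
#'   `theo_mz`, `ppm_error` (signed, observed vs theory), `isotope_score`
#'   (NA when no pattern given).
#' @export
predict_formulas <- function(query_mz, tolerance_ppm = 3,
                             ranges = list(C = c(0, 50), H = c(0, 100),
                                           N = c(0, 5), O = c(0, 40)),
                             adduct = "[M+H]+",
                             observed_pattern = NULL,
                             min_isotope_score = 95,
                             rdbe_filter = FALSE, nitrogen_rule = FALSE) {
  if (tolerance_ppm <= 0) stop("tolerance_ppm must be > 0")
  if (!length(ranges)) stop("element ranges must be non-empty")
  bad <- setdiff(names(ranges), names(.mono_masses))
  if (length(bad)) stop("unsupported element symbol: ", paste(bad, collapse = ", "))
  a <- .as_adduct(adduct)
  target <- query_mz * a$charge - a$delta       # neutral mass window center
  tol_da <- tolerance_ppm * 1e-6 * query_mz * a$charge

  els <- names(ranges)
  solve_el <- if ("H" %in% els) "H" else els[[length(els)]]
  others <- setdiff(els, solve_el)
  grid <- if (length(others)) {
    do.call(expand.grid, c(lapply(ranges[others],
                                  function(r) seq.int(r[1], r[2])),
                           KEEP.OUT.ATTRS = FALSE))
  } else data.frame(row.names = 1)
  base_mass <- if (length(others)) {
    as.numeric(as.matrix(grid) %*% .mono_masses[others])
  } else rep(0, nrow(grid))

  m_solve <- .mono_masses[[solve_el]]
  r_solve <- ranges[[solve_el]]
  lo <- pmax(r_solve[1], ceiling((target - tol_da - base_mass) / m_solve - 1e-9))
  hi <- pmin(r_solve[2], floor((target + tol_da - base_mass) / m_solve + 1e-9))
  rows <- which(lo <= hi)
  out <- do.call(rbind, lapply(rows, function(i) {
    n <- seq.int(lo[i], hi[i])
    cand <- grid[rep(i, length(n)), , drop = FALSE]
    cand[[solve_el]] <- n
    cand
  }))
  if (is.null(out)) out <- stats::setNames(
    as.data.frame(matrix(integer(0), 0, length(els))), els)
  out <- out[, els, drop = FALSE]
  rownames(out) <- NULL

  mass <- if (nrow(out)) {
    as.numeric(as.matrix(out) %*% .mono_masses[els])
  } else numeric(0)
  theo_mz <- (mass + a$delta) / a$charge
  ppm <- (query_mz - theo_mz) / theo_mz * 1e6
  keep <- abs(query_mz - theo_mz) <= tol_da / a$charge + 1e-12
  out <- out[keep, , drop = FALSE]; theo_mz <- theo_mz[keep]; ppm <- ppm[keep]

  cnt <- function(e) if (e %in% els) out[[e]] else 0
  if (nitrogen_rule && nrow(out)) {
    # N count parity must match nominal neutral-mass parity
    nmass <- round(theo_mz * a$charge - a$delta)
    keep <- (cnt("N") %% 2) == (nmass %% 2)
    out <- out[keep, , drop = FALSE]; theo_mz <- theo_mz[keep]; ppm <- ppm[keep]
  }
  if (rdbe_filter && nrow(out)) {
    rdbe <- cnt("C") + 1 - cnt("H") / 2 + cnt("N") / 2
    keep <- rdbe >= 0
    out <- out[keep, , drop = FALSE]; theo_mz <- theo_mz[keep]; ppm <- ppm[keep]
  }

  iso <- rep(NA_real_, nrow(out))
  if (!is.null(observed_pattern) && nrow(out)) {
    npk <- nrow(observed_pattern)
    iso <- vapply(seq_len(nrow(out)), function(i) {
      f <- stats::setNames(as.integer(out[i, ]), els)
      isotope_score(observed_pattern,
                    simulate_isotope_pattern(f, adduct = a, n_peaks = npk))
    }, numeric(1))
    keep <- iso >= min_isotope_score
    out <- out[keep, , drop = FALSE]
    theo_mz <- theo_mz[keep]; ppm <- ppm[keep]; iso <- iso[keep]
  }

  ord <- do.call(order, c(list(abs(ppm)), as.list(out)))
  out <- out[ord, , drop = FALSE]
  res <- cbind(out,
               data.frame(formula = vapply(seq_len(nrow(out)), function(i)
                 formula_string(stats::setNames(as.integer(out[i, ]), els)),
                 character(1)),
                 theo_mz = theo_mz[ord], ppm_error = ppm[ord],
                 isotope_score = iso[ord],
                 stringsAsFactors = FALSE))
  rownames(res) <- NULL
  res
}
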