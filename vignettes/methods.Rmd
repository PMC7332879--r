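---
title: "Ancient residue metabolomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancient residue metabolomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The inference

The package attributes plant-species use in an artifact by presence/absence
set intersection. Each sample — experimentally smoked reference pipe, blank
pipe, QC pool, or artifact residue — yields, after feature extraction,
alignment and curation, a *compound list*: the set of aligned feature rows
in which the sample has abundance. For an artifact list $T$ and reference
lists $R_s$ (one per candidate species $s$),

$$\mathrm{shared}(s) = |T \cap R_s|, \qquad
  \mathrm{exclusive}(s) = \bigl|R_s \setminus \bigcup_{t \ne s} R_t\bigr|,$$

and species are ranked by shared count. The inference is deliberately
presence/absence: residue abundances on a centuries-old artifact reflect
degradation and taphonomy at least as much as original deposition, so
abundance-weighted or probabilistic mixture deconvolution is out of scope.
The ranking is reported as evidence, not as a thresholded "use" call — a
species sharing zero compounds is simply unranked.

Intersections are computed on aligned row ids, not by re-matching masses
between lists. This assumes all runs — references, blanks, QC pools and
artifacts — were aligned in one batch/matrix, which mirrors the underlying
experimental design (QC standards acquired in the same batch as the
artifact extracts) and avoids stacking a second tolerance layer on top of
the aligner's.

## Feature extraction

The per-run chain mirrors the standard untargeted processing steps, with
the printed parameter values as defaults (see `default_config()`):

1. **Crop**: scans 1–1130, RT 0.01–12.51 min, *m/z* 100–1200. Inclusive
   bounds; an empty result is legal.
2. **Mass detection**: centroids below 6.0·10² counts are dropped. The
   threshold is inclusive (≥), as for every "minimum" parameter in the
   package; "baseline" cuts are exclusive (>). These boundary conventions
   are fixed in the config documentation and asserted by tests.
3. **Chromatogram building**: single-pass greedy connection. Scan by scan,
   each centroid joins the open trace whose running intensity-weighted
   mean *m/z* lies within the tolerance window (closest wins; within one
   scan, more intense centroids are assigned first); otherwise it opens a
   new trace. Traces need span ≥ 0.01 min and apex ≥ 5.0·10³. No algorithm
   variant is named by the source method; greedy closest-assignment is the
   simplest construction satisfying the stated parameters, and its
   order-sensitivity only matters for borderline cases flagged in tests.
4. **Duration filter**: the source text is ambiguous about whether
   0.01–12.01 min is a keep- or drop-window for mobile-phase artifacts.
   It is implemented as a configurable *keep*-window (default
   0.01–12.01 min): mobile-phase peaks accumulate at the extremes of the
   gradient, so keeping the interior excludes them.
5. **Deconvolution**: baseline cut-off. Maximal contiguous trace regions
   strictly above 9.0·10³ become candidates; kept if apex ≥ 1.0·10⁴ and
   duration within 0–2 min. Feature *m/z* is the intensity-weighted mean
   over the region, area the trapezoidal integral.
6. **Isotope grouping**: features within 0.05 min whose *m/z* differ by
   1.00336/z are chained (z ≤ 1 by default), with non-increasing heights
   when monotonic shape is on; the most intense member represents the
   group downstream.

**Tolerance semantics.** Every "X m/z or Y ppm" tolerance is the *wider* of
the absolute and relative windows at the query *m/z*
(`max(X, Y·m/z·10⁻⁶)`). The formula-prediction tolerance "0.0 m/z or
3.0 ppm" therefore degenerates to a pure ppm window.

## Alignment and curation

The join aligner processes runs in lexicographic run-id order (the
reference implementation leaves this unstated; greedy alignment is
order-sensitive for borderline pairs, so the order is pinned). Features are
matched to the best-scoring existing row within both tolerances,

$$\mathrm{score} = w_{mz}\Bigl(1 - \frac{\Delta m/z}{tol_{mz}}\Bigr)
                 + w_{rt}\Bigl(1 - \frac{\Delta RT}{tol_{rt}}\Bigr),$$

with $w_{mz} = w_{rt} = 10$; a run contributes at most one feature per row.
Cells record peak height, not area — the processing thresholds are all
height-driven — and the choice is configurable.

"Shared with the blank pipes" is read conservatively: a row present in
*any* blank run is removed (an all-blank-replicates option exists). Blank
columns are dropped afterwards. Merging a sample's TA/APW/MTBE columns is a
plain union with per-row maximum abundance; rows empty across the sample
are excluded.

## Formula prediction

Candidates are enumerated exhaustively over per-element count ranges
(default C 0–50, H 0–100, N 0–5, O 0–40), keeping formulas whose adduct
*m/z* lies within the ppm window, sorted by |mass error| with lexicographic
(C,H,N,O) tie-break. Hydrogen counts are solved arithmetically from the
mass window rather than looped; tests assert equality with a full
brute-force lattice enumeration.

**Hydrogen convention.** `[M+H]+` adds the hydrogen *atom* mass
(1.007825 Da) with no electron correction — the only convention that
reproduces the printed leucine enkephalin lock mass 556.2771. An
electron-corrected proton option exists (`adduct_spec(..., "proton")`).
The printed biomarker *m/z* values (nicotine "163.125") deviate from any
convention by >10 ppm and are treated as observed instrument values: stored
in the biomarker library, never used as theoretical ground truth.

**Isotope score.** Only a 95% minimum is stated by the source method, not a
formula. The package uses
$100\,(1 - \sum_i |obs_i - theo_i| / \sum_i theo_i)$ over envelope peaks
matched by index, clipped at 0 — simple, bounded in [0, 100], and monotone
in agreement. No ring-double-bond or nitrogen-rule filters are applied by
default (none are stated); both exist as off-by-default options.

## Ordination

Jaccard distances, presence/absence coding and the Pareto transform
$x' = (x - \bar{x})/\sqrt{s_x}$ are implemented in-package (they are the
method-specified parts); stress minimization is delegated to
`vegan::monoMDS` and eigendecomposition to `stats::prcomp`. NMDS defaults —
$k = 2$, 20 starts (first start classical scaling, rest random), Kruskal
stress-1, global model — are unreported by the source and fixed here;
`nmds_stress()` recomputes stress independently via pool-adjacent-violators
monotone regression as a cross-check. Whether Ward clustering fed the NMDS
input or only the display grouping is unstated; the package computes
`ward.D` (unsquared distances) on the Jaccard matrix and attaches it as a
display grouping, the default reading. Missing abundances are zeros for
PCA, matching the presence/absence semantics of the exported table;
zero-variance features are dropped with a warning since $\sqrt{s_x}$ is
undefined at 0.

## Radiocarbon calibration

The posterior over calendar years is the standard grid construction:
likelihood $\mathcal{N}(a;\, \mu(t), \sqrt{\sigma^2 + \tau(t)^2})$ with the
curve linearly interpolated, normalized over a 1-yr grid. HPD intervals
accumulate grid cells in decreasing density order and merge contiguous
runs. The published IntCal13 file cannot be redistributed inside the
package and the build environment has no network access; the engine is
therefore validated against synthetic curves and a brute-force quadrature
oracle, and the printed-date check (1520 ± 40 BP → 1334–1524 cal BP, 2σ)
runs whenever a local IntCal13 copy is present (path via the
`RESIDUOMICS_INTCAL13` environment variable or
`inst/extdata/intcal13.14c`).

## The synthetic-data generator

`make_study()` emulates the stated experimental design: 8 reference
species × 3 solvents × 5 replicate pipes, blank pipes, one QC pool per
(species + blank) × solvent (27 in the full design), and ancient samples
as weighted species mixtures. Within that stated world the generator's
free knobs, unquantified by the source, were fixed once at values a
practitioner would call realistic and are not revisited:

- **Cross-species signature overlap** 10% per pair, exact by construction
  (each unordered pair shares its own block of compounds). The source
  reports overlap counts only for its real data; 10% of a 40-compound
  signature gives distractor sharing comparable to its Table of shared
  counts.
- **Signature size** 40 compounds/species, **blank background** 15,
  **contaminants** 10 — within the per-run feature counts implied by the
  real data after curation.
- **Abundances** log-normal with mean log₁₀ height uniform in [4.7, 5.7]
  (so planted peaks clear the 1.0·10⁴ deconvolution minimum with margin),
  log₁₀ sd 0.15.
- **Peak shape** Gaussian, sd 0.05 min — no peak shape is stated; Gaussian
  is the minimal testable choice. **Scan interval** 0.3 s, the stated scan
  time.
- **Noise** 5 ppm per-centroid *m/z* sd and 0.02 min RT jitter by default
  (the levels the acceptance criteria stipulate), plus a sparse uniform
  noise floor strictly below the 6.0·10² detection level to exercise the
  detector threshold.
- **PRNG**: R's Mersenne-Twister, with each run drawing from a substream
  seeded deterministically from (seed, run id), so any single run is
  reproducible in isolation and studies are byte-identical under a fixed
  seed.

What the generator does *not* emulate: chromatographic drift and tailing,
correlated calibration error (its *m/z* errors are independent per
centroid), profile-mode peak shape, ion suppression, and MS² spectra beyond
optional per-compound fragment lists. A green end-to-end test therefore
establishes that the pipeline's logic recovers planted truth under
idealized noise — not that it would survive every instrumental artifact of
real acquisitions.

Two consequences of the stated noise levels are worth knowing. At the top
of the *m/z* range the builder window (max(0.01 Th, 5 ppm)) is ≈8 ppm, so
a 5 ppm per-centroid error sd occasionally splits a trace via outlier
centroids; duplicate near-identical rows can then survive blank
subtraction. This is faithful to how the real greedy builder behaves at
borderline tolerance, and is why the 1-to-1 recovery property is asserted
at noise sds of at most half the tolerances, as its precondition states.

## Numerical and degenerate-input choices

- Thresholds: inclusive for minima, exclusive for baselines (tested).
- Jaccard of two empty sets is 0 by convention, with a message.
- An all-zero attribution report ranks nothing and warns; ranking ties
  break alphabetically and are flagged, never silently resolved.
- Unresolved biomarker isobars are reported as `ambiguous` with all
  candidate names.
- `calibrate()` rejects ages outside the curve's ¹⁴C range, naming the
  supported range; posterior mass is renormalized to 1 on the grid.
- Config files are YAML; unknown keys are rejected rather than ignored.

## Known limitations

- No RT correction (loess/RANSAC) or gap-filling; alignment trusts the
  0.05 min tolerance.
- Greedy alignment is order-dependent for borderline features; the run
  order is pinned (lexicographic) to keep results reproducible rather than
  order-free.
- The formula element table covers C/H/N/O plus Na, K, P, S; wider
  chemistry requires extending the bundled table.
- mzML is not read or written — no mzML codec exists in the supported
  dependency set — so runs travel as the package's tabular scan CSV.
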