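# Centroided-run container and the package's tabular scan format.

#' Construct a centroided LC-MS run
#'
#' The package's canonical in-memory run object: a long table of centroids
#' with scan index and retention time, plus run metadata. Centroids are
#' sorted by scan then m/z on construction.
#'
#' @param scans data.frame with columns `scan` (1-based integer), `rt`
#'   (minutes), `mz` (Th), `intensity` (detector counts).
#' @param run_id,sample_id Identifiers.
#' @param role One of `"species_ref"`, `"blank"`, `"qc"`, `"ancient"`.
#' @param species Species code (`"BLANK"` for blank pipes, `"ANCIENT"` for
#'   artifact samples).
#' @param solvent Extract code, e.g. `"TA"`, `"APW"`, `"MTBE"`.
#' @return Object of class `centroid_run`.
#' @export
centroid_run <- function(scans, run_id = "run", sample_id = run_id,
                         role = "species_ref", species = NA_character_,
                         solvent = NA_character_) {
  stopifnot(is.data.frame(scans),
            all(c("scan", "rt", "mz", "intensity") %in% names(scans)))
  if (nrow(scans)) {
    if (any(scans$intensity <= 0)) stop("intensities must be > 0")
    scans <- scans[order(scans$scan, scans$mz), , drop = FALSE]
    rt_by_scan <- scans$rt[!duplicated(scans$scan)]   # already in scan order
    if (is.unsorted(rt_by_scan)) stop("RT must be non-decreasing across scans")
  }
  rownames(scans) <- NULL
  structure(list(scans = scans,
                 meta = list(run_id = run_id, sample_id = sample_id,
                             role = role, species = species,
                             solvent = solvent)),
            class = "centroid_run")
}

#' @export
print.centroid_run <- function(x, ...) {
  cat(sprintf("<centroid_run %s: %d centroids in %d scans, RT %.2f-%.2f min [%s/%s/%s]>\n",
              x$meta$run_id, nrow(x$scans),
              length(unique(x$scans$scan)),
              if (nrow(x$scans)) min(x$scans$rt) else NA,
              if (nrow(x$scans)) max(x$scans$rt) else NA,
              x$meta$role, x$meta$species, x$meta$solvent))
  invisible(x)
}

#' Write / read a run in the tabular scan CSV format
#'
#' Plain-text interchange format: columns `scan`, `rt`, `mz`, `intensity`;
#' run metadata in `#`-prefixed header comment lines.
#'
#' @param run A [centroid_run()].
#' @param path Output file path.
#' @return `write_scan_csv` the path invisibly; `read_scan_csv` a
#'   [centroid_run()].
#' @export
write_scan_csv <- function(run, path) {
  con <- file(path, "w")
  on.exit(close(con))
  m <- run$meta
  writeLines(sprintf("# run_id=%s sample_id=%s role=%s species=%s solvent=%s",
                     m$run_id, m$sample_id, m$role, m$species, m$solvent), con)
  utils::write.csv(run$scans, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scan_csv
#' @export
read_scan_csv <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- list(run_id = basename(path), sample_id = basename(path),
               role = "species_ref", species = NA_character_,
               solvent = NA_character_)
  if (startsWith(first, "#")) {
    kv <- regmatches(first, gregexpr("[a-z_]+=[^ ]+", first))[[1]]
    for (p in kv) {
      k <- sub("=.*$", "", p); v <- sub("^[a-z_]+=", "", p)
      meta[[k]] <- if (v == "NA") NA_character_ else v
    }
  }
  scans <- utils::read.csv(path, comment.char = "#")
  centroid_run(scans, run_id = meta$run_id, sample_id = meta$sample_id,
               role = meta$role, species = meta$species,
               solvent = meta$solvent)
}

#' m/z tolerance with "X m/z or Y ppm" semantics
#'
#' Matching windows everywhere in the package follow the convention of the
#' processing parameters they mirror: the effective window at m/z `m` is
#' `max(absolute, ppm * m / 1e6)` — the wider of the absolute and the
#' relative term.
#'
#' @param abs_th Absolute term in Th.
#' @param ppm Relative term in ppm.
#' @return Object of class `mz_tolerance`.
#' @export
mz_tolerance <- function(abs_th = 0.01, ppm = 5) {
  stopifnot(abs_th >= 0, ppm >= 0, abs_th + ppm > 0)
  structure(list(abs_th = abs_th, ppm = ppm), class = "mz_tolerance")
}

#' Effective tolerance window at a given m/z
#' @param tol An [mz_tolerance()].
#' @param mz m/z value(s) in Th.
#' @return Window half-width(s) in Th.
#' @export
tol_window <- function(tol, mz) pmax(tol$abs_th, tol$ppm * mz * 1e-6)
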