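# Species attribution by compound-list intersection, species ranking, and
# biomarker annotation with isobar discrimination.

#' Venn-style intersection counts against reference compound lists
#'
#' For a target sample (an artifact residue) and one reference compound
#' list per candidate species, computes per species the number of compounds
#' shared with the target and the number exclusive to that reference
#' (present in no other reference). All lists must come from the same
#' aligned matrix so that row ids are directly comparable.
#'
#' @param target A `compound_list` (see [merge_extracts()]).
#' @param references Named list, species code -> `compound_list`.
#' @return An `attribution_report`: list with `target`, `total_target`,
#'   `counts` (data.frame species / exclusive / shared, sorted by shared
#'   descending then species), `ranking`, `tied`.
#' @export
venn_counts <- function(target, references) {
  if (!length(references)) stop("need at least one reference list")
  ids <- vapply(references, function(r) r$matrix_id, character(1))
  if (any(ids != target$matrix_id))
    stop("compound lists come from different aligned matrices; row ids are incomparable")
  species <- names(references)
  shared <- vapply(species, function(s)
    length(intersect(target$rows, references[[s]]$rows)), integer(1))
  exclusive <- vapply(species, function(s) {
    others <- unique(unlist(lapply(references[setdiff(species, s)],
                                   function(r) r$rows)))
    length(setdiff(references[[s]]$rows, others))
  }, integer(1))
  counts <- data.frame(species = species, exclusive = exclusive,
                       shared = shared, stringsAsFactors = FALSE)
  counts <- counts[order(-counts$shared, counts$species), , drop = FALSE]
  rownames(counts) <- NULL
  pos <- counts$shared[counts$shared > 0]
  structure(list(target = target$sample_id,
                 total_target = length(target$rows),
                 counts = counts,
                 ranking = counts$species[counts$shared > 0],
                 tied = anyDuplicated(pos) > 0),
            class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat(sprintf("<attribution_report for %s: %d compounds>\n", x$target,
              x$total_target))
  print(x$counts)
  invisible(x)
}

#' Rank candidate species by shared-compound count
#'
#' Top-k species by count of compounds shared with the target, ties broken
#' alphabetically and flagged. Species sharing zero compounds are not
#' ranked; an all-zero report yields an empty ranking with a warning.
#'
#' @param report An `attribution_report` from [venn_counts()].
#' @param top_k Number of species to return (default all).
#' @return Character vector of species codes with attribute `tied`.
#' @export
rank_species <- function(report, top_k = Inf) {
  r <- report$ranking
  if (!length(r)) {
    warning("no species shares any compound with the target")
    return(structure(character(0), tied = FALSE))
  }
  k <- min(top_k, length(r))
  sh <- report$counts$shared[match(r, report$counts$species)]
  tied <- k < length(r) && sh[k] == sh[k + 1]
  structure(r[seq_len(k)], tied = tied || report$tied)
}

#' Bundled biomarker standards library
#'
#' The seven chemical standards characterized on the package's reference
#' chromatographic method: name, molecular formula, adduct, observed m/z
#' (instrument values, not theoretical), retention time. Loaded from the
#' plain-text file under `inst/extdata/biomarker_standards.csv`.
#'
#' @return data.frame with columns `name`, `formula`, `adduct`,
#'   `observed_mz`, `rt`.
#' @export
biomarker_library <- function() {
  path <- system.file("extdata", "biomarker_standards.csv",
                      package = "residuomics")
  lib <- utils::read.csv(path, stringsAsFactors = FALSE)
  theo <- mapply(adduct_mz, lib$formula, lib$adduct)
  stopifnot(all(abs(lib$observed_mz - theo) <= 0.05))  # sanity bound
  lib
}

# cosine similarity over matched fragment m/z (0.02 Th match window)
.fragment_cosine <- function(f1, f2, bin = 0.02) {
  if (!length(f1) || !length(f2)) return(0)
  matched <- sum(vapply(f1, function(a) any(abs(f2 - a) <= bin), logical(1)))
  matched / sqrt(length(f1) * length(f2))
}

#' Annotate aligned rows with biomarker standards
#'
#' Each aligned compound row is annotated with every library entry whose
#' observed m/z and RT both fall within tolerance. Isobaric entries (same
#' m/z within tolerance — e.g. nicotine and anabasine, or theobromine and
#' theophylline) are disambiguated by RT first; when several remain inside
#' the RT tolerance and fragment m/z lists are available for both the row
#' and the entries, a cosine similarity over 0.02 Th fragment bins decides
#' (threshold 0.7). Isobars that stay unresolved are reported with status
#' `"ambiguous"` and all candidate names — never silently chosen.
#'
#' @param mat An `aligned_matrix`.
#' @param library Biomarker table as from [biomarker_library()]; may carry
#'   a `fragments` list-column of numeric fragment m/z vectors.
#' @param mz_tol An [mz_tolerance()] (default ppm-only 10 ppm).
#' @param rt_tol RT tolerance in minutes (default 0.1).
#' @param row_fragments Optional named list, row id -> numeric fragment
#'   m/z vector, enabling the fragment-based tiebreak.
#' @return data.frame with `row_id`, `name` (semicolon-joined when
#'   ambiguous), `status` (`"unique"` or `"ambiguous"`); one row per
#'   annotated matrix row.
#' @export
annotate_biomarkers <- function(mat, library = biomarker_library(),
                                mz_tol = mz_tolerance(0, 10), rt_tol = 0.1,
                                row_fragments = NULL) {
  if (!nrow(library))
    return(data.frame(row_id = character(0), name = character(0),
                      status = character(0)))
  out <- list()
  for (i in seq_len(nrow(mat$rows))) {
    mz <- mat$rows$mz[i]; rt <- mat$rows$rt[i]
    hit <- which(abs(library$observed_mz - mz) <= tol_window(mz_tol, mz) &
                   abs(library$rt - rt) <= rt_tol)
    if (!length(hit)) next
    if (length(hit) > 1L) {
      rid <- mat$rows$row_id[i]
      frg <- row_fragments[[rid]]
      if (!is.null(frg) && !is.null(library$fragments)) {
        cs <- vapply(hit, function(h) {
          lf <- library$fragments[[h]]
          if (is.null(lf)) -1 else .fragment_cosine(frg, lf)
        }, numeric(1))
        if (sum(cs >= 0.7) == 1L) hit <- hit[cs >= 0.7]
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      row_id = mat$rows$row_id[i],
      name = paste(sort(library$name[hit]), collapse = ";"),
      status = if (length(hit) == 1L) "unique" else "ambiguous",
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(row_id = character(0), name = character(0),
                      status = character(0)))
  do.call(rbind, out)
}

#' Write an attribution report as TSV and JSON
#'
#' @param report An `attribution_report`.
#' @param path TSV path; a machine-readable JSON twin is written as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_attribution_report <- function(report, path) {
  utils::write.table(report$counts, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(target = report$target,
                            total_target = report$total_target,
                            counts = report$counts,
                            ranking = report$ranking, tied = report$tied),
                       paste0(path, ".json"), dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
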