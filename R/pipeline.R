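# Pipeline orchestration: one config object covering the eight processing
# steps plus curation, attribution and ordination; an end-to-end runner
# with structured logging and reproducible output bundles.

#' Default pipeline configuration
#'
#' Nested list whose sections mirror the numbered processing steps; the
#' defaults are the standard printed parameter values (crop scans 1-1130 /
#' RT 0.01-12.51 min / m/z 100-1200; centroid noise level 6.0e2;
#' chromatogram min span 0.01 min, min height 5.0e3, tolerance 0.01 Th or
#' 5 ppm; duration keep-window 0.01-12.01 min; baseline cut-off
#' deconvolution with min height 1.0e4, duration 0-2 min, baseline 9.0e3;
#' isotope grouping at 0.01 Th or 5 ppm, RT 0.05 min, monotonic, max
#' charge 1; join alignment at 0.01 Th or 5 ppm weight 10, RT 0.05 min
#' weight 10, same charge required; formula prediction over C0-50 H0-100
#' N0-5 O0-40 at 3 ppm, isotope filter minimum score 95).
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    feature_extraction = list(
      crop = list(scan_range = c(1, 1130), rt_range = c(0.01, 12.51),
                  mz_range = c(100, 1200)),
      mass_detection = list(noise_level = 6.0e2),
      chromatogram = list(min_span = 0.01, min_height = 5.0e3,
                          mz_tol_abs = 0.01, mz_tol_ppm = 5.0),
      duration_filter = list(rt_window = c(0.01, 12.01)),
      deconvolution = list(baseline = 9.0e3, min_height = 1.0e4,
                           duration_range = c(0, 2)),
      isotope_grouper = list(mz_tol_abs = 0.01, mz_tol_ppm = 5.0,
                             rt_tol = 0.05, max_charge = 1,
                             monotonic = TRUE)),
    alignment = list(mz_tol_abs = 0.01, mz_tol_ppm = 5.0, rt_tol = 0.05,
                     mz_weight = 10, rt_weight = 10,
                     require_same_charge = TRUE),
    curation = list(blank_rule = "any"),
    formula_prediction = list(charge = 1, adduct = "[M+H]+",
                              tolerance_ppm = 3.0,
                              ranges = list(C = c(0, 50), H = c(0, 100),
                                            N = c(0, 5), O = c(0, 40)),
                              min_isotope_score = 95.0),
    attribution = list(top_k = 3),
    ordination = list(enabled = TRUE, nmds_k = 2, nmds_starts = 20,
                      pca_k = 5),
    seed = 1L)
}

# printed reference values for deviation reporting
.paper_citations <- list(
  "feature_extraction.mass_detection.noise_level" = "noise level of 6.0E2",
  "feature_extraction.chromatogram.min_span" = "minimum time span was 0.01 min",
  "feature_extraction.chromatogram.min_height" = "minimum height was 5.0E3",
  "feature_extraction.chromatogram.mz_tol_abs" = "m/z tolerance was 0.01 m/z or 5.0 ppm",
  "feature_extraction.chromatogram.mz_tol_ppm" = "m/z tolerance was 0.01 m/z or 5.0 ppm",
  "feature_extraction.deconvolution.baseline" = "baseline level of 9.0E3",
  "feature_extraction.deconvolution.min_height" = "minimum peak height of 1.0E4",
  "feature_extraction.deconvolution.duration_range" = "peak duration range of 0.00-2.00 min",
  "feature_extraction.isotope_grouper.rt_tol" = "retention time tolerance was 0.05 absolute (min)",
  "feature_extraction.isotope_grouper.max_charge" = "maximum charge was 1",
  "alignment.mz_tol_abs" = "m/z tolerance was 0.01 m/z or 5.0 ppm",
  "alignment.mz_tol_ppm" = "m/z tolerance was 0.01 m/z or 5.0 ppm",
  "alignment.rt_tol" = "retention time tolerance was 0.05 absolute (min)",
  "alignment.mz_weight" = "weight for m/z was 10",
  "alignment.rt_weight" = "weight for RT was 10",
  "formula_prediction.tolerance_ppm" = "m/z tolerance: 0.0 m/z or 3.0 ppm",
  "formula_prediction.min_isotope_score" = "minimum score: 95.0%")

#' Save / load a pipeline configuration (YAML)
#'
#' Round-trip-stable YAML serialization; [load_config()] rejects unknown
#' keys so typos never silently fall back to defaults.
#'
#' @param config Configuration list (see [default_config()]).
#' @param path YAML file path.
#' @return `save_config` the path invisibly; `load_config` the full
#'   configuration (defaults overlaid with the file's values).
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.check_keys <- function(given, reference, prefix = "") {
  for (k in names(given)) {
    full <- paste0(prefix, k)
    if (!k %in% names(reference))
      stop("unknown configuration key: ", full)
    if (is.list(given[[k]]) && is.list(reference[[k]]) &&
        !is.null(names(reference[[k]])))
      .check_keys(given[[k]], reference[[k]], paste0(full, "."))
  }
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ref <- default_config()
  .check_keys(cfg, ref)
  utils::modifyList(ref, cfg)
}

.flatten_config <- function(x, prefix = "") {
  out <- list()
  for (k in names(x)) {
    full <- paste0(prefix, k)
    if (is.list(x[[k]]) && !is.null(names(x[[k]])) &&
        all(nzchar(names(x[[k]]))))
      out <- c(out, .flatten_config(x[[k]], paste0(full, ".")))
    else out[[full]] <- x[[k]]
  }
  out
}

#' Report configuration deviations from the standard parameter values
#'
#' Lists every parameter whose value differs from [default_config()], with
#' the printed reference value quoted where one exists.
#'
#' @param config Configuration list.
#' @return data.frame with `parameter`, `value`, `default`, `reference`;
#'   zero rows when the config is all defaults.
#' @export
validate_config <- function(config) {
  .check_keys(config, default_config())
  flat_c <- .flatten_config(config)
  flat_d <- .flatten_config(default_config())
  dev <- list()
  for (k in names(flat_d)) {
    v <- flat_c[[k]]
    if (is.null(v)) v <- flat_d[[k]]
    if (!isTRUE(all.equal(v, flat_d[[k]], check.attributes = FALSE))) {
      dev[[length(dev) + 1L]] <- data.frame(
        parameter = k,
        value = paste(format(v), collapse = ","),
        default = paste(format(flat_d[[k]]), collapse = ","),
        reference = if (!is.null(.paper_citations[[k]]))
          .paper_citations[[k]] else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(dev))
    return(data.frame(parameter = character(0), value = character(0),
                      default = character(0), reference = character(0)))
  do.call(rbind, dev)
}

.log_line <- function(log, stage, ...) {
  entry <- c(list(stage = stage), list(...))
  log$entries[[length(log$entries) + 1L]] <- entry
  log
}

#' Run the full attribution pipeline on a study
#'
#' Executes extract -> align -> blank-subtract -> merge -> attribute ->
#' ordinate on a study (typically from [make_study()]), in fixed order,
#' with per-stage in/out counts logged. Reference compound lists are the
#' QC-pool samples when present, else the union of each species' replicate
#' runs; each ancient sample is attributed against them. Identical config
#' and study give identical outputs.
#'
#' @param study A [make_study()] result, a list with `runs` (named
#'   [centroid_run()] list) and `manifest`, or the path of a study
#'   directory written by [write_study()].
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Optional output directory; when given, the matrix,
#'   compound lists, attribution reports, ordination coordinates, log and
#'   config snapshot are written there.
#' @return List with `features` (per run), `matrix` (post-curation
#'   `aligned_matrix`), `compound_lists`, `reports` (per ancient sample),
#'   `ordination` (`nmds`, `pca`), `log` (list of stage entries).
#' @export
run_pipeline <- function(study, config = default_config(), out_dir = NULL) {
  .check_keys(config, default_config())
  config <- utils::modifyList(default_config(), config)
  log <- list(entries = list())
  if (is.character(study)) study <- read_study(study)
  manifest <- study$manifest
  runs <- study$runs
  if (is.null(runs) || is.null(manifest)) stop("study needs runs + manifest")

  feats <- lapply(runs, extract_features, params = config$feature_extraction)
  log <- .log_line(log, "extract", runs = length(feats),
                   features = sum(vapply(feats, nrow, integer(1))))

  al <- config$alignment
  mat <- join_align(feats,
                    mz_tol = mz_tolerance(al$mz_tol_abs, al$mz_tol_ppm),
                    rt_tol = al$rt_tol, mz_weight = al$mz_weight,
                    rt_weight = al$rt_weight,
                    require_same_charge = al$require_same_charge,
                    metadata = manifest)
  log <- .log_line(log, "align", rows = nrow(mat$abundance),
                   cells = sum(!is.na(mat$abundance)))

  n_before <- nrow(mat$abundance)
  mat <- remove_blank_shared(mat, rule = config$curation$blank_rule)
  log <- .log_line(log, "blank_subtraction", rows_removed = n_before - nrow(mat$abundance),
                   rows = nrow(mat$abundance))

  samples <- unique(mat$cols$sample_id)
  lists <- stats::setNames(lapply(samples, merge_extracts, mat = mat), samples)
  log <- .log_line(log, "merge_extracts", samples = length(lists))

  # reference lists: QC pools when present, else union of replicate runs
  qc_samples <- unique(mat$cols$sample_id[mat$cols$role == "qc"])
  species_of <- function(s) unique(mat$cols$species[mat$cols$sample_id == s])
  refs <- list()
  if (length(qc_samples)) {
    for (s in qc_samples) {
      sp <- species_of(s)
      if (!sp %in% c("BLANK", "ANCIENT")) refs[[sp]] <- lists[[s]]
    }
  } else {
    ref_samples <- unique(mat$cols$sample_id[mat$cols$role == "species_ref"])
    for (s in ref_samples) {
      sp <- species_of(s)
      cl <- lists[[s]]
      if (is.null(refs[[sp]])) refs[[sp]] <- cl
      else {
        u <- union(refs[[sp]]$rows, cl$rows)
        refs[[sp]]$rows <- u
        refs[[sp]]$abundance <- stats::setNames(rep(NA_real_, length(u)), u)
      }
    }
  }

  anc_samples <- unique(mat$cols$sample_id[mat$cols$role == "ancient"])
  reports <- stats::setNames(lapply(anc_samples, function(s)
    venn_counts(lists[[s]], refs)), anc_samples)
  log <- .log_line(log, "attribute", targets = length(reports),
                   references = length(refs))

  ords <- list(nmds = NULL, pca = NULL)
  if (isTRUE(config$ordination$enabled) && length(lists) >= 3) {
    d <- jaccard_distances(lists)
    ords$nmds <- nmds(d, k = min(config$ordination$nmds_k, length(lists) - 1),
                      n_starts = config$ordination$nmds_starts,
                      seed = config$seed)
    ords$pca <- pareto_pca(mat, k = config$ordination$pca_k)
    log <- .log_line(log, "ordinate", stress = ords$nmds$stress)
  }

  res <- list(features = feats, matrix = mat, compound_lists = lists,
              references = refs, reports = reports, ordination = ords,
              log = log$entries, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_aligned_matrix(mat, file.path(out_dir, "aligned_matrix.csv"))
    for (s in names(reports))
      write_attribution_report(reports[[s]],
                               file.path(out_dir, paste0("attribution_", s, ".tsv")))
    if (!is.null(ords$nmds))
      utils::write.csv(data.frame(sample = rownames(ords$nmds$points),
                                  ords$nmds$points),
                       file.path(out_dir, "nmds_coordinates.csv"),
                       row.names = FALSE)
    save_config(config, file.path(out_dir, "config_snapshot.yaml"))
    writeLines(vapply(log$entries, function(e)
      jsonlite::toJSON(e, auto_unbox = TRUE), character(1)),
      file.path(out_dir, "pipeline_log.jsonl"))
  }
  res
}
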