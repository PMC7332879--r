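# On-disk study bundles: manifest CSV, per-run tabular scan CSVs, truth
# ledger JSON.

#' Write / read a study bundle
#'
#' A study directory holds `manifest.csv` (run metadata), one tabular scan
#' CSV per run under `runs/`, and — when the study carries ground truth —
#' `truth.json` with the per-run planted-compound ledger. All files are
#' plain text.
#'
#' @param study A [make_study()] result or a list with `runs` and
#'   `manifest`.
#' @param dir Study directory (created if needed).
#' @return `write_study` the directory invisibly; `read_study` a study
#'   list usable with [run_pipeline()].
#' @export
write_study <- function(study, dir) {
  dir.create(file.path(dir, "runs"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  for (id in names(study$runs))
    write_scan_csv(study$runs[[id]], file.path(dir, "runs", paste0(id, ".csv")))
  if (!is.null(study$truth))
    jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                         dataframe = "columns", digits = NA)
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv in ", dir)
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  runs <- list()
  for (id in manifest$run_id) {
    rpath <- file.path(dir, "runs", paste0(id, ".csv"))
    if (!file.exists(rpath)) stop("missing run file: ", rpath)
    runs[[id]] <- read_scan_csv(rpath)
  }
  truth <- NULL
  tpath <- file.path(dir, "truth.json")
  if (file.exists(tpath)) {
    truth <- jsonlite::read_json(tpath, simplifyVector = TRUE)
    truth <- lapply(truth, as.data.frame)
  }
  list(manifest = manifest, runs = runs, truth = truth)
}
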