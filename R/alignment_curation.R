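# Cross-run join alignment and post-export curation: blank-shared feature
# removal, merging solvent extracts into per-sample compound lists.

#' Join alignment of per-run feature lists
#'
#' Greedy cross-run matching into aligned compound rows. Runs are processed
#' in lexicographic run-id order; within a run, features are processed by
#' descending height (ties by m/z). Each feature is matched to the
#' best-scoring existing row within both tolerances, with
#' `score = w_mz * (1 - dmz / tol_mz) + w_rt * (1 - drt / tol_rt)`;
#' when `require_same_charge` is on, rows and features with determined,
#' differing charges never match. A feature with no admissible row — or
#' whose best row already holds a feature from the same run — opens a new
#' row. Cells record peak height; row consensus m/z is the height-weighted
#' mean of members and consensus RT the plain mean.
#'
#' Only representative features (`representative == TRUE`) of each isotope
#' group are aligned when that column is present.
#'
#' @param feature_lists Named list, run id -> feature data.frame.
#' @param mz_tol An [mz_tolerance()] (default 0.01 Th or 5 ppm).
#' @param rt_tol RT tolerance in minutes (default 0.05).
#' @param mz_weight,rt_weight Score weights (default 10 each).
#' @param require_same_charge Enforce charge agreement when both are
#'   determined (default TRUE).
#' @param metadata Optional data.frame with `run_id`, `sample_id`,
#'   `species`, `solvent`, `role` columns (e.g. a [make_study()] manifest);
#'   defaults to run ids with unknown metadata.
#' @return An `aligned_matrix`: list with `abundance` (rows x runs matrix,
#'   NA = absent), `rows` (consensus m/z/RT/charge per row), `cols`
#'   (run metadata), `matrix_id`.
#' @export
join_align <- function(feature_lists, mz_tol = mz_tolerance(0.01, 5),
                       rt_tol = 0.05, mz_weight = 10, rt_weight = 10,
                       require_same_charge = TRUE, metadata = NULL) {
  if (!length(feature_lists)) stop("need at least one run")
  if (is.null(names(feature_lists)))
    stop("feature_lists must be named by run id")
  run_ids <- sort(names(feature_lists))
  n_feat_total <- sum(vapply(feature_lists, nrow, integer(1)))
  cap <- max(16L, n_feat_total)
  row_mz <- numeric(cap); row_rt <- numeric(cap); row_charge <- rep(NA_integer_, cap)
  row_wsum <- numeric(cap); row_mzw <- numeric(cap)
  row_rtsum <- numeric(cap); row_n <- integer(cap)
  n_rows <- 0L
  cells <- vector("list", length(run_ids))
  for (ri in seq_along(run_ids)) {
    rid <- run_ids[ri]
    f <- feature_lists[[rid]]
    if (!is.null(f$representative)) f <- f[f$representative, , drop = FALSE]
    if (nrow(f)) f <- f[order(-f$height, f$mz), , drop = FALSE]
    taken <- logical(n_rows)
    assigned <- integer(nrow(f))
    for (i in seq_len(nrow(f))) {
      best <- 0L
      if (n_rows) {
        sl <- seq_len(n_rows)
        dmz <- abs(row_mz[sl] - f$mz[i])
        drt <- abs(row_rt[sl] - f$rt[i])
        tw <- tol_window(mz_tol, row_mz[sl])
        ok <- !taken & dmz <= tw & drt <= rt_tol
        if (require_same_charge && !is.na(f$charge[i]))
          ok <- ok & (is.na(row_charge[sl]) | row_charge[sl] == f$charge[i])
        if (any(ok)) {
          score <- mz_weight * (1 - dmz / tw) + rt_weight * (1 - drt / rt_tol)
          score[!ok] <- -Inf
          best <- which.max(score)
        }
      }
      if (!best) {
        n_rows <- n_rows + 1L
        if (n_rows > cap) {
          new <- (cap + 1L):(cap * 2L)
          cap <- cap * 2L
          length(row_mz) <- cap; length(row_rt) <- cap
          length(row_charge) <- cap; length(row_wsum) <- cap
          length(row_mzw) <- cap; length(row_rtsum) <- cap
          length(row_n) <- cap
          row_wsum[new] <- 0; row_mzw[new] <- 0
          row_rtsum[new] <- 0; row_n[new] <- 0L
        }
        best <- n_rows
        taken <- c(taken, FALSE)
      }
      taken[best] <- TRUE
      w <- f$height[i]
      row_mzw[best] <- row_mzw[best] + w * f$mz[i]
      row_wsum[best] <- row_wsum[best] + w
      row_mz[best] <- row_mzw[best] / row_wsum[best]
      row_rtsum[best] <- row_rtsum[best] + f$rt[i]
      row_n[best] <- row_n[best] + 1L
      row_rt[best] <- row_rtsum[best] / row_n[best]
      if (is.na(row_charge[best]) && !is.na(f$charge[i]))
        row_charge[best] <- f$charge[i]
      assigned[i] <- best
    }
    cells[[ri]] <- data.frame(row = assigned, height = f$height)
  }
  ab <- matrix(NA_real_, n_rows, length(run_ids),
               dimnames = list(sprintf("row%04d", seq_len(n_rows)), run_ids))
  for (ri in seq_along(run_ids))
    ab[cells[[ri]]$row, ri] <- cells[[ri]]$height
  sl <- seq_len(n_rows)
  rows <- data.frame(row_id = rownames(ab), mz = row_mz[sl], rt = row_rt[sl],
                     charge = row_charge[sl], stringsAsFactors = FALSE)
  cols <- data.frame(run_id = run_ids, sample_id = run_ids,
                     species = NA_character_, solvent = NA_character_,
                     role = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    m <- match(run_ids, metadata$run_id)
    for (cn in intersect(c("sample_id", "species", "solvent", "role"),
                         names(metadata)))
      cols[[cn]] <- metadata[[cn]][m]
  }
  structure(list(abundance = ab, rows = rows, cols = cols,
                 matrix_id = sprintf("am-%dx%d-%.4f-%.6f", n_rows,
                                     length(run_ids),
                                     sum(ab, na.rm = TRUE),
                                     sum(row_mz[sl]))),
            class = "aligned_matrix")
}

#' @export
print.aligned_matrix <- function(x, ...) {
  cat(sprintf("<aligned_matrix: %d compound rows x %d runs, %d filled cells>\n",
              nrow(x$abundance), ncol(x$abundance), sum(!is.na(x$abundance))))
  invisible(x)
}

.blank_cols <- function(mat) {
  which(!is.na(mat$cols$role) & mat$cols$role == "blank" |
          !is.na(mat$cols$species) & mat$cols$species == "BLANK")
}

#' Remove features shared with the blank pipes
#'
#' Deletes every aligned row with abundance in any blank-pipe column (the
#' conservative any-blank rule; `rule = "all"` requires presence in all
#' blank runs), then drops the blank columns themselves.
#'
#' @param mat An `aligned_matrix` with column roles assigned.
#' @param rule `"any"` (default) or `"all"`.
#' @return The curated `aligned_matrix`.
#' @export
remove_blank_shared <- function(mat, rule = c("any", "all")) {
  rule <- match.arg(rule)
  bc <- .blank_cols(mat)
  if (!length(bc)) {
    warning("no blank columns in matrix; returning unchanged")
    return(mat)
  }
  present <- !is.na(mat$abundance[, bc, drop = FALSE])
  drop_rows <- if (rule == "any") rowSums(present) > 0
  else rowSums(present) == length(bc)
  mat$abundance <- mat$abundance[!drop_rows, -bc, drop = FALSE]
  mat$rows <- mat$rows[!drop_rows, , drop = FALSE]
  mat$cols <- mat$cols[-bc, , drop = FALSE]
  rownames(mat$rows) <- NULL; rownames(mat$cols) <- NULL
  mat
}

#' Merge a sample's solvent extracts into one compound list
#'
#' Union semantics: a compound row belongs to the sample's list when it has
#' abundance in any of the sample's runs (typically the TA, APW and MTBE
#' extracts); rows absent everywhere are excluded. Per-row abundance is the
#' maximum across the sample's runs.
#'
#' @param mat An `aligned_matrix`.
#' @param sample_id Sample whose runs to merge.
#' @return A `compound_list`: list with `sample_id`, `rows` (row ids),
#'   `abundance` (named max heights), `matrix_id`.
#' @export
merge_extracts <- function(mat, sample_id) {
  ci <- which(mat$cols$sample_id == sample_id)
  if (!length(ci)) stop("unknown sample id: ", sample_id)
  sub <- mat$abundance[, ci, drop = FALSE]
  ab <- apply(sub, 1, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  keep <- !is.na(ab)
  structure(list(sample_id = sample_id,
                 rows = rownames(mat$abundance)[keep],
                 abundance = ab[keep],
                 matrix_id = mat$matrix_id),
            class = "compound_list")
}

#' @export
print.compound_list <- function(x, ...) {
  cat(sprintf("<compound_list %s: %d compounds>\n", x$sample_id,
              length(x$rows)))
  invisible(x)
}

#' Write an aligned matrix as CSV plus JSON sidecar
#'
#' The wide CSV holds the abundance matrix (rows x runs); the sidecar JSON
#' carries row consensus m/z/RT/charge and column metadata.
#'
#' @param mat An `aligned_matrix`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_aligned_matrix <- function(mat, path) {
  utils::write.csv(data.frame(row_id = rownames(mat$abundance),
                              mat$abundance, check.names = FALSE),
                   path, row.names = FALSE, na = "")
  jsonlite::write_json(list(rows = mat$rows, cols = mat$cols,
                            matrix_id = mat$matrix_id),
                       paste0(path, ".meta.json"), dataframe = "columns",
                       na = "null", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
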