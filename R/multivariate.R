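# Ordination: presence/absence Jaccard distances with NMDS and Ward
# clustering, Pareto-scaled PCA, and feature-count summaries.
# The Jaccard construction, presence/absence coding and Pareto transform
# are implemented here; eigendecomposition and NMDS stress minimization are
# delegated to stats::prcomp and vegan::monoMDS.

#' Jaccard distance matrix over compound lists
#'
#' `d(a, b) = 1 - |a intersect b| / |a union b|` on presence/absence row-id
#' sets. Two empty lists are at distance 0 by convention (with a message).
#'
#' @param lists Named list of `compound_list` objects (>= 2).
#' @return Symmetric distance matrix with zero diagonal, class
#'   `c("jaccard_dist", "matrix")`.
#' @export
jaccard_distances <- function(lists) {
  if (length(lists) < 2) stop("need at least 2 samples")
  n <- length(lists)
  ids <- names(lists)
  if (is.null(ids)) ids <- vapply(lists, function(l) l$sample_id, character(1))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- lists[[i]]$rows; b <- lists[[j]]$rows
    u <- length(union(a, b))
    if (u == 0) {
      message("both compound lists empty (", ids[i], ", ", ids[j],
              "); distance 0 by convention")
      dij <- 0
    } else dij <- 1 - length(intersect(a, b)) / u
    d[i, j] <- d[j, i] <- dij
  }
  structure(d, class = c("jaccard_dist", "matrix"))
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 NMDS (global model, primary/weak tie treatment) of a
#' distance matrix, best of `n_starts` configurations: the first start is
#' classical scaling, the rest are random. Deterministic under `seed`.
#' Ward clustering (`"ward.D"`, unsquared distances) of the same matrix is
#' attached as a display-grouping column.
#'
#' @param dist Symmetric distance matrix (e.g. [jaccard_distances()]).
#' @param k Embedding dimension (default 2; must be < number of samples).
#' @param n_starts Random starts (default 20).
#' @param seed Integer seed.
#' @param cut_k Number of Ward clusters to cut (default 0 = no cutting).
#' @return An `ordination`: list with `points` (samples x k), `stress`,
#'   `method = "nmds"`, `clusters` (Ward assignments or NULL), `hclust`.
#' @export
nmds <- function(dist, k = 2, n_starts = 20, seed = 1, cut_k = 0) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (k >= n) stop("k must be smaller than the number of samples")
  dd <- stats::as.dist(d)
  best <- NULL
  .with_seed(seed, {
    for (s in seq_len(n_starts)) {
      init <- if (s == 1) {
        y <- stats::cmdscale(dd, k = k)
        if (ncol(y) < k) cbind(y, matrix(0, n, k - ncol(y))) else y
      } else matrix(stats::runif(n * k, -1, 1), n, k)
      fit <- vegan::monoMDS(dd, y = init, k = k, model = "global")
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
  })
  hc <- stats::hclust(dd, method = "ward.D")
  pts <- best$points
  rownames(pts) <- rownames(d)
  structure(list(points = pts, stress = best$stress, method = "nmds",
                 clusters = if (cut_k > 0) stats::cutree(hc, k = cut_k)
                 else NULL,
                 hclust = hc),
            class = "ordination")
}

#' Recompute Kruskal stress-1 from an embedding
#'
#' Independent check of an NMDS solution: monotone (weak, primary-tie)
#' regression of embedded distances on the input dissimilarity order via
#' pool-adjacent-violators, then
#' `stress = sqrt(sum((d - dhat)^2) / sum(d^2))`.
#'
#' @param points Embedded coordinates (samples x k).
#' @param dist Input distance matrix.
#' @return Stress-1 value.
#' @export
nmds_stress <- function(points, dist) {
  d_emb <- as.vector(stats::dist(points))
  d_in <- as.vector(stats::as.dist(as.matrix(dist)))
  ord <- order(d_in, d_emb)   # primary ties: tied blocks sorted by d_emb
  y <- d_emb[ord]
  # pool-adjacent-violators, unit weights
  n <- length(y)
  val <- y; w <- rep(1, n); m <- n
  i <- 1L
  while (i < m) {
    if (val[i] > val[i + 1] + 1e-15) {
      val[i] <- (val[i] * w[i] + val[i + 1] * w[i + 1]) / (w[i] + w[i + 1])
      w[i] <- w[i] + w[i + 1]
      val <- val[-(i + 1)]; w <- w[-(i + 1)]
      m <- m - 1L
      if (i > 1L) i <- i - 1L
    } else i <- i + 1L
  }
  dhat <- rep(val, w)
  sqrt(sum((y - dhat)^2) / sum(y^2))
}

#' Pareto scaling
#'
#' Per-feature transform `x' = (x - mean(x)) / sqrt(sd(x))`, damping
#' high-abundance dominance while keeping some magnitude information. The
#' scaled feature variance equals the original feature's standard
#' deviation.
#'
#' @param x Samples x features numeric matrix.
#' @return List `scaled` (matrix, zero-variance features dropped with a
#'   warning), `dropped` (names/indices of dropped features).
#' @export
pareto_scale <- function(x) {
  sds <- apply(x, 2, stats::sd)
  zero <- sds == 0 | is.na(sds)
  if (any(zero))
    warning(sum(zero), " zero-variance feature(s) dropped before scaling")
  xk <- x[, !zero, drop = FALSE]
  mus <- colMeans(xk)
  scaled <- sweep(sweep(xk, 2, mus), 2, sqrt(sds[!zero]), "/")
  list(scaled = scaled, dropped = which(zero))
}

#' Pareto-scaled principal component analysis
#'
#' Missing abundances are coded 0 (presence/absence semantics of the
#' exported feature table), each feature is Pareto-scaled, and PCA is
#' computed on the scaled samples-by-features matrix with no feature
#' filtering. Explained-variance fractions are relative to the total
#' variance of the scaled data, so they sum to 1 at full rank.
#'
#' @param mat An `aligned_matrix`, or a samples x features numeric matrix.
#' @param k Number of components to return (default `min(dim) - 1`).
#' @return An `ordination`: `points` (scores), `loadings`,
#'   `var_fraction`, `method = "pca"`.
#' @export
pareto_pca <- function(mat, k = NULL) {
  x <- if (inherits(mat, "aligned_matrix")) {
    m <- t(mat$abundance)  # samples (runs) x features (compound rows)
    m[is.na(m)] <- 0
    m
  } else as.matrix(mat)
  ps <- pareto_scale(x)
  pc <- stats::prcomp(ps$scaled, center = FALSE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  if (is.null(k)) k <- length(pc$sdev)
  k <- min(k, length(pc$sdev))
  structure(list(points = pc$x[, seq_len(k), drop = FALSE],
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 var_fraction = pc$sdev[seq_len(k)]^2 / total_var,
                 method = "pca"),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  if (x$method == "nmds")
    cat(sprintf("<nmds ordination: %d samples, k=%d, stress %.4f>\n",
                nrow(x$points), ncol(x$points), x$stress))
  else
    cat(sprintf("<pca ordination: %d samples, %d components, var %s>\n",
                nrow(x$points), ncol(x$points),
                paste(sprintf("%.1f%%", 100 * x$var_fraction[seq_len(min(3, length(x$var_fraction)))]),
                      collapse = "/")))
  invisible(x)
}

#' Feature-count summary per run, aggregated by metadata group
#'
#' Counts the aligned rows with abundance in each run and aggregates
#' mean/median counts per group (the statistics behind per-solvent and
#' per-species box plots).
#'
#' @param mat An `aligned_matrix`.
#' @param group_by One of `"solvent"`, `"species"`, `"sample_id"`,
#'   `"role"`.
#' @return List `per_run` (run_id, group, n_features) and `summary`
#'   (group, n_runs, mean, median).
#' @export
feature_count_summary <- function(mat, group_by = "solvent") {
  if (!group_by %in% names(mat$cols) || group_by == "run_id")
    stop("unknown grouping key: ", group_by)
  counts <- colSums(!is.na(mat$abundance))
  per_run <- data.frame(run_id = mat$cols$run_id,
                        group = mat$cols[[group_by]],
                        n_features = as.integer(counts),
                        stringsAsFactors = FALSE)
  if (!nrow(per_run) || all(is.na(per_run$group)))
    return(list(per_run = per_run,
                summary = data.frame(group = character(0), n_runs = integer(0),
                                     mean = numeric(0), median = numeric(0))))
  agg <- do.call(rbind, lapply(split(per_run, per_run$group), function(d)
    data.frame(group = d$group[1], n_runs = nrow(d),
               mean = mean(d$n_features), median = stats::median(d$n_features),
               stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  list(per_run = per_run, summary = agg)
}
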