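# Synthetic centroided LC-MS studies with a full ground-truth ledger:
# per-species compound signatures with controlled pairwise overlap,
# solvent-dependent extraction, blank-pipe background, ancient mixtures
# with dropout and contaminants.

#' Simulation configuration
#'
#' Defaults state the emulated experimental design: 8 reference species
#' smoked in clay pipes, 3 sequential solvent extracts (TA, APW, MTBE),
#' 5 replicate pipes, blank pipes, QC pools per species-by-solvent
#' condition, and artifact ("ancient") samples as species mixtures with
#' compound dropout and environmental contaminants. Intensities are
#' log-normal in detector counts, m/z error is ppm-scale per centroid, RT
#' jitter is per compound per run. The PRNG is R's Mersenne-Twister; every
#' run draws from a substream seeded deterministically from
#' `(seed, run_id)`, so single runs are reproducible in isolation.
#'
#' @param species Character vector of species codes.
#' @param solvents Extract codes.
#' @param n_compounds Signature size per species.
#' @param shared_fraction Fraction of each signature shared with each other
#'   species (pairwise, exact by construction).
#' @param replicates Replicate pipes per species.
#' @param blank_compounds Pipe-background compounds present in every run.
#' @param contaminant_compounds Extra compounds planted only in ancient
#'   samples.
#' @param mix Named weights, species -> weight, for the default ancient
#'   mixture recipe.
#' @param dropout Fraction of eligible compounds lost from ancient samples
#'   (degradation).
#' @param mz_error_ppm Per-centroid m/z error sd, ppm.
#' @param rt_jitter_sd Per-run apex RT jitter sd, minutes.
#' @param intensity_sd Log10 intensity sd.
#' @param log10_abund Range of mean log10 apex heights (uniform); default
#'   clears the 1.0e4 deconvolution minimum with margin.
#' @param peak_width_sd Gaussian elution sd, minutes.
#' @param scan_interval Scan interval, seconds.
#' @param rt_range Acquisition RT window, minutes.
#' @param solvent_affinity_p Probability a solvent extracts a given
#'   compound (affinity subsets are resampled if empty).
#' @param isotopes Plant an A+1 isotopologue peak per compound.
#' @param noise_points Below-threshold noise centroids per scan.
#' @param noise_level Mass-detection noise level the floor stays under.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(species = c("AUV", "CSE", "NAT", "NQU",
                                   "NRU", "NTA", "RGL", "TBR"),
                       solvents = c("TA", "APW", "MTBE"),
                       n_compounds = 40L,
                       shared_fraction = 0.1,
                       replicates = 5L,
                       blank_compounds = 15L,
                       contaminant_compounds = 10L,
                       mix = c(NQU = 0.5, RGL = 0.5),
                       dropout = 0.3,
                       mz_error_ppm = 5,
                       rt_jitter_sd = 0.02,
                       intensity_sd = 0.15,
                       log10_abund = c(4.7, 5.7),
                       peak_width_sd = 0.05,
                       scan_interval = 0.3,
                       rt_range = c(0.01, 12.51),
                       solvent_affinity_p = 0.6,
                       isotopes = TRUE,
                       noise_points = 2L,
                       noise_level = 6.0e2,
                       seed = 1L) {
  stopifnot(shared_fraction >= 0, shared_fraction <= 1,
            dropout >= 0, dropout <= 1,
            mz_error_ppm >= 0, rt_jitter_sd >= 0, intensity_sd >= 0)
  cfg <- as.list(environment())
  cfg$rng_kind <- "Mersenne-Twister"   # named for reproducibility metadata
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic 31-bit substream seed from (seed, run id).
.run_seed <- function(seed, run_id) {
  h <- as.numeric(seed) %% 2147483647
  for (v in utf8ToInt(as.character(run_id)))
    h <- (h * 131 + v) %% 2147483647   # stays < 2^38, exact in doubles
  as.integer(h)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister")
  expr
}

.sample_affinity <- function(solvents, p) {
  repeat {
    aff <- solvents[stats::runif(length(solvents)) < p]
    if (length(aff)) return(paste(aff, collapse = ","))
  }
}

# Draw compound properties with minimum pairwise (m/z, RT) separation so
# distinct compounds never collide inside the alignment tolerances.
.draw_compounds <- function(n, cfg, existing_mz = numeric(0),
                            existing_rt = numeric(0), prefix = "cmp") {
  if (n == 0)
    return(data.frame(compound_id = character(0), mz = numeric(0),
                      rt = numeric(0), log10_abund = numeric(0),
                      affinity = character(0), iso_ratio = numeric(0),
                      stringsAsFactors = FALSE))
  lo <- cfg$rt_range[1] + 0.2; hi <- cfg$rt_range[2] - 0.5
  mz <- numeric(n); rt <- numeric(n)
  have_mz <- existing_mz; have_rt <- existing_rt
  for (i in seq_len(n)) {
    repeat {
      m <- stats::runif(1, 105, 1195)
      t <- stats::runif(1, lo, hi)
      clash <- abs(have_mz - m) < 1.1 & abs(have_rt - t) < 0.3
      if (!any(clash)) break
    }
    mz[i] <- m; rt[i] <- t
    have_mz <- c(have_mz, m); have_rt <- c(have_rt, t)
  }
  data.frame(compound_id = paste0(prefix, "_", seq_len(n)),
             mz = mz, rt = rt,
             log10_abund = stats::runif(n, cfg$log10_abund[1],
                                        cfg$log10_abund[2]),
             affinity = vapply(seq_len(n), function(i)
               .sample_affinity(cfg$solvents, cfg$solvent_affinity_p),
               character(1)),
             iso_ratio = stats::runif(n, 0.05, 0.30),
             stringsAsFactors = FALSE)
}

#' Generate species signatures with controlled pairwise overlap
#'
#' Builds one compound signature per species such that every unordered
#' species pair shares exactly `round(shared_fraction * n_compounds)`
#' compounds (distinct compounds per pair), the remainder being unique to
#' each species. Blank-pipe background compounds are generated alongside
#' (present in every run, full solvent affinity). Deterministic under the
#' config seed.
#'
#' @param config A [sim_config()].
#' @return List with `compounds` (property table with `provenance`),
#'   `membership` (species -> compound ids), `blank_ids`, and
#'   `shared_ledger` (data.frame species_a, species_b, compound_id).
#' @export
make_signatures <- function(config) {
  cfg <- config
  k <- length(cfg$species)
  n <- cfg$n_compounds
  n_shared <- round(cfg$shared_fraction * n)
  if (k >= 2 && n_shared * (k - 1) > n)
    stop("infeasible shared_fraction: ", cfg$shared_fraction,
         " needs ", n_shared * (k - 1), " shared compounds per species but signatures have ", n)
  if (k < 2 && cfg$shared_fraction > 0)
    stop("overlap requires >= 2 species")
  .with_seed(.run_seed(cfg$seed, "signatures"), {
    pairs <- if (k >= 2) utils::combn(cfg$species, 2) else matrix(character(0), 2, 0)
    n_pair_cmp <- ncol(pairs) * n_shared
    n_unique <- k * (n - n_shared * (k - 1))
    total <- n_pair_cmp + n_unique + cfg$blank_compounds
    cmp <- .draw_compounds(total, cfg)
    membership <- stats::setNames(vector("list", k), cfg$species)
    prov <- character(total)
    ledger <- list()
    at <- 0L
    for (j in seq_len(ncol(pairs))) {
      ids <- cmp$compound_id[at + seq_len(n_shared)]
      at <- at + n_shared
      a <- pairs[1, j]; b <- pairs[2, j]
      membership[[a]] <- c(membership[[a]], ids)
      membership[[b]] <- c(membership[[b]], ids)
      prov[match(ids, cmp$compound_id)] <- paste(a, b, sep = "+")
      if (n_shared)
        ledger[[j]] <- data.frame(species_a = a, species_b = b,
                                  compound_id = ids)
    }
    for (sp in cfg$species) {
      n_uni <- n - n_shared * (k - 1)
      ids <- cmp$compound_id[at + seq_len(n_uni)]
      at <- at + n_uni
      membership[[sp]] <- c(membership[[sp]], ids)
      prov[match(ids, cmp$compound_id)] <- sp
    }
    blank_ids <- cmp$compound_id[at + seq_len(cfg$blank_compounds)]
    prov[match(blank_ids, cmp$compound_id)] <- "blank"
    cmp$affinity[match(blank_ids, cmp$compound_id)] <-
      paste(cfg$solvents, collapse = ",")
    cmp$provenance <- prov
    list(compounds = cmp, membership = membership, blank_ids = blank_ids,
         shared_ledger = if (length(ledger)) do.call(rbind, ledger)
         else data.frame(species_a = character(0), species_b = character(0),
                         compound_id = character(0)))
  })
}

# Gaussian elution profiles for a set of planted compounds -> long scan table.
.render_scans <- function(planted, cfg) {
  scan_rt <- seq(cfg$rt_range[1], cfg$rt_range[2], by = cfg$scan_interval / 60)
  n_scan <- length(scan_rt)
  parts <- vector("list", nrow(planted) * 2L + 1L)
  pi_ <- 0L
  for (i in seq_len(nrow(planted))) {
    apex <- planted$apex_rt[i]
    h <- planted$height[i]
    sel <- which(abs(scan_rt - apex) <= 4 * cfg$peak_width_sd)
    if (!length(sel)) next
    inten <- h * exp(-(scan_rt[sel] - apex)^2 / (2 * cfg$peak_width_sd^2))
    keep <- inten >= 50
    sel <- sel[keep]; inten <- inten[keep]
    if (!length(sel)) next
    mzs <- planted$mz[i] *
      (1 + stats::rnorm(length(sel), 0, cfg$mz_error_ppm * 1e-6))
    pi_ <- pi_ + 1L
    parts[[pi_]] <- data.frame(scan = sel, rt = scan_rt[sel],
                               mz = mzs, intensity = inten)
    if (cfg$isotopes) {
      iso_h <- inten * planted$iso_ratio[i]
      k2 <- iso_h >= 50
      if (any(k2)) {
        pi_ <- pi_ + 1L
        parts[[pi_]] <- data.frame(
          scan = sel[k2], rt = scan_rt[sel][k2],
          mz = (planted$mz[i] + 1.00336) *
            (1 + stats::rnorm(sum(k2), 0, cfg$mz_error_ppm * 1e-6)),
          intensity = iso_h[k2])
      }
    }
  }
  if (cfg$noise_points > 0) {
    n_noise <- cfg$noise_points * n_scan
    pi_ <- pi_ + 1L
    parts[[pi_]] <- data.frame(
      scan = sample.int(n_scan, n_noise, replace = TRUE),
      rt = NA_real_,
      mz = stats::runif(n_noise, 100, 1200),
      intensity = stats::runif(n_noise, 50, cfg$noise_level - 1))
    parts[[pi_]]$rt <- scan_rt[parts[[pi_]]$scan]
  }
  out <- do.call(rbind, parts[seq_len(pi_)])
  if (is.null(out)) out <- data.frame(scan = integer(0), rt = numeric(0),
                                      mz = numeric(0), intensity = numeric(0))
  out
}

#' Simulate one centroided run
#'
#' Plants every compound of the weighted signature mixture that the solvent
#' extracts (optionally thinned by dropout, keeping
#' `ceiling((1 - dropout) * n_eligible)`), plus the blank-pipe background
#' and any extra (contaminant) compounds, as Gaussian elution profiles
#' sampled on the scan grid with per-centroid ppm m/z error, per-compound
#' RT jitter, and log-normal apex heights. A sparse sub-threshold noise
#' floor exercises the mass detector.
#'
#' @param signatures Result of [make_signatures()].
#' @param mix Named species weights (empty or all-zero only for blanks).
#' @param solvent Extract code.
#' @param config A [sim_config()].
#' @param run_id Run identifier (also selects the RNG substream).
#' @param role Run role: `"species_ref"`, `"blank"`, `"qc"`, `"ancient"`.
#' @param dropout Dropout fraction applied to the species compounds
#'   (default 0; ancient runs pass `config$dropout`).
#' @param extra_compounds Optional extra compound table (contaminants),
#'   same columns as `signatures$compounds`.
#' @param sample_id Sample identifier (defaults to run id).
#' @return List `run` (a [centroid_run()]) and `truth` (data.frame of
#'   planted compounds: id, true m/z, apex RT, height, provenance class).
#' @export
simulate_run <- function(signatures, mix, solvent, config,
                         run_id = "run", role = "species_ref",
                         dropout = 0, extra_compounds = NULL,
                         sample_id = run_id) {
  cfg <- config
  if (length(mix) && any(mix < 0)) stop("mix weights must be >= 0")
  mix <- mix[mix > 0]
  if (length(mix) && is.null(names(mix)))
    stop("mix must be a named weight vector")
  role <- match.arg(role, c("species_ref", "blank", "qc", "ancient"))
  cmp <- signatures$compounds
  .with_seed(.run_seed(cfg$seed, run_id), {
    planted <- list()
    if (length(mix)) {
      ids <- unique(unlist(signatures$membership[names(mix)]))
      sel <- cmp[match(ids, cmp$compound_id), , drop = FALSE]
      ok <- vapply(strsplit(sel$affinity, ","), function(a) solvent %in% a,
                   logical(1))
      sel <- sel[ok, , drop = FALSE]
      if (dropout > 0 && nrow(sel)) {
        n_keep <- ceiling((1 - dropout) * nrow(sel))
        sel <- sel[sort(sample.int(nrow(sel), n_keep)), , drop = FALSE]
      }
      if (nrow(sel)) {
        w <- vapply(sel$compound_id, function(id) {
          inm <- vapply(names(mix), function(sp)
            id %in% signatures$membership[[sp]], logical(1))
          sum(mix[inm])
        }, numeric(1))
        sel$weight <- w
        sel$class <- "species"
        planted[["species"]] <- sel
      }
    }
    blk <- cmp[match(signatures$blank_ids, cmp$compound_id), , drop = FALSE]
    ok <- vapply(strsplit(blk$affinity, ","), function(a) solvent %in% a,
                 logical(1))
    blk <- blk[ok, , drop = FALSE]
    if (nrow(blk)) {
      blk$weight <- 1; blk$class <- "blank"
      planted[["blank"]] <- blk
    }
    if (!is.null(extra_compounds) && nrow(extra_compounds)) {
      ext <- extra_compounds
      ok <- vapply(strsplit(ext$affinity, ","), function(a) solvent %in% a,
                   logical(1))
      ext <- ext[ok, , drop = FALSE]
      if (nrow(ext)) {
        ext$weight <- 1; ext$class <- "contaminant"
        planted[["extra"]] <- ext
      }
    }
    pl <- do.call(rbind, planted)
    if (is.null(pl)) {
      pl <- cmp[0, , drop = FALSE]
      pl$weight <- numeric(0); pl$class <- character(0)
    }
    pl$apex_rt <- pl$rt + stats::rnorm(nrow(pl), 0, cfg$rt_jitter_sd)
    pl$height <- 10^(pl$log10_abund +
                       stats::rnorm(nrow(pl), 0, cfg$intensity_sd)) * pl$weight
    scans <- .render_scans(pl, cfg)
    run <- centroid_run(scans, run_id = run_id, sample_id = sample_id,
                        role = role,
                        species = if (length(mix) == 1) names(mix)
                        else if (role == "blank") "BLANK"
                        else if (role == "ancient") "ANCIENT"
                        else paste(names(mix), collapse = "+"),
                        solvent = solvent)
    truth <- data.frame(compound_id = pl$compound_id, mz = pl$mz,
                        rt = pl$apex_rt, height = pl$height,
                        class = pl$class, provenance = pl$provenance,
                        stringsAsFactors = FALSE)
    list(run = run, truth = truth)
  })
}

#' Generate a full synthetic study
#'
#' Enumerates and simulates every run of the emulated design: per-species
#' replicate runs for each solvent, blank-pipe replicates, one QC pool per
#' (species + blank) x solvent condition (the pooled union of that
#' condition's replicate compound sets — with identical replicate
#' signatures this is one clean run of the full signature), and ancient
#' artifact samples (one run per solvent) built from the configured mixture
#' with dropout and sample-level contaminants shared across that sample's
#' three extracts.
#'
#' @param config A [sim_config()].
#' @param ancient_samples Named list, sample id -> named species weight
#'   vector; default one sample `"ANC1"` using `config$mix`.
#' @param include_replicates Simulate the per-replicate experimental runs
#'   (TRUE, the full design) or only QC pools, blanks and ancient samples
#'   (lean mode for pipelines that use QC references).
#' @param include_blanks Include blank-pipe replicate runs and the blank QC
#'   pool (default TRUE; the QC pool count is then
#'   `solvents x (species + 1)`).
#' @return List with `manifest` (run metadata data.frame), `runs` (named
#'   list of [centroid_run()]), `truth` (per-run planted-compound tables),
#'   `signatures`, and `contaminants` (per ancient sample).
#' @export
make_study <- function(config, ancient_samples = NULL,
                       include_replicates = TRUE, include_blanks = TRUE) {
  cfg <- config
  if (is.null(ancient_samples)) ancient_samples <- list(ANC1 = cfg$mix)
  sig <- make_signatures(cfg)
  manifest <- list(); runs <- list(); truth <- list()
  add <- function(res, sample_id, species, solvent, replicate, role) {
    id <- res$run$meta$run_id
    runs[[id]] <<- res$run
    truth[[id]] <<- res$truth
    manifest[[length(manifest) + 1L]] <<- data.frame(
      run_id = id, sample_id = sample_id, species = species,
      solvent = solvent, replicate = replicate, role = role,
      stringsAsFactors = FALSE)
  }
  if (include_replicates) {
    for (sp in cfg$species) for (sv in cfg$solvents)
      for (r in seq_len(cfg$replicates)) {
        id <- sprintf("REF_%s_%s_R%d", sp, sv, r)
        add(simulate_run(sig, stats::setNames(1, sp), sv, cfg, run_id = id,
                         role = "species_ref",
                         sample_id = sprintf("%s_R%d", sp, r)),
            sprintf("%s_R%d", sp, r), sp, sv, r, "species_ref")
      }
    if (include_blanks) for (sv in cfg$solvents) for (r in seq_len(cfg$replicates)) {
      id <- sprintf("BLK_%s_R%d", sv, r)
      add(simulate_run(sig, numeric(0), sv, cfg, run_id = id, role = "blank",
                       sample_id = sprintf("BLK_R%d", r)),
          sprintf("BLK_R%d", r), "BLANK", sv, r, "blank")
    }
  }
  # QC pools: one per (species + blank) x solvent
  qc_groups <- if (include_blanks) c(cfg$species, "BLANK") else cfg$species
  for (sp in qc_groups) for (sv in cfg$solvents) {
    id <- sprintf("QC_%s_%s", sp, sv)
    mix <- if (sp == "BLANK") numeric(0) else stats::setNames(1, sp)
    role <- if (sp == "BLANK") "blank" else "qc"
    add(simulate_run(sig, mix, sv, cfg, run_id = id,
                     role = if (sp == "BLANK") "blank" else "qc",
                     sample_id = sprintf("QC_%s", sp)),
        sprintf("QC_%s", sp), sp, sv, NA_integer_, "qc")
  }
  contaminants <- list()
  for (anc in names(ancient_samples)) {
    cont <- .with_seed(.run_seed(cfg$seed, paste0("contaminants_", anc)), {
      cc <- .draw_compounds(cfg$contaminant_compounds, cfg,
                            existing_mz = sig$compounds$mz,
                            existing_rt = sig$compounds$rt,
                            prefix = paste0("cont_", anc))
      cc$affinity <- rep(paste(cfg$solvents, collapse = ","), nrow(cc))
      cc$provenance <- rep("contaminant", nrow(cc))
      cc
    })
    contaminants[[anc]] <- cont
    for (sv in cfg$solvents) {
      id <- sprintf("ANC_%s_%s", anc, sv)
      add(simulate_run(sig, ancient_samples[[anc]], sv, cfg, run_id = id,
                       role = "ancient", dropout = cfg$dropout,
                       extra_compounds = cont, sample_id = anc),
          anc, "ANCIENT", sv, NA_integer_, "ancient")
    }
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  list(manifest = manifest, runs = runs, truth = truth, signatures = sig,
       contaminants = contaminants, config = cfg)
}
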