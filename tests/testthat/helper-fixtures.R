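# Shared fixtures: deterministic runs with planted Gaussian peaks, the
# brute-force formula-enumeration oracle, and a compact study config.

# Deterministic run: Gaussian elution profiles for given compounds, no
# noise, no m/z error. `compounds`: data.frame(mz, rt, height).
gaussian_run <- function(compounds, rt_range = c(0.01, 4), scan_interval = 0.3,
                         width_sd = 0.05, floor = 100, run_id = "t",
                         role = "species_ref", solvent = "TA",
                         species = "TST", sample_id = run_id) {
  scan_rt <- seq(rt_range[1], rt_range[2], by = scan_interval / 60)
  parts <- lapply(seq_len(nrow(compounds)), function(i) {
    sel <- which(abs(scan_rt - compounds$rt[i]) <= 4 * width_sd)
    inten <- compounds$height[i] *
      exp(-(scan_rt[sel] - compounds$rt[i])^2 / (2 * width_sd^2))
    keep <- inten >= floor
    data.frame(scan = sel[keep], rt = scan_rt[sel][keep],
               mz = rep(compounds$mz[i], sum(keep)), intensity = inten[keep])
  })
  centroid_run(do.call(rbind, parts), run_id = run_id, sample_id = sample_id,
               role = role, species = species, solvent = solvent)
}

# Independent brute-force formula oracle: full lattice enumeration over the
# element ranges (quadruple loop realized as an expanded grid), no solving
# tricks shared with the implementation.
brute_force_formulas <- function(query_mz, tolerance_ppm, ranges, adduct) {
  a <- if (inherits(adduct, "adduct_spec")) adduct else adduct_spec(adduct)
  masses <- c(C = 12.000000, H = 1.007825, N = 14.003074, O = 15.994915,
              Na = 22.989769)
  grid <- do.call(expand.grid,
                  c(lapply(ranges, function(r) seq.int(r[1], r[2])),
                    KEEP.OUT.ATTRS = FALSE))
  m <- as.matrix(grid) %*% masses[names(ranges)]
  mz <- (m + a$delta) / a$charge
  hit <- abs(mz - query_mz) <= tolerance_ppm * 1e-6 * query_mz
  g <- grid[hit, , drop = FALSE]
  rownames(g) <- NULL
  g
}

# formula candidates -> canonical sorted key strings for set comparison
formula_keys <- function(df, els = c("C", "H", "N", "O")) {
  if (!nrow(df)) return(character(0))
  sort(apply(as.matrix(df[, els, drop = FALSE]), 1, paste, collapse = "/"))
}

# Compact synthetic study used across tests (small RT window, 5 species).
small_sim_config <- function(seed, ...) {
  sim_config(species = c("AUV", "NQU", "NRU", "RGL", "TBR"),
             n_compounds = 25L, replicates = 1L, rt_range = c(0.2, 3.8),
             blank_compounds = 10L, contaminant_compounds = 5L,
             mix = c(NQU = 0.5, RGL = 0.5), dropout = 0.4, seed = seed, ...)
}

# Compound lists straight from a study's truth ledger (bypassing feature
# extraction), on compound ids as row ids.
truth_compound_lists <- function(study) {
  mid <- "truth-ledger"
  man <- study$manifest
  lists <- list()
  for (sid in unique(man$sample_id)) {
    rids <- unique(unlist(lapply(man$run_id[man$sample_id == sid],
                                 function(r) study$truth[[r]]$compound_id)))
    lists[[sid]] <- structure(list(sample_id = sid, rows = rids,
                                   abundance = NULL, matrix_id = mid),
                              class = "compound_list")
  }
  lists
}
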