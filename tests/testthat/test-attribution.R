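# Set-intersection species attribution, ranking, biomarker annotation.

cl <- function(id, rows, mid = "m1") {
  structure(list(sample_id = id, rows = rows, abundance = NULL,
                 matrix_id = mid), class = "compound_list")
}

test_that("venn counts follow set algebra on trivial configurations", {
  refs <- list(A = cl("A", paste0("r", 1:10)),
               B = cl("B", paste0("r", 11:15)),
               C = cl("C", paste0("r", 16:18)))
  # disjoint target
  rep0 <- venn_counts(cl("T", paste0("x", 1:5)), refs)
  expect_true(all(rep0$counts$shared == 0))
  expect_identical(rep0$counts$exclusive[rep0$counts$species == "A"], 10L)
  # target equal to one reference, references pairwise disjoint
  rep1 <- venn_counts(cl("T", paste0("r", 1:10)), refs)
  expect_identical(rep1$counts$shared[rep1$counts$species == "A"], 10L)
  expect_true(all(rep1$counts$shared[rep1$counts$species != "A"] == 0L))
  expect_identical(rep1$counts$exclusive,
                   rep1$counts$exclusive[order(-rep1$counts$shared,
                                               rep1$counts$species)])
  # overlapping references shrink exclusives
  refs2 <- list(A = cl("A", paste0("r", 1:10)),
                B = cl("B", paste0("r", 8:15)))
  rep2 <- venn_counts(cl("T", "r9"), refs2)
  expect_identical(rep2$counts$exclusive[rep2$counts$species == "A"], 7L)
  expect_identical(rep2$counts$exclusive[rep2$counts$species == "B"], 5L)
})

test_that("lists from different matrices are rejected", {
  expect_error(venn_counts(cl("T", "r1", mid = "m2"),
                           list(A = cl("A", "r1", mid = "m1"))),
               "incomparable")
})

test_that("species ranking follows shared counts with alphabetical tie-break", {
  refs <- list(RGL = cl("RGL", paste0("r", 1:40)),
               NQU = cl("NQU", paste0("q", 1:10)),
               CSE = cl("CSE", paste0("c", 1:8)))
  target <- cl("T", c(paste0("r", 1:33), paste0("q", 1:8), paste0("c", 1:6)))
  rep <- venn_counts(target, refs)
  expect_identical(rep$counts$shared, c(33L, 8L, 6L))
  expect_identical(rank_species(rep, 3), structure(c("RGL", "NQU", "CSE"),
                                                   tied = FALSE))
  # all-zero: empty ranking with warning
  rep0 <- venn_counts(cl("T", "zzz"), refs)
  expect_warning(r0 <- rank_species(rep0), "no species")
  expect_length(r0, 0)
  # two-way tie: alphabetical with flag
  refs_t <- list(B = cl("B", paste0("r", 1:5)), A = cl("A", paste0("r", 1:5)))
  rep_t <- venn_counts(cl("T", paste0("r", 1:5)), refs_t)
  rt <- rank_species(rep_t, 2)
  expect_identical(as.character(rt), c("A", "B"))
  expect_true(attr(rt, "tied"))
})

test_that("venn counts equal brute-force set algebra on study truth ledgers", {
  for (seed in c(3, 17)) {
    cfg <- small_sim_config(seed)
    st <- make_study(cfg, include_replicates = FALSE)
    lists <- truth_compound_lists(st)
    refs <- lists[paste0("QC_", cfg$species)]
    names(refs) <- cfg$species
    rep <- venn_counts(lists$ANC1, refs)
    # independent recount: double loop with element-wise membership tests
    for (sp in cfg$species) {
      n_shared <- 0L
      for (x in lists$ANC1$rows)
        if (x %in% refs[[sp]]$rows) n_shared <- n_shared + 1L
      expect_identical(rep$counts$shared[rep$counts$species == sp], n_shared)
      n_exc <- 0L
      for (x in refs[[sp]]$rows) {
        found <- FALSE
        for (o in setdiff(cfg$species, sp))
          if (x %in% refs[[o]]$rows) { found <- TRUE; break }
        if (!found) n_exc <- n_exc + 1L
      }
      expect_identical(rep$counts$exclusive[rep$counts$species == sp], n_exc)
    }
  }
})

test_that("adding target compounds never decreases shared counts", {
  refs <- list(A = cl("A", paste0("r", 1:10)), B = cl("B", paste0("r", 5:20)))
  base <- venn_counts(cl("T", paste0("r", 3:7)), refs)
  grown <- venn_counts(cl("T", paste0("r", 3:9)), refs)
  expect_true(all(grown$counts$shared[order(grown$counts$species)] >=
                    base$counts$shared[order(base$counts$species)]))
})

.mk_annot_matrix <- function(rows) {
  structure(list(
    abundance = matrix(1, nrow(rows), 1,
                       dimnames = list(rows$row_id, "r1")),
    rows = rows,
    cols = data.frame(run_id = "r1", sample_id = "s", species = "X",
                      solvent = "TA", role = "qc"),
    matrix_id = "ann"), class = "aligned_matrix")
}

test_that("biomarker annotation separates isobars by RT and reports ambiguity", {
  rows <- data.frame(row_id = c("a", "b", "c"),
                     mz = c(163.125, 163.125, 500.0),
                     rt = c(1.15, 1.30, 5.0), charge = NA_integer_,
                     stringsAsFactors = FALSE)
  m <- .mk_annot_matrix(rows)
  lib <- biomarker_library()
  # tight RT tolerance: nicotine (1.15) only, anabasine (1.48) excluded
  ann <- annotate_biomarkers(m, lib, mz_tol = mz_tolerance(0.01, 0),
                             rt_tol = 0.1)
  expect_identical(ann$name[ann$row_id == "a"], "nicotine")
  expect_identical(ann$status[ann$row_id == "a"], "unique")
  # wide RT tolerance: both isobars within reach -> ambiguous, never chosen
  ann2 <- annotate_biomarkers(m, lib, mz_tol = mz_tolerance(0.01, 0),
                              rt_tol = 0.25)
  expect_identical(ann2$name[ann2$row_id == "b"], "anabasine;nicotine")
  expect_identical(ann2$status[ann2$row_id == "b"], "ambiguous")
  # unmatched row gets no annotation
  expect_false("c" %in% ann2$row_id)
})

test_that("fragment cosine similarity resolves isobars when available", {
  rows <- data.frame(row_id = "b", mz = 163.125, rt = 1.30,
                     charge = NA_integer_, stringsAsFactors = FALSE)
  m <- .mk_annot_matrix(rows)
  lib <- biomarker_library()[c(1, 5), ]   # anabasine, nicotine
  # nicotine MS/MS-style fragments vs distinct anabasine fragments
  lib$fragments <- list(c(80.05, 92.05, 120.08), c(84.08, 106.07, 130.07))
  ann <- annotate_biomarkers(
    m, lib, mz_tol = mz_tolerance(0.01, 0), rt_tol = 0.25,
    row_fragments = list(b = c(84.081, 106.071, 130.071)))
  expect_identical(ann$name, "nicotine")
  expect_identical(ann$status, "unique")
  # empty library: no annotations
  expect_identical(nrow(annotate_biomarkers(m, biomarker_library()[0, ])), 0L)
})

test_that("bundled biomarker standards satisfy the adduct sanity bound", {
  lib <- biomarker_library()
  expect_identical(nrow(lib), 7L)
  theo <- mapply(adduct_mz, lib$formula, lib$adduct)
  expect_true(all(abs(lib$observed_mz - theo) <= 0.05))
  expect_identical(lib$rt[lib$name == "nicotine"], 1.15)
  # the two isobar pairs really are isobaric
  expect_identical(lib$observed_mz[lib$name == "nicotine"],
                   lib$observed_mz[lib$name == "anabasine"])
  expect_identical(lib$observed_mz[lib$name == "theobromine"],
                   lib$observed_mz[lib$name == "theophylline"])
})
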