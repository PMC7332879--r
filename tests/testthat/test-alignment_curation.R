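# Join alignment, blank subtraction, solvent-extract merging.

mk_feats <- function(mz, rt, height = rep(1e5, length(mz)),
                     charge = rep(NA_integer_, length(mz))) {
  data.frame(mz = mz, rt = rt, height = height, area = 1, charge = charge,
             iso_group = seq_along(mz), representative = TRUE)
}

test_that("a single run aligns to one row per feature", {
  f <- mk_feats(c(200, 300, 400), c(1, 2, 3))
  m <- join_align(list(r1 = f))
  expect_identical(dim(m$abundance), c(3L, 1L))
  expect_identical(sum(!is.na(m$abundance)), 3L)
  expect_equal(sort(m$rows$mz), c(200, 300, 400))
})

test_that("perturbed replicate runs align onto shared rows", {
  mz <- c(200, 450, 800); rt <- c(1, 2, 3)
  f1 <- mk_feats(mz, rt)
  f2 <- mk_feats(mz * (1 + 4e-6), rt + 0.02)   # <=5 ppm, <=0.02 min
  m <- join_align(list(a = f1, b = f2))
  expect_identical(nrow(m$abundance), 3L)
  expect_identical(sum(!is.na(m$abundance)), 6L)
  # consensus m/z within tolerance of both members
  for (i in 1:3)
    expect_lt(abs(m$rows$mz[i] - sort(mz)[i]) / sort(mz)[i], 5e-6)
})

test_that("RT separation beyond tolerance forces distinct rows", {
  f1 <- mk_feats(500, 2.0)
  f2 <- mk_feats(500, 2.2)   # 0.2 min apart at 0.05 tolerance
  m <- join_align(list(a = f1, b = f2))
  expect_identical(nrow(m$abundance), 2L)
})

test_that("one run contributes at most one feature per row", {
  # two same-run features both compatible with the same row
  f1 <- mk_feats(500, 2.0)
  f2 <- mk_feats(c(500.000, 500.004), c(2.0, 2.01), height = c(1e5, 9e4))
  m <- join_align(list(a = f1, b = f2))
  expect_identical(nrow(m$abundance), 2L)
  expect_identical(sum(!is.na(m$abundance)), 3L)
})

test_that("alignment conserves features as filled cells", {
  set.seed(6)
  lists <- lapply(1:4, function(i)
    mk_feats(runif(20, 100, 1200), runif(20, 0.5, 11)))
  names(lists) <- paste0("r", 1:4)
  m <- join_align(lists)
  expect_identical(sum(!is.na(m$abundance)), 80L)
})

test_that("charge agreement is enforced when both are determined", {
  f1 <- mk_feats(500, 2.0, charge = 1L)
  f2 <- mk_feats(500, 2.0, charge = 2L)
  m <- join_align(list(a = f1, b = f2), require_same_charge = TRUE)
  expect_identical(nrow(m$abundance), 2L)
  m2 <- join_align(list(a = f1, b = f2), require_same_charge = FALSE)
  expect_identical(nrow(m2$abundance), 1L)
})

test_that("input order does not change the induced partition for well-separated data", {
  set.seed(8)
  mz <- seq(150, 1150, by = 50); rt <- runif(length(mz), 1, 11)
  perturb <- function() mk_feats(mz * (1 + rnorm(length(mz), 0, 2e-6)),
                                 rt + rnorm(length(mz), 0, 0.01))
  lists <- list(r1 = perturb(), r2 = perturb(), r3 = perturb())
  m_fwd <- join_align(lists)
  m_rev <- join_align(rev(lists))
  # same partition: every row has the same member m/z set
  expect_identical(nrow(m_fwd$abundance), nrow(m_rev$abundance))
  expect_equal(sort(m_fwd$rows$mz), sort(m_rev$rows$mz), tolerance = 1e-12)
})

.mk_matrix <- function() {
  # 5 rows x 4 runs; rows 2 and 4 present in the blank
  ab <- matrix(NA_real_, 5, 4,
               dimnames = list(paste0("row", 1:5),
                               c("S1_TA", "S1_APW", "BLK_TA", "ANC_TA")))
  ab[1, 1] <- 10; ab[2, 1] <- 20; ab[2, 3] <- 5; ab[3, 2] <- 30
  ab[4, 3] <- 7; ab[4, 4] <- 40; ab[5, 4] <- 50
  structure(list(
    abundance = ab,
    rows = data.frame(row_id = rownames(ab), mz = 1:5, rt = 1:5,
                      charge = NA_integer_),
    cols = data.frame(run_id = colnames(ab),
                      sample_id = c("S1", "S1", "BLK", "ANC"),
                      species = c("SPA", "SPA", "BLANK", "ANCIENT"),
                      solvent = c("TA", "APW", "TA", "TA"),
                      role = c("qc", "qc", "blank", "ancient"),
                      stringsAsFactors = FALSE),
    matrix_id = "fix1"), class = "aligned_matrix")
}

test_that("blank subtraction removes exactly the blank-present rows", {
  m <- .mk_matrix()
  out <- remove_blank_shared(m)
  expect_identical(rownames(out$abundance), c("row1", "row3", "row5"))
  expect_false("BLK_TA" %in% out$cols$run_id)
  # no blank columns: identity with a warning
  m2 <- m
  keep <- m$cols$role != "blank"
  m2$abundance <- m$abundance[, keep]; m2$cols <- m$cols[keep, ]
  expect_warning(out2 <- remove_blank_shared(m2), "no blank")
  expect_identical(out2$abundance, m2$abundance)
})

test_that("merging extracts takes the union across a sample's solvents", {
  m <- .mk_matrix()
  cl <- merge_extracts(m, "S1")
  expect_setequal(cl$rows, c("row1", "row2", "row3"))
  expect_identical(unname(cl$abundance["row2"]), 20)
  # single-solvent presence is enough (union semantics)
  expect_true("row3" %in% cl$rows)
  expect_error(merge_extracts(m, "nope"), "unknown sample")
})

test_that("disjoint per-solvent sets merge additively and empty samples stay empty", {
  ab <- matrix(NA_real_, 6, 4,
               dimnames = list(paste0("row", 1:6),
                               c("S_TA", "S_APW", "S_MTBE", "E_TA")))
  ab[1:2, 1] <- 1; ab[3:4, 2] <- 1; ab[5:6, 3] <- 1
  m <- structure(list(
    abundance = ab,
    rows = data.frame(row_id = rownames(ab), mz = 1:6, rt = 1:6,
                      charge = NA_integer_),
    cols = data.frame(run_id = colnames(ab),
                      sample_id = c("S", "S", "S", "E"),
                      species = "SPA", solvent = c("TA", "APW", "MTBE", "TA"),
                      role = "qc", stringsAsFactors = FALSE),
    matrix_id = "fix2"), class = "aligned_matrix")
  expect_length(merge_extracts(m, "S")$rows, 6)   # 2 + 2 + 2 disjoint
  expect_length(merge_extracts(m, "E")$rows, 0)
  # monotone: removing a solvent column never grows the list
  m_sub <- m
  m_sub$abundance <- ab[, -3]; m_sub$cols <- m$cols[-3, ]
  expect_true(all(merge_extracts(m_sub, "S")$rows %in%
                    merge_extracts(m, "S")$rows))
  expect_lte(length(merge_extracts(m_sub, "S")$rows),
             length(merge_extracts(m, "S")$rows))
})

test_that("blank subtraction on a synthetic study removes the planted background rows", {
  # low-noise regime: the property under test is the removal logic, so
  # alignment must be unambiguous (spacing >> tolerance)
  cfg <- small_sim_config(55, mz_error_ppm = 1, rt_jitter_sd = 0.005)
  st <- make_study(cfg, include_replicates = FALSE)
  feats <- lapply(st$runs, extract_features)
  m <- join_align(feats, metadata = st$manifest)
  out <- remove_blank_shared(m)
  # row-level soundness: no surviving row was present in a blank column
  blank_cols <- which(m$cols$role == "blank" | m$cols$species == "BLANK")
  blank_rows <- rownames(m$abundance)[
    rowSums(!is.na(m$abundance[, blank_cols, drop = FALSE])) > 0]
  expect_length(intersect(rownames(out$abundance), blank_rows), 0)
  # no surviving row may match a blank-background compound (joint m/z + RT)
  blanks <- st$signatures$compounds[
    st$signatures$compounds$provenance == "blank", ]
  hits <- function(mat) vapply(seq_len(nrow(blanks)), function(i)
    any(abs(mat$rows$mz - blanks$mz[i]) / blanks$mz[i] < 10e-6 &
          abs(mat$rows$rt - blanks$rt[i]) < 0.1), logical(1))
  expect_false(any(hits(out)))
  # and blank rows were indeed present pre-subtraction
  expect_true(all(hits(m)))
})
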