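test_that("dice matches hand counts and empty-mask conventions", {
  dims <- c(4, 4, 4)
  a <- mk_mask(dims, fg = 1:4)
  b <- mk_mask(dims, fg = 3:4)
  expect_equal(dice(a, b), 2 * 2 / (4 + 2))      # |A|=4, |B|=2, overlap 2
  expect_equal(dice(a, a), 1.0)
  expect_equal(dice(mk_mask(dims, fg = 1:2), mk_mask(dims, fg = 5:6)), 0.0)
  expect_equal(dice(a, mk_mask(dims)), 0.0)      # one empty
  expect_true(is.nan(dice(mk_mask(dims), mk_mask(dims))))  # both empty
  expect_error(dice(a, mk_mask(c(5, 5, 5), fg = 1)), "grid mismatch")
})

test_that("dice and hausdorff are symmetric", {
  set.seed(3)
  for (i in 1:10) {
    a <- random_binary(c(6, 6, 6), 12, spacing = c(1, 1.5, 3))
    b <- random_binary(c(6, 6, 6), 9, spacing = c(1, 1.5, 3))
    expect_identical(dice(a, b), dice(b, a))
    expect_identical(hausdorff(a, b), hausdorff(b, a))
  }
})

test_that("hausdorff respects geometry: 3-4-5 triangle, identity, empties", {
  dims <- c(8, 8, 8)
  a <- mk_mask(dims, fg = cbind(1, 1, 1))
  b <- mk_mask(dims, fg = cbind(4, 5, 1))   # offsets (3, 4, 0) voxels
  expect_equal(hausdorff(a, b), 5.0)
  expect_equal(hausdorff(a, a), 0.0)
  expect_identical(hausdorff(mk_mask(dims), b), Inf)
  expect_true(is.nan(hausdorff(mk_mask(dims), mk_mask(dims))))
})

test_that("hausdorff scales linearly with spacing; dice does not change", {
  set.seed(5)
  for (i in 1:5) {
    v1 <- array(0L, dim = c(6, 6, 6)); v1[sample(216, 10)] <- 1L
    v2 <- array(0L, dim = c(6, 6, 6)); v2[sample(216, 10)] <- 1L
    a1 <- seg_mask(v1); b1 <- seg_mask(v2)
    a2 <- seg_mask(v1, spacing = c(2, 2, 2)); b2 <- seg_mask(v2, spacing = c(2, 2, 2))
    expect_equal(hausdorff(a2, b2), 2 * hausdorff(a1, b1))
    expect_identical(dice(a1, b1), dice(a2, b2))
  }
})

test_that("hausdorff equals the brute-force oracle on random anisotropic masks", {
  set.seed(99)
  for (i in 1:60) {
    sp <- stats::runif(3, 0.5, 3)
    dims <- sample(4:8, 3, replace = TRUE)
    a <- random_binary(dims, sample(1:15, 1), spacing = sp)
    b <- random_binary(dims, sample(1:15, 1), spacing = sp)
    expect_identical(hausdorff(a, b), oracle_hausdorff(a, b))
  }
})

test_that("percentile variant is bounded by the classic maximum", {
  set.seed(21)
  a <- random_binary(c(8, 8, 8), 40)
  b <- random_binary(c(8, 8, 8), 40)
  expect_lte(hausdorff(a, b, percentile = 95), hausdorff(a, b))
})

test_that("adding a shared voxel to both masks never decreases dice", {
  set.seed(17)
  for (i in 1:10) {
    a <- random_binary(c(5, 5, 5), 10)
    b <- random_binary(c(5, 5, 5), 10)
    free <- which(a$voxels == 0L & b$voxels == 0L)
    pick <- sample(free, 1)
    a2 <- a; a2$voxels[pick] <- 1L
    b2 <- b; b2$voxels[pick] <- 1L
    d1 <- dice(a, b); d2 <- dice(a2, b2)
    expect_gte(d2, if (is.nan(d1)) 0 else d1)
  }
})

test_that("metric table covers the full grid and reduces classes by mean", {
  spec <- class_spec(list(1L, 2L, 3L), c("enh", "nec", "ede"))
  dims <- c(6, 6, 6)
  gt <- array(0L, dim = dims)
  gt[1:2, 1, 1] <- 1L; gt[3:4, 1, 1] <- 2L   # class 3 empty everywhere
  m <- seg_mask(gt)
  ens <- case_ensemble("c1", list(a = m, b = m))
  fus <- fuse_cohort(list(ens), spec = spec)
  tab <- metric_table(list(ens), fus, spec)
  expect_equal(nrow(tab$cells), 2 * 3 * 2)      # sources x classes x metrics
  expect_equal(nrow(tab$reduced), 2 * 2)        # sources x metrics
  ident <- tab$cells[tab$cells$class_name == "enh" & tab$cells$source_id == "a", ]
  expect_equal(ident$value[ident$metric == "dice"], 1.0)
  expect_equal(ident$value[ident$metric == "hausdorff"], 0.0)
  # empty class: dice NaN poisons the class-mean dice; hausdorff NaN too
  red <- tab$reduced
  expect_true(is.nan(red$value[red$source_id == "a" & red$metric == "dice"]))
})

test_that("an infinite class value dominates the class-mean reduction", {
  spec <- class_spec(list(1L, 2L), c("x", "y"))
  dims <- c(6, 6, 6)
  gt <- array(0L, dim = dims); gt[1:3, 1, 1] <- 1L
  cand <- gt; cand[5, 5, 5] <- 2L             # candidate has class y, fusion lacks it
  ens <- case_ensemble("c1", list(a = seg_mask(cand), b = seg_mask(gt)))
  fus <- list(c1 = seg_mask(gt))
  tab <- metric_table(list(ens), fus, spec)
  red <- tab$reduced
  expect_identical(red$value[red$source_id == "a" & red$metric == "hausdorff"], Inf)
})

test_that("a glioma-shaped cohort yields 10 reduced cells per case", {
  spec <- class_spec(list(1L, 2L, 4L), c("enh", "nec", "ede"))
  dims <- c(6, 6, 6)
  set.seed(31)
  cands <- lapply(1:5, function(i) {
    v <- array(0L, dim = dims)
    v[1:3, 1:2, 1] <- 1L; v[4, 1:2, 1] <- 2L; v[5, 1:2, 1] <- 4L
    if (i > 1) v[sample(prod(dims), 3)] <- sample(c(1L, 2L, 4L), 3, TRUE)
    seg_mask(v)
  })
  names(cands) <- paste0("alg", 1:5)
  ens <- case_ensemble("c1", cands)
  fus <- fuse_cohort(list(ens), spec = spec)
  tab <- metric_table(list(ens), fus, spec)
  expect_equal(nrow(tab$reduced), 10)  # 5 algorithms x 2 metrics
})

test_that("metric CSV spells non-finite values as inf/nan", {
  cells <- data.frame(case_id = c("c1", "c2", "c3"), source_id = "s",
                      class_name = "fg", metric = "hausdorff",
                      value = c(Inf, NaN, 1.5), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".csv")
  write_metric_table(structure(list(cells = cells,
                                    reduced = NULL, roster = "s",
                                    class_names = "fg", metrics = "hausdorff",
                                    class_reduce = "none"),
                               class = "metric_table"), path)
  txt <- readLines(path)
  expect_true(any(grepl(",inf$", txt)))
  expect_true(any(grepl(",nan$", txt)))
})
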