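make_batch <- function(pm, cells_per_well, n_feat = 3, offsets = NULL, seed = 1) {
  set.seed(seed)
  feats <- sprintf("f%02d", seq_len(n_feat))
  rows <- lapply(seq_len(nrow(pm)), function(i) {
    n <- cells_per_well[[pm$well[i]]]
    if (n == 0) return(NULL)
    off <- if (!is.null(offsets) && pm$well[i] %in% names(offsets)) offsets[[pm$well[i]]] else 0
    m <- matrix(rnorm(n * n_feat), n, n_feat) + off
    d <- data.table::as.data.table(m); data.table::setnames(d, feats)
    cbind(data.table::data.table(plate_id = pm$plate_id[i], well = pm$well[i]), d)
  })
  ct <- cell_table(data.table::rbindlist(rows), pm)
  merge_batch(ct, pm)
}

test_that("well_cell_counts covers mapped wells, zero for empty ones", {
  pm <- tiny_platemap(n_veh = 2, n_treat = 2)
  b <- make_batch(pm, list(A1 = 3, B1 = 5, C1 = 2, D1 = 0))
  n <- well_cell_counts(b)
  expect_equal(nrow(n), 4)
  expect_equal(n[well == "A1", n], 3)
  expect_equal(n[well == "D1", n], 0)
})

test_that("QC filter applies strict count and reduction rules", {
  pm <- tiny_platemap(n_veh = 4, n_treat = 4)
  trt <- pm[pm$role == "test", ]$well
  veh <- pm[pm$role == "vehicle", ]$well

  # vehicle median 200: treated 99 is excluded (low_count), 100 is exactly a
  # 50% reduction and exactly the count threshold -> retained
  b <- make_batch(pm, as.list(c(setNames(rep(200, 4), veh),
                                setNames(c(99, 100, 150, 180), trt))))
  flt <- filter_wells(b)
  expect_equal(flt$exclusions$well, trt[1])
  expect_equal(flt$exclusions$reason, "low_count")
  expect_true(trt[2] %in% flt$batch$platemap$well)

  # vehicle median 1200: 588 cells = 51% reduction (excluded), 600 = exactly
  # 50% (retained)
  b <- make_batch(pm, as.list(c(setNames(rep(1200, 4), veh),
                                setNames(c(1100, 1000, 588, 600), trt))))
  flt <- filter_wells(b)
  expect_equal(flt$exclusions$well, trt[3])
  expect_equal(flt$exclusions$reason, "high_reduction")
  expect_true(trt[4] %in% flt$batch$platemap$well)

  # vehicle wells follow the same rules; losing all of them is fatal
  counts_all_low <- as.list(c(setNames(rep(50, 4), pm[pm$role == "vehicle", ]$well),
                              setNames(rep(1200, 4), trt)))
  b2 <- make_batch(pm, counts_all_low)
  expect_error(filter_wells(b2), "vehicle")
})

test_that("cell-level normalization matches hand-computed median/MAD values", {
  # one vehicle well with feature values {1,2,3,4,5}: med 3, raw MAD 1
  pm <- tiny_platemap(n_veh = 1, n_treat = 1)
  cells <- data.frame(plate_id = "P1", well = c(rep("A1", 5), "B1"),
                      f1 = c(1, 2, 3, 4, 5, 6))
  b <- merge_batch(cell_table(cells, pm), pm)
  nz1 <- normalize_cell_level(b, norm_params(mad_scale_constant = 1))
  expect_equal(nz1$cells$f1, c(-2, -1, 0, 1, 2, 3))       # treated x=6 -> z=3
  nz2 <- normalize_cell_level(b, norm_params(mad_scale_constant = 1.4826))
  expect_equal(nz2$cells[well == "B1", f1], 3 / 1.4826, tolerance = 1e-12)
  expect_equal(nz2$cells$f1[3], 0)                         # x = med -> 0

  # zero-MAD DMSO feature: dropped under the default policy, logged
  cells$f2 <- c(7, 7, 7, 1, 13, 9)   # med 7, raw MAD 0, sd > 0
  b2 <- merge_batch(cell_table(cells, pm), pm)
  expect_message(nz3 <- normalize_cell_level(b2), "zero DMSO MAD")
  expect_equal(nz3$dropped, "f2")
  # fallback_sd substitutes the DMSO cell-level SD where possible
  nz4 <- normalize_cell_level(b2, norm_params(zero_mad_policy = "fallback_sd"))
  expect_equal(nz4$dropped, character(0))
  # but a fully constant feature stays undefined and is dropped either way
  cells$f2 <- 7
  b3 <- merge_batch(cell_table(cells, pm), pm)
  expect_message(
    nz5 <- normalize_cell_level(b3, norm_params(zero_mad_policy = "fallback_sd")),
    "zero DMSO MAD")
  expect_equal(nz5$dropped, "f2")
})

test_that("well aggregation uses the standard median conventions", {
  z <- data.table::data.table(plate_id = "P1",
                              well = c("A1", "A1", "A1", "B1", "B1", "C1"),
                              f1 = c(1, 2, 9, 1, 3, 4))
  m <- aggregate_to_wells(z)
  expect_equal(m[well == "A1", f1], 2)   # odd count
  expect_equal(m[well == "B1", f1], 2)   # even count midpoint
  expect_equal(m[well == "C1", f1], 4)   # single cell
})

test_that("DMSO-SD scaling normalizes vehicle spread to one", {
  pm <- tiny_platemap(n_veh = 2, n_treat = 1)
  wm <- data.table::data.table(plate_id = "P1", well = c("A1", "B1", "C1"),
                               f1 = c(0, 2, 2))
  prof <- scale_by_dmso_sd(wm, pm)
  # DMSO medians {0,2}: sd = sqrt(2) (n-1 denominator); treated 2 -> sqrt(2)
  expect_equal(prof[well == "C1", f1], sqrt(2), tolerance = 1e-12)
  expect_equal(sd(prof[well %in% c("A1", "B1"), f1]), 1, tolerance = 1e-12)

  # identical DMSO medians: feature dropped with a message
  wm$f2 <- c(5, 5, 7)
  expect_message(prof2 <- scale_by_dmso_sd(wm, pm), "zero DMSO well-median SD")
  expect_false("f2" %in% attr(prof2, "features"))

  # fewer than two DMSO wells is an error
  pm1 <- tiny_platemap(n_veh = 1, n_treat = 2)
  expect_error(scale_by_dmso_sd(wm, pm1), "2 retained DMSO")
})

test_that("pipeline profile is invariant to positive affine feature maps", {
  pm <- tiny_platemap(n_veh = 4, n_treat = 4)
  counts <- as.list(setNames(rep(120, 8), pm$well))
  b <- make_batch(pm, counts, n_feat = 3,
                  offsets = list(E1 = 0.5, F1 = 1, G1 = 2, H1 = 3), seed = 9)
  prof1 <- normalize_batch(b)$profile
  b2 <- b
  b2$cells <- data.table::copy(b$cells)
  for (f in b$features) data.table::set(b2$cells, j = f, value = 3.7 * b2$cells[[f]] - 11)
  prof2 <- normalize_batch(b2)$profile
  feats <- attr(prof1, "features")
  expect_equal(as.data.frame(prof1)[, feats], as.data.frame(prof2)[, feats],
               tolerance = 1e-10)
})

test_that("profiles are invariant to cell-row permutations", {
  pm <- tiny_platemap(n_veh = 3, n_treat = 3)
  b <- make_batch(pm, as.list(setNames(rep(50, 6), pm$well)), seed = 3)
  prm <- norm_params(min_cells = 1)
  prof1 <- normalize_batch(b, prm)$profile
  b2 <- b
  set.seed(99)
  b2$cells <- b$cells[sample(.N)]
  data.table::setattr(b2$cells, "features", b$features)
  prof2 <- normalize_batch(b2, prm)$profile
  data.table::setkey(prof1, well); data.table::setkey(prof2, well)
  expect_equal(as.data.frame(prof1), as.data.frame(prof2), tolerance = 1e-12)
})

test_that("identically distributed vehicle and treated wells yield exchangeable profiles", {
  # all wells drawn from the same cell distribution: treated normalized
  # medians should be indistinguishable from vehicle ones
  pm <- tiny_platemap(n_veh = 12, n_treat = 36)
  b <- make_batch(pm, as.list(setNames(rep(200, 48), pm$well)), n_feat = 2, seed = 7)
  prof <- normalize_batch(b)$profile
  v <- prof[role == "vehicle", f01]
  t <- prof[role == "test", f01]
  expect_gt(stats::wilcox.test(v, t)$p.value, 0.01)
  expect_lt(abs(median(t)), 3)  # on the unit-SD normalized scale
})
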