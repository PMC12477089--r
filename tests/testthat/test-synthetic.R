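test_that("plate layout arithmetic yields 96 wells per plate", {
  cfg <- tiny_sim()
  gen <- generate_batch(cfg)
  pm <- gen$platemap
  expect_equal(nrow(pm), 96L)
  expect_equal(sum(pm$role == "vehicle"), 8L)
  expect_equal(sum(pm$role == "negative_control"), 8L)
  expect_equal(sum(pm$role == "cytotoxic_control"), 8L)
  expect_equal(sum(pm$role == "test"), 72L)  # 3 chemicals x 8 conc x 3 replicates
  # each test chemical: 8 concentrations, 3 adjacent replicate columns
  for (ch in unique(pm[role == "test", chemical])) {
    sub <- pm[chemical == ch]
    expect_equal(nrow(sub), 24L)
    expect_equal(length(unique(sub$concentration)), 8L)
    expect_equal(length(unique(sub$column)), 3L)
  }
  # concentrations are half-log spaced from the top
  cc <- sort(unique(pm[chemical == "chem01", concentration]), decreasing = TRUE)
  expect_equal(log10(cc[1] / cc[8]), 3.5, tolerance = 1e-12)
  expect_equal(diff(log10(cc)), rep(-0.5, 7), tolerance = 1e-12)

  # a truth table without 3 test chemicals on a plate is rejected
  bad <- sim_config(plates_per_batch = 2, n_features = 8, n_categories = 4,
                    chemicals = default_chemical_truth(1))
  expect_error(generate_batch(bad), "3 test chemicals")
})

test_that("generation is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_batch_csv(generate_batch(tiny_sim(seed = 77)), d1)
  write_batch_csv(generate_batch(tiny_sim(seed = 77)), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # and a different seed changes the data
  d3 <- withr::local_tempdir()
  write_batch_csv(generate_batch(tiny_sim(seed = 78)), d3)
  expect_false(identical(readLines(file.path(d1, "cells_plate1.csv")),
                         readLines(file.path(d3, "cells_plate1.csv"))))
})

test_that("zero-noise inert wells sit exactly at the vehicle mean", {
  cfg <- tiny_sim(seed = 5, noise = 0, density_beta = 0)
  gen <- generate_batch(cfg)
  inert <- gen$truth[E == 0 & role == "test", chemical]
  wells <- gen$platemap[chemical %in% c(inert, "DMSO"), well]
  cells <- gen$batch$cells[well %in% wells]
  X <- as.matrix(cells[, gen$batch$features, with = FALSE])
  expect_true(all(X == 0))
  # active wells are shifted on their affected features only
  act <- gen$truth[E > 0][1]
  top_wells <- gen$platemap[chemical == act$chemical][concentration == max(concentration), well]
  acells <- as.matrix(gen$batch$cells[well %in% top_wells, gen$batch$features, with = FALSE])
  cats <- as.integer(strsplit(act$affected_categories, ",")[[1]])
  fidx <- which(as.integer(sub("cat", "", gen$catalog$category)) %in% cats)
  expect_true(all(acells[, fidx] > 0))
  expect_true(all(acells[, -fidx] == 0))
})

test_that("generated vehicle wells pass QC and reproduce the count gradient", {
  counts <- data.table::rbindlist(lapply(1:12, function(s) {
    g <- generate_dmso_plate(sim_config(seed = s, n_features = 2, n_categories = 2,
                                        chemicals = default_chemical_truth(1)))
    cbind(g$counts, row = substr(g$counts$well, 1, 1))
  }))
  expect_gte(mean(counts$n >= 100), 0.99)
  row_means <- counts[, .(m = mean(n)), by = row][order(row)]
  expect_equal(cor(seq_len(8), row_means$m, method = "spearman"), -1)
})

test_that("within-category correlation of generated cells matches rho", {
  cfg <- sim_config(seed = 9, n_features = 12, n_categories = 3, rho = 0.5,
                    mean_cells = 1200, density_beta = 0,
                    chemicals = default_chemical_truth(1))
  g <- generate_dmso_plate(cfg)   # ~10^5 vehicle cells
  X <- as.matrix(g$batch$cells[, g$batch$features, with = FALSE])
  cm <- cor(X)
  cat_idx <- rep_len(1:3, 12)
  same <- outer(cat_idx, cat_idx, "==") & upper.tri(cm)
  expect_lt(max(abs(cm[same] - 0.5)), 0.05)
  expect_lt(max(abs(cm[!same & upper.tri(cm)])), 0.05)
})

test_that("oracle BMC is hill-scale equivariant and matches a scalar closed form", {
  # single affected feature, no density coupling, independent features:
  # the geometry reduces to scalars that can be recomputed longhand
  truth <- default_chemical_truth(1)
  truth[chemical == "chem01", `:=`(affected_categories = "1", ac50 = 1, E = 0.8)]
  truth[chemical == "chem02", E := 0]  # single active chemical
  # disable the cytotoxic count reduction so no well is QC-dropped and the
  # expected counts depend on row position only
  truth[chemical == "staurosporine", `:=`(tox_ec50 = NA_real_, tox_h = NA_real_)]
  cfg <- sim_config(seed = 1, plates_per_batch = 1, n_features = 6,
                    n_categories = 6, rho = 0, density_beta = 0,
                    mean_cells = 1200, chemicals = truth)
  ob <- oracle_bmc(cfg)
  got <- ob[chemical == "chem01", oracle_bmc]

  # longhand: sd_f, per-feature signal variance, Satterthwaite null, crossing
  mu_all <- rep(1200 * 0.97^(0:7), 12) # every column spans rows A..H
  mu_veh <- 1200 * 0.97^(0:7)
  sd_f <- sqrt(pi / 2 * mean(1 / mu_veh))
  h <- function(c) c^1.2 / (1^1.2 + c^1.2)
  shifts <- 0.8 * h(rep(100 * 10^(-(0:7) / 2), each = 3)) / sd_f
  sig_var <- var(c(shifts, rep(0, 96 - 24)))
  vbar <- mean(pi / (2 * mu_all) / sd_f^2)
  vveh <- mean(pi / (2 * mu_veh) / sd_f^2)
  S_aff <- sig_var + vbar
  # null distance: 5 unit-ish dims + 1 shrunk dim
  evs <- vveh * c(rep(1 / vbar, 5), 1 / S_aff)
  muD <- sum(evs); varD <- 2 * sum(evs^2)
  a <- varD / (2 * muD); nu <- 2 * muD^2 / varD
  med <- a * qchisq(0.5, nu)
  madf <- uniroot(function(t) pchisq((med + t) / a, nu) -
                    pchisq(max(med - t, 0) / a, nu) - 0.5,
                  c(1e-9, a * qchisq(0.9999, nu)))$root
  thr <- 1.4826 * madf
  r <- sqrt(thr * S_aff) * sd_f / 0.8
  expected <- (r / (1 - r))^(1 / 1.2)  # solve h(c) = r with ac50 = 1
  expect_equal(got, expected, tolerance = 0.02)

  # rescaling the concentration world (AC50 and tested range together) scales
  # the oracle BMC exactly; the distance geometry is unchanged because the
  # Hill shifts at the tested wells are identical
  truth2 <- data.table::copy(truth)
  truth2[chemical == "chem01", `:=`(ac50 = 2, top_conc = 200)]
  cfg2 <- sim_config(seed = 1, plates_per_batch = 1, n_features = 6,
                     n_categories = 6, rho = 0, density_beta = 0,
                     mean_cells = 1200, chemicals = truth2)
  ob2 <- oracle_bmc(cfg2)
  expect_equal(ob2[chemical == "chem01", oracle_bmc] / got, 2, tolerance = 1e-3)

  # implanted-inert chemicals have no crossing
  expect_true(is.na(ob[chemical == "chem03", oracle_bmc]))
  expect_equal(ob[chemical == "chem03", flag], "no_crossing")
})
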