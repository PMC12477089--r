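# Synthetic 96-well Cell Painting batches with implanted ground truth.
#
# Plate layout (one plate): columns 1-3, 4-6, 7-9 hold three test chemicals
# in triplicate (adjacent replicate columns); column 10 an inert
# negative-control series; column 11 a cytotoxic-control series; column 12
# eight solvent (DMSO) wells. Each series has 8 concentrations spaced by a
# half-log unit with the top concentration in row A, descending to row H.
# Well counts decline multiplicatively from row A to H and are drawn from a
# negative binomial; cytotoxicity scales the expected count by a declining
# Hill survival factor. Cell features are category-block equicorrelated
# normals; active chemicals shift the means of their affected features by a
# Hill curve, and a density-morphology coupling shifts all features of a well
# in proportion to the log-ratio of its realized cell count to the nominal
# seeding density.

#' Simulation configuration
#'
#' Defaults state the emulated experiment: four 96-well plates per batch,
#' ~1,200 analyzable cells per vehicle well with a 3% per-row decline from
#' row A to H, 120 features in 49 categories with within-category feature
#' correlation 0.5.
#'
#' @param seed Master seed; a fixed seed yields byte-identical output.
#' @param plates_per_batch Number of plates (each with its own 3 test
#'   chemicals), default 4.
#' @param n_features,n_categories Feature count (default 120, up to 1300) and
#'   category count (default 49; features are assigned round-robin).
#' @param mean_cells Mean analyzable cells in a row-A vehicle well (1,200).
#' @param row_gradient Multiplicative per-row count decline (0.97).
#' @param nb_size Negative-binomial size (dispersion) of well counts.
#' @param rho Within-category feature correlation (0 <= rho < 1).
#' @param noise Cell-level noise SD (1 = the unit in which effect sizes are
#'   stated; 0 gives noise-free feature values).
#' @param density_beta Density-morphology coupling: per-feature mean shift
#'   (in unit-noise SDs) per unit log cell-count ratio to `mean_cells`.
#' @param heavy_tails Use standardized Student-t (5 df) cell noise instead of
#'   normal.
#' @param chemicals Truth table from [default_chemical_truth()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, plates_per_batch = 4L, n_features = 120L,
                       n_categories = 49L, mean_cells = 1200, row_gradient = 0.97,
                       nb_size = 60, rho = 0.5, noise = 1, density_beta = 0.15,
                       heavy_tails = FALSE,
                       chemicals = default_chemical_truth(plates_per_batch)) {
  stopifnot(rho >= 0, rho < 1, n_features >= n_categories, mean_cells > 0,
            row_gradient > 0, row_gradient <= 1, plates_per_batch >= 1)
  structure(list(seed = as.integer(seed), plates_per_batch = as.integer(plates_per_batch),
                 n_features = as.integer(n_features), n_categories = as.integer(n_categories),
                 mean_cells = mean_cells, row_gradient = row_gradient,
                 nb_size = nb_size, rho = rho, noise = noise,
                 density_beta = density_beta, heavy_tails = heavy_tails,
                 chemicals = as.data.table(chemicals)),
            class = "sim_config")
}

#' Default implanted chemical truth
#'
#' Every plate carries one strong active (max shift 1 unit-noise SD on 3
#' categories), one moderate active (0.4 SD on 2 categories) and one inert
#' test chemical, plus the two plate controls: an inert negative control
#' ("sorbitol-like", top 25 uM) and a cytotoxic control
#' ("staurosporine-like", top 0.5 uM, count EC50 0.05 uM) on every plate.
#' Hill steepness is 1.2 throughout; AC50s vary across plates; affected
#' categories are disjoint between chemicals.
#'
#' @param plates_per_batch Number of plates.
#' @return data.table: `chemical, role, plate, E, ac50, hill_h, tox_ec50,
#'   tox_h, top_conc, affected_categories` (comma-separated category indices).
#' @export
default_chemical_truth <- function(plates_per_batch = 4L) {
  strong_ac50 <- c(0.5, 1, 2, 5)
  moderate_ac50 <- c(0.3, 1, 3, 10)
  rows <- list()
  cat_cursor <- 0L
  for (p in seq_len(plates_per_batch)) {
    idx <- 3L * (p - 1L)
    a50s <- strong_ac50[(p - 1L) %% 4L + 1L]
    a50m <- moderate_ac50[(p - 1L) %% 4L + 1L]
    rows[[length(rows) + 1L]] <- data.table(
      chemical = sprintf("chem%02d", idx + 1L), role = "test", plate = p,
      E = 1.0, ac50 = a50s, hill_h = 1.2, tox_ec50 = NA_real_, tox_h = NA_real_,
      top_conc = 100,
      affected_categories = paste(cat_cursor + 1:3, collapse = ","))
    cat_cursor <- cat_cursor + 3L
    rows[[length(rows) + 1L]] <- data.table(
      chemical = sprintf("chem%02d", idx + 2L), role = "test", plate = p,
      E = 0.4, ac50 = a50m, hill_h = 1.2, tox_ec50 = NA_real_, tox_h = NA_real_,
      top_conc = 100,
      affected_categories = paste(cat_cursor + 1:2, collapse = ","))
    cat_cursor <- cat_cursor + 2L
    rows[[length(rows) + 1L]] <- data.table(
      chemical = sprintf("chem%02d", idx + 3L), role = "test", plate = p,
      E = 0, ac50 = NA_real_, hill_h = NA_real_, tox_ec50 = NA_real_,
      tox_h = NA_real_, top_conc = 100, affected_categories = "")
  }
  controls <- data.table(
    chemical = c("sorbitol", "staurosporine"),
    role = c("negative_control", "cytotoxic_control"), plate = NA_integer_,
    E = c(0, 0), ac50 = NA_real_, hill_h = NA_real_,
    tox_ec50 = c(NA_real_, 0.05), tox_h = c(NA_real_, 2),
    top_conc = c(25, 0.5), affected_categories = "")
  rbindlist(c(rows, list(controls)))
}

#' Feature-to-category catalog of a simulation
#' @param config A [sim_config()].
#' @return A [feature_catalog] with features `f0001`.. assigned round-robin
#'   to categories `cat01`..
#' @export
synthetic_catalog <- function(config) {
  f <- sprintf("f%04d", seq_len(config$n_features))
  cat_idx <- rep_len(seq_len(config$n_categories), config$n_features)
  feature_catalog(data.table(feature = f,
                             category = sprintf("cat%02d", cat_idx)))
}

hill_frac <- function(c, ac50, h) c^h / (ac50^h + c^h)

half_log_series <- function(top, n = 8L) top * 10^(-(seq_len(n) - 1L) / 2)

# Expected (pre-noise) layout of one plate: one row per well with chemical,
# concentration, role, row index and expected cell count mu.
synthetic_plate_layout <- function(config, plate) {
  tr <- config$chemicals
  this_plate <- plate
  test3 <- tr[role == "test" & plate == this_plate][order(chemical)]
  if (nrow(test3) != 3L) stop("plate layout arithmetic failed: need 3 test chemicals per plate")
  ctrl <- tr[role %in% c("negative_control", "cytotoxic_control")]
  cols <- list()
  for (k in 1:3) {
    for (repcol in (3L * (k - 1L) + 1L):(3L * k)) {
      cols[[length(cols) + 1L]] <- data.table(
        column = repcol, row = PLATE_ROWS, chemical = test3$chemical[k],
        concentration = half_log_series(test3$top_conc[k]), role = "test")
    }
  }
  cols[[length(cols) + 1L]] <- data.table(
    column = 10L, row = PLATE_ROWS, chemical = ctrl[role == "negative_control", chemical],
    concentration = half_log_series(ctrl[role == "negative_control", top_conc]),
    role = "negative_control")
  cols[[length(cols) + 1L]] <- data.table(
    column = 11L, row = PLATE_ROWS, chemical = ctrl[role == "cytotoxic_control", chemical],
    concentration = half_log_series(ctrl[role == "cytotoxic_control", top_conc]),
    role = "cytotoxic_control")
  cols[[length(cols) + 1L]] <- data.table(
    column = 12L, row = PLATE_ROWS, chemical = "DMSO", concentration = 0,
    role = "vehicle")
  wells <- rbindlist(cols)
  if (nrow(wells) != 96L) stop("plate layout arithmetic did not produce 96 wells")
  wells[, plate_id := sprintf("P%d", plate)]
  wells[, well := well_id(row, column)]
  wells[, row_idx := match(row, PLATE_ROWS)]
  wells <- merge(wells, tr[, .(chemical, tox_ec50, tox_h)], by = "chemical",
                 all.x = TRUE, sort = FALSE)
  wells[, surv := 1]
  wells[!is.na(tox_ec50) & concentration > 0,
        surv := 1 / (1 + (concentration / tox_ec50)^tox_h)]
  wells[, mu := config$mean_cells * config$row_gradient^(row_idx - 1L) * surv]
  setorder(wells, column, row_idx)
  wells[]
}

draw_cell_noise <- function(n, m, heavy_tails) {
  if (heavy_tails) {
    matrix(rt(n * m, df = 5) / sqrt(5 / 3), n, m)
  } else {
    matrix(rnorm(n * m), n, m)
  }
}

# Generate the cell table of one plate. RNG state is the caller's.
generate_plate_cells <- function(config, wells, catalog) {
  F <- config$n_features
  K <- config$n_categories
  n <- rnbinom(nrow(wells), mu = wells$mu, size = config$nb_size)
  shift <- synthetic_well_shifts_mat(config, wells, n, catalog)
  widx <- rep(seq_len(nrow(wells)), n)
  N <- length(widx)
  if (N == 0L) stop("plate generated no cells")
  cat_of_feature <- as.integer(sub("cat", "", catalog$category))
  if (config$noise > 0) {
    Zc <- draw_cell_noise(N, K, config$heavy_tails)
    Zi <- draw_cell_noise(N, F, config$heavy_tails)
    X <- config$noise * (sqrt(config$rho) * Zc[, cat_of_feature, drop = FALSE] +
                           sqrt(1 - config$rho) * Zi)
  } else {
    X <- matrix(0, N, F)
  }
  X <- X + shift[widx, , drop = FALSE]
  dt <- as.data.table(X)
  setnames(dt, catalog$feature)
  dt[, `:=`(plate_id = wells$plate_id[widx], well = wells$well[widx])]
  setcolorder(dt, c("plate_id", "well", catalog$feature))
  setattr(dt, "features", catalog$feature)
  setattr(dt, "class", c("cell_table", class(dt)))
  list(cells = dt, n = n)
}

# shift matrix with density coupling applied per well (rows).
synthetic_well_shifts_mat <- function(config, wells, n, catalog) {
  F <- config$n_features
  tr <- config$chemicals
  shift <- matrix(0, nrow = nrow(wells), ncol = F)
  cat_of_feature <- as.integer(sub("cat", "", catalog$category))
  for (i in seq_len(nrow(tr))) {
    if (tr$E[i] == 0 || tr$affected_categories[i] == "") next
    cats <- as.integer(strsplit(tr$affected_categories[i], ",")[[1]])
    fidx <- which(cat_of_feature %in% cats)
    widx <- which(wells$chemical == tr$chemical[i] & wells$concentration > 0)
    if (!length(widx) || !length(fidx)) next
    amp <- tr$E[i] * hill_frac(wells$concentration[widx], tr$ac50[i], tr$hill_h[i])
    shift[widx, fidx] <- shift[widx, fidx] + amp
  }
  if (config$density_beta != 0) {
    dens <- config$density_beta * log(pmax(n, 1) / config$mean_cells)
    shift <- shift + matrix(dens, nrow(wells), F)
  }
  shift
}

#' Generate a synthetic batch with implanted ground truth
#'
#' @param config A [sim_config()].
#' @return list: `batch` (a merged `batch` over all plates), `tables` (per
#'   plate `cell_table`s), `platemap`, `catalog`, `truth` (the chemical truth
#'   table), `counts` (realized per-well cell counts), `config`.
#' @export
generate_batch <- function(config = sim_config()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  catalog <- synthetic_catalog(config)
  tables <- list()
  maps <- list()
  counts <- list()
  for (p in seq_len(config$plates_per_batch)) {
    wells <- synthetic_plate_layout(config, p)
    gen <- generate_plate_cells(config, wells, catalog)
    tables[[p]] <- gen$cells
    maps[[p]] <- wells[, .(plate_id, row, column, chemical, concentration, role)]
    counts[[p]] <- data.table(plate_id = wells$plate_id, well = wells$well, n = gen$n)
  }
  pm <- platemap(rbindlist(maps))
  b <- merge_batch(tables, pm, batch_id = sprintf("sim_seed%d", config$seed))
  list(batch = b, tables = tables, platemap = pm, catalog = catalog,
       truth = copy(config$chemicals), counts = rbindlist(counts), config = config)
}

#' Generate a DMSO-only 96-well plate
#'
#' All 96 wells are vehicle-treated; the row-wise count gradient, negative
#' binomial count noise and the density-morphology coupling still apply, so
#' cell count and well profiles are coupled the way the background
#' variability study assumes.
#'
#' @param config A [sim_config()] (chemical truth is ignored).
#' @return list `batch`, `catalog`, `counts`, `config`.
#' @export
generate_dmso_plate <- function(config = sim_config()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  catalog <- synthetic_catalog(config)
  wells <- CJ(column = PLATE_COLS, row = PLATE_ROWS)[order(column, match(row, PLATE_ROWS))]
  wells[, `:=`(plate_id = "DMSO1", chemical = "DMSO", concentration = 0,
               role = "vehicle", row_idx = match(row, PLATE_ROWS))]
  wells[, well := well_id(row, column)]
  wells[, mu := config$mean_cells * config$row_gradient^(row_idx - 1L)]
  gen <- generate_plate_cells(config, wells, catalog)
  pm <- platemap(wells[, .(plate_id, row, column, chemical, concentration, role)])
  b <- merge_batch(gen$cells, pm, batch_id = sprintf("dmso_seed%d", config$seed))
  list(batch = b, catalog = catalog,
       counts = data.table(plate_id = wells$plate_id, well = wells$well, n = gen$n),
       config = config)
}

#' Write a generated batch to CSV files plus a truth JSON
#'
#' @param gen Output of [generate_batch()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_batch_csv <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(platemap = file.path(dir, "platemap.csv"),
             catalog = file.path(dir, "feature_catalog.csv"),
             truth = file.path(dir, "truth.json"))
  write_platemap(gen$platemap, paths["platemap"])
  fwrite(gen$catalog, paths["catalog"])
  for (p in seq_along(gen$tables)) {
    f <- file.path(dir, sprintf("cells_plate%d.csv", p))
    write_cell_table(gen$tables[[p]], f)
    paths[sprintf("cells_plate%d", p)] <- f
  }
  jsonlite::write_json(gen$truth, paths["truth"], digits = NA, na = "null")
  invisible(paths)
}
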