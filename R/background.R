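#' Systematic reference-placement normalizations of a DMSO-only plate
#'
#' Emulates the solvent-control-position study: each of the 8 rows and 12
#' columns of a single vehicle-treated 96-well plate is designated in turn as
#' the solvent control (20 localized iterations), plus one whole-plate
#' iteration using every well as the reference ("the mean of the entire plate
#' used as the center"). In each iteration the normalization statistics
#' (cell-level median/MAD and well-median SD) are computed from the
#' designated reference wells only, PCA is refitted on the re-normalized
#' plate, and Mahalanobis distances of all wells are computed from the
#' reference-well centroid. QC filters apply with the usual thresholds; an
#' iteration whose reference set is emptied by QC is skipped with a message.
#'
#' @param plate A `batch` holding one plate whose wells are all
#'   vehicle-treated.
#' @param params [norm_params()].
#' @param var_threshold PCA variance threshold.
#' @return list of iterations; each has `label` (`whole_plate`, `row:A`..,
#'   `column:1`..), `reference` (data.table of reference wells) and
#'   `distances` (a `distance_result` for all retained wells).
#' @export
iterate_reference_normalizations <- function(plate, params = norm_params(),
                                             var_threshold = 0.95) {
  pm <- plate$platemap
  if (length(unique(pm$plate_id)) != 1L) stop("expected a single plate")
  if (!all(pm$role == "vehicle")) stop("expected a DMSO-only plate (all wells vehicle)")
  flt <- filter_wells(plate, params)
  fpm <- flt$batch$platemap
  # raw well medians are iteration-independent (the cell-level median/MAD
  # transform is affine, so it commutes with the per-well median); only the
  # reference statistics change between iterations
  raw_wm <- flt$batch$cells[, lapply(.SD, median), by = .(plate_id, well)]
  labels <- c("whole_plate", paste0("row:", PLATE_ROWS), paste0("column:", PLATE_COLS))
  out <- list()
  for (lab in labels) {
    ref <- switch(substr(lab, 1, 3),
      who = fpm[, .(plate_id, well)],
      "row" = fpm[row == sub("row:", "", lab), .(plate_id, well)],
      col = fpm[column == as.integer(sub("column:", "", lab)), .(plate_id, well)])
    if (nrow(ref) < 2L) {
      message("skipping iteration ", lab, ": reference set emptied by QC")
      next
    }
    # re-normalize with the designated wells as the reference set: mark only
    # those wells as vehicle and rerun the normalization statistics
    pm2 <- copy(fpm)
    pm2[, role := "test"]
    pm2[ref, on = c("plate_id", "well"), role := "vehicle"]
    pm2 <- platemap(pm2)
    b2 <- list(cells = flt$batch$cells, platemap = pm2,
               features = plate$features, batch_id = plate$batch_id)
    class(b2) <- "batch"
    st <- dmso_cell_stats(b2, params)
    if (!length(st$keep)) {
      stop("no features with non-zero reference MAD in iteration ", lab)
    }
    idx <- match(st$keep, plate$features)
    W <- sweep(sweep(as.matrix(raw_wm[, st$keep, with = FALSE]), 2L,
                     st$med[idx]), 2L, st$scale[idx], "/")
    wm <- cbind(raw_wm[, .(plate_id, well)], as.data.table(W))
    setnames(wm, c("plate_id", "well", st$keep))
    prof <- scale_by_dmso_sd(wm, pm2, params)
    space <- fit_pca(prof, var_threshold)
    d <- mahalanobis_distances(space, prof, reference_wells = ref,
                               scope = paste0("reference:", lab))
    out[[lab]] <- list(label = lab, reference = ref, distances = d)
  }
  attr(out, "counts") <- flt$counts
  out
}

regression_summary <- function(d) {
  n <- nrow(d)
  if (var(d$distance) == 0) {
    # exactly constant response: slope 0 and R^2 defined as 0, so the
    # adjusted value is its no-association floor -1/(n-2)
    return(list(slope = 0, intercept = d$distance[1], t_value = 0,
                p_value = 1, adj_r_squared = 1 - (n - 1) / (n - 2),
                r_squared = 0, n = n))
  }
  s <- summary(lm(distance ~ n, data = d))
  co <- s$coefficients
  list(slope = co[2, 1], intercept = co[1, 1], t_value = co[2, 3],
       p_value = co[2, 4], adj_r_squared = s$adj.r.squared,
       r_squared = s$r.squared, n = n)
}

#' OLS regression of Mahalanobis distance on cell count
#'
#' @param distances A `distance_result` (or data.table with `plate_id`,
#'   `well`, `distance`).
#' @param counts data.table `plate_id, well, n` (e.g. from
#'   [well_cell_counts()]).
#' @return list `slope`, `intercept`, `t_value`, `p_value`,
#'   `adj_r_squared`, `r_squared`, `n`.
#' @export
regress_distance_on_count <- function(distances, counts) {
  d <- merge(as.data.table(distances)[, .(plate_id, well, distance)],
             as.data.table(counts)[, .(plate_id, well, n)],
             by = c("plate_id", "well"))
  if (nrow(d) < 3L) stop("need at least 3 wells for regression")
  if (var(d$n) == 0) stop("zero variance in cell counts")
  regression_summary(d)
}

#' Pooled regression over the localized reference iterations
#'
#' Pools the (distance, cell count) pairs of all localized (row and column)
#' iterations — the whole-plate iteration is excluded — and fits one OLS
#' model, reproducing the combined 20-iteration regression of the
#' reference-placement study.
#'
#' @param iterations Output of [iterate_reference_normalizations()].
#' @param counts data.table `plate_id, well, n`.
#' @param include_whole_plate Pool the whole-plate iteration too (default
#'   FALSE).
#' @return As [regress_distance_on_count()].
#' @export
combined_regression <- function(iterations, counts, include_whole_plate = FALSE) {
  labs <- names(iterations)
  if (!include_whole_plate) labs <- setdiff(labs, "whole_plate")
  if (length(labs) < 2L) stop("need at least 2 iterations to pool")
  pooled <- rbindlist(lapply(iterations[labs], function(it) {
    as.data.table(it$distances)[, .(plate_id, well, distance)]
  }))
  d <- merge(pooled, as.data.table(counts)[, .(plate_id, well, n)],
             by = c("plate_id", "well"), allow.cartesian = TRUE)
  if (var(d$n) == 0) stop("zero variance in cell counts")
  regression_summary(d)
}

#' Lay out per-well values as an 8 x 12 plate grid
#'
#' @param values Named numeric vector keyed by well label ("A1".."H12"), or a
#'   data.table with columns `well` and a single value column.
#' @return data.table with column `row` then `1`..`12`; wells without a value
#'   are `NA` (written blank by `fwrite`).
#' @export
plate_heatmap_table <- function(values) {
  if (is.data.frame(values)) {
    dt <- as.data.table(values)
    vcol <- setdiff(names(dt), c("plate_id", "well"))[1]
    values <- setNames(dt[[vcol]], dt$well)
  }
  sw <- split_well(names(values))
  grid <- matrix(NA_real_, nrow = 8, ncol = 12, dimnames = list(PLATE_ROWS, PLATE_COLS))
  grid[cbind(match(sw$row, PLATE_ROWS), sw$column)] <- as.numeric(values)
  out <- data.table(row = PLATE_ROWS)
  out <- cbind(out, as.data.table(grid))
  setnames(out, c("row", as.character(PLATE_COLS)))
  out[]
}

#' Convert a plate grid back to a per-well map
#' @param grid A grid table from [plate_heatmap_table()].
#' @return Named numeric vector keyed by well, omitting blank cells.
#' @export
heatmap_to_map <- function(grid) {
  grid <- as.data.table(grid)
  vals <- unlist(lapply(as.character(PLATE_COLS), function(cc) {
    setNames(grid[[cc]], well_id(grid$row, as.integer(cc)))
  }))
  vals[!is.na(vals)]
}

#' Run the full background-variability study on a DMSO-only plate
#'
#' @param plate A single-plate DMSO-only `batch`.
#' @param params,var_threshold Passed through.
#' @return list: `iterations`, `counts`, `whole_plate` (regression summary),
#'   `localized` (data.table of per-iteration regression summaries),
#'   `pooled` (combined regression over the 20 localized iterations),
#'   `count_grid`, `distance_grid` (whole-plate reference distances).
#' @export
background_variability <- function(plate, params = norm_params(),
                                   var_threshold = 0.95) {
  its <- iterate_reference_normalizations(plate, params, var_threshold)
  counts <- attr(its, "counts")
  wp <- regress_distance_on_count(its[["whole_plate"]]$distances, counts)
  loc_labels <- setdiff(names(its), "whole_plate")
  loc <- rbindlist(lapply(loc_labels, function(lab) {
    r <- regress_distance_on_count(its[[lab]]$distances, counts)
    data.table(label = lab, slope = r$slope, t_value = r$t_value,
               p_value = r$p_value, adj_r_squared = r$adj_r_squared)
  }))
  pooled <- combined_regression(its, counts)
  list(iterations = its, counts = counts, whole_plate = wp, localized = loc,
       pooled = pooled,
       count_grid = plate_heatmap_table(setNames(counts$n, counts$well)),
       distance_grid = plate_heatmap_table(
         setNames(its[["whole_plate"]]$distances$distance,
                  its[["whole_plate"]]$distances$well)))
}
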