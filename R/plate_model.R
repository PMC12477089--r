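#' @import data.table
#' @importFrom stats median sd mad prcomp cov mahalanobis lm pt qt dt rnorm
#'   rnbinom runif optim optimHess uniroot qchisq pchisq quantile setNames
#'   complete.cases coef rt var
#' @importFrom utils head modifyList
NULL

PLATE_ROWS <- LETTERS[1:8]
PLATE_COLS <- 1:12
WELL_ROLES <- c("vehicle", "test", "cytotoxic_control", "negative_control")

#' Well address helpers
#'
#' `well_id()` builds microplate well labels ("A1".."H12") from a row letter
#' and a 1-based column number; `split_well()` is the inverse.
#'
#' @param row Row letters in `A`–`H`.
#' @param column Column numbers in `1`–`12`.
#' @return `well_id()`: character labels. `split_well()`: a `data.table` with
#'   columns `row` and `column`.
#' @examples
#' well_id("A", 1)
#' split_well("H12")
#' @export
well_id <- function(row, column) {
  paste0(row, as.integer(column))
}

#' @rdname well_id
#' @param well Well labels such as "B07" or "B7".
#' @export
split_well <- function(well) {
  row <- toupper(substr(well, 1, 1))
  column <- suppressWarnings(as.integer(substring(well, 2)))
  bad <- !(row %in% PLATE_ROWS) | is.na(column) | !(column %in% PLATE_COLS)
  if (any(bad)) {
    stop("malformed well label(s): ", paste(unique(well[bad]), collapse = ", "))
  }
  data.table(row = row, column = column)
}

#' Construct and validate a plate map
#'
#' A plate map assigns every well of one or more 96-well plates a chemical,
#' a treatment concentration (micromolar) and a role. Roles follow the
#' standard screening layout: `vehicle` (solvent-only wells, DMSO at
#' concentration 0), `test`, `cytotoxic_control` and `negative_control`.
#'
#' @param df A data.frame with columns `plate_id`, `row`, `column`,
#'   `chemical`, `concentration`, `role`.
#' @return A `platemap` (a `data.table` with an additional `well` column).
#' @export
platemap <- function(df) {
  df <- as.data.table(df)
  need <- c("plate_id", "row", "column", "chemical", "concentration", "role")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("plate map missing column(s): ", paste(miss, collapse = ", "))
  df[, plate_id := as.character(plate_id)]
  df[, row := toupper(as.character(row))]
  bad_row <- !df$row %in% PLATE_ROWS
  if (any(bad_row)) stop("invalid row label(s): ", paste(unique(df$row[bad_row]), collapse = ", "))
  df[, column := suppressWarnings(as.integer(column))]
  bad_col <- is.na(df$column) | !df$column %in% PLATE_COLS
  if (any(bad_col)) stop("invalid column number(s) outside 1-12")
  df[, chemical := as.character(chemical)]
  df[, concentration := as.numeric(concentration)]
  if (any(is.na(df$concentration) | df$concentration < 0)) {
    stop("concentration must be a non-negative number")
  }
  df[, role := as.character(role)]
  bad_role <- !df$role %in% WELL_ROLES
  if (any(bad_role)) {
    stop("unknown role token(s): ", paste(unique(df$role[bad_role]), collapse = ", "))
  }
  df[, well := well_id(row, column)]
  dup <- df[duplicated(df, by = c("plate_id", "well"))]
  if (nrow(dup)) {
    stop("duplicate well(s) in plate map: ",
         paste(unique(paste0(dup$plate_id, ":", dup$well)), collapse = ", "))
  }
  setcolorder(df, c("plate_id", "well", "row", "column", "chemical", "concentration", "role"))
  setattr(df, "class", c("platemap", class(df)))
  df[]
}

#' Read a plate map from CSV
#'
#' @param path CSV file with header
#'   `plate_id,row,column,chemical,concentration,role`.
#' @return A validated [platemap].
#' @export
read_platemap <- function(path) {
  if (!file.exists(path)) stop("plate map file not found: ", path)
  platemap(fread(path, colClasses = list(character = "row")))
}

#' Write a plate map to CSV
#' @param pm A [platemap].
#' @param path Output file.
#' @export
write_platemap <- function(pm, path) {
  fwrite(pm[, c("plate_id", "row", "column", "chemical", "concentration", "role")], path)
  invisible(path)
}

feature_names <- function(x) attr(x, "features")

#' Construct a cell-level feature table
#'
#' One row per segmented cell: `plate_id`, `well`, then numeric feature
#' columns. Cells must lie in wells present in the plate map; cells with any
#' missing feature value are dropped (with a message reporting the count),
#' matching the assumption of complete upstream image-analysis exports.
#'
#' @param df data.frame with `plate_id`, `well` and feature columns.
#' @param pm A [platemap] used to cross-reference wells.
#' @return A `cell_table` (data.table) with attribute `features`.
#' @export
cell_table <- function(df, pm) {
  df <- as.data.table(df)
  if (!all(c("plate_id", "well") %in% names(df))) {
    stop("cell table must have plate_id and well columns")
  }
  if (nrow(df) == 0L) stop("no cells in table")
  feats <- setdiff(names(df), c("plate_id", "well"))
  if (length(feats) == 0L) stop("cell table has no feature columns")
  df[, plate_id := as.character(plate_id)]
  df[, well := toupper(as.character(well))]
  # normalize zero-padded labels like "A01"
  sw <- split_well(df$well)
  df[, well := well_id(sw$row, sw$column)]
  known <- pm[, paste0(plate_id, ":", well)]
  key <- df[, paste0(plate_id, ":", well)]
  if (!all(key %in% known)) {
    stop("cell(s) reference unmapped well(s): ",
         paste(head(unique(key[!key %in% known]), 5), collapse = ", "))
  }
  for (f in feats) {
    if (!is.numeric(df[[f]])) {
      v <- suppressWarnings(as.numeric(df[[f]]))
      if (anyNA(v) && !anyNA(df[[f]])) {
        stop("non-numeric feature value in column ", f,
             " at row ", which(is.na(v))[1])
      }
      set(df, j = f, value = v)
    }
  }
  cc <- complete.cases(df[, ..feats])
  if (!all(cc)) {
    message(sum(!cc), " cell(s) with missing feature values dropped at ingest")
    df <- df[cc]
    if (nrow(df) == 0L) stop("no cells left after dropping incomplete rows")
  }
  setcolorder(df, c("plate_id", "well", feats))
  setattr(df, "features", feats)
  setattr(df, "class", c("cell_table", class(df)))
  df[]
}

#' Read a cell-level feature table from CSV
#'
#' @param path Long-format CSV, one row per cell: `plate_id,well,<features...>`.
#' @param pm A [platemap].
#' @return A `cell_table`.
#' @export
read_cell_table <- function(path, pm) {
  if (!file.exists(path)) stop("cell table file not found: ", path)
  df <- fread(path)
  if (nrow(df) == 0L) stop("no cells in file: ", path)
  cell_table(df, pm)
}

#' Write a cell table to CSV
#' @param ct A `cell_table`.
#' @param path Output file.
#' @export
write_cell_table <- function(ct, path) {
  fwrite(ct, path)
  invisible(path)
}

#' Feature-to-category catalog
#'
#' Maps each morphological feature to exactly one of K categories (the
#' conventional grouping of the ~1,300 Cell Painting features into 49
#' categories such as intensity/texture/morphology per compartment).
#'
#' @param df data.frame with columns `feature`, `category`.
#' @return A `feature_catalog` data.table.
#' @export
feature_catalog <- function(df) {
  df <- as.data.table(df)
  if (!all(c("feature", "category") %in% names(df))) {
    stop("catalog must have feature and category columns")
  }
  df[, feature := as.character(feature)]
  df[, category := as.character(category)]
  if (anyDuplicated(df$feature)) {
    stop("catalog maps feature(s) to more than one category: ",
         paste(head(unique(df$feature[duplicated(df$feature)]), 5), collapse = ", "))
  }
  setattr(df, "class", c("feature_catalog", class(df)))
  df[]
}

#' @rdname feature_catalog
#' @param path CSV with header `feature,category`.
#' @export
read_feature_catalog <- function(path) {
  if (!file.exists(path)) stop("feature catalog file not found: ", path)
  feature_catalog(fread(path))
}

#' Merge plates into one analysis batch
#'
#' Raw cell tables of all plates of one experiment are merged and treated as
#' one batch: normalization statistics, PCA and the distance covariance are
#' estimated batch-wide. All plates must share an identical feature set and
#' the batch must contain at least one vehicle well.
#'
#' @param tables A `cell_table` or list of `cell_table`s (one per plate).
#' @param pm A [platemap] covering all plates.
#' @param batch_id Identifier stored with the batch.
#' @return A `batch`: list with elements `cells`, `platemap`, `features`,
#'   `batch_id`.
#' @export
merge_batch <- function(tables, pm, batch_id = "batch") {
  if (inherits(tables, "cell_table")) tables <- list(tables)
  if (!length(tables)) stop("no cell tables to merge")
  featsets <- lapply(tables, feature_names)
  ref <- featsets[[1]]
  for (i in seq_along(featsets)) {
    if (!setequal(featsets[[i]], ref)) {
      stop("mismatched feature sets between plates; difference: ",
           paste(c(setdiff(ref, featsets[[i]]), setdiff(featsets[[i]], ref)),
                 collapse = ", "))
    }
  }
  tables <- lapply(tables, function(t) setcolorder(as.data.table(t), c("plate_id", "well", ref)))
  cells <- rbindlist(tables)
  if (!any(pm$role == "vehicle")) stop("batch plate map has no vehicle well")
  b <- list(cells = cells, platemap = pm, features = ref, batch_id = batch_id)
  class(b) <- "batch"
  b
}

#' @export
print.batch <- function(x, ...) {
  cat(sprintf("<batch '%s'> %d plates, %d mapped wells, %d cells, %d features\n",
              x$batch_id, length(unique(x$platemap$plate_id)), nrow(x$platemap),
              nrow(x$cells), length(x$features)))
  invisible(x)
}
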