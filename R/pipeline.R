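#' Pipeline run configuration
#'
#' Bundles every knob of an end-to-end run. Fully serializable: the resolved
#' configuration is written as JSON next to the outputs of [run_pipeline()].
#'
#' @param platemap_csv,cell_csvs,catalog_csv Input paths (ignored when
#'   `simulate` is a [sim_config()]).
#' @param simulate Optional [sim_config()]; when given, inputs are generated
#'   instead of read.
#' @param out_dir Output directory.
#' @param params [norm_params()].
#' @param var_threshold PCA cumulative-variance threshold (default 0.95).
#' @param squared Distance convention (default squared).
#' @param categorical Also compute per-category distances and fits.
#' @param batch_mode `"experiment"` normalizes all plates together (default);
#'   `"plate"` processes each plate as its own batch (the plate-wise
#'   sensitivity mode).
#' @param models Model family subset, default all ten.
#' @param error_model `"t4"` or `"gaussian"`.
#' @param n_boot Bootstrap resamples for BMC confidence limits.
#' @param seed Master seed; all randomness (simulation, bootstrap) derives
#'   from it.
#' @return A `run_config` list.
#' @export
run_config <- function(platemap_csv = NULL, cell_csvs = NULL, catalog_csv = NULL,
                       simulate = NULL, out_dir = NULL,
                       params = norm_params(), var_threshold = 0.95,
                       squared = TRUE, categorical = FALSE,
                       batch_mode = c("experiment", "plate"),
                       models = cr_model_names(), error_model = "t4",
                       n_boot = 500L, seed = 1L) {
  batch_mode <- match.arg(batch_mode)
  structure(list(platemap_csv = platemap_csv, cell_csvs = cell_csvs,
                 catalog_csv = catalog_csv, simulate = simulate,
                 out_dir = out_dir, params = params,
                 var_threshold = var_threshold, squared = squared,
                 categorical = categorical, batch_mode = batch_mode,
                 models = models, error_model = error_model,
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "run_config")
}

load_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    gen <- generate_batch(config$simulate)
    list(batch = gen$batch, catalog = gen$catalog, truth = gen$truth)
  } else {
    pm <- read_platemap(config$platemap_csv)
    tables <- lapply(config$cell_csvs, read_cell_table, pm = pm)
    catalog <- if (!is.null(config$catalog_csv)) read_feature_catalog(config$catalog_csv)
    list(batch = merge_batch(tables, pm), catalog = catalog, truth = NULL)
  }
}

analyze_batch <- function(batch, config, catalog = NULL) {
  nb <- normalize_batch(batch, config$params)
  space <- fit_pca(nb$profile, config$var_threshold)
  dist_global <- mahalanobis_distances(space, nb$profile, squared = config$squared)
  dists <- list(global = dist_global)
  fits <- list(fit_batch_distances(dist_global,
                                   mad_scale_constant = config$params$mad_scale_constant,
                                   n_boot = config$n_boot, seed = config$seed,
                                   models = config$models,
                                   error_model = config$error_model))
  if (isTRUE(config$categorical)) {
    if (is.null(catalog)) stop("categorical analysis requested but no feature catalog given")
    cd <- categorical_distances(nb$profile, catalog, config$var_threshold,
                                squared = config$squared)
    dists <- c(dists, cd)
    for (d in cd) {
      f <- tryCatch(fit_batch_distances(d,
                                        mad_scale_constant = config$params$mad_scale_constant,
                                        n_boot = config$n_boot, seed = config$seed,
                                        models = config$models,
                                        error_model = config$error_model),
                    error = function(e) NULL)
      if (!is.null(f)) fits[[length(fits) + 1L]] <- f
    }
  }
  list(profile = nb$profile, exclusions = nb$exclusions, counts = nb$counts,
       dropped_features = nb$dropped_features, space = space,
       distances = dists, fits = rbindlist(fits))
}

#' Run the full pipeline end to end
#'
#' simulate/ingest, normalize, reduce, distance, fit, report. Deterministic
#' given the configuration and seed. When `config$out_dir` is set, writes
#' `normalized_profile.csv`, `exclusions.csv`, `distances.csv`, `fits.csv`
#' and `manifest.json` (the serialized configuration, a content hash and
#' per-stage drop counts) per batch.
#'
#' @param config A [run_config()].
#' @return In experiment mode, the result bundle of the batch (list with
#'   `profile`, `exclusions`, `counts`, `space`, `distances`, `fits`,
#'   `truth`); in plate mode, a named list of per-plate bundles.
#' @export
run_pipeline <- function(config) {
  inp <- load_inputs(config)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", what, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  if (config$batch_mode == "plate") {
    plates <- unique(inp$batch$platemap$plate_id)
    res <- lapply(plates, function(p) {
      cells <- inp$batch$cells[plate_id == p]
      setattr(cells, "features", inp$batch$features)
      pm <- platemap(inp$batch$platemap[plate_id == p])
      b <- list(cells = cells, platemap = pm, features = inp$batch$features,
                batch_id = paste0(inp$batch$batch_id, ":", p))
      class(b) <- "batch"
      stage(p, analyze_batch(b, config, inp$catalog))
    })
    names(res) <- plates
    if (!is.null(config$out_dir)) {
      for (p in plates) write_bundle(res[[p]], file.path(config$out_dir, p), config)
    }
    return(invisible(res))
  }
  res <- stage("batch", analyze_batch(inp$batch, config, inp$catalog))
  res$truth <- inp$truth
  if (!is.null(config$out_dir)) write_bundle(res, config$out_dir, config)
  invisible(res)
}

serializable_config <- function(config) {
  cfg <- unclass(config)
  cfg$params <- unclass(cfg$params)
  if (!is.null(cfg$simulate)) {
    cfg$simulate <- unclass(cfg$simulate)
    cfg$simulate$chemicals <- as.data.frame(cfg$simulate$chemicals)
  }
  cfg
}

write_bundle <- function(res, dir, config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_well_profile(res$profile, file.path(dir, "normalized_profile.csv"))
  fwrite(res$exclusions, file.path(dir, "exclusions.csv"))
  write_distances(res$distances, file.path(dir, "distances.csv"))
  fwrite(res$fits, file.path(dir, "fits.csv"))
  cfg <- serializable_config(config)
  manifest <- list(
    config = cfg,
    config_hash = hash_config(cfg),
    n_wells_retained = nrow(res$profile),
    n_wells_excluded = nrow(res$exclusions),
    n_features = length(attr(res$profile, "features")),
    n_features_dropped = length(res$dropped_features),
    pca_components = res$space$k)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, na = "null", pretty = TRUE)
  invisible(dir)
}

# small stable polynomial hash of the serialized config (no extra deps)
hash_config <- function(cfg) {
  s <- as.character(jsonlite::toJSON(cfg, digits = NA, auto_unbox = TRUE, na = "null"))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
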