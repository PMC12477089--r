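# Shared fixture builders. Everything is generated in code; no data files.

# A minimal hand-built plate map: n_treat wells of one chemical at distinct
# concentrations plus n_veh vehicle wells, all on one plate.
tiny_platemap <- function(n_veh = 4, n_treat = 4, plate_id = "P1",
                          chemical = "chemX") {
  stopifnot(n_veh + n_treat <= 96)
  rows <- rep(LETTERS[1:8], times = 12)
  cols <- rep(1:12, each = 8)
  idx <- seq_len(n_veh + n_treat)
  platemap(data.frame(
    plate_id = plate_id, row = rows[idx], column = cols[idx],
    chemical = c(rep("DMSO", n_veh), rep(chemical, n_treat)),
    concentration = c(rep(0, n_veh), 10^seq(0, length.out = n_treat, by = 0.5)),
    role = c(rep("vehicle", n_veh), rep("test", n_treat))))
}

# Deterministic cell table: n_cells per well, n_feat features, standard
# normal noise around per-well offsets (named vector keyed by well).
tiny_cells <- function(pm, n_cells = 20, n_feat = 4, offsets = NULL, seed = 1) {
  set.seed(seed)
  feats <- sprintf("f%02d", seq_len(n_feat))
  rows <- lapply(seq_len(nrow(pm)), function(i) {
    off <- if (!is.null(offsets) && pm$well[i] %in% names(offsets)) {
      offsets[[pm$well[i]]]
    } else 0
    m <- matrix(rnorm(n_cells * n_feat), n_cells, n_feat) + off
    d <- data.table::as.data.table(m)
    data.table::setnames(d, feats)
    cbind(data.table::data.table(plate_id = pm$plate_id[i], well = pm$well[i]), d)
  })
  cell_table(data.table::rbindlist(rows), pm)
}

# Small full-plate simulation config used across tests (fast: ~150 cells/well).
tiny_sim <- function(seed = 1, plates = 1, n_feat = 24, n_cat = 8,
                     mean_cells = 150, ...) {
  sim_config(seed = seed, plates_per_batch = plates, n_features = n_feat,
             n_categories = n_cat, mean_cells = mean_cells,
             chemicals = default_chemical_truth(plates), ...)
}

# Noise-free Hill responses: 8 half-log concentrations in triplicate.
hill_series <- function(tp = 10, ga = 1, p = 2, top = 100, reps = 3) {
  conc <- rep(top * 10^(-(0:7) / 2), each = reps)
  list(conc = conc, resp = tp / (1 + (ga / conc)^p))
}

# Build a well_profile directly from a matrix (bypasses normalization) so the
# distance layer can be tested against closed forms and brute-force oracles.
profile_from_matrix <- function(X, roles = NULL) {
  n <- nrow(X)
  stopifnot(n <= 96)
  if (is.null(roles)) roles <- rep(c("vehicle", "test"), c(min(3, n), max(0, n - 3)))
  rows <- rep(LETTERS[1:8], times = 12)[seq_len(n)]
  cols <- rep(1:12, each = 8)[seq_len(n)]
  prof <- data.table::data.table(
    plate_id = "P1", well = paste0(rows, cols), row = rows, column = cols,
    chemical = ifelse(roles == "vehicle", "DMSO", "chemX"),
    concentration = ifelse(roles == "vehicle", 0, 1), role = roles)
  feats <- sprintf("f%02d", seq_len(ncol(X)))
  for (j in seq_along(feats)) data.table::set(prof, j = feats[j], value = X[, j])
  data.table::setattr(prof, "features", feats)
  data.table::setattr(prof, "class", c("well_profile", class(prof)))
  prof
}

# Brute-force squared Mahalanobis from the raw well x feature matrix.
brute_mahalanobis <- function(X, ref_idx) {
  S <- cov(X)
  mu <- colMeans(X[ref_idx, , drop = FALSE])
  Si <- MASS::ginv(S)
  apply(X, 1, function(r) drop(t(r - mu) %*% Si %*% (r - mu)))
}

# Construct a cr_fit by hand (for closed-form BMC checks).
manual_hill_fit <- function(tp, ga, p, x_range = c(0.01, 100)) {
  structure(list(model = "hill", converged = TRUE,
                 par = list(tp = tp, ga = ga, p = p), sigma = 0.1,
                 loglik = 0, aic = 0, npar = 4, u = NULL,
                 fun = function(par, x) par$tp / (1 + (par$ga / x)^par$p),
                 s_min = 1e-8, error_model = "t4", x_range = x_range),
            class = "cr_fit")
}
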