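profile_matrix <- function(profile) {
  feats <- attr(profile, "features")
  X <- as.matrix(profile[, ..feats])
  rownames(X) <- profile[, paste0(plate_id, ":", well)]
  X
}

#' Fit a PCA space on a normalized well profile
#'
#' Columns are centered and unit-scaled (`prcomp(center = TRUE,
#' scale. = TRUE)`), then the smallest number of leading components whose
#' cumulative variance fraction reaches `var_threshold` is retained.
#' Zero-variance features (scaling undefined) are dropped with a message.
#' Component signs are fixed so each component's largest-magnitude loading is
#' positive; distances are invariant to this, it only stabilizes serialized
#' output.
#'
#' @param profile A `well_profile` from [normalize_batch()].
#' @param var_threshold Cumulative explained-variance fraction to retain
#'   (default 0.95; use 1 to retain all components).
#' @return A `pc_space`: list with `scores` (wells x k), `rotation`, `center`,
#'   `scale`, `sdev` (all components), `k`, `features`, `wells`,
#'   `dropped_features`.
#' @export
fit_pca <- function(profile, var_threshold = 0.95) {
  if (nrow(profile) < 2L) stop("need at least 2 wells for PCA")
  X <- profile_matrix(profile)
  v <- apply(X, 2L, var)
  dropped <- colnames(X)[v == 0]
  if (length(dropped)) {
    message("dropping ", length(dropped), " zero-variance feature(s) before PCA")
    X <- X[, v > 0, drop = FALSE]
  }
  if (ncol(X) < 1L) stop("no features with non-zero variance")
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  # sign convention: largest-|loading| positive
  flip <- apply(pc$rotation, 2L, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2L, flip, "*")
  pc$x <- sweep(pc$x, 2L, flip, "*")
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(varfrac) >= var_threshold - 1e-9)[1]
  if (is.na(k)) k <- length(varfrac)
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 center = pc$center, scale = pc$scale, sdev = pc$sdev,
                 k = k, features = colnames(X),
                 wells = profile[, .(plate_id, well)],
                 dropped_features = dropped),
            class = "pc_space")
}

#' @export
print.pc_space <- function(x, ...) {
  varfrac <- x$sdev^2 / sum(x$sdev^2)
  cat(sprintf("<pc_space> %d wells x %d features; k = %d (%.1f%% variance)\n",
              nrow(x$scores), length(x$features), x$k,
              100 * sum(varfrac[seq_len(x$k)])))
  invisible(x)
}

#' Mahalanobis distances of wells from a reference centroid
#'
#' Distances are computed in the retained PC space: the covariance of the
#' retained scores over all wells of the batch is inverted with the
#' Moore-Penrose generalized inverse (`MASS::ginv`), and the center is the
#' mean score of the reference wells (by default the vehicle wells). The
#' squared-distance convention is used by default, matching
#' `stats::mahalanobis`.
#'
#' @param space A `pc_space` from [fit_pca()].
#' @param profile The `well_profile` the space was fitted on (supplies well
#'   roles for the default reference).
#' @param reference_wells Optional data.frame `plate_id, well` defining the
#'   centroid; default: wells with role `vehicle`.
#' @param squared If `FALSE`, return the square root of the quadratic form.
#' @param scope Label stored with the result (`"global"` or
#'   `"category:<name>"`).
#' @return A `distance_result` data.table: `plate_id, well, chemical,
#'   concentration, role, scope, distance`; attributes `reference`
#'   (data.table of reference wells) and `squared`.
#' @export
mahalanobis_distances <- function(space, profile, reference_wells = NULL,
                                  squared = TRUE, scope = "global") {
  if (is.null(reference_wells)) {
    reference_wells <- profile[role == "vehicle", .(plate_id, well)]
  }
  reference_wells <- as.data.table(reference_wells)[, .(plate_id, well)]
  if (nrow(reference_wells) == 0L) stop("empty reference well set")
  key <- space$wells[, paste0(plate_id, ":", well)]
  ref_idx <- which(key %in% reference_wells[, paste0(plate_id, ":", well)])
  if (!length(ref_idx)) stop("reference wells not found in profile")
  S <- cov(space$scores)
  Sinv <- MASS::ginv(S)
  mu <- colMeans(space$scores[ref_idx, , drop = FALSE])
  d <- mahalanobis(space$scores, mu, Sinv, inverted = TRUE)
  if (!squared) d <- sqrt(pmax(d, 0))
  out <- profile[, .(plate_id, well, chemical, concentration, role)]
  out[, scope := scope]
  out[, distance := d]
  setattr(out, "reference", reference_wells)
  setattr(out, "squared", squared)
  setattr(out, "class", c("distance_result", class(out)))
  out[]
}

#' Per-category PCA and Mahalanobis distances
#'
#' The feature set is split by the catalog into category subsets, and each
#' subset is treated as an independent dataset: PCA is refitted and distances
#' recomputed per category. Categories with no surviving feature are skipped
#' with a message.
#'
#' @param profile A `well_profile`.
#' @param catalog A [feature_catalog] covering the profile's features.
#' @param var_threshold Passed to [fit_pca()].
#' @param reference_wells,squared Passed to [mahalanobis_distances()].
#' @return Named list of `distance_result`s, one per category.
#' @export
categorical_distances <- function(profile, catalog, var_threshold = 0.95,
                                  reference_wells = NULL, squared = TRUE) {
  feats <- attr(profile, "features")
  unmapped <- setdiff(feats, catalog$feature)
  if (length(unmapped)) {
    stop("catalog does not cover feature(s): ", paste(head(unmapped, 5), collapse = ", "))
  }
  cats <- unique(catalog[feature %in% feats, category])
  res <- list()
  for (cc in cats) {
    cf <- intersect(feats, catalog[category == cc, feature])
    if (length(cf) < 1L) {
      message("skipping category with no surviving features: ", cc)
      next
    }
    sub <- profile[, c("plate_id", "well", "row", "column", "chemical",
                       "concentration", "role", cf), with = FALSE]
    setattr(sub, "features", cf)
    setattr(sub, "class", c("well_profile", class(sub)))
    sp <- tryCatch(fit_pca(sub, var_threshold), error = function(e) NULL)
    if (is.null(sp)) {
      message("skipping category (PCA failed): ", cc)
      next
    }
    res[[cc]] <- mahalanobis_distances(sp, sub, reference_wells, squared,
                                       scope = paste0("category:", cc))
  }
  res
}

#' Write distance results to CSV
#' @param results A `distance_result` or list of them.
#' @param path Output file.
#' @export
write_distances <- function(results, path) {
  if (inherits(results, "distance_result")) results <- list(results)
  fwrite(rbindlist(results), path)
  invisible(path)
}
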